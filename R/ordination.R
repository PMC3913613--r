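as_matrix_input <- function(x) {
  if (inherits(x, "count_table")) x$counts
  else if (inherits(x, "abundance_table")) x$abund
  else as.matrix(x)
}

#' Hellinger transformation
#'
#' Square root of per-sample relative abundances:
#' `sqrt(y_ij / y_i.)`. Each transformed row has Euclidean norm 1, so
#' Euclidean distances between transformed rows equal Hellinger distances
#' between the original profiles — down-weighting dominant taxa and making
#' community data compatible with linear ordination (PCA/RDA).
#'
#' @param x counts or relative abundances: matrix, [count_table()] or
#'   [abundance_table()].
#' @return numeric matrix of the same shape.
#' @export
hellinger <- function(x) {
  m <- as_matrix_input(x)
  rs <- rowSums(m)
  if (any(rs <= 0))
    stop("zero-sum row(s): ", paste(rownames(m)[rs <= 0], collapse = ", "))
  sqrt(m / rs)
}

#' Principal component analysis (scaling 1)
#'
#' Column-centres the matrix and takes its singular value decomposition.
#' Eigenvalues are `d_k^2 / (n - 1)`; scaling-1 ("distance") sample
#' scores are `U D / sqrt(n - 1)`, so inter-sample distances in the
#' ordination approximate Euclidean distances of the input.
#'
#' @param x samples x features matrix (or table object).
#' @return An object of class `ordination`: `eigenvalues`, `scores`
#'   (samples x axes), `proportion` of variance per axis, `center`.
#' @export
pca <- function(x) {
  m <- as_matrix_input(x)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 samples")
  ctr <- colMeans(m)
  mc <- sweep(m, 2, ctr)
  sv <- svd(mc)
  tol <- max(sv$d) * 1e-9
  keep <- which(sv$d > tol)
  ev <- sv$d[keep]^2 / (n - 1)
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], length(keep)) /
    sqrt(n - 1)
  dimnames(scores) <- list(rownames(m), paste0("PC", seq_along(keep)))
  structure(list(eigenvalues = ev,
                 scores = scores,
                 proportion = ev / sum(ev),
                 center = ctr), class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  k <- min(5, length(x$eigenvalues))
  cat(sprintf("PCA: %d axes; first %d explain %s\n",
              length(x$eigenvalues), k,
              paste(sprintf("%.1f%%", 100 * x$proportion[1:k]), collapse = ", ")))
  invisible(x)
}

#' Weighted-average species scores
#'
#' Projects species into a sample ordination: the score of species j on
#' axis k is the abundance-weighted mean of the sample scores,
#' `sum_i w_ij s_ik / sum_i w_ij`, placing each species at the centroid of
#' the samples it occurs in.
#'
#' @param abund samples x species abundances (matrix or
#'   [abundance_table()]); samples must match the ordination.
#' @param ord an [pca()] `ordination`.
#' @return species x axes score matrix; species with zero total abundance
#'   are dropped with a warning.
#' @export
weighted_average_scores <- function(abund, ord) {
  w <- as_matrix_input(abund)
  stopifnot(inherits(ord, "ordination"), nrow(w) == nrow(ord$scores))
  if (!is.null(rownames(w)) && !is.null(rownames(ord$scores)) &&
      !identical(rownames(w), rownames(ord$scores)))
    stop("samples of abundance table and ordination do not match")
  tot <- colSums(w)
  if (any(tot == 0)) {
    warning("dropping species with zero total abundance: ",
            paste(colnames(w)[tot == 0], collapse = ", "))
    w <- w[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  scores <- crossprod(w, ord$scores) / tot
  rownames(scores) <- colnames(w)
  scores
}

# Projection helpers on a QR decomposition (empty design -> zero fit).
qfit <- function(qrd, y) if (is.null(qrd)) y * 0 else qr.fitted(qrd, y)
qres <- function(qrd, y) if (is.null(qrd)) y else qr.resid(qrd, y)

# Constrained inertia and pseudo-F for day after conditioning on subject.
rda_core <- function(Yc, day_mat, subj_qr, n, g) {
  m <- ncol(day_mat)
  fit_cond <- qfit(subj_qr, Yc)
  Yr <- Yc - fit_cond
  dayr <- qres(subj_qr, day_mat)
  if (sum(dayr^2) < 1e-12 * max(1, sum(day_mat^2)))
    stop("day is collinear with the subject term")
  fit_day <- qr.fitted(qr(dayr), Yr)
  conditioned <- sum(fit_cond^2) / (n - 1)
  constrained <- sum(fit_day^2) / (n - 1)
  total <- sum(Yc^2) / (n - 1)
  residual <- total - conditioned - constrained
  f <- (constrained / m) / (residual / (n - g - m))
  list(total = total, conditioned = conditioned, constrained = constrained,
       residual = residual, f = f, m = m)
}

make_day_matrix <- function(day, n, day_as_factor) {
  if (day_as_factor) {
    dm <- model.matrix(~factor(day))[, -1, drop = FALSE]
  } else {
    dm <- matrix(as.numeric(day), ncol = 1)
  }
  sweep(dm, 2, colMeans(dm))
}

#' Partial redundancy analysis: community ~ day, conditioned on subject
#'
#' Splits the total inertia (sum of column variances, divisor n - 1) of a
#' Hellinger-transformed community matrix into the fraction explained by
#' inter-subject differences (the conditioning term), the additional
#' fraction explained by sampling day after removing the subject effect
#' (the constrained term), and the residual. The constrained term's
#' semipartial R-squared is reported with the Ezekiel adjustment
#' `1 - (1 - R2) (n - g - 1) / (n - g - 1 - m)`, where g is the number of
#' subject dummy variables and m the day degrees of freedom.
#'
#' @param Y samples x features matrix, typically [hellinger()] output.
#' @param day numeric covariate (biofilm age in days).
#' @param subject grouping factor; `NULL` for an unconditioned analysis.
#' @param day_as_factor treat day as a categorical factor (m = levels - 1)
#'   instead of a single linear trend.
#' @param n_perm if > 0, a within-subject permutation p-value for the day
#'   term is computed via [stratified_permutation_test()].
#' @param seed RNG seed for the permutation test.
#' @return An object of class `rda_partition`: inertias, fractions,
#'   `adj_r2` of the constrained term, `pseudo_f`, dfs, and `p_value`
#'   (`NA` when `n_perm = 0`).
#' @export
partial_rda <- function(Y, day, subject = NULL, day_as_factor = FALSE,
                        n_perm = 0, seed = 1) {
  Y <- as_matrix_input(Y)
  n <- nrow(Y)
  stopifnot(length(day) == n)
  Yc <- sweep(Y, 2, colMeans(Y))
  if (!is.null(subject)) {
    subject <- factor(subject)
    stopifnot(length(subject) == n)
    single_day <- tapply(day, subject, function(d) length(unique(d)) < 2)
    if (any(single_day))
      warning("subject(s) observed at a single day only: ",
              paste(names(single_day)[single_day], collapse = ", "))
    if (nlevels(subject) > 1) {
      Z <- model.matrix(~subject)[, -1, drop = FALSE]
      g <- ncol(Z)
      subj_qr <- qr(sweep(Z, 2, colMeans(Z)))
    } else {
      g <- 0L
      subj_qr <- NULL
    }
  } else {
    g <- 0L
    subj_qr <- NULL
  }
  dm <- make_day_matrix(day, n, day_as_factor)
  core <- rda_core(Yc, dm, subj_qr, n, g)
  r2 <- core$constrained / core$total
  adj_r2 <- 1 - (1 - r2) * (n - g - 1) / (n - g - 1 - core$m)
  p <- NA_real_
  if (n_perm > 0) {
    p <- stratified_permutation_test(Y, day, subject, n_perm = n_perm,
                                     seed = seed,
                                     day_as_factor = day_as_factor)$p_value
  }
  structure(list(total = core$total,
                 conditioned = core$conditioned,
                 constrained = core$constrained,
                 residual = core$residual,
                 fractions = c(conditioned = core$conditioned / core$total,
                               constrained = core$constrained / core$total,
                               residual = core$residual / core$total),
                 adj_r2 = adj_r2, pseudo_f = core$f,
                 df = c(day = core$m, subject = g,
                        residual = n - g - core$m),
                 p_value = p), class = "rda_partition")
}

#' @export
print.rda_partition <- function(x, ...) {
  cat("Partial RDA variance partition\n")
  cat(sprintf("  subject (conditioned): %.1f%%\n", 100 * x$fractions["conditioned"]))
  cat(sprintf("  day (constrained):     %.2f%% (adj R2 %.4f, F %.3f%s)\n",
              100 * x$fractions["constrained"], x$adj_r2, x$pseudo_f,
              if (is.na(x$p_value)) "" else sprintf(", p = %.4g", x$p_value)))
  cat(sprintf("  residual:              %.1f%%\n", 100 * x$fractions["residual"]))
  invisible(x)
}

#' Within-subject permutation test for the day effect in partial RDA
#'
#' Permutes day labels only within each subject (samples never move
#' between subjects), recomputes the pseudo-F of the constrained term for
#' each permutation, and reports
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`.
#'
#' @inheritParams partial_rda
#' @param n_perm number of permutations (>= 1).
#' @param return_perms also return the permutation index matrix (rows =
#'   permutations), used to audit the stratification.
#' @return list: `p_value`, `f_observed`, `f_perm` (vector), and
#'   optionally `perm_index`.
#' @export
stratified_permutation_test <- function(Y, day, subject = NULL, n_perm = 999,
                                        seed = 1, day_as_factor = FALSE,
                                        return_perms = FALSE) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  Y <- as_matrix_input(Y)
  n <- nrow(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  if (!is.null(subject)) {
    subject <- factor(subject)
    if (nlevels(subject) > 1) {
      Z <- model.matrix(~subject)[, -1, drop = FALSE]
      g <- ncol(Z)
      subj_qr <- qr(sweep(Z, 2, colMeans(Z)))
    } else {
      g <- 0L
      subj_qr <- NULL
    }
    strata <- split(seq_len(n), subject)
  } else {
    g <- 0L
    subj_qr <- NULL
    strata <- list(seq_len(n))
  }
  f_obs <- rda_core(Yc, make_day_matrix(day, n, day_as_factor), subj_qr, n, g)$f
  perm_index <- if (return_perms) matrix(NA_integer_, n_perm, n) else NULL
  f_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      idx <- seq_len(n)
      for (s in strata) idx[s] <- s[sample.int(length(s))]
      if (return_perms) perm_index[b, ] <<- idx
      rda_core(Yc, make_day_matrix(day[idx], n, day_as_factor),
               subj_qr, n, g)$f
    }, 0)
  })
  out <- list(p_value = (1 + sum(f_perm >= f_obs)) / (1 + n_perm),
              f_observed = f_obs, f_perm = f_perm, n_perm = n_perm)
  if (return_perms) out$perm_index <- perm_index
  out
}

#' Multivariate dispersion homogeneity test
#'
#' Embeds the distance matrix by principal coordinates, measures each
#' sample's distance to its group centroid in that space, and tests
#' whether mean dispersion differs between groups by the one-way ANOVA F
#' of those distances, with a permutation p-value (group labels permuted,
#' optionally within strata).
#'
#' @param dist a `dist` object or symmetric distance matrix.
#' @param groups factor of group memberships; groups of size 1 are
#'   excluded with a warning.
#' @param n_perm number of permutations.
#' @param strata optional stratification factor for the permutations.
#' @param seed RNG seed.
#' @return list: `p_value`, `f_observed`, per-sample `distances`, group
#'   means.
#' @export
dispersion_test <- function(dist, groups, n_perm = 999, strata = NULL, seed = 1) {
  d <- as.matrix(dist)
  n <- nrow(d)
  groups <- factor(groups)
  stopifnot(length(groups) == n)
  sizes <- table(groups)
  if (any(sizes < 2)) {
    drop_g <- names(sizes)[sizes < 2]
    warning("excluding group(s) of size 1: ", paste(drop_g, collapse = ", "))
    keep <- !(groups %in% drop_g)
    d <- d[keep, keep, drop = FALSE]
    groups <- droplevels(groups[keep])
    if (!is.null(strata)) strata <- strata[keep]
    n <- nrow(d)
  }
  if (nlevels(groups) < 2) stop("need at least 2 groups of size >= 2")
  # principal-coordinate embedding; tiny negative eigenvalues clamped
  G <- -0.5 * d^2
  G <- sweep(G, 1, rowMeans(G))
  G <- sweep(G, 2, colMeans(G))  # = (I - 11'/n) A (I - 11'/n) after both sweeps
  eig <- eigen((G + t(G)) / 2, symmetric = TRUE)
  ev <- eig$values
  ev[ev < 0 & ev > -1e-9 * max(abs(ev), 1)] <- 0
  pos <- ev > 0
  coords <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev[pos]), sum(pos))
  centroid_dist <- function(grp) {
    cen <- rowsum(coords, grp) / as.vector(table(grp))
    sqrt(rowSums((coords - cen[as.integer(grp), , drop = FALSE])^2))
  }
  f_stat <- function(z, grp) {
    gm <- tapply(z, grp, mean)
    ssb <- sum(table(grp) * (gm - mean(z))^2)
    ssw <- sum((z - gm[as.integer(grp)])^2)
    if (ssb < 1e-12 && ssw < 1e-12) return(0)
    dfb <- nlevels(grp) - 1
    dfw <- length(z) - nlevels(grp)
    (ssb / dfb) / (ssw / dfw)
  }
  z_obs <- centroid_dist(groups)
  f_obs <- f_stat(z_obs, groups)
  strata_idx <- if (is.null(strata)) list(seq_len(n)) else split(seq_len(n), strata)
  f_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      idx <- seq_len(n)
      for (s in strata_idx) idx[s] <- s[sample.int(length(s))]
      gp <- groups[idx]
      f_stat(centroid_dist(gp), gp)
    }, 0)
  })
  list(p_value = (1 + sum(f_perm >= f_obs)) / (1 + n_perm),
       f_observed = f_obs, distances = z_obs,
       group_means = tapply(z_obs, groups, mean), n_perm = n_perm)
}
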