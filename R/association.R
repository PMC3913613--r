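#' Spearman rank-correlation distance between species
#'
#' `d(j, j') = 1 - rho(j, j')` with Spearman's rho computed with midranks
#' for ties; ranges over \[0, 2\], 0 on the diagonal. Species with zero
#' variance across samples have undefined correlation; their off-diagonal
#' distances are set to 1 (no information) with a warning.
#'
#' @param abund samples x species matrix (or [abundance_table()]).
#' @return species x species distance matrix.
#' @export
spearman_distance <- function(abund) {
  m <- as_matrix_input(abund)
  if (nrow(m) < 3) stop("need at least 3 samples")
  const <- apply(m, 2, function(x) length(unique(x)) == 1)
  rho <- suppressWarnings(cor(m, method = "spearman"))
  if (any(const)) {
    warning("zero-variance species, distance set to 1: ",
            paste(colnames(m)[const], collapse = ", "))
    rho[const, ] <- 0
    rho[, const] <- 0
  }
  d <- 1 - rho
  diag(d) <- 0
  d
}

# column-wise midranks
rank_columns <- function(m) apply(m, 2, rank, ties.method = "average")

#' RV coefficient between two multivariate data sets
#'
#' Escoufier's RV: a matrix-level generalisation of the squared
#' correlation between two sets of variables measured on the same
#' samples, `trace(X'Y Y'X) / sqrt(trace((X'X)^2) trace((Y'Y)^2))` on
#' column-centred matrices. With `rank = TRUE` (the default), columns are
#' first replaced by midranks, giving a Spearman-flavoured RV suited to
#' skewed abundance data. 0 = no linear association, 1 = one set is a
#' rotation/scaling of the other.
#'
#' @param x,y samples x variables matrices with matching rows.
#' @param rank apply a column-wise midrank transform before centring.
#' @return RV in \[0, 1\].
#' @export
rv_coefficient <- function(x, y, rank = TRUE) {
  x <- as_matrix_input(x); y <- as_matrix_input(y)
  if (nrow(x) != nrow(y)) stop("x and y must have the same samples")
  if (ncol(x) == 0 || ncol(y) == 0) stop("empty matrix")
  if (rank) { x <- rank_columns(x); y <- rank_columns(y) }
  drop_const <- function(m, nm) {
    const <- apply(m, 2, function(v) var(v) == 0)
    if (any(const)) {
      warning("dropping constant column(s) of ", nm)
      m <- m[, !const, drop = FALSE]
      if (ncol(m) == 0) stop("all columns of ", nm, " are constant")
    }
    m
  }
  x <- drop_const(x, "x"); y <- drop_const(y, "y")
  xc <- scale(x, scale = FALSE); yc <- scale(y, scale = FALSE)
  sxy <- crossprod(xc, yc)
  sxx <- crossprod(xc); syy <- crossprod(yc)
  sum(sxy^2) / sqrt(sum(sxx^2) * sum(syy^2))
}

#' Permutation test for the RV coefficient
#'
#' Permutes the rows of `y` (breaking the sample pairing) and reports
#' `p = (1 + #{RV_perm >= RV_obs}) / (1 + n_perm)`.
#'
#' @inheritParams rv_coefficient
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @return list: `rv`, `p_value`, `n_perm`, `rv_perm`.
#' @export
rv_permutation_test <- function(x, y, n_perm = 999, seed = 1, rank = TRUE) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  x <- as_matrix_input(x); y <- as_matrix_input(y)
  rv_obs <- rv_coefficient(x, y, rank = rank)
  rv_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b)
      suppressWarnings(rv_coefficient(x, y[sample.int(nrow(y)), , drop = FALSE],
                                      rank = rank)), 0)
  })
  list(rv = rv_obs,
       p_value = (1 + sum(rv_perm >= rv_obs)) / (1 + n_perm),
       n_perm = n_perm, rv_perm = rv_perm)
}

anosim_r <- function(rank_d, groups_i, within_pair) {
  rb <- mean(rank_d[!within_pair])
  rw <- mean(rank_d[within_pair])
  n <- length(groups_i)
  (rb - rw) / (n * (n - 1) / 4)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of whether between-group dissimilarities exceed
#' within-group dissimilarities. All n(n-1)/2 distances are ranked with
#' midranks; `R = (mean between-rank - mean within-rank) / (n(n-1)/4)`,
#' which lies in \[-1, 1\] with R = 1 at perfect separation and R ~ 0
#' when grouping is unrelated to distance. Significance by unrestricted
#' permutation of group labels.
#'
#' @param dist distance matrix or `dist`.
#' @param groups grouping factor; every group must have >= 2 members.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return An object of class `anosim_result`: `r`, `p_value`, `n_perm`,
#'   group sizes, and the permuted statistics.
#' @export
anosim <- function(dist, groups, n_perm = 999, seed = 1) {
  d <- as_dist_matrix(as.matrix(dist))
  groups <- factor(groups)
  n <- nrow(d)
  stopifnot(length(groups) == n)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group must have size >= 2")
  ut <- upper.tri(d)
  rank_d <- rank(d[ut], ties.method = "average")
  pair_i <- row(d)[ut]; pair_j <- col(d)[ut]
  gi <- as.integer(groups)
  r_obs <- anosim_r(rank_d, gi, gi[pair_i] == gi[pair_j])
  r_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      gp <- gi[sample.int(n)]
      anosim_r(rank_d, gp, gp[pair_i] == gp[pair_j])
    }, 0)
  })
  structure(list(r = r_obs,
                 p_value = (1 + sum(r_perm >= r_obs)) / (1 + n_perm),
                 n_perm = n_perm,
                 group_sizes = table(groups),
                 r_perm = r_perm), class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%d permutations)\n",
              x$r, x$p_value, x$n_perm))
  invisible(x)
}
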