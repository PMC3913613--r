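as_dist_matrix <- function(dist) {
  d <- as.matrix(dist)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8) || any(diag(d) > 1e-8))
    stop("need a symmetric distance matrix with zero diagonal")
  d
}

#' Average-linkage (UPGMA) clustering cut at K groups
#'
#' @param dist symmetric distance matrix (or `dist`) with zero diagonal.
#' @param k number of clusters, 1 <= k <= n.
#' @return integer cluster labels, named by item.
#' @export
average_linkage <- function(dist, k) {
  d <- as_dist_matrix(dist)
  n <- nrow(d)
  if (k > n) stop("k exceeds the number of items")
  if (k == n) return(setNames(seq_len(n), rownames(d)))
  hc <- hclust(as.dist(d), method = "average")
  cutree(hc, k = k)
}

#' Partitioning Around Medoids (k-medoids)
#'
#' Greedy BUILD initialisation followed by steepest-descent SWAP until no
#' medoid exchange reduces the total distance-to-medoid cost;
#' deterministic for a given distance matrix.
#'
#' @inheritParams average_linkage
#' @return list: integer `labels` (named), `medoids` (item indices),
#'   total `cost`.
#' @export
pam_cluster <- function(dist, k) {
  d <- as_dist_matrix(dist)
  n <- nrow(d)
  if (k > n) stop("k exceeds the number of items")
  if (k == n)  # every item its own medoid
    return(list(labels = setNames(seq_len(n), rownames(d)),
                medoids = seq_len(n), cost = 0))
  fit <- cluster::pam(as.dist(d), k = k, diss = TRUE)
  labels <- setNames(as.integer(fit$clustering), rownames(d))
  medoids <- fit$id.med
  cost <- sum(vapply(seq_len(n), function(i) min(d[i, medoids]), 0))
  list(labels = labels, medoids = medoids, cost = cost)
}

#' Area under the consensus CDF
#'
#' The empirical CDF is taken over the n(n-1)/2 upper-triangular consensus
#' entries and integrated exactly over \[0, 1\] (step sum over distinct
#' entry values). A perfectly clean two-block consensus matrix (all
#' entries 0 or 1) has maximal area only when mass sits at 0; a matrix of
#' all ones has area 0 and a matrix of all zeros area 1 — the area grows
#' as pairs are separated.
#'
#' @param m consensus matrix (items x items, values in \[0, 1\]).
#' @return the area, a number in \[0, 1\].
#' @export
consensus_cdf_area <- function(m) {
  x <- m[upper.tri(m)]
  if (!length(x)) stop("consensus matrix has fewer than 2 items")
  v <- sort(unique(x))
  cdf <- vapply(v, function(t) mean(x <= t), 0)
  upper <- c(v[-1], 1)
  sum(cdf * (upper - v))
}

#' Select the number of clusters by the delta-area criterion
#'
#' Relative change in the area under the consensus CDF as K grows:
#' `delta(2) = A(2)`, `delta(K) = (A(K) - A(K-1)) / A(K-1)`. The selected
#' K is the largest one whose relative gain still exceeds `epsilon` — the
#' elbow at which adding clusters stops restructuring the consensus.
#'
#' @param areas numeric vector of A(K) for consecutive K starting at 2.
#' @param epsilon relative-gain cutoff (default 0.1).
#' @return list: selected `k`, the `delta` vector (named by K), `areas`.
#' @export
select_k <- function(areas, epsilon = 0.1) {
  ks <- seq.int(2, length.out = length(areas))
  delta <- numeric(length(areas))
  delta[1] <- areas[1]
  if (length(areas) > 1) {
    for (i in 2:length(areas)) {
      if (areas[i - 1] == 0) {
        warning("A(K-1) = 0; using absolute area as delta for K = ", ks[i])
        delta[i] <- areas[i]
      } else {
        delta[i] <- (areas[i] - areas[i - 1]) / areas[i - 1]
      }
    }
  }
  names(delta) <- names(areas) <- ks
  passing <- ks[delta > epsilon]
  list(k = if (length(passing)) max(passing) else ks[1],
       delta = delta, areas = areas, epsilon = epsilon)
}

#' Item consensus
#'
#' For item i and cluster k, the mean consensus of i with the members of
#' k (excluding i itself): `m_i(k) = sum_{j in k, j != i} M(i,j) /
#' (|k| - [i in k])`. High consensus with the own cluster and low with
#' all others marks a robustly placed item.
#'
#' @param m consensus matrix.
#' @param labels cluster assignment of each item (same order as `m`).
#' @return items x clusters matrix of item-consensus scores; `NA` where
#'   the score is undefined (item in a singleton cluster).
#' @export
item_consensus <- function(m, labels) {
  n <- nrow(m)
  stopifnot(length(labels) == n)
  ks <- sort(unique(labels))
  out <- matrix(NA_real_, n, length(ks),
                dimnames = list(rownames(m), as.character(ks)))
  for (ki in seq_along(ks)) {
    members <- which(labels == ks[ki])
    for (i in seq_len(n)) {
      others <- setdiff(members, i)
      if (length(others) == 0) next  # singleton cluster containing i
      out[i, ki] <- sum(m[i, others]) / length(others)
    }
  }
  out
}

#' Robust cluster members by item-consensus thresholds
#'
#' An item is a robust member of its assigned cluster iff its item
#' consensus is at least `hi` for that cluster and at most `lo` for every
#' other cluster (both boundaries inclusive).
#'
#' @param item_cons items x clusters matrix from [item_consensus()].
#' @param labels cluster assignments.
#' @param hi own-cluster threshold (default 0.6).
#' @param lo other-cluster threshold (default 0.4).
#' @return An object of class `robust_clusters`: `clusters` (list of
#'   member names per cluster), `labels` (robust members only), and
#'   `excluded` (data.frame of item, reason).
#' @export
robust_members <- function(item_cons, labels, hi = 0.6, lo = 0.4) {
  items <- rownames(item_cons)
  if (is.null(items)) items <- as.character(seq_along(labels))
  ks <- colnames(item_cons)
  keep <- logical(length(labels))
  reason <- character(length(labels))
  for (i in seq_along(labels)) {
    own <- as.character(labels[i])
    mi <- item_cons[i, ]
    if (is.na(mi[own])) {
      reason[i] <- "undefined item consensus (singleton cluster)"
    } else if (mi[own] < hi) {
      reason[i] <- sprintf("own-cluster consensus %.3f < %.2f", mi[own], hi)
    } else if (any(mi[setdiff(ks, own)] > lo, na.rm = TRUE)) {
      reason[i] <- sprintf("other-cluster consensus %.3f > %.2f",
                           max(mi[setdiff(ks, own)], na.rm = TRUE), lo)
    } else {
      keep[i] <- TRUE
    }
  }
  robust_labels <- setNames(labels[keep], items[keep])
  structure(list(
    clusters = split(items[keep], labels[keep]),
    labels = robust_labels,
    excluded = data.frame(item = items[!keep], reason = reason[!keep])),
    class = "robust_clusters")
}

#' @export
print.robust_clusters <- function(x, ...) {
  cat(sprintf("robust_clusters: %d clusters, %d members, %d excluded\n",
              length(x$clusters), length(x$labels), nrow(x$excluded)))
  for (k in names(x$clusters))
    cat(sprintf("  cluster %s (%d): %s\n", k, length(x$clusters[[k]]),
                paste(utils::head(x$clusters[[k]], 6), collapse = ", ")))
  invisible(x)
}

#' Consensus clustering over random item subsamples
#'
#' Monti-style consensus clustering: H times, draw `ceiling(p * n)` items
#' without replacement, restrict the distance matrix to them, cluster
#' into K groups, and record which co-sampled pairs co-clustered. The
#' consensus matrix M_K(i, j) is the fraction of co-sampling draws in
#' which i and j landed in the same cluster; the final K-cluster
#' assignment re-clusters 1 - M_K by average linkage. Cluster number is
#' selected by the delta-area criterion over the consensus CDFs, and
#' item-consensus scores support the robustness filter
#' ([robust_members()]).
#'
#' @param dist full item-by-item distance matrix (e.g. 1 - Spearman
#'   correlation of species abundance profiles, or Euclidean distances of
#'   subject PCA scores). Subsampling masks this matrix: for
#'   correlation-based distances computed across all samples, restricting
#'   the item set leaves pairwise correlations unchanged, so masking is
#'   exact.
#' @param method base clusterer: `"average"` (UPGMA) or `"pam"`.
#' @param k_range candidate cluster numbers (subset of 2..n-1).
#' @param H number of subsamples.
#' @param p sampling proportion in (0, 1].
#' @param seed RNG seed.
#' @param epsilon delta-area cutoff passed to [select_k()].
#' @param strict error (instead of recording) if some pair was never
#'   co-sampled.
#' @return An object of class `consensus_run`: per-K consensus matrices
#'   `M`, `areas`, `delta`, selected `k`, per-K `assignments`,
#'   `item_consensus` matrices, the count of never-co-sampled pairs, and
#'   the run parameters.
#' @export
consensus_cluster <- function(dist, method = c("average", "pam"),
                              k_range = 2:6, H = 1000, p = 0.8, seed = 1,
                              epsilon = 0.1, strict = FALSE) {
  method <- match.arg(method)
  d <- as_dist_matrix(dist)
  n <- nrow(d)
  if (is.null(rownames(d))) dimnames(d) <- list(seq_len(n), seq_len(n))
  stopifnot(H >= 1, p > 0, p <= 1)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2 || max(k_range) > n - 1)
    stop("k_range must lie within [2, n - 1]")
  m_sub <- ceiling(p * n)
  cosampled <- matrix(0, n, n)
  coclustered <- lapply(k_range, function(k) matrix(0, n, n))
  names(coclustered) <- k_range
  with_seed(seed, {
    for (h in seq_len(H)) {
      idx <- if (m_sub == n) seq_len(n) else sort(sample.int(n, m_sub))
      cosampled[idx, idx] <- cosampled[idx, idx] + 1
      dsub <- d[idx, idx, drop = FALSE]
      if (method == "average") {
        hc <- hclust(as.dist(dsub), method = "average")
        for (k in k_range) {
          lab <- cutree(hc, k = k)
          for (cl in unique(lab)) {
            ii <- idx[lab == cl]
            coclustered[[as.character(k)]][ii, ii] <-
              coclustered[[as.character(k)]][ii, ii] + 1
          }
        }
      } else {
        for (k in k_range) {
          lab <- pam_cluster(dsub, k)$labels
          for (cl in unique(lab)) {
            ii <- idx[lab == cl]
            coclustered[[as.character(k)]][ii, ii] <-
              coclustered[[as.character(k)]][ii, ii] + 1
          }
        }
      }
    }
  })
  never <- sum(cosampled[upper.tri(cosampled)] == 0)
  if (never > 0 && strict)
    stop(never, " item pair(s) never co-sampled; increase H")
  M <- lapply(coclustered, function(cc) {
    m <- ifelse(cosampled > 0, cc / cosampled, 0)  # never co-sampled -> 0
    diag(m) <- 1
    dimnames(m) <- dimnames(d)
    m
  })
  assignments <- setNames(vector("list", length(k_range)), names(M))
  item_cons <- setNames(vector("list", length(k_range)), names(M))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    assignments[[i]] <- average_linkage(1 - M[[i]], k)
    item_cons[[i]] <- item_consensus(M[[i]], assignments[[i]])
  }
  areas <- vapply(M, consensus_cdf_area, 0)
  sel <- select_k(areas, epsilon = epsilon)
  kc <- as.character(sel$k)
  structure(list(k_range = k_range, M = M, areas = areas,
                 delta = sel$delta, k = sel$k,
                 assignments = assignments, item_consensus = item_cons,
                 labels = assignments[[kc]],
                 never_cosampled = never,
                 method = method, H = H, p = p, seed = seed,
                 epsilon = epsilon),
            class = "consensus_run")
}

#' @export
print.consensus_run <- function(x, ...) {
  cat(sprintf("consensus_run: %s linkage on %d items, H = %d, p = %.2f\n",
              x$method, nrow(x$M[[1]]), x$H, x$p))
  cat("  K:     ", paste(format(x$k_range), collapse = " "), "\n")
  cat("  A(K):  ", paste(sprintf("%.3f", x$areas), collapse = " "), "\n")
  cat("  delta: ", paste(sprintf("%.3f", x$delta), collapse = " "), "\n")
  cat(sprintf("  selected K = %d\n", x$k))
  invisible(x)
}
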