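# Independent reference implementations used only to cross-check package
# results. Deliberately naive and self-contained.

# O(n^3) UPGMA: repeatedly merge the closest pair of clusters, linkage =
# unweighted mean of all cross-cluster original distances. Returns the
# partition at each K as a list (K = n, n-1, ..., 1).
naive_upgma_partitions <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  partitions <- list()
  labels <- seq_len(n)
  partitions[[as.character(n)]] <- labels
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      dij <- mean(d[clusters[[i]], clusters[[j]]])
      if (dij < best_d - 1e-12) { best_d <- dij; best <- c(i, j) }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    labels <- integer(n)
    for (k in seq_along(clusters)) labels[clusters[[k]]] <- k
    partitions[[as.character(length(clusters))]] <- labels
  }
  partitions
}

# exhaustive k-medoids: minimal total distance-to-nearest-medoid cost
exhaustive_pam_cost <- function(d, k) {
  n <- nrow(d)
  subsets <- utils::combn(n, k)
  min(apply(subsets, 2, function(med)
    sum(apply(d[, med, drop = FALSE], 1, min))))
}

# pair-counting adjusted Rand index (independent of the contingency
# formula used by the package)
pair_count_ari <- function(a, b) {
  n <- length(a)
  s_ab <- s_a <- s_b <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
    s_ab <- s_ab + (same_a && same_b)
    s_a <- s_a + same_a
    s_b <- s_b + same_b
  }
  np <- n * (n - 1) / 2
  expected <- s_a * s_b / np
  max_idx <- (s_a + s_b) / 2
  if (max_idx == expected) return(if (s_ab == max_idx) 1 else 0)
  (s_ab - expected) / (max_idx - expected)
}

# partitions equal up to relabeling?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# small labelled count table used across io tests
toy_count_table <- function() {
  counts <- matrix(c(5L, 0L, 1L,
                     2L, 2L, 2L,
                     1L, 3L, 6L,
                     4L, 4L, 2L), 4, 3, byrow = TRUE,
                   dimnames = list(c("Ad01", "Ad03", "Bd01", "Bd03"),
                                   c("Otu001", "Otu002", "Otu003")))
  count_table(counts, data.frame(sample = rownames(counts),
                                 subject = c("A", "A", "B", "B"),
                                 day = c(1, 3, 1, 3)))
}

# direct Hellinger distance between two composition vectors
hellinger_distance_direct <- function(x, y) {
  px <- x / sum(x); py <- y / sum(y)
  sqrt(sum((sqrt(px) - sqrt(py))^2))
}
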