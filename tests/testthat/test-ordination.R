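test_that("Hellinger transform has unit-norm rows and the distance identity", {
  expect_equal(unname(hellinger(matrix(c(1, 1, 2), 1,
                                       dimnames = list("s", NULL)))[1, ]),
               c(0.5, 0.5, sqrt(0.5)), tolerance = 1e-6)
  expect_equal(unname(hellinger(matrix(c(0, 0, 4), 1,
                                       dimnames = list("s", NULL)))[1, ]),
               c(0, 0, 1))
  set.seed(1)
  m <- matrix(rpois(60, 8) + 1, 6, 10,
              dimnames = list(paste0("s", 1:6), paste0("f", 1:10)))
  h <- hellinger(m)
  expect_equal(unname(sqrt(rowSums(h^2))), rep(1, 6), tolerance = 1e-12)
  # Euclidean distance of transformed rows = Hellinger distance of profiles
  expect_equal(as.matrix(dist(h))[1, 2],
               hellinger_distance_direct(m[1, ], m[2, ]), tolerance = 1e-12)
  m[2, ] <- 0
  expect_error(hellinger(m), "s2")
})

test_that("PCA matches an independent eigendecomposition and preserves distance", {
  # worked 3 x 2 example: eigenvalues of the covariance matrix
  m <- matrix(c(0, 0, 1, 0, 0, 2), 3, 2, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("x", "y")))
  ord <- pca(m)
  expect_equal(sort(ord$eigenvalues, decreasing = TRUE),
               sort(eigen(cov(m))$values, decreasing = TRUE), tolerance = 1e-12)
  expect_equal(sum(ord$eigenvalues), sum(diag(cov(m))), tolerance = 1e-12)

  # collinear points load a single axis
  line <- cbind(1:5, 2 * (1:5))
  rownames(line) <- paste0("s", 1:5)
  expect_equal(pca(line)$proportion[1], 1, tolerance = 1e-9)

  # scaling-1 scores reproduce pairwise sample distances on full-rank data
  # (scores carry a global 1/sqrt(n - 1) factor, so distances match after
  # removing it)
  set.seed(2)
  full <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("s", 1:8), NULL))
  ordf <- pca(full)
  d_in <- dist(sweep(full, 2, colMeans(full)))
  d_sc <- dist(ordf$scores) * sqrt(nrow(full) - 1)
  expect_lt(max(abs(d_in - d_sc) / d_in), 1e-9)

  expect_error(pca(full[1, , drop = FALSE]), "2 samples")
})

test_that("weighted-average species scores are abundance-weighted centroids", {
  abund <- matrix(c(1, 0,    # only1: present only in s1
                    1, 1,    # both: equal abundance in the two samples
                    1, 3),   # wt: weights (1, 3)
                  2, 3, dimnames = list(c("s1", "s2"),
                                        c("only1", "both", "wt")))
  ord <- pca(matrix(c(0, 0, 4, 2), 2, 2,
                    dimnames = list(c("s1", "s2"), NULL)))
  sc <- weighted_average_scores(abund, ord)
  # present in exactly one sample -> that sample's score
  expect_equal(unname(sc["only1", ]), unname(ord$scores["s1", ]))
  # equal abundance in both samples -> midpoint
  expect_equal(unname(sc["both", ]), unname(colMeans(ord$scores)))
  # weighted mean with weights (1, 3)
  expect_equal(unname(sc["wt", 1]),
               unname((1 * ord$scores["s1", 1] + 3 * ord$scores["s2", 1]) / 4))
  abund[, 2] <- 0
  expect_warning(weighted_average_scores(abund, ord), "zero total")
})

test_that("partial RDA partitions variance as constructed", {
  set.seed(3)
  n_subj <- 8; days <- c(1, 3, 5, 9, 14)
  subject <- factor(rep(seq_len(n_subj), each = length(days)))
  day <- rep(days, n_subj)
  base <- matrix(rnorm(n_subj * 6, sd = 3), n_subj, 6)
  # community = subject mean + tiny noise, day unrelated
  Y <- base[as.integer(subject), ] + matrix(rnorm(length(subject) * 6, sd = 0.01),
                                            ncol = 6)
  part <- partial_rda(Y, day, subject)
  expect_gt(part$fractions["conditioned"], 0.95)
  expect_lt(part$fractions["constrained"], 0.01)
  expect_equal(unname(sum(part$fractions)), 1, tolerance = 1e-9)

  # Y an exact linear function of day, no conditioning: everything constrained
  Y2 <- outer(day, c(1, -2, 0.5))
  part2 <- partial_rda(Y2, day, subject = NULL)
  expect_equal(unname(part2$fractions["constrained"]), 1, tolerance = 1e-9)

  # single-level subject factor behaves like no conditioning
  part3 <- partial_rda(Y2 + rnorm(length(Y2)), day,
                       factor(rep("only", length(day))))
  expect_equal(unname(part3$fractions["conditioned"]), 0, tolerance = 1e-12)

  # day collinear with subject (each subject sampled on one day) errors,
  # after warning about the confounded design
  subj_conf <- factor(rep(1:5, each = 3))
  day_conf <- rep(days, each = 3)
  expect_error(suppressWarnings(partial_rda(matrix(rnorm(45), 15, 3),
                                            day_conf, subj_conf)),
               "collinear")
})

test_that("partial RDA agrees with vegan's rda on the same model", {
  skip_if_not_installed("vegan")
  set.seed(8)
  n_subj <- 6; days <- c(1, 3, 5, 9)
  subject <- factor(rep(seq_len(n_subj), each = length(days)))
  day <- rep(days, n_subj)
  Y <- matrix(rpois(length(day) * 12, 20), ncol = 12)
  h <- hellinger(Y / rowSums(Y))
  part <- partial_rda(h, day, subject)
  vfit <- vegan::rda(h ~ day + Condition(subject),
                     data = data.frame(day = day, subject = subject))
  expect_equal(part$total, vfit$tot.chi, tolerance = 1e-9)
  expect_equal(part$conditioned, vfit$pCCA$tot.chi, tolerance = 1e-9)
  expect_equal(part$constrained, vfit$CCA$tot.chi, tolerance = 1e-9)
})

test_that("the stratified permutation test shuffles days within subjects only", {
  set.seed(5)
  n_subj <- 6; days <- c(1, 3, 5)
  subject <- factor(rep(seq_len(n_subj), each = 3))
  day <- rep(days, n_subj)
  Y <- matrix(rnorm(18 * 4), 18, 4)
  res <- stratified_permutation_test(Y, day, subject, n_perm = 50, seed = 9,
                                     return_perms = TRUE)
  expect_true(all(res$f_perm >= 0))
  expect_gt(res$p_value, 0); expect_lte(res$p_value, 1)
  # every permutation maps each subject's samples onto themselves
  for (b in seq_len(nrow(res$perm_index)))
    expect_identical(subject[res$perm_index[b, ]], subject)
  # determinism
  res2 <- stratified_permutation_test(Y, day, subject, n_perm = 50, seed = 9)
  expect_identical(res$p_value, res2$p_value)
})

test_that("the stratified test detects a planted day effect", {
  hits <- 0
  for (sd in 1:5) {
    sim <- simulate_dataset(simulation_design(day_effect = 0.3, seed = 300 + sd))
    h <- hellinger(sim$table)
    md <- sim$table$metadata
    p <- stratified_permutation_test(h, md$day, factor(md$subject),
                                     n_perm = 49, seed = sd)$p_value
    hits <- hits + (p <= 0.05)
  }
  expect_gte(hits, 4)
})

test_that("dispersion test finds scale differences and handles degenerate input", {
  set.seed(11)
  # one group's points scaled x3 around its centroid
  a <- matrix(rnorm(20 * 3), 20, 3)
  b <- matrix(rnorm(20 * 3, sd = 3), 20, 3)
  d <- dist(rbind(a, b))
  g <- factor(rep(c("a", "b"), each = 20))
  res <- dispersion_test(d, g, n_perm = 99, seed = 1)
  expect_lte(res$p_value, 0.05)
  expect_gt(res$group_means["b"], res$group_means["a"])

  # identical groups duplicated: F = 0, p = 1
  pts <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), 4, 2, byrow = TRUE)
  dd <- dist(rbind(pts, pts))
  gg <- factor(rep(c("x", "y"), each = 4))
  deg <- dispersion_test(dd, gg, n_perm = 19, seed = 2)
  expect_equal(deg$f_observed, 0)
  expect_equal(deg$p_value, 1)

  # groups of size 1 are excluded with a warning
  expect_warning(dispersion_test(dist(rbind(a, b, 0)),
                                 factor(c(as.character(g), "solo")),
                                 n_perm = 19, seed = 3), "size 1")
})

test_that("dispersion distances match vegan's betadisper", {
  skip_if_not_installed("vegan")
  set.seed(12)
  m <- matrix(rnorm(30), 10, 3)
  g <- factor(rep(1:2, each = 5))
  d <- dist(m)
  ours <- dispersion_test(d, g, n_perm = 9, seed = 1)
  bd <- vegan::betadisper(d, g, type = "centroid")
  expect_equal(unname(ours$distances), unname(bd$distances), tolerance = 1e-8)
})
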