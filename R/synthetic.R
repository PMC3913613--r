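# Dirichlet draw; zero concentrations yield exact zero weights.
rdirichlet1 <- function(alpha) {
  g <- numeric(length(alpha))
  pos <- alpha > 0
  g[pos] <- rgamma(sum(pos), shape = alpha[pos], rate = 1)
  if (sum(g) == 0) stop("degenerate Dirichlet draw: all concentrations zero")
  g / sum(g)
}

#' Simulation design for a planted-cluster oral community
#'
#' Describes a longitudinal 16S-style study: subjects carry one of a few
#' community types, each type mixing a set of mutually exclusive species
#' clusters in type-specific proportions; each sample is an over-dispersed
#' multinomial draw at fixed sequencing depth. Defaults emulate a
#' 31-subject, 5-day design with three community types whose
#' cluster-mixing rows are (0.60, 0.40, 0), (0.32, 0.66, 0.02) and
#' (0.54, 0.20, 0.27), sampled at 1,042 reads per sample with no
#' systematic day effect.
#'
#' @param n_subjects number of subjects.
#' @param days sampling days (biofilm age, days).
#' @param species_per_cluster species count in each planted cluster.
#' @param subject_type_probs prior over community types (simplex).
#' @param mixing_matrix type x cluster weights; rows sum to 1.
#' @param within_cluster_dirichlet concentration of each species'
#'   within-cluster share (flat by default).
#' @param kappa between-subject concentration around the type's mixing
#'   row: larger = subjects of a type more alike.
#' @param overdispersion per-sample Dirichlet concentration tau: larger =
#'   less within-subject (day-to-day) compositional noise.
#' @param depth reads per sample.
#' @param day_effect per-day log-fold change applied to cluster-1 species
#'   (0 = no temporal trend).
#' @param uncultured_fraction fraction of species given names containing
#'   "uncultured", exercising the species name filter.
#' @param seed RNG seed.
#' @return A `simulation_design` list of the above.
#' @export
simulation_design <- function(n_subjects = 31,
                              days = c(1, 3, 5, 9, 14),
                              species_per_cluster = c(12, 10, 8),
                              subject_type_probs = rep(1 / 3, 3),
                              mixing_matrix = rbind(c(0.60, 0.40, 0.00),
                                                    c(0.32, 0.66, 0.02),
                                                    c(0.54, 0.20, 0.27)),
                              within_cluster_dirichlet = 1.0,
                              kappa = 30,
                              overdispersion = 50,
                              depth = 1042,
                              day_effect = 0,
                              uncultured_fraction = 0.10,
                              seed = 1) {
  mixing_matrix <- as.matrix(mixing_matrix)
  stopifnot(n_subjects >= 2, length(days) >= 1, depth >= 1,
            kappa > 0, overdispersion > 0, within_cluster_dirichlet > 0,
            nrow(mixing_matrix) == length(subject_type_probs),
            ncol(mixing_matrix) == length(species_per_cluster))
  rs <- rowSums(mixing_matrix)
  if (any(abs(rs - 1) > 0.02))
    stop("mixing_matrix rows must sum to 1")
  mixing_matrix <- mixing_matrix / rs  # absorb printed-percentage rounding
  if (abs(sum(subject_type_probs) - 1) > 1e-9)
    stop("subject_type_probs must sum to 1")
  structure(list(n_subjects = n_subjects, days = days,
                 species_per_cluster = species_per_cluster,
                 subject_type_probs = subject_type_probs,
                 mixing_matrix = mixing_matrix,
                 within_cluster_dirichlet = within_cluster_dirichlet,
                 kappa = kappa, overdispersion = overdispersion,
                 depth = depth, day_effect = day_effect,
                 uncultured_fraction = uncultured_fraction, seed = seed),
            class = "simulation_design")
}

#' Simulate a species count table with planted cluster structure
#'
#' Generative model: (1) each cluster's internal species shares are one
#' Dirichlet draw per dataset — every species has a characteristic
#' relative abundance, so the species of a cluster rise and fall together
#' across subjects; (2) each subject draws a community type from
#' `subject_type_probs`, and its cluster weights are a
#' Dirichlet(kappa x type mixing row) perturbation of its type's mixing
#' row; (3) each (subject, day) sample draws proportions from
#' Dirichlet(tau x subject profile) — over-dispersion across time points —
#' optionally tilts cluster-1 species by exp(day_effect x day), and draws
#' counts from a multinomial at the design depth. A synthetic full lineage
#' is attached to every species so the real collapse/filter path is
#' exercised; a fraction of species receive "uncultured" names.
#'
#' @param design a [simulation_design()].
#' @return list with `table` (a [count_table()] with metadata), `tax` (a
#'   `taxonomy_map`), and `truth`: planted species clusters
#'   (`species`: feature id, species name, cluster, uncultured flag),
#'   subject types (`subjects`), and realised per-subject cluster weights
#'   (`weights`).
#' @export
simulate_dataset <- function(design = simulation_design()) {
  stopifnot(inherits(design, "simulation_design"))
  with_seed(design$seed, {
    n_clust <- length(design$species_per_cluster)
    n_species <- sum(design$species_per_cluster)
    cluster_of <- rep(seq_len(n_clust), design$species_per_cluster)
    feature_ids <- sprintf("Sp%03d", seq_len(n_species))

    # synthetic binomials; a random fraction gets "uncultured" names
    genus_of <- sprintf("Genus%d", cluster_of * 100 + unlist(lapply(
      design$species_per_cluster, function(k) ((seq_len(k) - 1) %/% 3) + 1)))
    epithet <- sprintf("species%d", seq_len(n_species))
    uncult <- rep(FALSE, n_species)
    n_unc <- round(design$uncultured_fraction * n_species)
    if (n_unc > 0) uncult[sample(n_species, n_unc)] <- TRUE
    species_entry <- ifelse(uncult,
                            sprintf("uncultured_bacterium_%d", seq_len(n_species)),
                            paste(genus_of, epithet, sep = "_"))
    lineage <- lapply(seq_len(n_species), function(j)
      c("Bacteria", sprintf("Phylum%d", cluster_of[j]),
        sprintf("Class%d", cluster_of[j]), sprintf("Order%d", cluster_of[j]),
        sprintf("Family%d", cluster_of[j]), genus_of[j], species_entry[j]))
    names(lineage) <- feature_ids
    tax <- structure(list(lineage = lineage,
                          confidence = setNames(rep(list(rep(NA_real_, 7)),
                                                    n_species), feature_ids)),
                     class = "taxonomy_map")

    # characteristic within-cluster species shares, one draw per dataset
    shares <- numeric(n_species)
    for (cl in seq_len(n_clust)) {
      idx <- which(cluster_of == cl)
      shares[idx] <- rdirichlet1(rep(design$within_cluster_dirichlet, length(idx)))
    }

    subjects <- sprintf("S%02d", seq_len(design$n_subjects))
    types <- sample(length(design$subject_type_probs), design$n_subjects,
                    replace = TRUE, prob = design$subject_type_probs)
    weights <- matrix(0, design$n_subjects, n_clust,
                      dimnames = list(subjects, NULL))
    profiles <- matrix(0, design$n_subjects, n_species,
                       dimnames = list(subjects, feature_ids))
    for (s in seq_len(design$n_subjects)) {
      w <- rdirichlet1(design$kappa * design$mixing_matrix[types[s], ])
      weights[s, ] <- w
      profiles[s, ] <- w[cluster_of] * shares
    }

    n_samp <- design$n_subjects * length(design$days)
    counts <- matrix(0L, n_samp, n_species)
    sample_ids <- character(n_samp)
    md_subject <- character(n_samp)
    md_day <- numeric(n_samp)
    i <- 0L
    for (s in seq_len(design$n_subjects)) {
      for (d in design$days) {
        i <- i + 1L
        q <- rdirichlet1(design$overdispersion * profiles[s, ])
        if (design$day_effect != 0) {
          tilt <- ifelse(cluster_of == 1L, exp(design$day_effect * d), 1)
          q <- q * tilt
          q <- q / sum(q)
        }
        counts[i, ] <- as.integer(rmultinom(1, design$depth, q))
        sample_ids[i] <- sprintf("%sd%02d", subjects[s], d)
        md_subject[i] <- subjects[s]
        md_day[i] <- d
      }
    }
    dimnames(counts) <- list(sample_ids, feature_ids)
    table <- count_table(counts, data.frame(sample = sample_ids,
                                            subject = md_subject,
                                            day = md_day))
    truth <- list(
      species = data.frame(feature_id = feature_ids,
                           species = gsub("_", " ", species_entry),
                           cluster = cluster_of,
                           uncultured = uncult),
      subjects = data.frame(subject = subjects, type = types),
      weights = weights)
    list(table = table, tax = tax, truth = truth, design = design)
  })
}

#' Write a simulated dataset to standard text formats
#'
#' Emits a mothur shared file, a constaxonomy file, a metadata TSV, and a
#' planted-truth TSV into `dir`.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return named character vector of the four paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(shared = file.path(dir, "community.shared"),
             constaxonomy = file.path(dir, "community.cons.taxonomy"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_shared(sim$table, paths["shared"])
  write_constaxonomy(sim$tax, paths["constaxonomy"],
                     sizes = setNames(colSums(sim$table$counts),
                                      colnames(sim$table$counts)))
  utils::write.table(sim$table$metadata, paths["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$species, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items:
#' 1 for identical partitions (up to relabeling), ~0 for independent ones.
#'
#' @param labels_a,labels_b label vectors; if both are named their names
#'   must be the same item set (order-free), otherwise equal length and a
#'   shared order are assumed.
#' @return ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    if (!setequal(names(labels_a), names(labels_b)))
      stop("partitions are over different item sets")
    labels_b <- labels_b[names(labels_a)]
  } else if (length(labels_a) != length(labels_b)) {
    stop("partitions are over different item sets")
  }
  tab <- table(labels_a, labels_b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected)  # degenerate cases: all-singleton / single-cluster
    return(if (sum_ij == max_idx) 1 else 0)
  (sum_ij - expected) / (max_idx - expected)
}
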