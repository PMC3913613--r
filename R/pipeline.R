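#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis. Provide either the
#' three input paths (`shared`, `constaxonomy`, `metadata`) or a
#' [simulation_design()]. Defaults mirror the study protocol the package
#' implements: rarefaction to 1,042 reads, species consensus clustering
#' with 1,000 subsamples at proportion 0.8, subject consensus clustering
#' (PAM) with 10,000 subsamples, 1,000 stratified permutations for the
#' RDA day test, 100,000 ANOSIM permutations, 999 RV permutations.
#'
#' @param shared,constaxonomy,metadata input file paths, or `NULL` when
#'   simulating.
#' @param simulation a [simulation_design()], or `NULL` when reading files.
#' @param depth rarefaction depth.
#' @param exclude_subjects subject ids dropped before any analysis (e.g.
#'   outlying individuals).
#' @param strict_depth drop under-depth samples instead of keeping them.
#' @param renormalize_after_filter rescale species abundances to sum 1
#'   after the species-name filter.
#' @param species_h,species_p,species_k_range consensus-clustering
#'   settings for species (subsample count, sampling proportion, K range).
#' @param subject_h,subject_p,subject_k_range,subject_method consensus
#'   settings for subjects.
#' @param n_axes number of PCA axes fed to subject clustering (`NULL` =
#'   all).
#' @param epsilon delta-area cutoff for selecting K.
#' @param n_perm_rda,n_perm_anosim,n_perm_rv permutation counts.
#' @param day_as_factor treat day as categorical in the RDA.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(shared = NULL, constaxonomy = NULL, metadata = NULL,
                            simulation = NULL,
                            depth = 1042, exclude_subjects = character(),
                            strict_depth = FALSE,
                            renormalize_after_filter = FALSE,
                            species_h = 1000, species_p = 0.8,
                            species_k_range = 2:6,
                            subject_h = 10000, subject_p = 0.8,
                            subject_k_range = 2:6, subject_method = "pam",
                            n_axes = NULL, epsilon = 0.1,
                            n_perm_rda = 1000, n_perm_anosim = 100000,
                            n_perm_rv = 999, day_as_factor = FALSE,
                            seed = 1) {
  if (is.null(simulation) && (is.null(shared) || is.null(constaxonomy) ||
                              is.null(metadata)))
    stop("provide shared + constaxonomy + metadata paths, or a simulation design")
  stopifnot(depth >= 1, species_h >= 1, subject_h >= 1,
            n_perm_rda >= 1, n_perm_anosim >= 1, n_perm_rv >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys are the arguments of [pipeline_config()]; a `simulation`
#' mapping holds [simulation_design()] arguments (`mixing_matrix` as a
#' list of rows).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulation)) {
    sim <- raw$simulation
    if (!is.null(sim$mixing_matrix))
      sim$mixing_matrix <- do.call(rbind, sim$mixing_matrix)
    raw$simulation <- do.call(simulation_design, sim)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full community-analysis pipeline
#'
#' Executes, in order: load (or simulate) inputs; exclude subjects;
#' rarefy; collapse OTUs to species-level relative abundances and apply
#' the species-name filter; (a) alpha diversity and the mixed-effects
#' time model (random-intercept vs random-slope compared by AIC);
#' (b) Hellinger transform and partial RDA (day, conditioned on subject)
#' with a stratified permutation test and a dispersion homogeneity test;
#' (c) species consensus clustering on 1 - Spearman distances, the
#' item-consensus robustness filter, and pairwise RV tests between robust
#' species clusters on rank-transformed subject-mean abundances;
#' (d) subject-mean table, Hellinger, PCA, consensus PAM of subjects, and
#' ANOSIM of the resulting partition; (e) the species-cluster composition
#' of each subject cluster. When the input is simulated, planted-truth
#' recovery (adjusted Rand indices) is reported as well.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `pipeline_report`; see the elements
#'   `diversity`, `mixed_model`, `rda`, `dispersion`, `species_consensus`,
#'   `robust_species`, `rv_pairs`, `subject_consensus`, `anosim`,
#'   `composition`, and (for simulated input) `recovery`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- sapply(c("simulate", "rarefy", "rda", "dispersion",
                    "species_consensus", "subject_consensus", "anosim", "rv"),
                  function(s) derive_seed(config$seed, s))
  truth <- NULL
  inputs <- stage("load", {
    if (!is.null(config$simulation)) {
      design <- config$simulation
      design$seed <- seeds[["simulate"]]
      sim <- simulate_dataset(design)
      truth <- sim$truth
      list(table = sim$table, tax = sim$tax, truth = sim$truth)
    } else {
      tab <- read_shared(config$shared)
      md <- read_metadata(config$metadata)
      list(table = attach_metadata(tab, md),
           tax = read_constaxonomy(config$constaxonomy), truth = NULL)
    }
  })
  table <- inputs$table
  truth <- inputs$truth

  if (length(config$exclude_subjects)) {
    table <- stage("exclude", {
      missing <- setdiff(config$exclude_subjects, table$metadata$subject)
      if (length(missing)) stop("excluded subject(s) not in metadata: ",
                                paste(missing, collapse = ", "))
      keep <- !(table$metadata$subject %in% config$exclude_subjects)
      count_table(table$counts[keep, , drop = FALSE],
                  table$metadata[keep, , drop = FALSE])
    })
  }

  table <- stage("rarefy",
                 rarefy(table, config$depth, seed = seeds[["rarefy"]],
                        strict_depth = config$strict_depth))

  species <- stage("species_table", {
    sp <- collapse_by_rank(table, inputs$tax, "species")
    sp <- filter_species_names(sp, renormalize = config$renormalize_after_filter)
    observed <- colSums(sp$abund) > 0  # never-observed species carry no signal
    structure(list(abund = sp$abund[, observed, drop = FALSE],
                   metadata = sp$metadata, filtered = sp$filtered),
              class = "abundance_table")
  })

  # (a) alpha diversity
  div <- stage("alpha", diversity_records(table))
  mixed <- stage("mixed_model", {
    fit_ri <- suppressWarnings(fit_mixed_model(div, random_slope = FALSE))
    fit_rs <- tryCatch(
      suppressMessages(suppressWarnings(fit_mixed_model(div, random_slope = TRUE))),
      error = function(e) NULL)
    chosen <- if (!is.null(fit_rs) && fit_rs$aic < fit_ri$aic) fit_rs else fit_ri
    list(chosen = chosen,
         aic = c(random_intercept = fit_ri$aic,
                 random_slope = if (is.null(fit_rs)) NA_real_ else fit_rs$aic),
         p_day = chosen$p_day)
  })

  # (b) beta diversity: partial RDA at the OTU level
  hel <- stage("hellinger", hellinger(table))
  rda <- stage("rda",
               partial_rda(hel, table$metadata$day, table$metadata$subject,
                           day_as_factor = config$day_as_factor,
                           n_perm = config$n_perm_rda, seed = seeds[["rda"]]))
  disp <- stage("dispersion",
                dispersion_test(stats::dist(hel), factor(table$metadata$day),
                                n_perm = min(config$n_perm_rda, 999),
                                strata = table$metadata$subject,
                                seed = seeds[["dispersion"]]))

  # (c) species consensus clustering + RV between robust clusters
  spd <- stage("spearman", spearman_distance(species))
  sp_run <- stage("species_consensus",
                  consensus_cluster(spd, method = "average",
                                    k_range = config$species_k_range,
                                    H = config$species_h, p = config$species_p,
                                    seed = seeds[["species_consensus"]],
                                    epsilon = config$epsilon))
  robust <- stage("robust_species",
                  robust_members(sp_run$item_consensus[[as.character(sp_run$k)]],
                                 sp_run$labels))
  subj_means <- stage("subject_means", mean_by_subject(species))
  rv_pairs <- stage("rv", {
    ids <- names(robust$clusters)
    pairs <- if (length(ids) >= 2) utils::combn(ids, 2, simplify = FALSE) else list()
    out <- lapply(seq_along(pairs), function(i) {
      a <- pairs[[i]][1]; b <- pairs[[i]][2]
      res <- rv_permutation_test(
        subj_means$abund[, robust$clusters[[a]], drop = FALSE],
        subj_means$abund[, robust$clusters[[b]], drop = FALSE],
        n_perm = config$n_perm_rv,
        seed = (as.numeric(seeds[["rv"]]) + i) %% 2147483629, rank = TRUE)
      list(clusters = c(a, b), rv = res$rv, p_value = res$p_value)
    })
    names(out) <- vapply(pairs, paste, "", collapse = "-")
    out
  })

  # (d) subject consensus clustering + ANOSIM
  subj_hel <- stage("subject_hellinger", hellinger(subj_means))
  subj_pca <- stage("subject_pca", pca(subj_hel))
  scores <- subj_pca$scores
  if (!is.null(config$n_axes))
    scores <- scores[, seq_len(min(config$n_axes, ncol(scores))), drop = FALSE]
  subj_run <- stage("subject_consensus",
                    consensus_cluster(as.matrix(stats::dist(scores)),
                                      method = config$subject_method,
                                      k_range = config$subject_k_range,
                                      H = config$subject_h, p = config$subject_p,
                                      seed = seeds[["subject_consensus"]],
                                      epsilon = config$epsilon))
  ano <- stage("anosim", {
    grp <- factor(subj_run$labels)
    # ANOSIM is undefined for singleton groups; test the partition on the
    # subjects that form clusters of size >= 2
    sizes <- table(grp)
    if (any(sizes < 2)) {
      warning("excluding singleton subject cluster(s) from ANOSIM: ",
              paste(names(sizes)[sizes < 2], collapse = ", "))
      keep <- grp %in% names(sizes)[sizes >= 2]
      grp <- droplevels(grp[keep])
      if (nlevels(grp) < 2) stop("fewer than 2 non-singleton subject clusters")
      anosim(stats::dist(subj_hel[keep, , drop = FALSE]), grp,
             n_perm = config$n_perm_anosim, seed = seeds[["anosim"]])
    } else {
      anosim(stats::dist(subj_hel), grp,
             n_perm = config$n_perm_anosim, seed = seeds[["anosim"]])
    }
  })

  # (e) composition of subject clusters by species cluster
  comp <- stage("composition",
                composition_by_cluster(subj_means, robust, subj_run$labels))

  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- stage("recovery", {
      truth_sp <- setNames(truth$species$cluster, truth$species$species)
      common <- intersect(names(robust$labels), names(truth_sp))
      truth_subj <- setNames(truth$subjects$type, truth$subjects$subject)
      list(species_ari = adjusted_rand_index(robust$labels[common],
                                             truth_sp[common]),
           subject_ari = adjusted_rand_index(
             subj_run$labels, truth_subj[names(subj_run$labels)]),
           n_species_compared = length(common))
    })
  }

  structure(list(config = config, seeds = seeds,
                 table = table, species = species,
                 diversity = div, mixed_model = mixed,
                 rda = rda, dispersion = disp,
                 species_consensus = sp_run, robust_species = robust,
                 rv_pairs = rv_pairs,
                 subject_pca = subj_pca, subject_consensus = subj_run,
                 anosim = ano, composition = comp,
                 recovery = recovery),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== oralclust pipeline report ==\n")
  cat(sprintf("samples: %d  species retained: %d\n",
              nrow(x$table$counts), ncol(x$species$abund)))
  cat(sprintf("alpha: day p = %.4g (model: %s)\n", x$mixed_model$p_day,
              if (x$mixed_model$chosen$random_slope) "random slope" else "random intercept"))
  cat(sprintf("beta: subject %.1f%%, day %.2f%% (adj R2 %.4f, p = %.4g)\n",
              100 * x$rda$fractions["conditioned"],
              100 * x$rda$fractions["constrained"], x$rda$adj_r2, x$rda$p_value))
  cat(sprintf("species clusters: K = %d (%d robust members)\n",
              x$species_consensus$k, length(x$robust_species$labels)))
  cat(sprintf("subject clusters: K = %d, ANOSIM R = %.3f (p = %.4g)\n",
              x$subject_consensus$k, x$anosim$r, x$anosim$p_value))
  if (!is.null(x$recovery))
    cat(sprintf("recovery: species ARI %.3f, subject ARI %.3f\n",
                x$recovery$species_ari, x$recovery$subject_ari))
  invisible(x)
}

#' Species-cluster composition of subject clusters
#'
#' For each subject, sums the relative abundances of robust species per
#' species cluster; averages these masses over the subjects of each
#' subject cluster; and normalises to fractions over the species
#' clusters. Subjects with zero robust-species mass are excluded with a
#' warning.
#'
#' @param abund subject-mean [abundance_table()] (rows = subjects).
#' @param species_clusters a [robust_members()] `robust_clusters` object.
#' @param subject_clusters named vector of subject cluster labels.
#' @return matrix: subject clusters x species clusters, rows summing to 1.
#' @export
composition_by_cluster <- function(abund, species_clusters, subject_clusters) {
  stopifnot(inherits(abund, "abundance_table"),
            inherits(species_clusters, "robust_clusters"))
  if (!length(species_clusters$clusters)) stop("no species clusters")
  m <- abund$abund
  subjects <- rownames(m)
  if (is.null(names(subject_clusters)))
    names(subject_clusters) <- subjects
  subjects <- intersect(subjects, names(subject_clusters))
  mass <- sapply(species_clusters$clusters, function(members)
    rowSums(m[subjects, intersect(members, colnames(m)), drop = FALSE]))
  mass <- matrix(mass, nrow = length(subjects),
                 dimnames = list(subjects, names(species_clusters$clusters)))
  tot <- rowSums(mass)
  if (any(tot == 0)) {
    warning("excluding subject(s) with zero robust-species mass: ",
            paste(subjects[tot == 0], collapse = ", "))
    mass <- mass[tot > 0, , drop = FALSE]
    subjects <- rownames(mass)
  }
  grp <- factor(subject_clusters[subjects])
  avg <- rowsum(mass, grp) / as.vector(table(grp))
  avg / rowSums(avg)
}
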