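RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a stage seed from a master seed; keeps results < 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629L)
}

#' Construct a sample-by-feature count table
#'
#' The central container of the package: a non-negative integer matrix with
#' samples in rows and OTUs (or taxa) in columns, plus per-sample metadata
#' giving the subject each sample belongs to and the biofilm maturation day
#' on which it was taken.
#'
#' @param counts integer matrix, samples x features, with dimnames.
#' @param metadata `NULL`, or a data.frame with columns `sample`, `subject`,
#'   `day`, one row per sample of `counts` (any order; matched by id).
#' @return An object of class `count_table`: a list with elements `counts`
#'   (integer matrix) and `metadata` (data.frame or `NULL`).
#' @export
count_table <- function(counts, metadata = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample (row) and feature (column) names")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "integer"
  if (!is.null(metadata)) {
    metadata <- validate_metadata(metadata, rownames(counts))
  }
  structure(list(counts = counts, metadata = metadata), class = "count_table")
}

validate_metadata <- function(metadata, sample_ids) {
  metadata <- as.data.frame(metadata)
  need <- c("sample", "subject", "day")
  if (!all(need %in% names(metadata)))
    stop("metadata must have columns sample, subject, day")
  if (anyDuplicated(metadata$sample))
    stop("duplicate sample id in metadata: ",
         paste(unique(metadata$sample[duplicated(metadata$sample)]), collapse = ", "))
  missing <- setdiff(sample_ids, metadata$sample)
  if (length(missing))
    stop("samples missing from metadata: ", paste(missing, collapse = ", "))
  metadata <- metadata[match(sample_ids, metadata$sample), need, drop = FALSE]
  rownames(metadata) <- NULL
  if (anyDuplicated(metadata[c("subject", "day")]))
    stop("duplicate (subject, day) pair in metadata")
  metadata$day <- as.numeric(metadata$day)
  if (any(metadata$day <= 0 | metadata$day != round(metadata$day)))
    stop("day must be a positive integer")
  metadata
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d features\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$metadata))
    cat(sprintf("  %d subjects, days: %s\n",
                length(unique(x$metadata$subject)),
                paste(sort(unique(x$metadata$day)), collapse = ", ")))
  invisible(x)
}

#' Construct a relative-abundance table
#'
#' Same layout as [count_table()] but cells are per-sample fractions. Rows
#' sum to 1 unless features were removed after normalisation, in which case
#' the `filtered` flag records that row sums may fall below 1.
#'
#' @param abund numeric matrix, samples x features, values in \[0, 1\].
#' @param metadata as in [count_table()].
#' @param filtered logical; `TRUE` when features were dropped after the
#'   division by sample totals, so rows are allowed to sum to less than 1.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(abund, metadata = NULL, filtered = FALSE) {
  abund <- as.matrix(abund)
  if (is.null(rownames(abund)) || is.null(colnames(abund)))
    stop("abundances must have sample and feature names")
  if (any(abund < 0) || any(abund > 1 + 1e-9))
    stop("abundances must lie in [0, 1]")
  rs <- rowSums(abund)
  if (!filtered && any(abs(rs - 1) > 1e-9))
    stop("rows must sum to 1 (got ", format(rs[which.max(abs(rs - 1))]), ")")
  if (filtered && any(rs > 1 + 1e-9))
    stop("rows must sum to at most 1")
  if (!is.null(metadata)) metadata <- validate_metadata(metadata, rownames(abund))
  structure(list(abund = abund, metadata = metadata, filtered = filtered),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d features%s\n",
              nrow(x$abund), ncol(x$abund),
              if (x$filtered) " (filtered; rows may sum to < 1)" else ""))
  invisible(x)
}

#' Read a mothur shared-format OTU count table
#'
#' Parses the tab-separated mothur `.shared` dialect: a header line
#' `label Group numOtus Otu001 ...` followed by one row per sample. The
#' `Group` column provides sample ids; `label` (the OTU similarity cutoff)
#' is carried along as an attribute.
#'
#' @param path path to a shared file.
#' @return A [count_table()] without metadata (attach via
#'   [attach_metadata()]).
#' @export
read_shared <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  if (length(header) < 4 || !identical(header[1:3], c("label", "Group", "numOtus")))
    stop("not a shared file: header must start with 'label Group numOtus'")
  otu_ids <- header[-(1:3)]
  n_otus <- length(otu_ids)
  rows <- cells[-1]
  samples <- character(length(rows))
  counts <- matrix(0L, length(rows), n_otus, dimnames = list(NULL, otu_ids))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != n_otus + 3L)
      stop(sprintf("line %d: expected %d fields, found %d", i + 1L,
                   n_otus + 3L, length(r)))
    declared <- suppressWarnings(as.integer(r[3]))
    if (is.na(declared) || declared != n_otus)
      stop(sprintf("line %d: numOtus field (%s) disagrees with %d OTU columns",
                   i + 1L, r[3], n_otus))
    vals <- suppressWarnings(as.numeric(r[-(1:3)]))
    if (anyNA(vals) || any(vals != round(vals)))
      stop(sprintf("line %d: non-integer count", i + 1L))
    samples[i] <- r[2]
    counts[i, ] <- as.integer(vals)
  }
  if (anyDuplicated(samples)) stop("duplicate sample id in shared file")
  rownames(counts) <- samples
  out <- count_table(counts)
  attr(out, "label") <- cells[[1]][1]
  attr(out, "shared_label") <- rows[[1]][1]
  out
}

#' Write a count table in mothur shared format
#'
#' @param table a [count_table()].
#' @param path output path.
#' @param label OTU-definition label written in the first column
#'   (mothur's similarity cutoff, e.g. `"0.03"`).
#' @return `path`, invisibly.
#' @export
write_shared <- function(table, path, label = "0.03") {
  stopifnot(inherits(table, "count_table"))
  m <- table$counts
  header <- paste(c("label", "Group", "numOtus", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(label, rownames(m)[i], ncol(m), m[i, ]), collapse = "\t"), "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a mothur constaxonomy file
#'
#' Parses the `OTU Size Taxonomy` dialect where the lineage is
#' semicolon-separated, deepest rank last, each name optionally carrying a
#' bootstrap confidence in parentheses, e.g.
#' `Bacteria(100);Firmicutes(100);...;Streptococcus(95);`.
#'
#' @param path path to a constaxonomy file.
#' @return An object of class `taxonomy_map`: a list with `lineage` (named
#'   list of character vectors, domain first) and `confidence` (named list
#'   of numeric vectors, `NA` where absent).
#' @export
read_constaxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  if (length(header) < 3 || !("Taxonomy" %in% header))
    stop("not a constaxonomy file: missing Taxonomy column")
  tax_col <- match("Taxonomy", header)
  otu_col <- match("OTU", header)
  rows <- cells[-1]
  otus <- vapply(rows, `[`, "", otu_col)
  if (anyDuplicated(otus))
    stop("duplicate OTU id: ", paste(unique(otus[duplicated(otus)]), collapse = ", "))
  lineage <- vector("list", length(rows))
  confidence <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    tax <- rows[[i]][tax_col]
    parts <- strsplit(sub(";$", "", tax), ";", fixed = TRUE)[[1]]
    conf <- suppressWarnings(as.numeric(sub("^.*\\((\\d+\\.?\\d*)\\)$", "\\1", parts)))
    names <- sub("\\(\\d+\\.?\\d*\\)$", "", parts)
    if (any(!nzchar(names))) stop("empty lineage name for OTU ", otus[i])
    lineage[[i]] <- names
    confidence[[i]] <- conf
  }
  names(lineage) <- names(confidence) <- otus
  structure(list(lineage = lineage, confidence = confidence),
            class = "taxonomy_map")
}

#' Write a taxonomy map in mothur constaxonomy format
#'
#' @param tax a `taxonomy_map`.
#' @param path output path.
#' @param sizes optional named integer vector of per-OTU sequence totals
#'   for the `Size` column (defaults to 1).
#' @return `path`, invisibly.
#' @export
write_constaxonomy <- function(tax, path, sizes = NULL) {
  stopifnot(inherits(tax, "taxonomy_map"))
  otus <- names(tax$lineage)
  if (is.null(sizes)) sizes <- stats::setNames(rep(1L, length(otus)), otus)
  body <- vapply(otus, function(o) {
    conf <- tax$confidence[[o]]
    nm <- tax$lineage[[o]]
    ann <- ifelse(is.na(conf), nm, sprintf("%s(%g)", nm, conf))
    paste(o, sizes[[o]], paste0(paste(ann, collapse = ";"), ";"), sep = "\t")
  }, "")
  writeLines(c("OTU\tSize\tTaxonomy", body), path)
  invisible(path)
}

#' Read per-sample metadata (subject and sampling day)
#'
#' @param path a TSV with columns `sample`, `subject`, `day`.
#' @param expected_days days regarded as usual for this study design;
#'   other values are accepted with a warning.
#' @return data.frame with columns sample, subject, day.
#' @export
read_metadata <- function(path, expected_days = c(1, 3, 5, 9, 14)) {
  if (!file.exists(path)) stop("file not found: ", path)
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", comment.char = "#")
  need <- c("sample", "subject", "day")
  if (!all(need %in% names(md)))
    stop("metadata must have columns sample, subject, day")
  if (anyDuplicated(md$sample))
    stop("duplicate sample id in metadata: ",
         paste(unique(md$sample[duplicated(md$sample)]), collapse = ", "))
  md$day <- as.numeric(md$day)
  odd <- setdiff(unique(md$day), expected_days)
  if (length(odd))
    warning("unexpected day values: ", paste(odd, collapse = ", "))
  md[need]
}

#' Attach sample metadata to a count table
#'
#' @param table a [count_table()].
#' @param metadata data.frame with columns sample, subject, day covering
#'   every sample of `table` (extra rows are dropped).
#' @return the table with metadata attached, samples in table order.
#' @export
attach_metadata <- function(table, metadata) {
  stopifnot(inherits(table, "count_table"))
  count_table(table$counts, metadata)
}

#' Rarefy a count table to a common depth
#'
#' Each sample whose total is at least `depth` is replaced by a
#' without-replacement draw of exactly `depth` reads (multivariate
#' hypergeometric), removing unequal-sampling-effort bias. Samples below
#' `depth` are kept unchanged and flagged in the `under_depth` attribute,
#' so that low-coverage samples are retained (with reservation) rather
#' than silently lost; set `strict_depth = TRUE` to drop them instead.
#'
#' @param table a [count_table()].
#' @param depth target reads per sample (default 1042).
#' @param seed RNG seed.
#' @param strict_depth drop under-depth samples instead of keeping them.
#' @return A rarefied [count_table()]; attribute `under_depth` names the
#'   samples left unrarefied (or dropped).
#' @export
rarefy <- function(table, depth = 1042, seed = 1, strict_depth = FALSE) {
  stopifnot(inherits(table, "count_table"), depth >= 1)
  m <- table$counts
  totals <- rowSums(m)
  under <- rownames(m)[totals < depth]
  if (length(under))
    warning("samples below depth ", depth, " kept unchanged: ",
            paste(under, collapse = ", "))
  out <- with_seed(seed, {
    res <- m
    for (i in seq_len(nrow(m))) {
      if (totals[i] < depth) next
      if (totals[i] == depth) next
      reads <- rep.int(seq_len(ncol(m)), m[i, ])
      keep <- sample(reads, depth, replace = FALSE)
      res[i, ] <- tabulate(keep, nbins = ncol(m))
    }
    res
  })
  if (strict_depth && length(under)) out <- out[setdiff(rownames(out), under), , drop = FALSE]
  md <- table$metadata
  if (!is.null(md)) md <- md[md$sample %in% rownames(out), , drop = FALSE]
  res <- count_table(out, md)
  attr(res, "under_depth") <- under
  res
}

# Name of `otu` at `rank`; unresolved lineages become
# "<deepest name> unclassified" so the downstream name filter can act on
# them. Underscores in taxon names are normalised to spaces.
rank_name <- function(tax, otu, rank_idx) {
  lin <- tax$lineage[[otu]]
  if (is.null(lin)) stop("feature missing from taxonomy: ", otu)
  nm <- if (length(lin) >= rank_idx) lin[rank_idx]
        else paste(lin[length(lin)], "unclassified")
  gsub("_", " ", nm)
}

#' Collapse a count table to taxon-level relative abundances
#'
#' Counts are summed over OTUs sharing the same name at the requested rank
#' and divided by the per-sample total (taken before any dropping), so
#' that rows sum to 1. OTUs whose lineage does not reach the requested
#' rank are assigned the name `"<deepest resolved name> unclassified"`,
#' which the species name filter later removes.
#'
#' @param table a [count_table()].
#' @param tax a `taxonomy_map` covering every feature of `table`.
#' @param rank one of "domain", "phylum", "class", "order", "family",
#'   "genus", "species".
#' @return An [abundance_table()] at the requested rank.
#' @export
collapse_by_rank <- function(table, tax, rank = "species") {
  stopifnot(inherits(table, "count_table"), inherits(tax, "taxonomy_map"))
  rank_idx <- match(match.arg(rank, RANKS), RANKS)
  m <- table$counts
  missing <- setdiff(colnames(m), names(tax$lineage))
  if (length(missing))
    stop("features missing from taxonomy: ", paste(missing, collapse = ", "))
  names_at <- vapply(colnames(m), function(o) rank_name(tax, o, rank_idx), "")
  groups <- factor(names_at, levels = unique(names_at))
  collapsed <- t(rowsum(t(m), groups))
  totals <- rowSums(m)
  if (any(totals == 0)) stop("zero-total sample: ",
                             paste(rownames(m)[totals == 0], collapse = ", "))
  abund <- collapsed / totals
  abundance_table(abund, table$metadata)
}

#' Drop taxa not resolved to species level
#'
#' Removes features whose name contains "uncultured" or "unclassified"
#' (case-insensitive substring match) — the names given to taxa that could
#' not be distinguished at species level. Remaining abundances keep their
#' original denominators by default, preserving comparability of the
#' retained fractions across samples; set `renormalize = TRUE` to rescale
#' each row back to sum 1.
#'
#' @param table species-level [abundance_table()].
#' @param renormalize rescale rows to sum 1 after dropping (default FALSE).
#' @return A filtered [abundance_table()].
#' @export
filter_species_names <- function(table, renormalize = FALSE) {
  stopifnot(inherits(table, "abundance_table"))
  nm <- colnames(table$abund)
  bad <- grepl("uncultured", nm, ignore.case = TRUE) |
         grepl("unclassified", nm, ignore.case = TRUE)
  if (all(bad)) stop("no species-level taxa survive filtering")
  abund <- table$abund[, !bad, drop = FALSE]
  if (renormalize) {
    abund <- abund / rowSums(abund)
    abundance_table(abund, table$metadata, filtered = FALSE)
  } else {
    abundance_table(abund, table$metadata, filtered = TRUE)
  }
}

#' Average relative abundances over each subject's time points
#'
#' @param table an [abundance_table()] with metadata.
#' @return An [abundance_table()] with one row per subject (the unweighted
#'   mean over that subject's available time points); metadata carries
#'   subject ids with `day = NA`.
#' @export
mean_by_subject <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (is.null(table$metadata)) stop("metadata required")
  subj <- factor(table$metadata$subject, levels = unique(table$metadata$subject))
  means <- rowsum(table$abund, subj) / as.vector(table(subj))
  structure(list(abund = means,
                 metadata = data.frame(sample = rownames(means),
                                       subject = rownames(means),
                                       day = NA_real_),
                 filtered = table$filtered),
            class = "abundance_table")
}

#' Taxa passing a mean-abundance threshold
#'
#' Reports taxa whose mean relative abundance across subjects is at least
#' `threshold` (boundary inclusive), with their per-subject mean
#' abundances, sorted by overall mean, descending.
#'
#' @param table an [abundance_table()] with metadata.
#' @param threshold fraction in \[0, 1\] (default 0.01, i.e. 1 percent).
#' @return data.frame: `taxon`, `mean_abundance`, then one column per
#'   subject.
#' @export
abundant_taxa_summary <- function(table, threshold = 0.01) {
  stopifnot(threshold >= 0, threshold <= 1)
  subj_means <- mean_by_subject(table)$abund
  overall <- colMeans(subj_means)
  keep <- which(overall >= threshold)
  ord <- keep[order(overall[keep], decreasing = TRUE)]
  out <- data.frame(taxon = colnames(subj_means)[ord],
                    mean_abundance = unname(overall[ord]))
  cbind(out, as.data.frame(t(subj_means[, ord, drop = FALSE])))
}
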