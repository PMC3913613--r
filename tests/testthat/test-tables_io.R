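test_that("shared files parse, validate, and round-trip bit-exactly", {
  path <- withr::local_tempfile(fileext = ".shared")
  writeLines(c("label\tGroup\tnumOtus\tOtu001\tOtu002\tOtu003",
               "0.03\ts1\t3\t5\t0\t1",
               "0.03\ts2\t3\t2\t2\t2"), path)
  tab <- read_shared(path)
  expect_identical(unname(tab$counts),
                   matrix(c(5L, 0L, 1L, 2L, 2L, 2L), 2, byrow = TRUE))
  expect_identical(rownames(tab$counts), c("s1", "s2"))

  # numOtus disagreeing with the column count is a format error
  bad <- withr::local_tempfile()
  writeLines(c("label\tGroup\tnumOtus\tOtu001\tOtu002",
               "0.03\ts1\t5\t1\t2"), bad)
  expect_error(read_shared(bad), "numOtus")

  ragged <- withr::local_tempfile()
  writeLines(c("label\tGroup\tnumOtus\tOtu001\tOtu002",
               "0.03\ts1\t2\t1"), ragged)
  expect_error(read_shared(ragged), "line 2")

  noninteger <- withr::local_tempfile()
  writeLines(c("label\tGroup\tnumOtus\tOtu001",
               "0.03\ts1\t1\t2.5"), noninteger)
  expect_error(read_shared(noninteger), "non-integer")

  # write -> read reproduces the matrix exactly
  out <- withr::local_tempfile(fileext = ".shared")
  write_shared(tab, out)
  expect_identical(read_shared(out)$counts, tab$counts)
})

test_that("constaxonomy files parse lineages and confidences", {
  path <- withr::local_tempfile(fileext = ".taxonomy")
  writeLines(c("OTU\tSize\tTaxonomy",
               "Otu001\t10\tBacteria(100);Firmicutes(100);Bacilli(100);Lactobacillales(99);Streptococcaceae(97);Streptococcus(95);",
               "Otu002\t4\tBacteria;Bacteroidetes;"), path)
  tax <- read_constaxonomy(path)
  expect_identical(tax$lineage$Otu001[6], "Streptococcus")
  expect_length(tax$lineage$Otu001, 6)   # lineage stored as given, no padding
  expect_equal(tax$confidence$Otu001[6], 95)
  expect_length(tax$lineage$Otu002, 2)
  expect_true(all(is.na(tax$confidence$Otu002)))

  dup <- withr::local_tempfile()
  writeLines(c("OTU\tSize\tTaxonomy",
               "Otu001\t1\tBacteria;", "Otu001\t1\tBacteria;"), dup)
  expect_error(read_constaxonomy(dup), "duplicate OTU")

  nocol <- withr::local_tempfile()
  writeLines(c("OTU\tSize", "Otu001\t1"), nocol)
  expect_error(read_constaxonomy(nocol), "Taxonomy")

  out <- withr::local_tempfile()
  write_constaxonomy(tax, out)
  rt <- read_constaxonomy(out)
  expect_identical(rt$lineage, tax$lineage)
})

test_that("metadata reads, rejects duplicates, warns on unusual days", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tsubject\tday",
               "p35d01\tp35\t1", "p35d03\tp35\t3"), path)
  md <- read_metadata(path)
  expect_identical(md$sample, c("p35d01", "p35d03"))
  expect_identical(md$day, c(1, 3))

  dup <- withr::local_tempfile()
  writeLines(c("sample\tsubject\tday", "a\tx\t1", "a\tx\t3"), dup)
  expect_error(read_metadata(dup), "duplicate sample")

  odd <- withr::local_tempfile()
  writeLines(c("sample\tsubject\tday", "a\tx\t7"), odd)
  expect_warning(read_metadata(odd), "unexpected day")

  # attaching requires complete coverage of table samples
  tab <- toy_count_table()
  expect_error(attach_metadata(count_table(tab$counts),
                               data.frame(sample = "Ad01", subject = "A", day = 1)),
               "missing")
})

test_that("rarefaction draws without replacement and keeps under-depth samples", {
  m <- matrix(c(2L, 0L, 0L), 1, dimnames = list("s1", c("a", "b", "c")))
  tab <- count_table(m)
  expect_identical(rarefy(tab, 2, seed = 1)$counts, m)  # forced draw

  tab2 <- toy_count_table()
  r <- rarefy(tab2, 6, seed = 5)
  expect_true(all(r$counts <= tab2$counts))
  expect_identical(unname(rowSums(r$counts)),
                   pmin(6, unname(rowSums(tab2$counts))))
  # depth equal to a sample total leaves it unchanged
  expect_identical(r$counts["Ad01", ], tab2$counts["Ad01", ])

  # under-depth sample kept unchanged and flagged
  expect_warning(ru <- rarefy(tab2, 9, seed = 1), "below depth")
  expect_identical(ru$counts["Ad01", ], tab2$counts["Ad01", ])
  expect_true("Ad01" %in% attr(ru, "under_depth"))
  # strict mode drops it instead
  expect_warning(rs <- rarefy(tab2, 9, seed = 1, strict_depth = TRUE))
  expect_false("Ad01" %in% rownames(rs$counts))
})

test_that("rarefaction matches the hypergeometric expectation", {
  # sample (600, 400), depth 100: first-feature mean = 60, with the
  # hypergeometric sd of a single draw governing the Monte Carlo error
  m <- matrix(c(600L, 400L), 1, dimnames = list("s", c("a", "b")))
  tab <- count_table(m)
  n_rep <- 10000
  draws <- vapply(seq_len(n_rep), function(i)
    rarefy(tab, 100, seed = i)$counts[1, 1], 0L)
  hyper_sd <- sqrt(100 * 0.6 * 0.4 * (1000 - 100) / (1000 - 1))
  expect_lt(abs(mean(draws) - 60), 3 * hyper_sd / sqrt(n_rep))
  expect_equal(sd(draws), hyper_sd, tolerance = 0.05)
})

test_that("collapsing by rank conserves mass and merges shared names", {
  counts <- matrix(c(4L, 6L, 0L,
                     2L, 3L, 5L), 2, 3, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("Otu1", "Otu2", "Otu3")))
  tab <- count_table(counts)
  lineage <- list(
    Otu1 = c("Bacteria", "Firmicutes", "Bacilli", "Lactobacillales",
             "Streptococcaceae", "Streptococcus", "Streptococcus_sanguinis"),
    Otu2 = c("Bacteria", "Firmicutes", "Bacilli", "Lactobacillales",
             "Streptococcaceae", "Streptococcus", "Streptococcus_mitis"),
    Otu3 = c("Bacteria", "Bacteroidetes", "Bacteroidia", "Bacteroidales",
             "Prevotellaceae", "Prevotella", "Prevotella_intermedia"))
  tax <- structure(list(lineage = lineage,
                        confidence = lapply(lineage, function(l) rep(NA_real_, 7))),
                   class = "taxonomy_map")
  gen <- collapse_by_rank(tab, tax, "genus")
  expect_equal(gen$abund["s1", "Streptococcus"], 1.0)
  expect_equal(unname(rowSums(gen$abund)), c(1, 1), tolerance = 1e-9)
  sp <- collapse_by_rank(tab, tax, "species")
  expect_equal(unname(sp$abund["s2", ]), c(0.2, 0.3, 0.5))
  expect_identical(colnames(sp$abund)[1], "Streptococcus sanguinis")

  # three genera with totals (50, 30, 20) of 100 -> (0.5, 0.3, 0.2)
  c2 <- matrix(c(50L, 30L, 20L), 1, dimnames = list("s", names(lineage)))
  g2 <- collapse_by_rank(count_table(c2), tax, "species")
  expect_equal(unname(g2$abund[1, ]), c(0.5, 0.3, 0.2))

  # missing feature is an error
  c3 <- matrix(1L, 1, 1, dimnames = list("s", "OtuX"))
  expect_error(collapse_by_rank(count_table(c3), tax), "missing from taxonomy")

  # lineage ending above species gets an "unclassified" species name
  lineage$Otu3 <- lineage$Otu3[1:6]
  tax2 <- structure(list(lineage = lineage,
                         confidence = lapply(lineage, function(l) rep(NA_real_, length(l)))),
                    class = "taxonomy_map")
  sp2 <- collapse_by_rank(tab, tax2, "species")
  expect_true(any(grepl("unclassified", colnames(sp2$abund))))
})

test_that("species name filter removes unresolved taxa without renormalizing", {
  ab <- matrix(c(0.5, 0.3, 0.2,
                 0.1, 0.6, 0.3), 2, 3, byrow = TRUE,
               dimnames = list(c("s1", "s2"),
                               c("Prevotella intermedia", "uncultured bacterium",
                                 "Streptococcus sanguinis")))
  tab <- abundance_table(ab)
  f <- filter_species_names(tab)
  expect_identical(colnames(f$abund),
                   c("Prevotella intermedia", "Streptococcus sanguinis"))
  expect_true(f$filtered)
  expect_equal(unname(f$abund[1, ]), c(0.5, 0.2))  # denominators preserved
  fr <- filter_species_names(tab, renormalize = TRUE)
  expect_equal(unname(rowSums(fr$abund)), c(1, 1), tolerance = 1e-9)

  # unclassified names and case variants are removed too
  colnames(ab) <- c("ok species", "Unclassified Prevotella", "Genus unclassified")
  expect_identical(colnames(filter_species_names(abundance_table(ab))$abund),
                   "ok species")
  colnames(ab) <- c("uncultured a", "uncultured b", "UNCULTURED c")
  expect_error(filter_species_names(abundance_table(ab)), "survive")

  # all-clean input is untouched
  colnames(ab) <- c("a b", "c d", "e f")
  expect_identical(filter_species_names(abundance_table(ab))$abund, ab)
})

test_that("subject means and the abundance summary aggregate correctly", {
  ab <- matrix(c(0.2, 0.8,
                 0.4, 0.6,
                 1.0, 0.0), 3, 2, byrow = TRUE,
               dimnames = list(c("Ad1", "Ad3", "Bd1"), c("x y", "z w")))
  tab <- abundance_table(ab, data.frame(sample = rownames(ab),
                                        subject = c("A", "A", "B"),
                                        day = c(1, 3, 1)))
  m <- mean_by_subject(tab)
  expect_equal(nrow(m$abund), 2)            # one row per subject
  expect_equal(m$abund["A", "x y"], 0.3)    # mean of 0.2 and 0.4
  expect_equal(unname(m$abund["B", ]), c(1, 0))  # single sample: identity

  s_all <- abundant_taxa_summary(tab, 0)
  expect_setequal(s_all$taxon, colnames(ab))
  # taxon exactly at the threshold is included; sorted descending
  expect_identical(abundant_taxa_summary(tab, 0.65)$taxon, "x y")
  expect_identical(s_all$taxon[1], "x y")
  expect_equal(nrow(abundant_taxa_summary(tab, 1)), 0)
})
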