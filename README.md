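# oralclust

Consensus clustering and diversity analysis of longitudinal oral biofilm
communities.

Oral biofilms assemble over days, and 16S rRNA profiling of many
subjects at several maturation time points produces a sample-by-OTU
count table with strong subject structure. `oralclust` answers three
questions about such data:

1. **Alpha diversity over time.** Effective richness
   `^1D = exp(-Σ p_i log p_i)` (the Shannon numbers equivalent) per
   sample, and a mixed-effects model `log(^1D) ~ day + (1 | subject)`
   (REML; optional random slope, structures compared by AIC) testing for
   a maturation trend.
2. **Beta diversity partitioning.** Hellinger-transformed counts in a
   partial redundancy analysis, `community ~ day + Condition(subject)`:
   how much compositional variance is inter-individual, and how much is
   within-subject temporal turnover (Ezekiel-adjusted semipartial R²,
   pseudo-F tested by permuting days within subjects).
3. **Mutually exclusive species clusters and subject types.**
   Monti-style consensus clustering — H random item subsamples at
   proportion p, consensus matrix M_K(i,j) = co-clustering fraction
   among co-sampling draws, cluster number from the relative change
   Δ(K) in the area under the consensus CDF, and an item-consensus
   robustness filter (own cluster ≥ 0.6, every other ≤ 0.4). Species
   are clustered by average linkage on 1 − Spearman ρ; subjects by PAM
   on their PCA scores. Discovered partitions are evaluated by ANOSIM,
   and inter-cluster association by the RV matrix correlation on
   midranked abundances, both with permutation tests.

A Dirichlet-multinomial community simulator with planted species
clusters and subject types (31 subjects × 5 days at 1,042 reads/sample
by default) makes the whole pipeline verifiable against known truth.
Input formats are mothur `shared` and `constaxonomy` files plus a
sample/subject/day TSV; everything is driven from R.

## Worked example

```r
library(oralclust)

cfg <- pipeline_config(simulation = simulation_design(),
                       species_h = 1000, subject_h = 2000,
                       n_perm_rda = 999, n_perm_anosim = 9999,
                       n_perm_rv = 999, seed = 1)
rep <- run_pipeline(cfg)
print(rep)
#> == oralclust pipeline report ==
#> samples: 155  species retained: 27
#> alpha: day p = 0.6452 (model: random intercept)
#> beta: subject 56.5%, day 0.41% (adj R2 -0.0040, p = 0.275)
#> species clusters: K = 3 (27 robust members)
#> subject clusters: K = 3, ANOSIM R = 0.868 (p = 0.0001)
#> recovery: species ARI 0.894, subject ARI 0.900
```

Reading this: 27 species survive the name filter; alpha diversity shows
no day trend (p = 0.65), matching the simulator's zero planted day
effect; 56.5% of Hellinger-space variance is inter-individual while day
explains essentially nothing (adjusted R² ≈ 0); the delta-area rule
selects three species clusters and three subject clusters, recovering
the planted partitions (adjusted Rand ≈ 0.9) with strong subject
separation (ANOSIM R = 0.868). The K-selection trace behind that
decision:

```r
print(rep$species_consensus)
#> consensus_run: average linkage on 27 items, H = 1000, p = 0.80
#>   K:      2 3 4 5 6
#>   A(K):   0.484 0.682 0.717 0.742 0.763
#>   delta:  0.484 0.408 0.052 0.034 0.029
#>   selected K = 3
```

and the association between robust species clusters (the two
strongly mixed clusters show a large RV; the sparse third cluster is
nearly independent of cluster 1):

```r
for (nm in names(rep$rv_pairs))
  cat(sprintf("%s: RV = %.3f, p = %.3g\n",
              nm, rep$rv_pairs[[nm]]$rv, rep$rv_pairs[[nm]]$p_value))
#> 1-2: RV = 0.056, p = 0.762
#> 1-3: RV = 0.348, p = 0.002
#> 2-3: RV = 0.538, p = 0.001
```

File-based analyses use the same entry point with paths instead of a
simulation design:

```r
cfg <- pipeline_config(shared = "community.shared",
                       constaxonomy = "community.cons.taxonomy",
                       metadata = "metadata.tsv",
                       exclude_subjects = "p35",   # drop an outlier subject
                       seed = 1)
rep <- run_pipeline(cfg)
```

or a YAML file via `read_pipeline_config()`. Per-stage functions
(`rarefy()`, `collapse_by_rank()`, `effective_richness()`,
`fit_mixed_model()`, `hellinger()`, `partial_rda()`,
`consensus_cluster()`, `robust_members()`, `anosim()`,
`rv_coefficient()`, `simulate_dataset()`, ...) are exported for use
outside the pipeline.

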