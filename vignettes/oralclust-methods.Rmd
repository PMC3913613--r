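---
title: "Methods: consensus clustering and diversity analysis of oral biofilm communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus clustering and diversity analysis of oral biofilm communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Dental biofilms assemble over days. Given 16S rRNA amplicon profiles of
biofilm samples collected from many subjects at several maturation time
points, three questions arise:

1. Does alpha diversity change systematically as the biofilm matures?
2. How much of the compositional (beta-diversity) variation is explained
   by maturation time, once the large subject-to-subject differences are
   removed?
3. Are there groups of species that consistently co-occur — and mutually
   exclude other groups — across subjects, and do subjects fall into
   corresponding community types?

`oralclust` implements this analysis as a reusable pipeline operating on
a mothur-style sample-by-OTU count table, an OTU taxonomy, and a
sample-to-(subject, day) metadata table, together with a synthetic
community generator that plants known cluster structure so every stage
can be validated end to end.

# Input processing

**Rarefaction.** Samples are downsampled without replacement
(multivariate hypergeometric, the same semantics as mothur's
`sub.sample`) to a common depth, 1,042 reads by default, to remove
unequal-effort bias. Samples below the target depth are *kept unchanged*
and flagged rather than dropped — low-coverage longitudinal samples are
too valuable to discard silently — with `strict_depth = TRUE` available
to drop them.

**Species table.** OTU counts are summed over identical names at a
chosen rank and divided by the per-sample total *before* any feature is
removed. Names containing "uncultured" or "unclassified"
(case-insensitive substring match — the filter is given as terms, not a
grammar), and lineages that never reach species rank, are then dropped.
By default the remaining fractions are **not** renormalised: keeping the
original denominators preserves comparability of the retained fractions
across samples. `renormalize_after_filter = TRUE` exposes the
alternative, since either convention is defensible.

# Alpha diversity and the time model

Alpha diversity is the Hill number of order one (effective richness),
$^1\!D = \exp(-\sum_i p_i \ln p_i)$: the number of equally abundant
species that would reproduce the observed Shannon entropy. It equals the
species count for an even community, 1 for a monoculture, and is
invariant to rescaling counts.

The time model is a mixed-effects regression of $\log {}^1\!D$ on day
with a per-subject random intercept (optionally a random slope), fitted
by REML:

$$\log {}^1\!D_{sj} = \beta_0 + \beta_1\,\mathrm{day}_j + b_s
  (+\, c_s\,\mathrm{day}_j) + \varepsilon_{sj}.$$

A note on the response distribution: effective richness is positive and
right-skewed, which suggests a gamma family with log link. We instead
model $\log {}^1\!D$ as Gaussian: the log-normal is a close working
approximation to a log-link gamma for this kind of response, and it
admits an exact REML criterion, so the random-intercept and
random-slope structures can be compared by AIC (identical fixed
effects, both REML) without quasi-likelihood machinery. The choice is
recorded in the fit's `response` field. Day enters as a numeric
covariate — the random-slope structure only makes sense for a numeric
trend. The day effect is tested with a Wald $t$ statistic using
Satterthwaite degrees of freedom, which is better calibrated at ~30
subjects than a normal approximation; the null-calibration test in the
package verifies approximate uniformity of this p-value.

# Beta diversity: partial redundancy analysis

Counts are Hellinger-transformed, $y_{ij} \mapsto \sqrt{y_{ij}/y_{i+}}$,
so that Euclidean distance between rows equals the Hellinger distance
between profiles — the standard device that makes community data
compatible with linear ordination while damping dominant taxa.

The model is *community ~ day, conditioned on subject*. Total inertia
(the sum of column variances, divisor $n-1$) splits into

* the **conditioned** fraction — inertia captured by projecting the
  centred community matrix onto the subject indicator subspace
  (inter-individual differences);
* the **constrained** fraction — the additional inertia explained by
  day after residualising both the community matrix and day on the
  subject indicators (within-subject temporal turnover);
* the **residual**.

The constrained term's semipartial $R^2$ is reported with the Ezekiel
adjustment $1-(1-R^2)\,(n-g-1)/(n-g-1-m)$, where $g$ is the number of
subject dummies and $m$ the day degrees of freedom (1 for numeric day;
`day_as_factor = TRUE` uses levels − 1). Significance uses the pseudo-F
$(\mathrm{constrained}/m)\,/\,(\mathrm{residual}/(n-g-m))$ under
permutations of day labels *within* each subject — samples never move
between subjects, respecting the longitudinal design. Permutation
p-values use the add-one convention $p = (1+\#\{F^* \ge F\})/(1+B)$ and
so are never zero. Homogeneity of multivariate dispersion across days is
checked by embedding the distance matrix in principal coordinates
(eigenvalues within $-10^{-9}$ of zero are clamped), measuring each
sample's distance to its group centroid, and permuting labels (within
subjects) around the one-way ANOVA F of those distances; the degenerate
all-equal case is defined as $F = 0$, $p = 1$.

# Consensus clustering

The core of the package is a Monti-style consensus clustering engine.
For $H$ subsamples, a fraction $p$ of the items (species or subjects) is
drawn without replacement, the distance matrix is restricted to them,
and the base clusterer is run at each candidate $K$. The consensus
$M_K(i,j)$ is the fraction of draws containing both $i$ and $j$ in which
they co-clustered. Restricting a correlation-based distance to an item
subset leaves pairwise correlations unchanged, so the subsample distance
is implemented as masking of the full matrix; the equivalence is exact.
Pairs never co-sampled (negligible probability at the default $H$ and
$p$, but the contract must be total) get consensus 0 and are counted in
the run log; `strict = TRUE` turns that into an error. The final
assignment at each $K$ re-clusters $1-M_K$ by average linkage, the
convention of the consensus-clustering literature.

**Choosing K.** For each $K$ the empirical CDF of the
$n(n-1)/2$ upper-triangular consensus entries is integrated exactly over
$[0,1]$: $A(K) = \int_0^1 \mathrm{ECDF}(x)\,dx$, an exact step sum over
the distinct entry values rather than a binned histogram, so the value
is deterministic and oracle-checkable. Note the orientation this
implies: a consensus matrix of all ones has $A = 0$ and one of all zeros
has $A = 1$ — area accrues as pairs are *separated*. The relative gain
$\Delta(2) = A(2)$, $\Delta(K) = (A(K)-A(K-1))/A(K-1)$ flattens once new
clusters stop restructuring the consensus; the selected $K^*$ is the
largest $K$ with $\Delta(K) > \varepsilon$. The cutoff
$\varepsilon = 0.1$ is a package choice — the delta-area criterion is
usually applied by eye — so $\varepsilon$ is configurable and the full
$\Delta(K)$ table is always reported for the user to override $K^*$.

**Robust members.** The item consensus
$m_i(k) = \sum_{j \in k,\, j \ne i} M_K(i,j) / (|k| - [i \in k])$
measures how firmly item $i$ sits in cluster $k$; it is undefined
(reported missing) for an item alone in its cluster. An item is a
*robust* member iff $m_i(\text{own}) \ge 0.6$ and $m_i(k) \le 0.4$ for
every other $k$, both boundaries inclusive.

**Base clusterers.** Species use average-linkage (UPGMA) agglomeration
on $1-\rho_\mathrm{Spearman}$ distances; subjects use partitioning
around medoids (PAM: greedy BUILD, then steepest-descent SWAP) on
Euclidean distances of their PCA scores. Both are deterministic for a
given distance matrix. PAM is a descent heuristic: its cost can never
beat the exhaustive-medoid optimum, and the test suite measures that it
attains the optimum on the large majority of small random instances —
but local optima exist even at $n \le 8$, so exact global optimality is
not a contract of the algorithm.

# Subject clustering and association statistics

Per-subject mean species abundances (unweighted over available time
points) are Hellinger-transformed and ordinated by PCA (column-centred
SVD; eigenvalues $d_k^2/(n-1)$; scaling-1 scores $U D/\sqrt{n-1}$, which
preserve inter-sample distances up to a global factor). Species are
projected into the sample space as abundance-weighted averages of the
sample scores. Subject consensus clustering runs PAM on the full score
matrix by default — truncation to the leading axes is available via
`n_axes`, but with ~30 subjects the trailing axes carry little weight
and discarding them is an extra arbitrary choice.

The discovered partition is evaluated by **ANOSIM** on Euclidean
distances of the Hellinger-transformed subject-by-species table: with
midranked distances,
$R = (\bar r_\mathrm{between} - \bar r_\mathrm{within}) / (n(n-1)/4)$,
1 at perfect separation, ~0 when grouping is unrelated to distance, and
invariant under monotone transforms of the distances. Significance is by
unrestricted permutation of group labels (no strata apply: groups are
discovered subject types, not a repeated-measures factor). Clusters with
a single subject are excluded from the test, since within-group
dissimilarity is undefined for them.

Association between two robust species clusters is Escoufier's **RV
coefficient** on column-wise midranked, column-centred abundance
matrices,
$\mathrm{RV} = \mathrm{tr}(X^\top Y Y^\top X) / \sqrt{\mathrm{tr}((X^\top X)^2)\,\mathrm{tr}((Y^\top Y)^2)}$,
with significance by permuting the rows of one matrix. The label
"multivariate coefficient of variation" sometimes attached to this
quantity is nonstandard; the symbol, range and pairwise-matrix usage
identify it as the RV matrix correlation. The midrank transform suits
skewed abundances and is the default; `rank = FALSE` gives the classical
RV, for which the orthogonal-rotation invariance
$\mathrm{RV}(X, YQ) = \mathrm{RV}(X, Y)$ holds exactly (ranking is not
rotation-equivariant, so the invariance is stated for the unranked
form). RV is computed on subject-mean tables by default; sample-level
tables can be passed instead.

# The synthetic community generator

`simulate_dataset()` emulates the study design the pipeline targets: 31
subjects sampled on days 1, 3, 5, 9 and 14 at 1,042 reads per sample,
with three mutually exclusive species clusters (12, 10 and 8 species)
and three equiprobable subject community types mixing them in
proportions (0.60, 0.40, 0), (0.32, 0.66, 0.02) and (0.54, 0.20, 0.27)
(the last row is proportionally renormalised from printed percentages
that sum to 101%). The generative model:

1. **Characteristic species shares.** Each cluster's internal species
   proportions are drawn once per dataset from a flat Dirichlet. This is
   a deliberate interpretation: a species has a characteristic typical
   abundance, so the members of a cluster rise and fall together across
   subjects — which is what makes a species cluster a recoverable,
   coherent block. Redrawing shares per subject would leave cluster
   membership with almost no rank-correlation signature.
2. **Subjects.** Each subject draws a type, then cluster weights from
   Dirichlet($\kappa \times$ type mixing row) with $\kappa = 30$:
   subjects of a type resemble but do not duplicate each other
   (cluster-share s.d. ≈ 0.09 around a 0.5 weight).
3. **Samples.** Each (subject, day) draws proportions from
   Dirichlet($\tau \times$ subject profile) with $\tau = 50$ — the
   day-to-day over-dispersion real 16S data show relative to a plain
   multinomial; larger $\tau$ means more stable within-subject profiles
   (a monotonicity the tests check). An optional `day_effect` tilts
   cluster-1 species by $e^{\text{day\_effect} \times \text{day}}$; the
   default 0 encodes the absence of a systematic maturation trend.
   Counts are multinomial at the design depth. $\tau$ and $\kappa$ are
   free parameters of the emulation — real within-subject dispersion is
   not identifiable from published summary statistics — and both are
   exposed in the design object.

Species receive synthetic binomial names ("Genus101 species3"), with a
10% fraction renamed "uncultured_bacterium_*" so the species name filter
is exercised on every simulated run; a full synthetic lineage is
attached so the collapse path runs exactly as on real data.

**What the generator does not emulate** — and hence what passing tests
do not demonstrate about real data: sequencing noise, chimeras and
misclassification; phylogenetic correlation between species; uneven or
missing time points; more than the planted number of community types;
and species outside the planted clusters. One emergent artifact is worth
knowing: flat Dirichlet shares make some species very rare (< 1 read per
sample), and rare species are mutually rank-correlated simply through
shared zero midranks, so a "rare species" subcluster genuinely exists in
many simulated datasets. With $\varepsilon = 0.1$ the delta-area rule
then sometimes reports $K = 4$; the full $\Delta(K)$ trace makes such
cases visible, and the item-consensus filter keeps the affected members
from contaminating downstream statistics. Zero-inflation-driven rank
correlation is equally real in actual 16S species tables.

# Numerical and reproducibility choices

* All randomised stages take explicit seeds; the pipeline derives
  per-stage seeds from one master seed, so any stage can be re-run in
  isolation and a rerun with the same configuration reproduces every
  statistic exactly.
* Rank ties use midranks throughout (Spearman distances, ANOSIM, RV).
* Species with zero variance across samples have undefined rank
  correlation; their distances are set to 1 (no information) with a
  warning, and the pipeline drops species never observed at all.
* UPGMA merge order and PAM swaps inherit the deterministic tie-breaking
  of their implementations; consensus runs are therefore exactly
  reproducible.
* Permutation p-values use the add-one convention and never equal 0.
* The composition summary (species-cluster make-up of each subject
  cluster) is normalised over robust-cluster species only — the robust
  clusters are the discovered objects — with subjects of zero
  robust-species mass excluded with a warning.

# Problem sizes used by the test and acceptance suites

The suites run the full design (31 subjects × 5 days, depth 1,042) but
scale resampling: species consensus at $H = 200$–1,000 subsamples,
subject consensus at $H$ up to 2,000, permutation tests at 99–9,999
permutations, 50-seed recovery experiments, 100-replicate mixed-model
recovery and 200-replicate null-calibration studies. These sizes give
Monte Carlo error comfortably below the decision thresholds being
tested; analyses of real data should use the defaults
($H = 1{,}000$ / $10{,}000$, ANOSIM at $10^5$ permutations).

# Known limitations

* The mixed model is a log-Gaussian approximation, not a gamma GLMM; for
  responses with strong gamma-type mean–variance coupling the two can
  differ in the tail of the day test.
* PAM is a local search (see above); consensus clustering largely
  averages away the rare suboptimal runs, but single PAM calls on
  adversarial distances need not be globally optimal.
* The delta-area cutoff $\varepsilon$ is a heuristic; inspect the
  reported $A(K)$/$\Delta(K)$ trace rather than trusting $K^*$ blindly.
* ANOSIM on a partition *discovered from the same data* overstates
  separation; treat its R as descriptive, not inferential.
* The pipeline starts at the OTU table: denoising, chimera removal and
  taxonomic classification are upstream concerns.
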