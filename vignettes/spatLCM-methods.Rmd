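---
title: "Region-resolved LCM proteomics: models and methods"
author: "spatLCM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-resolved LCM proteomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatLCM)
```

# Scope and data model

spatLCM analyzes laser-capture-microdissection (LCM) spatial proteomics
of synovial tissue. Each sample is one pathologist-annotated region of
interest (ROI) from one donor, labelled with one of five
histopathological region types: normal-healthy lining (`NH_SL`),
normal-healthy sublining (`NH_SSL`), RA lining (`RA_SL`), RA
fibrous-rich sublining (`RA_fibrous_SSL`) and RA immune-rich sublining
(`RA_immune_SSL`). The quantitative input is a DIA protein-group
intensity matrix (the tab-separated `pg_matrix` dialect produced by DIA
search engines), in which an empty or zero cell encodes non-detection,
not a measured zero. The central container, `ProteoExperiment`, extends
`SummarizedExperiment` with an explicit logical missingness mask and a
processing-state flag (`raw`, `log2`, `normalized`, `imputed`), so each
stage can assert the contract it requires instead of silently operating
on the wrong scale.

Two conventions are fixed at import. Zero intensities become missing,
because a DIA intensity of zero encodes non-detection and would
otherwise break the log2 transform. Multi-gene protein groups map to
their first listed gene symbol; this is our deterministic convention
for obtaining a single-gene key for the single-cell integration, since
protein-group-to-gene mapping for ambiguous groups has no canonical
answer.

# Preprocessing

**Missingness filter.** A protein is retained when its overall missing
fraction is below 0.5, *or* some region group observed it in every
sample. The second clause reads the requirement of "fewer than one
missing value in any ROI group" as "zero missing in at least one region
group": over integers, "fewer than one" is zero, and the OR keeps
region-complete proteins that would otherwise be discarded when they
are genuinely absent from other regions — which is exactly the
region-specific signal the downstream marker extraction looks for. The
rule is tested against an exhaustive truth-table evaluation of all
2^10 missingness patterns of a ten-sample design.

**Log2 and median normalization.** Intensities are log2 transformed
(the transform refuses non-missing values at or below zero — those must
have been mapped to missing upstream). Median normalization subtracts
each sample's observed median and adds back the grand median of the
per-sample medians, so all samples end at a common median *on the
original log2 intensity scale*, which keeps fold changes interpretable.
The operation is idempotent.

**Imputation.** Remaining missing values (missing-not-at-random,
intensity-dependent) are imputed by iterative chained random-forest
regression: missing cells are initialized at the protein's observed
mean, proteins are swept in decreasing-missingness order, and each
protein's missing cells are re-predicted from all other proteins'
current values by a `ranger` forest, until the relative change of the
imputed cells stops decreasing or `maxIter` sweeps are reached. The
scheme is a contract rather than a mandated algorithm: any nonlinear
ensemble regressor that recovers a collinear protein's hidden value and
is deterministic under its seed satisfies it. Observed cells are never
modified (tested for exact equality), and all forests are seeded with
one worker thread so runs are reproducible.

**PCA.** Quality control uses protein-centred (unscaled) SVD-based PCA,
the standard choice for log-intensity matrices. Sign indeterminacy is
resolved by making the largest-magnitude loading of each component
positive. For a two-group design the loadings of the separating
component are proportional to the per-protein mean shift, which is why
the package reports the Pearson correlation between loadings and DE
log2 fold changes as a cross-validation of both computations; on a
planted shift design this correlation exceeds 0.95.

# Differential expression

Pairwise contrasts among the five region types (10 in total) use a
group-means linear model per protein with empirical-Bayes variance
moderation. With per-protein residual variance $s^2$ on $d$ degrees of
freedom, the prior $(d_0, s_0^2)$ is estimated by method of moments on
$\log s^2$ (matching the classical moderated-t construction: the excess
of $\operatorname{var}(\log s^2)$ over $\psi'(d/2)$ is inverted through
the trigamma function), the posterior variance is
$\tilde{s}^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$, and the moderated
statistic $t = \Delta\bar{x} / (\tilde{s}\sqrt{1/n_a + 1/n_b})$ is
referred to $t_{d_0+d}$, two-sided. The implementation is written here
and cross-checked in the test suite against limma's `eBayes` on a
shared fixture (prior estimates and statistics agree to numerical
precision) and against the two limiting regimes: heterogeneous
variances drive $d_0 \to 0$ and recover the per-protein Student test,
homogeneous variances drive $d_0 \to \infty$ and recover a pooled-
variance z-like statistic. FDR control is Benjamini–Hochberg
(`stats::p.adjust`), and a protein is called significant at FDR < 0.05
with fold change > 2, i.e. $|\log_2 \mathrm{FC}| > 1$. Group
comparisons of single proteins use one-way ANOVA with Tukey HSD
(`stats::aov` + `stats::TukeyHSD`), validated against a from-scratch
SSB/SSW and studentized-range computation.

DE is computed on the imputed matrix, following the stage order
filter → transform/normalize → impute → DE. Samples are treated as
independent (no donor blocking), matching the tests the study design
prescribes; the synthetic generator nevertheless plants small
donor-level random intercepts so that simulations do not understate
real within-donor correlation.

# Region-specific markers

For each region, every protein gets an unpaired two-tailed two-sample
*t* test of that region versus all other samples, read as the classical
equal-variance Student test (Welch is available behind a flag), plus
Cohen's d with the pooled $(n-1)$-weighted SD — pooled rather than
unpooled is our default where the original convention is not stated.
A protein with $p < 10^{-2}$ and $d > 0$ in at least one region is
assigned to the region where its effect size is highest; exact ties
(a measure-zero event on real data) break by the fixed canonical region
order for determinism. Only up-regulated ($d > 0$) markers are kept.
Marker sets are therefore pairwise disjoint and, with the unassigned
remainder, partition the protein universe. Note that tightening the p
threshold shrinks the assigned universe monotonically but can move an
individual protein between regions when its best region drops out while
a weaker one stays eligible; the tests check the monotone-universe
property and assignment stability, not per-set monotonicity, which does
not hold for an argmax rule.

# The Query integration

The single-cell reference is a features × clusters average-expression
matrix with 77 clusters annotated into six cell types (9 B/plasma, 5
endothelial, 15 myeloid, 14 NK, 10 stromal, 24 T). Each feature row is
z-normalized across clusters, $z = (X - \mu)/\sigma$ with the $(n-1)$
SD; constant rows get $z = 0$. The normalization axis is per feature
across clusters: the method asks where a gene is *relatively*
over-expressed among clusters, and normalizing within a cluster instead
would erase exactly that cell-type specificity. The score of a
(region, cluster) pair is the sum of the cluster's z values over the
region's marker genes divided by the number of marker genes — i.e.
their mean. Genes absent from the reference feature list are excluded
from numerator *and* denominator: with the emulated ~99.3% feature
coverage the distinction is minor, but dividing by the full set size
would deflate every score by an arbitrary coverage factor. A region
whose marker genes have no overlap with the features is flagged
undefined rather than silently zero. Positive scores are enrichment,
negative ones depletion; the two map views blank the opposite sign and
omit a cluster only when it has no entry of the view's sign in any
region (a sign-based rule, no magnitude cutoff).

# Preranked GSEA

Pathway readout of each pairwise contrast uses the standard weighted
Kolmogorov–Smirnov preranked statistic on the log2 fold-change ranking:
hits increment the running sum proportionally to |log2 FC| (weight
exponent 1, normalized to sum 1), misses decrement by 1/(N − set size),
and the enrichment score is the extremum. The null is gene-label
permutation (set-size draws from the ranking), NES divides ES by the
mean |null ES| of matching sign, the permutation p value is the
fraction of same-sign null ES at least as extreme (with the +1
continuity correction), and FDR uses the standard sign-pooled NES null.
The original analysis ran through an external enrichment service; this
package implements the computation that service performs, cross-checks
its ES against `fgsea` to 1e-10 on shared fixtures, and treats
service-exact FDR values as a non-goal. Defaults `minSize = 10`,
`maxSize = 500` are conventional guardrails against degenerate sets.

# The synthetic-data generator

Because the study's deposited intensity matrix is not an input, every
stage is validated on generated data with planted ground truth. The
default design mirrors the cohort: 3 NH donors contributing lining and
sublining ROIs and 6 RA donors all contributing a lining ROI, four of
which also contribute fibrous- and immune-sublining ROIs — 20 samples
across the five region types. Balanced designs (`donorsPerGroup = n`)
are used for calibration simulations. Per-protein baseline log2
abundance is N(20, 2) (log-normal intensities around 10^6, typical of
DIA protein groups); residual noise SD is 0.5 log2 units and donor
intercepts have SD 0.2 — noise at or below typical planted effects of
1.5–2 log2 units. Per-sample global shifts drawn U(−1, 1) exercise
median normalization. Missingness is missing-not-at-random through a
logistic on underlying log2 abundance with default intercept 14.3 and
slope −0.8 (~15% missing at baseline, concentrated in low-abundance
proteins), emulating DIA intensity-dependent dropout;
`missingParams = c(-Inf, 0)` disables it for calibration runs where
dropout is not the object under test. The cluster-reference generator
covers 99.3% of the study's gene symbols plus 20% unrelated background
features, and raises each linked cluster's expression of its region's
marker genes by `linkLog2`.

What the generator does *not* emulate: peptide-level quantification and
roll-up, batch or run-order effects, correlated protein modules,
shared-marker overlap between regions (planted sets are disjoint), or a
reference built from real single-cell counts. Passing tests therefore
demonstrate correctness of the computations and their calibration under
a plausible generative model, not performance on any particular real
dataset.

# Numerical choices and problem sizes

Tolerances: round-trip TSV I/O is exact to 1e-9 relative; z rows are
checked to 1e-9; orthonormality and PCA reconstruction to 1e-8.
Degenerate inputs are handled by convention where a convention is
defensible (constant reference features get z = 0; zero pooled variance
yields p = 1, d = 0 with a degenerate flag) and by hard errors where
they indicate an upstream mistake (all-missing proteins at imputation,
non-positive intensities at log2, empty filter results, regions with no
reference overlap). Test and validation runs use deliberately small
problem sizes — a few hundred proteins, 4–5 samples per region, 20
seeds for recovery runs, 100–200 replicates for type-I calibration,
1000 permutations for GSEA calibration — chosen so the full suite
completes in minutes while keeping Monte-Carlo error well inside the
asserted bands.

# Known limitations

Donor effects are simulated but not modelled (no random-effect or
blocked contrasts); multi-gene protein groups use a first-token
convention; GSEA FDR values are permutation-based and will not
numerically match any specific external service; the imputation
contract guarantees reproducibility and sane recovery, not optimality;
and printed marker counts from the original cohort are not reproducible
without the deposited matrix, which is out of scope by design.
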