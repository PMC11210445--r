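---
title: "Methods: lipid co-regulation analysis across diagnosis-genotype groups"
author: "lipidlands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lipid co-regulation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidlands)
```

This vignette documents the statistical model behind `lipidlands`, the
choices that were genuinely open when the package was designed, and what
the synthetic-cohort tests do and do not establish about real data.

## The analysis model

The pipeline targets a samples × species abundance table from a targeted
lipid panel (five Biocrates p180 classes: C, PC.aa, PC.ae, SM, lysoPC),
with per-sample metadata including a six-level diagnosis-genotype group
(NCI−, NCI+, MCI−, MCI+, AD−, AD+; "+" marks APOEε4 carriers; NCI− is the
reference throughout).

**Preprocessing.** Species missing in strictly more than 17% of samples are
removed; ties at exactly the threshold are retained. Surviving missing
values are imputed as exactly zero: in a targeted assay a missing
measurement means the species fell below the limit of detection, so zero is
the scientifically defensible value, not an imputation model. Abundances
are converted to mole percent (each species as a percentage of the sample's
summed panel abundance), z-scored per species with the n−1 denominator, and
residualized on covariates. The pipeline order — normalize, standardize,
then residualize — makes the z-scores the modeled response, keeping
residuals comparable across species. A stage machine enforces this order:
each stage checks its input's declared stage and refuses re-application, so
an already-standardized matrix cannot be standardized again by accident.
Zero-variance species are an error, not a silent drop — with zero imputation
they indicate a species that should have been filtered.

**Residualization.** Per species, ordinary least squares on an intercept
plus the covariates (batch and sex dummy-coded), solved by QR; residuals
are exactly orthogonal to the design. For serum, where donors contribute
repeated draws, a linear mixed model with a donor random intercept (REML,
`lme4`) replaces OLS and the *conditional* residuals — observed minus fixed
effects minus the predicted donor intercept — are carried forward, because
downstream analyses treat samples, not donors, as units. Donors with a
single visit are pooled into one shared grouping level so their (otherwise
unidentified) intercepts borrow strength; if *no* donor has repeated
visits the random effect is unidentifiable and the function falls back to
OLS with a message. Per-species non-convergence likewise falls back to OLS
and is recorded in the matrix's lineage. Education is deliberately *not* a
default covariate; education-corrected runs add it to the same
residualization design (`education_mode = "covariate"` in
`pipeline_config()`), flagged in the lineage.

**Differential screen.** Welch's unequal-variance t test (two-sided,
Welch–Satterthwaite df) of every species, each non-reference group against
NCI−. Welch rather than pooled Student is the default because the group
sizes are severely unbalanced (41 vs 6 in the brain design); the pooled
variant remains available via `var_equal = TRUE`. Species with p < 0.05 in
at least one comparison form the candidate set for the network and
clustering stages — an intentionally liberal screen whose purpose is
enrichment, not inference.

**WLCNA.** On the residualized candidate matrix, the network is built from
Pearson correlations (canonical for co-expression-style networks on
z-scored residuals; Spearman is a config option, and is used elsewhere for
sample-profile comparisons where outliers dominate). The adjacency is
unsigned, `a = |r|^β`, so strong anti-correlation counts as adjacency — a
deliberate choice for compositional data where closure induces negative
correlation (see Limitations). The soft power β is chosen as the smallest
candidate whose connectivity distribution fits a scale-free log-log line
with signed R² ≥ 0.8 (10 connectivity bins), falling back to the
conventional default β = 6; at panel scale (30–120 species) the scale-free
criterion rarely binds, which is expected — it was formulated for
thousands of genes. Topological overlap
ω_ij = (ℓ_ij + a_ij)/(min(k_i, k_j) + 1 − a_ij) with
ℓ_ij = Σ_{u≠i,j} a_iu a_uj smooths the adjacency by shared neighborhood;
1 − ω is the clustering dissimilarity.

**Module detection.** Average-linkage hierarchical clustering of 1 − ω with
a *static* cut at `cut_height_quantile` (default 0.99) × the tallest merge
height. The proportional-to-maximum rule is the load-bearing numerical
choice: pure-noise panels produce uniformly tall merges, so the cut falls
below essentially all of them and everything dissolves into singletons
(→ unassigned), while planted blocks merge far below the cut and survive.
A cut at a fixed quantile *of the merge-height distribution* was considered
and rejected: on noise it always leaves a handful of large spurious
clusters. Clusters smaller than `min_module_size` (default 5 — small
because lipid panels are small) are set to grey/unassigned; modules whose
eigenlipids correlate above `merge_correlation` (default 0.75, absolute
value because the network is unsigned) are merged iteratively, largest
correlation first; the size rule is re-applied after merging. Surviving
modules are labeled turquoise, blue, brown, … by descending size. The full
dynamic hybrid tree cut with PAM assignment was left out of scope: at
≤ 120 species the static cut is transparent and auditable, and the tests
show it recovers planted structure.

**Eigenlipids and group statistics.** A module's eigenlipid is the first
principal component of its samples × members submatrix (columns centered,
not rescaled — members are already z-scored). Its sign is arbitrary in an
unsigned network; the convention fixes the mean correlation between scores
and member profiles to be nonnegative. Group-level assessment is one-way
ANOVA of the scores across the six groups plus all 15 pairwise two-sided
Mann–Whitney tests (non-parametric because eigenlipid distributions are
routinely skewed), starred at p < 0.10 / 0.05 / 0.01. Eigenlipids are
computed on the same residualized matrix the modules came from.

**Group-profile correlations.** The (g, h) entry is the mean Spearman
correlation between the species profiles of individual samples of group g
and of group h, over all cross pairs (unordered within-group pairs,
excluding self-pairs, on the diagonal; a single-sample group has an
undefined diagonal entry, reported NA).

**Clustering and enrichment.** K-means on Euclidean distances over the
module's species, Lloyd iterations, best of 50 random restarts (k-means++
seeding was considered and not adopted: at 50 restarts on ≤ 600 samples the
multi-restart contract already dominates initialization quality, and base
R's `kmeans()` is the transparent, widely understood implementation). k is
selected from 2..10 by maximum mean silhouette, ties to the smaller k, with
the inertia curve retained for elbow inspection; a run whose best
silhouette is below 0.25 is flagged "weak structure" rather than blocked.
Each (cluster, group) cell is tested with a two-sided Fisher exact test on
its marginal 2×2 table, *uncorrected* across cells — the cells are
descriptive highlights, not a simultaneous inference family — with
direction (enrichment/depletion) from the odds ratio. Two-sided is assumed
for depletion as well, since a one-sided convention was not compelling.

**Cognition associations.** Per feature: OLS of the cognitive global random
slope (CGRS; or its pathology-adjusted variant) on the standardized feature
plus a covariate preset — `lipid_brain` = {age, sex, education, PMI},
`gene` = {batch, RIN, age, education, sex}, `gene_pathology` adds amyloid
load and tangle density. Standardizing the feature makes betas per-SD and
comparable across species. Complete cases only. Benjamini–Hochberg within
each (outcome, preset) family, never pooled across lipid and gene families.
For serum, one record per donor (the last visit) enters these models rather
than a mixed model: association betas then have the familiar per-donor
interpretation, at some efficiency cost (flagged in the result metadata).

**Mediation.** Path a from `mediator ~ x + controls`, paths b and c′ from
`y ~ x + mediator + controls`, total c from `y ~ x + controls`. Binary
group contrasts (NCI− vs NCI+, NCI− vs MCI−; reference coded 0) are fitted
with a linear-probability model rather than logistic regression — with LPM
the decomposition c = c′ + a·b holds *exactly* by OLS algebra for any
outcome, which makes the indirect effect interpretable and testable; a
logistic variant would break the identity. The indirect effect a·b gets a
percentile bootstrap CI (resampling complete cases, seeded) with Sobel z
as the secondary test. Default 2000 bootstrap replicates.

## The synthetic cohort generator

`generate_lipidomics()` draws log-normal abundances
`exp(μ_i + σ·(√ρ·f_m(s) + √(1−ρ)·ε) + σ·δ_{m,g} + covariate effects
(+ donor intercept))`: per-species baselines μ_i ~ N(log 50, 1) span the
orders of magnitude a real panel shows; each planted module m has a latent
factor f_m giving within-module correlation ρ (default 0.7); δ_{m,g} are
group shifts in units of the total SD σ (`noise_sd`, default 0.3 ≈ a 30%
CV, typical for targeted assays — at this σ the exp() transform attenuates
planted Pearson correlations by under 2%, so ρ is meaningful on the
abundance scale). Default group shifts mirror the motivating biology: a
module-1 shift shared by NCI+ and MCI−, a negative MCI+ shift in module 2
(acylcarnitine-like), and late-disease shifts in module 3. Values below the
per-species `lod_quantile` (default 5%) are censored to missing. The brain
design has 99 single-draw donors with group proportions
(41, 6, 22, 6, 15, 9)/99; serum has 271 donors with truncated-Poisson visit
counts (mean 2, max 5, ≈ 542 draws) and a per-(donor, species) random
intercept (SD 0.3). Education is shifted +3.4 years for NCI+ donors
(matching the observed NCI+ vs NCI− gap) and receives an `a_path`
contribution from the module-1 factor; CGRS is linear in the module-1
factor, education, and disease severity plus noise — so the unsupervised
and supervised stages share one planted signal and the mediation analysis
has a known truth. `simulate_mediation()` provides the clean three-variable
system (x → m → y) for path-recovery checks, and `generate_expression()`
produces batch/RIN/age/sex-structured expression whose planted
CGRS-associations are independent of the generated pathology variables.

What the generator does **not** emulate: instrument drift and batch ×
species interactions beyond additive shifts; informative (abundance-
dependent beyond the LOD quantile) missingness; non-Gaussian factor
distributions; the full 188-metabolite panel beyond the five lipid classes;
and any calibration of effect sizes to the real cohort, whose within-group
variances are not published. Passing tests therefore certify the
*machinery* — that each stage recovers what it is designed to recover under
its own assumptions — not that real brain lipidomes satisfy those
assumptions.

## Problem sizes and numerical choices

The test suite and acceptance script run at deliberately desk-friendly
sizes chosen to keep Monte-Carlo error small relative to the asserted
tolerances: module recovery on 100-sample / 119-species cohorts averaged
over seeds; mixed-model recovery at 50 donors × 4 visits over 10–20 seeds;
mediation at n = 500 with 1000 bootstrap replicates; null calibrations at
100 species × 5 comparisons over 10 seeds. Exact kernels are compared to
enumeration oracles at |Δ| < 1e−12 (TOM) or to machine precision (BH);
Monte-Carlo quantities use tolerances derived from their sampling error.
Two power figures were re-derived from first principles while freezing the
tests: a one-way ANOVA with a +1 SD shift in one of six groups of 20 has
exact noncentral-F power 0.888 (the empirical rate is checked against that
oracle), and pairwise Mann–Whitney tests at n = 15/group need a ≈1.5 SD
shift for ~90% per-comparison power, so the qualitative
"NCI+ and MCI− differ from everyone but not from each other" pattern is
planted at 1.5 SD.

Seeds: a single master seed drives everything; each stochastic stage uses a
child seed derived by a stable hash of the stage name (`derive_seed()`), so
stages can be re-run in isolation and whole runs are bitwise reproducible
(the manifest records MD5 hashes of every output file).

## Known limitations

* **Compositional closure.** Mole percent is a closure operation: when a
  co-regulated module rises, every other species' Mol% must fall, inducing
  negative cross-module correlation that an *unsigned* network reads as
  adjacency. With planted modules occupying half the panel's abundance
  mass, cross-module |r| reaches ~0.5 and modules can genuinely merge; in
  the degenerate case of a panel consisting *only* of a few equal modules,
  no correlation-network method can separate them after closure. Real
  panels, with many uncorrelated background species, sit in the benign
  regime — but module merges in small panels should be inspected with this
  artifact in mind (e.g., via the eigenlipid correlation matrix).
* The static cut trades the adaptivity of dynamic tree cut for
  transparency; very unequal module tightness can shave members into grey.
* The linear-probability mediation model can predict outside [0, 1] for
  extreme exposures; it is used for its exact effect decomposition, not for
  probability forecasts.
* Table-style reconstruction of ANOVA from printed means/SDs inherits the
  rounding of those summaries; agreement is expected to ~0.01–0.05 in p,
  not machine precision. A skewed covariate summarized by mean/SD (e.g.,
  post-mortem interval) may have been tested non-parametrically in the
  source material; reconstruction cannot distinguish that, so such rows are
  not part of the package's checked surface.

## Session info

```{r}
sessionInfo()
```
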