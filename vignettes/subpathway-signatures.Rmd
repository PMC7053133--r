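---
title: "Prognostic subpathway signatures: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prognostic subpathway signatures: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subpathSig)
```

# Scope

`subpathSig` implements a multi-cohort strategy for discovering and
validating prognostic *functional* signatures — subpathways and pathways
rather than single genes — from survival-annotated expression cohorts.
This vignette documents the statistical model at each stage, the tunable
parameters and why their defaults are what they are, what the synthetic
generator does and does not emulate, and the places where the design was
genuinely open and a choice had to be made.

# The pipeline stage by stage

## Subpathway mining

Pathways enter as undirected graphs (gene nodes, unordered edges; TSV or
SIF edge lists via `readEdgeList()`). A subpathway is a **maximal set of
genes whose pairwise shortest-path distances are all at most `k`**. This
"distance similarity" rule is realized exactly as stated: build the k-th
graph power (connect every pair at distance ≤ k) and enumerate its maximal
cliques (`igraph::max_cliques()`). Disconnected pairs have infinite
distance and never share a subpathway; an isolated gene forms a singleton.

- `k` (default **3**, dimensionless graph distance): the locality scale of
  a functional module. k = 1 gives ordinary cliques (very fragmented);
  large k dissolves into connected components. 3 is the conventional
  default for this rule and is what the package's reference analyses use.
- Output order is deterministic (descending size, then lexicographically
  smallest member), so subpathway indices `path:XXXXX_j` are stable.

The correctness contract is strong: on every random graph of ≤ 8 nodes the
test suite compares the output against brute-force enumeration of all
maximal distance-bounded subsets.

## Single-sample activity

For sample *s* with |N| genes, ranks r = 1 (highest expression) … |N| with
average ranks for ties, and weights

$$w_{g,s} = r_{g,s}\,e^{\,\sigma\, r_{g,s}/|N|},\qquad \sigma = +1
\text{ (default) or } -1 .$$

Raw subpathway activity is the contrast of mean weights between member and
non-member genes, and each feature is z-normalized across samples.

Numerical and convention choices, all of which are deliberate and tested:

- **Exponent sign.** The weight formula is implemented as printed, with
  $e^{+r/|N|}$, even though such weights *grow* with rank (the
  lowest-expressed genes dominate). Descriptions of this weighting scheme
  sometimes call the weights "decreasing", so `sign = -1` is offered as an
  explicit alternative ($r\,e^{-r/|N|}$); the default is the literal
  formula. Because every downstream quantity is either a contrast or
  rank-based, both conventions yield internally consistent pipelines.
  One visible consequence of the default: activity is *anti*-correlated
  with the member genes' expression.
- **Ties** share average ranks — deterministic and standard.
- **Normalization SD** is the population SD (divide by *n*), fixed and
  documented so that small-cohort scores are reproducible to the last bit.
  A constant raw row cannot be z-scored; it becomes all zeros and is
  flagged in `rowData(activity)$constant`.
- **Missing values are rejected** at input: the weighting needs a complete
  ranking, so imputation is the caller's responsibility.
- **Gene-level "activity"** is the expression value itself (normalized the
  same way), since a singleton contrast would be dominated by the
  complement mean.

Rank-basedness gives a useful invariance: any within-sample monotone
transform of expression (log, quantile-normalization, counts vs CPM)
leaves the activity matrix unchanged. This is why microarray intensities
and RNA-seq counts can be scored by the same machinery without
cross-platform normalization (which is explicitly out of scope).

## Cox screening and integrated scoring

Each feature's normalized activity is screened by univariate Cox
proportional hazards regression per training cohort (Breslow tie handling,
convergence tolerance 1e-8; two-sided Wald p-values — the convention of
standard survival software). Degenerate fits (no events, constant
covariate, non-convergence, collinearity) are **flagged with p = 1**
rather than raised, so a screen over hundreds of features never crashes on
one pathological row.

For cohort combinations (all subsets of sizes {5, 6, 7} of the 7 training
cohorts — 29 combinations),

$$\mathrm{ipScore} = \frac{1}{N}\sum_{i=1}^{N} -\log_{10} p_i ,$$

with p-values clipped below at 1e-300. Ranking is by descending ipScore
with lexicographic tie-break (ipScore is the only score computed, so it is
the ranking key); the top 30 per combination feed both the serial
cumulative sets (the 28 prefixes of sizes 3–30, assessable on test
cohorts) and the frequency count.

**Frequency definition.** Selection counts a feature's membership over
*all* 29 top-30 lists with cutoff ≥ 20. A variant counting only the other
28 lists (`exclude_self = TRUE`) is provided; the two differ by at most 1
and the all-lists reading matches the selection rule as stated. Ranking
and counting are done **per feature level** (gene / subpathway / pathway),
since mixing levels in one top-30 list would let the more numerous level
crowd out the others.

**Test-set assessment** of a multi-feature set clusters samples by K-means
(K = 2, Euclidean) on the set's standardized activity rows and compares
the two groups by a log-rank test. K-means is made deterministic by
initializing centers at the per-feature 25th/75th percentile points
(Lloyd, ≤ 100 iterations); the higher-mean cluster is "high". For a single
feature this reduces exactly to the 1-D percentile-initialized split
(`splitTwoGroups()`). Both the Cox p (continuous activity) and the
log-rank p (K = 2 groups) are available; Cox p is the default ranking
input, log-rank the default set-level assessment.

## Meta-analytic validation

Per-cohort log hazard ratios (continuous normalized activity as the
covariate — the default; a high/low group variant can be built from
`splitTwoGroups`) are pooled on the **log scale** by inverse variance.
Heterogeneity uses Cochran's Q about the fixed-effect pooled value,
$I^2 = \max(0, (Q - df)/Q)\cdot 100$, and the DerSimonian–Laird moment
estimator for $\tau^2$ (floored at 0) — DL because it is the default of
the standard meta-analysis software this workflow mirrors, and no
alternative estimator is prescribed for this procedure. Model choice is
automatic: fixed-effect when $I^2 < 50\%$ (the conventional substantial-
heterogeneity threshold), DL random-effects otherwise; the choice is
recorded in the result. Leave-one-out sensitivity, platform subgroups
(microarray vs RNA-seq) and tabular funnel data (±1.96·SE pseudo-CIs over
an SE grid) complete the validation; funnel symmetry is assessed visually
from the exported table, so no Egger/Begg test is included. The in-package
pooling is cross-checked against `metafor::rma` (FE and DL) in the unit
tests.

## Drug sensitivity and chemotherapy response

Activity is correlated with log IC50 by Spearman rank correlation within
the classical-subtype subset. Significance uses a **subset permutation
test**: B (default 10,000) random subsets of the same size are drawn from
all cell lines, and p = N/B where N counts null correlations *strictly
below* the observed one. This is a left-tail test as stated — sensible for
the expected negative correlation (higher protective activity, greater
drug sensitivity); the documentation warns about positive observed
correlations and a two-sided option is provided. Null subsets may
coincide with the true classical subset; they are retained (excluding
them would bias the null). The minimum subset size is 2 so that the test
can be checked against exhaustive enumeration on tiny inputs; sizes below
4 warn, as the rank correlation is then degenerate (±1).

Response groups (CR/PR/SD vs PD by default) are compared by a two-sided
Wilcoxon rank-sum test: exact when both groups have ≤ 10 samples and no
ties, otherwise the tie-corrected normal approximation.

# The synthetic generator

`generateCohorts(simulationConfig(...))` builds the multi-cohort inputs
the pipeline assumes, with a planted ground truth:

- **Expression**: i.i.d. per-gene Gaussian noise (SD `noise_sd`, default 1)
  around gene baselines ~ N(6, 1.5) on log2 scale, plus cohort-specific
  per-gene mean shifts ~ N(0, `cohort_shift_sd` = 0.2) to mimic mild
  inter-study heterogeneity. RNA-seq-flavored cohorts (by default the last
  two of eleven, mirroring a 9 microarray + 2 RNA-seq design) are
  exponentiated and rounded to counts — rank-based scoring makes this a
  near-no-op apart from low-count ties, which is exactly the property it
  exercises.
- **Planted subpathway**: `planted_set_size` (10) member genes share a
  latent per-sample factor f ~ N(0,1) through an additive shift of
  `factor_loading` (2) log2-units per SD, so the set's normalized activity
  tracks f (|Spearman| > 0.5 is a tested contract at n = 200).
- **Survival**: exponential proportional hazards with linear predictor
  `planted_log_hr` (−0.5) times the planted set's normalized activity *as
  computed by the package's own scoring* — so the Cox screen's estimand
  equals the planted coefficient by construction, and parameter recovery
  (pooled log HR within ±0.1 over 11×500 samples) is a meaningful test of
  the whole chain. Baseline hazard 0.05/month (median survival ≈ 14
  months, realistic for advanced pancreatic cancer); independent
  exponential censoring with its rate tuned by root-finding so the
  expected censored fraction equals `censor_rate` (0.3).
- **Decoys**: 200 random gene sets of the planted size. The count is a
  deliberate scale-down of the ~1800-subpathway universe of a real
  KEGG-derived collection: large enough that a top-30 list is an actual
  filter (30 of 201), small enough that the reference analyses run in
  seconds per cohort.
- **Cell lines and drugs**: 60 cell lines scored like a cohort; within the
  classical fraction (0.45) log IC50 is coupled to activity through a
  Gaussian copula with Pearson parameter 2·sin(π·ρ/6) so the *rank*
  correlation targets `ic50_rho` (−0.5); non-classical lines are
  uncoupled. Four drugs named after the standard chemotherapy agents of
  this disease setting. Response labels threshold activity + N(0,1) noise
  at its quartiles into PD/SD/PR/CR.
- **Determinism**: everything runs under the config seed and restores the
  caller's RNG state; identical config + seed is bit-identical.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: probe effects, batch structure, and
normalization artefacts of real microarrays; library-size and
overdispersion structure of real RNA-seq; correlated pathway topology
(decoys are random sets, not graph-mined modules); non-proportional
hazards or informative censoring; cohort-level confounding between
platform and effect size. Results on synthetic bundles demonstrate the
pipeline's statistical correctness and calibration, not biological
validity of any particular signature.

# Reference problem sizes

The test suite and the acceptance script run the full pipeline at 7
training + 4 test cohorts × 500 samples × 1000 genes × 201 features
(about a minute end-to-end), replicate-based contracts at one cohort ×
300–500 samples × 150 genes, null calibration over 200 features spread
across 4 independent cohorts (activities scored on a shared expression
matrix are cross-correlated, so a single-cohort fraction of p < 0.05 is
overdispersed; pooling independent cohorts keeps the type-I estimate
stable), and permutation checks at B = 500–10,000. These sizes were chosen
so every statistical contract has useful power while the whole suite stays
fast enough to run routinely.

# Known limitations

- The printed weight formula (growing with rank) and the verbal
  "decreasing weights" cannot both be honored; the formula wins by
  default and the alternative is one switch away.
- Frequency selection among correlated decoys admits ties at the maximum
  count; selection reports all candidates at the cutoff rather than
  forcing a unique winner (the subsequent biological triage among
  candidates is a judgment step, deliberately not automated).
- Meta-analysis assumes the per-cohort log HR estimates are approximately
  normal with known SEs; very small cohorts (few events) violate this.
- The permutation test's left tail is only meaningful for negative
  observed correlations; use the two-sided option otherwise.

```{r example, eval = FALSE}
cfg <- simulationConfig(seed = 1)
bundle <- generateCohorts(cfg)
disc <- runDiscovery(bundle)
val <- runValidation(bundle, activity = disc$activity)
val$meta
```
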