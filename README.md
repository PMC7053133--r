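# subpathSig

Discovery and validation of **prognostic functional subpathway signatures**
from multi-cohort transcriptomes.

In cancers with few robust gene-level prognostic markers (the motivating
setting is pancreatic ductal adenocarcinoma), single genes screened in one
cohort rarely replicate in the next. `subpathSig` implements an integrated
strategy that works at the level of *subpathways* — locally connected gene
modules mined from pathway graphs — and scores each feature's prognostic
evidence jointly across many training-cohort combinations before selecting
a signature, then validates the selected signature by meta-analysis across
all cohorts and by its association with drug sensitivity and chemotherapy
response.

## The method

**Subpathway mining.** A pathway is an undirected graph whose nodes are
genes. A subpathway is a *maximal* gene set in which every pair of genes
lies within shortest-path distance *k* (default *k* = 3) — equivalently, a
maximal clique of the graph's *k*-th power.

**Single-sample activity.** For each sample *s*, genes are ranked in
descending order of expression (rank *r* = 1 is the highest) and weighted

> w(g, s) = r(g, s) · exp(r(g, s) / |N|),

where |N| is the number of genes. The raw activity of subpathway *i* is the
in-set/out-of-set contrast of mean weights

> sPA(i, s) = mean{ w(g, s) : g ∈ i } − mean{ w(g, s) : g ∉ i },

and activities are z-normalized per feature across samples (population SD).
Gene-level features use the expression value itself, normalized the same
way.

**Integrated prognostic score.** Each feature's normalized activity is
screened by univariate Cox regression in every training cohort. For each of
the 29 combinations of 7 training cohorts (all subsets of sizes 5, 6 and
7),

> ipScore = mean over the combination's cohorts of −log10(Cox p).

The top 30 features of each combination are recorded; the 28 cumulative
prefix sets (sizes 3–30) can be assessed on held-out test cohorts via K = 2
clustering of samples and a log-rank test. Features appearing in ≥ 20 of
the 29 top-30 lists are the selected candidates, and their relevance to a
reference gene catalogue is quantified by a hypergeometric test.

**Validation.** Per-cohort log hazard ratios of the selected signature are
pooled by inverse-variance meta-analysis: fixed-effect when Cochran's
I² < 50 %, DerSimonian–Laird random-effects otherwise, with leave-one-out
sensitivity, platform-subgroup (microarray vs RNA-seq) pooling, and funnel
data export. Drug association uses Spearman correlation of activity with
log IC50 within the classical molecular subtype, with a subset permutation
test (p = N/B over B = 10,000 redraws of subsets of the same size), and a
Wilcoxon rank-sum contrast of activity between CR/PR/SD and PD response
groups.

A synthetic multi-cohort generator (`generateCohorts`) plants a protective
subpathway (exponential proportional-hazards survival with log HR −0.5 per
SD of its normalized activity by default) so the entire pipeline is
testable end-to-end without external data.

## Worked example

```r
library(subpathSig)

cfg <- simulationConfig(n_cohorts = 5, samples_per_cohort = 200,
                        n_genes = 300, n_decoy_sets = 50, seed = 42)
bundle <- generateCohorts(cfg)
bundle
#> SyntheticCohortBundle: 5 cohorts (cohort01, ..., cohort05)
#>   planted subpathway 'path:00982_1'; 51 feature sets; 60 cell lines; 4 drugs

disc <- runDiscovery(bundle, train_cohorts = names(bundle@expression)[1:4],
                     sizes = c(3L, 4L), top_k = 10L, cutoff = 4L)
head(disc$frequency, 3)
#>        feature count selected      level
#> 1 path:00982_1     5     TRUE subpathway
#> 2 path:10003_1     5     TRUE subpathway
#> 3 path:10025_1     5     TRUE subpathway

val <- runValidation(bundle, activity = disc$activity, B = 2000)
val$meta
#> MetaResult (fixed-effect, 5 studies)
#>   pooled HR 0.551 [0.502, 0.605], p = 8.11e-36
#>   Q = 2.429 (df 4), I2 = 0.0%, tau2 = 0.0000
head(val$drug, 2)
#>          drug        rho n_classical perm_N perm_B perm_p
#> 1  irinotecan -0.5726496          26      0   2000  0e+00
#> 2 gemcitabine -0.6964103          26      1   2000  5e-04
```

The planted subpathway `path:00982_1` tops every per-combination ranking
(count 5 of 5 combinations) and is selected; its pooled hazard ratio of
0.551 per SD of activity (CI excluding 1, I² = 0 so a fixed-effect model is
used) recovers the planted protective effect, and its cell-line activity is
negatively correlated with IC50 within the classical subtype (permutation
p ≤ 0.0005 for irinotecan and gemcitabine here).

Lower-level building blocks are exported individually, e.g.

```r
rankWeights(c(TP53 = 8.1, KRAS = 6.4, CYP2C8 = 3.2))$weights
#>     TP53     KRAS   CYP2C8
#> 1.395612 3.895468 8.154845
mineSubpathways(pathwayGraph("path:00982", edge_list), k = 3)
```

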