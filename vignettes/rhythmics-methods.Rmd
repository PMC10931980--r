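---
title: "Methods: circadian calling, differential analysis, and CLR network inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circadian calling, differential analysis, and CLR network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmics)
library(dplyr)
```

# Scope and data model

`rhythmics` analyses diel time-course omics experiments with a
genotype-by-treatment design: a wild type (`WT`), a hormone-biosynthesis
mutant (`MUT`), and the treated mutant (`MUT_GA`), grown under a 16 h
light : 8 h dark cycle. The motivating system is gibberellin (GA)-mediated
rhythmic leaf growth in maize, where GA deficiency dampens diel growth
rhythms and exogenous GA restores them. The transcriptome is sampled at
t = 0, 4, 8, 12, 16, 20, 24, 30, 36, 42, 48 h after treatment with 2
biological replicates; the metabolome at t = 12, 36 h (light) and 20, 42 h
(dark) with 3 replicates.

Everything revolves around one container, `tc_experiment`: a non-negative
features x samples matrix (FPKM for expression, arbitrary abundance units
for metabolites) plus a sample sheet (`condition`, `time_h`, `replicate`,
and a light/dark flag derived from the photoperiod). All user-facing
functions take this container or plain data frames and return tibbles, so
stages chain with the pipe.

# The synthetic-data generator

Because the analyses are threshold-driven, every stage is validated on
simulated data with planted ground truth (`sim_config()`,
`generate_experiment()`, `generate_metabolome()`). The generator emulates
the study design above and plants four kinds of structure:

* **Rhythms.** A rhythmic gene's expectation is
  `baseline * 2^offset_c(t) * (1 + A * cos(2*pi*(t - phase)/24))`, with
  phase uniform on [0, 24) and relative amplitude `A` uniform on
  [0.4, 0.8] by default. Non-rhythmic genes omit the cosine.
* **Genotype offsets and restoration.** A fraction `frac_deg` (default
  0.3) of genes carries a log2 offset in the mutant, |offset| uniform on
  [1, 3] with random sign. Under treatment the offset decays as
  `offset * exp(-restore_rate * t)` (default 0.1 / h), so the treated
  mutant converges to WT over the 48 h window — the "gradual recovery"
  pattern the design is meant to produce.
* **Regulation.** `n_edges` TF -> target links add the TF's centred latent
  log2 profile to the target (`coupling` = 1 by default). TFs are drawn
  preferentially from the rhythmic genes: a perfectly flat regulator
  carries no information to its targets, and a regulatory benchmark built
  on flat TFs would be vacuous.
* **Metabolite coupling.** A fraction of metabolites track a driver gene's
  latent profile, re-centred on the driver's WT mean so that genotype
  offsets and their restoration — not only the oscillation — propagate
  into the metabolome. The remaining metabolites are flat.

Observed values multiply the expectation by mean-one lognormal noise with
coefficient of variation `noise_cv` (default 0.1; the within-replicate
scatter of the real data is not published, so this is an exposed choice).
Multiplicative noise keeps values strictly positive and makes `noise_cv`
directly comparable with relative amplitude. Fractions convert to counts
by rounding half-up, so truth counts are deterministic; one integer seed
fixes the entire simulation byte-for-byte.

What the generator does *not* emulate: count-level overdispersion,
batch effects, missing values, unequal replicate numbers, or secondary
(non-24 h) periodicities. Passing recovery tests on this generator
therefore demonstrates correctness of the decision rules and estimators
under the stated noise model, not performance on arbitrary real data.

# Circadian calling

A feature is circadian in a condition when it passes **both** of:

1. **Cosine screen** (`cosine_screen()`): per-time-point replicate means
   are correlated with 24-h cosine templates over a 1-h grid of candidate
   peak phases (24 candidates, matching the 24 hourly phase groups used
   downstream). `R` is the best correlation; `CV` — the population
   sd/mean of the per-time-point means — proxies relative amplitude. The
   defaults require `CV >= 0.3` and `R >= 0.9`, both inclusive.
2. **JTK-style rank test** (`jtk_cycle()`): all replicate observations are
   compared with phase-lagged cosine references via the Kendall-type
   statistic S over reference-comparable pairs. Repeated sampling times
   and the cosine's symmetry tie the reference, partitioning samples into
   ordered groups; S is then a shifted Jonckheere–Terpstra statistic and
   its exact null for a given tie pattern is computed by convolving
   Mann–Whitney (Gaussian-binomial) distributions. The exact null is used
   up to 30 samples; beyond that a normal approximation with continuity
   correction takes over. The per-feature p is Bonferroni-corrected over
   the lag grid (2-h steps by default), then Benjamini–Hochberg adjusted
   across features within the condition; the default calls `q < 0.01`.

Combining the two criteria with AND follows the convention of requiring
agreement between an amplitude-shape screen and a nonparametric test;
`combine = "or"` is available. The period is fixed at 24 h — period
estimation is out of scope. Replicates are averaged for the cosine screen
(the template fit concerns the mean profile) but kept separate for the
rank test, which benefits from every observation.

Numerical details worth knowing:

* Because the two-sided statistic gives a lag and its antiphase identical
  p, the reported `best_lag` is the concordant (largest-S) lag among the
  minimum-p lags, then the smallest such lag.
* `jtk_tau` is S divided by the number of reference-comparable pairs, so
  perfect concordance scores 1 even under a tied reference.
* Constant profiles return `R = 0` with a `degenerate` flag and JTK p = 1;
  all-zero profiles are retained as non-circadian rather than erroring.
* The exact-null tables are cached per tie pattern, so a 1,000-gene,
  22-sample condition costs well under a minute on one core.

On the default study conditions (1,000 genes, 30% rhythmic, amplitudes
0.4–0.8, `noise_cv` 0.1), the WT-condition recovery measured by the
acceptance suite is sensitivity ≈ 0.95, zero false positives among flat
genes, and phase error ≤ 2 h for ≈ 100% of true positives. The residual
sensitivity loss is concentrated at planted amplitudes near 0.4, where the
profile CV sits almost exactly at the 0.3 screen boundary; this is a
property of the published threshold at this design, not of the estimator.
Recovery is evaluated in the WT condition because the treatment condition
deliberately superimposes a decaying level trend on ~30% of genes, which
confounds planted rhythm parameters with the restoration transient.

# Differential expression and restoration

`deg_call()` computes, per matched time point, the log2 fold-change
`log2((mean_A + 1)/(mean_B + 1))` on the FPKM scale and a Welch t-test on
log2(FPKM + 1) replicate values, with BH adjustment across features within
each time point. A gene is a DEG when at least one time point shows
|log2FC| >= 1 and q < 0.05. The t-test is a deliberate, documented
simplification of count-model engines: the threshold logic is what the
analysis depends on, and it is reproduced exactly. With two replicates per
cell the per-time-point p-values are coarse; the |log2FC| >= 1 requirement
is what keeps the false-positive rate negligible, and the synthetic
recovery test shows >= 90% recall on 2-log2-unit planted offsets.

`classify_restoration()` combines the WT-vs-mutant and treated-vs-mutant
contrasts at the genotype-significant time points: a gene lower in the
mutant that the treatment raises is `up_restored`, the mirror case
`down_restored`, everything else `other`.

# Metabolites: OPLS-DA VIP and DAM calling

`fit_oplsda()` implements two-class orthogonal projections to latent
structures discriminant analysis by NIPALS: one orthogonal-signal
correction component followed by one predictive PLS component, on centred,
unit-variance-scaled log2(abundance + 1). VIP is taken from the first
predictive component; with a single predictive component the definition
collapses to `VIP_j = sqrt(p) * |w_j| / ||w||`, which satisfies
`sum(VIP^2) = p` identically — asserted to 1e-6 on every fit. One
orthogonal component is the default because nothing in the source design
motivates more; `n_orth` is exposed.

`dam_call()` flags a metabolite as differentially accumulated when
`VIP >= 1` **and** the raw group-mean fold change is >= 2 or <= 0.5 (all
thresholds inclusive, fold change pooled over matched samples). Treatment
direction (`up_by_GA` / `down_by_GA`) compares the mutant-vs-WT deficit
with the treated-vs-mutant response sign. Note that VIP is a *relative*
measure — mean VIP² is 1 by construction — so DAM calling is only
meaningful when responders are a minority against a stable background.

`rhythmic_dam()` addresses a rule the source design leaves unstated: with
only two light (12, 36 h) and two dark (20, 42 h) metabolome time points,
a metabolite is called rhythmically accumulating when the sign of
(dark − light) replicate means agrees across both diurnal cycles *and* a
pooled dark-vs-light Welch test gives p < 0.05. This is a constructed
criterion; it should not be expected to reproduce any particular published
metabolite list. `dam_class_summary()` rounds percentages half-up to one
decimal and drops a trailing ".0", matching the convention of the printed
tables (e.g. 11/55 prints as "20%").

# CLR network inference

`build_grn()` implements the context likelihood of relatedness algorithm:

1. Pairwise mutual information over the analysis genes (TFs ∪ targets) on
   log2(FPKM + 1) profiles, by default with the third-order B-spline
   soft-binning estimator with 6 bins (the estimator of the original CLR
   work; built on `splines::splineDesign`, non-negative by construction).
   Equal-frequency hard binning is available as `estimator = "bins"`.
2. Per-gene background standardization: `Z_i(j) = max(0, (MI_ij - mu_i) /
   sigma_i)` over gene i's off-diagonal MI values.
3. The combined score `f = sqrt(Z_i^2 + Z_j^2)`, with edges retained when
   `f > 4.5` — strictly, so f = 4.5 exactly is *not* an edge.

All conditions' samples are concatenated by default (66 observations);
a single condition can be selected. The background set for mu and sigma is
the full analysis gene set. On the planted benchmark (20 TFs, 200 targets,
40 edges, `noise_cv` 0.1) the f-ranking's area under the precision-recall
curve is >= 5x the edge-density baseline. Recovering any particular
published edge list is not a goal: the 4.5 cutoff's provenance does not
pin down the MI estimator, so absolute edge counts are
estimator-dependent (the estimator and bin count are recorded in the
result's metadata attribute).

# Integration

`gene_metabolite_correlation()` pairs the two experiments on shared
(condition, time) cells — all three conditions at the four metabolome
time points, n = 12 cells — using per-cell replicate means, Pearson by
default. A within-condition pairing (n = 4) would make the t-transform
p-values nearly meaningless, which is why pooling across conditions is the
default and is stated here prominently. Stars follow the usual strict
convention (`**` p < 0.01, `*` p < 0.05); a BH-adjusted q across the whole
gene x metabolite grid is reported alongside the raw p.

`assemble_network()` joins CLR edges (TF -> target) with significant
correlations (gene — metabolite) into a typed tripartite network whose
node flags carry the circadian and DAM verdicts; `export_network()` writes
SIF and GraphML (via igraph), and `read_network()` round-trips them.

# Pipeline and reproducibility

`run_pipeline()` executes simulate/load → circadian calling → DEGs and
restoration → pattern clustering → DAMs → CLR → integration, writing every
stage table as TSV (floats at 6 significant digits), the echoed
configuration, and a JSON summary whose counts equal the row counts of the
stage tables. One master seed drives the simulation and the clustering
restarts, so two runs with the same configuration are byte-identical — the
determinism is asserted in the test suite. Expression matrices written by
`write_experiment()` use 17-significant-digit decimal representation and
are re-read with the C library's correctly rounded parser, so write/read
round-trips are bit-exact.

Problem sizes used by the test and acceptance suites — 1,000 genes for
rhythm recovery, 2,000 white-noise profiles for null calibration, a
220-gene network benchmark, 150-gene pipeline runs — were chosen as the
smallest sizes at which the binomial/recovery bounds being asserted are
statistically meaningful.

# Known limitations

* The JTK exact null assumes continuous (untied) observations; tied data
  contribute zero-sign pairs to S but the null is not re-derived for data
  ties.
* With 2 replicates the Welch test is low-powered; the DEG caller leans on
  the fold-change threshold, as the source analysis does.
* `pct_dark`-style summaries and the rhythmic-DAM rule are constructed
  definitions for a 4-point metabolome; treat them as conventions, not
  inference.
* k-means pattern clustering is seed-stable but not label-stable across
  k; the hierarchical option gives a deterministic alternative.
* CLR reports an undirected association score restricted to TF -> target
  pairs; it does not infer causal direction.
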