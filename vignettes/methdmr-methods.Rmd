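---
title: "Methods: windowed DMR discovery and liver-metastasis risk modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed DMR discovery and liver-metastasis risk modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `methdmr`, the
parameters that matter, the design decisions taken where the procedure
was genuinely open, and what the synthetic-cohort tests do and do not
establish about real data.

# The analysis problem

Targeted bisulfite sequencing of a colorectal cancer cohort yields, for
every sample, per-CpG counts of methylated and unmethylated read calls.
The package answers two questions. First, which genomic regions are
differentially methylated between stage II patients whose disease later
metastasized (unfavorable prognosis) and those who stayed
metastasis-free, in a way that also tracks tumor progression and falls
in regulatory (promoter) territory — the *prognostic markers*. Second,
can the methylation profile of a resected primary tumor predict future
liver metastasis (LIM) — the *predictive model*.

# Windowed differential methylation

## Aggregation

CpG sites are pooled on a fixed, non-overlapping grid of 1000-bp windows
anchored at coordinate 1 (window *k* spans `[1000k + 1, 1000(k + 1)]`,
1-based inclusive; all genomic intervals in the package are 1-based
inclusive, converted to 0-based half-open only at BED boundaries). A
site contributes to a sample's window only when its read coverage in
that sample is at least `min_site_coverage = 2`; this is a per-site,
per-sample read-depth floor. The window methylation level is total
methylated calls over total calls — dividing by read calls (not by the
number of CpG positions) is the only reading that keeps the level in
[0, 1] for multi-read data. Plus- and minus-strand calls at a CpG
dinucleotide are treated as independent sites; no merging rule is
applied, which may shift absolute site counts relative to pipelines
that pool strands.

## The test

Each window is tested with a binomial logistic regression of the
per-sample (methylated, unmethylated) counts on a two-level group
factor, and the group term is assessed by the 1-df likelihood-ratio
chi-square. Because the model is saturated in the grouping, the fitted
proportions are exactly the pooled per-group proportions and the
statistic has a closed form (equivalently, the G-test on the pooled
2×2 table). Two consequences:

* the fit cannot fail, even under complete separation — the log-
  likelihood terms with zero counts vanish under the `0·log 0 = 0`
  convention, so no pseudo-count fallback is ever needed;
* the test is exact maximum likelihood, not an iterative approximation,
  and is fully vectorized across windows.

The reported effect (`meth_diff`, percentage points) is the unweighted
mean of per-sample levels in the test group minus the control group,
matching the view of the window level as a per-sample quantity; a
pooled-count variant is available via `diff_method = "pooled"`.
Windows where a group has no covered sample are flagged untestable
(`p = NA`). FDR control is Benjamini–Hochberg (`stats::p.adjust`);
q-values are filled batch-wise so that the adjustment always refers to
one well-defined family of tests.

The binomial working model ignores extra-binomial (biological)
variation between samples. This mirrors the widely used
logistic-regression DMR callers; with strongly overdispersed data the
test is anti-conservative, which is why the synthetic generator's
default dispersion is kept near the binomial limit (below) and why the
package documents this as its main statistical limitation.

# The prognostic funnel

Three filters are computed on three deliberately different sample
bases and intersected:

1. **Candidate gate** — unfavorable vs favorable stage II primaries
   only; keep windows with q ≤ 0.05 and |Δ| ≥ 10 percentage points.
2. **Stage trend** — all 70 tumor and tumor-adjacent samples, grouped
   adjacent → I → II → IV; keep windows whose Jonckheere–Terpstra
   two-sided p ≤ 0.05. A window needs a non-`NA` level in every group;
   windows failing that are excluded and counted.
3. **Promoter overlap** — sample-free; keep windows sharing ≥ 1 base
   with a promoter.

The intersection object reports every Venn region so the funnel is
fully auditable. Marker direction (hyper/hypo) is the sign of the
candidate-gate difference: hypermethylated means elevated in the
unfavorable group. Wilcoxon rank-sum screens (age split at 60 years;
smoker vs non-smoker with unknowns excluded; BH across markers,
flagged at q < 0.1) check that markers are not explained by these
confounders.

## Jonckheere–Terpstra details

The statistic is the sum over ordered group pairs of
`#{x < y} + 0.5·#{x = y}`. The test is two-sided — both increasing and
decreasing trends are biologically meaningful (hyper- and
hypomethylated markers both occur). Modes:

* **normal**: tie-corrected null variance (Hollander–Wolfe form) with a
  0.5 continuity correction. Enumeration of the exact assignment
  distribution shows this approximation is accurate (within 0.02 at
  every achievable statistic value) for near-balanced groups from a
  pooled n of about 10 upward, which is the regime where it is used;
  for very small or extremely unbalanced groups — e.g. sizes (1, m),
  whose null is a discrete uniform — no smooth approximation can track
  the exact two-sided p, and mid-range deviations reach ≈ 0.1.
* **permutation**: label permutations preserving group sizes; two-sided
  empirical p with add-one smoothing, reproducible given
  `(seed, n_perm)`.
* **auto** (default policy): permutation for pooled n ≤ 12, normal
  above — so the normal approximation is never relied on below its
  accurate regime.

## Promoter definition

Promoters span 1500 bp upstream to 500 bp downstream of the TSS,
strand-aware ("upstream" is strand-relative), clipped at coordinate 1;
2001 bp when unclipped. The TSS is taken per gene (the paper-style
gene-level counting); a per-transcript mode exists behind the
`feature` argument. Overlap semantics are BEDTools-compatible (≥ 1
shared base); when a window overlaps several promoters the gene whose
TSS is nearest the window midpoint is reported, ties broken by
lexicographic gene id — deterministic by construction.

# The predictive model

Candidates for the LIM model are re-tested per training set at the
stricter gate (|Δ| ≥ 20 pp, q ≤ 0.05). The classifier is an
L1-penalized logistic regression (`glmnet`): columns mean-imputed and
standardized to zero mean/unit variance on the training data, penalty
chosen by stratified 10-fold cross-validated deviance at `lambda.min`
(the one-standard-error rule is available), penalized coefficients
reported without refit. Standardization inside every fold keeps the
penalty comparable across folds.

Leave-one-out cross-validation wraps the *entire* selection: for each
of the n samples, candidates are re-selected on the other n − 1, the
model is fit there, and the held-out probability is recorded. The
held-out sample therefore never influences selection, standardization
or penalty choice — a property asserted by a perturbation (leakage)
test. The inner CV fold assignment of fold *i* derives from
`seed + i`; the LOOCV folds themselves are deterministic.

Two scoring conventions matter:

* A fold whose training set loses a class is scored at its training
  prevalence and flagged (a boundary case).
* A fold with no candidates, or whose LASSO selects no markers, is
  scored at the uninformative constant 0.5. Scoring such folds at
  their training prevalence would encode the held-out label — the
  prevalence is (k − 1)/(n − 1) when a positive is held out versus
  k/(n − 1) for a negative — and drives the pooled null AUC toward 0,
  the known pessimistic-bias artifact of pooled LOOCV. The constant
  removes the artifact; under label permutation the pooled AUC is
  centred on 0.5 as it should be.

The pooled ROC sweeps thresholds over the unique scores; the AUC is
the Mann–Whitney concordant-pair fraction with ties counted 0.5
(identical to the trapezoidal area), and the reported
sensitivity/specificity pair sits at the Youden-maximizing threshold,
ties resolved toward higher specificity. The final model refits on all
samples, stores its standardization, and scores external samples with
either `mean_impute` (missing markers at the training mean, hence zero
contribution on the standardized scale) or `drop_renorm` (missing
coefficients removed, predictor recentred by their training-mean
contribution); the two coincide under the training standardization,
and the policy used is recorded.

# Survival

LIM-free survival uses the product-limit estimator and the two-group
log-rank test from the `survival` package, with events before
censoring at tied times. Patients dying LIM-free are treated as
censored. Time is in days; rate-at-time queries use 365-day years.
For stratification, samples are split by their pooled LOOCV score at
the model threshold (predicted LIM-positive vs negative). The
degenerate comparison with no events in either group returns p = 1
with a flag.

# The synthetic cohort

`sim_config()` encodes the study conditions the package is exercised
under: 59 primary tumors (11 stage I, 38 stage II — 17 unfavorable /
21 favorable — and 10 stage IV), 11 tumor-adjacent and 11 metastatic
samples (6 LIM, 5 LUM), with the clinical margins of the cohort table
(36/23 male/female; 32/27 below/at-or-above age 60, 16/22 within
stage II; 16 smokers, 42 non-smokers, 1 unknown; 22 LIM-positive
patients among 59).

Counts are generated per CpG and sample: coverage is negative-binomial
(mean 30, size 5, floor 1; ~10 CpGs per window), the methylation
fraction is beta-distributed around the window's mean with dispersion
`bb_dispersion`, and the methylated count is binomial given both.
Window means are a two-component mixture (≈ 0.1 promoter-like for 35%
of windows, ≈ 0.8 gene-body-like otherwise). Planted classes:
`dmr` (30 pp shift in unfavorable stage II), `trend` (+0.15 per stage
step), `prognostic` (both, and always promoter-covered by the toy
annotation), `predictive` (40 pp shift in LIM-positive samples,
including metastatic LIM). Effects keep means inside [0.02, 0.98] or
the configuration is rejected. Survival times are exponential for
LIM patients (median 600 days, a realistic early-event scale) and
uniform administrative censoring at 1000–2920 days otherwise.

The default dispersion is `bb_dispersion = 0.001`, near the binomial
limit. This is deliberate: the generator's role is to produce data
with the statistical structure the analysis assumes, so that
calibration statements (null rejection ≈ 5%) test the implementation
rather than the working model. Real bisulfite data is more dispersed
(ρ ≈ 0.02–0.1); setting the parameter there demonstrates the
anti-conservativeness of the binomial LRT — a limitation shared with
the logistic-regression callers this package mirrors, and the main
caveat when transferring test results to real cohorts. The generator
also does not emulate sequence-context effects, strand structure,
copy-number variation, or correlated neighbouring windows.

Default problem sizes — 2000 windows × 81 samples × ~10 CpGs/window for
the end-to-end runs, 150–500 windows for the focused simulations, 50
replicates for the LOOCV null — were chosen so the whole suite runs in
minutes on a single core while keeping Monte-Carlo error well inside
the asserted bands; they stand in for the study's ~80 Mb target space.

# Known limitations

* Binomial (not beta-binomial) working model for the window test; no
  dispersion shrinkage. Anti-conservative under strong biological
  overdispersion.
* The normal-mode trend p-value is an approximation; it is only used
  above pooled n = 12 (auto mode), and exact/permutation modes cover
  the small-sample range.
* Pooled-LOOCV ROC estimates carry the usual caveats of pooling
  heterogeneous fold models; the uninformative-fold convention above
  removes the prevalence artifact but cannot make pooled AUC a proper
  unbiased estimate.
* The funnel counts depend on the cohort at hand; the headline counts
  of any particular study are not reproducible without its raw data,
  and the package instead guarantees the analogous funnel on any
  input, with every gate logged.
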