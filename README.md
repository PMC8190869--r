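# methdmr

Discovery of prognostic differentially methylated regions (DMRs) in
primary colorectal tumors and prediction of liver-metastasis (LIM) risk
from targeted bisulfite sequencing, as a tested, reusable R pipeline.

## Who this is for

Cancer epigenomics groups analysing targeted bisulfite sequencing of
tumor cohorts: per-CpG methylated/unmethylated read counts (Bismark
coverage files), a clinical sample sheet, and a GENCODE-style gene
annotation go in; prognostic marker windows, a penalized logistic
risk model with cross-validated performance, and metastasis-free
survival stratification come out. A synthetic-cohort generator with
planted signals makes every stage testable without patient data.

## The method

**Windowed DMR calling.** CpG counts are aggregated on a fixed grid of
1000-bp windows (per-site coverage ≥ 2). The methylation level of window
*w* in sample *s* is

```
L_ws = (methylated read calls in w) / (total read calls in w)
```

Each window is tested between two groups with a binomial logistic
regression of per-sample counts on the group indicator; the p-value is
the 1-df likelihood-ratio chi-square, and the effect is the difference
of group-mean levels in percentage points. Benjamini–Hochberg FDR gives
q-values.

**Prognostic marker funnel.** Three independent filters are intersected
(stage II unfavorable vs favorable DMRs at |Δ| ≥ 10 pp and q ≤ 0.05; a
two-sided Jonckheere–Terpstra trend across tumor-adjacent → stage I →
II → IV at p ≤ 0.05 over the 70 tumor/adjacent samples; overlap with a
promoter, TSS −1500/+500 bp strand-aware), followed by Wilcoxon
age/smoking confounder screens at q < 0.1.

**LIM risk model.** On the 59 primary tumors, candidate DMRs (|Δ| ≥ 20
pp, q ≤ 0.05, LIM vs LIM-free) feed an L1-penalized logistic regression
(10-fold cross-validated penalty). Leave-one-out cross-validation
re-selects candidates within every fold — the held-out sample never
touches selection, standardization or penalty choice — and the pooled
held-out probabilities give the ROC/AUC with a Youden operating point.
The final model refits on all samples, annotates its markers
(promoter / gene body / intergenic, hyper/hypo), scores external
metastatic samples even when some markers are unavailable, and
stratifies Kaplan–Meier LIM-free survival with a log-rank test.

## Worked example

```r
library(methdmr)

cohort <- simulate_cohort(sim_config(seed = 1))   # 81 samples, 2000 windows
run    <- run_all(cohort, pipeline_config(seed = 1))
print(run)
```

```
methdmr workflow run
  windows tiled:        2000
  DMRs tested:          2000
  candidate DMRs:       85
  trend-significant:    191
  promoter-overlapping: 971
  prognostic markers:   34 (24 hyper / 10 hypo)
  LOOCV pooled AUC:     1 (sens 100%, spec 100%)
  final markers:        5 of 21 candidates
  external AUC:         1
  log-rank p:           4.568e-16
```

The synthetic cohort plants 30 prognostic windows (30 pp effect plus a
stage-monotone trend, promoter-covered) and 5 LIM-predictive windows
(40 pp); the funnel recovers the planted prognostic windows (34 markers
include all 30), the LOOCV-wrapped LASSO finds the 5 predictive markers
and separates LIM from LUM metastatic samples perfectly at this planted
effect size, and the predicted-positive group has sharply shorter
LIM-free survival. On real cohorts the effects are weaker and the AUCs
correspondingly lower; the point of the example is that the machinery
recovers exactly what was planted.

Individual stages are ordinary functions returning classed objects with
`print`/`summary`/`coef`/`predict` methods: `tile_windows()`,
`dmr_test()`, `adjust_fdr()`, `filter_dmrs()`, `jonckheere_test()`,
`trend_filter()`, `extract_promoters()`, `classify_windows()`,
`intersect_filters()`, `loocv_scores()`, `roc_curve()`, `final_model()`,
`score_external()`, `kaplan_meier()`, `logrank_test()`.

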