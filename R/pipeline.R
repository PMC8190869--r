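#' Pipeline configuration with the protocol's default thresholds
#'
#' Collects every tunable threshold of the workflow. The defaults are the
#' protocol values used throughout: 1000-bp windows with per-site coverage
#' >= 2; prognostic DMR gate q <= 0.05 and |difference| >= 10 percentage
#' points; predictive candidate gate q <= 0.05 and |difference| >= 20;
#' stage-trend alpha 0.05; confounder screen q < 0.1; promoters 1500 bp
#' upstream / 500 bp downstream of the TSS.
#'
#' @param window_size Window width in bp.
#' @param min_site_coverage Minimum per-CpG read coverage.
#' @param prognostic_q,prognostic_diff Prognostic DMR gate.
#' @param predictive_q,predictive_diff Predictive candidate gate.
#' @param trend_alpha Stage-trend significance threshold.
#' @param confounder_q Confounder screen threshold.
#' @param promoter_upstream,promoter_downstream Promoter extent in bp.
#' @param survival_year_days Days per year for rate-at-time queries.
#' @param seed Integer seed for all stochastic steps.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(window_size = 1000, min_site_coverage = 2,
                            prognostic_q = 0.05, prognostic_diff = 10,
                            predictive_q = 0.05, predictive_diff = 20,
                            trend_alpha = 0.05, confounder_q = 0.1,
                            promoter_upstream = 1500,
                            promoter_downstream = 500,
                            survival_year_days = 365,
                            seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(window_size > 0, min_site_coverage >= 0,
            prognostic_q >= 0, prognostic_q <= 1,
            predictive_q >= 0, predictive_q <= 1,
            trend_alpha >= 0, trend_alpha <= 1,
            promoter_upstream >= 0, promoter_downstream >= 0)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "pipeline_config"
  cfg
}

.load_inputs <- function(coverage_dir, sample_sheet, gtf) {
  samples <- read_sample_sheet(sample_sheet)
  paths <- file.path(coverage_dir, paste0(samples$sample_id, ".cov"))
  gz <- !file.exists(paths) & file.exists(paste0(paths, ".gz"))
  paths[gz] <- paste0(paths[gz], ".gz")
  missing <- !file.exists(paths)
  if (any(missing)) stop("coverage file missing for sample ",
                         samples$sample_id[which(missing)[1L]])
  sites <- lapply(paths, read_bismark_coverage)
  names(sites) <- samples$sample_id
  genes <- if (!is.null(gtf)) read_gtf_genes(gtf) else NULL
  list(samples = samples, sites = sites, genes = genes)
}

#' Run the full DMR discovery and liver-metastasis prediction workflow
#'
#' Executes the two analysis branches end to end on a cohort. The
#' prognostic branch (stage II unfavorable vs favorable DMRs, stage-trend
#' filter over the 70 tumor + adjacent samples, promoter overlap,
#' three-way intersection, age/smoking confounder screen) and the
#' predictive branch (LOOCV-wrapped LASSO of LIM status on the 59
#' primaries, pooled ROC, final marker model, external scoring of the
#' metastatic samples, LIM-free survival stratified at the model
#' threshold) share the window tiling but no selection state. All counts
#' of the filter funnel are collected in `funnel`.
#'
#' @param cohort Either a `sim_cohort` object or `NULL` (then
#'   `coverage_dir`/`sample_sheet` must be given).
#' @param config A [pipeline_config()].
#' @param coverage_dir,sample_sheet,gtf File-based inputs used when
#'   `cohort` is `NULL`; `gtf` may also be a gene annotation data frame.
#' @param annotation Optional annotation data frame overriding `gtf`
#'   (e.g. from [simulate_annotation()]).
#' @return An object of class `methdmr_run` with elements `windows`,
#'   `prognostic` (candidate table, trend set, prognostic set, confounder
#'   tables), `predictive` (LOOCV scores, pooled ROC, final model,
#'   external scoring), `survival` (overall and stratified curves,
#'   log-rank), `funnel`, `config`.
#' @export
run_all <- function(cohort = NULL, config = pipeline_config(),
                    coverage_dir = NULL, sample_sheet = NULL, gtf = NULL,
                    annotation = NULL) {
  if (is.null(cohort)) {
    inp <- .load_inputs(coverage_dir, sample_sheet, gtf)
    samples <- inp$samples; sites <- inp$sites
    if (is.null(annotation)) annotation <- inp$genes
  } else {
    samples <- validate_sample_sheet(cohort$samples)
    sites <- cohort$sites
    if (is.null(annotation)) annotation <- simulate_annotation(cohort)
  }
  mw <- tile_windows(sites, window_size = config$window_size,
                     min_site_coverage = config$min_site_coverage)
  funnel <- list(n_samples = nrow(samples),
                 n_windows = nrow(mw$windows))

  ## ---- prognostic branch (stage II prognosis) ----
  st2 <- samples[samples$tissue == "primary" & samples$stage == "II", ]
  unfav <- st2$sample_id[!is.na(st2$prognosis) &
                           st2$prognosis == "unfavorable"]
  fav <- st2$sample_id[!is.na(st2$prognosis) & st2$prognosis == "favorable"]
  dmr <- dmr_test(mw, unfav, fav)
  dmr$q <- adjust_fdr(dmr$p)
  funnel$n_tested <- sum(!dmr$untestable)
  cand <- filter_dmrs(dmr, config$prognostic_q, config$prognostic_diff)
  funnel$n_candidate <- nrow(cand)

  trend_samples <- samples[samples$tissue %in% c("primary", "adjacent"), ]
  tr <- trend_filter(mw, trend_samples, alpha = config$trend_alpha,
                     seed = config$seed)
  funnel$n_trend_tested <- attr(tr, "n_tested")
  funnel$n_trend <- nrow(tr)

  promoters <- if (!is.null(annotation) && nrow(annotation) > 0L) {
    extract_promoters(annotation, upstream = config$promoter_upstream,
                      downstream = config$promoter_downstream)
  } else NULL
  prom_set <- if (!is.null(promoters)) {
    promoter_filter(mw$windows, promoters)
  } else mw$windows[integer(0), ]
  funnel$n_promoter <- nrow(prom_set)

  prog <- intersect_filters(cand, tr, prom_set,
                            window_size = config$window_size)
  funnel$n_prognostic <- prog$counts$intersection
  funnel$n_hyper <- prog$n_hyper
  funnel$n_hypo <- prog$n_hypo
  funnel$venn <- prog$counts

  conf_age <- conf_smoke <- NULL
  if (funnel$n_prognostic > 0L) {
    conf_age <- confounder_wilcoxon(prog, mw, st2, split = "age_median",
                                    q_max = config$confounder_q)
    conf_smoke <- confounder_wilcoxon(prog, mw, st2, split = "smoking",
                                      q_max = config$confounder_q)
    funnel$n_confounded_age <- attr(conf_age, "n_significant")
    funnel$n_confounded_smoking <- attr(conf_smoke, "n_significant")
  }

  ## ---- predictive branch (LIM risk on the 59 primaries) ----
  pri <- samples[samples$tissue == "primary", ]
  labels <- stats::setNames(!is.na(pri$lim) & pri$lim, pri$sample_id)
  loocv <- loocv_scores(mw[, pri$sample_id], labels,
                        q_max = config$predictive_q,
                        min_abs_diff = config$predictive_diff,
                        seed = config$seed)
  pooled_roc <- roc_curve(loocv$scores, labels)
  model <- final_model(mw[, pri$sample_id], labels,
                       q_max = config$predictive_q,
                       min_abs_diff = config$predictive_diff,
                       seed = config$seed,
                       promoters = promoters, genes = annotation,
                       threshold = pooled_roc$threshold)
  funnel$n_loocv_candidates_median <-
    stats::median(vapply(loocv$folds, function(f) length(f$candidates), 0))
  funnel$n_final_candidates <- length(model$candidates)
  funnel$n_final_markers <- length(model$markers)

  met <- samples[samples$tissue == "metastatic", ]
  external <- NULL
  if (nrow(met) > 0L && length(model$markers) > 0L) {
    ext_labels <- stats::setNames(!is.na(met$lim) & met$lim, met$sample_id)
    external <- score_external(model, mw[, met$sample_id],
                               labels = ext_labels)
    funnel$n_external_markers_available <- external$n_available
  }

  ## ---- survival (LIM-free, stratified at the model threshold) ----
  surv <- NULL
  ok <- !is.na(pri$followup_days) & !is.na(pri$lim_event)
  if (any(ok)) {
    km_all <- kaplan_meier(pri$followup_days[ok], pri$lim_event[ok])
    pred_pos <- loocv$scores[pri$sample_id] >= pooled_roc$threshold
    lr <- NULL
    km_pos <- km_neg <- NULL
    if (any(pred_pos & ok) && any(!pred_pos & ok)) {
      km_pos <- kaplan_meier(pri$followup_days[ok & pred_pos],
                             pri$lim_event[ok & pred_pos])
      km_neg <- kaplan_meier(pri$followup_days[ok & !pred_pos],
                             pri$lim_event[ok & !pred_pos])
      lr <- logrank_test(pri$followup_days[ok & pred_pos],
                         pri$lim_event[ok & pred_pos],
                         pri$followup_days[ok & !pred_pos],
                         pri$lim_event[ok & !pred_pos])
    }
    surv <- list(overall = km_all,
                 rate_1yr = survival_rate_at(km_all,
                                             config$survival_year_days),
                 median_days = km_all$median,
                 predicted_positive = km_pos, predicted_negative = km_neg,
                 logrank = lr)
  }

  structure(list(
    windows = mw,
    samples = samples,
    prognostic = list(dmr_table = dmr, candidates = cand, trend = tr,
                      set = prog, confounder_age = conf_age,
                      confounder_smoking = conf_smoke),
    predictive = list(loocv = loocv, roc = pooled_roc, model = model,
                      external = external),
    survival = surv,
    funnel = funnel,
    config = config
  ), class = "methdmr_run")
}

#' @export
print.methdmr_run <- function(x, ...) {
  f <- x$funnel
  cat("methdmr workflow run\n")
  cat("  windows tiled:        ", f$n_windows, "\n", sep = "")
  cat("  DMRs tested:          ", f$n_tested, "\n", sep = "")
  cat("  candidate DMRs:       ", f$n_candidate, "\n", sep = "")
  cat("  trend-significant:    ", f$n_trend, "\n", sep = "")
  cat("  promoter-overlapping: ", f$n_promoter, "\n", sep = "")
  cat("  prognostic markers:   ", f$n_prognostic, " (", f$n_hyper,
      " hyper / ", f$n_hypo, " hypo)\n", sep = "")
  cat("  LOOCV pooled AUC:     ", signif(x$predictive$roc$auc, 4),
      " (sens ", signif(100 * x$predictive$roc$sensitivity, 3),
      "%, spec ", signif(100 * x$predictive$roc$specificity, 3), "%)\n",
      sep = "")
  cat("  final markers:        ", f$n_final_markers, " of ",
      f$n_final_candidates, " candidates\n", sep = "")
  if (!is.null(x$predictive$external))
    cat("  external AUC:         ",
        signif(x$predictive$external$roc$auc, 4), "\n", sep = "")
  if (!is.null(x$survival) && !is.null(x$survival$logrank))
    cat("  log-rank p:           ",
        signif(x$survival$logrank$p, 4), "\n", sep = "")
  invisible(x)
}

#' Serialize the funnel report and the final model
#'
#' Writes `funnel.json` (all gate counts), `model.json` (markers,
#' coefficients, intercept, standardization, threshold), the final marker
#' table and the pooled LOOCV scores to `outdir`. Used for the workflow's
#' reproducibility contract: identical inputs, configuration and seed
#' produce byte-identical files.
#'
#' @param run A `methdmr_run` object.
#' @param outdir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- file.path(outdir, "funnel.json")
  jsonlite::write_json(run$funnel, fp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  model <- run$predictive$model
  mp <- file.path(outdir, "model.json")
  jsonlite::write_json(list(
    markers = model$markers,
    coefficients = as.list(model$coefficients),
    intercept = model$intercept,
    center = as.list(model$center[model$markers]),
    scale = as.list(model$scale[model$markers]),
    lambda = model$lambda,
    threshold = model$threshold
  ), mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tp <- file.path(outdir, "markers.tsv")
  utils::write.table(model$marker_table, tp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sp <- file.path(outdir, "loocv_scores.tsv")
  utils::write.table(
    data.frame(sample_id = names(run$predictive$loocv$scores),
               score = unname(run$predictive$loocv$scores),
               label = unname(run$predictive$loocv$labels)),
    sp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fp, mp, tp, sp))
}
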