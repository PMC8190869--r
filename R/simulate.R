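#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: a colorectal
#' cancer cohort of 59 primary tumors (11 stage I, 38 stage II of which 17
#' have an unfavorable prognosis, 10 stage IV), 11 tumor-adjacent samples
#' and 11 metastatic samples (6 liver, 5 lung), with per-CpG beta-binomial
#' counts, planted group-differential and stage-trend windows, and
#' censored liver-metastasis-free survival.
#'
#' Planted window classes: `dmr` windows differ between unfavorable and
#' favorable stage II primaries; `trend` windows increase (or decrease)
#' monotonically across adjacent, I, II, IV; `prognostic` windows carry
#' both signals (and are promoter-covered by [simulate_annotation()]);
#' `predictive` windows differ between LIM-positive and LIM-negative
#' samples.
#'
#' @param n_windows Number of 1000-bp windows on the synthetic chromosome.
#' @param cpgs_per_window Mean CpG sites per window (Poisson, floor 1).
#' @param coverage_mean,coverage_size Negative-binomial per-CpG read
#'   coverage (floor 1).
#' @param baseline_low,baseline_high Means of the two baseline methylation
#'   components (promoter-like low, gene-body-like high).
#' @param promoter_like_frac Fraction of windows in the low component.
#' @param bb_dispersion Beta-binomial overdispersion rho in \[0, 1); 0 is
#'   pure binomial. The default is mild so that window-aggregated counts
#'   stay close to the binomial working model of the differential test.
#' @param n_dmr,dmr_effect Count and effect (percentage points) of planted
#'   prognosis-differential windows.
#' @param n_trend,trend_increment Count and per-stage mean increment of
#'   planted stage-trend windows.
#' @param n_prognostic Planted windows carrying both signals.
#' @param n_predictive,predictive_effect Count and effect of planted
#'   LIM-differential windows.
#' @param hyper_frac Fraction of planted windows that are hypermethylated
#'   in the test group (the rest are hypomethylated).
#' @param event_median_days Median of the exponential LIM event-time
#'   distribution for LIM-positive patients.
#' @param censor_range_days Follow-up (censoring) window in days for
#'   LIM-free patients.
#' @param promoter_fraction Fraction of windows that
#'   [simulate_annotation()] covers with a promoter.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_windows = 2000,
                       cpgs_per_window = 10,
                       coverage_mean = 30, coverage_size = 5,
                       baseline_low = 0.1, baseline_high = 0.8,
                       promoter_like_frac = 0.35,
                       bb_dispersion = 0.001,
                       n_dmr = 50, dmr_effect = 30,
                       n_trend = 50, trend_increment = 0.15,
                       n_prognostic = 30,
                       n_predictive = 5, predictive_effect = 40,
                       hyper_frac = 0.8,
                       event_median_days = 600,
                       censor_range_days = c(1000, 2920),
                       promoter_fraction = 0.4,
                       seed = 1L) {
  cfg <- list(n_windows = n_windows, cpgs_per_window = cpgs_per_window,
              coverage_mean = coverage_mean, coverage_size = coverage_size,
              baseline_low = baseline_low, baseline_high = baseline_high,
              promoter_like_frac = promoter_like_frac,
              bb_dispersion = bb_dispersion,
              n_dmr = n_dmr, dmr_effect = dmr_effect,
              n_trend = n_trend, trend_increment = trend_increment,
              n_prognostic = n_prognostic,
              n_predictive = n_predictive,
              predictive_effect = predictive_effect,
              hyper_frac = hyper_frac,
              event_median_days = event_median_days,
              censor_range_days = censor_range_days,
              promoter_fraction = promoter_fraction,
              seed = as.integer(seed))
  with(cfg, {
    if (n_windows <= 0 || cpgs_per_window <= 0) stop("counts must be positive")
    if (bb_dispersion < 0 || bb_dispersion >= 1)
      stop("bb_dispersion must be in [0, 1)")
    if (n_dmr + n_trend + n_prognostic + n_predictive > n_windows)
      stop("more planted windows than windows")
    top <- 0.2 + trend_increment * 3 + dmr_effect / 100
    if (top > 0.98 || 0.2 + predictive_effect / 100 > 0.98)
      stop("planted mean shift leaves [0.02, 0.98]")
  })
  class(cfg) <- "sim_config"
  cfg
}

# Beta-binomial draw: n trials each with success prob from a beta with
# mean mu and dispersion rho; rho = 0 collapses to binomial.
.rbetabinom <- function(n_draws, size, mu, rho) {
  if (rho == 0) return(stats::rbinom(n_draws, size, mu))
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  stats::rbinom(n_draws, size, stats::rbeta(n_draws, a, b))
}

#' Simulate window-level methylation counts for two groups
#'
#' Direct window-level generator used for test calibration and power
#' studies: per sample and window, CpG coverages are negative-binomial
#' (floor 1) and methylated counts beta-binomial around the window mean.
#' Both groups share the window means except at the planted windows, where
#' the test group's mean is shifted by `effect_pp` percentage points.
#'
#' @param n_test,n_control Samples per group.
#' @param n_windows Number of windows.
#' @param n_planted Number of planted differential windows (0 for a null
#'   calibration set).
#' @param effect_pp Planted effect in percentage points.
#' @param direction `"hyper"`, `"hypo"` or `"mixed"` (80/20).
#' @param cpgs_per_window,coverage_mean,coverage_size,bb_dispersion As in
#'   [sim_config()].
#' @param seed Integer seed.
#' @return A `meth_windows` object with samples `T1..`, `C1..`; the keys
#'   of planted windows are attached as attribute `truth`.
#' @export
simulate_window_counts <- function(n_test, n_control, n_windows = 2000,
                                   n_planted = 0, effect_pp = 30,
                                   direction = "hyper",
                                   cpgs_per_window = 10,
                                   coverage_mean = 30, coverage_size = 5,
                                   bb_dispersion = 0.001, seed = 1L) {
  set.seed(seed)
  W <- n_windows
  S <- n_test + n_control
  ids <- c(paste0("T", seq_len(n_test)), paste0("C", seq_len(n_control)))
  is_test <- c(rep(TRUE, n_test), rep(FALSE, n_control))
  base <- stats::runif(W, 0.1, 0.9)
  planted <- sort(sample.int(W, n_planted))
  dirs <- rep(1, n_planted)
  if (direction == "hypo") dirs <- rep(-1, n_planted)
  if (direction == "mixed")
    dirs <- ifelse(stats::runif(n_planted) < 0.8, 1, -1)
  eff <- effect_pp / 100
  base[planted] <- ifelse(dirs > 0,
                          stats::runif(n_planted, 0.05, 0.95 - eff),
                          stats::runif(n_planted, 0.05 + eff, 0.95))
  ncpg <- pmax(1L, stats::rpois(W, cpgs_per_window))
  meth <- cov <- matrix(0, W, S, dimnames = list(NULL, ids))
  mu_grp <- cbind(test = base, control = base)
  mu_grp[planted, "test"] <- base[planted] + dirs * eff
  win_of <- rep(seq_len(W), ncpg)
  Tn <- length(win_of)
  for (s in seq_len(S)) {
    mu <- if (is_test[s]) mu_grp[win_of, "test"] else mu_grp[win_of, "control"]
    cv <- pmax(1L, stats::rnbinom(Tn, mu = coverage_mean, size = coverage_size))
    mm <- .rbetabinom(Tn, cv, mu, bb_dispersion)
    meth[, s] <- rowsum(mm, win_of)[, 1L]
    cov[, s] <- rowsum(cv, win_of)[, 1L]
  }
  windows <- data.frame(chrom = "chr1",
                        start = (seq_len(W) - 1L) * 1000L + 1L,
                        end = seq_len(W) * 1000L)
  mw <- meth_windows(windows, meth, cov,
                     nsites = matrix(ncpg, W, S), window_size = 1000)
  attr(mw, "truth") <- data.frame(
    key = mw$windows$key[planted],
    direction = ifelse(dirs > 0, "hyper", "hypo"),
    effect_pp = rep(effect_pp, length(planted)))
  mw
}

.stage_index <- c(adjacent = 0, I = 1, II = 2, IV = 3)

# Sample sheet matching the cohort's clinical margins: 59 primaries
# (stage I 11 with 1 LIM + 1 LUM; stage II 38 with 11 LIM + 6 LUM, i.e.
# 17 unfavorable; stage IV 10 all LIM, 2 also LUM), 36 male / 23 female,
# 32 aged < 60 / 27 >= 60 (16/22 within stage II), 16 smokers / 42
# non-smokers / 1 unknown, plus 11 adjacent and 11 metastatic samples.
.build_sample_sheet <- function(cfg) {
  stage <- c(rep("I", 11), rep("II", 38), rep("IV", 10))
  pid <- sprintf("P%02d", 1:59)
  lim <- rep(FALSE, 59); lum <- rep(FALSE, 59)
  lim[1] <- TRUE; lum[2] <- TRUE                  # stage I
  lim[12:22] <- TRUE; lum[23:28] <- TRUE          # stage II
  lim[50:59] <- TRUE; lum[50:51] <- TRUE          # stage IV
  prognosis <- rep(NA_character_, 59)
  prognosis[stage == "II"] <- ifelse(lim[stage == "II"] | lum[stage == "II"],
                                     "unfavorable", "favorable")
  sex <- rep("female", 59)
  sex[c(1:7, 12:30, 50:59)] <- "male"             # 36 male / 23 female
  age <- numeric(59)
  young_ii <- c(12:19, 29:36)                      # 16 of 38 stage II < 60
  young_other <- c(1:8, 50:57)                     # 16 of the remaining 21
  young <- c(young_ii, young_other)
  age[young] <- 40 + (seq_along(young) - 1) %% 20
  old <- setdiff(1:59, young)
  age[old] <- 60 + (seq_along(old) - 1) %% 19
  smoker <- rep("no", 59)
  smoker[c(12:21, 1:3, 50:52)] <- "yes"            # 16 smokers
  smoker[49] <- NA                                 # 1 unknown (stage II)
  followup <- numeric(59); event <- lim
  n_lim <- sum(lim)
  t_ev <- stats::rexp(n_lim, rate = log(2) / cfg$event_median_days)
  followup[lim] <- pmin(pmax(round(t_ev), 30), cfg$censor_range_days[2] - 1)
  followup[!lim] <- round(stats::runif(59 - n_lim, cfg$censor_range_days[1],
                                       cfg$censor_range_days[2]))
  primaries <- data.frame(
    sample_id = sprintf("T%02d", 1:59), patient_id = pid,
    tissue = "primary", stage = stage, prognosis = prognosis,
    lim = lim, lum = lum, followup_days = followup, lim_event = event,
    age = age, sex = sex, smoker = smoker)
  adj_idx <- 29:39  # favorable stage II patients contribute adjacent tissue
  adjacent <- data.frame(
    sample_id = sprintf("A%02d", seq_along(adj_idx)),
    patient_id = pid[adj_idx], tissue = "adjacent", stage = "adjacent",
    prognosis = NA_character_, lim = NA, lum = NA,
    followup_days = NA_real_, lim_event = NA,
    age = age[adj_idx], sex = sex[adj_idx], smoker = smoker[adj_idx])
  met_idx <- c(12:17, 23:27)  # 6 LIM then 5 LUM metastatic samples
  metastatic <- data.frame(
    sample_id = sprintf("M%02d", seq_along(met_idx)),
    patient_id = pid[met_idx], tissue = "metastatic",
    stage = stage[met_idx], prognosis = NA_character_,
    lim = c(rep(TRUE, 6), rep(FALSE, 5)),
    lum = c(rep(FALSE, 6), rep(TRUE, 5)),
    followup_days = NA_real_, lim_event = NA,
    age = age[met_idx], sex = sex[met_idx], smoker = smoker[met_idx])
  rbind(primaries, adjacent, metastatic)
}

#' Simulate a full synthetic cohort
#'
#' Generates the sample sheet, per-sample per-CpG methylation counts
#' (Bismark coverage layout) and the truth table of planted windows for a
#' cohort with the structure described in [sim_config()]. All windows lie
#' consecutively on a synthetic chromosome `chr1`. Output is fully
#' reproducible from `config$seed`; with `outdir` set, the Bismark
#' coverage files, sample sheet and truth table are also written to disk.
#'
#' @param config A [sim_config()] object.
#' @param outdir Optional output directory for on-disk files.
#' @return An object of class `sim_cohort`: list with `samples` (sample
#'   sheet data frame), `sites` (named list of per-sample CpG count data
#'   frames), `truth` (planted windows: `key`, `class`, `direction`),
#'   `config`.
#' @export
simulate_cohort <- function(config = sim_config(), outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sheet <- .build_sample_sheet(config)
  W <- config$n_windows
  S <- nrow(sheet)

  # window classes
  planted_total <- config$n_dmr + config$n_trend + config$n_prognostic +
    config$n_predictive
  picks <- sample.int(W, planted_total)
  cls <- rep("null", W)
  i <- 0
  take <- function(n) picks[seq_len(n) + i]
  w_dmr <- take(config$n_dmr); i <- i + config$n_dmr
  w_trend <- take(config$n_trend); i <- i + config$n_trend
  w_prog <- take(config$n_prognostic); i <- i + config$n_prognostic
  w_pred <- take(config$n_predictive)
  cls[w_dmr] <- "dmr"; cls[w_trend] <- "trend"
  cls[w_prog] <- "prognostic"; cls[w_pred] <- "predictive"

  base <- ifelse(stats::runif(W) < config$promoter_like_frac,
                 config$baseline_low, config$baseline_high)
  base <- pmin(0.98, pmax(0.02, base + stats::runif(W, -0.05, 0.05)))
  dirs <- rep(0, W)
  planted <- c(w_dmr, w_trend, w_prog, w_pred)
  dirs[planted] <- ifelse(stats::runif(length(planted)) < config$hyper_frac,
                          1, -1)
  # planted windows get a baseline with room for the full shift
  shift_max <- pmax(config$dmr_effect, config$predictive_effect) / 100 +
    3 * config$trend_increment
  base[planted] <- ifelse(dirs[planted] > 0,
                          stats::runif(length(planted), 0.05,
                                       max(0.06, 0.95 - shift_max)),
                          stats::runif(length(planted),
                                       min(0.94, 0.05 + shift_max), 0.95))

  unfav <- sheet$tissue == "primary" & !is.na(sheet$prognosis) &
    sheet$prognosis == "unfavorable"
  limpos <- !is.na(sheet$lim) & sheet$lim &
    sheet$tissue %in% c("primary", "metastatic")
  sidx <- .stage_index[sheet$stage]

  mu <- matrix(rep(base, S), W, S)  # windows x samples mean methylation
  eff_dmr <- config$dmr_effect / 100
  eff_pred <- config$predictive_effect / 100
  for (w in c(w_dmr, w_prog)) mu[w, unfav] <- mu[w, unfav] + dirs[w] * eff_dmr
  for (w in c(w_trend, w_prog))
    mu[w, ] <- mu[w, ] + dirs[w] * config$trend_increment * sidx
  for (w in w_pred) mu[w, limpos] <- mu[w, limpos] + dirs[w] * eff_pred
  mu[] <- pmin(0.98, pmax(0.02, mu))

  ncpg <- pmax(1L, stats::rpois(W, config$cpgs_per_window))
  win_of <- rep(seq_len(W), ncpg)
  offs <- unlist(lapply(ncpg, function(k) sort(sample.int(1000L, k))))
  pos <- (win_of - 1L) * 1000L + offs
  Tn <- length(pos)
  sites <- vector("list", S)
  names(sites) <- sheet$sample_id
  for (s in seq_len(S)) {
    cv <- pmax(1L, stats::rnbinom(Tn, mu = config$coverage_mean,
                                  size = config$coverage_size))
    mm <- .rbetabinom(Tn, cv, mu[win_of, s], config$bb_dispersion)
    sites[[s]] <- data.frame(chrom = "chr1", pos = pos,
                             meth = as.integer(mm),
                             unmeth = as.integer(cv - mm))
  }
  key <- window_key("chr1", (seq_len(W) - 1L) * 1000L + 1L,
                    seq_len(W) * 1000L)
  truth <- data.frame(key = key[planted],
                      window = planted,
                      class = cls[planted],
                      direction = ifelse(dirs[planted] > 0, "hyper", "hypo"))
  out <- structure(list(samples = sheet, sites = sites, truth = truth,
                        config = config),
                   class = "sim_cohort")
  if (!is.null(outdir)) write_cohort(out, outdir)
  out
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic cohort: ", nrow(x$samples), " samples, ",
      x$config$n_windows, " windows, ", nrow(x$truth),
      " planted windows\n", sep = "")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits one Bismark coverage file per sample (`<sample_id>.cov`), the
#' sample sheet (`sample_sheet.tsv`) and the planted-window truth table
#' (`truth.tsv`).
#'
#' @param cohort A `sim_cohort` object.
#' @param outdir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (sid in names(cohort$sites)) {
    df <- cohort$sites[[sid]]
    pct <- ifelse(df$meth + df$unmeth > 0,
                  round(100 * df$meth / (df$meth + df$unmeth), 2), 0)
    out <- data.frame(df$chrom, df$pos, df$pos, pct, df$meth, df$unmeth)
    utils::write.table(out, file.path(outdir, paste0(sid, ".cov")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  utils::write.table(cohort$samples, file.path(outdir, "sample_sheet.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(outdir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' Simulate a toy gene annotation matching a cohort
#'
#' Places genes on both strands of the synthetic chromosome so that their
#' promoters (1500 bp upstream / 500 bp downstream of the TSS) cover
#' approximately `promoter_fraction` of the cohort's windows, always
#' including every planted prognostic window; with `promoter_fraction = 0`
#' the annotation is empty. Deterministic given the cohort's seed.
#'
#' @param cohort A `sim_cohort` object.
#' @param promoter_fraction Overrides `config$promoter_fraction` if given.
#' @param path Optional path to also write the annotation as GTF.
#' @return The annotation data frame (gene and transcript records, same
#'   columns as [read_gtf_genes()]); invisibly `NULL` columns if empty.
#' @export
simulate_annotation <- function(cohort, promoter_fraction = NULL,
                                path = NULL) {
  cfg <- cohort$config
  frac <- if (is.null(promoter_fraction)) cfg$promoter_fraction else
    promoter_fraction
  empty <- data.frame(gene_id = character(), gene_name = character(),
                      chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      feature = character())
  if (frac <= 0) {
    if (!is.null(path)) .write_gtf(empty, path)
    return(empty)
  }
  set.seed(cfg$seed + 1L)
  W <- cfg$n_windows
  prog <- cohort$truth$window[cohort$truth$class == "prognostic"]
  # each promoter spans ~2 windows of the grid
  n_target <- max(length(prog), ceiling(frac * W / 2))
  pool <- setdiff(seq_len(W), prog)
  extra <- sample(pool, max(0, n_target - length(prog)))
  wins <- sort(c(prog, extra))
  start <- (wins - 1L) * 1000L + 1L
  end <- wins * 1000L
  plus <- seq_along(wins) %% 2L == 1L
  tss <- ifelse(plus, start + 700L, end - 700L)
  gstart <- ifelse(plus, tss, pmax(1L, tss - 2500L))
  gend <- ifelse(plus, tss + 2500L, tss)
  genes <- data.frame(
    gene_id = sprintf("SYNG%04d", wins),
    gene_name = sprintf("SYN%04d", wins),
    chrom = "chr1", start = as.integer(gstart), end = as.integer(gend),
    strand = ifelse(plus, "+", "-"), feature = "gene")
  tx <- genes; tx$feature <- "transcript"
  ann <- rbind(genes, tx)
  ann <- ann[order(ann$start, ann$feature), , drop = FALSE]
  rownames(ann) <- NULL
  if (!is.null(path)) .write_gtf(ann, path)
  ann
}

.write_gtf <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##description: synthetic toy annotation", con)
  if (nrow(ann) > 0L) {
    attrs <- ifelse(
      ann$feature == "gene",
      sprintf('gene_id "%s"; gene_name "%s"; gene_type "protein_coding";',
              ann$gene_id, ann$gene_name),
      sprintf(paste0('gene_id "%s"; transcript_id "%s.1"; gene_name "%s"; ',
                     'gene_type "protein_coding";'),
              ann$gene_id, ann$gene_id, ann$gene_name))
    writeLines(sprintf("%s\tsynthetic\t%s\t%d\t%d\t.\t%s\t.\t%s",
                       ann$chrom, ann$feature, ann$start, ann$end,
                       ann$strand, attrs), con)
  }
  invisible(path)
}
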