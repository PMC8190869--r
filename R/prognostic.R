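.set_keys <- function(x) {
  if (is.character(x)) return(x)
  if (is.data.frame(x)) {
    if ("key" %in% names(x)) return(x$key)
    return(window_key(x$chrom, x$start, x$end))
  }
  stop("window set must be a data frame or a character vector of keys")
}

.check_grid <- function(keys, window_size) {
  if (length(keys) == 0L) return(invisible(TRUE))
  m <- regmatches(keys, regexec("^(.+):([0-9]+)-([0-9]+)$", keys))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad)) stop("malformed window key: ", keys[which(bad)[1L]])
  start <- as.numeric(vapply(m, `[[`, "", 3L))
  end <- as.numeric(vapply(m, `[[`, "", 4L))
  off <- which(start %% window_size != 1 | end - start + 1 != window_size)
  if (length(off) > 0L)
    stop("window not on the ", window_size, "-bp grid: ", keys[off[1L]])
  invisible(TRUE)
}

#' Intersect the three prognostic marker filters
#'
#' Combines the three windows sets of the prognostic funnel — (a) DMRs
#' passing the q-value / methylation-difference gate, (b) windows with a
#' significant stage trend, and (c) windows overlapping a gene promoter —
#' into their three-way intersection, and tallies every Venn region plus
#' the hyper/hypo direction split of the final markers.
#'
#' @param candidate_set DMR result data frame (q/diff-filtered); its rows
#'   for intersecting windows are carried into `markers`.
#' @param trend_set Window set passing the trend filter (data frame or key
#'   vector).
#' @param promoter_set Window set overlapping promoters (data frame or key
#'   vector).
#' @param window_size Grid width used to validate that all three sets are
#'   keyed on the same window grid.
#' @return An object of class `prognostic_set`: list with `markers` (rows
#'   of `candidate_set` in the intersection), `counts` (all input sizes and
#'   the seven Venn region sizes), `n_hyper`, `n_hypo`.
#' @export
intersect_filters <- function(candidate_set, trend_set, promoter_set,
                              window_size = 1000) {
  a <- unique(.set_keys(candidate_set))
  b <- unique(.set_keys(trend_set))
  c_ <- unique(.set_keys(promoter_set))
  for (k in list(a, b, c_)) .check_grid(k, window_size)
  abc <- intersect(intersect(a, b), c_)
  markers <- if (is.data.frame(candidate_set)) {
    candidate_set[.set_keys(candidate_set) %in% abc, , drop = FALSE]
  } else {
    data.frame(key = abc)
  }
  counts <- list(
    candidate = length(a), trend = length(b), promoter = length(c_),
    intersection = length(abc),
    candidate_only = length(setdiff(a, union(b, c_))),
    trend_only = length(setdiff(b, union(a, c_))),
    promoter_only = length(setdiff(c_, union(a, b))),
    candidate_trend = length(setdiff(intersect(a, b), c_)),
    candidate_promoter = length(setdiff(intersect(a, c_), b)),
    trend_promoter = length(setdiff(intersect(b, c_), a))
  )
  n_hyper <- n_hypo <- NA_integer_
  if (is.data.frame(markers) && "meth_diff" %in% names(markers)) {
    n_hyper <- sum(markers$meth_diff > 0, na.rm = TRUE)
    n_hypo <- sum(markers$meth_diff < 0, na.rm = TRUE)
  }
  structure(list(markers = markers, counts = counts,
                 n_hyper = n_hyper, n_hypo = n_hypo),
            class = "prognostic_set")
}

#' @export
print.prognostic_set <- function(x, ...) {
  cat("Prognostic DMR selection\n")
  cat("  candidate (q/diff gate): ", x$counts$candidate, "\n", sep = "")
  cat("  stage trend:             ", x$counts$trend, "\n", sep = "")
  cat("  promoter overlap:        ", x$counts$promoter, "\n", sep = "")
  cat("  final markers:           ", x$counts$intersection,
      " (", x$n_hyper, " hyper / ", x$n_hypo, " hypo)\n", sep = "")
  invisible(x)
}

#' Wilcoxon confounder check on marker methylation levels
#'
#' For each marker window, compares per-sample methylation levels between
#' two patient groups defined by a potential confounder — age split at
#' 60 years (`"age_median"`) or smoking status (`"smoking"`, samples with
#' unknown status excluded) — with a two-sided Wilcoxon rank-sum test, then
#' applies Benjamini-Hochberg adjustment across markers. The exact null
#' distribution is used when both groups have fewer than 10 samples and
#' there are no ties; otherwise the normal approximation with tie
#' correction and continuity correction.
#'
#' @param markers Marker windows: a `prognostic_set`, DMR data frame, or
#'   vector of window keys.
#' @param x A `meth_windows` object holding the samples to test.
#' @param samples Sample sheet rows for the samples to test (e.g. the 38
#'   stage II primaries).
#' @param split `"age_median"` or `"smoking"`.
#' @param q_max Significance threshold on the adjusted values (default 0.1).
#' @param age_cut Age split point in years (default 60; groups are
#'   `< age_cut` vs `>= age_cut`).
#' @return Data frame with one row per marker (`key`, `p`, `q`) plus
#'   attributes `n_significant`, `group_sizes`.
#' @export
confounder_wilcoxon <- function(markers, x, samples,
                                split = c("age_median", "smoking"),
                                q_max = 0.1, age_cut = 60) {
  split <- match.arg(split)
  keys <- if (inherits(markers, "prognostic_set")) {
    .set_keys(markers$markers)
  } else .set_keys(markers)
  if (split == "age_median") {
    samples <- samples[!is.na(samples$age), , drop = FALSE]
    g <- samples$age >= age_cut
  } else {
    samples <- samples[!is.na(samples$smoker), , drop = FALSE]
    g <- samples$smoker == "yes"
  }
  if (sum(g) == 0L || sum(!g) == 0L)
    stop("confounder split yields an empty group")
  lv <- meth_levels(x)[keys, samples$sample_id, drop = FALSE]
  p <- vapply(seq_along(keys), function(i) {
    a <- lv[i, g]; b <- lv[i, !g]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) == 0L || length(b) == 0L) return(NA_real_)
    if (length(unique(c(a, b))) == 1L) return(1)
    exact <- length(a) < 10L && length(b) < 10L &&
      !any(duplicated(c(a, b)))
    suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  }, 0)
  q <- adjust_fdr(p)
  out <- data.frame(key = keys, p = p, q = q)
  attr(out, "n_significant") <- sum(!is.na(q) & q < q_max)
  attr(out, "group_sizes") <- c(sum(g), sum(!g))
  out
}

.pct <- function(k, n) round(100 * k / n, 1)

#' Summarize a cohort's clinical characteristics
#'
#' Computes the counts and percentages of the standard clinical summary
#' table for the primary-tumor samples of a cohort: sex, age split at 60,
#' smoking history, stage distribution, per-stage liver (LIM) and lung
#' (LUM) metastasis rates, and the share of LIM among metastatic patients.
#'
#' @param samples Sample sheet data frame.
#' @param age_cut Age split in years (default 60).
#' @return A list of named count/percentage vectors.
#' @export
cohort_summary <- function(samples, age_cut = 60) {
  pri <- samples[samples$tissue == "primary", , drop = FALSE]
  n <- nrow(pri)
  stage_n <- vapply(c("I", "II", "IV"), function(s) sum(pri$stage == s), 0L)
  lim <- !is.na(pri$lim) & pri$lim
  lum <- !is.na(pri$lum) & pri$lum
  met <- lim | lum
  lim_by_stage <- vapply(c("I", "II", "IV"),
                         function(s) sum(lim & pri$stage == s), 0L)
  lum_by_stage <- vapply(c("I", "II", "IV"),
                         function(s) sum(lum & pri$stage == s), 0L)
  list(
    n = n,
    sex = c(male = .pct(sum(pri$sex == "male", na.rm = TRUE), n),
            female = .pct(sum(pri$sex == "female", na.rm = TRUE), n)),
    age = c(under = .pct(sum(pri$age < age_cut, na.rm = TRUE), n),
            over = .pct(sum(pri$age >= age_cut, na.rm = TRUE), n)),
    median_age = stats::median(pri$age, na.rm = TRUE),
    smoking = c(smoker = .pct(sum(pri$smoker == "yes", na.rm = TRUE), n),
                nonsmoker = .pct(sum(pri$smoker == "no", na.rm = TRUE), n),
                unknown = .pct(sum(is.na(pri$smoker)), n)),
    stage_counts = stage_n,
    stage_pct = .pct(stage_n, n),
    lim_counts = lim_by_stage,
    lim_pct_within_stage = .pct(lim_by_stage, stage_n),
    lum_counts = lum_by_stage,
    lum_pct_within_stage = .pct(lum_by_stage, stage_n),
    no_metastasis_pct = .pct(sum(!met), n),
    n_metastatic = sum(met),
    lim_among_metastatic_pct = .pct(sum(lim), sum(met))
  )
}
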