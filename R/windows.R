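#' Tile CpG sites into fixed genomic windows
#'
#' Aggregates per-CpG methylated/unmethylated read counts into a fixed,
#' non-overlapping grid of `window_size`-bp windows anchored at coordinate 1
#' (windows are `[k*window_size + 1, (k+1)*window_size]`, 1-based inclusive).
#' A CpG site contributes to a sample's window sums only when its read
#' coverage in that sample is at least `min_site_coverage`. A window is kept
#' when at least one sample has nonzero aggregated coverage and at least one
#' sample has `min_sites_per_window` contributing sites.
#'
#' @param sites Named list of per-sample CpG data frames as returned by
#'   [read_bismark_coverage()] (columns `chrom`, `pos`, `meth`, `unmeth`);
#'   names are sample ids.
#' @param window_size Window width in bp (default 1000).
#' @param min_site_coverage Minimum per-site read coverage for a site to
#'   count (default 2).
#' @param min_sites_per_window Minimum contributing CpG sites (in the
#'   best-covered sample) for a window to be emitted.
#' @return A `meth_windows` object: list with a `windows` data frame
#'   (`chrom`, `start`, `end`, `key`) and windows-by-samples matrices
#'   `meth`, `cov` and `nsites`.
#' @export
tile_windows <- function(sites, window_size = 1000, min_site_coverage = 2,
                         min_sites_per_window = 1) {
  if (window_size <= 0) stop("window_size must be positive")
  if (is.null(names(sites)) || any(names(sites) == ""))
    stop("'sites' must be a named list keyed by sample id")
  samples <- names(sites)
  per <- lapply(sites, function(df) {
    covg <- df$meth + df$unmeth
    keep <- covg >= min_site_coverage
    df <- df[keep, , drop = FALSE]
    if (nrow(df) == 0L) {
      return(data.frame(key = character(), meth = integer(),
                        cov = integer(), n = integer()))
    }
    widx <- (df$pos - 1L) %/% window_size
    key <- paste0(df$chrom, ":", widx)
    agg_m <- rowsum(df$meth, key)
    agg_c <- rowsum(df$meth + df$unmeth, key)
    agg_n <- rowsum(rep(1L, nrow(df)), key)
    data.frame(key = rownames(agg_m), meth = agg_m[, 1L],
               cov = agg_c[, 1L], n = agg_n[, 1L])
  })
  all_keys <- unique(unlist(lapply(per, `[[`, "key"), use.names = FALSE))
  if (length(all_keys) == 0L) stop("no covered windows after filtering")
  parts <- strsplit(all_keys, ":", fixed = TRUE)
  chrom <- vapply(parts, `[[`, "", 1L)
  widx <- as.numeric(vapply(parts, `[[`, "", 2L))
  ord <- order(chrom, widx)
  all_keys <- all_keys[ord]; chrom <- chrom[ord]; widx <- widx[ord]
  W <- length(all_keys); S <- length(samples)
  meth <- matrix(0, W, S, dimnames = list(all_keys, samples))
  covm <- matrix(0, W, S, dimnames = list(all_keys, samples))
  nsit <- matrix(0L, W, S, dimnames = list(all_keys, samples))
  for (s in samples) {
    p <- per[[s]]
    ix <- match(p$key, all_keys)
    meth[ix, s] <- p$meth
    covm[ix, s] <- p$cov
    nsit[ix, s] <- p$n
  }
  keep <- apply(nsit, 1L, max) >= min_sites_per_window & rowSums(covm) > 0
  start <- as.integer(widx * window_size + 1)
  windows <- data.frame(chrom = chrom, start = start,
                        end = as.integer(start + window_size - 1L),
                        key = window_key(chrom, start, start + window_size - 1L))
  rownames(meth) <- rownames(covm) <- rownames(nsit) <- windows$key
  structure(list(windows = windows[keep, , drop = FALSE],
                 meth = meth[keep, , drop = FALSE],
                 cov = covm[keep, , drop = FALSE],
                 nsites = nsit[keep, , drop = FALSE],
                 window_size = window_size),
            class = "meth_windows")
}

#' Construct a meth_windows object from window-level count matrices
#'
#' Used when counts are already aggregated per window (e.g. by the
#' synthetic generator's window-level mode).
#'
#' @param windows Data frame with `chrom`, `start`, `end`.
#' @param meth,cov Windows-by-samples integer matrices.
#' @param nsites Optional matrix of contributing CpG counts.
#' @param window_size Grid width in bp.
#' @return A `meth_windows` object.
#' @export
meth_windows <- function(windows, meth, cov, nsites = NULL,
                         window_size = 1000) {
  stopifnot(nrow(windows) == nrow(meth), all(dim(meth) == dim(cov)))
  if (any(meth > cov)) stop("meth counts exceed coverage")
  if (is.null(nsites)) nsites <- matrix(1L, nrow(meth), ncol(meth))
  windows$key <- window_key(windows$chrom, windows$start, windows$end)
  colnames(nsites) <- colnames(cov) <- colnames(meth)
  rownames(meth) <- rownames(cov) <- rownames(nsites) <- windows$key
  structure(list(windows = windows, meth = meth, cov = cov, nsites = nsites,
                 window_size = window_size),
            class = "meth_windows")
}

#' @export
print.meth_windows <- function(x, ...) {
  cat("meth_windows: ", nrow(x$windows), " windows x ", ncol(x$meth),
      " samples (", x$window_size, " bp grid)\n", sep = "")
  invisible(x)
}

#' @export
dim.meth_windows <- function(x) dim(x$meth)

#' Subset a meth_windows object by windows and/or samples
#'
#' @param x A `meth_windows` object.
#' @param i Window selector (indices, logical, or window keys).
#' @param j Sample selector (indices, logical, or sample ids).
#' @param ... Ignored.
#' @export
`[.meth_windows` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$meth))
  if (missing(j)) j <- seq_len(ncol(x$meth))
  if (is.character(i)) i <- match(i, x$windows$key)
  structure(list(windows = x$windows[i, , drop = FALSE],
                 meth = x$meth[i, j, drop = FALSE],
                 cov = x$cov[i, j, drop = FALSE],
                 nsites = x$nsites[i, j, drop = FALSE],
                 window_size = x$window_size),
            class = "meth_windows")
}

#' Per-sample window methylation levels
#'
#' Methylation level of a window in a sample is the total methylated read
#' calls divided by the total read calls over the window's CpG sites; `NA`
#' where a sample has no coverage in the window.
#'
#' @param x A `meth_windows` object.
#' @return A windows-by-samples numeric matrix with values in \[0, 1\].
#' @export
meth_levels <- function(x) {
  lv <- x$meth / x$cov
  lv[x$cov == 0] <- NA_real_
  lv
}

# Binomial log-likelihood term with the 0*log(0) = 0 convention.
.ll <- function(m, u, p) {
  out <- numeric(length(m))
  nz <- m > 0
  out[nz] <- m[nz] * log(p[nz])
  nz <- u > 0
  out[nz] <- out[nz] + u[nz] * log(1 - p[nz])
  out
}

#' Test windows for differential methylation between two groups
#'
#' For every window, fits a binomial logistic regression of the per-sample
#' (methylated, unmethylated) counts on a two-level group indicator and
#' tests the group term with a 1-df likelihood-ratio chi-square. Because
#' the model is saturated in the grouping, the maximum-likelihood fitted
#' proportions are the pooled per-group proportions and the statistic has a
#' closed form, so the fit cannot fail even under complete separation.
#'
#' The methylation difference is reported in percentage points as the
#' unweighted mean of per-sample window levels in the test group minus the
#' control group (samples with no coverage in the window are dropped);
#' `diff_method = "pooled"` uses pooled counts instead. Windows where
#' either group has no covered sample get `p = NA` and are flagged
#' untestable.
#'
#' @param x A `meth_windows` object.
#' @param test_ids,control_ids Sample ids of the test and control groups.
#' @param diff_method `"mean"` (default) or `"pooled"`.
#' @return A data frame with one row per window: `chrom`, `start`, `end`,
#'   `key`, `meth_diff` (percentage points, test minus control), `p`, `q`
#'   (`NA` until [adjust_fdr()] is applied), `direction` (`"hyper"` when
#'   `meth_diff > 0`, else `"hypo"`) and `untestable`.
#' @export
dmr_test <- function(x, test_ids, control_ids,
                     diff_method = c("mean", "pooled")) {
  diff_method <- match.arg(diff_method)
  stopifnot(inherits(x, "meth_windows"))
  miss <- setdiff(c(test_ids, control_ids), colnames(x$meth))
  if (length(miss) > 0L) stop("unknown sample ids: ", paste(miss, collapse = ", "))
  if (length(intersect(test_ids, control_ids)) > 0L)
    stop("test and control groups overlap")
  m1 <- x$meth[, test_ids, drop = FALSE]
  c1 <- x$cov[, test_ids, drop = FALSE]
  m2 <- x$meth[, control_ids, drop = FALSE]
  c2 <- x$cov[, control_ids, drop = FALSE]
  M1 <- rowSums(m1); C1 <- rowSums(c1)
  M2 <- rowSums(m2); C2 <- rowSums(c2)
  n_cov1 <- rowSums(c1 > 0); n_cov2 <- rowSums(c2 > 0)
  untestable <- n_cov1 == 0 | n_cov2 == 0

  p1 <- ifelse(C1 > 0, M1 / C1, NA_real_)
  p2 <- ifelse(C2 > 0, M2 / C2, NA_real_)
  p0 <- ifelse(C1 + C2 > 0, (M1 + M2) / (C1 + C2), NA_real_)
  lrt <- 2 * (.ll(M1, C1 - M1, p1) + .ll(M2, C2 - M2, p2) -
                .ll(M1 + M2, C1 + C2 - M1 - M2, p0))
  lrt[lrt < 0] <- 0  # guard tiny negative rounding
  pval <- stats::pchisq(lrt, df = 1L, lower.tail = FALSE)
  pval[untestable] <- NA_real_

  if (diff_method == "mean") {
    l1 <- m1 / c1; l1[c1 == 0] <- NA
    l2 <- m2 / c2; l2[c2 == 0] <- NA
    diff <- 100 * (rowMeans(l1, na.rm = TRUE) - rowMeans(l2, na.rm = TRUE))
  } else {
    diff <- 100 * (p1 - p2)
  }
  diff[untestable] <- NA_real_

  out <- x$windows
  out$meth_diff <- as.numeric(diff)
  out$p <- as.numeric(pval)
  out$q <- NA_real_
  out$direction <- ifelse(out$meth_diff > 0, "hyper", "hypo")
  out$direction[is.na(out$meth_diff)] <- NA_character_
  out$untestable <- untestable
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment over the non-`NA` entries; `NA`s pass through.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Vector of q-values, same length and order.
#' @export
adjust_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must be in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Filter DMR results by FDR and absolute methylation difference
#'
#' @param results DMR result data frame with `q` populated.
#' @param q_max Maximum q-value (e.g. 0.05).
#' @param min_abs_diff Minimum absolute methylation difference in
#'   percentage points (e.g. 10 for the prognostic gate, 20 for the
#'   predictive candidate gate).
#' @return The retained rows, input order preserved.
#' @export
filter_dmrs <- function(results, q_max, min_abs_diff) {
  if (all(is.na(results$q)) && nrow(results) > 0L)
    stop("q column not populated; run adjust_fdr() first")
  keep <- !is.na(results$q) & results$q <= q_max &
    !is.na(results$meth_diff) & abs(results$meth_diff) >= min_abs_diff
  results[keep, , drop = FALSE]
}
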