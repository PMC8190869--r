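# Jonckheere-Terpstra statistic: sum over ordered group pairs (i < j) of
# #{x in g_i, y in g_j : x < y} + 0.5 * #{x == y}.
.jt_stat <- function(groups) {
  k <- length(groups)
  s <- 0
  for (i in seq_len(k - 1L)) {
    xi <- groups[[i]]
    for (j in seq.int(i + 1L, k)) {
      xj <- groups[[j]]
      s <- s + sum(outer(xi, xj, "<")) + 0.5 * sum(outer(xi, xj, "=="))
    }
  }
  s
}

# Tie-corrected null mean and variance (Hollander-Wolfe form) of the JT
# statistic for group sizes n and pooled tie-group sizes t.
.jt_null <- function(n, t) {
  N <- sum(n)
  mu <- (N^2 - sum(n^2)) / 4
  v1 <- (N * (N - 1) * (2 * N + 5) -
           sum(n * (n - 1) * (2 * n + 5)) -
           sum(t * (t - 1) * (2 * t + 5))) / 72
  v2 <- sum(n * (n - 1) * (n - 2)) * sum(t * (t - 1) * (t - 2)) /
    (36 * N * (N - 1) * (N - 2))
  v3 <- sum(n * (n - 1)) * sum(t * (t - 1)) / (8 * N * (N - 1))
  list(mean = mu, var = v1 + v2 + v3)
}

#' Jonckheere-Terpstra test for an ordered trend across groups
#'
#' Tests for a monotone trend of a numeric response across groups supplied
#' in a prespecified order, using the sum of pairwise Mann-Whitney counts
#' (ties counted 0.5). Two p-value modes are available: a tie-corrected
#' normal approximation with a 0.5 continuity correction, and a label
#' permutation mode returning the two-sided empirical p-value with
#' add-one smoothing. `mode = "auto"` uses permutation when the pooled
#' sample size is at most 12 and the normal approximation otherwise.
#' The test is two-sided: both increasing and decreasing trends reject.
#'
#' @param groups List of numeric vectors in the hypothesized order
#'   (at least 2 non-empty groups).
#' @param mode `"auto"`, `"normal"` or `"permutation"`.
#' @param n_perm Number of permutations (permutation mode).
#' @param seed Integer seed for the permutation mode.
#' @return An object of class `jonckheere`: list with `jt_stat`, `z`, `p`,
#'   `mode`, `n_per_group`, `degenerate`.
#' @export
jonckheere_test <- function(groups, mode = c("auto", "normal", "permutation"),
                            n_perm = 10000, seed = 1L) {
  mode <- match.arg(mode)
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  if (length(groups) < 2L || any(lengths(groups) == 0L))
    stop("need >= 2 non-empty groups")
  n <- lengths(groups)
  N <- sum(n)
  pooled <- unlist(groups, use.names = FALSE)
  if (mode == "auto") mode <- if (N <= 12L) "permutation" else "normal"
  jt <- .jt_stat(groups)
  nullm <- .jt_null(n, as.numeric(table(pooled)))
  res <- list(jt_stat = jt, n_per_group = n, mode = mode,
              degenerate = FALSE)
  if (nullm$var <= 0 || length(unique(pooled)) == 1L) {
    res$z <- 0; res$p <- 1; res$degenerate <- TRUE
    class(res) <- "jonckheere"
    return(res)
  }
  if (mode == "normal") {
    d <- jt - nullm$mean
    dcc <- sign(d) * max(0, abs(d) - 0.5)  # continuity correction
    z <- dcc / sqrt(nullm$var)
    res$z <- z
    res$p <- min(1, 2 * stats::pnorm(-abs(z)))
  } else {
    set.seed(seed)
    idx <- rep(seq_along(groups), n)
    obs <- abs(jt - nullm$mean)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      perm <- split(pooled[sample.int(N)], idx)
      if (abs(.jt_stat(perm) - nullm$mean) >= obs - 1e-12) hits <- hits + 1L
    }
    res$z <- (jt - nullm$mean) / sqrt(nullm$var)
    res$p <- (1 + hits) / (n_perm + 1)
  }
  class(res) <- "jonckheere"
  res
}

#' @export
print.jonckheere <- function(x, ...) {
  cat("Jonckheere-Terpstra trend test (", x$mode, ")\n", sep = "")
  cat("  JT = ", x$jt_stat, ", z = ", signif(x$z, 4),
      ", p = ", signif(x$p, 4), "\n", sep = "")
  cat("  group sizes:", paste(x$n_per_group, collapse = ", "), "\n")
  if (x$degenerate) cat("  degenerate: all pooled values identical\n")
  invisible(x)
}

#' Jonckheere trend test for every window across ordered sample groups
#'
#' Runs [jonckheere_test()] on each window's per-sample methylation levels,
#' with samples grouped by `samples$stage` in the given order. Samples with
#' an `NA` level in a window are dropped for that window; windows where any
#' ordered group becomes empty are flagged untestable.
#'
#' @param x A `meth_windows` object.
#' @param samples Sample sheet data frame (needs `sample_id`, `stage`);
#'   only samples whose stage is in `order` are used.
#' @param order Ordered group labels (default adjacent, I, II, IV).
#' @param mode,n_perm,seed Passed to [jonckheere_test()].
#' @return Data frame with one row per window: window columns plus
#'   `jt_stat`, `z`, `p`, `untestable`.
#' @export
trend_test_all <- function(x, samples, order = c("adjacent", "I", "II", "IV"),
                           mode = "normal", n_perm = 10000, seed = 1L) {
  samples <- samples[samples$stage %in% order, , drop = FALSE]
  ids <- samples$sample_id
  miss <- setdiff(ids, colnames(x$meth))
  if (length(miss) > 0L) stop("samples absent from windows: ",
                              paste(miss, collapse = ", "))
  grp <- factor(samples$stage, levels = order)
  lv <- meth_levels(x)[, ids, drop = FALSE]
  W <- nrow(lv)
  jt <- z <- p <- rep(NA_real_, W)
  untestable <- rep(FALSE, W)
  gidx <- as.integer(grp)
  for (w in seq_len(W)) {
    vals <- lv[w, ]
    ok <- !is.na(vals)
    tab <- tabulate(gidx[ok], nbins = length(order))
    if (any(tab == 0L)) { untestable[w] <- TRUE; next }
    res <- jonckheere_test(split(vals[ok], gidx[ok]), mode = mode,
                           n_perm = n_perm, seed = seed)
    jt[w] <- res$jt_stat; z[w] <- res$z; p[w] <- res$p
  }
  out <- x$windows
  out$jt_stat <- jt; out$z <- z; out$p <- p
  out$untestable <- untestable
  rownames(out) <- NULL
  out
}

#' Select windows with a significant stage trend
#'
#' @inheritParams trend_test_all
#' @param alpha Significance threshold on the trend p-value (default 0.05).
#' @return The windows (rows of `x$windows` plus trend columns) with
#'   `p <= alpha`; untestable windows are excluded and their count is
#'   attached as attribute `n_untestable`.
#' @export
trend_filter <- function(x, samples, order = c("adjacent", "I", "II", "IV"),
                         alpha = 0.05, mode = "normal", n_perm = 10000,
                         seed = 1L) {
  res <- trend_test_all(x, samples, order = order, mode = mode,
                        n_perm = n_perm, seed = seed)
  keep <- !res$untestable & !is.na(res$p) & res$p <= alpha
  out <- res[keep, , drop = FALSE]
  attr(out, "n_untestable") <- sum(res$untestable)
  attr(out, "n_tested") <- sum(!res$untestable)
  out
}
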