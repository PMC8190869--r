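# Independent brute-force oracles used to check the package's statistics.
# These are deliberately naive implementations, kept separate from the
# code paths they validate.

# Step-up Benjamini-Hochberg from the textbook formula:
# q_(i) = min_{j >= i} m * p_(j) / j, capped at 1.
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- pmin(1, m * ps / seq_len(m))
  for (i in rev(seq_len(m - 1))) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[ord] <- q
  out
}

# Jonckheere-Terpstra statistic straight from its definition: for every
# ordered pair of groups, count increasing cross-group value pairs (ties
# contribute one half).
jt_bruteforce <- function(groups) {
  s <- 0
  k <- length(groups)
  for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
    lt <- outer(groups[[i]], groups[[j]], `<`)
    eq <- outer(groups[[i]], groups[[j]], `==`)
    s <- s + sum(lt) + 0.5 * sum(eq)
  }
  s
}

# Exact permutation distribution of the JT statistic: enumerate every
# assignment of the pooled values to groups of the given sizes.
jt_exact_distribution <- function(values, sizes) {
  stats_out <- numeric(0)
  recurse <- function(remaining, gi, acc) {
    if (gi > length(sizes)) {
      stats_out[length(stats_out) + 1] <<- jt_bruteforce(acc)
      return(invisible(NULL))
    }
    idx <- utils::combn(length(remaining), sizes[gi], simplify = FALSE)
    for (ix in idx) {
      recurse(remaining[-ix], gi + 1, c(acc, list(remaining[ix])))
    }
  }
  recurse(values, 1, list())
  stats_out
}

# Exact two-sided p for an observed JT value: distance from the null mean
# over the exhaustive assignment distribution.
jt_exact_p <- function(dist, observed) {
  mu <- mean(dist)
  mean(abs(dist - mu) >= abs(observed - mu) - 1e-9)
}

# All-pairs interval overlap scan (1-based inclusive, >= 1 shared base).
overlap_bruteforce <- function(windows, regions) {
  hit <- logical(nrow(windows))
  for (r in seq_len(nrow(regions))) {
    hit <- hit | (windows$chrom == regions$chrom[r] &
                    windows$start <= regions$end[r] &
                    windows$end >= regions$start[r])
  }
  hit
}

# AUC by exhaustive concordant-pair counting, ties counted 0.5.
auc_bruteforce <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# A scaled-down cohort configuration for tests that only need the sample
# sheet or a handful of windows.
tiny_config <- function(n_windows = 20, seed = 1, ...) {
  sim_config(n_windows = n_windows, n_dmr = 2, n_trend = 2,
             n_prognostic = 2, n_predictive = 2, seed = seed, ...)
}

# Small two-group window fixture with exact counts.
make_mw <- function(meth, cov, chrom = "chr1") {
  W <- nrow(meth)
  windows <- data.frame(chrom = chrom,
                        start = (seq_len(W) - 1L) * 1000L + 1L,
                        end = seq_len(W) * 1000L)
  meth_windows(windows, meth, cov)
}
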