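test_that("tiling assigns sites to the fixed 1-anchored grid and sums counts", {
  sites <- list(
    s1 = data.frame(chrom = "chr11", pos = c(1861001L, 1861500L),
                    meth = c(3L, 5L), unmeth = c(7L, 5L)),
    s2 = data.frame(chrom = "chr11", pos = 1861999L,
                    meth = 2L, unmeth = 2L))
  mw <- tile_windows(sites)
  expect_equal(mw$windows$key, "chr11:1861001-1862000")
  expect_equal(unname(mw$meth[1, ]), c(8, 2))
  expect_equal(unname(mw$cov[1, ]), c(20, 4))
  expect_equal(unname(meth_levels(mw)[1, "s1"]), 0.4)
})

test_that("sites below the per-site coverage floor are excluded from sums", {
  sites <- list(
    s1 = data.frame(chrom = "chr1", pos = c(10L, 20L),
                    meth = c(1L, 4L), unmeth = c(0L, 4L)))
  mw <- tile_windows(sites, min_site_coverage = 2)
  expect_equal(unname(mw$cov[1, 1]), 8)   # the coverage-1 site dropped
  expect_equal(unname(mw$nsites[1, 1]), 1L)
  mw1 <- tile_windows(sites, min_site_coverage = 1)
  expect_equal(unname(mw1$cov[1, 1]), 9)
  expect_error(tile_windows(sites, window_size = 0), "positive")
})

test_that("identical groups give zero difference and a null p-value", {
  meth <- matrix(c(5, 3, 5, 3), 2, 2)
  cov <- matrix(10, 2, 2)
  mw <- make_mw(meth, cov)
  colnames(mw$meth) <- colnames(mw$cov) <- colnames(mw$nsites) <- c("a", "b")
  res <- dmr_test(mw, "a", "b")
  expect_equal(res$meth_diff, c(0, 0))
  expect_true(all(res$p >= 0.99))
})

test_that("the window LRT tracks the Fisher exact test on a 2x2 fixture", {
  mw <- make_mw(matrix(c(18, 5), 1, 2), matrix(c(20, 20), 1, 2))
  colnames(mw$meth) <- colnames(mw$cov) <- colnames(mw$nsites) <- c("t", "c")
  res <- dmr_test(mw, "t", "c")
  # frozen from the closed-form likelihood-ratio statistic:
  # G = 2[18 log(.9/.575) + 2 log(.1/.425) + 5 log(.25/.575) + 15 log(.75/.425)]
  expect_equal(res$p, 1.272281e-05, tolerance = 1e-5)
  # order-of-magnitude agreement with the Fisher exact oracle (the exact
  # test is conservative at these extreme discrete counts: ratio ~5.4)
  fisher_p <- fisher.test(matrix(c(18, 2, 5, 15), 2, byrow = TRUE))$p.value
  expect_gt(res$p, fisher_p / 10)
  expect_lt(res$p, fisher_p * 10)
  expect_equal(res$direction, "hyper")
})

test_that("fully separated methylation yields the extreme difference", {
  mw <- make_mw(matrix(c(20, 20, 0, 0), 1, 4), matrix(20, 1, 4))
  colnames(mw$meth) <- colnames(mw$cov) <- colnames(mw$nsites) <-
    c("t1", "t2", "c1", "c2")
  res <- dmr_test(mw, c("t1", "t2"), c("c1", "c2"))
  expect_equal(res$meth_diff, 100)
  expect_equal(res$direction, "hyper")
  expect_true(is.finite(res$p) && res$p < 1e-10)
})

test_that("swapping group labels preserves p and flips the difference sign", {
  mw <- simulate_window_counts(5, 5, n_windows = 100, n_planted = 20,
                               effect_pp = 25, seed = 11)
  t_ids <- paste0("T", 1:5); c_ids <- paste0("C", 1:5)
  a <- dmr_test(mw, t_ids, c_ids)
  b <- dmr_test(mw, c_ids, t_ids)
  expect_equal(a$p, b$p)
  expect_equal(a$meth_diff, -b$meth_diff)
})

test_that("windows uncovered in one group are flagged untestable", {
  mw <- make_mw(matrix(c(0, 5), 1, 2), matrix(c(0, 10), 1, 2))
  colnames(mw$meth) <- colnames(mw$cov) <- colnames(mw$nsites) <- c("t", "c")
  res <- dmr_test(mw, "t", "c")
  expect_true(res$untestable)
  expect_true(is.na(res$p))
})

test_that("BH adjustment matches the hand-applied step-up formula", {
  expect_equal(adjust_fdr(0.03), 0.03)
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_fdr(c(0.01, NA, 0.5)), c(0.02, NA, 0.5))
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH adjustment equals the brute-force oracle on random vectors", {
  set.seed(401)
  for (i in 1:100) {
    p <- runif(sample(1:50, 1))
    expect_equal(adjust_fdr(p), bh_bruteforce(p))
  }
})

test_that("the q/difference gate keeps exactly the passing windows", {
  res <- data.frame(key = c("a", "b", "c"),
                    meth_diff = c(12, -12, 50),
                    q = c(0.04, 0.04, 0.06))
  kept <- filter_dmrs(res, q_max = 0.05, min_abs_diff = 10)
  expect_equal(kept$key, c("a", "b"))   # |diff| is symmetric, q gates "c"
  expect_error(filter_dmrs(data.frame(meth_diff = 1, q = NA), 0.05, 10),
               "adjust_fdr")
})

test_that("planted differential windows are recovered through the gate", {
  mw <- simulate_window_counts(10, 10, n_windows = 500, n_planted = 50,
                               effect_pp = 30, seed = 21)
  res <- dmr_test(mw, paste0("T", 1:10), paste0("C", 1:10))
  res$q <- adjust_fdr(res$p)
  hits <- filter_dmrs(res, 0.05, 10)
  truth <- attr(mw, "truth")
  expect_gte(mean(truth$key %in% hits$key), 0.9)
  expect_gte(mean(hits$key %in% truth$key), 0.9)
})
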