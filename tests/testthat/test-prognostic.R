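grid_key <- function(i) window_key("chr1", (i - 1L) * 1000L + 1L, i * 1000L)

test_that("the three-way intersection equals brute-force set algebra", {
  A <- grid_key(1:6); B <- grid_key(4:9); C <- grid_key(5:12)
  ps <- intersect_filters(A, B, C)
  expect_setequal(ps$markers$key, grid_key(5:6))
  expect_equal(ps$counts$intersection, 2L)
  expect_equal(ps$counts$candidate, 6L)
  expect_equal(ps$counts$trend, 6L)
  expect_equal(ps$counts$promoter, 8L)
  # Venn regions partition each input set
  with(ps$counts, {
    expect_equal(candidate_only + candidate_trend + candidate_promoter +
                   intersection, candidate)
    expect_equal(trend_only + candidate_trend + trend_promoter +
                   intersection, trend)
  })
  # order independence and idempotence
  ps2 <- intersect_filters(A, C, B)
  expect_setequal(ps2$markers$key, ps$markers$key)
  ps3 <- intersect_filters(ps$markers$key, B, C)
  expect_setequal(ps3$markers$key, ps$markers$key)
})

test_that("empty or disjoint inputs give an empty intersection with counts kept", {
  expect_equal(intersect_filters(grid_key(1:3), character(0),
                                 grid_key(1:3))$counts$intersection, 0L)
  ps <- intersect_filters(grid_key(1:3), grid_key(4:6), grid_key(1:6))
  expect_equal(ps$counts$intersection, 0L)
  expect_equal(ps$counts$candidate, 3L)
  expect_equal(ps$counts$trend, 3L)
})

test_that("inconsistent window grids are rejected", {
  expect_error(intersect_filters(c("chr1:1500-2499"), grid_key(1:2),
                                 grid_key(1:2)), "grid")
})

test_that("direction tallies come from the difference sign", {
  cand <- data.frame(key = grid_key(1:4),
                     meth_diff = c(15, -12, 30, -25))
  ps <- intersect_filters(cand, grid_key(1:4), grid_key(1:4))
  expect_equal(ps$n_hyper, 2L)
  expect_equal(ps$n_hypo, 2L)
  expect_equal(ps$n_hyper + ps$n_hypo, nrow(ps$markers))
})

test_that("identical distributions give p = 1 in the confounder screen", {
  ids <- sprintf("s%02d", 1:38)
  samples <- data.frame(sample_id = ids, patient_id = ids,
                        tissue = "primary", stage = "II",
                        age = c(rep(50, 16), rep(65, 22)),
                        smoker = c(rep("yes", 16), rep("no", 21), NA))
  cov <- matrix(100L, 3, 38, dimnames = list(NULL, ids))
  meth <- matrix(rep(c(30L, 50L, 70L), 38), 3, 38, dimnames = list(NULL, ids))
  mw <- make_mw(meth, cov)
  colnames(mw$meth) <- colnames(mw$cov) <- colnames(mw$nsites) <- ids
  tab <- confounder_wilcoxon(mw$windows$key, mw, samples, split = "age_median")
  expect_true(all(tab$p == 1))
  expect_equal(attr(tab, "n_significant"), 0L)
  expect_equal(attr(tab, "group_sizes"), c(22, 16))
})

test_that("a strong age-associated shift is detected at q < 0.1", {
  set.seed(43)
  ids <- sprintf("s%02d", 1:38)
  samples <- data.frame(sample_id = ids, patient_id = ids,
                        tissue = "primary", stage = "II",
                        age = c(rep(50, 16), rep(65, 22)),
                        smoker = "no")
  old <- samples$age >= 60
  lv <- matrix(runif(5 * 38, 0.2, 0.4), 5, 38)
  lv[1, old] <- lv[1, old] + 0.4
  cov <- matrix(200L, 5, 38)
  meth <- matrix(rbinom(5 * 38, 200L, lv), 5, 38)
  mw <- make_mw(meth, cov)
  colnames(mw$meth) <- colnames(mw$cov) <- colnames(mw$nsites) <- ids
  tab <- confounder_wilcoxon(mw$windows$key, mw, samples, split = "age_median")
  expect_lt(tab$q[1], 0.1)
  expect_error(confounder_wilcoxon(mw$windows$key, mw,
                                   transform(samples, age = 70),
                                   split = "age_median"), "empty")
})

test_that("null marker levels stay below the FDR threshold", {
  set.seed(47)
  ids <- sprintf("s%02d", 1:38)
  samples <- data.frame(sample_id = ids, patient_id = ids,
                        tissue = "primary", stage = "II",
                        age = c(rep(50, 16), rep(65, 22)), smoker = "no")
  hits <- vapply(1:5, function(rep) {
    meth <- matrix(rbinom(200 * 38, 100L, 0.4), 200, 38)
    mw <- make_mw(meth, matrix(100L, 200, 38))
    colnames(mw$meth) <- colnames(mw$cov) <- colnames(mw$nsites) <- ids
    attr(confounder_wilcoxon(mw$windows$key, mw, samples,
                             split = "age_median"), "n_significant")
  }, 0L)
  expect_gte(sum(hits == 0L), 4L)  # zero significant in the large majority
})

test_that("cohort summary reproduces the clinical table arithmetic", {
  co <- simulate_cohort(tiny_config(n_windows = 10, seed = 2))
  s <- cohort_summary(co$samples)
  expect_equal(s$n, 59L)
  expect_equal(unname(s$stage_counts), c(11L, 38L, 10L))
  expect_equal(unname(s$stage_pct), c(18.6, 64.4, 16.9))
  expect_equal(unname(s$sex), c(61.0, 39.0))
  expect_equal(unname(s$age), c(54.2, 45.8))
  expect_equal(unname(s$smoking), c(27.1, 71.2, 1.7))
  expect_equal(s$no_metastasis_pct, 50.8)
  expect_equal(s$n_metastatic, 29L)
  expect_equal(s$lim_among_metastatic_pct, 75.9)
  expect_equal(unname(s$lim_counts), c(1L, 11L, 10L))
  expect_equal(unname(s$lum_counts), c(1L, 6L, 2L))
})
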