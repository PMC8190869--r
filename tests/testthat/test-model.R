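test_that("ROC handles the canonical fixtures", {
  perfect <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  flat <- roc_curve(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(flat$auc, 0.5)
  mixed <- roc_curve(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))
  expect_equal(mixed$auc, 0.75)   # 3 of 4 pairs concordant
  expect_error(roc_curve(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("AUC equals exhaustive pair counting on random fixtures", {
  set.seed(53)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    scores <- round(runif(n), sample(1:3, 1))  # rounding makes ties
    r <- roc_curve(scores, labels)
    expect_equal(r$auc, auc_bruteforce(scores, labels))
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
  }
})

test_that("candidate selection recovers planted windows and honors the gate", {
  mw <- simulate_window_counts(12, 12, n_windows = 300, n_planted = 10,
                               effect_pp = 30, seed = 59)
  t_ids <- paste0("T", 1:12); c_ids <- paste0("C", 1:12)
  cand <- select_candidates(mw, t_ids, c_ids, q_max = 0.05,
                            min_abs_diff = 20)
  truth <- attr(mw, "truth")
  expect_true(all(truth$key %in% cand))
  all_cand <- select_candidates(mw, t_ids, c_ids, q_max = 1, min_abs_diff = 0)
  tab <- attr(all_cand, "dmr_table")
  expect_equal(sort(all_cand), sort(tab$key[!tab$untestable]))
  expect_error(select_candidates(mw, "T1", c_ids), "2 samples per class")
})

test_that("a perfectly separating column is selected among noise", {
  set.seed(61)
  picked <- vapply(1:5, function(rep) {
    n <- 40
    X <- matrix(runif(n * 51), n, 51)
    colnames(X) <- c("signal", paste0("noise", 1:50))
    y <- rep(c(TRUE, FALSE), each = n / 2)
    X[, "signal"] <- ifelse(y, runif(n, 0.7, 1), runif(n, 0, 0.3))
    mod <- fit_lasso(X, y, seed = rep)
    "signal" %in% mod$markers
  }, TRUE)
  expect_gte(mean(picked), 0.95)
})

test_that("with no candidates the null model predicts the prevalence", {
  y <- c(rep(TRUE, 3), rep(FALSE, 7))
  expect_warning(mod <- fit_lasso(NULL, y), "null model")
  expect_equal(length(mod$markers), 0L)
  newX <- matrix(runif(4), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(predict(mod, newX)), rep(0.3, 2))
})

test_that("duplicated columns leave the prediction invariant", {
  set.seed(67)
  n <- 40
  X <- matrix(runif(n * 10), n, 10, dimnames = list(NULL, paste0("w", 1:10)))
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X[, 1] <- ifelse(y, runif(n, 0.6, 1), runif(n, 0, 0.4))
  Xdup <- cbind(X, w1b = X[, 1])
  m1 <- fit_lasso(X, y, seed = 3)
  m2 <- fit_lasso(Xdup, y, seed = 3)
  p1 <- predict(m1, X)
  p2 <- predict(m2, Xdup)
  expect_equal(p1, p2, tolerance = 0.05)
})

test_that("LOOCV never leaks the held-out sample into fold internals", {
  mw <- simulate_window_counts(8, 10, n_windows = 120, n_planted = 4,
                               effect_pp = 40, seed = 71)
  ids <- colnames(mw$meth)
  labels <- setNames(startsWith(ids, "T"), ids)
  base <- loocv_scores(mw, labels, seed = 9)
  # perturb the held-out sample's counts drastically
  mw2 <- mw
  held <- ids[1]
  mw2$meth[, held] <- pmin(mw2$cov[, held], mw2$meth[, held] + 50)
  pert <- loocv_scores(mw2, labels, seed = 9)
  expect_identical(base$folds[[held]]$candidates,
                   pert$folds[[held]]$candidates)
  expect_identical(base$folds[[held]]$coefficients,
                   pert$folds[[held]]$coefficients)
  # the held-out score itself may change; other folds' scores do change
  # only through their own training sets, which include the perturbed sample
})

test_that("degenerate LOOCV with one sample per class flags both folds", {
  mw <- simulate_window_counts(1, 1, n_windows = 30, seed = 73)
  labels <- setNames(c(TRUE, FALSE), colnames(mw$meth))
  res <- loocv_scores(mw, labels)
  expect_setequal(res$flagged, names(labels))
  expect_true(all(res$scores %in% c(0, 1)))
})

test_that("planted markers give high pooled LOOCV AUC", {
  mw <- simulate_window_counts(10, 14, n_windows = 200, n_planted = 5,
                               effect_pp = 40, seed = 79)
  labels <- setNames(startsWith(colnames(mw$meth), "T"), colnames(mw$meth))
  res <- loocv_scores(mw, labels, seed = 11)
  expect_gt(roc_curve(res$scores, labels)$auc, 0.85)
})

test_that("the final model annotates markers with context and direction", {
  co <- simulate_cohort(sim_config(n_windows = 200, seed = 83))
  mw <- tile_windows(co$sites)
  ann <- simulate_annotation(co)
  pri <- co$samples[co$samples$tissue == "primary", ]
  labels <- setNames(!is.na(pri$lim) & pri$lim, pri$sample_id)
  pr <- extract_promoters(ann)
  mod <- final_model(mw[, pri$sample_id], labels, seed = 2,
                     promoters = pr, genes = ann)
  expect_s3_class(mod, "dmr_lasso")
  expect_named(mod$marker_table,
               c("key", "chrom", "start", "end", "gene_context",
                 "gene_name", "direction", "coefficient"))
  expect_true(all(mod$marker_table$gene_context %in%
                    c("promoter", "gene_body", "intergenic")))
  expect_true(all(mod$marker_table$direction %in% c("hyper", "hypo")))
  expect_equal(coef(mod)[["(Intercept)"]], mod$intercept)
})

test_that("external scoring policies coincide when all markers are present", {
  set.seed(89)
  n <- 30
  X <- matrix(runif(n * 6), n, 6, dimnames = list(NULL, paste0("w", 1:6)))
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X[, 1] <- ifelse(y, runif(n, 0.6, 1), runif(n, 0, 0.4))
  X[, 2] <- ifelse(y, runif(n, 0, 0.4), runif(n, 0.6, 1))
  mod <- fit_lasso(X, y, seed = 1)
  Xnew <- matrix(runif(5 * 6), 5, 6, dimnames = list(paste0("e", 1:5),
                                                     colnames(X)))
  a <- predict(mod, Xnew, missing_policy = "mean_impute")
  b <- predict(mod, Xnew, missing_policy = "drop_renorm")
  expect_equal(a, b)
})

test_that("missing markers drop their standardized terms from the predictor", {
  set.seed(97)
  markers <- paste0("w", 1:5)
  mod <- structure(list(
    markers = markers,
    coefficients = setNames(c(1.2, -0.8, 0.5, 0.3, -0.1), markers),
    intercept = -0.4,
    center = setNames(runif(5, 0.3, 0.6), markers),
    scale = setNames(runif(5, 0.05, 0.2), markers),
    candidates = markers, lambda = 0.01, lambda_rule = "min",
    threshold = 0.5, prevalence = 0.4, n_train = 40), class = "dmr_lasso")
  Xnew <- matrix(runif(4 * 5), 4, 5, dimnames = list(NULL, markers))
  full <- predict(mod, Xnew, type = "link")
  drop2 <- markers[1:2]
  reduced <- predict(mod, Xnew[, setdiff(markers, drop2), drop = FALSE],
                     type = "link")
  manual <- full
  for (m in drop2) {
    z <- (Xnew[, m] - mod$center[m]) / mod$scale[m]
    manual <- manual - mod$coefficients[m] * z
  }
  expect_equal(unname(reduced), unname(manual))
})

test_that("external samples are scored and evaluated against labels", {
  co <- simulate_cohort(sim_config(n_windows = 200, seed = 101))
  mw <- tile_windows(co$sites)
  pri <- co$samples[co$samples$tissue == "primary", ]
  met <- co$samples[co$samples$tissue == "metastatic", ]
  labels <- setNames(!is.na(pri$lim) & pri$lim, pri$sample_id)
  mod <- final_model(mw[, pri$sample_id], labels, seed = 2)
  ext <- score_external(mod, mw[, met$sample_id],
                        labels = setNames(met$lim, met$sample_id))
  expect_equal(length(ext$scores), 11L)
  expect_equal(ext$n_available, length(mod$markers))
  expect_gt(ext$roc$auc, 0.9)   # LIM vs LUM separation on planted markers
})
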