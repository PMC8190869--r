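#' Select candidate DMR windows on a training set
#'
#' Runs the window-level differential methylation test between the two
#' label groups of the training samples, applies Benjamini-Hochberg FDR
#' adjustment, and keeps windows passing the candidate gate
#' (default: methylation difference >= 20 percentage points, q <= 0.05).
#' Only the supplied sample ids are used, so the held-out sample of a
#' cross-validation fold never influences selection.
#'
#' @param x A `meth_windows` object.
#' @param test_ids,control_ids Training sample ids of the two classes
#'   (e.g. LIM-positive vs LIM-negative).
#' @param q_max,min_abs_diff Candidate thresholds.
#' @return Character vector of selected window keys, with the full DMR
#'   table attached as attribute `dmr_table`.
#' @export
select_candidates <- function(x, test_ids, control_ids,
                              q_max = 0.05, min_abs_diff = 20) {
  if (length(test_ids) < 2L || length(control_ids) < 2L)
    stop("need at least 2 samples per class for candidate selection")
  res <- dmr_test(x, test_ids, control_ids)
  res$q <- adjust_fdr(res$p)
  sel <- filter_dmrs(res, q_max = q_max, min_abs_diff = min_abs_diff)
  structure(sel$key, dmr_table = res)
}

.standardize <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(z = sweep(sweep(X, 2L, ctr), 2L, scl, "/"), center = ctr, scale = scl)
}

.impute_col_mean <- function(X, means = NULL) {
  if (is.null(means)) means <- colMeans(X, na.rm = TRUE)
  means[!is.finite(means)] <- 0
  for (j in seq_len(ncol(X))) {
    na <- is.na(X[, j])
    if (any(na)) X[na, j] <- means[j]
  }
  list(X = X, means = means)
}

.stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    ix <- which(y == cls)
    fold[ix] <- sample(rep_len(seq_len(n_folds), length(ix)))
  }
  fold
}

#' Fit an L1-penalized logistic regression on candidate windows
#'
#' Columns are mean-imputed and standardized to zero mean and unit
#' variance on the training data, then a logistic LASSO path is fit with
#' \pkg{glmnet} and the penalty chosen by stratified k-fold
#' cross-validated binomial deviance (the `lambda.min` convention by
#' default, `lambda_rule = "1se"` for the one-standard-error rule).
#' Penalized coefficients are reported as-is (no relaxed refit); the
#' selected markers are the windows with nonzero coefficients. With zero
#' candidates the null model (intercept at the training log-odds) is
#' returned with a warning.
#'
#' @param X Numeric matrix, training samples in rows and candidate windows
#'   in columns (column names are window keys); values are methylation
#'   levels in \[0, 1\], `NA` allowed.
#' @param y Binary labels (logical or 0/1), length `nrow(X)`.
#' @param n_folds Folds for the inner penalty-selection CV (default 10;
#'   reduced automatically when a class is smaller).
#' @param seed Integer seed governing the inner CV fold assignment.
#' @param lambda_rule `"min"` or `"1se"`.
#' @param threshold Probability cut-point stored in the model (default 0.5;
#'   typically reset to the Youden point of pooled LOOCV scores).
#' @return An object of class `dmr_lasso` with elements `markers`,
#'   `coefficients` (nonzero, on the standardized scale), `intercept`,
#'   `center`, `scale`, `candidates`, `lambda`, `threshold`, `prevalence`.
#' @export
fit_lasso <- function(X, y, n_folds = 10, seed = 1L,
                      lambda_rule = c("min", "1se"), threshold = 0.5) {
  lambda_rule <- match.arg(lambda_rule)
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2L) stop("both classes must be present in training")
  prev <- mean(y)
  if (is.null(X) || ncol(X) == 0L) {
    warning("no candidate windows; returning the null model")
    mod <- list(markers = character(0), coefficients = numeric(0),
                intercept = stats::qlogis(prev), center = numeric(0),
                scale = numeric(0), candidates = character(0),
                lambda = NA_real_, lambda_rule = lambda_rule,
                threshold = threshold, prevalence = prev, n_train = length(y))
    class(mod) <- "dmr_lasso"
    return(mod)
  }
  imp <- .impute_col_mean(X)
  std <- .standardize(imp$X)
  Z <- std$z
  dummy <- FALSE
  if (ncol(Z) == 1L) {  # glmnet needs >= 2 columns
    Z <- cbind(Z, `.dummy` = 0)
    dummy <- TRUE
  }
  nf <- min(n_folds, sum(y == 1L), sum(y == 0L))
  nf <- max(nf, 3L)
  set.seed(seed)
  foldid <- .stratified_folds(y, nf)
  cv <- glmnet::cv.glmnet(Z, y, family = "binomial", alpha = 1,
                          standardize = FALSE, foldid = foldid,
                          type.measure = "deviance")
  lam <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
  beta <- as.numeric(stats::coef(cv, s = lam))
  names(beta) <- c("(Intercept)", colnames(Z))
  if (dummy) beta <- beta[names(beta) != ".dummy"]
  coefs <- beta[-1L]
  nz <- coefs != 0
  mod <- list(markers = names(coefs)[nz], coefficients = coefs[nz],
              intercept = unname(beta[1L]),
              center = std$center, scale = std$scale,
              impute_means = imp$means,
              candidates = colnames(X), lambda = lam,
              lambda_rule = lambda_rule, threshold = threshold,
              prevalence = prev, n_train = length(y))
  class(mod) <- "dmr_lasso"
  mod
}

#' @export
print.dmr_lasso <- function(x, ...) {
  cat("L1-penalized logistic DMR model\n")
  cat("  candidates: ", length(x$candidates),
      ", selected markers: ", length(x$markers), "\n", sep = "")
  cat("  lambda = ", signif(x$lambda, 4), " (", x$lambda_rule,
      "), threshold = ", signif(x$threshold, 4), "\n", sep = "")
  cat("  trained on ", x$n_train, " samples (prevalence ",
      signif(x$prevalence, 3), ")\n", sep = "")
  invisible(x)
}

#' @export
coef.dmr_lasso <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
summary.dmr_lasso <- function(object, ...) {
  df <- data.frame(marker = object$markers,
                   coefficient = unname(object$coefficients),
                   center = unname(object$center[object$markers]),
                   scale = unname(object$scale[object$markers]))
  df[order(-abs(df$coefficient)), , drop = FALSE]
}

#' Predict liver-metastasis probability for new samples
#'
#' Standardizes the new samples' marker levels with the training center
#' and scale and applies the fitted coefficients. Markers absent from
#' `newdata` (or `NA` in a sample) are handled by `missing_policy`:
#' `"mean_impute"` sets them to the training mean, so they contribute
#' nothing on the standardized scale; `"drop_renorm"` removes their
#' coefficients and recenters the linear predictor by the training-mean
#' contribution of the dropped markers (zero after standardization, so the
#' two policies coincide under the training standardization).
#'
#' @param object A `dmr_lasso` model.
#' @param newdata Matrix of methylation levels, samples in rows, window
#'   keys as column names. Marker columns may be absent.
#' @param missing_policy `"mean_impute"` (default) or `"drop_renorm"`.
#' @param type `"response"` (probability), `"link"` or `"class"`.
#' @param ... Ignored.
#' @return Numeric vector (or logical for `type = "class"`), one per row.
#' @export
predict.dmr_lasso <- function(object, newdata,
                              missing_policy = c("mean_impute", "drop_renorm"),
                              type = c("response", "link", "class"), ...) {
  missing_policy <- match.arg(missing_policy)
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  n <- nrow(newdata)
  eta <- rep(object$intercept, n)
  markers <- object$markers
  available <- markers[markers %in% colnames(newdata) &
                         vapply(markers, function(m)
                           m %in% colnames(newdata) &&
                             any(!is.na(newdata[, m])), TRUE)]
  use <- if (missing_policy == "drop_renorm") available else markers
  for (m in use) {
    v <- if (m %in% colnames(newdata)) newdata[, m] else rep(NA_real_, n)
    z <- (v - object$center[m]) / object$scale[m]
    z[is.na(z)] <- 0  # training mean on the standardized scale
    eta <- eta + object$coefficients[m] * z
  }
  switch(type,
         link = eta,
         response = stats::plogis(eta),
         class = stats::plogis(eta) >= object$threshold)
}

#' ROC curve and AUC from probability scores
#'
#' Sweeps the classification threshold over the unique scores (rule:
#' score >= threshold is called positive) and reports the (FPR, TPR)
#' sequence, the AUC computed as the Mann-Whitney concordant-pair fraction
#' with ties counted 0.5 (identical to the trapezoidal area under the
#' empirical curve), and the sensitivity/specificity pair at the
#' Youden-maximizing threshold (ties broken toward higher specificity).
#'
#' @param scores Numeric probability scores.
#' @param labels Binary labels (logical or 0/1); both classes required.
#' @return An object of class `roc_summary`: list with `points` (data
#'   frame `threshold`, `fpr`, `tpr`), `auc`, `sensitivity`,
#'   `specificity`, `threshold`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(labels & scores >= t) / n1, 0)
  fpr <- vapply(thr, function(t) sum(!labels & scores >= t) / n0, 0)
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  j <- pts$tpr - pts$fpr
  best <- which(j == max(j))
  # among Youden ties prefer higher specificity (smaller fpr)
  best <- best[order(pts$fpr[best], -pts$tpr[best])][1L]
  structure(list(points = pts, auc = auc,
                 sensitivity = pts$tpr[best],
                 specificity = 1 - pts$fpr[best],
                 threshold = pts$threshold[best]),
            class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat("ROC: AUC = ", signif(x$auc, 4),
      ", sensitivity = ", signif(100 * x$sensitivity, 3),
      "%, specificity = ", signif(100 * x$specificity, 3),
      "% at threshold ", signif(x$threshold, 4), "\n", sep = "")
  invisible(x)
}

#' Leave-one-out cross-validated probability scores
#'
#' Each sample is held out once; candidate windows are re-selected on the
#' remaining samples only, the LASSO model is fit there, and the held-out
#' sample's probability is recorded. The per-fold candidate re-selection
#' is mandatory: the held-out sample never enters selection,
#' standardization or penalty choice. A fold whose training set loses a
#' class is scored at the training prevalence and flagged. A fold with no
#' candidates, or whose LASSO selects no markers, is scored at the
#' uninformative constant 0.5: its training prevalence would differ
#' systematically between folds holding out a positive vs a negative
#' sample and bias the pooled AUC toward 0 under the null.
#'
#' @param x A `meth_windows` object restricted to the cohort samples.
#' @param labels Named logical/binary vector of class labels, names are the
#'   sample ids of `x`.
#' @param q_max,min_abs_diff Candidate thresholds (defaults 0.05 and 20).
#' @param seed Integer seed; the inner CV fold assignment of fold *i* uses
#'   `seed + i`. LOOCV folds themselves are deterministic.
#' @param n_folds Inner CV folds for penalty selection.
#' @param lambda_rule `"min"` or `"1se"`.
#' @return An object of class `dmr_loocv`: list with `scores` (named, one
#'   per sample), `labels`, `folds` (per-fold candidates, marker count,
#'   coefficients), `flagged` (ids of degenerate folds).
#' @export
loocv_scores <- function(x, labels, q_max = 0.05, min_abs_diff = 20,
                         seed = 1L, n_folds = 10, lambda_rule = "min") {
  ids <- names(labels)
  if (is.null(ids)) stop("labels must be named by sample id")
  miss <- setdiff(ids, colnames(x$meth))
  if (length(miss) > 0L) stop("samples absent from windows: ",
                              paste(miss, collapse = ", "))
  labels <- as.logical(labels)
  names(labels) <- ids
  lv <- t(meth_levels(x)[, ids, drop = FALSE])
  scores <- stats::setNames(rep(NA_real_, length(ids)), ids)
  folds <- vector("list", length(ids))
  names(folds) <- ids
  flagged <- character(0)
  for (i in seq_along(ids)) {
    held <- ids[i]
    train <- setdiff(ids, held)
    ytr <- labels[train]
    if (length(unique(ytr)) < 2L || sum(ytr) < 2L || sum(!ytr) < 2L) {
      scores[held] <- mean(ytr)
      flagged <- c(flagged, held)
      folds[[i]] <- list(candidates = character(0), n_markers = 0L,
                         degenerate = TRUE)
      next
    }
    cand <- select_candidates(x[, train], train[ytr], train[!ytr],
                              q_max = q_max, min_abs_diff = min_abs_diff)
    cand <- as.character(cand)
    if (length(cand) == 0L) {
      # an uninformative fold is scored at 0.5, not at its training
      # prevalence: prevalence differs systematically between folds that
      # hold out a positive vs a negative sample, which biases the pooled
      # AUC toward 0 under the null
      scores[held] <- 0.5
      folds[[i]] <- list(candidates = character(0), n_markers = 0L,
                         degenerate = FALSE)
      next
    }
    mod <- suppressWarnings(
      fit_lasso(lv[train, cand, drop = FALSE], ytr,
                n_folds = n_folds, seed = seed + i,
                lambda_rule = lambda_rule))
    scores[held] <- if (length(mod$markers) == 0L) 0.5 else
      predict(mod, lv[held, cand, drop = FALSE])
    folds[[i]] <- list(candidates = cand, n_markers = length(mod$markers),
                       coefficients = coef(mod), degenerate = FALSE)
  }
  structure(list(scores = scores, labels = labels, folds = folds,
                 flagged = flagged),
            class = "dmr_loocv")
}

#' @export
print.dmr_loocv <- function(x, ...) {
  cat("LOOCV pooled scores for ", length(x$scores), " samples (",
      sum(x$labels), " positive)\n", sep = "")
  if (length(x$flagged) > 0L)
    cat("  degenerate folds:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Fit the final predictive model on the full cohort
#'
#' After LOOCV evaluation, candidate windows are re-selected on all
#' samples and a single LASSO fit yields the final marker panel. When an
#' annotation is supplied the markers are annotated with their gene
#' context (promoter / gene body / intergenic, nearest-TSS gene) and their
#' hyper/hypo direction from the full-cohort methylation difference.
#'
#' @inheritParams loocv_scores
#' @param promoters,genes Optional annotation (see [extract_promoters()],
#'   [read_gtf_genes()]) for the marker table.
#' @param threshold Probability cut-point stored in the model.
#' @return A `dmr_lasso` model with an additional `marker_table` data
#'   frame (`key`, `chrom`, `start`, `end`, `gene_context`, `gene_name`,
#'   `direction`, `coefficient`).
#' @export
final_model <- function(x, labels, q_max = 0.05, min_abs_diff = 20,
                        seed = 1L, n_folds = 10, lambda_rule = "min",
                        promoters = NULL, genes = NULL, threshold = 0.5) {
  ids <- names(labels)
  labels <- as.logical(labels)
  names(labels) <- ids
  cand <- select_candidates(x[, ids], ids[labels], ids[!labels],
                            q_max = q_max, min_abs_diff = min_abs_diff)
  dmr_tab <- attr(cand, "dmr_table")
  cand <- as.character(cand)
  lv <- t(meth_levels(x)[, ids, drop = FALSE])
  mod <- fit_lasso(if (length(cand) > 0L) lv[, cand, drop = FALSE] else NULL,
                   labels, n_folds = n_folds, seed = seed,
                   lambda_rule = lambda_rule, threshold = threshold)
  if (length(mod$markers) > 0L) {
    mw <- x$windows[match(mod$markers, x$windows$key), , drop = FALSE]
    ctx <- if (!is.null(promoters) || !is.null(genes)) {
      classify_windows(mw, promoters, genes)
    } else {
      data.frame(context = rep(NA_character_, nrow(mw)),
                 gene_name = rep(NA_character_, nrow(mw)))
    }
    dirn <- dmr_tab$direction[match(mod$markers, dmr_tab$key)]
    mod$marker_table <- data.frame(
      key = mod$markers, chrom = mw$chrom, start = mw$start, end = mw$end,
      gene_context = ctx$context, gene_name = ctx$gene_name,
      direction = dirn,
      coefficient = unname(mod$coefficients))
  } else {
    mod$marker_table <- data.frame(key = character(0), chrom = character(0),
                                   start = integer(0), end = integer(0),
                                   gene_context = character(0),
                                   gene_name = character(0),
                                   direction = character(0),
                                   coefficient = numeric(0))
  }
  mod$dmr_table <- dmr_tab
  mod
}

#' Score external samples with a fitted model
#'
#' Applies a fitted `dmr_lasso` model to samples measured separately from
#' the training cohort (e.g. metastatic tumor samples), tolerating markers
#' that are unavailable in the external data via the model's missing-data
#' policies. With labels supplied, a ROC summary against them is returned.
#'
#' @param model A `dmr_lasso` model.
#' @param x A `meth_windows` object (or a samples-by-windows level matrix)
#'   for the external samples.
#' @param labels Optional binary labels for ROC evaluation (named or in
#'   sample order).
#' @param missing_policy `"mean_impute"` (default) or `"drop_renorm"`.
#' @return An object of class `external_score`: list with `scores`,
#'   `n_available`, `missing_markers`, `policy`, and `roc` when labels are
#'   given.
#' @export
score_external <- function(model, x, labels = NULL,
                           missing_policy = c("mean_impute", "drop_renorm")) {
  missing_policy <- match.arg(missing_policy)
  lv <- if (inherits(x, "meth_windows")) t(meth_levels(x)) else as.matrix(x)
  avail <- model$markers[model$markers %in% colnames(lv)]
  avail <- avail[vapply(avail, function(m) any(!is.na(lv[, m])), TRUE)]
  if (length(model$markers) > 0L && length(avail) == 0L)
    stop("no model marker is measurable in the external samples")
  scores <- predict(model, lv, missing_policy = missing_policy)
  names(scores) <- rownames(lv)
  out <- list(scores = scores, n_available = length(avail),
              missing_markers = setdiff(model$markers, avail),
              policy = missing_policy)
  if (!is.null(labels)) out$roc <- roc_curve(scores, labels)
  class(out) <- "external_score"
  out
}

#' @export
print.external_score <- function(x, ...) {
  cat("External scoring (", x$policy, "): ", length(x$scores),
      " samples, ", x$n_available, " markers available\n", sep = "")
  if (!is.null(x$roc)) print(x$roc)
  invisible(x)
}
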