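#' Kaplan-Meier estimate of liver-metastasis-free survival
#'
#' Product-limit estimator of the survival function from right-censored
#' follow-up times. Tied events at a time are processed simultaneously and
#' censoring at the same time is processed after the events, the standard
#' convention.
#'
#' @param times Follow-up times in days (non-negative).
#' @param events Binary event indicators (1/TRUE = liver metastasis
#'   observed; 0/FALSE = censored).
#' @return An object of class `km_curve`: list with `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` (the estimate after each listed time)
#'   and `median` (smallest time with S(t) <= 0.5, `NA` if never reached).
#' @export
kaplan_meier <- function(times, events) {
  if (any(times < 0)) stop("negative follow-up time")
  events <- as.integer(as.logical(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  med <- unname(summary(fit)$table["median"])
  structure(list(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 surv = fit$surv, median = med),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: ", sum(x$n_event), " events / ",
      x$n_risk[1L], " at risk; median ",
      if (is.na(x$median)) "not reached" else paste(x$median, "days"),
      "\n", sep = "")
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "Days", ylab = "LIM-free survival", ...) {
  t <- c(0, x$time)
  s <- c(1, x$surv)
  graphics::plot(t, s, type = "s", ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Survival probability at a time point
#'
#' Right-continuous step-function evaluation of a Kaplan-Meier curve.
#'
#' @param curve A `km_curve` object.
#' @param t Time in days (vectorized).
#' @return S(t), with S(t) = 1 before the first listed time.
#' @export
survival_rate_at <- function(curve, t) {
  if (any(t < 0)) stop("time must be non-negative")
  vapply(t, function(ti) {
    ix <- which(curve$time <= ti)
    if (length(ix) == 0L) 1 else curve$surv[max(ix)]
  }, 0)
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank statistic with hypergeometric variance at each
#' event time, two-sided p from the chi-square distribution. With no
#' events in either group the comparison is degenerate and `p = 1` is
#' returned with a flag.
#'
#' @param times_a,events_a Times and event indicators of group A.
#' @param times_b,events_b Times and event indicators of group B.
#' @return List with `chi_square`, `p`, `degenerate`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  ea <- as.integer(as.logical(events_a))
  eb <- as.integer(as.logical(events_b))
  if (sum(ea) + sum(eb) == 0L) {
    return(list(chi_square = 0, p = 1, degenerate = TRUE))
  }
  times <- c(times_a, times_b)
  events <- c(ea, eb)
  grp <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(times, events) ~ grp)
  chisq <- unname(sd$chisq)
  list(chi_square = chisq,
       p = stats::pchisq(chisq, df = 1L, lower.tail = FALSE),
       degenerate = FALSE)
}
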