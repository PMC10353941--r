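# Kaplan-Meier estimation and log-rank testing (survival package wrappers).

#' Kaplan-Meier product-limit estimate
#'
#' @param times Non-negative follow-up times.
#' @param events Binary event indicators (1 = event of interest, 0 =
#'   censored).
#' @return A `data.frame` step function: `time`, `n_risk`, `n_event`,
#'   `survival` (right-continuous, non-increasing, S(0) = 1).
#' @export
kaplan_meier <- function(times, events) {
  if (any(times < 0)) stop("times must be non-negative")
  stopifnot(length(times) == length(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard (Mantel-Haenszel) log-rank test with Breslow-style handling of
#' tied event times: the chi-square statistic sums (observed - expected)^2 /
#' variance over event times, 1 df.
#'
#' @param times Non-negative follow-up times.
#' @param events Binary event indicators.
#' @param group Two-level group labels.
#' @return A list with `chisq`, `p` (two-sided), `observed` and `expected`
#'   event counts per group.
#' @export
log_rank_test <- function(times, events, group) {
  if (any(times < 0)) stop("times must be non-negative")
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) stop("group must have exactly two non-empty levels")
  fit <- survival::survdiff(survival::Surv(times, events) ~ group)
  list(chisq = unname(fit$chisq),
       p = stats::pchisq(fit$chisq, df = 1, lower.tail = FALSE),
       observed = fit$obs,
       expected = fit$exp)
}
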