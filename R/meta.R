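# Inverse-variance fixed-effects pooling and SE reconstruction from printed
# two-sided Wald P-values.

#' Reconstruct a standard error from an estimate and its Wald P-value
#'
#' Published cohort tables often print an effect estimate and a two-sided
#' Wald P-value but no SE. Under the Wald convention P = 2 * (1 - Phi(|b|/se)),
#' so se = |b| / z with z the upper-(P/2) standard-normal quantile. Because
#' printed P-values are rounded (typically 2 significant figures), pooled
#' ratios re-derived this way can shift by about +/- 0.01.
#'
#' @param estimate_log Log-scale effect estimate (log OR / log SHR); nonzero.
#' @param p Two-sided Wald P-value in (0, 1).
#' @return The reconstructed standard error.
#' @examples
#' se_from_wald_p(log(0.69), 0.13)   # ~0.245
#' @export
se_from_wald_p <- function(estimate_log, p) {
  if (any(p <= 0 | p >= 1)) stop("p must be in (0, 1)")
  if (any(estimate_log == 0)) stop("estimate_log must be nonzero")
  abs(estimate_log) / stats::qnorm(1 - p / 2)
}

#' Build a cohort estimate record for pooling
#'
#' @param cohort Cohort label.
#' @param estimate Log-scale effect (log OR or log SHR). Alternatively pass
#'   `ratio` (OR/SHR) and it is logged.
#' @param se Standard error on the log scale; if missing, reconstructed from
#'   `p` via [se_from_wald_p()].
#' @param p Two-sided Wald P (used to reconstruct `se` when absent).
#' @param ratio Effect on the ratio scale (alternative to `estimate`).
#' @param effect_scale `"log_or"` or `"log_shr"`.
#' @return A one-row `data.frame` with columns `cohort`, `effect_scale`,
#'   `estimate`, `se`, `p`.
#' @export
cohort_estimate <- function(cohort, estimate = NULL, se = NULL, p = NULL,
                            ratio = NULL, effect_scale = "log_or") {
  if (is.null(estimate)) {
    if (is.null(ratio)) stop("supply estimate (log scale) or ratio")
    estimate <- log(ratio)
  }
  if (is.null(se)) {
    if (is.null(p)) stop("supply se or a Wald p to reconstruct it")
    se <- se_from_wald_p(estimate, p)
  } else if (!is.null(p)) {
    # consistency check: the printed P should reproduce the SE within 5%
    se_p <- se_from_wald_p(estimate, p)
    if (abs(se_p - se) / se > 0.05) {
      warning(sprintf("cohort %s: SE reconstructed from p (%.4f) differs from supplied SE (%.4f) by > 5%%",
                      cohort, se_p, se))
    }
  }
  data.frame(cohort = cohort, effect_scale = effect_scale,
             estimate = estimate, se = se,
             p = if (is.null(p)) NA_real_ else p,
             stringsAsFactors = FALSE)
}

#' Inverse-variance fixed-effects meta-analysis
#'
#' Pools log-scale cohort estimates with weights 1/se^2:
#' pooled = sum(w_i * b_i) / sum(w_i), pooled se = 1/sqrt(sum(w_i)), with a
#' two-sided P from the standard normal.
#'
#' @param estimates A `data.frame` of cohort estimates (rows from
#'   [cohort_estimate()], or any table with columns `cohort`, `estimate`,
#'   `se`, and optionally `effect_scale`, `p`).
#' @param allow_mixed_scales Pool across different `effect_scale` values
#'   (default `FALSE`; mixing log ORs and log SHRs errors unless overridden).
#' @return A list of class `meta_result`: `pooled_estimate`, `pooled_se`,
#'   `ratio` (= exp(pooled)), `ci95` (ratio scale), `p`, `weights`
#'   (normalized, named by cohort), `k`.
#' @examples
#' est <- rbind(
#'   cohort_estimate("CHS", ratio = 0.69, p = 0.13, effect_scale = "log_shr"),
#'   cohort_estimate("FHS", ratio = 0.51, p = 0.068, effect_scale = "log_shr")
#' )
#' fixed_effects_meta(est)  # pooled SHR 0.63, P ~ 0.024
#' @export
fixed_effects_meta <- function(estimates, allow_mixed_scales = FALSE) {
  stopifnot(is.data.frame(estimates), nrow(estimates) >= 2)
  if (!is.null(estimates$effect_scale) && !allow_mixed_scales &&
      length(unique(estimates$effect_scale)) > 1) {
    stop("mixed effect scales; set allow_mixed_scales = TRUE to override")
  }
  if (is.null(estimates$se) || anyNA(estimates$se)) {
    if (is.null(estimates$p)) stop("SEs absent and no p column to reconstruct them")
    miss <- is.na(estimates$se)
    estimates$se[miss] <- se_from_wald_p(estimates$estimate[miss],
                                         estimates$p[miss])
  }
  stopifnot(all(estimates$se > 0))
  w <- 1 / estimates$se^2
  pooled <- sum(w * estimates$estimate) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  z <- pooled / pooled_se
  structure(list(
    pooled_estimate = pooled,
    pooled_se = pooled_se,
    ratio = exp(pooled),
    ci95 = exp(pooled + c(-1, 1) * stats::qnorm(0.975) * pooled_se),
    p = 2 * stats::pnorm(-abs(z)),
    weights = stats::setNames(w / sum(w), estimates$cohort),
    k = nrow(estimates)
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Fixed-effects meta-analysis (k = %d)\n", x$k))
  cat(sprintf("  pooled ratio %.3f [%.3f, %.3f], P = %.3g\n",
              x$ratio, x$ci95[1], x$ci95[2], x$p))
  invisible(x)
}
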