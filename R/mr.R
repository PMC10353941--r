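# Two-sample Mendelian-randomization estimators from GWAS summary
# statistics: per-instrument ratio estimates, inverse-variance weighted with
# multiplicative random effects, weighted median with parametric-bootstrap
# SE, and Egger regression; plus fixed-effects pooling across outcome
# studies in either causal direction.

mr_result <- function(method, estimate, se, extra = list()) {
  z <- estimate / se
  structure(c(list(
    method = method,
    estimate = estimate,
    se = se,
    or = exp(estimate),
    ci95 = exp(estimate + c(-1, 1) * stats::qnorm(0.975) * se),
    p = 2 * stats::pnorm(-abs(z))
  ), extra), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR (%s): OR %.3f [%.3f, %.3f], P = %.3g\n",
              x$method, x$or, x$ci95[1], x$ci95[2], x$p))
  invisible(x)
}

check_instruments <- function(instruments, k_min = 1) {
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  stopifnot(all(need %in% names(instruments)))
  if (any(instruments$se_exposure <= 0) || any(instruments$se_outcome <= 0)) {
    stop("instrument SEs must be positive")
  }
  zero <- instruments$beta_exposure == 0
  if (any(zero)) {
    warning(sprintf("%d instrument(s) with zero exposure beta dropped", sum(zero)))
    instruments <- instruments[!zero, , drop = FALSE]
  }
  if (nrow(instruments) < k_min) {
    stop(sprintf("need at least %d instrument(s), have %d", k_min,
                 nrow(instruments)))
  }
  instruments
}

#' Per-instrument ratio (Wald) estimates
#'
#' For each instrument j, beta_j = Gamma_j / gamma_j (outcome over exposure
#' association) with first-order delta-method SE sigma_j =
#' se_outcome_j / |gamma_j|. Instruments with gamma = 0 are dropped with a
#' warning.
#'
#' @param instruments A `data.frame` with columns `variant_id` (optional),
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`.
#' @return The instrument table with added columns `beta_ratio`, `se_ratio`.
#' @export
ratio_estimates <- function(instruments) {
  instruments <- check_instruments(instruments)
  instruments$beta_ratio <- instruments$beta_outcome / instruments$beta_exposure
  instruments$se_ratio <- instruments$se_outcome / abs(instruments$beta_exposure)
  instruments
}

#' Inverse-variance weighted MR (multiplicative random effects)
#'
#' Pools ratio estimates with weights 1/sigma_j^2. The SE is the fixed-
#' effects SE inflated by max(1, sqrt(phi)) where
#' phi = sum((beta_j - theta)^2 / sigma_j^2) / (k - 1) is the multiplicative
#' overdispersion; phi > 1 is also a crude signal of heterogeneity /
#' pleiotropy. With a single instrument, falls back to that instrument's
#' ratio estimate with a warning.
#'
#' @inheritParams ratio_estimates
#' @return An `mr_estimate` list (method `"ivw_mre"`, or `"ratio_single"`
#'   on fallback) with dispersion `phi`.
#' @export
ivw_estimate <- function(instruments) {
  r <- ratio_estimates(instruments)
  k <- nrow(r)
  if (k < 2) {
    warning("fewer than 2 instruments; returning single-ratio estimate")
    return(mr_result("ratio_single", r$beta_ratio[1], r$se_ratio[1],
                     extra = list(phi = NA_real_, k = 1L)))
  }
  w <- 1 / r$se_ratio^2
  theta <- sum(w * r$beta_ratio) / sum(w)
  phi <- sum(w * (r$beta_ratio - theta)^2) / (k - 1)
  se <- (1 / sqrt(sum(w))) * max(1, sqrt(phi))
  mr_result("ivw_mre", theta, se, extra = list(phi = phi, k = k))
}

# Interpolated weighted median: sort beta ascending (stable), normalize
# weights, s_j = cumsum(w) - w_j/2, linearly interpolate beta at s = 0.5.
weighted_median <- function(beta, weight) {
  ord <- order(beta)            # stable in R; ties keep input order
  b <- beta[ord]
  w <- weight[ord] / sum(weight)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(b[1])
  if (0.5 >= s[length(s)]) return(b[length(b)])
  stats::approx(s, b, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median MR estimate
#'
#' The median of the inverse-variance-weighted ratio-estimate distribution,
#' consistent even when up to 50% of the instrument weight comes from
#' invalid (pleiotropic) instruments. The SE is a parametric bootstrap:
#' each replicate resamples beta_j ~ Normal(beta_j, sigma_j) and recomputes
#' the weighted median (weights held fixed).
#'
#' @inheritParams ratio_estimates
#' @param n_boot Bootstrap replicates for the SE (default 1000). `n_boot = 0`
#'   returns the point estimate with `se = NA`.
#' @param seed RNG seed for the bootstrap (default 1234; `NULL` leaves the
#'   RNG state alone).
#' @return An `mr_estimate` list (method `"weighted_median"`).
#' @export
weighted_median_estimate <- function(instruments, n_boot = 1000, seed = 1234) {
  r <- ratio_estimates(check_instruments(instruments, k_min = 3))
  w <- 1 / r$se_ratio^2
  theta <- weighted_median(r$beta_ratio, w)
  se <- NA_real_
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    k <- nrow(r)
    draws <- matrix(stats::rnorm(n_boot * k, mean = r$beta_ratio,
                                 sd = r$se_ratio), nrow = k)
    boot <- apply(draws, 2, weighted_median, weight = w)
    se <- stats::sd(boot)
  }
  mr_result("weighted_median", theta, se, extra = list(k = nrow(r),
                                                       n_boot = n_boot))
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with an
#' intercept, weights 1/se_outcome^2, after orienting all exposure betas
#' positive. The slope is the causal estimate; the intercept estimates
#' average directional pleiotropy.
#'
#' @inheritParams ratio_estimates
#' @return An `mr_estimate` list (method `"egger"`) with `intercept`,
#'   `intercept_se`, `intercept_p`.
#' @export
egger_estimate <- function(instruments) {
  r <- check_instruments(instruments, k_min = 3)
  flip <- sign(r$beta_exposure)
  g <- r$beta_exposure * flip
  G <- r$beta_outcome * flip
  if (stats::sd(g) < 1e-3 * mean(abs(g))) {
    warning("near-zero spread in exposure betas; Egger slope is weakly identified")
  }
  fit <- stats::lm(G ~ g, weights = 1 / r$se_outcome^2)
  sm <- summary(fit)$coefficients
  z_int <- sm["(Intercept)", "Estimate"] / sm["(Intercept)", "Std. Error"]
  mr_result("egger", sm["g", "Estimate"], sm["g", "Std. Error"],
            extra = list(intercept = sm["(Intercept)", "Estimate"],
                         intercept_se = sm["(Intercept)", "Std. Error"],
                         intercept_p = 2 * stats::pnorm(-abs(z_int)),
                         k = nrow(r)))
}

#' Run MR across one or more outcome studies and pool
#'
#' Matches instruments between the exposure table and each outcome study by
#' `variant_id`, computes all estimators per study, and pools the chosen
#' primary estimator across studies with [fixed_effects_meta()]. Studies in
#' which fewer than half of the instruments match are skipped with a
#' warning. `direction` is a label carried into the output (the reverse
#' analysis simply swaps which trait plays exposure and outcome upstream).
#'
#' @param exposure_stats A `data.frame` with `variant_id`, `beta`, `se` for
#'   the exposure trait.
#' @param outcome_stats_list Named list of outcome-study `data.frame`s with
#'   `variant_id`, `beta`, `se`.
#' @param direction `"forward"` or `"reverse"` (label only).
#' @param primary Primary estimator to pool: `"weighted_median"` (default),
#'   `"ivw_mre"`, or `"egger"`.
#' @param n_boot,seed Passed to [weighted_median_estimate()].
#' @return A list with `per_study` (named list of per-study estimator
#'   lists), `pooled` (a `meta_result`, or the single study's primary
#'   estimate), `primary`, `direction`.
#' @export
run_mr <- function(exposure_stats, outcome_stats_list,
                   direction = c("forward", "reverse"),
                   primary = c("weighted_median", "ivw_mre", "egger"),
                   n_boot = 1000, seed = 1234) {
  direction <- match.arg(direction)
  primary <- match.arg(primary)
  if (is.data.frame(outcome_stats_list)) {
    outcome_stats_list <- list(outcome = outcome_stats_list)
  }
  if (is.null(names(outcome_stats_list))) {
    names(outcome_stats_list) <- paste0("study", seq_along(outcome_stats_list))
  }
  per_study <- list()
  for (nm in names(outcome_stats_list)) {
    out <- outcome_stats_list[[nm]]
    m <- match(exposure_stats$variant_id, out$variant_id)
    matched <- !is.na(m)
    if (mean(matched) < 0.5) {
      warning(sprintf("study %s: <50%% of instruments matched; skipped", nm))
      next
    }
    if (!all(matched)) {
      warning(sprintf("study %s: %d unmatched instrument(s) dropped",
                      nm, sum(!matched)))
    }
    ins <- data.frame(
      variant_id = exposure_stats$variant_id[matched],
      beta_exposure = exposure_stats$beta[matched],
      se_exposure = exposure_stats$se[matched],
      beta_outcome = out$beta[m[matched]],
      se_outcome = out$se[m[matched]],
      stringsAsFactors = FALSE)
    per_study[[nm]] <- list(
      instruments = ins,
      ivw_mre = ivw_estimate(ins),
      weighted_median = weighted_median_estimate(ins, n_boot = n_boot,
                                                 seed = seed),
      egger = egger_estimate(ins))
  }
  if (!length(per_study)) stop("no outcome study had enough matched instruments")
  est <- do.call(rbind, lapply(names(per_study), function(nm) {
    e <- per_study[[nm]][[primary]]
    data.frame(cohort = nm, estimate = e$estimate, se = e$se,
               effect_scale = "log_or", stringsAsFactors = FALSE)
  }))
  pooled <- if (nrow(est) >= 2) fixed_effects_meta(est) else
    per_study[[1]][[primary]]
  list(per_study = per_study, pooled = pooled, primary = primary,
       direction = direction)
}
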