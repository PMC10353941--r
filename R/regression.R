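# Cohort-level regression models: logistic (IRLS via glm), proportional-odds
# ordinal logistic (MASS::polr with standard-normal P-values), composite
# neuropathology score, and APOE risk binning.

#' Fit a logistic regression with Wald tests
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' `stats::glm`). Reports per-coefficient estimate, SE, z and two-sided Wald
#' P-value. Coefficients diverging beyond 15 on the log-odds scale indicate
#' (quasi-)separation and raise an error naming the covariate.
#'
#' @param formula Model formula with a binary outcome.
#' @param data Covariate table.
#' @return A list of class `chipscope_fit` with `coefficients` (a
#'   `data.frame`: term, estimate, se, z, p), `model` (the `glm` object),
#'   and `n`.
#' @export
fit_logistic <- function(formula, data) {
  fit <- stats::glm(formula, data = data, family = stats::binomial())
  b <- stats::coef(fit)
  diverged <- names(b)[!is.na(b) & abs(b) > 15 & names(b) != "(Intercept)"]
  if (length(diverged)) {
    stop("separation detected (|log-odds| > 15) for: ",
         paste(diverged, collapse = ", "))
  }
  se <- sqrt(diag(stats::vcov(fit)))
  z <- b / se
  structure(list(
    coefficients = data.frame(term = names(b), estimate = unname(b),
                              se = unname(se), z = unname(z),
                              p = unname(2 * stats::pnorm(-abs(z))),
                              stringsAsFactors = FALSE),
    model = fit,
    n = stats::nobs(fit)
  ), class = "chipscope_fit")
}

#' Fit a proportional-odds ordinal logistic regression
#'
#' Wraps `MASS::polr` (logistic link). Two-sided P-values compare the
#' t-statistic (estimate / SE) against the standard normal — the convention
#' used for the neuropathology models here — rather than a t-distribution.
#' If the outcome has only two observed levels the model reduces to ordinary
#' logistic regression ([fit_logistic()]) with a warning; empty levels are
#' dropped with a warning.
#'
#' @param formula Model formula; outcome must be an ordered factor or
#'   integer-like vector with >= 2 observed levels.
#' @param data Covariate table.
#' @return A `chipscope_fit` list; `coefficients` contains the slope terms
#'   (thresholds are in `zeta`).
#' @export
fit_ordinal_logistic <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- mf[[1]]
  if (!is.factor(y)) y <- factor(y, ordered = TRUE)
  observed <- levels(y)[levels(y) %in% unique(as.character(y))]
  if (length(observed) < length(levels(y))) {
    warning("empty outcome level(s) collapsed: ",
            paste(setdiff(levels(y), observed), collapse = ", "))
    y <- factor(as.character(y), levels = observed, ordered = TRUE)
  }
  if (length(observed) < 2) stop("outcome has fewer than 2 observed levels")
  data[[as.character(formula[[2]])]] <- y
  if (length(observed) == 2) {
    warning("outcome has 2 levels; reducing to logistic regression")
    data[[as.character(formula[[2]])]] <- as.integer(y) - 1L
    return(fit_logistic(formula, data))
  }
  fit <- MASS::polr(formula, data = data, method = "logistic", Hess = TRUE)
  sm <- summary(fit)
  ct <- sm$coefficients
  slopes <- ct[seq_along(stats::coef(fit)), , drop = FALSE]
  tval <- slopes[, "t value"]
  structure(list(
    coefficients = data.frame(term = rownames(slopes),
                              estimate = slopes[, "Value"],
                              se = slopes[, "Std. Error"],
                              z = tval,
                              p = 2 * stats::pnorm(-abs(tval)),
                              row.names = NULL,
                              stringsAsFactors = FALSE),
    zeta = fit$zeta,
    model = fit,
    n = fit$n
  ), class = "chipscope_fit")
}

#' @export
print.chipscope_fit <- function(x, ...) {
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Group a Braak neurofibrillary-tangle stage
#'
#' Stages 0/I/II map to group 1, III/IV to 2, V/VI to 3.
#'
#' @param stage Integer Braak stage 0-6.
#' @return Integer group 1-3.
#' @export
braak_group <- function(stage) {
  if (any(stage < 0 | stage > 6, na.rm = TRUE)) stop("Braak stage must be 0-6")
  ifelse(stage <= 2, 1L, ifelse(stage <= 4, 2L, 3L))
}

#' Composite Alzheimer's neuropathologic change (ADNC) score
#'
#' CERAD neuritic plaque score (0-3) plus grouped Braak stage (1-3), giving
#' a composite that ranges 1-6.
#'
#' @param cerad Integer CERAD score 0-3.
#' @param braak_group Integer grouped Braak stage 1-3 (see [braak_group()]).
#' @return Integer composite score in 1..6.
#' @export
composite_adnc_score <- function(cerad, braak_group) {
  if (any(cerad < 0 | cerad > 3, na.rm = TRUE)) stop("cerad must be 0-3")
  if (any(braak_group < 1 | braak_group > 3, na.rm = TRUE)) {
    stop("braak_group must be 1-3")
  }
  as.integer(cerad + braak_group)
}

#' Bin APOE genotypes into AD-risk groups
#'
#' `e3e3` is neutral; `e2e2`/`e2e3` are low-risk; any genotype carrying an
#' e4 allele (`e2e4`, `e3e4`, `e4e4`) is high-risk.
#'
#' @param apoe Character vector of genotypes among
#'   `e2e2, e2e3, e2e4, e3e3, e3e4, e4e4`.
#' @return Factor with levels `neutral`, `low`, `high`.
#' @export
apoe_risk_bin <- function(apoe) {
  valid <- c("e2e2", "e2e3", "e2e4", "e3e3", "e3e4", "e4e4")
  if (!all(apoe %in% valid)) {
    stop("invalid APOE genotype(s): ",
         paste(unique(apoe[!apoe %in% valid]), collapse = ", "))
  }
  factor(ifelse(grepl("e4", apoe), "high",
                ifelse(apoe == "e3e3", "neutral", "low")),
         levels = c("neutral", "low", "high"))
}
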