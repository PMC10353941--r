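# Stratified association runs: fit the model per stratum per cohort, then
# pool across cohorts within each stratum.

#' Stratified logistic association with within-stratum meta-analysis
#'
#' Subjects are partitioned by APOE risk bin (neutral e3e3; low e2e2/e2e3;
#' high any e4 allele), sex, or CHIP driver gene. Within each stratum, the
#' configured logistic model is fitted per cohort and the CHIP (or carrier-
#' subset) coefficient is pooled across cohorts with an inverse-variance
#' fixed-effects meta-analysis. Strata in which a cohort lacks both outcome
#' classes or any CHIP variation are skipped with a warning and recorded.
#'
#' @param subjects A subject table with columns `cohort`, `ad` (0/1),
#'   `chip` (0/1 carrier flag), `age`, `sex`, `apoe`, and (for
#'   `strata = "driver_gene"`) `driver_genes` (comma-separated).
#' @param strata One of `"apoe"`, `"sex"`, `"driver_gene"`.
#' @param covariates Character vector of adjustment covariates present in
#'   `subjects` (default `c("age", "sex")`; `sex` is dropped automatically
#'   when stratifying by sex).
#' @return A list with `per_cohort` (a `data.frame` of per-stratum,
#'   per-cohort CHIP estimates), `meta` (named list of `meta_result` per
#'   stratum, or the single-cohort estimate), and `skipped` (a `data.frame`
#'   of degenerate stratum/cohort pairs).
#' @export
run_stratified_meta <- function(subjects, strata = c("apoe", "sex", "driver_gene"),
                                covariates = c("age", "sex")) {
  strata <- match.arg(strata)
  stopifnot(all(c("cohort", "ad", "chip") %in% names(subjects)))
  if (strata == "apoe") {
    subjects$.stratum <- as.character(apoe_risk_bin(subjects$apoe))
    levels_use <- c("neutral", "low", "high")
  } else if (strata == "sex") {
    subjects$.stratum <- as.character(subjects$sex)
    covariates <- setdiff(covariates, "sex")
    levels_use <- unique(subjects$.stratum)
  } else {
    genes <- sort(unique(unlist(strsplit(
      subjects$driver_genes[subjects$chip == 1 & nzchar(subjects$driver_genes)], ","))))
    levels_use <- genes
  }

  rhs <- paste(c("chip", covariates), collapse = " + ")
  fml <- stats::as.formula(paste("ad ~", rhs))

  per_cohort <- list()
  skipped <- list()
  for (st in levels_use) {
    for (co in unique(subjects$cohort)) {
      if (strata == "driver_gene") {
        # carriers of this gene vs all non-carriers, within cohort
        sub <- subjects[subjects$cohort == co, , drop = FALSE]
        has_gene <- sub$chip == 1 &
          vapply(strsplit(sub$driver_genes, ","), function(g) st %in% g, TRUE)
        sub <- sub[has_gene | sub$chip == 0, , drop = FALSE]
        sub$chip <- as.integer(has_gene[has_gene | sub$chip == 0])
      } else {
        sub <- subjects[subjects$cohort == co & subjects$.stratum == st, ,
                        drop = FALSE]
      }
      ok <- nrow(sub) > length(covariates) + 2 &&
        length(unique(sub$ad)) == 2 && length(unique(sub$chip)) == 2
      if (!ok) {
        warning(sprintf("stratum %s / cohort %s degenerate; skipped", st, co))
        skipped[[length(skipped) + 1]] <- data.frame(stratum = st, cohort = co)
        next
      }
      fit <- tryCatch(fit_logistic(fml, sub), error = function(e) NULL)
      if (is.null(fit)) {
        warning(sprintf("stratum %s / cohort %s failed to fit; skipped", st, co))
        skipped[[length(skipped) + 1]] <- data.frame(stratum = st, cohort = co)
        next
      }
      cf <- fit$coefficients[fit$coefficients$term == "chip", ]
      per_cohort[[length(per_cohort) + 1]] <- data.frame(
        stratum = st, cohort = co, estimate = cf$estimate, se = cf$se,
        or = exp(cf$estimate), ci_low = exp(cf$estimate - 1.96 * cf$se),
        ci_high = exp(cf$estimate + 1.96 * cf$se), p = cf$p,
        stringsAsFactors = FALSE)
    }
  }
  per_cohort <- if (length(per_cohort)) do.call(rbind, per_cohort) else
    data.frame(stratum = character(), cohort = character(), estimate = numeric(),
               se = numeric(), or = numeric(), ci_low = numeric(),
               ci_high = numeric(), p = numeric())
  meta <- list()
  for (st in unique(per_cohort$stratum)) {
    rows <- per_cohort[per_cohort$stratum == st, , drop = FALSE]
    meta[[st]] <- if (nrow(rows) >= 2) {
      fixed_effects_meta(data.frame(cohort = rows$cohort, estimate = rows$estimate,
                                    se = rows$se, effect_scale = "log_or"))
    } else {
      rows
    }
  }
  list(per_cohort = per_cohort,
       meta = meta,
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(stratum = character(), cohort = character()))
}
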