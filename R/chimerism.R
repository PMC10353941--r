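# Brain chimerism: estimating the fraction of mutant microglia (MG) per
# brain sample from amplicon VAF and single-nucleus cell-type composition.
#
# Logic: CHIP mutations are heterozygous, so 2 x VAF is the fraction of
# mutant nuclei. Assuming (conservatively) that every nonmicroglial
# hematopoietic nucleus is mutant, the remaining mutant nuclei must be MG:
#   mut_mg = round(total * vaf * 2 - non_mg),   prop_mut_mg = mut_mg / mg.

#' Amplicon VAF with a detection-limit check
#'
#' Deep amplicon sequencing of the mutation site gives VAF = alt/(alt+ref).
#' A measured VAF is only called "detected" if it clears the detection
#' limit, which is the larger of 3/depth and the upper 95% binomial bound of
#' the negative-control alt fraction (a brain sample from a donor without
#' CHIP, sequenced with the same primers). Without a negative control the
#' limit falls back to 3/depth with a warning.
#'
#' @param alt_reads,ref_reads Read counts at the mutation site.
#' @param min_depth Minimum amplicon depth (default 500).
#' @param negative_control Optional list/data.frame with `alt_reads`,
#'   `ref_reads` for the negative-control sample.
#' @return A list: `vaf`, `detected` (logical), `detection_limit`, `depth`.
#' @export
amplicon_vaf <- function(alt_reads, ref_reads, min_depth = 500,
                         negative_control = NULL) {
  depth <- alt_reads + ref_reads
  if (depth < min_depth) {
    stop(sprintf("amplicon depth %d below minimum %d", depth, min_depth))
  }
  vaf <- alt_reads / depth
  limit <- 3 / depth
  if (is.null(negative_control)) {
    warning("no negative control supplied; detection limit falls back to 3/depth")
  } else {
    nc_depth <- negative_control$alt_reads + negative_control$ref_reads
    nc_upper <- stats::binom.test(negative_control$alt_reads,
                                  nc_depth)$conf.int[2]
    limit <- max(limit, nc_upper)
  }
  list(vaf = vaf, detected = vaf >= limit, detection_limit = limit,
       depth = depth)
}

#' Convert a heterozygous VAF to percent mutant cells
#'
#' For heterozygous mutations each mutant cell contributes one mutant of two
#' alleles, so percent mutant cells = 2 x VAF x 100. VAFs above 0.5 violate
#' the heterozygous assumption and are flagged with a warning.
#'
#' @param vaf Variant allele fraction in `[0, 1]`.
#' @return Percentage of mutant cells.
#' @examples
#' percent_mutant_cells(0.28)  # 56
#' percent_mutant_cells(0.02)  # 4
#' @export
percent_mutant_cells <- function(vaf) {
  if (any(vaf < 0 | vaf > 1)) stop("vaf must be in [0, 1]")
  if (any(vaf > 0.5)) {
    warning("VAF > 0.5 violates the heterozygous assumption; flagged")
  }
  2 * vaf * 100
}

#' Estimate the number and proportion of mutant microglia
#'
#' `total * vaf * 2` is the total mutant nucleus burden in the sample. All
#' `non_mg` nonmicroglial hematopoietic nuclei are conservatively assumed
#' mutant and subtracted; the remainder, rounded (half-to-even), is the
#' mutant MG count, and dividing by the MG count gives the proportion of
#' mutant MG. A negative remainder (the conservative assumption overshoots
#' at low VAF) is floored at 0 with a warning. Proportions above 1 are
#' reported raw and also clamped.
#'
#' @param vaf Amplicon VAF of the CHIP variant in the unsorted sample
#'   (0 to 0.5 under the heterozygous assumption; larger values error).
#' @param total Total nuclei identified in the single-nucleus assay.
#' @param mg Number of microglial nuclei (> 0).
#' @param non_mg Number of nonmicroglial hematopoietic nuclei
#'   (monocyte + DC + T cell + B cell).
#' @return A list of class `mutant_mg_estimate`: `vaf`, `total`, `mg`,
#'   `non_mg`, `mut_mg`, `prop_mut_mg` (raw), `prop_unadjusted` (raw,
#'   ignoring the non-MG subtraction), `prop_mut_mg_clamped`,
#'   `prop_unadjusted_clamped`, `clamped` (logical).
#' @examples
#' est <- estimate_mutant_mg(vaf = 0.035, total = 11762, mg = 801, non_mg = 64)
#' est$mut_mg               # 759
#' round(100 * est$prop_mut_mg, 1)  # 94.8
#' @export
estimate_mutant_mg <- function(vaf, total, mg, non_mg) {
  if (mg <= 0) stop("mg must be positive")
  if (total < mg + non_mg) stop("total must be at least mg + non_mg")
  if (vaf < 0 || vaf > 0.5) stop("vaf must be in [0, 0.5] (heterozygous assumption)")
  raw <- total * vaf * 2 - non_mg
  if (raw < 0) {
    warning("total mutant burden below non-MG hematopoietic count; mut_mg floored at 0")
  }
  mut_mg <- max(0, round(raw))
  prop <- mut_mg / mg
  prop_unadj <- vaf * total * 2 / mg
  clamped <- prop > 1 || prop_unadj > 1
  structure(list(
    vaf = vaf, total = total, mg = mg, non_mg = non_mg,
    mut_mg = mut_mg,
    prop_mut_mg = prop,
    prop_unadjusted = prop_unadj,
    prop_mut_mg_clamped = min(1, prop),
    prop_unadjusted_clamped = min(1, prop_unadj),
    clamped = clamped
  ), class = "mutant_mg_estimate")
}

#' @export
print.mutant_mg_estimate <- function(x, ...) {
  cat(sprintf("Mutant MG: %d of %d (%.1f%%%s); unadjusted %.1f%%%s\n",
              x$mut_mg, x$mg, 100 * x$prop_mut_mg,
              if (x$prop_mut_mg > 1) ", clamped to 100% for reporting" else "",
              100 * x$prop_unadjusted,
              if (x$prop_unadjusted > 1) " (clamped to 100% for reporting)"
              else ""))
  invisible(x)
}

#' Simulated confidence interval for percent mutant microglia
#'
#' Propagates the two binomial sampling layers behind the estimator: the
#' amplicon VAF (alt alleles among `n_genomes` haploid genomes, default
#' 200,000, i.e. 100,000 input nuclei) and the MG fraction (MG nuclei among
#' `n_nuclei` assayed nuclei, default 8,000). Each replicate redraws both,
#' recomputes the estimator with the non-MG hematopoietic fraction held
#' fixed, and the 2.5/97.5 percentiles of the replicates give the 95% CI.
#'
#' @param vaf Point VAF.
#' @param pct_mg MG fraction of nuclei (> 0).
#' @param non_mg Non-MG hematopoietic nucleus count in the observed sample.
#' @param total Total nuclei in the observed sample (used to scale `non_mg`
#'   to the simulated `n_nuclei`); defaults to `n_nuclei`.
#' @param n_genomes Haploid genomes behind the amplicon library
#'   (default 200000).
#' @param n_nuclei Nuclei assessed in the single-nucleus assay
#'   (default 8000).
#' @param n_sims Simulation replicates (default 1e6; tests use 1e4).
#' @param seed RNG seed (`NULL` leaves the RNG state alone).
#' @param keep_draws Return the replicate estimates (default `FALSE`).
#' @return A list: `ci_low`, `ci_high` (proportions), `point` (the
#'   estimator at the input values), `n_sims`, and optionally `draws`.
#' @export
simulate_mutant_mg_ci <- function(vaf, pct_mg, non_mg, total = n_nuclei,
                                  n_genomes = 200000, n_nuclei = 8000,
                                  n_sims = 1e6, seed = NULL,
                                  keep_draws = FALSE) {
  if (pct_mg <= 0) stop("pct_mg must be positive (estimator undefined at 0)")
  if (!is.null(seed)) set.seed(seed)
  non_mg_sim <- non_mg * n_nuclei / total
  vaf_sim <- stats::rbinom(n_sims, n_genomes, vaf) / n_genomes
  mg_sim <- stats::rbinom(n_sims, n_nuclei, pct_mg)
  ok <- mg_sim > 0
  if (!all(ok)) {
    warning(sprintf("%d replicate(s) drew zero MG nuclei; dropped", sum(!ok)))
  }
  est <- pmax(0, n_nuclei * vaf_sim[ok] * 2 - non_mg_sim) / mg_sim[ok]
  ci <- stats::quantile(est, c(0.025, 0.975), names = FALSE)
  point <- max(0, n_nuclei * vaf * 2 - non_mg_sim) / (n_nuclei * pct_mg)
  out <- list(ci_low = ci[1], ci_high = ci[2], point = point,
              n_sims = sum(ok))
  if (keep_draws) out$draws <- est
  out
}

#' Microglial fraction of the glial pool
#'
#' MG / (MG + oligodendrocytes + astrocytes).
#'
#' @param mg,oligodendrocyte,astrocyte Nucleus counts.
#' @return Fraction in `[0, 1]`.
#' @export
mg_glia_fraction <- function(mg, oligodendrocyte, astrocyte) {
  denom <- mg + oligodendrocyte + astrocyte
  if (any(denom <= 0)) stop("glial pool (MG + oligo + astro) must be positive")
  mg / denom
}

#' Quasibinomial test for a group difference in MG/glia fraction
#'
#' Binomial-family GLM of MG successes out of the glial pool on a two-level
#' group, with the dispersion estimated from Pearson residuals
#' (quasibinomial). The two-sided Wald P compares the coefficient over its
#' dispersion-inflated SE to the standard normal.
#'
#' @param compositions A `data.frame` with columns `MG`, `oligodendrocyte`,
#'   `astrocyte` (counts per sample).
#' @param group Two-level group labels (e.g. CHIP carrier vs control).
#' @return A list: `coefficient` (log-odds difference), `se`, `p`,
#'   `dispersion`, `model`.
#' @export
quasibinomial_group_test <- function(compositions, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) stop("group must have two non-empty levels")
  mg <- compositions$MG
  glia_rest <- compositions$oligodendrocyte + compositions$astrocyte
  if (any(tapply(mg, group, sum) == 0)) {
    stop("a group has all-zero MG counts; effect unidentifiable")
  }
  fit <- stats::glm(cbind(mg, glia_rest) ~ group,
                    family = stats::quasibinomial())
  sm <- summary(fit)
  b <- unname(stats::coef(fit)[2])
  se <- unname(sm$coefficients[2, "Std. Error"])
  list(coefficient = b, se = se,
       p = 2 * stats::pnorm(-abs(b / se)),
       dispersion = sm$dispersion, model = fit)
}

#' Pearson correlation between blood and brain mutant fractions
#'
#' Pearson r with the two-sided P from t = r * sqrt((n-2)/(1-r^2)) on n-2
#' degrees of freedom.
#'
#' @param blood,brain Paired mutant-cell fractions (n >= 3, non-constant).
#' @return A list: `r`, `r_squared`, `p`, `n`.
#' @export
blood_brain_correlation <- function(blood, brain) {
  stopifnot(length(blood) == length(brain))
  if (length(blood) < 3) stop("need at least 3 pairs")
  if (stats::sd(blood) == 0 || stats::sd(brain) == 0) {
    stop("constant input; correlation undefined")
  }
  ct <- stats::cor.test(blood, brain, method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p = ct$p.value, n = length(blood))
}

#' Fold enrichment of a sorted over an unsorted fraction
#'
#' @param sorted_frac Fraction in the sorted gate.
#' @param unsorted_frac Fraction in the unsorted sample (> 0).
#' @return `sorted_frac / unsorted_frac`.
#' @export
fold_enrichment <- function(sorted_frac, unsorted_frac) {
  if (any(unsorted_frac <= 0)) stop("unsorted fraction must be positive")
  sorted_frac / unsorted_frac
}
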