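# Seeded synthetic-data generators emulating the statistical structure of
# every input the pipeline consumes: cohort phenotype tables with
# age-dependent CHIP prevalence and AD outcomes (case-control or
# longitudinal with competing death), depth-dependent VAF observations,
# GWAS summary statistics with a planted causal effect, and brain samples
# (amplicon read counts + single-nucleus compositions) with known truth.

#' Simulation configuration with study-scale defaults
#'
#' Defaults emulate the study conditions of the cohorts the pipeline was
#' designed around: an ADSP-like case-control cohort of 5,000 subjects
#' (median age ~81, ~43% AD cases), CHIP prevalence rising with age to ~20%
#' at 80, a right-skewed Beta(1.5, 20) clone-size (VAF) distribution
#' truncated to (0, 0.5), ~38x WGS vs ~80x WES sequencing depth with a
#' 3-alt-read detection floor, a planted protective CHIP-AD odds ratio of
#' 0.64, APOE genotype frequencies from the printed FHS counts, a
#' 24-instrument MR design with true OR 0.90, and autopsy-style brain samples
#' (8,000 nuclei, ~2% MG, amplicon depth 5,000).
#'
#' @param seed Default seed carried by the config (generators also accept an
#'   explicit `seed`).
#' @param n_subjects Cohort size.
#' @param chip_age_intercept,chip_age_slope Logistic parameters of CHIP
#'   prevalence by age: P(CHIP) = plogis(intercept + slope * age).
#' @param clone_beta Shape parameters of the truncated Beta clone-VAF
#'   distribution.
#' @param depth_mean Named mean sequencing depths per platform.
#' @param true_or_chip_ad Planted CHIP-AD odds ratio (case-control mode).
#' @param true_shr_chip_ad Planted cause-specific hazard ratio
#'   (longitudinal mode).
#' @param apoe_frequencies Named 6-genotype probability vector.
#' @param ad_baseline_hazard,death_hazard Per-year rates (longitudinal mode).
#' @param followup_years Administrative censoring horizon.
#' @param case_fraction_target Approximate marginal AD fraction
#'   (case-control mode).
#' @param mr List: `k_instruments`, `gamma_range` (absolute exposure-beta
#'   range), `se_exposure`, `se_outcome`, `theta_true` (log odds),
#'   `pleiotropy` (`"none"`, `"balanced"`, `"directional"`),
#'   `pleiotropy_frac`, `pleiotropy_size`.
#' @param brain List: `true_mutant_mg_frac`, `pct_mg`, `non_mg_frac`,
#'   `n_nuclei`, `amplicon_depth`, `error_rate` (negative-control
#'   artifact rate).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_subjects = 5000L,
                       chip_age_intercept = -6.19,
                       chip_age_slope = 0.06,
                       clone_beta = c(1.5, 20),
                       depth_mean = c(wgs = 38, wes = 80),
                       true_or_chip_ad = 0.64,
                       true_shr_chip_ad = 0.63,
                       apoe_frequencies = c(e2e2 = 11, e2e3 = 299, e2e4 = 46,
                                            e3e3 = 1584, e3e4 = 458,
                                            e4e4 = 39) / 2437,
                       ad_baseline_hazard = 0.004,
                       death_hazard = 0.03,
                       followup_years = 20,
                       case_fraction_target = 0.43,
                       mr = list(k_instruments = 24L,
                                 gamma_range = c(0.05, 0.15),
                                 se_exposure = 0.01,
                                 se_outcome = 0.02,
                                 theta_true = log(0.90),
                                 pleiotropy = "none",
                                 pleiotropy_frac = 0.3,
                                 pleiotropy_size = 0.1),
                       brain = list(true_mutant_mg_frac = 0.5,
                                    pct_mg = 0.02,
                                    non_mg_frac = 0.0015,
                                    n_nuclei = 8000L,
                                    amplicon_depth = 5000L,
                                    error_rate = 1e-4)) {
  stopifnot(abs(sum(apoe_frequencies) - 1) < 1e-8,
            ad_baseline_hazard > 0, death_hazard > 0,
            clone_beta > 0)
  structure(as.list(environment()), class = "sim_config")
}

# Truncated Beta(a, b) on (lo, hi) by inverse-CDF sampling.
rbeta_trunc <- function(n, shape1, shape2, lo = 0, hi = 0.5) {
  u <- stats::runif(n, stats::pbeta(lo, shape1, shape2),
                    stats::pbeta(hi, shape1, shape2))
  stats::qbeta(u, shape1, shape2)
}

#' Generate a synthetic cohort phenotype table
#'
#' Ages, sex and APOE genotype are drawn per config; CHIP carrier status
#' follows the age-dependent logistic prevalence and carriers get a clone
#' VAF from the truncated Beta. In `case_control` mode the AD outcome is
#' Bernoulli with the planted odds ratio for CHIP on the log-odds scale
#' (plus age, sex and APOE effects). In `longitudinal` mode AD and death
#' times are competing exponential hazards (planted hazard ratio on the AD
#' cause-specific hazard) with administrative censoring. Ages >= 90 are
#' coded as 90.
#'
#' @param config A [sim_config()].
#' @param mode `"case_control"` or `"longitudinal"`.
#' @param cohort Cohort label stamped on the rows.
#' @param seed RNG seed (defaults to `config$seed`).
#' @return A `data.frame` with columns `subject_id`, `cohort`, `age`, `sex`,
#'   `apoe`, `chip`, `vaf`, `driver_genes`, and either `ad` (0/1) or
#'   `time`/`event` (`"ad"`, `"death"`, `"censored"`).
#' @export
gen_cohort <- function(config = sim_config(),
                       mode = c("case_control", "longitudinal"),
                       cohort = "SYN", seed = config$seed) {
  mode <- match.arg(mode)
  set.seed(seed)
  n <- config$n_subjects
  age_mean <- if (mode == "case_control") 81 else 68
  age <- pmin(90, pmax(55, round(stats::rnorm(n, age_mean, 6))))
  sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.55, 0.45))
  apoe <- sample(names(config$apoe_frequencies), n, replace = TRUE,
                 prob = config$apoe_frequencies)
  chip <- stats::rbinom(n, 1, stats::plogis(config$chip_age_intercept +
                                              config$chip_age_slope * age))
  vaf <- ifelse(chip == 1,
                rbeta_trunc(n, config$clone_beta[1], config$clone_beta[2]),
                0)
  genes <- c("DNMT3A", "TET2", "ASXL1", "SF3B1", "GNB1")
  driver <- ifelse(chip == 1,
                   sample(genes, n, replace = TRUE,
                          prob = c(0.5, 0.25, 0.12, 0.08, 0.05)),
                   "")
  apoe_lp <- log(3) * (grepl("e4", apoe) + (apoe == "e4e4")) +
    log(0.6) * (apoe %in% c("e2e2", "e2e3"))
  out <- data.frame(subject_id = sprintf("%s_%05d", cohort, seq_len(n)),
                    cohort = cohort, age = age, sex = sex, apoe = apoe,
                    chip = chip, vaf = vaf, driver_genes = driver,
                    stringsAsFactors = FALSE)
  if (mode == "case_control") {
    lp <- stats::qlogis(config$case_fraction_target) +
      0.03 * (age - age_mean) + 0.1 * (sex == "female") + apoe_lp +
      log(config$true_or_chip_ad) * chip
    out$ad <- stats::rbinom(n, 1, stats::plogis(lp))
  } else {
    h_ad <- config$ad_baseline_hazard *
      exp(0.09 * (age - age_mean) + apoe_lp +
            log(config$true_shr_chip_ad) * chip)
    h_death <- config$death_hazard * exp(0.08 * (age - age_mean))
    t_ad <- stats::rexp(n, h_ad)
    t_death <- stats::rexp(n, h_death)
    t <- pmin(t_ad, t_death, config$followup_years)
    out$time <- t
    out$event <- ifelse(t == config$followup_years, "censored",
                        ifelse(t_ad <= t_death, "ad", "death"))
  }
  out
}

#' Generate depth-dependent observed VAFs for one platform
#'
#' True clone VAFs are drawn from the truncated Beta; per-clone depth is
#' Poisson around the platform mean; alt reads are Binomial(depth, VAF). A
#' clone is detected when it has at least 3 alt reads, so the deeper
#' platform detects more (and smaller) clones.
#'
#' @param config A [sim_config()].
#' @param platform `"wgs"` (~38x) or `"wes"` (~80x).
#' @param n_clones Number of true clones to simulate.
#' @param true_vafs Optional vector of true clone VAFs (to observe the same
#'   clones on both platforms); drawn from the Beta when `NULL`.
#' @param seed RNG seed.
#' @return A `data.frame`: `true_vaf`, `depth`, `alt_reads`, `obs_vaf`,
#'   `detected`.
#' @export
gen_vaf_observations <- function(config = sim_config(),
                                 platform = c("wgs", "wes"),
                                 n_clones = 2000, true_vafs = NULL,
                                 seed = config$seed) {
  platform <- match.arg(platform)
  set.seed(seed)
  if (is.null(true_vafs)) {
    true_vafs <- rbeta_trunc(n_clones, config$clone_beta[1],
                             config$clone_beta[2])
  }
  n <- length(true_vafs)
  depth <- pmax(1, stats::rpois(n, config$depth_mean[[platform]]))
  alt <- stats::rbinom(n, depth, true_vafs)
  data.frame(true_vaf = true_vafs, depth = depth, alt_reads = alt,
             obs_vaf = alt / depth, detected = alt >= 3)
}

#' Generate MR summary statistics with a planted causal effect
#'
#' Exposure effects gamma_j are uniform over `mr$gamma_range`, oriented to
#' the exposure-increasing allele (gamma > 0, as in harmonized summary
#' statistics); outcome effects are
#' Gamma_j = theta * gamma_j + alpha_j + noise, where alpha_j implements the
#' configured pleiotropy mode (`none`; `balanced` — zero-mean; `directional`
#' — a constant offset on a fraction of instruments). Observed betas add
#' estimation noise at the configured SEs. The reverse-direction table is
#' generated with theta = 0 by default (no reverse causation).
#'
#' @param config A [sim_config()].
#' @param direction `"forward"` (exposure -> outcome effect = theta_true) or
#'   `"reverse"` (theta = `theta_reverse`).
#' @param theta_reverse Planted reverse effect (default 0).
#' @param seed RNG seed.
#' @return A `data.frame` instrument table: `variant_id`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`, plus the latent
#'   `gamma_true` and `alpha` columns for diagnostics.
#' @export
gen_mr_summary_stats <- function(config = sim_config(),
                                 direction = c("forward", "reverse"),
                                 theta_reverse = 0, seed = config$seed) {
  direction <- match.arg(direction)
  m <- config$mr
  stopifnot(m$k_instruments >= 3)
  set.seed(seed)
  k <- m$k_instruments
  # instruments oriented to the exposure-increasing allele (as harmonized
  # summary statistics are), so gamma > 0 and a constant outcome offset is
  # genuinely directional on the ratio scale
  gamma <- stats::runif(k, m$gamma_range[1], m$gamma_range[2])
  theta <- if (direction == "forward") m$theta_true else theta_reverse
  alpha <- rep(0, k)
  if (m$pleiotropy != "none") {
    bad <- seq_len(ceiling(m$pleiotropy_frac * k))
    alpha[bad] <- if (m$pleiotropy == "directional") m$pleiotropy_size else
      stats::rnorm(length(bad), 0, m$pleiotropy_size)
  }
  data.frame(
    variant_id = sprintf("rs%06d", seq_len(k)),
    beta_exposure = gamma + stats::rnorm(k, 0, m$se_exposure),
    se_exposure = rep(m$se_exposure, k),
    beta_outcome = theta * gamma + alpha + stats::rnorm(k, 0, m$se_outcome),
    se_outcome = rep(m$se_outcome, k),
    gamma_true = gamma, alpha = alpha,
    stringsAsFactors = FALSE)
}

#' Generate a synthetic brain sample with known truth
#'
#' Draws a single-nucleus composition from a multinomial over cell-type
#' clusters, derives the bulk VAF implied by the planted mutant-MG fraction
#' (inverse of the [estimate_mutant_mg()] map, using realized counts:
#' VAF = (mutant_mg + non_mg) / (2 * total), all non-MG hematopoietic
#' nuclei mutant), and draws amplicon reads Binomial(depth, VAF). A
#' negative-control amplicon is drawn at the configured artifact error rate.
#'
#' @param config A [sim_config()].
#' @param sample_id Sample label.
#' @param seed RNG seed.
#' @return A list: `amplicon` (`data.frame` with sample/unsorted gate and
#'   negative-control rows), `composition` (one-row `data.frame` of cluster
#'   counts), `truth` (list: `mutant_mg_frac`, `vaf`, `mg`, `non_mg`,
#'   `total`).
#' @export
gen_brain_sample <- function(config = sim_config(), sample_id = "SYN1",
                             seed = config$seed) {
  b <- config$brain
  set.seed(seed)
  p_non_mg <- b$non_mg_frac
  probs <- c(MG = b$pct_mg,
             monocyte = 0.4 * p_non_mg, DC = 0.1 * p_non_mg,
             T_cell = 0.4 * p_non_mg, B_cell = 0.1 * p_non_mg,
             neuron = NA, oligodendrocyte = NA, astrocyte = NA, other = NA)
  rest <- 1 - b$pct_mg - p_non_mg
  probs[c("neuron", "oligodendrocyte", "astrocyte", "other")] <-
    rest * c(0.38, 0.45, 0.12, 0.05)
  counts <- as.vector(stats::rmultinom(1, b$n_nuclei, probs))
  names(counts) <- names(probs)
  total <- sum(counts)
  mg <- counts[["MG"]]
  non_mg <- sum(counts[c("monocyte", "DC", "T_cell", "B_cell")])
  mut_mg_true <- round(b$true_mutant_mg_frac * mg)
  vaf_true <- (mut_mg_true + non_mg) / (2 * total)
  depth <- b$amplicon_depth
  alt <- stats::rbinom(1, depth, vaf_true)
  nc_alt <- stats::rbinom(1, depth, b$error_rate)
  amplicon <- data.frame(
    sample_id = c(sample_id, paste0(sample_id, "_NC")),
    region = c("occipital", "occipital"),
    gate = c("unsorted", "unsorted"),
    variant_id = "chip_var",
    ref_reads = c(depth - alt, depth - nc_alt),
    alt_reads = c(alt, nc_alt),
    replicate = 1L,
    is_negative_control = c(FALSE, TRUE),
    stringsAsFactors = FALSE)
  composition <- data.frame(sample_id = sample_id, t(counts),
                            total = total, stringsAsFactors = FALSE)
  list(amplicon = amplicon, composition = composition,
       truth = list(mutant_mg_frac = if (mg > 0) mut_mg_true / mg else NA_real_,
                    vaf = vaf_true, mg = mg, non_mg = non_mg, total = total))
}
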