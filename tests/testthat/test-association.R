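# Association statistics: SE reconstruction, fixed-effects pooling,
# logistic and ordinal regression, composite neuropathology scoring,
# Kaplan-Meier / log-rank, and stratified meta-analysis.

test_that("SEs reconstructed from Wald P-values match quantile arithmetic", {
  # z = qnorm(1 - 0.13/2) = 1.5141, se = |ln 0.69|/z
  expect_equal(se_from_wald_p(log(0.69), 0.13), 0.2451, tolerance = 1e-3)
  expect_equal(se_from_wald_p(log(0.51), 0.068), 0.3690, tolerance = 1e-3)
  # p = 0.0455 has z ~ 2, so se ~ ln(2)/2
  expect_equal(se_from_wald_p(log(2), 0.0455), log(2) / 2, tolerance = 1e-3)
  expect_error(se_from_wald_p(0.5, 1), "in \\(0, 1\\)")
  expect_error(se_from_wald_p(0, 0.05), "nonzero")
})

test_that("Wald-P reconstruction inverts the P-value computation exactly", {
  for (b in c(-0.7, 0.2, 1.3)) {
    for (se in c(0.35, 0.6)) {
      p <- 2 * pnorm(-abs(b / se))
      expect_equal(se_from_wald_p(b, p), se, tolerance = 1e-10)
    }
  }
})

test_that("fixed-effects meta of the two longitudinal cohorts gives pooled SHR 0.63", {
  est <- rbind(
    cohort_estimate("CHS", ratio = 0.69, p = 0.13, effect_scale = "log_shr"),
    cohort_estimate("FHS", ratio = 0.51, p = 0.068, effect_scale = "log_shr")
  )
  m <- fixed_effects_meta(est)
  expect_equal(round(m$ratio, 2), 0.63)
  expect_lt(abs(m$p - 0.024), 0.002)
})

test_that("meta-analysis identities: symmetry, hand arithmetic, and pooling bounds", {
  # two identical estimates -> pooled unchanged, se/sqrt(2)
  est <- data.frame(cohort = c("a", "b"), estimate = c(-0.4, -0.4),
                    se = c(0.2, 0.2))
  m <- fixed_effects_meta(est)
  expect_equal(m$pooled_estimate, -0.4)
  expect_equal(m$pooled_se, 0.2 / sqrt(2))
  # three hand-picked estimates: weights (100, 25, 6.25)
  est3 <- data.frame(cohort = c("a", "b", "c"),
                     estimate = c(0.2, -0.1, 0.4), se = c(0.1, 0.2, 0.4))
  m3 <- fixed_effects_meta(est3)
  expect_equal(m3$pooled_estimate, 20 / 131.25, tolerance = 1e-12)
  expect_equal(m3$pooled_se, 1 / sqrt(131.25), tolerance = 1e-12)
  # pooled estimate within input range, pooled se below every input se,
  # weights normalized
  expect_true(m3$pooled_estimate >= min(est3$estimate) &&
                m3$pooled_estimate <= max(est3$estimate))
  expect_true(m3$pooled_se < min(est3$se))
  expect_equal(sum(m3$weights), 1)
  expect_error(fixed_effects_meta(data.frame(
    cohort = c("a", "b"), estimate = c(0.1, 0.2), se = c(0.1, 0.1),
    effect_scale = c("log_or", "log_shr"))), "mixed")
})

test_that("fixed-effects pooling agrees with metafor", {
  skip_if_not_installed("metafor")
  est <- data.frame(cohort = c("a", "b", "c"),
                    estimate = c(-0.45, -0.67, -0.21),
                    se = c(0.13, 0.37, 0.25))
  m <- fixed_effects_meta(est)
  rma <- metafor::rma(yi = est$estimate, sei = est$se, method = "FE")
  expect_equal(m$pooled_estimate, as.numeric(rma$beta), tolerance = 1e-10)
  expect_equal(m$pooled_se, rma$se, tolerance = 1e-10)
})

test_that("logistic coefficient on a 2x2 table equals the closed-form log OR", {
  for (tab in list(c(20, 30, 15, 35), c(8, 40, 12, 60), c(55, 45, 40, 60))) {
    df <- expand_2x2(tab[1], tab[2], tab[3], tab[4])
    fit <- fit_logistic(y ~ x, df)
    b <- fit$coefficients$estimate[fit$coefficients$term == "x"]
    expect_equal(b, log(tab[1] * tab[4] / (tab[2] * tab[3])),
                 tolerance = 1e-8)
  }
})

test_that("logistic inference is calibrated under the null", {
  set.seed(314)
  inside <- replicate(200, {
    df <- data.frame(x = rbinom(400, 1, 0.3), y = rbinom(400, 1, 0.4))
    fit <- fit_logistic(y ~ x, df)
    abs(fit$coefficients$z[fit$coefficients$term == "x"]) < 1.96
  })
  expect_gt(mean(inside), 0.90)
})

test_that("logistic separation raises an error naming the covariate", {
  df <- data.frame(x = c(rep(0, 20), rep(1, 20)),
                   y = c(rep(0, 20), rep(1, 20)))
  expect_error(suppressWarnings(fit_logistic(y ~ x, df)), "separation.*x")
})

test_that("ordinal fit reduces to logistic with a 2-level outcome", {
  set.seed(5)
  df <- data.frame(x = rnorm(300))
  df$y <- rbinom(300, 1, plogis(-0.3 + 0.8 * df$x))
  ref <- fit_logistic(y ~ x, df)
  expect_warning(ord <- fit_ordinal_logistic(y ~ x, df), "2 levels")
  expect_equal(ord$coefficients$estimate[ord$coefficients$term == "x"],
               ref$coefficients$estimate[ref$coefficients$term == "x"],
               tolerance = 1e-6)
})

test_that("ordinal fit matches a brute-force likelihood oracle", {
  set.seed(8)
  x <- rnorm(150)
  cum <- cbind(plogis(-0.5 - 0.9 * x), plogis(0.7 - 0.9 * x))
  u <- runif(150)
  y <- 1L + (u > cum[, 1]) + (u > cum[, 2])
  fit <- fit_ordinal_logistic(y ~ x, data.frame(x = x, y = y))
  oracle <- polr_nll_oracle(y, x)
  expect_equal(fit$coefficients$estimate, oracle$beta, tolerance = 1e-4)
  # P-values use the standard-normal reference on t = estimate/se
  expect_equal(fit$coefficients$p,
               2 * pnorm(-abs(fit$coefficients$z)), tolerance = 1e-12)
})

test_that("ordinal fit recovers a planted proportional-odds effect", {
  set.seed(21)
  hits <- replicate(40, {
    x <- rnorm(400)
    cum <- cbind(plogis(-0.8 - log(0.5) * x), plogis(0.8 - log(0.5) * x))
    u <- runif(400)
    y <- 1L + (u > cum[, 1]) + (u > cum[, 2])
    fit <- fit_ordinal_logistic(y ~ x, data.frame(x = x, y = y))
    abs(fit$coefficients$estimate[1] - log(0.5)) < 0.3
  })
  expect_gte(mean(hits), 0.9)
})

test_that("composite neuropathology score spans 1 to 6", {
  expect_equal(composite_adnc_score(0, 1), 1L)
  expect_equal(composite_adnc_score(3, 3), 6L)
  expect_equal(composite_adnc_score(2, 1), 3L)
  expect_error(composite_adnc_score(4, 1), "0-3")
  expect_error(composite_adnc_score(1, 0), "1-3")
  expect_equal(braak_group(c(0, 2, 3, 4, 5, 6)), c(1L, 1L, 2L, 2L, 3L, 3L))
})

test_that("Kaplan-Meier matches closed-form and hand-computed tables", {
  # no events: survival stays at 1
  km0 <- kaplan_meier(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km0$survival == 1))
  # all events, no censoring: empirical survival
  km1 <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km1$survival, c(2 / 3, 1 / 3, 0))
  # 6 subjects, one censored at t = 2: hand product-limit table
  km2 <- kaplan_meier(c(1, 2, 2, 3, 4, 5), c(1, 1, 0, 1, 1, 1))
  expect_equal(km2$time, c(1, 2, 3, 4, 5))
  expect_equal(km2$survival, c(5 / 6, 2 / 3, 4 / 9, 2 / 9, 0))
  expect_error(kaplan_meier(c(-1, 2), c(1, 1)), "non-negative")
})

test_that("Kaplan-Meier without censoring equals the empirical survival function", {
  set.seed(99)
  t <- sample(1:40, 60, replace = TRUE)
  km <- kaplan_meier(t, rep(1, 60))
  emp <- vapply(km$time, function(tt) mean(t > tt), 1)
  expect_equal(km$survival, emp, tolerance = 1e-12)
})

test_that("log-rank test matches a hand O/E oracle and is symmetric", {
  t <- c(1, 3, 5, 7, 2, 4, 6, 8)
  e <- c(1, 1, 1, 0, 1, 1, 0, 1)
  g <- rep(c("a", "b"), each = 4)
  res <- log_rank_test(t, e, g)
  oracle <- log_rank_oracle(t, e, g)
  expect_equal(res$chisq, oracle$chisq, tolerance = 1e-6)
  expect_equal(res$p, oracle$p, tolerance = 1e-6)
  # relabeling the groups leaves the statistic unchanged
  res2 <- log_rank_test(t, e, rev(g))
  expect_equal(res$chisq, res2$chisq, tolerance = 1e-12)
  # duplicated data in both arms: no difference
  res0 <- log_rank_test(rep(c(1, 2, 3), 2), rep(1, 6), rep(c("a", "b"), 3))
  expect_equal(res0$chisq, 0, tolerance = 1e-12)
  expect_equal(res0$p, 1)
})

test_that("log-rank test has ~5% type-I error and power against HR 3", {
  set.seed(2024)
  rejections <- replicate(2000, {
    t <- rexp(60, 0.1)
    g <- rep(0:1, each = 30)
    log_rank_test(pmin(t, 15), as.integer(t < 15), g)$p < 0.05
  })
  expect_lt(abs(mean(rejections) - 0.05), 0.012)
  power <- replicate(30, {
    t1 <- rexp(200, 0.05)
    t2 <- rexp(200, 0.15)
    t <- c(t1, t2)
    g <- rep(0:1, each = 200)
    log_rank_test(pmin(t, 20), as.integer(t < 20), g)$p < 0.01
  })
  expect_gte(mean(power), 0.95)
})

test_that("APOE genotypes bin by the any-e4 rule", {
  bins <- apoe_risk_bin(c("e2e3", "e2e4", "e3e3", "e3e4"))
  expect_equal(as.character(bins), c("low", "high", "neutral", "high"))
  expect_error(apoe_risk_bin("e1e3"), "invalid")
})

test_that("a single all-inclusive stratum reproduces the unstratified fit", {
  cfg <- sim_config(n_subjects = 1500)
  co <- gen_cohort(cfg, "case_control", cohort = "A", seed = 11)
  co$apoe <- "e3e3"  # everyone in one APOE stratum
  res <- suppressWarnings(run_stratified_meta(co, strata = "apoe"))
  direct <- fit_logistic(ad ~ chip + age + sex, co)
  b <- direct$coefficients[direct$coefficients$term == "chip", ]
  row <- res$per_cohort[res$per_cohort$stratum == "neutral", ]
  expect_equal(row$estimate, b$estimate, tolerance = 1e-10)
  expect_equal(row$se, b$se, tolerance = 1e-10)
})

test_that("stratified pooling separates strata with planted heterogeneity", {
  set.seed(77)
  n <- 4000
  make_cohort <- function(cohort, seed) {
    set.seed(seed)
    sex <- sample(c("female", "male"), n, replace = TRUE)
    apoe <- sample(c("e3e3", "e3e4"), n, replace = TRUE)
    chip <- rbinom(n, 1, 0.25)
    age <- round(rnorm(n, 78, 5))
    # protective CHIP effect only in the neutral (e3e3) stratum
    lp <- -0.3 + log(0.4) * chip * (apoe == "e3e3")
    data.frame(cohort = cohort, age = age, sex = sex, apoe = apoe,
               chip = chip, ad = rbinom(n, 1, plogis(lp)),
               driver_genes = ifelse(chip == 1, "DNMT3A", ""),
               stringsAsFactors = FALSE)
  }
  subjects <- rbind(make_cohort("A", 1), make_cohort("B", 2))
  res <- suppressWarnings(run_stratified_meta(subjects, strata = "apoe"))
  expect_lt(res$meta$neutral$pooled_estimate, log(0.6))
  expect_gt(res$meta$high$pooled_estimate, log(0.7))
})
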