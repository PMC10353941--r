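# Brain chimerism: amplicon VAF detection, the mutant-microglia estimator
# and its simulated confidence interval, glial-fraction testing, and the
# blood-brain correlation.

test_that("amplicon VAF applies the negative-control detection limit", {
  nc <- list(alt_reads = 0, ref_reads = 10000)
  # negative control itself: zero mutant alleles
  ncv <- amplicon_vaf(0, 10000, negative_control = nc)
  expect_equal(ncv$vaf, 0)
  expect_false(ncv$detected)
  # clear signal well above the limit
  av <- amplicon_vaf(35, 965, negative_control = nc)
  expect_equal(av$vaf, 0.035)
  expect_true(av$detected)
  # 1 alt read in 10,000 sits below the 3/depth floor
  low <- amplicon_vaf(1, 9999, negative_control = nc)
  expect_false(low$detected)
  expect_gte(low$detection_limit, 3 / 10000)
  # no negative control: fall back to 3/depth with a warning
  expect_warning(fb <- amplicon_vaf(10, 990), "negative control")
  expect_equal(fb$detection_limit, 3 / 1000)
  expect_error(amplicon_vaf(5, 100), "below minimum")
})

test_that("detection limit respects an elevated negative-control background", {
  noisy_nc <- list(alt_reads = 20, ref_reads = 9980)
  av <- amplicon_vaf(25, 9975, negative_control = noisy_nc)
  expect_gt(av$detection_limit,
            stats::binom.test(20, 10000)$conf.int[1])
  expect_false(av$detected)  # 0.0025 below the NC upper bound
})

test_that("heterozygous VAF converts to percent mutant cells by doubling", {
  expect_equal(percent_mutant_cells(0.28), 56)
  expect_equal(percent_mutant_cells(0.02), 4)
  expect_equal(percent_mutant_cells(0), 0)
  expect_warning(percent_mutant_cells(0.6), "heterozygous")
  expect_error(percent_mutant_cells(-0.1), "\\[0, 1\\]")
})

test_that("the mutant-MG estimator reproduces the worked brain-sample arithmetic", {
  est <- estimate_mutant_mg(vaf = 0.035, total = 11762, mg = 801, non_mg = 64)
  expect_equal(est$mut_mg, 759)
  expect_equal(round(100 * est$prop_mut_mg, 1), 94.8)
  # ignoring the non-MG subtraction overshoots past 100%
  expect_equal(round(100 * est$prop_unadjusted), 103)
  expect_true(est$clamped)
  expect_equal(est$prop_unadjusted_clamped, 1)
  # zero VAF: no mutant microglia (the conservative subtraction overshoots)
  z <- suppressWarnings(estimate_mutant_mg(0, 11762, 801, 64))
  expect_equal(z$mut_mg, 0)
  expect_equal(z$prop_mut_mg, 0)
  expect_error(estimate_mutant_mg(0.03, 1000, 0, 10), "mg must be positive")
  expect_error(estimate_mutant_mg(0.6, 1000, 100, 10), "heterozygous")
})

test_that("estimator is monotone in VAF and non-MG count, and flooring works", {
  vafs <- seq(0.01, 0.3, by = 0.01)
  props <- vapply(vafs,
                  function(v) estimate_mutant_mg(v, 10000, 500, 50)$prop_mut_mg,
                  1)
  expect_true(all(diff(props) >= 0))
  non_mgs <- seq(0, 400, by = 50)
  props2 <- vapply(non_mgs,
                   function(nm) estimate_mutant_mg(0.05, 10000, 500, nm)$prop_mut_mg,
                   1)
  expect_true(all(diff(props2) <= 0))
  # unadjusted >= adjusted always
  for (v in c(0.01, 0.05, 0.2)) {
    e <- estimate_mutant_mg(v, 10000, 500, 120)
    expect_gte(e$prop_unadjusted, e$prop_mut_mg)
  }
  # conservative overshoot at low VAF floors at zero with a warning
  expect_warning(fl <- estimate_mutant_mg(0.001, 10000, 500, 100), "floored")
  expect_equal(fl$mut_mg, 0)
})

test_that("CI simulation is seed-reproducible and narrows with sample size", {
  ci1 <- simulate_mutant_mg_ci(0.011, 0.02, 12, n_sims = 5000, seed = 7)
  ci2 <- simulate_mutant_mg_ci(0.011, 0.02, 12, n_sims = 5000, seed = 7)
  expect_identical(ci1$ci_low, ci2$ci_low)
  expect_identical(ci1$ci_high, ci2$ci_high)
  # point estimate inside its own CI across parameter sets
  for (p in list(c(0.011, 0.02), c(0.03, 0.05), c(0.002, 0.01))) {
    ci <- simulate_mutant_mg_ci(p[1], p[2], 10, n_sims = 5000, seed = 3)
    expect_gte(ci$point, ci$ci_low)
    expect_lte(ci$point, ci$ci_high)
  }
  # law of large numbers: huge libraries/nuclei shrink the CI below 1 point
  big <- simulate_mutant_mg_ci(0.011, 0.02, 12, n_genomes = 1e9,
                               n_nuclei = 1e8, n_sims = 5000, seed = 7)
  expect_lt(big$ci_high - big$ci_low, 0.01)
  small <- simulate_mutant_mg_ci(0.011, 0.02, 12, n_sims = 5000, seed = 7)
  expect_gt(small$ci_high - small$ci_low, big$ci_high - big$ci_low)
  expect_error(simulate_mutant_mg_ci(0.01, 0, 10), "positive")
})

test_that("CI width scales roughly as 1/sqrt(n_nuclei) for the MG term", {
  w <- vapply(c(2000, 8000, 32000), function(nn) {
    ci <- simulate_mutant_mg_ci(0.011, 0.02, 0, n_genomes = 1e9,
                                n_nuclei = nn, n_sims = 20000, seed = 5)
    ci$ci_high - ci$ci_low
  }, 1)
  # quadrupling nuclei should halve the width (ratio ~2, generous band)
  expect_equal(w[1] / w[2], 2, tolerance = 0.3)
  expect_equal(w[2] / w[3], 2, tolerance = 0.3)
})

test_that("MG fraction of the glial pool and fold enrichment are simple ratios", {
  expect_equal(mg_glia_fraction(50, 700, 250), 0.05)
  expect_equal(mg_glia_fraction(0, 700, 250), 0)
  expect_equal(mg_glia_fraction(c(50, 82, 20), c(700, 650, 900),
                                c(250, 268, 80)),
               c(50 / 1000, 82 / 1000, 20 / 1000))
  expect_error(mg_glia_fraction(0, 0, 0), "positive")
  expect_equal(fold_enrichment(0.25, 0.01), 25)
  expect_equal(fold_enrichment(0.1, 0.1), 1)
  expect_equal(fold_enrichment(c(0.23, 0.069), c(0.02, 0.006)),
               c(11.5, 11.5))
  expect_error(fold_enrichment(0.2, 0), "positive")
})

test_that("quasibinomial test is null-calibrated and nests the binomial GLM", {
  # equal proportions: coefficient ~ 0
  comp <- data.frame(MG = c(50, 52, 50, 52), oligodendrocyte = rep(700, 4),
                     astrocyte = rep(250, 4))
  res <- quasibinomial_group_test(comp, c("a", "a", "b", "b"))
  expect_equal(res$coefficient, 0, tolerance = 1e-10)
  expect_equal(res$p, 1, tolerance = 1e-6)
  # pure binomial data: dispersion ~ 1 and P close to the binomial GLM's
  set.seed(404)
  glia <- rep(1000, 12)
  grp <- rep(c("a", "b"), each = 6)
  mg <- rbinom(12, glia, ifelse(grp == "a", 0.05, 0.07))
  comp2 <- data.frame(MG = mg, oligodendrocyte = round(0.8 * (glia - mg)),
                      astrocyte = glia - mg - round(0.8 * (glia - mg)))
  res2 <- quasibinomial_group_test(comp2, grp)
  bin <- stats::glm(cbind(mg, glia - mg) ~ grp, family = binomial())
  pb <- 2 * pnorm(-abs(coef(bin)[2] / sqrt(diag(vcov(bin)))[2]))
  expect_equal(res2$p, unname(pb), tolerance = 0.05)
  expect_error(quasibinomial_group_test(
    data.frame(MG = c(0, 0, 5, 6), oligodendrocyte = rep(100, 4),
               astrocyte = rep(50, 4)), c("a", "a", "b", "b")), "all-zero")
})

test_that("quasibinomial test detects a 5.1% vs 8.2% MG-fraction shift", {
  set.seed(88)
  hits <- replicate(30, {
    glia <- round(runif(10, 800, 2500))
    grp <- rep(c("control", "chip"), c(4, 6))
    p <- ifelse(grp == "control", 0.051, 0.082)
    mg <- rbinom(10, glia, p)
    comp <- data.frame(MG = mg,
                       oligodendrocyte = round(0.8 * (glia - mg)),
                       astrocyte = glia - mg - round(0.8 * (glia - mg)))
    quasibinomial_group_test(comp, grp)$p < 0.05
  })
  expect_gt(mean(hits), 0.5)
})

test_that("blood-brain correlation matches hand arithmetic", {
  # perfectly linear pairs
  lin <- blood_brain_correlation(c(0.1, 0.2, 0.3, 0.4), c(0.2, 0.4, 0.6, 0.8))
  expect_equal(lin$r, 1)
  expect_equal(lin$r_squared, 1)
  # 4 hand points: r and t computed from first principles
  x <- c(1, 2, 3, 5)
  y <- c(2, 1, 4, 6)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt(2 / (1 - r_hand^2))
  res <- blood_brain_correlation(x, y)
  expect_equal(res$r, r_hand, tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df = 2), tolerance = 1e-10)
  # the strong-correlation regime at n = 6: r^2 ~ 0.96 gives P < 0.01
  set.seed(12)
  b <- c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5)
  m <- 0.9 * b + c(0.01, -0.02, 0.015, -0.01, 0.02, -0.005)
  res6 <- blood_brain_correlation(b, m)
  expect_gt(res6$r_squared, 0.9)
  expect_lt(res6$p, 0.01)
  expect_error(blood_brain_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(blood_brain_correlation(c(1, 2), c(1, 2)), "at least 3")
})

test_that("replicate amplicon libraries give concordant VAFs", {
  set.seed(515)
  depth <- 5000
  ok <- replicate(300, {
    v <- runif(1, 0.01, 0.3)
    v1 <- rbinom(1, depth, v) / depth
    v2 <- rbinom(1, depth, v) / depth
    sd_pair <- sqrt(2 * v * (1 - v) / depth)
    abs(v1 - v2) < 3 * sd_pair
  })
  expect_gte(mean(ok), 0.99)
})
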