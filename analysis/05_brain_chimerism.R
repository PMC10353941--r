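#!/usr/bin/env Rscript
# Brain chimerism: per-sample percent mutant microglia with simulated 95%
# CIs, the blood-brain mutant-fraction correlation, and the MG/glia
# fraction comparison, on the simulated brain samples plus the published
# worked example.
suppressPackageStartupMessages(library(chipscope))

# the published worked example, recomputed
est <- estimate_mutant_mg(vaf = 0.035, total = 11762, mg = 801, non_mg = 64)
message(sprintf("worked example: mut_mg = %d, %.1f%% of MG (unadjusted %.0f%%)",
                est$mut_mg, 100 * est$prop_mut_mg, 100 * est$prop_unadjusted))

rows <- list()
pairs <- list()
for (i in 1:6) {
  amp <- read.delim(sprintf("results/sim/brain_%d_amplicon.tsv", i))
  comp <- read.delim(sprintf("results/sim/brain_%d_composition.tsv", i))
  truth <- read.delim(sprintf("results/sim/brain_%d_truth.tsv", i))
  smp <- amp[!amp$is_negative_control, ]
  nc <- amp[amp$is_negative_control, ]
  av <- amplicon_vaf(smp$alt_reads, smp$ref_reads,
                     negative_control = list(alt_reads = nc$alt_reads,
                                             ref_reads = nc$ref_reads))
  non_mg <- comp$monocyte + comp$DC + comp$T_cell + comp$B_cell
  e <- estimate_mutant_mg(av$vaf, comp$total, comp$MG, non_mg)
  ci <- simulate_mutant_mg_ci(av$vaf, comp$MG / comp$total, non_mg,
                              total = comp$total,
                              n_genomes = smp$alt_reads + smp$ref_reads,
                              n_nuclei = comp$total,
                              n_sims = 1e5, seed = 300 + i)
  rows[[i]] <- data.frame(
    sample = comp$sample_id, vaf = av$vaf, detected = av$detected,
    pct_mutant_mg = 100 * e$prop_mut_mg_clamped,
    ci_low = 100 * ci$ci_low, ci_high = 100 * min(1, ci$ci_high),
    true_pct = 100 * truth$mutant_mg_frac)
  # paired blood fraction: clone's blood VAF doubles to mutant cell fraction
  pairs[[i]] <- data.frame(blood = 2 * truth$vaf,
                           brain = e$prop_mut_mg_clamped)
}
tab <- do.call(rbind, rows)
write_tsv(tab, "results/chimerism.tsv")
print(tab, digits = 3)

pairs <- do.call(rbind, pairs)
bb <- blood_brain_correlation(pairs$blood, pairs$brain)
message(sprintf("blood-brain correlation: r = %.3f (R^2 = %.2f), P = %.2g",
                bb$r, bb$r_squared, bb$p))

# MG/glia fraction: CHIP-carrier-like vs control-like compositions
set.seed(99)
glia <- round(runif(10, 1500, 4000))
grp <- rep(c("control", "chip"), c(4, 6))
mg <- rbinom(10, glia, ifelse(grp == "control", 0.051, 0.082))
comp <- data.frame(MG = mg, oligodendrocyte = round(0.8 * (glia - mg)),
                   astrocyte = glia - mg - round(0.8 * (glia - mg)))
qb <- quasibinomial_group_test(comp, grp)
frac <- mg_glia_fraction(comp$MG, comp$oligodendrocyte, comp$astrocyte)
message(sprintf("MG/glia fraction: control %.1f%%, CHIP %.1f%%; quasibinomial P = %.2g",
                100 * mean(frac[grp == "control"]),
                100 * mean(frac[grp == "chip"]), qb$p))
write_tsv(data.frame(sample = seq_along(grp), group = grp,
                     mg_glia_fraction = frac),
          "results/mg_glia_fraction.tsv")
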