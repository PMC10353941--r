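#!/usr/bin/env Rscript
# Generate the synthetic study inputs: an ADSP-like case-control cohort, a
# pair of TOPMed-like longitudinal cohorts, depth-dependent VAF panels for
# both sequencing platforms, MR summary statistics, and brain samples.
suppressPackageStartupMessages(library(chipscope))

dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)
cfg <- sim_config(seed = 20260925L)

cc <- gen_cohort(cfg, "case_control", cohort = "SYN_CC", seed = 101)
write_tsv(cc, "results/sim/cohort_case_control.tsv")

lg1 <- gen_cohort(cfg, "longitudinal", cohort = "SYN_L1", seed = 102)
lg2 <- gen_cohort(cfg, "longitudinal", cohort = "SYN_L2", seed = 103)
write_tsv(rbind(lg1, lg2), "results/sim/cohort_longitudinal.tsv")

set.seed(104)
clones <- chipscope:::rbeta_trunc(2000, cfg$clone_beta[1], cfg$clone_beta[2])
wgs <- gen_vaf_observations(cfg, "wgs", true_vafs = clones, seed = 105)
wes <- gen_vaf_observations(cfg, "wes", true_vafs = clones, seed = 106)
write_tsv(cbind(platform = "wgs", wgs), "results/sim/vafs_wgs.tsv")
write_tsv(cbind(platform = "wes", wes), "results/sim/vafs_wes.tsv")

fwd <- gen_mr_summary_stats(cfg, "forward", seed = 107)
rev <- gen_mr_summary_stats(cfg, "reverse", seed = 108)
write_tsv(fwd, "results/sim/mr_forward.tsv")
write_tsv(rev, "results/sim/mr_reverse.tsv")

# donors span the observed 30-95% range of mutant-MG fractions
mut_fracs <- seq(0.30, 0.95, length.out = 6)
for (i in 1:6) {
  cfg_i <- cfg
  cfg_i$brain$true_mutant_mg_frac <- mut_fracs[i]
  bs <- gen_brain_sample(cfg_i, sample_id = sprintf("SYNBR%d", i), seed = 200 + i)
  write_tsv(bs$amplicon, sprintf("results/sim/brain_%d_amplicon.tsv", i))
  write_tsv(bs$composition, sprintf("results/sim/brain_%d_composition.tsv", i))
  write_tsv(as.data.frame(bs$truth), sprintf("results/sim/brain_%d_truth.tsv", i))
}

message("simulated inputs written under results/sim/: ",
        sprintf("cohort n=%d (%.1f%% AD, %.1f%% CHIP), %d clones per platform",
                nrow(cc), 100 * mean(cc$ad), 100 * mean(cc$chip),
                length(clones)))
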