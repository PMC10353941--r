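#!/usr/bin/env Rscript
# CHIP calling and cross-depth harmonization on the simulated VAF panels:
# the deeper (WES-like, ~80x) platform detects more clones than the
# shallower (WGS-like, ~38x) one; the empirical KS-minimizing cutoff
# restricts the deeper carrier set until its VAF distribution matches.
suppressPackageStartupMessages(library(chipscope))

wgs <- read.delim("results/sim/vafs_wgs.tsv")
wes <- read.delim("results/sim/vafs_wes.tsv")

message(sprintf("detected clone fraction: WGS %.1f%%, WES %.1f%%",
                100 * mean(wgs$detected), 100 * mean(wes$detected)))

h <- harmonize_vaf_cutoff(wgs$obs_vaf[wgs$detected],
                          wes$obs_vaf[wes$detected])
message(sprintf("harmonized VAF cutoff: %.3f (KS distance %.3f)",
                h$cutoff, h$ks_distance))
write_tsv(h$grid, "results/harmonization_grid.tsv")
write_tsv(data.frame(cutoff = h$cutoff, ks_distance = h$ks_distance),
          "results/harmonization_choice.tsv")

# carrier classification demo on the shipped example fixtures
wl <- read_whitelist(system.file("extdata", "example_whitelist.tsv",
                                 package = "chipscope"))
calls <- read_variant_calls(system.file("extdata", "example_calls.tsv",
                                        package = "chipscope"))
status <- assign_carrier_status(classify_chip_variants(calls, wl),
                                cutoff = h$cutoff)
write_tsv(status, "results/example_chip_status.tsv")
print(status)
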