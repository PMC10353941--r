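Package: chipscope
Title: Clonal Hematopoiesis, Alzheimer's Disease and Microglial Chimerism Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic pipeline linking clonal hematopoiesis of indeterminate
    potential (CHIP) to Alzheimer's disease: CHIP carrier classification from
    somatic variant calls against a configurable gene/variant whitelist,
    variant-allele-fraction (VAF) harmonization across sequencing depths,
    association statistics with inverse-variance fixed-effects meta-analysis,
    two-sample Mendelian-randomization estimators (ratio, IVW with
    multiplicative random effects, weighted median, Egger), and a
    brain-chimerism calculation estimating the fraction of mutant microglia
    from amplicon VAFs and single-nucleus cell-type compositions, with
    simulation-based confidence intervals. Seeded synthetic-data generators
    emulate every input so the whole chain runs without restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    MASS,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
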