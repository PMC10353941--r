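---
title: "Methods: CHIP, Alzheimer's disease, and microglial chimerism"
author: "chipscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CHIP, Alzheimer's disease, and microglial chimerism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipscope)
```

# The scientific problem

Clonal hematopoiesis of indeterminate potential (CHIP) is an age-related
expansion of a mutated hematopoietic stem-cell clone, detectable in blood as
somatic variants in a small set of driver genes (*DNMT3A*, *TET2*, *ASXL1*,
...). Because CHIP mutations alter myeloid cell function, and because
microglia (MG) — the brain's macrophage-like cells — are central to
Alzheimer's disease (AD) risk, an association between CHIP and AD is
biologically plausible. `chipscope` implements the full analytic chain
needed to study that association from variant calls to brain:

1. **CHIP calling** from somatic variant calls against a configurable
   whitelist, with variant-allele-fraction (VAF) based clone-size
   categories.
2. **Cross-depth VAF harmonization**, because deeper sequencing detects
   smaller clones and inflates apparent prevalence.
3. **Association statistics** — logistic and proportional-odds models,
   Kaplan–Meier / log-rank, and inverse-variance fixed-effects
   meta-analysis, including pooling of *published* cohort estimates whose
   SEs must be reconstructed from Wald P-values.
4. **Mendelian randomization (MR)** from GWAS summary statistics, in both
   causal directions.
5. **Brain chimerism** — the estimator of the fraction of mutant MG in a
   brain specimen from amplicon VAF and single-nucleus composition, with
   simulation-based confidence intervals.
6. **Synthetic data generators** for every input, since the motivating
   cohort datasets are controlled-access.

# Models and conventions

## VAF and carrier status

VAF = alt/(alt + ref). A minimum total depth of 20 is required before a VAF
is emitted (below that, binomial noise at VAF ~0.02 overwhelms the
estimate). Carriers are categorized by maximum CHIP VAF into `none`, `low`
(VAF ≤ cutoff) and `high` (VAF > cutoff); the inequality is strict, so a
clone exactly at the cutoff is `low`. VAFs above 0.5 (possible loss of
heterozygosity or copy-number change) are retained but flagged. The
whitelist grammar has three rule kinds — `any_truncating`,
`listed_positions`, `listed_protein_changes` — because published per-gene
CHIP criteria mix exactly these shapes; users supply their own gene list.

## Harmonizing the VAF cutoff across depths

A ~38× whole-genome cohort and an ~80× whole-exome cohort see different
parts of the clone-size spectrum. We operationalize "choose a cutoff that
makes the distributions match" as: over a candidate grid (default 0.02–0.20
in steps of 0.005), pick the cutoff minimizing the two-sample
Kolmogorov–Smirnov distance between the reference cohort's carrier VAFs and
the deeper cohort's VAFs above the cutoff, breaking ties toward the smaller
cutoff. This is reproducible and directly expresses the "nearly identical
distribution" goal; the shipped default cutoff is 0.08. On fully resampled
synthetic platforms the KS-minimizing grid point can land one step away
(e.g. 0.075/0.07) because binomial read noise blurs the detection boundary;
the planted-truncation recovery (deep set = shallow set plus sub-cutoff
clones) identifies 0.08 exactly.

## SE reconstruction and fixed-effects pooling

Published cohort tables often print a ratio estimate and a two-sided Wald
P-value. Under the Wald convention, se = |log ratio| / Φ⁻¹(1 − P/2), which
lets printed estimates enter an inverse-variance fixed-effects pool:
pooled = Σ(θᵢ/sᵢ²)/Σ(1/sᵢ²), se = 1/√Σ(1/sᵢ²). Because printed P-values
carry 2 significant figures, pooled ratios re-derived this way can shift by
about ±0.01 on the ratio scale; this is documented rather than hidden.
Pooling across different effect scales (log OR vs log SHR) errors unless
explicitly overridden.

## Regression conventions

Logistic models are fitted by IRLS (`stats::glm`); coefficients beyond 15
on the log-odds scale are treated as (quasi-)separation and error, naming
the covariate. Ordinal outcomes (CERAD 0–3; Braak stage grouped 0/I/II → 1,
III/IV → 2, V/VI → 3; their composite sum 1–6) use the proportional-odds
model (`MASS::polr`); **P-values compare t = estimate/SE to the standard
normal**, the convention used in the neuropathology analyses this package
reproduces, not a t-reference. APOE genotypes bin into neutral (ε3ε3),
low-risk (ε2ε2/ε2ε3) and high-risk (any ε4 allele — including ε2ε4, since
it carries an ε4 allele). Log-rank tests use Breslow-style aggregation of
tied event times. Fine–Gray competing-risks models are *consumed* as
published subdistribution hazard ratios, not fitted: the packaged CRR
implementations are standard and out of scope; internally the longitudinal
stage offers cause-specific Kaplan–Meier and log-rank only.

## Mendelian randomization

All estimators start from per-instrument ratio estimates βⱼ = Γⱼ/γⱼ with
first-order SEs σⱼ = se(Γⱼ)/|γⱼ|.

* **IVW (multiplicative random effects):** inverse-variance pooled ratio;
  the SE is inflated by max(1, √φ), φ = Σ(βⱼ−θ)²/σⱼ² / (k−1). φ also serves
  as a crude pleiotropy/heterogeneity signal.
* **Weighted median** (the primary estimator): sort βⱼ, form
  sⱼ = cumulative normalized weight − wⱼ/2, and interpolate β at s = 0.5.
  Ties in βⱼ are broken by stable sort. It is consistent when valid
  instruments carry more than half the weight. The SE is a parametric
  bootstrap (βⱼ* ~ N(βⱼ, σⱼ); default 1,000 draws, seed 1234) — the
  published analyses delegate this to a package without stating the scheme,
  so the bootstrap is made explicit and seeded here.
* **Egger:** weighted least squares of Γ on γ with an intercept (weights
  1/se(Γ)²) after orienting γ > 0; the intercept estimates average
  directional pleiotropy.

Allele harmonization (effect-allele alignment, palindromic SNPs) is assumed
done upstream; the synthetic generator therefore emits instruments oriented
to the exposure-increasing allele (γ > 0). This matters for the
"directional" pleiotropy mode: with unoriented signs a constant outcome
offset averages out on the ratio scale and is not directional at all.

## The brain-chimerism estimator

CHIP mutations are heterozygous, so 2 × VAF estimates the fraction of
mutant nuclei. Conservatively assuming every nonmicroglial hematopoietic
nucleus (monocytes, dendritic cells, T and B cells) is mutant:

```
mut_mg      = round(total × vaf × 2 − non_mg)
prop_mut_mg = mut_mg / mg
```

Negative `mut_mg` (the conservative assumption overshoots at low VAF) is
floored at 0 with a warning. Proportions above 1 are reported both raw and
clamped — the unadjusted variant `vaf × total × 2 / mg` can legitimately
exceed 100% and both values are informative. Rounding is R's
round-half-to-even; at the shipped worked example (VAF 0.035, 11,762
nuclei, 801 MG, 64 non-MG) either rounding convention gives 759 mutant MG,
i.e. 94.8% of MG (unadjusted: 103%).

Amplicon VAFs carry a detection limit: the larger of 3/depth and the upper
95% binomial bound of the negative-control alt fraction (a no-CHIP brain
sequenced with the same primers). Without a negative control the 3/depth
floor applies, with a warning.

**Confidence intervals** propagate the two binomial layers: the alt-allele
count among `n_genomes` haploid genomes (default 200,000, i.e. 100,000
input nuclei — the smallest library in the motivating experiments) and the
MG count among `n_nuclei` assayed nuclei (default 8,000, the approximate
median). Each replicate redraws both, recomputes the estimator with the
non-MG count held fixed (only the VAF and MG-fraction layers are
simulated), and the 2.5/97.5 percentiles form the CI. The production
default is 10⁶ replicates; tests use 10⁴, where empirical coverage is
within two points of nominal. When the CI is applied to data whose VAF was
measured at a different binomial size (e.g. the synthetic generator's
5,000× amplicon fixture), pass that size as `n_genomes`; the defaults
describe the motivating experiments, not every dataset.

The MG/glia fraction is MG/(MG + oligodendrocytes + astrocytes) — the
"total glial pool" is exactly these three clusters. Group differences use a
quasibinomial GLM of MG counts out of the glial pool, with the Wald P from
the standard normal on the dispersion-inflated SE (this also makes the
dispersion-1 case agree with an ordinary binomial GLM). Blood–brain
concordance is a Pearson correlation with the P-value from
t = r√((n−2)/(1−r²)).

# What the synthetic generators emulate — and what they do not

The generators are pure functions of (config, seed) and emulate:

* **Cohorts:** age/sex/APOE per configured frequencies (APOE defaults from
  a published cohort's printed genotype counts, with the combined
  ε2ε2/ε2ε3 count split on Hardy–Weinberg proportions); CHIP prevalence
  rising logistically with age (~7% at 60, ~20% at 80, ~30% at 90,
  matching the 10–30%-over-70 range reported for CHIP); clone VAFs from
  Beta(1.5, 20) truncated to (0, 0.5) — a realistic right-skewed spectrum,
  chosen once since no parametric clone-size law is published; AD outcomes
  either case-control (~43% cases, matching the replication cohort's
  case/control balance) with the planted odds ratio 0.64 on the log-odds
  scale, or longitudinal with competing exponential AD and death hazards
  and administrative censoring at 20 years. Ages ≥ 90 are coded as 90.
* **Platform depth:** Poisson depths around 38× (WGS-like) or 80× (WES-like),
  binomial alt reads, detection at ≥ 3 alt reads — a common somatic-calling
  floor standing in for a full caller.
* **MR summary stats:** 24 instruments, exposure betas uniform on
  [0.05, 0.15] (strong, genome-wide-significant scale against an SE of
  0.01), outcome SE 0.02, true effect ln(0.90); pleiotropy modes none /
  balanced / directional (directional offset 0.1 on 30% of instruments —
  a *large* violation, which is the scenario in which median-based
  robustness is visible). The reverse-direction table uses a null effect.
* **Brain samples:** multinomial nucleus compositions (~2% MG, ~0.15%
  non-MG hematopoietic — about 7% of the hematopoietic pool, matching the
  observed share), bulk VAF derived by inverting the chimerism estimator at
  the planted mutant-MG fraction, binomial amplicon reads at 5,000×, and a
  negative control at a 10⁻⁴ artifact rate.

They do **not** emulate: family structure and relatedness, caller-specific
artifact modes, LD between instruments, selection bias in case-control
recruitment, between-region heterogeneity within a donor, or overdispersed
(non-multinomial) composition sampling. Passing tests therefore demonstrate
that the estimators recover what they claim under clean sampling
assumptions, not that those assumptions hold in any particular cohort.

# Numerical choices and degenerate inputs

* Logistic convergence is `glm`'s IRLS default; separation detection at
  |coef| > 15.
* Harmonization ties break toward the smaller cutoff (within 1e-12);
  cutoffs that empty the deeper set are excluded with a warning.
* The weighted median returns an endpoint when 0.5 falls outside the
  interpolation range (possible with k = 3 and very unequal weights).
* `simulate_mutant_mg_ci` drops replicates that draw zero MG nuclei (with a
  warning); pct_mg = 0 errors.
* Two-level ordinal outcomes reduce to logistic regression; empty levels
  collapse with a warning.
* Degenerate strata (one outcome class, or no CHIP variation) are skipped
  and recorded, not silently dropped.

# Problem sizes used by the test suite

The suite runs the headline checks at reduced but informative sizes, chosen
as the package's own test design: planted-OR recovery at n = 5,000 × 200
seeds (the recovery fit adjusts for age, sex and the APOE risk bin — the
planted effect is conditional on APOE, and binning avoids sparse-cell
separation from the rare ε2ε2 genotype); weighted-median accuracy over 500
seeds and pleiotropy robustness over 200; CI coverage over 500 outer
replicates at 10⁴ simulation draws; log-rank type-I error over 2,000
replicates; the brain round trip over 500 generated samples at 2,000 CI
draws each.

# Known limitations

* The whitelist grammar covers truncating/position/protein-change rules but
  not hotspot-window or consequence-class rules some curations use.
* Fixed-effects pooling of printed estimates inherits the rounding of the
  source tables (~±0.01 on the ratio scale).
* The chimerism estimator treats the non-MG hematopoietic count as both
  fully mutant and exactly known; both choices are conservative for the
  MG fraction but bias it downward when non-MG contamination is
  overestimated.
* MR here implements ratio/IVW/weighted-median/Egger; outlier-removal and
  mode-based methods are intentionally out of scope, with IVW dispersion φ
  reported as the pleiotropy signal.
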