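# End-to-end orchestration over synthetic inputs: simulate -> CHIP calling /
# harmonization -> association + meta -> Mendelian randomization -> brain
# chimerism, with a JSON run manifest recording seeds, versions, stage
# status and output checksums.

#' Pipeline configuration
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed; stage seeds are derived as small offsets.
#' @param stages Character vector of stages to run, in order, among
#'   `"call"`, `"harmonize"`, `"assoc"`, `"mr"`, `"chimerism"`.
#' @param sim A [sim_config()] driving the synthetic inputs.
#' @param vaf_cutoff Carrier VAF cutoff (default 0.08).
#' @param min_depth Minimum depth for VAF computation.
#' @param n_sims_ci Replicates for the chimerism CI simulation.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = c("call", "harmonize", "assoc", "mr",
                                       "chimerism"),
                            sim = sim_config(seed = seed),
                            vaf_cutoff = 0.08, min_depth = 20,
                            n_sims_ci = 1e4) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 sim = sim, vaf_cutoff = vaf_cutoff, min_depth = min_depth,
                 n_sims_ci = n_sims_ci),
            class = "pipeline_config")
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the enabled stages in order. Each stage writes its tables under
#' `out_dir`; the manifest (`manifest.json`) records the package version,
#' the seeds used, each stage's status (`ok`, `failed`, `skipped`) and md5
#' checksums of every output file. A failed stage skips all downstream
#' stages. Reruns with the same config are bit-identical for deterministic
#' stages.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  all_stages <- c("call", "harmonize", "assoc", "mr", "chimerism")
  manifest <- list(
    package = "chipscope",
    version = as.character(utils::packageVersion("chipscope")),
    seed = config$seed,
    stages = list(),
    outputs = list()
  )
  failed <- FALSE
  for (stage in all_stages) {
    if (!(stage %in% config$stages)) {
      manifest$stages[[stage]] <- list(status = "skipped",
                                       reason = "disabled")
      next
    }
    if (failed) {
      manifest$stages[[stage]] <- list(status = "skipped",
                                       reason = "upstream failure")
      next
    }
    res <- tryCatch({
      files <- switch(stage,
                      call = stage_call(config),
                      harmonize = stage_harmonize(config),
                      assoc = stage_assoc(config),
                      mr = stage_mr(config),
                      chimerism = stage_chimerism(config))
      list(status = "ok", files = files)
    }, error = function(e) list(status = "failed",
                                error = conditionMessage(e)))
    manifest$stages[[stage]] <- res[setdiff(names(res), "files")]
    if (res$status == "failed") {
      failed <- TRUE
    } else {
      for (f in res$files) {
        manifest$outputs[[basename(f)]] <-
          unname(tools::md5sum(f))
      }
    }
  }
  manifest$n_failures <- sum(vapply(manifest$stages,
                                    function(s) s$status == "failed", TRUE))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

stage_call <- function(config) {
  cohort <- gen_cohort(config$sim, mode = "case_control", cohort = "SYN",
                       seed = config$seed)
  # synthetic carriers' clone VAFs become the call-level max VAF directly
  status <- data.frame(sample_id = cohort$subject_id,
                       is_carrier = cohort$chip == 1,
                       max_vaf = cohort$vaf,
                       driver_genes = cohort$driver_genes,
                       stringsAsFactors = FALSE)
  status$vaf_category <- ifelse(!status$is_carrier, "none",
                                ifelse(status$max_vaf > config$vaf_cutoff,
                                       "high", "low"))
  f1 <- file.path(config$out_dir, "cohort.tsv")
  f2 <- file.path(config$out_dir, "chip_status.tsv")
  write_tsv(cohort, f1)
  write_tsv(status, f2)
  c(f1, f2)
}

stage_harmonize <- function(config) {
  set.seed(config$seed + 1L)
  clones <- rbeta_trunc(2000, config$sim$clone_beta[1],
                        config$sim$clone_beta[2])
  wgs <- gen_vaf_observations(config$sim, "wgs", true_vafs = clones,
                              seed = config$seed + 2L)
  wes <- gen_vaf_observations(config$sim, "wes", true_vafs = clones,
                              seed = config$seed + 3L)
  h <- harmonize_vaf_cutoff(wgs$obs_vaf[wgs$detected],
                            wes$obs_vaf[wes$detected])
  f <- file.path(config$out_dir, "harmonization.tsv")
  write_tsv(h$grid, f)
  f2 <- file.path(config$out_dir, "harmonization_choice.tsv")
  write_tsv(data.frame(cutoff = h$cutoff, ks_distance = h$ks_distance), f2)
  c(f, f2)
}

stage_assoc <- function(config) {
  cohorts <- list(
    SYN_A = gen_cohort(config$sim, "case_control", "SYN_A",
                       seed = config$seed + 10L),
    SYN_B = gen_cohort(config$sim, "case_control", "SYN_B",
                       seed = config$seed + 11L))
  est <- do.call(rbind, lapply(cohorts, function(co) {
    fit <- fit_logistic(ad ~ chip + age + sex, co)
    cf <- fit$coefficients[fit$coefficients$term == "chip", ]
    data.frame(cohort = co$cohort[1], estimate = cf$estimate, se = cf$se,
               p = cf$p, effect_scale = "log_or", stringsAsFactors = FALSE)
  }))
  meta <- fixed_effects_meta(est)
  f1 <- file.path(config$out_dir, "assoc_per_cohort.tsv")
  write_tsv(est, f1)
  f2 <- file.path(config$out_dir, "assoc_meta.tsv")
  write_tsv(data.frame(pooled_or = meta$ratio, ci_low = meta$ci95[1],
                       ci_high = meta$ci95[2], p = meta$p), f2)
  c(f1, f2)
}

stage_mr <- function(config) {
  ins <- gen_mr_summary_stats(config$sim, "forward", seed = config$seed + 20L)
  exposure <- data.frame(variant_id = ins$variant_id,
                         beta = ins$beta_exposure, se = ins$se_exposure)
  outcome <- data.frame(variant_id = ins$variant_id,
                        beta = ins$beta_outcome, se = ins$se_outcome)
  res <- run_mr(exposure, list(synthetic_gwas = outcome),
                direction = "forward", seed = config$seed + 21L)
  rows <- do.call(rbind, lapply(names(res$per_study), function(nm) {
    do.call(rbind, lapply(c("ivw_mre", "weighted_median", "egger"),
                          function(mth) {
      e <- res$per_study[[nm]][[mth]]
      data.frame(study = nm, method = mth, or = e$or, ci_low = e$ci95[1],
                 ci_high = e$ci95[2], p = e$p, stringsAsFactors = FALSE)
    }))
  }))
  f <- file.path(config$out_dir, "mr_results.tsv")
  write_tsv(rows, f)
  f
}

stage_chimerism <- function(config) {
  rows <- list()
  for (i in 1:3) {
    bs <- gen_brain_sample(config$sim, sample_id = sprintf("SYN_BR%d", i),
                           seed = config$seed + 30L + i)
    amp <- bs$amplicon[!bs$amplicon$is_negative_control, ]
    nc <- bs$amplicon[bs$amplicon$is_negative_control, ]
    av <- amplicon_vaf(amp$alt_reads, amp$ref_reads,
                       negative_control = list(alt_reads = nc$alt_reads,
                                               ref_reads = nc$ref_reads))
    comp <- bs$composition
    non_mg <- comp$monocyte + comp$DC + comp$T_cell + comp$B_cell
    est <- estimate_mutant_mg(av$vaf, comp$total, comp$MG, non_mg)
    ci <- simulate_mutant_mg_ci(av$vaf, comp$MG / comp$total, non_mg,
                                total = comp$total,
                                n_nuclei = comp$total,
                                n_sims = config$n_sims_ci,
                                seed = config$seed + 40L + i)
    rows[[i]] <- data.frame(sample = comp$sample_id, region = amp$region,
                            vaf = av$vaf, detected = av$detected,
                            pct_mutant_mg = 100 * est$prop_mut_mg_clamped,
                            ci_low = 100 * ci$ci_low,
                            ci_high = 100 * min(1, ci$ci_high),
                            true_pct = 100 * bs$truth$mutant_mg_frac,
                            stringsAsFactors = FALSE)
  }
  f <- file.path(config$out_dir, "chimerism.tsv")
  write_tsv(do.call(rbind, rows), f)
  f
}
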