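# CHIP carrier classification: VAF computation, whitelist matching,
# per-subject carrier status, and cross-depth VAF cutoff harmonization.

#' Compute variant allele fraction (VAF) from read counts
#'
#' VAF = alt / (alt + ref). Sites with total depth below `min_depth` carry
#' too much binomial noise for a usable clone-size estimate and are returned
#' as `NA` with a warning.
#'
#' @param alt_reads Integer vector of alternate-allele read counts.
#' @param ref_reads Integer vector of reference-allele read counts.
#' @param min_depth Minimum total depth required to emit a VAF (default 20).
#' @return Numeric vector of VAFs in `[0, 1]`; `NA` where depth is
#'   insufficient.
#' @examples
#' compute_vaf(28, 72)        # 0.28
#' compute_vaf(7, 193)        # 0.035
#' @export
compute_vaf <- function(alt_reads, ref_reads, min_depth = 20) {
  stopifnot(length(alt_reads) == length(ref_reads))
  if (any(alt_reads < 0, na.rm = TRUE) || any(ref_reads < 0, na.rm = TRUE)) {
    stop("read counts must be non-negative")
  }
  depth <- alt_reads + ref_reads
  vaf <- ifelse(depth > 0, alt_reads / depth, NA_real_)
  low <- !is.na(depth) & depth < min_depth
  if (any(low)) {
    warning(sprintf("insufficient depth (< %d) at %d site(s); VAF not emitted",
                    min_depth, sum(low)))
    vaf[low] <- NA_real_
  }
  vaf
}

#' Construct a CHIP whitelist
#'
#' A whitelist entry names a driver gene and the rule under which a variant
#' in that gene counts as CHIP:
#' * `any_truncating` — any nonsense/frameshift/splice (truncating) variant;
#' * `listed_positions` — only variants at the listed genomic positions;
#' * `listed_protein_changes` — only the listed protein changes.
#'
#' @param gene Character vector of gene symbols (must be unique).
#' @param rule One of `"any_truncating"`, `"listed_positions"`,
#'   `"listed_protein_changes"` per gene.
#' @param detail List (or comma-separated character) of positions/protein
#'   changes per gene; may be empty only for `any_truncating`.
#' @return A `data.frame` of class `chip_whitelist`.
#' @export
chip_whitelist <- function(gene, rule, detail = vector("list", length(gene))) {
  rule <- match.arg(rule,
                    c("any_truncating", "listed_positions", "listed_protein_changes"),
                    several.ok = TRUE)
  rule <- rep_len(rule, length(gene))
  if (anyDuplicated(gene)) stop("whitelist gene names must be unique")
  if (is.character(detail)) detail <- strsplit(detail, ",[ ]*")
  detail <- lapply(detail, function(d) d[nzchar(d)])
  empty <- vapply(detail, length, 1L) == 0L & rule != "any_truncating"
  if (any(empty)) {
    stop("whitelist rule(s) other than any_truncating need non-empty detail: ",
         paste(gene[empty], collapse = ", "))
  }
  out <- data.frame(gene = gene, rule = rule, stringsAsFactors = FALSE)
  out$detail <- detail
  class(out) <- c("chip_whitelist", "data.frame")
  out
}

#' Read a CHIP whitelist from a TSV file
#'
#' Expected columns: `gene`, `rule`, `detail` (comma-separated list; may be
#' empty for `any_truncating`).
#'
#' @param path Path to a tab-separated whitelist file.
#' @return A [chip_whitelist()] object.
#' @export
read_whitelist <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("gene", "rule", "detail")
  if (!all(need %in% names(df))) {
    stop("whitelist file must have columns: ", paste(need, collapse = ", "))
  }
  df$detail[is.na(df$detail) | df$detail == "."] <- ""
  chip_whitelist(df$gene, df$rule, df$detail)
}

# Truncating = nonsense (stop gained, "*" / "Ter" / trailing X), frameshift
# ("fs"), or annotated splice change. Missense p.A123B is not truncating.
is_truncating <- function(protein_change) {
  pc <- ifelse(is.na(protein_change), "", protein_change)
  grepl("\\*", pc) | grepl("Ter", pc, fixed = TRUE) |
    grepl("fs", pc, ignore.case = TRUE) |
    grepl("splice", pc, ignore.case = TRUE) |
    grepl("X$", pc)
}

#' Classify variant calls as CHIP against a whitelist
#'
#' A call is CHIP iff its gene appears in the whitelist and the call
#' satisfies that gene's rule. All calls are retained; non-matching calls get
#' `is_chip = FALSE`. Calls with a missing gene are classified non-CHIP with
#' a warning.
#'
#' @param calls A `data.frame` of variant calls with at least columns
#'   `sample_id`, `chrom`, `pos`, `ref`, `alt`, `gene`, and optionally
#'   `protein_change`, `ref_reads`, `alt_reads`.
#' @param whitelist A [chip_whitelist()].
#' @return `calls` with an added logical column `is_chip`.
#' @export
classify_chip_variants <- function(calls, whitelist) {
  stopifnot(inherits(whitelist, "chip_whitelist"))
  if (nrow(calls) == 0) {
    calls$is_chip <- logical(0)
    return(calls)
  }
  if (is.null(calls$protein_change)) calls$protein_change <- NA_character_
  missing_gene <- is.na(calls$gene) | calls$gene == ""
  if (any(missing_gene)) {
    warning(sprintf("%d call(s) missing gene annotation; classified non-CHIP",
                    sum(missing_gene)))
  }
  idx <- match(calls$gene, whitelist$gene)
  is_chip <- logical(nrow(calls))
  hit <- !is.na(idx) & !missing_gene
  for (i in which(hit)) {
    rule <- whitelist$rule[idx[i]]
    detail <- whitelist$detail[[idx[i]]]
    is_chip[i] <- switch(
      rule,
      any_truncating = is_truncating(calls$protein_change[i]),
      listed_positions = as.character(calls$pos[i]) %in% detail,
      listed_protein_changes = !is.na(calls$protein_change[i]) &&
        calls$protein_change[i] %in% detail
    )
  }
  calls$is_chip <- is_chip
  calls
}

#' Assign per-subject CHIP carrier status
#'
#' Groups classified calls by sample, takes the maximum VAF over CHIP
#' variants, and assigns the three-level clone-size category used throughout
#' the association analyses: `none` (no CHIP), `low` (VAF <= cutoff), `high`
#' (VAF > cutoff; the inequality is strict, so a VAF exactly at the cutoff is
#' `low`).
#'
#' @param calls A classified call table (see [classify_chip_variants()]) with
#'   `sample_id`, `gene`, `ref_reads`, `alt_reads`, `is_chip`.
#' @param cutoff VAF cutoff in (0, 0.5] separating small from large clones
#'   (default 0.08, the shipped cross-depth harmonization value).
#' @param min_depth Minimum depth for VAF computation (default 20).
#' @param samples Optional character vector of sample ids to report (so
#'   subjects with no calls at all appear as non-carriers).
#' @return A `data.frame` with one row per sample: `sample_id`, `is_carrier`,
#'   `max_vaf`, `driver_genes` (comma-separated), `vaf_category`
#'   (factor none/low/high). VAFs above 0.5 (possible LOH/CNV) are retained
#'   but flagged via the logical column `vaf_gt_half`.
#' @export
assign_carrier_status <- function(calls, cutoff = 0.08, min_depth = 20,
                                  samples = NULL) {
  stopifnot(cutoff > 0, cutoff <= 0.5)
  if (is.null(calls$is_chip)) stop("calls must be classified first (is_chip column)")
  if (is.null(samples)) samples <- unique(calls$sample_id)
  calls$vaf <- compute_vaf(calls$alt_reads, calls$ref_reads, min_depth)
  chip <- calls[calls$is_chip & !is.na(calls$vaf) & calls$vaf > 0, , drop = FALSE]
  out <- data.frame(sample_id = samples,
                    is_carrier = FALSE,
                    max_vaf = 0,
                    driver_genes = "",
                    stringsAsFactors = FALSE)
  if (nrow(chip) > 0) {
    split_chip <- split(chip, chip$sample_id)
    for (sid in names(split_chip)) {
      j <- match(sid, out$sample_id)
      if (is.na(j)) next
      g <- split_chip[[sid]]
      out$is_carrier[j] <- TRUE
      out$max_vaf[j] <- max(g$vaf)
      out$driver_genes[j] <- paste(sort(unique(g$gene)), collapse = ",")
    }
  }
  out$vaf_category <- factor(
    ifelse(!out$is_carrier, "none", ifelse(out$max_vaf > cutoff, "high", "low")),
    levels = c("none", "low", "high")
  )
  out$vaf_gt_half <- out$max_vaf > 0.5
  if (any(out$vaf_gt_half)) {
    warning(sprintf("%d sample(s) with max VAF > 0.5 (possible LOH/CNV); retained, flagged",
                    sum(out$vaf_gt_half)))
  }
  out
}

#' Harmonize a VAF cutoff across sequencing depths
#'
#' Deeper sequencing detects smaller clones, inflating carrier prevalence and
#' shifting the VAF distribution. To compare cohorts, the deeper cohort's
#' carrier definition is restricted to VAF > c, with c chosen so the
#' truncated deeper distribution is as close as possible to the reference
#' (shallower) distribution. Closeness is the two-sample Kolmogorov-Smirnov
#' distance; ties are broken toward the smaller cutoff.
#'
#' @param vafs_reference Numeric vector of VAFs in the reference cohort.
#' @param vafs_deeper Numeric vector of VAFs in the deeper-sequenced cohort.
#' @param grid Candidate cutoffs, ascending (default `seq(0.02, 0.20, 0.005)`).
#' @return A list with `cutoff` (chosen value), `ks_distance` (at the chosen
#'   cutoff), and `grid` (a `data.frame` of all candidate cutoffs and their
#'   KS distances; excluded cutoffs have `NA`).
#' @export
harmonize_vaf_cutoff <- function(vafs_reference, vafs_deeper,
                                 grid = seq(0.02, 0.20, by = 0.005)) {
  stopifnot(length(vafs_reference) > 0, length(vafs_deeper) > 0)
  if (is.unsorted(grid)) stop("grid must be sorted ascending")
  dist <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    kept <- vafs_deeper[vafs_deeper > grid[i]]
    if (length(kept) == 0) {
      warning(sprintf("cutoff %.3f leaves no VAFs in the deeper set; excluded",
                      grid[i]))
      next
    }
    dist[i] <- suppressWarnings(
      stats::ks.test(vafs_reference, kept)$statistic
    )
  }
  if (all(is.na(dist))) stop("no candidate cutoff leaves a non-empty deeper set")
  best <- which(dist <= min(dist, na.rm = TRUE) + 1e-12)[1]
  list(cutoff = grid[best],
       ks_distance = dist[best],
       grid = data.frame(cutoff = grid, ks_distance = dist))
}
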