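# Readers and writers. TSV dialect: tab-separated, header row, UTF-8, '.'
# for missing values.

variant_call_columns <- c("sample_id", "chrom", "pos", "ref", "alt", "gene",
                          "protein_change", "ref_reads", "alt_reads")

#' Read somatic variant calls from VCF or TSV
#'
#' VCF v4.2 input must carry per-sample allelic depths in an `AD` FORMAT
#' field (`ref,alt`); gene and protein-change annotations are taken from
#' `GENE` and `PCHANGE` INFO keys when present. TSV input must have the
#' documented columns (`sample_id, chrom, pos, ref, alt, gene,
#' protein_change, ref_reads, alt_reads`). Positions are 1-based in both.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"vcf"`, or `"tsv"`.
#' @return A `data.frame` of variant calls, one row per sample x variant
#'   with non-missing depths.
#' @export
read_variant_calls <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "tsv") {
    if (file.size(path) == 0) {
      warning("empty variant file: ", path)
      return(empty_calls())
    }
    df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = ".")
    missing_cols <- setdiff(variant_call_columns, names(df))
    if (length(missing_cols)) {
      stop("variant TSV missing column(s): ", paste(missing_cols, collapse = ", "))
    }
    if (nrow(df) == 0) {
      warning("no variant records in ", path)
      return(empty_calls())
    }
    bad <- which(is.na(df$pos) | df$pos < 1 | is.na(df$ref_reads) |
                   is.na(df$alt_reads) | df$ref == df$alt)
    if (length(bad)) {
      stop("malformed variant row(s) at line(s): ",
           paste(bad + 1L, collapse = ", "))
    }
    df$pos <- as.integer(df$pos)
    return(df[variant_call_columns])
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0) {
    warning("no variant records in ", path)
    return(empty_calls())
  }
  fmt <- unique(v@gt[, "FORMAT"])
  if (!any(grepl("(^|:)AD(:|$)", fmt))) {
    stop("VCF lacks the AD FORMAT field; cannot extract allelic depths")
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  info_field <- function(key) {
    val <- vcfR::extract.info(v, element = key)
    if (is.null(val)) rep(NA_character_, nrow(v@fix)) else val
  }
  gene <- info_field("GENE")
  pchange <- info_field("PCHANGE")
  rows <- list()
  for (s in colnames(ad)) {
    present <- !is.na(ad[, s])
    if (!any(present)) next
    parts <- strsplit(ad[present, s], ",")
    rr <- as.integer(vapply(parts, `[`, "", 1L))
    aa <- as.integer(vapply(parts, `[`, "", 2L))
    rows[[s]] <- data.frame(
      sample_id = s,
      chrom = v@fix[present, "CHROM"],
      pos = as.integer(v@fix[present, "POS"]),
      ref = v@fix[present, "REF"],
      alt = v@fix[present, "ALT"],
      gene = gene[present],
      protein_change = pchange[present],
      ref_reads = rr, alt_reads = aa,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    warning("no per-sample AD entries in ", path)
    return(empty_calls())
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_calls <- function() {
  df <- data.frame(sample_id = character(), chrom = character(),
                   pos = integer(), ref = character(), alt = character(),
                   gene = character(), protein_change = character(),
                   ref_reads = integer(), alt_reads = integer(),
                   stringsAsFactors = FALSE)
  df
}

#' Read GWAS summary statistics
#'
#' Requires columns `variant_id`, `beta`, `se`; optional columns (effect
#' alleles, flip indicator) are passed through. SEs must be positive and
#' `variant_id` unique.
#'
#' @param path Tab-separated summary-statistics file.
#' @return A `data.frame`.
#' @export
read_summary_stats <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = ".")
  need <- c("variant_id", "beta", "se")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("summary-stat file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad_se <- which(!is.finite(df$se) | df$se <= 0)
  if (length(bad_se)) {
    stop("non-positive/missing SE at row(s): ", paste(bad_se, collapse = ", "))
  }
  dup <- df$variant_id[duplicated(df$variant_id)]
  if (length(dup)) {
    stop("duplicate variant_id(s): ", paste(unique(dup), collapse = ", "))
  }
  df
}

#' Write a table in the pipeline's TSV dialect
#'
#' Tab-separated, header row, no quoting, `.` for missing.
#'
#' @param x A `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  is_list_col <- vapply(x, is.list, TRUE)
  x[is_list_col] <- lapply(x[is_list_col], function(col) {
    vapply(col, paste, "", collapse = ",")
  })
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}
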