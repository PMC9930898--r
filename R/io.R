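# Plain-text interchange: summary-statistic TSVs, scoring files in the
# PGS-catalog layout, phenotype tables, and dosage VCFs.

#' Write / read a summary-statistic table
#'
#' Tab-separated with columns `snp_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `beta`, `se`, `p`, `n`, `maf`, `source`.
#'
#' @param stats A `summary_stats` data frame.
#' @param path File path.
#' @return `read_summary_stats` returns a `summary_stats` data frame.
#' @export
write_summary_stats <- function(stats, path) {
  cols <- intersect(
    c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
      "beta", "se", "p", "n", "maf", "source", "flag"),
    names(stats)
  )
  utils::write.table(as.data.frame(stats)[cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_stats
#' @export
read_summary_stats <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character"))
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Write / read a scoring file
#'
#' PGS-catalog-like layout: `#` header metadata lines (`#method=`,
#' `#p_threshold=`) followed by a tab-separated table `rsID`,
#' `effect_allele`, `other_allele`, `effect_weight`.
#'
#' @param score A [score_file()].
#' @param path File path.
#' @return `read_score_file` returns a [score_file()].
#' @export
write_score_file <- function(score, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#method=%s", attr(score, "method") %||% "unknown"), con)
  pt <- attr(score, "p_threshold")
  if (!is.null(pt) && !is.na(pt)) writeLines(sprintf("#p_threshold=%g", pt), con)
  df <- data.frame(
    rsID = score$snp_id, effect_allele = score$effect_allele,
    other_allele = score$other_allele, effect_weight = score$weight
  )
  suppressWarnings(
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  )
  invisible(path)
}

#' @rdname write_score_file
#' @export
read_score_file <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  get_meta <- function(key, default) {
    hit <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (length(hit)) sub(paste0("^#", key, "="), "", hit[1]) else default
  }
  score_file(df$rsID, df$effect_allele, df$other_allele, df$effect_weight,
             method = get_meta("method", "unknown"),
             p_threshold = as.numeric(get_meta("p_threshold", NA)))
}

#' Write / read a phenotype and covariate table
#'
#' Tab-separated `sample_meta` table (`sample_id`, `cohort`, `status`,
#' covariates, `call_rate`).
#'
#' @param sample_meta Data frame (e.g. a panel's `sample_meta`).
#' @param path File path.
#' @return `read_phenotypes` returns the data frame.
#' @export
write_phenotypes <- function(sample_meta, path) {
  utils::write.table(sample_meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a genotype panel as a dosage VCF
#'
#' VCFv4.2 with an `INFO` key carrying the imputation INFO score and a
#' `DS` FORMAT field holding dosages (missing as `.`).  Sample metadata
#' must be written separately ([write_phenotypes()]).
#'
#' @param panel A [genotype_panel()].
#' @param path Output path (`.vcf`).
#' @return The path, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  stop_if_not_panel(panel)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation INFO score\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$sample_meta$sample_id), collapse = "\t")
  ), con)
  m <- panel$snp_meta
  ds <- t(panel$dosages)
  txt <- matrix(sprintf("%.3f", ds), nrow(ds), ncol(ds))
  txt[is.na(ds)] <- "."
  lines <- vapply(seq_len(nrow(m)), function(j) {
    paste(c(m$chrom[j], m$pos[j], m$snp_id[j], m$other_allele[j],
            m$effect_allele[j], ".", "PASS",
            sprintf("INFO=%.4f", m$info[j]), "DS", txt[j, ]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read a dosage VCF into a genotype panel
#'
#' Parses a VCF written by [write_panel_vcf()] (or any VCF with a `DS`
#' FORMAT field and an `INFO=` score) via the vcfR package.  The ALT
#' allele is taken as the effect allele; MAF is recomputed from the
#' dosages.
#'
#' @param path VCF path.
#' @param sample_meta Optional sample metadata to attach (defaults to a
#'   minimal table of sample ids).
#' @return A [genotype_panel()].
#' @export
read_panel_vcf <- function(path, sample_meta = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCFs requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info <- suppressWarnings(as.numeric(sub(".*INFO=([0-9.eE+-]+).*", "\\1",
                                          vcfR::getINFO(v))))
  g <- t(ds)
  maf <- pmin(colMeans(g, na.rm = TRUE) / 2, 1 - colMeans(g, na.rm = TRUE) / 2)
  snp_meta <- data.frame(
    snp_id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
    effect_allele = fix$ALT, other_allele = fix$REF,
    maf = maf, info = ifelse(is.na(info), 1, info),
    stringsAsFactors = FALSE
  )
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(sample_id = rownames(g), stringsAsFactors = FALSE)
  }
  genotype_panel(g, snp_meta, sample_meta)
}
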