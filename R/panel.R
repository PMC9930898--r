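#' Genotype panel container
#'
#' A `genotype_panel` bundles a samples-by-SNPs dosage matrix with per-SNP
#' and per-sample metadata.  Dosages count copies of the effect (minor)
#' allele on a continuous `[0, 2]` scale so that hard-called and imputed
#' data share one representation; missing genotypes are `NA`.
#'
#' @param dosages Numeric matrix, samples in rows and SNPs in columns,
#'   values in `[0, 2]` or `NA`.
#' @param snp_meta Data frame with one row per SNP: `snp_id`, `chrom`,
#'   `pos` (1-based), `effect_allele`, `other_allele`, `maf`, `info`.
#'   Extra columns (e.g. `is_pseudo`) are preserved.
#' @param sample_meta Data frame with one row per sample; must contain
#'   `sample_id`.  Conventional columns: `cohort`, `status` (0/1 or a
#'   continuous phenotype), `age`, `sex`, `site`, `call_rate`.
#'
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosages, snp_meta, sample_meta) {
  dosages <- as.matrix(dosages)
  stopifnot(is.data.frame(snp_meta), is.data.frame(sample_meta))
  if (nrow(snp_meta) != ncol(dosages)) {
    stop("snp_meta rows must match dosage columns", call. = FALSE)
  }
  if (nrow(sample_meta) != nrow(dosages)) {
    stop("sample_meta rows must match dosage rows", call. = FALSE)
  }
  need <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele", "maf", "info")
  miss <- setdiff(need, names(snp_meta))
  if (length(miss)) stop("snp_meta lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (!"sample_id" %in% names(sample_meta)) stop("sample_meta lacks sample_id", call. = FALSE)
  if (anyDuplicated(snp_meta$snp_id)) stop("duplicate snp ids", call. = FALSE)
  rng <- range(dosages, na.rm = TRUE)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 2) {
    stop("dosages must lie in [0, 2] (or be NA)", call. = FALSE)
  }
  # positions must be strictly increasing within a chromosome
  for (ch in unique(snp_meta$chrom)) {
    p <- snp_meta$pos[snp_meta$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("positions not strictly increasing within chromosome ", ch, call. = FALSE)
    }
  }
  colnames(dosages) <- snp_meta$snp_id
  rownames(dosages) <- sample_meta$sample_id
  structure(
    list(dosages = dosages, snp_meta = snp_meta, sample_meta = sample_meta),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "<genotype_panel> %d samples x %d SNPs\n",
    nrow(x$dosages), ncol(x$dosages)
  ))
  if ("cohort" %in% names(x$sample_meta)) {
    tb <- table(x$sample_meta$cohort)
    cat("  cohorts:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  if ("status" %in% names(x$sample_meta) && !all(is.na(x$sample_meta$status))) {
    st <- x$sample_meta$status
    if (all(st %in% c(0, 1, NA))) {
      cat(sprintf("  cases: %d (%.1f%%)\n", sum(st == 1, na.rm = TRUE),
                  100 * mean(st == 1, na.rm = TRUE)))
    }
  }
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosages)

#' Subset a genotype panel
#'
#' @param panel A [genotype_panel()].
#' @param snps SNP ids, or a logical/integer index over SNP columns.
#' @param samples Sample ids, or a logical/integer index over rows.
#' @return The subsetted panel.
#' @export
subset_panel <- function(panel, snps = NULL, samples = NULL) {
  stop_if_not_panel(panel)
  if (!is.null(snps)) {
    j <- if (is.character(snps)) match(snps, panel$snp_meta$snp_id) else seq_len(ncol(panel$dosages))[snps]
    if (anyNA(j)) stop("unknown snp ids in subset", call. = FALSE)
    panel$dosages <- panel$dosages[, j, drop = FALSE]
    panel$snp_meta <- panel$snp_meta[j, , drop = FALSE]
    rownames(panel$snp_meta) <- NULL
  }
  if (!is.null(samples)) {
    i <- if (is.character(samples)) match(samples, panel$sample_meta$sample_id) else seq_len(nrow(panel$dosages))[samples]
    if (anyNA(i)) stop("unknown sample ids in subset", call. = FALSE)
    panel$dosages <- panel$dosages[i, , drop = FALSE]
    panel$sample_meta <- panel$sample_meta[i, , drop = FALSE]
    rownames(panel$sample_meta) <- NULL
  }
  panel
}

#' Empirical minor allele frequency per SNP
#'
#' Recomputed from the dosage matrix (not metadata): half the mean dosage,
#' folded onto the minor allele so the result lies in `[0, 0.5]`.
#'
#' @param panel A [genotype_panel()].
#' @param folded Fold frequencies above 0.5 onto the minor allele
#'   (default `TRUE`).
#' @return Named numeric vector over SNPs.
#' @export
empirical_maf <- function(panel, folded = TRUE) {
  stop_if_not_panel(panel)
  f <- colMeans(panel$dosages, na.rm = TRUE) / 2
  if (folded) f <- pmin(f, 1 - f)
  f
}

#' Per-SNP and per-sample call rates
#'
#' @param panel A [genotype_panel()].
#' @return List with `snp` and `sample` call-rate vectors.
#' @export
call_rates <- function(panel) {
  stop_if_not_panel(panel)
  list(
    snp = colMeans(!is.na(panel$dosages)),
    sample = rowMeans(!is.na(panel$dosages))
  )
}

# Hard-call dosages to 0/1/2 for count-based procedures (HWE, kinship).
hard_calls <- function(panel) {
  g <- round(panel$dosages)
  g[g < 0] <- 0
  g[g > 2] <- 2
  g
}

# Genotype class counts (n_AA, n_Aa, n_aa) for one hard-called vector,
# where 'a' is the effect (dosage-counted) allele.
genotype_counts <- function(g) {
  g <- g[!is.na(g)]
  c(n_AA = sum(g == 0), n_Aa = sum(g == 1), n_aa = sum(g == 2))
}
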