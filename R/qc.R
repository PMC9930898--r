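#' Quality-control thresholds
#'
#' Container for every tunable in the genotype QC stage.  Defaults follow
#' standard GWAS practice: MAF > 1%, SNP call rate > 95%, imputation
#' quality product `2*MAF*(1-MAF)*INFO >= 0.05`, Hardy-Weinberg exact
#' p-value cutoffs of `1e-6` in controls and a stricter `1e-11` in cases
#' (so disease-associated departures in cases are not discarded),
#' first-degree kinship cutoff 0.177, and sliding-window LD pruning with
#' window 100 SNPs, step 5, `r^2 < 0.2`.
#'
#' @param maf_min Minimum minor-allele frequency (strict `>`).
#' @param snp_callrate_min Minimum SNP call rate (strict `>`).
#' @param info_product_min Imputation-quality product floor (non-strict `>=`).
#' @param hwe_p_controls,hwe_p_cases HWE p-value cutoffs per stratum;
#'   `hwe_p_cases` must be at most `hwe_p_controls`.
#' @param kinship_max Kinship coefficient above which a pair is treated
#'   as first-degree-or-closer.
#' @param prune_window,prune_step,prune_r2 LD-pruning window size (SNPs),
#'   step, and squared-correlation cutoff.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.01, snp_callrate_min = 0.95,
                          info_product_min = 0.05,
                          hwe_p_controls = 1e-6, hwe_p_cases = 1e-11,
                          kinship_max = 0.177,
                          prune_window = 100L, prune_step = 5L,
                          prune_r2 = 0.2) {
  stopifnot(
    maf_min > 0, maf_min < 0.5,
    snp_callrate_min > 0, snp_callrate_min <= 1,
    info_product_min > 0,
    hwe_p_controls > 0, hwe_p_controls < 1,
    hwe_p_cases > 0, hwe_p_cases < 1,
    hwe_p_cases <= hwe_p_controls,
    kinship_max > 0,
    prune_window >= 1, prune_step >= 1,
    prune_r2 > 0, prune_r2 < 1
  )
  structure(
    list(
      maf_min = maf_min, snp_callrate_min = snp_callrate_min,
      info_product_min = info_product_min,
      hwe_p_controls = hwe_p_controls, hwe_p_cases = hwe_p_cases,
      kinship_max = kinship_max,
      prune_window = as.integer(prune_window),
      prune_step = as.integer(prune_step),
      prune_r2 = prune_r2
    ),
    class = "qc_thresholds"
  )
}

drop_log_row <- function(snp_id, stage, reason, statistic) {
  data.frame(
    snp_id = as.character(snp_id),
    stage = rep_len(as.character(stage), length(snp_id)),
    reason = rep_len(as.character(reason), length(snp_id)),
    statistic = as.numeric(statistic), stringsAsFactors = FALSE
  )
}

#' Filter SNPs on minor-allele frequency and call rate
#'
#' Retains SNPs whose empirical MAF (recomputed from dosages, folded onto
#' the minor allele) exceeds `maf_min` and whose call rate exceeds
#' `snp_callrate_min`; both comparisons are strict.
#'
#' @param panel A [genotype_panel()].
#' @param thresholds A [qc_thresholds()].
#' @return The filtered panel, with attribute `"drop_log"`: a data frame
#'   (`snp_id`, `stage`, `reason`, `statistic`) of removed SNPs.
#' @export
filter_maf_callrate <- function(panel, thresholds = qc_thresholds()) {
  stop_if_not_panel(panel)
  if (ncol(panel$dosages) == 0) stop("empty panel", call. = FALSE)
  maf <- empirical_maf(panel)
  cr <- call_rates(panel)$snp
  bad_maf <- maf <= thresholds$maf_min | is.na(maf)
  bad_cr <- cr <= thresholds$snp_callrate_min
  log <- rbind(
    drop_log_row(panel$snp_meta$snp_id[bad_maf], "maf_callrate", "maf", maf[bad_maf]),
    drop_log_row(panel$snp_meta$snp_id[bad_cr & !bad_maf], "maf_callrate",
                 "call_rate", cr[bad_cr & !bad_maf])
  )
  out <- subset_panel(panel, snps = !(bad_maf | bad_cr))
  attr(out, "drop_log") <- log
  out
}

#' Imputation-quality filter
#'
#' Retains SNP `j` iff `2 * MAF_j * (1 - MAF_j) * INFO_j >=
#' info_product_min` (non-strict), so a rare SNP must clear a higher
#' INFO bar than a common one.
#'
#' @param snp_meta Data frame with `snp_id`, `maf` in `(0, 0.5]` and
#'   `info` in `(0, 1]` columns (e.g. a panel's `snp_meta`).
#' @param thresholds A [qc_thresholds()].
#' @return Character vector of retained `snp_id`s, with attribute
#'   `"product"`: the per-SNP quality product (named, all SNPs).
#' @export
imputation_quality_filter <- function(snp_meta, thresholds = qc_thresholds()) {
  stopifnot(all(c("snp_id", "maf", "info") %in% names(snp_meta)))
  if (any(snp_meta$maf <= 0 | snp_meta$maf > 0.5)) {
    stop("MAF out of (0, 0.5]", call. = FALSE)
  }
  if (any(snp_meta$info <= 0 | snp_meta$info > 1)) {
    stop("INFO out of (0, 1]", call. = FALSE)
  }
  prod <- 2 * snp_meta$maf * (1 - snp_meta$maf) * snp_meta$info
  names(prod) <- snp_meta$snp_id
  keep <- snp_meta$snp_id[prod >= thresholds$info_product_min]
  attr(keep, "product") <- prod
  keep
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test from genotype class counts.  Conditional on the
#' observed allele counts, the number of heterozygotes has a known exact
#' distribution under HWE; the p-value sums the probabilities of all
#' heterozygote counts no more probable than the observed one.  This
#' behaves correctly at the extreme significance levels used for
#' stratified filtering, where a chi-square approximation would not.
#'
#' @param counts Integer vector `(n_AA, n_Aa, n_aa)` of genotype class
#'   counts.
#' @return The exact p-value.
#' @export
hwe_exact_test <- function(counts) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  counts <- as.integer(round(counts))
  n <- sum(counts)
  if (n == 0) stop("all-zero genotype counts", call. = FALSE)
  n_ab <- counts[2]
  n_a <- 2L * counts[3] + counts[2] # minor-allele count (by convention)
  n_b <- 2L * n - n_a
  if (n_a > n_b) { tmp <- n_a; n_a <- n_b; n_b <- tmp; }
  # possible heterozygote counts share the parity of the rare allele count
  h <- seq(n_a %% 2L, n_a, by = 2L)
  # log P(n_het = h | n, n_a) under HWE, via the multinomial/allele-count ratio
  logp <- h * log(2) +
    lgamma(n + 1) - lgamma((n_a - h) / 2 + 1) - lgamma(h + 1) -
    lgamma((n_b - h) / 2 + 1) +
    lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- match(n_ab, h)
  if (is.na(obs)) stop("heterozygote count inconsistent with allele counts", call. = FALSE)
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Stratified Hardy-Weinberg filter
#'
#' Applies [hwe_exact_test()] separately within controls and within
#' cases (on hard-called genotypes) and drops a SNP when its control
#' p-value falls below `hwe_p_controls` or its case p-value below the
#' stricter `hwe_p_cases`.
#'
#' @param panel A [genotype_panel()] whose `sample_meta$status` is 0/1.
#' @param thresholds A [qc_thresholds()].
#' @return Filtered panel with a `"drop_log"` attribute.
#' @export
stratified_hwe_filter <- function(panel, thresholds = qc_thresholds()) {
  stop_if_not_panel(panel)
  st <- panel$sample_meta$status
  if (!all(st %in% c(0, 1)) || length(unique(st)) < 2) {
    stop("need both cases and controls with 0/1 status", call. = FALSE)
  }
  g <- hard_calls(panel)
  p_of <- function(rows) {
    apply(g[rows, , drop = FALSE], 2, function(col) {
      cts <- genotype_counts(col)
      if (sum(cts) == 0) return(NA_real_)
      hwe_exact_test(cts)
    })
  }
  p_ctrl <- p_of(which(st == 0))
  p_case <- p_of(which(st == 1))
  bad_ctrl <- !is.na(p_ctrl) & p_ctrl < thresholds$hwe_p_controls
  bad_case <- !is.na(p_case) & p_case < thresholds$hwe_p_cases
  log <- rbind(
    drop_log_row(panel$snp_meta$snp_id[bad_ctrl], "hwe", "hwe_controls", p_ctrl[bad_ctrl]),
    drop_log_row(panel$snp_meta$snp_id[bad_case & !bad_ctrl], "hwe",
                 "hwe_cases", p_case[bad_case & !bad_ctrl])
  )
  out <- subset_panel(panel, snps = !(bad_ctrl | bad_case))
  attr(out, "drop_log") <- log
  out
}

#' Robust pairwise kinship matrix
#'
#' KING-robust style estimator from hard-called genotypes: for a pair
#' `(i, j)`,
#' `phi = (N_AaAa - 2 * N_AAaa) / (N_Aa(i) + N_Aa(j))`,
#' where `N_AaAa` counts SNPs at which both are heterozygous, `N_AAaa`
#' counts opposite homozygotes, and `N_Aa(.)` counts heterozygous SNPs
#' per individual.  Duplicates give ~0.5, parent-offspring ~0.25,
#' unrelated ~0, without requiring allele-frequency estimates.
#'
#' @param panel A [genotype_panel()] with at least 2 samples.
#' @return A symmetric matrix of class `kinship_matrix` with diagonal
#'   0.5 and sample ids as dimnames.
#' @export
kinship_matrix <- function(panel) {
  stop_if_not_panel(panel)
  n <- nrow(panel$dosages)
  if (n < 2) stop("need at least two samples", call. = FALSE)
  if (ncol(panel$dosages) < 50) {
    warning("fewer than 50 SNPs; kinship estimates will be unstable")
  }
  g <- hard_calls(panel)
  obs <- !is.na(g)
  g0 <- g
  g0[!obs] <- 0
  het <- (g == 1) & obs
  homA <- (g == 0) & obs
  homa <- (g == 2) & obs
  # pairwise counts via crossproducts over observed genotypes
  n_hethet <- tcrossprod(het * 1)
  n_opp <- tcrossprod(homA * 1, homa * 1)
  n_opp <- n_opp + t(n_opp)
  # per-individual het counts restricted to SNPs observed in both members
  het_i <- tcrossprod(het * 1, obs * 1) # het in i among SNPs observed in j
  denom <- het_i + t(het_i)
  phi <- (n_hethet - 2 * n_opp) / denom
  phi[denom == 0] <- 0
  diag(phi) <- 0.5
  dimnames(phi) <- list(panel$sample_meta$sample_id, panel$sample_meta$sample_id)
  class(phi) <- c("kinship_matrix", class(phi))
  phi
}

#' Remove related individuals
#'
#' Iterates over pairs with kinship above `kinship_max`, removing from
#' each the member with the lower sample call rate (ties broken by
#' removing the later sample id), until no pair exceeds the threshold.
#'
#' @param panel A [genotype_panel()].
#' @param kinship A [kinship_matrix()] over the panel's samples.
#' @param thresholds A [qc_thresholds()].
#' @return Filtered panel with attribute `"removed"`: the dropped ids,
#'   in removal order.
#' @export
remove_relatives <- function(panel, kinship, thresholds = qc_thresholds()) {
  stop_if_not_panel(panel)
  ids <- panel$sample_meta$sample_id
  stopifnot(identical(rownames(kinship), ids))
  cr <- panel$sample_meta$call_rate %||% call_rates(panel)$sample
  names(cr) <- ids
  phi <- unclass(kinship)
  diag(phi) <- 0
  alive <- ids
  removed <- character(0)
  repeat {
    sub <- phi[alive, alive, drop = FALSE]
    idx <- which(sub > thresholds$kinship_max, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    if (nrow(idx) == 0) break
    # process the worst pair first for determinism
    worst <- idx[which.max(sub[idx]), ]
    a <- alive[worst[1]]; b <- alive[worst[2]]
    drop_id <- if (cr[a] < cr[b]) a
      else if (cr[b] < cr[a]) b
      else max(a, b) # tie: remove the later sample id
    removed <- c(removed, drop_id)
    alive <- setdiff(alive, drop_id)
  }
  out <- subset_panel(panel, samples = alive)
  attr(out, "removed") <- removed
  out
}

# Pairwise squared correlation between dosage columns (mean-imputed).
dosage_r2 <- function(g) {
  if (anyNA(g)) {
    mu <- colMeans(g, na.rm = TRUE)
    na <- which(is.na(g), arr.ind = TRUE)
    g[na] <- mu[na[, 2]]
  }
  suppressWarnings(cor(g))^2
}

#' Sliding-window LD pruning
#'
#' PLINK-style `indep-pairwise` pruning: windows of `prune_window` SNPs
#' advanced by `prune_step`, within chromosome.  Inside each window,
#' while any retained pair has squared dosage correlation at or above
#' `prune_r2`, the member of the worst offending pair with the lower
#' empirical MAF is dropped (ties: drop the later position).  The result
#' is deterministic and order-stable.
#'
#' @param panel A position-sorted [genotype_panel()].
#' @param thresholds A [qc_thresholds()].
#' @return Character vector of retained SNP ids, in panel order.
#' @export
ld_prune <- function(panel, thresholds = qc_thresholds()) {
  stop_if_not_panel(panel)
  meta <- panel$snp_meta
  for (ch in unique(meta$chrom)) {
    if (is.unsorted(meta$pos[meta$chrom == ch], strictly = TRUE)) {
      stop("SNP positions must be sorted within chromosome", call. = FALSE)
    }
  }
  maf <- empirical_maf(panel)
  keep <- rep(TRUE, ncol(panel$dosages))
  names(keep) <- meta$snp_id
  for (ch in unique(meta$chrom)) {
    cols <- which(meta$chrom == ch)
    m <- length(cols)
    starts <- seq(1L, max(1L, m), by = thresholds$prune_step)
    for (s in starts) {
      win <- cols[s:min(m, s + thresholds$prune_window - 1L)]
      win <- win[keep[win]]
      if (length(win) < 2) next
      r2 <- dosage_r2(panel$dosages[, win, drop = FALSE])
      diag(r2) <- 0
      repeat {
        live <- keep[win]
        if (sum(live) < 2) break
        sub <- r2[live, live, drop = FALSE]
        mx <- max(sub, na.rm = TRUE)
        if (is.na(mx) || mx < thresholds$prune_r2) break
        ij <- which(sub == mx, arr.ind = TRUE)[1, ]
        pair <- win[live][ij]
        # drop lower-MAF member; tie -> later position
        drop <- if (maf[pair[1]] < maf[pair[2]]) pair[1]
          else if (maf[pair[2]] < maf[pair[1]]) pair[2]
          else pair[which.max(meta$pos[pair])]
        keep[drop] <- FALSE
      }
    }
  }
  meta$snp_id[keep]
}

#' Exclude SNPs falling in predefined regions
#'
#' Drops SNPs whose position lies inside any supplied region.  Regions
#' are 1-based and inclusive at both ends (so a SNP exactly at `start`
#' or `end` is removed) — the convention used for published long-range
#' LD exclusion lists.
#'
#' @param panel A [genotype_panel()].
#' @param regions Data frame with columns `chrom`, `start`, `end`.
#' @return Filtered panel with a `"drop_log"` attribute.
#' @export
exclude_regions <- function(panel, regions) {
  stop_if_not_panel(panel)
  if (is.null(regions) || nrow(regions) == 0) {
    attr(panel, "drop_log") <- drop_log_row(character(0), character(0),
                                            character(0), numeric(0))
    return(panel)
  }
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  if (any(regions$end < regions$start)) stop("malformed region (end < start)", call. = FALSE)
  meta <- panel$snp_meta
  bad <- rep(FALSE, nrow(meta))
  for (i in seq_len(nrow(regions))) {
    bad <- bad | (meta$chrom == regions$chrom[i] &
                    meta$pos >= regions$start[i] &
                    meta$pos <= regions$end[i])
  }
  log <- drop_log_row(meta$snp_id[bad], "regions", "long_range_ld", meta$pos[bad])
  out <- subset_panel(panel, snps = !bad)
  attr(out, "drop_log") <- log
  out
}

#' Principal components of ancestry
#'
#' PCs of the column-standardized dosage matrix (each SNP centered and
#' scaled to unit variance; missing dosages imputed to the SNP mean).
#' Constant SNPs are dropped with a warning.  Signs are fixed so that
#' each component's largest-magnitude SNP loading is positive.
#'
#' @param panel A (typically LD-pruned) [genotype_panel()].
#' @param k Number of components, `< min(n_samples, n_snps)`.
#' @return `n x k` score matrix with rownames = sample ids and columns
#'   `PC1..PCk`; attribute `"loadings"` carries the SNP loadings.
#' @export
compute_pcs <- function(panel, k = 10L) {
  stop_if_not_panel(panel)
  g <- panel$dosages
  if (anyNA(g)) {
    mu <- colMeans(g, na.rm = TRUE)
    na <- which(is.na(g), arr.ind = TRUE)
    g[na] <- mu[na[, 2]]
  }
  sds <- apply(g, 2, sd)
  const <- sds == 0 | is.na(sds)
  if (any(const)) {
    warning(sum(const), " constant SNP column(s) dropped before PCA")
    g <- g[, !const, drop = FALSE]
  }
  if (k >= min(dim(g))) stop("k must be < min(n_samples, n_snps)", call. = FALSE)
  z <- scale(g)
  sv <- svd(z, nu = k, nv = k)
  # sign convention: largest-|loading| entry positive per component
  for (j in seq_len(k)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  dimnames(scores) <- list(panel$sample_meta$sample_id, paste0("PC", seq_len(k)))
  attr(scores, "loadings") <- sv$v
  scores
}
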