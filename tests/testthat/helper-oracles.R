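# Independent oracles used against the package implementations.

# Exact HWE p-value by direct enumeration: probability of each genotype
# configuration with the observed allele counts, computed from binomial
# coefficients (no shared code with hwe_exact_test, which works in log
# space over heterozygote counts).
hwe_enumeration_oracle <- function(counts) {
  n <- sum(counts)
  na_ <- 2 * counts[3] + counts[2]
  nb <- 2 * n - na_
  rare <- min(na_, nb)
  hs <- seq(rare %% 2, rare, by = 2)
  probs <- sapply(hs, function(h) {
    naa <- (min(na_, nb) - h) / 2
    nAA <- n - naa - h
    # multinomial count of genotype assignments x 2^h over allele pairings
    choose(n, naa) * choose(n - naa, h) * 2^h / choose(2 * n, min(na_, nb))
  })
  probs <- probs / sum(probs)
  obs <- probs[hs == counts[2]]
  sum(probs[probs <= obs * (1 + 1e-9)])
}

# O(n^2) pairwise AUC oracle.
auc_pairwise_oracle <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  tot <- 0
  for (s in cs) tot <- tot + sum(s > ct) + 0.5 * sum(s == ct)
  tot / (length(cs) * length(ct))
}

# Brute-force greedy clumping on the full pairwise r^2 matrix.
clump_bruteforce_oracle <- function(stats, dosages, p_threshold, clump_r2,
                                    window_kb) {
  s <- stats[!is.na(stats$p) & stats$p <= p_threshold, ]
  s <- s[order(s$p, s$chrom, s$pos), ]
  g <- dosages[, match(s$snp_id, colnames(dosages)), drop = FALSE]
  r2 <- suppressWarnings(cor(g))^2
  taken <- rep(FALSE, nrow(s))
  index <- character(0)
  for (i in seq_len(nrow(s))) {
    if (taken[i]) next
    index <- c(index, s$snp_id[i])
    taken[i] <- TRUE
    for (j in seq_len(nrow(s))) {
      if (taken[j]) next
      if (s$chrom[j] == s$chrom[i] &&
          abs(s$pos[j] - s$pos[i]) <= window_kb * 1000 &&
          !is.na(r2[i, j]) && r2[i, j] >= clump_r2) {
        taken[j] <- TRUE
      }
    }
  }
  index
}

# Soft-threshold closed form for the lasso with orthonormal columns
# (gaussian loss, no intercept): beta_j = S(x_j'y / n, lambda).
soft_threshold <- function(z, lambda) sign(z) * pmax(abs(z) - lambda, 0)

# Small deterministic panel for hand-checked fixtures.
toy_panel <- function(dosages, maf = NULL, info = NULL, chrom = "1",
                      status = NULL, cohort = "a", call_rate = NULL) {
  m <- ncol(dosages)
  n <- nrow(dosages)
  snp_meta <- data.frame(
    snp_id = paste0("snp", seq_len(m)), chrom = chrom,
    pos = seq_len(m) * 1000L,
    effect_allele = "A", other_allele = "G",
    maf = maf %||% pmin(colMeans(dosages, na.rm = TRUE) / 2,
                        1 - colMeans(dosages, na.rm = TRUE) / 2),
    info = info %||% rep(1, m),
    stringsAsFactors = FALSE
  )
  sample_meta <- data.frame(
    sample_id = paste0("s", seq_len(n)), cohort = cohort,
    status = status %||% NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(call_rate)) sample_meta$call_rate <- call_rate
  genotype_panel(dosages, snp_meta, sample_meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A standard phenotyped two-cohort panel reused across tests.
demo_panel <- function(n_snps = 150, causal = 10, seed = 42,
                       n_samples = c(a = 500, b = 400), het_sd = 0,
                       ld_rho = 0.6, effect_sd = 0.3) {
  cfg <- sim_cohort_config(
    n_samples = n_samples, n_snps = n_snps, causal_snp_count = causal,
    effect_size_sd = effect_sd, cohort_effect_heterogeneity_sd = het_sd,
    ld_rho = ld_rho, missing_rate = 0.01, seed = seed
  )
  simulate_case_control(simulate_genotypes(cfg), cfg)
}
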