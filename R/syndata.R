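#' Configuration for a multi-cohort case-control genotype simulation
#'
#' Defines the study conditions for [simulate_genotypes()] and
#' [simulate_case_control()]: per-cohort sample sizes, the LD-block
#' structure of the SNP panel, allele-frequency and imputation-quality
#' ranges, the genetic architecture of the binary phenotype, and covariate
#' effects.  Genotypes are generated by thresholding a latent Gaussian
#' with AR(`ld_rho`) correlation within blocks, so the panel is
#' Hardy-Weinberg consistent at each SNP's frequency by construction.
#'
#' @param n_samples Named (or unnamed) integer vector of per-cohort sample
#'   sizes.
#' @param n_snps Number of SNPs on the panel.
#' @param ld_block_size SNPs per LD block; correlation resets at block
#'   boundaries.
#' @param ld_rho Lag-1 haplotype correlation within a block, in `[0, 1)`.
#' @param maf_range Minor-allele-frequency range, within `(0, 0.5]`.
#' @param causal_snp_count Number of causal SNPs for the phenotype model
#'   (default: 50, capped at `n_snps`).
#' @param effect_size_sd SD of causal log-odds-ratios (shared component).
#' @param cohort_effect_heterogeneity_sd SD of cohort-specific deviations
#'   around each shared causal effect; `0` means all cohorts share
#'   identical SNP effects.
#' @param prevalence Per-cohort case prevalence, each in `(0, 1)`;
#'   recycled across cohorts.
#' @param covariate_effects Named numeric: log-odds effects for `age`
#'   (per SD), `sex` (female vs male) and `site` (per site contrast).
#' @param info_range Imputation INFO score range, within `(0, 1]`.
#' @param missing_rate Per-genotype missingness probability, in `[0, 1)`.
#' @param seed Integer seed; every stochastic step is reproducible from it.
#'
#' @return A list of class `sim_cohort_config`.
#' @export
sim_cohort_config <- function(n_samples = c(cohort1 = 1500, cohort2 = 450, cohort3 = 700, cohort4 = 350),
                              n_snps = 1000,
                              ld_block_size = 20,
                              ld_rho = 0.7,
                              maf_range = c(0.05, 0.5),
                              causal_snp_count = NULL,
                              effect_size_sd = 0.15,
                              cohort_effect_heterogeneity_sd = 0,
                              prevalence = 0.33,
                              covariate_effects = c(age = 0.2, sex = 0.3, site = 0.1),
                              info_range = c(0.6, 1),
                              missing_rate = 0.01,
                              seed = 1L) {
  if (is.null(causal_snp_count)) causal_snp_count <- min(50, n_snps)
  stopifnot(
    length(n_samples) >= 1, all(n_samples >= 1),
    n_snps >= 1, ld_block_size >= 1,
    ld_rho >= 0, ld_rho < 1,
    length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
    maf_range[1] <= maf_range[2],
    causal_snp_count >= 0, causal_snp_count <= n_snps,
    effect_size_sd >= 0, cohort_effect_heterogeneity_sd >= 0,
    all(prevalence > 0), all(prevalence < 1),
    length(info_range) == 2, info_range[1] > 0, info_range[2] <= 1,
    missing_rate >= 0, missing_rate < 1
  )
  if (is.null(names(n_samples))) {
    names(n_samples) <- paste0("cohort", seq_along(n_samples))
  }
  prevalence <- rep_len(prevalence, length(n_samples))
  names(prevalence) <- names(n_samples)
  structure(
    list(
      n_samples = n_samples, n_snps = as.integer(n_snps),
      ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
      maf_range = maf_range, causal_snp_count = as.integer(causal_snp_count),
      effect_size_sd = effect_size_sd,
      cohort_effect_heterogeneity_sd = cohort_effect_heterogeneity_sd,
      prevalence = prevalence, covariate_effects = covariate_effects,
      info_range = info_range, missing_rate = missing_rate,
      seed = as.integer(seed)
    ),
    class = "sim_cohort_config"
  )
}

# One haplotype draw for all samples: latent AR(rho) Gaussian per block,
# thresholded at qnorm(maf_j) so allele frequency is maf_j exactly.
simulate_haplotypes <- function(n, maf, ld_block_size, ld_rho) {
  m <- length(maf)
  z <- matrix(rnorm(n * m), n, m)
  if (ld_rho > 0 && m > 1) {
    s <- sqrt(1 - ld_rho^2)
    for (j in 2:m) {
      if ((j - 1) %% ld_block_size == 0) next # block boundary: independent
      z[, j] <- ld_rho * z[, j - 1] + s * z[, j]
    }
  }
  thr <- qnorm(maf)
  # allele = 1 (minor) where latent falls below the maf quantile
  sweep(z, 2, thr, `<`) * 1L
}

#' Simulate an LD-structured multi-cohort genotype panel
#'
#' Draws two independent haplotypes per sample from a latent Gaussian with
#' AR(`ld_rho`) correlation within LD blocks and sums them, giving
#' Hardy-Weinberg-consistent genotypes at each SNP's minor-allele
#' frequency.  MAFs are drawn uniformly in `maf_range` (shared across
#' cohorts), INFO scores uniformly in `info_range`, and genotypes are set
#' missing independently at `missing_rate`.  Covariates (age, sex,
#' enrollment site) and per-sample call rates are attached; phenotypes are
#' added separately by [simulate_case_control()].
#'
#' @param config A [sim_cohort_config()].
#' @return A [genotype_panel()] without phenotypes (`status` all `NA`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_cohort_config"))
  with_seed(config$seed, {
    m <- config$n_snps
    n <- sum(config$n_samples)
    maf <- runif(m, config$maf_range[1], config$maf_range[2])
    info <- runif(m, config$info_range[1], config$info_range[2])
    g <- simulate_haplotypes(n, maf, config$ld_block_size, config$ld_rho) +
      simulate_haplotypes(n, maf, config$ld_block_size, config$ld_rho)
    storage.mode(g) <- "double"
    if (config$missing_rate > 0) {
      g[runif(length(g)) < config$missing_rate] <- NA_real_
    }
    snp_meta <- data.frame(
      snp_id = sprintf("rs%06d", seq_len(m)),
      chrom = "1",
      pos = seq_len(m) * 5000L,
      effect_allele = "A",
      other_allele = "G",
      maf = maf,
      info = info,
      stringsAsFactors = FALSE
    )
    cohort <- rep(names(config$n_samples), config$n_samples)
    sample_meta <- data.frame(
      sample_id = sprintf("S%06d", seq_len(n)),
      cohort = cohort,
      status = NA_real_,
      age = rnorm(n),
      sex = rbinom(n, 1, 0.5),
      site = sample(paste0("site", 1:3), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    sample_meta$call_rate <- rowMeans(!is.na(g))
    genotype_panel(g, snp_meta, sample_meta)
  })
}

#' Attach a simulated case-control phenotype to a genotype panel
#'
#' Case status follows an additive logistic model: causal SNPs get shared
#' log-odds effects `N(0, effect_size_sd^2)` plus cohort-specific
#' deviations `N(0, cohort_effect_heterogeneity_sd^2)`; covariate effects
#' are added; and each cohort's intercept is tuned numerically so the
#' expected case fraction matches that cohort's target prevalence.  The
#' planted per-cohort effect table is attached for parameter-recovery
#' checks.
#'
#' @param panel A phenotype-free [genotype_panel()] from
#'   [simulate_genotypes()].
#' @param config The same [sim_cohort_config()] used to build the panel.
#' @param causal_snps Optional character vector of SNP ids to use as the
#'   causal set (default: sampled); or a named numeric vector of fixed
#'   log-odds-ratios.
#' @return The panel with `status` filled in and attribute
#'   `"ground_truth"`: a data frame of per-cohort causal effects.
#' @export
simulate_case_control <- function(panel, config, causal_snps = NULL) {
  stop_if_not_panel(panel)
  stopifnot(inherits(config, "sim_cohort_config"))
  if (any(!is.na(panel$sample_meta$status))) {
    stop("panel already has phenotypes", call. = FALSE)
  }
  with_seed(config$seed + 1L, {
    ids <- panel$snp_meta$snp_id
    if (is.null(causal_snps)) {
      causal <- if (config$causal_snp_count > 0) {
        sample(ids, config$causal_snp_count)
      } else {
        character(0)
      }
      beta0 <- rnorm(length(causal), 0, config$effect_size_sd)
    } else if (is.numeric(causal_snps)) {
      causal <- names(causal_snps)
      beta0 <- unname(causal_snps)
    } else {
      causal <- causal_snps
      beta0 <- rnorm(length(causal), 0, config$effect_size_sd)
    }
    stopifnot(all(causal %in% ids))
    cohorts <- names(config$n_samples)
    K <- length(cohorts)
    # per-cohort effects: shared + heterogeneity deviation
    betas <- matrix(rep(beta0, K), ncol = K,
                    dimnames = list(causal, cohorts))
    if (config$cohort_effect_heterogeneity_sd > 0 && length(causal)) {
      betas <- betas + matrix(
        rnorm(length(causal) * K, 0, config$cohort_effect_heterogeneity_sd),
        ncol = K
      )
    }
    sm <- panel$sample_meta
    site_num <- as.integer(factor(sm$site)) - 1
    eta_cov <- config$covariate_effects["age"] * sm$age +
      config$covariate_effects["sex"] * sm$sex +
      config$covariate_effects["site"] * site_num
    g_causal <- panel$dosages[, causal, drop = FALSE]
    if (length(causal)) {
      # mean-impute missing dosages for the generating model
      mu <- colMeans(g_causal, na.rm = TRUE)
      for (j in seq_along(causal)) {
        gj <- g_causal[, j]
        gj[is.na(gj)] <- mu[j]
        g_causal[, j] <- gj - mu[j] # center so intercept tuning is stable
      }
    }
    status <- numeric(nrow(sm))
    for (k in cohorts) {
      rows <- which(sm$cohort == k)
      eta <- eta_cov[rows]
      if (length(causal)) eta <- eta + g_causal[rows, , drop = FALSE] %*% betas[, k]
      target <- config$prevalence[[k]]
      b0 <- uniroot(
        function(b) mean(plogis(b + eta)) - target,
        interval = c(-20, 20), tol = 1e-10
      )$root
      status[rows] <- rbinom(length(rows), 1, plogis(b0 + eta))
    }
    panel$sample_meta$status <- status
    truth <- data.frame(
      snp_id = rep(causal, K),
      cohort = rep(cohorts, each = length(causal)),
      beta = as.vector(betas),
      stringsAsFactors = FALSE
    )
    attr(panel, "ground_truth") <- truth
    panel
  })
}

#' Configuration for a one-sample Mendelian randomization simulation
#'
#' Encodes a confounded exposure-outcome design: `k_true` uniformly
#' strong SNPs (effect magnitude near `gamma_sd`, random sign) drive a
#' continuous exposure,
#' an unmeasured confounder loads on exposure and outcome with `kappa_x`
#' and `kappa_y`, the exposure has causal effect `tau` on the outcome,
#' and `pleiotropy_count` instruments get direct outcome effects
#' `N(0, alpha_sd^2)`.  The default dimensions follow the reference
#' design of 500 samples and 50,000 candidate instruments of which 9 are
#' real.
#'
#' @param n Sample size.
#' @param m Candidate SNP count.
#' @param k_true Number of true instruments (must be `<= m`).
#' @param gamma_sd Scale of true instrument effects on the exposure
#'   (each effect has magnitude within 10% of this, random sign).
#' @param tau Causal effect of exposure on outcome.
#' @param kappa_x,kappa_y Confounder loadings on exposure and outcome.
#' @param pleiotropy_count Number of true instruments given direct
#'   (invalid) outcome effects.
#' @param alpha_sd SD of the direct pleiotropic effects.
#' @param screen_p Liberal marginal screening threshold carried with the
#'   design (used by downstream screening).
#' @param sigma_x,sigma_y Residual noise SDs of exposure and outcome.
#'   The defaults make the unmeasured confounder the dominant
#'   non-genetic source of variation, the regime in which spurious
#'   instruments cluster tightly near the confounded (OLS) estimate.
#' @param confounded_count Number of null SNPs given direct effects on
#'   the unmeasured confounder (default 0).  These create *correlated*
#'   spurious instruments — invalid candidates that all act through the
#'   same confounder and therefore share a consistent biased Wald ratio
#'   `kappa_y / kappa_x` — as opposed to the pure-chance spurious
#'   correlations of the remaining null SNPs.
#' @param confounder_effect_sd SD of those SNP-on-confounder effects.
#' @param maf_range Candidate-SNP allele-frequency range.
#' @param seed Integer seed.
#' @return A list of class `sim_mr_config`.
#' @export
sim_mr_config <- function(n = 500, m = 50000, k_true = 9,
                          gamma_sd = 0.7, tau = 0.2,
                          kappa_x = 2, kappa_y = 2,
                          pleiotropy_count = 0, alpha_sd = 0,
                          screen_p = 1e-2,
                          sigma_x = 0.5, sigma_y = 0.5,
                          confounded_count = 0, confounder_effect_sd = 0.2,
                          maf_range = c(0.05, 0.5),
                          seed = 1L) {
  stopifnot(
    n >= 10, m >= 1, k_true >= 0, k_true <= m,
    gamma_sd > 0, alpha_sd >= 0, pleiotropy_count >= 0,
    pleiotropy_count <= k_true,
    screen_p > 0, screen_p <= 1,
    sigma_x > 0, sigma_y > 0,
    confounded_count >= 0, k_true + confounded_count <= m,
    confounder_effect_sd >= 0
  )
  structure(
    list(
      n = as.integer(n), m = as.integer(m), k_true = as.integer(k_true),
      gamma_sd = gamma_sd, tau = tau, kappa_x = kappa_x, kappa_y = kappa_y,
      pleiotropy_count = as.integer(pleiotropy_count), alpha_sd = alpha_sd,
      screen_p = screen_p, sigma_x = sigma_x, sigma_y = sigma_y,
      confounded_count = as.integer(confounded_count),
      confounder_effect_sd = confounder_effect_sd,
      maf_range = maf_range, seed = as.integer(seed)
    ),
    class = "sim_mr_config"
  )
}

#' Simulate a confounded one-sample Mendelian randomization dataset
#'
#' Candidate SNPs are drawn independently (binomial at each SNP's MAF);
#' exposure `X = G_true %*% gamma + kappa_x * U + eps` and outcome
#' `Y = tau * X + kappa_y * U + G_pleio %*% alpha + e`, with
#' `eps ~ N(0, sigma_x^2)`, `e ~ N(0, sigma_y^2)` i.i.d.  The confounder
#' is `U = G_conf %*% c + N(0, 1)`: standard normal by default, with an
#' added genetic component over `confounded_count` null SNPs when
#' correlated spurious instruments are requested.
#' Ground truth (causal effect, true and
#' invalid instrument ids) is returned alongside the data.
#'
#' @param config A [sim_mr_config()].
#' @return A list of class `mr_dataset` with elements `panel`
#'   (a [genotype_panel()] over candidate instruments), `exposure`,
#'   `outcome`, `confounder`, and `truth` (list: `tau`, `gamma`,
#'   `true_ids`, `pleiotropic_ids`).
#' @export
simulate_mr <- function(config) {
  stopifnot(inherits(config, "sim_mr_config"))
  with_seed(config$seed, {
    n <- config$n; m <- config$m
    maf <- runif(m, config$maf_range[1], config$maf_range[2])
    g <- matrix(rbinom(n * m, 2L, rep(maf, each = n)), n, m)
    storage.mode(g) <- "double"
    true_idx <- if (config$k_true > 0) seq_len(config$k_true) else integer(0)
    # uniformly strong instruments: magnitude near gamma_sd, random sign —
    # every "true" instrument is genuinely informative of the exposure
    gamma <- sample(c(-1, 1), config$k_true, replace = TRUE) *
      config$gamma_sd * runif(config$k_true, 0.9, 1.1)
    conf_idx <- if (config$confounded_count > 0) {
      config$k_true + seq_len(config$confounded_count)
    } else {
      integer(0)
    }
    cvec <- rnorm(length(conf_idx), 0, config$confounder_effect_sd)
    u <- drop(g[, conf_idx, drop = FALSE] %*% cvec) + rnorm(n)
    x <- drop(g[, true_idx, drop = FALSE] %*% gamma) + config$kappa_x * u +
      rnorm(n, 0, config$sigma_x)
    pleio_idx <- if (config$pleiotropy_count > 0) {
      true_idx[seq_len(config$pleiotropy_count)]
    } else {
      integer(0)
    }
    alpha <- rnorm(length(pleio_idx), 0, config$alpha_sd)
    y <- config$tau * x + config$kappa_y * u +
      drop(g[, pleio_idx, drop = FALSE] %*% alpha) +
      rnorm(n, 0, config$sigma_y)
    snp_meta <- data.frame(
      snp_id = sprintf("mr%06d", seq_len(m)),
      chrom = "1",
      pos = seq_len(m) * 1000L,
      effect_allele = "A", other_allele = "G",
      maf = maf, info = 1,
      is_pseudo = FALSE,
      stringsAsFactors = FALSE
    )
    sample_meta <- data.frame(
      sample_id = sprintf("M%06d", seq_len(n)),
      cohort = "mr", status = NA_real_, call_rate = 1,
      stringsAsFactors = FALSE
    )
    panel <- genotype_panel(g, snp_meta, sample_meta)
    structure(
      list(
        panel = panel, exposure = x, outcome = y, confounder = u,
        truth = list(
          tau = config$tau, gamma = gamma,
          true_ids = snp_meta$snp_id[true_idx],
          pleiotropic_ids = snp_meta$snp_id[pleio_idx],
          confounded_ids = snp_meta$snp_id[conf_idx]
        )
      ),
      class = "mr_dataset"
    )
  })
}

#' Generate permutation pseudo-instruments ("noise variables")
#'
#' For every real SNP on the panel, forms one pseudo-SNP by independently
#' permuting that SNP's dosage vector across samples.  Permutation
#' preserves each SNP's marginal dosage distribution (and hence its MAF
#' exactly) while destroying any association with phenotypes, exposures
#' and confounders, so pseudo-SNPs behave as guaranteed-null candidate
#' instruments.
#'
#' @param panel A [genotype_panel()] of real SNPs.
#' @param seed Integer seed for the permutations.
#' @return A [genotype_panel()] of the pseudo-SNPs only, with ids
#'   prefixed `pseudo_` and `is_pseudo = TRUE` in `snp_meta`.
#' @export
make_pseudo_instruments <- function(panel, seed = 1L) {
  stop_if_not_panel(panel)
  if (ncol(panel$dosages) == 0) stop("empty panel", call. = FALSE)
  with_seed(seed, {
    n <- nrow(panel$dosages)
    g <- apply(panel$dosages, 2, function(col) col[sample.int(n)])
    meta <- panel$snp_meta
    meta$snp_id <- paste0("pseudo_", meta$snp_id)
    meta$is_pseudo <- TRUE
    genotype_panel(g, meta, panel$sample_meta)
  })
}

#' Column-bind two genotype panels over the same samples
#'
#' @param a,b Panels sharing the same samples in the same order.  SNP
#'   positions are made globally unique by placing `b` on its own
#'   pseudo-chromosome when positions collide.
#' @return Combined [genotype_panel()].
#' @export
bind_panels <- function(a, b) {
  stop_if_not_panel(a); stop_if_not_panel(b)
  stopifnot(identical(a$sample_meta$sample_id, b$sample_meta$sample_id))
  meta_b <- b$snp_meta
  if (any(paste(meta_b$chrom, meta_b$pos) %in%
          paste(a$snp_meta$chrom, a$snp_meta$pos))) {
    meta_b$chrom <- paste0(meta_b$chrom, "p")
  }
  cols <- intersect(names(a$snp_meta), names(meta_b))
  meta <- rbind(a$snp_meta[cols], meta_b[cols])
  rownames(meta) <- NULL
  genotype_panel(cbind(a$dosages, b$dosages), meta, a$sample_meta)
}
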