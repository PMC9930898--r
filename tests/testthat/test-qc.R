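test_that("MAF/call-rate filter straddles its thresholds strictly", {
  set.seed(1)
  n <- 1000
  make_col <- function(maf) rbinom(n, 2, maf)
  g <- cbind(
    make_col(0.009), make_col(0.011), make_col(0.3), make_col(0.25),
    make_col(0.4), make_col(0.35), make_col(0.2), make_col(0.15),
    make_col(0.3), make_col(0.25)
  )
  # force empirical frequencies to exactly the intended values
  g[, 1] <- rep(c(2, 0), c(9, n - 9))            # maf 0.009
  g[, 2] <- rep(c(2, 0), c(11, n - 11))          # maf 0.011
  g[1:60, 3] <- NA                               # call rate 0.94
  g[1:40, 4] <- NA                               # call rate 0.96
  g[1:50, 5] <- NA                               # call rate exactly 0.95 -> dropped (strict)
  p <- toy_panel(g)
  out <- filter_maf_callrate(p)
  kept <- out$snp_meta$snp_id
  expect_false("snp1" %in% kept)
  expect_true("snp2" %in% kept)
  expect_false("snp3" %in% kept)
  expect_true("snp4" %in% kept)
  expect_false("snp5" %in% kept)
  expect_equal(ncol(out$dosages), 7)
  log <- attr(out, "drop_log")
  expect_setequal(log$snp_id, c("snp1", "snp3", "snp5"))
})

test_that("imputation-quality rule matches brute force on a grid", {
  grid <- expand.grid(maf = seq(0.01, 0.5, by = 0.016),
                      info = seq(0.05, 1, by = 0.04))
  meta <- data.frame(snp_id = paste0("g", seq_len(nrow(grid))),
                     maf = grid$maf, info = grid$info)
  kept <- imputation_quality_filter(meta)
  oracle <- meta$snp_id[2 * grid$maf * (1 - grid$maf) * grid$info >= 0.05]
  expect_identical(sort(kept), sort(oracle))
  # boundary: product exactly 0.05 is retained (non-strict)
  bd <- data.frame(snp_id = "b", maf = 0.5, info = 0.1)
  expect_identical(imputation_quality_filter(bd)[1], "b")
  # 2 * 0.01 * 0.99 * 1 = 0.0198 < 0.05 -> dropped
  lo <- data.frame(snp_id = "l", maf = 0.01, info = 1)
  expect_length(imputation_quality_filter(lo), 0)
  expect_error(imputation_quality_filter(data.frame(snp_id = "x", maf = 0.6, info = 1)))
})

test_that("HWE exact test agrees with full enumeration", {
  # perfect equilibrium: p-value in the upper region
  expect_gt(hwe_exact_test(c(25, 50, 25)), 0.5)
  # complete heterozygote deficit at n = 100
  expect_lt(hwe_exact_test(c(50, 0, 50)), 1e-11)
  # exhaustive: every genotype configuration with n <= 50
  for (n in c(2, 3, 7, 20, 50)) {
    for (naa in 0:n) {
      for (nab in 0:(n - naa)) {
        cts <- c(n - naa - nab, nab, naa)
        expect_equal(hwe_exact_test(cts), hwe_enumeration_oracle(cts),
                     tolerance = 1e-9)
      }
    }
  }
  # randomized configurations up to n = 200
  set.seed(99)
  for (i in 1:500) {
    n <- sample(51:200, 1)
    cts <- as.vector(rmultinom(1, n, c(0.45, 0.4, 0.15)))
    expect_equal(hwe_exact_test(cts), hwe_enumeration_oracle(cts),
                 tolerance = 1e-9)
  }
  expect_error(hwe_exact_test(c(0, 0, 0)))
})

test_that("stratified HWE filter drops by stratum at its two thresholds", {
  set.seed(3)
  n <- 600
  status <- rep(c(0, 1), each = n / 2)
  good <- rbinom(n, 2, 0.3)
  # SNP violating HWE badly in controls only
  bad_ctrl <- c(sample(rep(c(0, 2), each = n / 4)), rbinom(n / 2, 2, 0.3))
  # SNP violating HWE badly in cases only
  bad_case <- c(rbinom(n / 2, 2, 0.3), sample(rep(c(0, 2), each = n / 4)))
  p <- toy_panel(cbind(good, bad_ctrl, bad_case), status = status)
  out <- stratified_hwe_filter(p)
  expect_identical(out$snp_meta$snp_id, "snp1")
  log <- attr(out, "drop_log")
  expect_setequal(log$reason, c("hwe_controls", "hwe_cases"))
  # a null panel loses (essentially) nothing at 1e-6 / 1e-11
  cfg <- sim_cohort_config(n_samples = c(a = 800), n_snps = 300,
                           causal_snp_count = 0, missing_rate = 0, seed = 4)
  pn <- simulate_case_control(simulate_genotypes(cfg), cfg)
  outn <- stratified_hwe_filter(pn)
  expect_equal(ncol(outn$dosages), 300)
  expect_error(stratified_hwe_filter(toy_panel(cbind(good), status = rep(1, n))))
})

test_that("kinship estimator recovers duplicate, unrelated and parent-offspring", {
  set.seed(5)
  m <- 5000
  maf <- runif(m, 0.1, 0.5)
  draw <- function() rbinom(m, 2, maf)
  # gamete transmission: child gets one allele from parent, one from population
  a <- draw(); b <- draw()
  transmit <- function(g) ifelse(g == 1, rbinom(m, 1, 0.5), g / 2)
  child_a <- transmit(a) + rbinom(m, 1, maf)
  g <- rbind(a, b, a, child_a) # duplicate pair (1,3); parent-offspring (1,4)
  p <- toy_panel(g) # samples in rows
  phi <- kinship_matrix(p)
  expect_lt(abs(phi[1, 3] - 0.5), 0.02)
  expect_lt(abs(phi[1, 2]), 0.02)
  expect_lt(abs(phi[2, 4]), 0.02)
  expect_lt(abs(phi[1, 4] - 0.25), 0.02)
  expect_identical(phi, t(phi))
})

test_that("relative removal drops the lower-call-rate member, iteratively", {
  set.seed(6)
  m <- 500
  maf <- runif(m, 0.2, 0.5)
  a <- rbinom(m, 2, maf)
  g <- rbind(a, a, rbinom(m, 2, maf), a) # samples 1,2,4 mutually duplicates
  p <- toy_panel(g, call_rate = c(0.99, 0.95, 0.98, 0.97))
  phi <- kinship_matrix(p)
  out <- remove_relatives(p, phi)
  kept <- out$sample_meta$sample_id
  # 0.95 and 0.97 leave; the invariant holds on the survivors
  expect_setequal(kept, c("s1", "s3"))
  phi2 <- kinship_matrix(out)
  expect_true(all(phi2[upper.tri(phi2)] <= 0.177))
  # no related pair: identity
  p_free <- subset_panel(p, samples = c("s1", "s3"))
  out2 <- remove_relatives(p_free, kinship_matrix(p_free))
  expect_identical(out2$sample_meta$sample_id, c("s1", "s3"))
  # greedy result is a feasible subset matching exhaustive search feasibility
  best_size <- max(sapply(1:15, function(k) {
    ids <- c("s1", "s2", "s3", "s4")
    keep <- ids[as.logical(bitwAnd(rep(k, 4), c(1, 2, 4, 8)))]
    sub <- unclass(phi)[keep, keep, drop = FALSE]
    if (all(sub[upper.tri(sub)] <= 0.177)) length(keep) else 0
  }))
  expect_equal(length(kept), best_size)
})

test_that("LD pruning leaves no within-window pair at or above the cutoff", {
  cfg <- sim_cohort_config(n_samples = c(a = 800), n_snps = 120,
                           ld_block_size = 30, ld_rho = 0.85,
                           missing_rate = 0, seed = 7)
  p <- simulate_genotypes(cfg)
  th <- qc_thresholds(prune_window = 50, prune_step = 5, prune_r2 = 0.2)
  kept <- ld_prune(p, th)
  expect_lt(length(kept), 120)
  idx <- match(kept, p$snp_meta$snp_id)
  # exhaustive post-hoc check over every retained pair within 50 SNPs
  for (i in seq_along(idx)) {
    for (j in seq_along(idx)) {
      if (j <= i || idx[j] - idx[i] >= 50) next
      r2 <- cor(p$dosages[, idx[i]], p$dosages[, idx[j]])^2
      expect_lt(r2, 0.2)
    }
  }
  # independent SNPs: all retained
  cfg0 <- sim_cohort_config(n_samples = c(a = 2000), n_snps = 40, ld_rho = 0,
                            missing_rate = 0, seed = 8)
  p0 <- simulate_genotypes(cfg0)
  expect_length(ld_prune(p0, th), 40)
  # perfect duplicate columns: exactly one survives
  g <- p0$dosages[, 1]
  pd <- toy_panel(cbind(g, g))
  expect_length(ld_prune(pd, th), 1)
})

test_that("region exclusion is 1-based inclusive at both boundaries", {
  g <- matrix(rbinom(20 * 30, 2, 0.3), 30, 20)
  p <- toy_panel(g) # positions 1000, 2000, ..., 20000
  regions <- data.frame(chrom = "1", start = c(3000, 15000), end = c(6000, 17000))
  out <- exclude_regions(p, regions)
  # SNPs at 3000..6000 (4) and 15000..17000 (3) drop, boundaries included
  expect_equal(ncol(out$dosages), 13)
  expect_false("snp3" %in% out$snp_meta$snp_id)  # at region start
  expect_false("snp6" %in% out$snp_meta$snp_id)  # at region end
  expect_identical(exclude_regions(p, NULL)$snp_meta, p$snp_meta)
  expect_error(exclude_regions(p, data.frame(chrom = "1", start = 5, end = 1)))
})

test_that("ancestry PCs separate populations and are orthogonal", {
  set.seed(10)
  n <- 300; m <- 400
  maf1 <- runif(m, 0.1, 0.5)
  shift <- sample(c(-1, 1), m, TRUE) * runif(m, 0.05, 0.15)
  maf2 <- pmin(pmax(maf1 + shift, 0.05), 0.5)
  g <- rbind(
    matrix(rbinom(n / 2 * m, 2, rep(maf1, each = n / 2)), n / 2, m, byrow = FALSE),
    matrix(rbinom(n / 2 * m, 2, rep(maf2, each = n / 2)), n / 2, m, byrow = FALSE)
  )
  p <- toy_panel(g)
  pcs <- compute_pcs(p, 4)
  pop <- rep(c(0, 1), each = n / 2)
  expect_gt(abs(cor(pcs[, 1], pop)), 0.9)
  ortho <- crossprod(pcs)
  expect_lt(max(abs(ortho[upper.tri(ortho)])), 1e-6)
  # planted rank-1 direction recovered
  set.seed(11)
  u <- rnorm(200)
  v <- rnorm(100)
  x <- u %*% t(v)
  x <- (x - min(x)) / (max(x) - min(x)) * 2 + matrix(rnorm(200 * 100, 0, 0.05), 200, 100)
  x <- pmin(pmax(x, 0), 2)
  pl <- toy_panel(x)
  p1 <- compute_pcs(pl, 1)
  expect_gt(abs(cor(p1[, 1], u)), 0.95)
})
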