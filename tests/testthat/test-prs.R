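test_that("clumping keeps the most significant member of an LD pair", {
  set.seed(61)
  g1 <- rbinom(500, 2, 0.3)
  p <- toy_panel(cbind(g1, g1, rbinom(500, 2, 0.3)))
  stats <- data.frame(
    snp_id = c("snp1", "snp2", "snp3"), chrom = "1", pos = c(1000, 2000, 3000),
    effect_allele = "A", other_allele = "G",
    beta = c(0.5, 0.4, 0.2), se = 0.1, p = c(1e-8, 1e-4, 1e-2),
    n = 500, maf = 0.3, source = "x", flag = ""
  )
  out <- clump(stats, p, clump_params(p_threshold = 0.05))
  expect_setequal(out$snp_id, c("snp1", "snp3"))
  expect_equal(out$weight[out$snp_id == "snp1"], 0.5)
  # near-1 exclusive r2 bound: imperfectly correlated SNPs all survive
  g2 <- g1; flip <- sample(500, 150); g2[flip] <- rbinom(150, 2, 0.3)
  p2 <- toy_panel(cbind(g1, g2, rbinom(500, 2, 0.3)))
  out_all <- clump(stats, p2, clump_params(p_threshold = 1, clump_r2 = 0.999))
  expect_setequal(out_all$snp_id, c("snp1", "snp2", "snp3"))
  # empty post-threshold set warns and returns an empty score
  expect_warning(out0 <- clump(stats, p, clump_params(p_threshold = 1e-12)))
  expect_equal(nrow(out0), 0)
})

test_that("clumping equals the brute-force greedy oracle on LD panels", {
  for (seed in c(62, 63, 64)) {
    cfg <- sim_cohort_config(
      n_samples = c(a = 400), n_snps = 200, ld_block_size = 25, ld_rho = 0.8,
      causal_snp_count = 20, missing_rate = 0, seed = seed
    )
    p <- simulate_case_control(simulate_genotypes(cfg), cfg)
    stats <- gwas_marginal(p)
    for (pt in c(1, 0.2)) {
      pars <- clump_params(p_threshold = pt, clump_r2 = 0.2,
                           clump_window_kb = 100)
      got <- clump(stats, p, pars)$snp_id
      g <- p$dosages
      mu <- colMeans(g, na.rm = TRUE)
      nas <- which(is.na(g), arr.ind = TRUE)
      g[nas] <- mu[nas[, 2]]
      stats2 <- stats
      stats2$pos <- p$snp_meta$pos[match(stats$snp_id, p$snp_meta$snp_id)]
      want <- clump_bruteforce_oracle(stats2, g, pt, 0.2, 100)
      expect_identical(sort(got), sort(want))
    }
  }
})

test_that("score computation matches hand-computed weighted sums", {
  g <- matrix(c(
    0, 1, 2, 1, 0,
    2, 2, 0, 1, 1,
    1, 0, 1, 2, 2,
    0, 0, 0, 0, 2
  ), nrow = 4, byrow = TRUE)
  p <- toy_panel(g)
  w <- c(0.5, -0.2, 0.1, 0.3, 1.5)
  sc <- score_file(paste0("snp", 1:5), rep("A", 5), rep("G", 5), w)
  got <- compute_score(p, sc)
  want <- as.vector(g %*% w)
  expect_equal(as.vector(got), want, tolerance = 1e-12)
  # all-zero weights give all-zero scores
  sc0 <- score_file(paste0("snp", 1:5), rep("A", 5), rep("G", 5), rep(0, 5))
  expect_true(all(compute_score(p, sc0) == 0))
  # single SNP with unit weight returns that SNP's dosage
  sc1 <- score_file("snp3", "A", "G", 1)
  expect_equal(as.vector(compute_score(p, sc1)), g[, 3])
  # swapped alleles contribute 2 - g
  scs <- score_file("snp3", "G", "A", 1)
  expect_equal(as.vector(compute_score(p, scs)), 2 - g[, 3])
  # absent SNPs contribute zero and are counted
  sca <- score_file(c("snp1", "nope"), c("A", "A"), c("G", "G"), c(1, 5))
  got2 <- compute_score(p, sca)
  expect_equal(as.vector(got2), g[, 1])
  expect_equal(attr(got2, "n_missing"), 1L)
})

test_that("scoring is invariant to SNP order, batching, and affine rescaling", {
  cfg <- sim_cohort_config(n_samples = c(a = 100), n_snps = 30,
                           missing_rate = 0.05, seed = 65)
  p <- simulate_genotypes(cfg)
  set.seed(66)
  w <- rnorm(30)
  ids <- p$snp_meta$snp_id
  sc <- score_file(ids, p$snp_meta$effect_allele, p$snp_meta$other_allele, w)
  s_full <- compute_score(p, sc)
  perm <- sample(30)
  sc_perm <- score_file(ids[perm], p$snp_meta$effect_allele[perm],
                        p$snp_meta$other_allele[perm], w[perm])
  expect_equal(s_full, compute_score(p, sc_perm))
  s_batch <- compute_score(p, sc[1:13, ]) + compute_score(p, sc[14:30, ])
  expect_equal(as.vector(s_full), as.vector(s_batch))
  # standardized-genotype scoring with rescaled weights is an affine
  # transform of raw-dosage scoring, so ranking metrics are unchanged
  imp <- apply(p$dosages, 2, function(c) { c[is.na(c)] <- mean(c, na.rm = TRUE); c })
  z <- scale(imp)
  s_std <- as.vector(z %*% (w * apply(imp, 2, sd)))
  expect_gt(cor(s_std, s_full), 0.999999)
  lab <- rep(c(0, 1), 50)
  expect_equal(auc(s_std, lab), auc(unname(s_full), lab))
})

test_that("lasso path matches the soft-threshold closed form when orthonormal", {
  set.seed(67)
  n <- 400
  q <- qr.Q(qr(matrix(rnorm(n * 8), n, 8))) * sqrt(n) # X'X = n I
  beta <- c(2, -1.5, 1, 0.5, 0, 0, 0, 0)
  y <- drop(q %*% beta) + rnorm(n, 0, 0.5)
  for (lam in c(0.1, 0.5, 1.2)) {
    fit <- glmnet::glmnet(q, y, family = "gaussian", lambda = lam,
                          standardize = FALSE, intercept = FALSE,
                          thresh = 1e-12)
    got <- as.vector(coef(fit))[-1]
    want <- soft_threshold(drop(crossprod(q, y)) / n, lam)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("joint lasso shrinks to covariates-only at extreme penalty", {
  p <- demo_panel(n_snps = 60, causal = 10, seed = 68)
  X <- cbind(age = p$sample_meta$age, sex = p$sample_meta$sex)
  fit <- fit_joint_lasso(p, covariates = X,
                         candidate_snps = p$snp_meta$snp_id,
                         lambda_grid = c(1e3), seed = 1)
  expect_equal(fit$n_selected, 0)
  expect_equal(nrow(fit$score), 0)
})

test_that("lasso with planted signal beats top-k marginal selection on recall", {
  hits <- sapply(1:8, function(s) {
    cfg <- sim_cohort_config(
      n_samples = c(a = 1500), n_snps = 300, ld_block_size = 20, ld_rho = 0.8,
      causal_snp_count = 10, effect_size_sd = 0.35, missing_rate = 0, seed = 100 + s
    )
    p <- simulate_case_control(simulate_genotypes(cfg), cfg)
    truth <- unique(attr(p, "ground_truth")$snp_id)
    st <- gwas_marginal(p)
    top10 <- st$snp_id[order(st$p)][1:10]
    fit <- fit_joint_lasso(p, candidate_snps = st$snp_id, seed = s)
    sel <- fit$score$snp_id[order(-abs(fit$score$weight))]
    sel10 <- head(sel, 10)
    c(lasso = sum(sel10 %in% truth), ct = sum(top10 %in% truth))
  })
  expect_gte(mean(hits["lasso", ] >= hits["ct", ]), 0.5)
})

test_that("validation refit recalibrates winner's-curse-inflated weights", {
  set.seed(70)
  shrunk <- replicate(20, {
    n <- 800; m <- 120
    g <- matrix(rbinom(n * m, 2, 0.3), n, m)
    beta <- rnorm(m, 0, 0.08)
    eta <- drop(scale(g, scale = FALSE) %*% beta)
    y <- rbinom(n, 1, plogis(eta))
    tr <- 1:500; va <- 501:800
    cf <- sapply(1:m, function(j) {
      summary(glm(y[tr] ~ g[tr, j], family = binomial()))$coefficients[2, c(1, 4)]
    })
    bhat <- cf[1, ]
    pv <- cf[2, ]
    keep <- order(pv)[1:10] # most significant: winner's-curse inflated
    prs <- g[va, keep] %*% bhat[keep]
    coef(glm(y[va] ~ prs, family = binomial()))[2]
  })
  expect_lt(mean(shrunk), 1)
})

test_that("refit model predicts well when the score is the linear predictor", {
  set.seed(71)
  n <- 3000
  eta <- rnorm(n, 0, 1.5)
  y <- rbinom(n, 1, plogis(eta))
  model <- refit_score_model(eta[1:1500], y[1:1500])
  pred <- model$predict(eta[1501:n])
  oracle_auc <- auc(eta[1501:n], y[1501:n])
  expect_lt(abs(auc(pred, y[1501:n]) - oracle_auc), 0.02)
  # null score: coefficient CI covers zero most of the time
  cover <- replicate(40, {
    s <- rnorm(500)
    yy <- rbinom(500, 1, 0.4)
    f <- glm(yy ~ s, family = binomial())
    ci <- coef(f)[2] + c(-1.96, 1.96) * sqrt(diag(vcov(f)))[2]
    ci[1] < 0 && ci[2] > 0
  })
  expect_gte(mean(cover), 0.85)
  expect_error(refit_score_model(rnorm(10), rep(1, 10)))
})
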