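test_that("screening matches the null expectation and respects thresholds", {
  mc <- sim_mr_config(n = 500, m = 20000, k_true = 0, kappa_x = 0,
                      kappa_y = 0, seed = 91)
  d <- simulate_mr(mc)
  hits <- screen_candidates(d, 1e-3)
  expect_lt(abs(nrow(hits) - 20), 3 * sqrt(20))
  expect_equal(nrow(screen_candidates(d, 1)), 20000)
  # strong true instruments (first-stage F well above 10) are all selected
  mc2 <- sim_mr_config(n = 800, m = 200, k_true = 9, gamma_sd = 1,
                       kappa_x = 1, kappa_y = 1, seed = 92)
  d2 <- simulate_mr(mc2)
  hits2 <- screen_candidates(d2, 1e-3)
  expect_gte(sum(d2$truth$true_ids %in% hits2$snp_id), 8)
})

test_that("Wald ratio arithmetic and delta-method SE are right", {
  expect_equal(wald_ratio(0.2, 0.01, 0.05, 0.02)$estimate, 0.25)
  expect_equal(wald_ratio(0.2, 0.01, 0.05, 0.02)$se, 0.1)
  expect_equal(wald_ratio(0.4, 0, 0.4 * 0.7, 0)$estimate, 0.7)
  expect_error(wald_ratio(0, 1, 1, 1))
  # SE matches Monte-Carlo spread when the exposure side is precise
  set.seed(93)
  bx <- 0.5; sy <- 0.03
  draws <- rnorm(5000, 0.1, sy) / rnorm(5000, bx, 1e-4)
  got <- wald_ratio(bx, 1e-4, 0.1, sy)$se
  expect_lt(abs(got - sd(draws)) / sd(draws), 0.15)
})

test_that("OLS estimate behaves under duplication and confounding", {
  set.seed(94)
  x <- rnorm(500); y <- 0.3 * x + rnorm(500)
  e1 <- ols_estimate(x, y)
  e2 <- ols_estimate(c(x, x), c(y, y))
  expect_equal(e1$estimate, e2$estimate)
  expect_equal(e2$se, e1$se * sqrt(499 / 998) / 1, tolerance = 0.01)
  expect_error(ols_estimate(rep(1, 10), rnorm(10)))
  expect_true(e1$ci[1] < e1$estimate && e1$estimate < e1$ci[2])
})

test_that("GRS-IV reduces to the Wald ratio with one instrument", {
  mc <- sim_mr_config(n = 2000, m = 20, k_true = 3, kappa_x = 0.5,
                      kappa_y = 0.5, seed = 95)
  d <- simulate_mr(mc)
  id <- d$truth$true_ids[1]
  g <- d$panel$dosages[, id]
  bx <- coef(lm(d$exposure ~ g))[2]
  by <- coef(lm(d$outcome ~ g))[2]
  iv <- grs_iv_estimate(d, id)
  expect_equal(iv$estimate, unname(by / bx), tolerance = 1e-10)
  # invariance to positive rescaling of the weights
  iv2 <- grs_iv_estimate(d, d$truth$true_ids,
                         weights = c(1, 2, 0.5))
  iv3 <- grs_iv_estimate(d, d$truth$true_ids,
                         weights = 10 * c(1, 2, 0.5))
  expect_equal(iv2$estimate, iv3$estimate, tolerance = 1e-12)
  expect_equal(iv2$se, iv3$se, tolerance = 1e-12)
})

test_that("valid-instrument GRS-IV confidence intervals cover tau", {
  hits <- vapply(1:150, function(s) {
    mc <- sim_mr_config(n = 2000, m = 10, k_true = 10, gamma_sd = 0.3,
                        kappa_x = 1, kappa_y = 1, sigma_x = 1, sigma_y = 1,
                        tau = 0.2, seed = 700 + s)
    d <- simulate_mr(mc)
    e <- grs_iv_estimate(d, d$truth$true_ids)
    e$ci[1] <= 0.2 && 0.2 <= e$ci[2]
  }, logical(1))
  expect_gt(mean(hits), 0.89)
})

test_that("Egger regression matches weighted least squares and finds pleiotropy", {
  # 3-point hand fixture against the closed form
  bx <- c(0.2, 0.5, 0.8); by <- c(0.11, 0.24, 0.42); sy <- c(0.02, 0.04, 0.05)
  w <- 1 / sy^2
  X <- cbind(1, bx)
  cf_hand <- solve(crossprod(X * sqrt(w)), crossprod(X * sqrt(w), by * sqrt(w)))
  e <- egger_estimate(bx, rep(0.01, 3), by, sy)
  expect_equal(e$estimate, cf_hand[2], tolerance = 1e-10)
  expect_equal(e$intercept, cf_hand[1], tolerance = 1e-10)
  expect_error(egger_estimate(bx[1:2], 1:2, by[1:2], 1:2))
  # constant directional pleiotropy lands in the intercept, slope stays tau
  set.seed(96)
  k <- 40
  bx2 <- runif(k, 0.2, 1)
  by2 <- 0.3 * bx2 + 0.15 + rnorm(k, 0, 0.02)
  e2 <- egger_estimate(bx2, rep(0.01, k), by2, rep(0.02, k))
  expect_lt(abs(e2$estimate - 0.3), 0.05)
  expect_lt(abs(e2$intercept - 0.15), 0.03)
  # orientation: flipping instrument signs leaves the estimate unchanged
  flip <- rep(c(1, -1), k / 2)
  e3 <- egger_estimate(bx2 * flip, rep(0.01, k), by2 * flip, rep(0.02, k))
  expect_equal(e3$estimate, e2$estimate, tolerance = 1e-10)
})

test_that("plurality mode finds the majority cluster", {
  r <- c(rep(0.5, 7), rep(0.9, 3))
  s <- rep(0.05, 10)
  m <- plurality_mode_estimate(r, s, seed = 5)
  expect_lt(abs(m$estimate - 0.5), 0.05)
  # identical ratios return exactly that value with zero SE
  m0 <- plurality_mode_estimate(rep(0.42, 5), rep(0.1, 5))
  expect_equal(m0$estimate, 0.42)
  expect_equal(m0$se, 0)
  # mixture simulations: mode lands on the valid-cluster value
  set.seed(97)
  ok <- replicate(100, {
    r <- c(rnorm(8, 0.3, 0.02), rnorm(4, 0.9, 0.02))
    s <- rep(0.02, 12)
    abs(plurality_mode_estimate(r, s, n_boot = 50, seed = 1)$estimate - 0.3) < 0.05
  })
  expect_gt(mean(ok), 0.9)
})

test_that("with one instrument all single-instrument estimators coincide", {
  mc <- sim_mr_config(n = 1500, m = 5, k_true = 1, kappa_x = 0.5,
                      kappa_y = 0.5, seed = 98)
  d <- simulate_mr(mc)
  id <- d$truth$true_ids
  g <- d$panel$dosages[, id]
  bx <- coef(lm(d$exposure ~ g))[2]
  by <- coef(lm(d$outcome ~ g))[2]
  wr <- wald_ratio(bx, 0.1, by, 0.1)
  iv <- grs_iv_estimate(d, id)
  expect_equal(iv$estimate, unname(wr$estimate), tolerance = 1e-10)
})

test_that("pseudo ratios concentrate near the OLS estimate under confounding", {
  mc <- sim_mr_config(m = 5000, seed = 99)
  d <- simulate_mr(mc)
  det <- detect_spurious(d, mc$screen_p, seed = 100)
  ols <- ols_estimate(d$exposure, d$outcome)$estimate
  expect_lt(abs(det$center - ols), 2 * mad(det$pseudo_ratios$ratio))
  # the pseudo candidates' own ratios mostly fall inside the flag band
  inside <- abs(det$pseudo_ratios$ratio - det$center) <= det$spread
  expect_gte(mean(inside), 0.9)
})

test_that("spurious detection keeps true instruments and flags nulls", {
  res <- sapply(1:20, function(s) {
    mc <- sim_mr_config(m = 5000, seed = s)
    d <- simulate_mr(mc)
    det <- detect_spurious(d, mc$screen_p, seed = s + 1000)
    nulls <- setdiff(det$ratios$snp_id, d$truth$true_ids)
    c(kept = sum(d$truth$true_ids %in% det$valid),
      flagged = mean(nulls %in% det$spurious))
  })
  expect_gte(median(res["kept", ]), 7)
  expect_gte(median(res["flagged", ]), 0.8)
})

test_that("the unconfounded limitation case flags valid instruments too", {
  mc <- sim_mr_config(n = 500, m = 3000, k_true = 9, kappa_x = 0,
                      kappa_y = 0, seed = 101)
  d <- simulate_mr(mc)
  det <- detect_spurious(d, mc$screen_p, seed = 102)
  # the pseudo cluster sits at tau itself, so true instruments are flagged:
  # a documented failure mode detected by comparing the center to tau
  expect_lt(abs(det$center - 0.2), 3 * mad(det$pseudo_ratios$ratio))
  expect_gt(length(det$spurious), 0)
  expect_true(any(d$truth$true_ids %in% det$spurious))
})

test_that("the full pipeline reproduces the spurious-instrument story", {
  mc <- sim_mr_config(m = 5000, seed = 103)
  d <- simulate_mr(mc)
  tab <- mr_pipeline(d, p_threshold = mc$screen_p, seed = 104)
  expect_setequal(
    tab$method,
    c("ols", "grs_iv_naive", "grs_iv_filtered", "egger", "plurality_mode")
  )
  est <- setNames(tab$estimate, tab$method)
  tau <- d$truth$tau
  expect_lt(abs(est["grs_iv_naive"] - est["ols"]), abs(est["grs_iv_naive"] - tau))
  expect_lt(abs(est["grs_iv_filtered"] - tau), abs(est["grs_iv_naive"] - tau))
  # the largest group of candidates with similar ratios is the spurious
  # cluster, so the plurality-rule mode lands near OLS, not tau
  expect_lt(abs(est["plurality_mode"] - est["ols"]),
            abs(est["plurality_mode"] - tau))
  # unconfounded data: all five estimates mutually consistent
  mc0 <- sim_mr_config(n = 2000, m = 300, k_true = 9, kappa_x = 0,
                       kappa_y = 0, seed = 105)
  d0 <- simulate_mr(mc0)
  tab0 <- mr_pipeline(d0, p_threshold = 1e-3, filter_spurious = FALSE,
                      seed = 106)
  done <- tab0[!is.na(tab0$estimate), ]
  expect_true(all(done$ci_low <= 0.2 + 0.1) && all(done$ci_high >= 0.2 - 0.1))
})

test_that("Egger tracks the confounded value under correlated spurious instruments", {
  # null SNPs acting through the shared confounder carry a consistent
  # biased ratio; with many of them the Egger slope sits near OLS and
  # far from the causal effect
  hits <- vapply(1:8, function(s) {
    mc <- sim_mr_config(m = 5000, confounded_count = 60, seed = s)
    d <- simulate_mr(mc)
    sc <- screen_candidates(d, mc$screen_p)
    real <- sc[!sc$is_pseudo, ]
    g <- d$panel$dosages[, match(real$snp_id, d$panel$snp_meta$snp_id),
                         drop = FALSE]
    outa <- prsmr:::marginal_assoc(g, d$outcome)
    e <- egger_estimate(real$beta_x, real$se_x, outa$beta, outa$se)
    ols <- ols_estimate(d$exposure, d$outcome)$estimate
    abs(e$estimate - ols) < abs(e$estimate - d$truth$tau)
  }, logical(1))
  expect_gte(mean(hits), 0.75)
})
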