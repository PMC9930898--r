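#' Screen candidate instruments against the exposure
#'
#' Per-SNP marginal simple regression of the exposure on dosage
#' (closed-form, vectorized), returning the candidates — real and pseudo
#' alike — whose Wald p-value is at or below the (deliberately liberal)
#' threshold.
#'
#' @param data An `mr_dataset` (see [simulate_mr()]), or any list with a
#'   `panel` and `exposure`.
#' @param p_threshold Screening threshold in `(0, 1]`.
#' @return Data frame over the selected SNPs: `snp_id`, `is_pseudo`,
#'   `beta_x`, `se_x`, `p`.
#' @export
screen_candidates <- function(data, p_threshold = 1e-3) {
  stopifnot(p_threshold > 0, p_threshold <= 1)
  g <- data$panel$dosages
  x <- data$exposure
  n <- length(x)
  stopifnot(nrow(g) == n)
  gc_ <- sweep(g, 2, colMeans(g))
  xc <- x - mean(x)
  sxx <- colSums(gc_^2)
  sxy <- drop(crossprod(gc_, xc))
  beta <- sxy / sxx
  rss <- sum(xc^2) - beta * sxy
  se <- sqrt(rss / (n - 2) / sxx)
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df = n - 2)
  meta <- data$panel$snp_meta
  keep <- which(!is.na(p) & p <= p_threshold)
  data.frame(
    snp_id = meta$snp_id[keep],
    is_pseudo = (meta$is_pseudo %||% rep(FALSE, nrow(meta)))[keep],
    beta_x = beta[keep], se_x = se[keep], p = p[keep],
    stringsAsFactors = FALSE
  )
}

# Marginal outcome associations for a set of SNP columns (same closed form).
marginal_assoc <- function(g, y) {
  n <- length(y)
  gc_ <- sweep(g, 2, colMeans(g))
  yc <- y - mean(y)
  sxx <- colSums(gc_^2)
  sxy <- drop(crossprod(gc_, yc))
  beta <- sxy / sxx
  rss <- sum(yc^2) - beta * sxy
  se <- sqrt(rss / (n - 2) / sxx)
  data.frame(beta = beta, se = se)
}

#' Wald ratio causal estimate from one instrument
#'
#' `ratio = beta_y / beta_x` with the first-order delta-method standard
#' error `|se_y / beta_x|` (exposure-side uncertainty enters only at
#' second order and is ignored, the usual convention for strong
#' instruments).
#'
#' @param beta_x,se_x Instrument-exposure association and its SE.
#' @param beta_y,se_y Instrument-outcome association and its SE.
#' @return List: `estimate`, `se`.
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y) {
  if (any(beta_x == 0)) stop("beta_x must be nonzero", call. = FALSE)
  list(estimate = beta_y / beta_x, se = abs(se_y / beta_x))
}

causal_estimate <- function(estimate, se, method, n_instruments = NA_integer_,
                            n_spurious = NA_integer_, extra = NULL) {
  estimate <- unname(estimate)
  se <- unname(se)
  out <- list(
    estimate = estimate, se = se,
    ci = c(estimate - 1.96 * se, estimate + 1.96 * se),
    method = method, n_instruments = n_instruments,
    n_spurious = n_spurious
  )
  out <- c(out, extra)
  class(out) <- "causal_estimate"
  out
}

#' @export
print.causal_estimate <- function(x, ...) {
  cat(sprintf("<%s> estimate %.4f (95%% CI [%.4f, %.4f])\n",
              x$method, x$estimate, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Ordinary least squares exposure-outcome estimate
#'
#' The slope of the outcome on the exposure (plus covariates) — the
#' estimate one would obtain without accounting for unmeasured
#' confounding, used as the confounded benchmark.
#'
#' @param x Exposure vector.
#' @param y Outcome vector.
#' @param covariates Optional covariate matrix.
#' @return A `causal_estimate` with method `"ols"`.
#' @export
ols_estimate <- function(x, y, covariates = NULL) {
  if (sd(x) == 0) stop("constant exposure", call. = FALSE)
  X <- cbind(1, x)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  if (qr(X)$rank < ncol(X)) stop("collinear design", call. = FALSE)
  fit <- lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  XtXi <- chol2inv(chol(crossprod(X)))
  se <- sqrt(rss / fit$df.residual * XtXi[2, 2])
  causal_estimate(fit$coefficients[2], se, "ols")
}

#' Genetic-risk-score instrumental-variable estimate
#'
#' Builds the score `GRS = G %*% w` over the instrument set and computes
#' the single-instrument two-stage estimate
#' `cov(Y, GRS) / cov(X, GRS)`, equivalent to 2SLS with the GRS as the
#' only instrument; the IV standard error uses the 2SLS residual
#' variance.  Reduces to the SNP's Wald ratio when the set has one
#' member.
#'
#' @param data An `mr_dataset`.
#' @param instruments Character vector of instrument SNP ids.
#' @param weights Optional per-SNP weights (default: the marginal
#'   exposure-association betas).
#' @param method Label for the returned estimate.
#' @return A `causal_estimate`.
#' @export
grs_iv_estimate <- function(data, instruments, weights = NULL,
                            method = "grs_iv") {
  stopifnot(length(instruments) >= 1)
  idx <- match(instruments, data$panel$snp_meta$snp_id)
  stopifnot(!anyNA(idx))
  g <- data$panel$dosages[, idx, drop = FALSE]
  x <- data$exposure
  y <- data$outcome
  if (is.null(weights)) {
    weights <- marginal_assoc(g, x)$beta
  }
  grs <- drop(g %*% weights)
  cxz <- cov(x, grs)
  if (abs(cxz) < 1e-12 * sd(x) * max(sd(grs), 1e-300)) {
    stop("weak instrument: cov(X, GRS) ~ 0", call. = FALSE)
  }
  est <- cov(y, grs) / cxz
  n <- length(y)
  # 2SLS standard error: residuals at the IV estimate, first-stage fit
  zc <- grs - mean(grs)
  xc <- x - mean(x)
  yc <- y - mean(y)
  resid <- yc - est * xc
  sig2 <- sum(resid^2) / (n - 2)
  se <- sqrt(sig2 * sum(zc^2)) / abs(sum(zc * xc))
  causal_estimate(est, se, method, n_instruments = length(instruments))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome associations on exposure associations
#' with a free intercept, weights `1 / se_y^2`.  Instruments are first
#' oriented so every `beta_x >= 0`.  The slope estimates the causal
#' effect; the intercept estimates average directional pleiotropy.
#'
#' @param beta_x,se_x,beta_y,se_y Per-instrument association estimates
#'   and SEs (at least 3 instruments).
#' @return A `causal_estimate` with method `"egger"` and extra fields
#'   `intercept`, `intercept_se`.
#' @export
egger_estimate <- function(beta_x, se_x, beta_y, se_y) {
  k <- length(beta_x)
  if (k < 3) stop("Egger regression needs at least 3 instruments", call. = FALSE)
  flip <- beta_x < 0
  bx <- abs(beta_x)
  by <- ifelse(flip, -beta_y, beta_y)
  w <- 1 / se_y^2
  X <- cbind(1, bx)
  W <- sqrt(w)
  fit <- lm.fit(X * W, by * W)
  cf <- fit$coefficients
  XtXi <- chol2inv(chol(crossprod(X * W)))
  # scaled (multiplicative overdispersion) errors, floored at 1
  sig2 <- max(1, sum(fit$residuals^2) / (k - 2))
  ses <- sqrt(diag(XtXi) * sig2)
  causal_estimate(
    unname(cf[2]), ses[2], "egger",
    n_instruments = k,
    extra = list(intercept = unname(cf[1]), intercept_se = ses[1])
  )
}

#' Plurality-rule mode causal estimate
#'
#' Mode of the precision-weighted kernel density of the per-instrument
#' Wald ratios (Gaussian kernel, Silverman bandwidth, weights
#' `1 / se^2`).  Valid under the plurality rule: the largest group of
#' instruments sharing a ratio is the valid one.  The standard error is
#' a seeded bootstrap over instruments.
#'
#' @param ratios Wald ratio estimates (at least 2).
#' @param ses Their standard errors.
#' @param n_boot Bootstrap resamples for the SE (default 500).
#' @param seed Bootstrap seed.
#' @return A `causal_estimate` with method `"plurality_mode"`.
#' @export
plurality_mode_estimate <- function(ratios, ses, n_boot = 500L, seed = 1L) {
  stopifnot(length(ratios) >= 2, length(ses) == length(ratios))
  mode_of <- function(r, s) {
    if (diff(range(r)) < 1e-12) return(r[1])
    w <- 1 / s^2
    # Silverman bandwidth from the unweighted sample; density() would
    # otherwise warn that weights are ignored in bandwidth selection
    d <- density(r, weights = w / sum(w), bw = bw.nrd0(r))
    d$x[which.max(d$y)]
  }
  est <- mode_of(ratios, ses)
  se <- if (diff(range(ratios)) < 1e-12) 0 else with_seed(seed, {
    k <- length(ratios)
    boots <- replicate(n_boot, {
      i <- sample.int(k, k, replace = TRUE)
      mode_of(ratios[i], ses[i])
    })
    sd(boots)
  })
  causal_estimate(est, se, "plurality_mode", n_instruments = length(ratios))
}

#' Detect spurious instruments with permutation pseudo-SNPs
#'
#' Implements resampling-based removal of spurious instruments.  Pseudo
#' (permuted, guaranteed-null) SNPs that survive the liberal exposure
#' screen are spurious by construction, and under confounding their
#' Wald ratios cluster near the confounded (OLS-like) value.  The
#' procedure: (1) Wald ratios for all screened candidates, real and
#' pseudo; (2) the spurious-cluster center `c*` is the
#' precision-weighted median of the screened pseudo ratios — pseudo
#' generation is repeated with fresh derived seeds, aggregating, until
#' at least `min_pseudo` pseudo candidates have been screened in;
#' (3) spread `h = 3 * MAD` of the pseudo ratios; (4) real candidates
#' with `|ratio - c*| <= h` are flagged spurious.
#'
#' When the data are unconfounded the spurious cluster sits at the causal
#' effect itself and valid instruments are flagged too; compare `c*`
#' with a plurality-mode estimate to diagnose that regime.
#'
#' @param data An `mr_dataset` over the real SNPs.
#' @param p_threshold Screening threshold (shared with the real screen).
#' @param min_pseudo Minimum screened-in pseudo candidates to aggregate
#'   before estimating the cluster (default 20).
#' @param max_resamples Pseudo-set regenerations before giving up
#'   (default 50).
#' @param seed Seed for pseudo generation.
#' @return List: `valid` and `spurious` (real SNP id vectors), `center`
#'   (`c*`), `spread` (`h`), `ratios` (data frame over screened real
#'   candidates), `pseudo_ratios`, `n_pseudo_screened`.
#' @export
detect_spurious <- function(data, p_threshold = 1e-3, min_pseudo = 20L,
                            max_resamples = 50L, seed = 1L) {
  screened <- screen_candidates(data, p_threshold)
  real <- screened[!screened$is_pseudo, , drop = FALSE]
  g_real <- data$panel$dosages[, match(real$snp_id, data$panel$snp_meta$snp_id),
                               drop = FALSE]
  out_real <- marginal_assoc(g_real, data$outcome)
  wr <- wald_ratio(real$beta_x, real$se_x, out_real$beta, out_real$se)
  real$ratio <- wr$estimate
  real$ratio_se <- wr$se

  # accumulate screened-in pseudo candidates across regenerated pseudo sets
  seeds <- derive_seeds(seed, max_resamples)
  pr <- list()
  n_ps <- 0L
  for (b in seq_len(max_resamples)) {
    pseudo <- make_pseudo_instruments(data$panel, seed = seeds[b])
    pdat <- list(panel = pseudo, exposure = data$exposure)
    ps <- screen_candidates(pdat, p_threshold)
    if (nrow(ps) > 0) {
      gp <- pseudo$dosages[, match(ps$snp_id, pseudo$snp_meta$snp_id),
                           drop = FALSE]
      op <- marginal_assoc(gp, data$outcome)
      wrp <- wald_ratio(ps$beta_x, ps$se_x, op$beta, op$se)
      pr[[length(pr) + 1]] <- data.frame(ratio = wrp$estimate, se = wrp$se)
      n_ps <- n_ps + nrow(ps)
    }
    if (n_ps >= min_pseudo) break
  }
  if (n_ps == 0) {
    stop("no pseudo candidates screened in after ", max_resamples,
         " resamples; no detectable spurious regime", call. = FALSE)
  }
  pseudo_ratios <- do.call(rbind, pr)
  center <- weighted_median(pseudo_ratios$ratio, 1 / pseudo_ratios$se^2)
  spread <- 3 * mad(pseudo_ratios$ratio, center = center)
  spurious <- real$snp_id[abs(real$ratio - center) <= spread]
  list(
    valid = setdiff(real$snp_id, spurious),
    spurious = spurious,
    center = center, spread = spread,
    ratios = real,
    pseudo_ratios = pseudo_ratios,
    n_pseudo_screened = n_ps
  )
}

#' Full Mendelian-randomization comparison pipeline
#'
#' Screens candidates, optionally runs spurious-instrument detection,
#' and emits five causal estimates in one tidy table: OLS, the naive GRS
#' over all screened real candidates, the GRS restricted to
#' spurious-filtered instruments, Egger regression on the naive set, and
#' the plurality-rule mode.
#'
#' @param data An `mr_dataset`.
#' @param p_threshold Screening threshold.
#' @param filter_spurious Run [detect_spurious()] (default `TRUE`).
#' @param seed Seed for the resampling stages.
#' @return Data frame: `method`, `estimate`, `se`, `ci_low`, `ci_high`,
#'   `n_instruments`, `n_spurious`, `note`; attribute `"detection"`
#'   holds the [detect_spurious()] result when run.
#' @export
mr_pipeline <- function(data, p_threshold = 1e-3, filter_spurious = TRUE,
                        seed = 1L) {
  screened <- screen_candidates(data, p_threshold)
  real <- screened[!screened$is_pseudo, , drop = FALSE]
  est <- list()
  add <- function(e, note = "") {
    est[[length(est) + 1]] <<- data.frame(
      method = e$method, estimate = e$estimate, se = e$se,
      ci_low = e$ci[1], ci_high = e$ci[2],
      n_instruments = e$n_instruments, n_spurious = e$n_spurious,
      note = note, stringsAsFactors = FALSE
    )
  }
  add_na <- function(method, note) {
    est[[length(est) + 1]] <<- data.frame(
      method = method, estimate = NA_real_, se = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_,
      n_instruments = NA_integer_, n_spurious = NA_integer_,
      note = note, stringsAsFactors = FALSE
    )
  }
  add(ols_estimate(data$exposure, data$outcome))
  if (nrow(real) >= 1) {
    add(grs_iv_estimate(data, real$snp_id, method = "grs_iv_naive"))
  } else {
    add_na("grs_iv_naive", "no screened candidates")
  }
  det <- NULL
  if (filter_spurious) {
    det <- tryCatch(
      detect_spurious(data, p_threshold, seed = seed),
      error = function(e) conditionMessage(e)
    )
    if (is.list(det) && length(det$valid) >= 1) {
      e <- grs_iv_estimate(data, det$valid, method = "grs_iv_filtered")
      e$n_spurious <- length(det$spurious)
      add(e)
    } else {
      add_na("grs_iv_filtered",
             if (is.character(det)) det else "all candidates flagged spurious")
    }
  } else {
    add_na("grs_iv_filtered", "filtering disabled")
  }
  if (nrow(real) >= 3) {
    g <- data$panel$dosages[, match(real$snp_id, data$panel$snp_meta$snp_id),
                            drop = FALSE]
    outa <- marginal_assoc(g, data$outcome)
    add(egger_estimate(real$beta_x, real$se_x, outa$beta, outa$se))
    wr <- wald_ratio(real$beta_x, real$se_x, outa$beta, outa$se)
    add(plurality_mode_estimate(wr$estimate, wr$se, seed = seed))
  } else {
    add_na("egger", "fewer than 3 screened candidates")
    add_na("plurality_mode", "fewer than 2 screened candidates")
  }
  out <- do.call(rbind, est)
  attr(out, "detection") <- if (is.list(det)) det else NULL
  out
}
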