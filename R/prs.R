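#' Score file (SNP set with effect-allele weights)
#'
#' The concrete realization of a genetic risk score `GRS_i = sum_{j in S}
#' beta_j * g_ij`: a table of SNP ids, effect alleles and per-allele
#' weights, plus provenance.  Weights are stored on the raw-dosage scale
#' regardless of the scale used during fitting.
#'
#' @param snp_id,effect_allele,other_allele,weight Parallel vectors
#'   defining the set `S`.
#' @param method Provenance label (e.g. `"ct"`, `"lasso"`, `"ei"`).
#' @param p_threshold Optional p-value threshold used to build the set.
#' @return A data frame of class `score_file`.
#' @export
score_file <- function(snp_id, effect_allele, other_allele, weight,
                       method = "manual", p_threshold = NA_real_) {
  stopifnot(!anyDuplicated(snp_id), all(is.finite(weight)))
  out <- data.frame(
    snp_id = snp_id, effect_allele = effect_allele,
    other_allele = other_allele, weight = weight,
    stringsAsFactors = FALSE
  )
  attr(out, "method") <- method
  attr(out, "p_threshold") <- p_threshold
  class(out) <- c("score_file", "data.frame")
  out
}

#' Clumping parameters
#'
#' @param p_threshold P-value inclusion cutoff `p_T` in `(0, 1]`.
#' @param clump_r2 Squared-correlation cutoff above which a SNP is
#'   claimed by a more significant index SNP (default 0.1).
#' @param clump_window_kb Physical window around the index SNP, in kb
#'   (default 250).
#' @return A list of class `clump_params`.
#' @export
clump_params <- function(p_threshold = 1, clump_r2 = 0.1, clump_window_kb = 250) {
  stopifnot(p_threshold > 0, p_threshold <= 1,
            clump_r2 > 0, clump_r2 < 1, clump_window_kb > 0)
  structure(
    list(p_threshold = p_threshold, clump_r2 = clump_r2,
         clump_window_kb = clump_window_kb),
    class = "clump_params"
  )
}

#' Greedy LD clumping with p-value thresholding
#'
#' Sorts SNPs with `p <= p_threshold` by ascending p-value (ties broken
#' by chromosome then position) and repeatedly takes the most significant
#' unclaimed SNP as an index, claiming every unclaimed SNP within
#' `clump_window_kb` of it whose squared dosage correlation in the
#' reference panel is at least `clump_r2`.  The index SNPs with their
#' summary-statistic effects form the score.
#'
#' @param stats A `summary_stats` data frame.
#' @param reference A [genotype_panel()] providing LD (SNPs absent from
#'   it are logged and skipped).
#' @param params A [clump_params()].
#' @return A [score_file()]; attribute `"skipped"` lists stats SNPs
#'   missing from the reference.
#' @export
clump <- function(stats, reference, params = clump_params()) {
  stop_if_not_panel(reference)
  s <- as.data.frame(stats)
  s <- s[!is.na(s$p) & !is.na(s$beta), ]
  skipped <- setdiff(s$snp_id, reference$snp_meta$snp_id)
  s <- s[s$snp_id %in% reference$snp_meta$snp_id, ]
  s <- s[s$p <= params$p_threshold, ]
  if (nrow(s) == 0) {
    warning("no SNPs pass the p-value threshold; empty score")
    out <- score_file(character(0), character(0), character(0), numeric(0),
                      method = "ct", p_threshold = params$p_threshold)
    attr(out, "skipped") <- skipped
    return(out)
  }
  s <- s[order(s$p, s$chrom, s$pos), ]
  ref_idx <- match(s$snp_id, reference$snp_meta$snp_id)
  g <- reference$dosages[, ref_idx, drop = FALSE]
  if (anyNA(g)) {
    mu <- colMeans(g, na.rm = TRUE)
    na <- which(is.na(g), arr.ind = TRUE)
    g[na] <- mu[na[, 2]]
  }
  m <- nrow(s)
  claimed <- rep(FALSE, m)
  index <- logical(m)
  win <- params$clump_window_kb * 1000
  for (i in seq_len(m)) {
    if (claimed[i]) next
    index[i] <- TRUE
    near <- which(!claimed & !index &
                    s$chrom == s$chrom[i] &
                    abs(s$pos - s$pos[i]) <= win)
    if (length(near)) {
      r2 <- suppressWarnings(cor(g[, i], g[, near, drop = FALSE]))^2
      r2[is.na(r2)] <- 0
      claimed[near[r2 >= params$clump_r2]] <- TRUE
    }
  }
  sel <- s[index, ]
  out <- score_file(sel$snp_id, sel$effect_allele, sel$other_allele, sel$beta,
                    method = "ct", p_threshold = params$p_threshold)
  attr(out, "skipped") <- skipped
  out
}

#' Compute genetic risk scores
#'
#' Evaluates `GRS_i = sum_{j in S} beta_j * g_ij` for every sample.
#' Dosages are oriented to the score's effect allele (swapped alleles
#' contribute `2 - g`); missing dosages are imputed to twice the SNP's
#' empirical allele frequency; score SNPs absent from the panel (or with
#' irreconcilable alleles) contribute 0 and are counted in the
#' `"n_missing"` attribute.
#'
#' @param panel A [genotype_panel()].
#' @param score A [score_file()].
#' @return Named numeric vector of per-sample scores.
#' @export
compute_score <- function(panel, score) {
  stop_if_not_panel(panel)
  n <- nrow(panel$dosages)
  out <- setNames(numeric(n), panel$sample_meta$sample_id)
  if (nrow(score) == 0) {
    attr(out, "n_missing") <- 0L
    return(out)
  }
  idx <- match(score$snp_id, panel$snp_meta$snp_id)
  missing_ct <- sum(is.na(idx))
  keep <- which(!is.na(idx))
  for (r in keep) {
    j <- idx[r]
    g <- panel$dosages[, j]
    ea_panel <- toupper(panel$snp_meta$effect_allele[j])
    oa_panel <- toupper(panel$snp_meta$other_allele[j])
    ea <- toupper(score$effect_allele[r])
    oa <- toupper(score$other_allele[r])
    if (ea == ea_panel && oa == oa_panel) {
      # aligned
    } else if (ea == oa_panel && oa == ea_panel) {
      g <- 2 - g
    } else {
      missing_ct <- missing_ct + 1L
      next
    }
    mu <- mean(g, na.rm = TRUE)
    g[is.na(g)] <- mu
    out <- out + score$weight[r] * g
  }
  attr(out, "n_missing") <- missing_ct
  out
}

#' Joint penalized (LASSO) polygenic score
#'
#' Fits an L1-penalized logistic regression of the phenotype on all
#' candidate SNP dosages simultaneously, with covariates left
#' unpenalized, so that LD pruning and effect estimation happen jointly:
#' the penalty forces most SNP coefficients exactly to zero.  SNP
#' dosages are standardized internally; returned weights are on the raw
#' dosage scale.  The penalty `lambda` is chosen by an internal
#' stratified 90/10 split of the training data, scored by validation AUC
#' (binary) or R-squared (continuous).
#'
#' @param panel A [genotype_panel()] (training samples).
#' @param phenotype Numeric response; defaults to `sample_meta$status`.
#' @param covariates Optional covariate matrix (unpenalized).
#' @param candidate_snps Character vector of SNP ids to offer the model
#'   (typically those at `p <= p_T` from a marginal scan).
#' @param lambda_grid Optional penalty grid; default is glmnet's path of
#'   100 log-spaced values.
#' @param family `"binary"` or `"continuous"`.
#' @param seed Seed for the internal validation split.
#' @return List with `score` (a [score_file()] of the nonzero-weight
#'   SNPs), `n_entered`, `n_selected`, `lambda`, and the internal
#'   validation metric per lambda (`path`).
#' @export
fit_joint_lasso <- function(panel, phenotype = NULL, covariates = NULL,
                            candidate_snps, lambda_grid = NULL,
                            family = c("binary", "continuous"), seed = 1L) {
  stop_if_not_panel(panel)
  family <- match.arg(family)
  y <- phenotype %||% panel$sample_meta$status
  candidate_snps <- intersect(candidate_snps, panel$snp_meta$snp_id)
  if (length(candidate_snps) == 0) stop("no candidate SNPs", call. = FALSE)
  g <- panel$dosages[, candidate_snps, drop = FALSE]
  if (anyNA(g)) {
    mu <- colMeans(g, na.rm = TRUE)
    na <- which(is.na(g), arr.ind = TRUE)
    g[na] <- mu[na[, 2]]
  }
  # drop constant SNPs (cannot be standardized)
  keep <- apply(g, 2, var) > 1e-12
  g <- g[, keep, drop = FALSE]
  candidate_snps <- candidate_snps[keep]
  ncv <- 0L
  X <- g
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(covariates))
    ncv <- ncol(cv)
    X <- cbind(cv, g)
  }
  pf <- c(rep(0, ncv), rep(1, ncol(g)))
  fam <- if (family == "binary") "binomial" else "gaussian"

  # internal stratified 90/10 split for lambda selection
  idx_val <- with_seed(seed, {
    if (family == "binary") {
      c(sample(which(y == 0), max(1, round(0.1 * sum(y == 0)))),
        sample(which(y == 1), max(1, round(0.1 * sum(y == 1)))))
    } else {
      sample(seq_along(y), max(1, round(0.1 * length(y))))
    }
  })
  idx_tr <- setdiff(seq_along(y), idx_val)
  fit <- glmnet::glmnet(
    X[idx_tr, , drop = FALSE], y[idx_tr], family = fam,
    penalty.factor = pf, lambda = lambda_grid, standardize = TRUE,
    nlambda = 100
  )
  pred <- predict(fit, X[idx_val, , drop = FALSE], type = "response")
  metric <- apply(pred, 2, function(ph) {
    if (family == "binary") {
      if (length(unique(y[idx_val])) < 2) return(NA_real_)
      auc(ph, y[idx_val])
    } else {
      if (sd(ph) == 0) return(NA_real_)
      r_squared(ph, y[idx_val])
    }
  })
  best <- which.max(metric)
  lambda_best <- fit$lambda[best]
  # refit on the full training data at the chosen lambda
  final <- glmnet::glmnet(
    X, y, family = fam, penalty.factor = pf,
    lambda = fit$lambda, standardize = TRUE
  )
  cf <- as.matrix(coef(final, s = lambda_best))[, 1]
  snp_cf <- cf[candidate_snps]
  nz <- which(snp_cf != 0)
  sel <- candidate_snps[nz]
  meta <- panel$snp_meta[match(sel, panel$snp_meta$snp_id), ]
  score <- score_file(sel, meta$effect_allele, meta$other_allele,
                      unname(snp_cf[nz]), method = "lasso")
  covariate_coef <- cf[seq_len(ncv + 1)] # intercept + covariates
  list(
    score = score,
    n_entered = length(candidate_snps),
    n_selected = length(sel),
    lambda = lambda_best,
    covariate_coef = covariate_coef,
    path = data.frame(lambda = fit$lambda, metric = metric)
  )
}

#' Refit a score-based prediction model on validation data
#'
#' Regresses the phenotype on the computed risk score plus covariates in
#' a held-out validation set (re-estimating the score coefficient guards
#' against winner's-curse-inflated discovery weights), and returns a
#' prediction contract for test data.
#'
#' @param prs Numeric risk scores for the validation samples.
#' @param phenotype Validation phenotype (binary 0/1 or continuous).
#' @param covariates Optional validation covariate matrix.
#' @param family `"auto"`, `"binary"` or `"continuous"`.
#' @return List of class `score_model` with `coefficients`, `family`,
#'   and `predict(prs, covariates)` returning response-scale predictions.
#' @export
refit_score_model <- function(prs, phenotype, covariates = NULL,
                              family = c("auto", "binary", "continuous")) {
  family <- match.arg(family)
  if (family == "auto") {
    family <- if (all(phenotype %in% c(0, 1))) "binary" else "continuous"
  }
  if (length(unique(phenotype)) < 2) {
    stop("degenerate validation phenotype", call. = FALSE)
  }
  df <- data.frame(y = phenotype, prs = prs)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  fam <- if (family == "binary") binomial() else gaussian()
  fit <- glm(y ~ ., data = df, family = fam)
  cf <- coef(fit)
  structure(
    list(
      coefficients = cf,
      family = family,
      predict = function(prs, covariates = NULL) {
        nd <- data.frame(prs = prs)
        if (!is.null(covariates)) nd <- cbind(nd, as.data.frame(covariates))
        predict(fit, newdata = nd, type = "response")
      }
    ),
    class = "score_model"
  )
}
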