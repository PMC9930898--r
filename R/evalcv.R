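#' Area under the ROC curve
#'
#' Mann-Whitney rank form: the probability that a randomly chosen case
#' outscores a randomly chosen control, with ties counting one half.  A
#' label-independent score gives 0.5 in expectation.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels (1 = case).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("need both classes", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Squared correlation between predicted and observed values
#'
#' @param predicted,observed Numeric vectors of equal length (>= 3).
#' @return Squared Pearson correlation.
#' @export
r_squared <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(predicted) >= 3)
  if (sd(observed) == 0 || sd(predicted) == 0) {
    stop("constant input", call. = FALSE)
  }
  cor(predicted, observed)^2
}

#' Repeated stratified nested cross-validation plan
#'
#' For each of `R` repetitions, assigns every sample to one of five folds
#' by stratified sampling within cohort-by-status strata, then splits
#' each fold's held-out 20% in (stratified) half into a validation and a
#' test set — yielding the 80% train / 10% validation / 10% test design.
#' The same plan object is meant to drive every compared method.
#'
#' @param sample_meta Data frame with `sample_id`, `cohort`, `status`.
#' @param R Number of repetitions (default 10).
#' @param seed Integer seed; identical plans under identical seeds.
#' @param n_folds Number of folds (default 5).
#' @return List of class `cv_plan`; `plan[[r]][[f]]` has `train`,
#'   `validation`, `test` sample-id vectors.  Attribute `"strata"`
#'   records the stratum labels.
#' @export
make_cv_plan <- function(sample_meta, R = 10L, seed = 1L, n_folds = 5L) {
  stopifnot(all(c("sample_id", "cohort", "status") %in% names(sample_meta)))
  strat <- interaction(sample_meta$cohort, sample_meta$status, drop = TRUE)
  small <- names(which(table(strat) < n_folds))
  if (length(small)) {
    warning("strata too small to stratify, merged: ",
            paste(small, collapse = ", "))
    levels(strat)[levels(strat) %in% small] <- "merged"
  }
  ids <- sample_meta$sample_id
  seeds <- derive_seeds(seed, R)
  plan <- lapply(seq_len(R), function(r) {
    with_seed(seeds[r], {
      fold <- integer(length(ids))
      for (s in levels(strat)) {
        rows <- which(strat == s)
        fold[rows] <- sample(rep_len(seq_len(n_folds), length(rows)))
      }
      lapply(seq_len(n_folds), function(f) {
        held <- which(fold == f)
        # stratified half-split of the held-out fold into validation/test
        val <- unlist(lapply(levels(strat), function(s) {
          rows <- held[strat[held] == s]
          if (length(rows) == 0) return(integer(0))
          sample(rows, floor(length(rows) / 2))
        }))
        test <- setdiff(held, val)
        list(
          train = ids[fold != f],
          validation = ids[val],
          test = ids[test]
        )
      })
    })
  })
  structure(plan, class = "cv_plan", strata = strat, seed = seed)
}

#' Per-fold score means by case status
#'
#' Summarizes, per repetition and fold, the mean genetic score among
#' cases and among controls (long format, ready for plotting).
#'
#' @param fold_scores Data frame with columns `rep`, `fold`, `score`,
#'   `status` — one row per test-set sample, scores excluding
#'   covariate contributions.
#' @return Data frame `rep`, `fold`, `group` (case/control), `mean_score`.
#' @export
score_means_by_status <- function(fold_scores) {
  stopifnot(all(c("rep", "fold", "score", "status") %in% names(fold_scores)))
  agg <- aggregate(
    score ~ rep + fold + status, data = fold_scores,
    FUN = mean
  )
  agg$group <- ifelse(agg$status == 1, "case", "control")
  agg$status <- NULL
  names(agg)[names(agg) == "score"] <- "mean_score"
  agg[order(agg$rep, agg$fold, agg$group), c("rep", "fold", "group", "mean_score")]
}

#' Bias-variance tradeoff for pooled versus subgroup-specific effects
#'
#' Closed-form mean-squared-error comparison for one SNP effect that
#' differs between two subgroups.  The pooled estimator is the
#' precision-weighted mean with weight `lambda = w1 / (w1 + w2)`,
#' `w_g = n_g * info`; for subgroup 1 it has bias
#' `(1 - lambda) * (beta2 - beta1)` and variance `1 / (w1 + w2)`, while
#' the subgroup-specific estimator is unbiased with variance `1 / w1`.
#' The break-even effect difference is where the two MSEs cross.
#'
#' @param beta1,beta2 True subgroup effects.
#' @param n1,n2 Subgroup sample sizes.
#' @param info Per-observation Fisher information (same for both groups).
#' @return List: `mse_pooled`, `mse_subgroup`, `lambda`,
#'   `break_even_delta` (the `|beta1 - beta2|` at which the MSEs are
#'   equal), and `prefer` (`"pooled"` or `"subgroup"`), all from
#'   subgroup 1's perspective.
#' @export
subgroup_mse_tradeoff <- function(beta1, beta2, n1, n2, info = 1) {
  stopifnot(n1 > 0, n2 > 0, info > 0)
  w1 <- n1 * info
  w2 <- n2 * info
  lambda <- w1 / (w1 + w2)
  bias <- (1 - lambda) * (beta2 - beta1)
  mse_pooled <- bias^2 + 1 / (w1 + w2)
  mse_subgroup <- 1 / w1
  # equality: ((1-l)*d)^2 + 1/(w1+w2) = 1/w1
  break_even <- sqrt((1 / w1 - 1 / (w1 + w2))) / (1 - lambda)
  list(
    mse_pooled = mse_pooled,
    mse_subgroup = mse_subgroup,
    lambda = lambda,
    break_even_delta = break_even,
    prefer = if (mse_pooled <= mse_subgroup) "pooled" else "subgroup"
  )
}

# Build the covariate matrix used throughout the comparison runner:
# age, sex, site contrasts, cohort contrasts, and k ancestry PCs.
design_covariates <- function(panel, pcs = NULL) {
  sm <- panel$sample_meta
  X <- cbind(age = sm$age, sex = sm$sex)
  if (length(unique(sm$site)) > 1) {
    X <- cbind(X, model.matrix(~site, data = sm)[, -1, drop = FALSE])
  }
  if (length(unique(sm$cohort)) > 1) {
    X <- cbind(X, model.matrix(~cohort, data = sm)[, -1, drop = FALSE])
  }
  if (!is.null(pcs)) X <- cbind(X, pcs)
  rownames(X) <- sm$sample_id
  X
}

#' Compare score-construction methods under one cross-validation plan
#'
#' The central harness: for every repetition and fold of `plan`, runs
#' discovery on the training 80% (a combined-data marginal scan for
#' `"ct"` and `"lasso"`; per-cohort scans pooled by inverse-variance
#' meta-analysis for `"meta_ct"`), builds scores at every `p_T` in the
#' grid (greedy clumping for the C+T variants; the joint LASSO for
#' `"lasso"`), re-estimates the score and covariate coefficients on the
#' validation 10% (C+T variants only — the LASSO tunes itself on
#' training data and skips validation), and evaluates AUC (binary) or
#' R-squared (continuous) on the test 10%.  Every method sees the
#' identical plan.
#'
#' @param panel A phenotyped [genotype_panel()].
#' @param plan A [make_cv_plan()] plan over the panel's samples.
#' @param methods Subset of `c("ct", "meta_ct", "lasso")`.
#' @param p_grid P-value thresholds to sweep.
#' @param params A [clump_params()] (the `p_threshold` field is
#'   overridden by `p_grid`).
#' @param n_pcs Ancestry PCs to include as covariates (computed on the
#'   full panel once; 0 to skip).
#' @param seed Seed for the LASSO's internal split.
#' @return List with `folds` (per rep x fold x method x p_T metric rows,
#'   incl. predictor counts and case/control mean scores) and `summary`
#'   (median and IQR per method x p_T) — both plain data frames.
#' @export
run_method_comparison <- function(panel, plan,
                                  methods = c("ct", "meta_ct", "lasso"),
                                  p_grid = c(1e-4, 1e-3, 1e-2, 0.05, 0.1, 1),
                                  params = clump_params(),
                                  n_pcs = 0L, seed = 1L) {
  stop_if_not_panel(panel)
  methods <- match.arg(methods, c("ct", "meta_ct", "lasso"), several.ok = TRUE)
  sm <- panel$sample_meta
  ids <- sm$sample_id
  pcs <- if (n_pcs > 0) compute_pcs(panel, n_pcs) else NULL
  X <- design_covariates(panel, pcs)
  plan_hash <- paste(unlist(plan), collapse = "|")
  rows <- list()
  for (r in seq_along(plan)) {
    for (f in seq_along(plan[[r]])) {
      split <- plan[[r]][[f]]
      stopifnot(identical(
        plan_hash,
        paste(unlist(plan), collapse = "|")
      )) # same plan drives every method
      tr <- match(split$train, ids)
      va <- match(split$validation, ids)
      te <- match(split$test, ids)
      p_tr <- subset_panel(panel, samples = tr)
      y <- sm$status

      stats_comb <- gwas_marginal(p_tr, covariates = X[tr, , drop = FALSE],
                                  source = "combined")
      stats_by_method <- list()
      if (any(c("ct", "lasso") %in% methods)) stats_by_method$ct <- stats_comb
      if ("meta_ct" %in% methods) {
        per <- lapply(unique(sm$cohort[tr]), function(k) {
          rows_k <- tr[sm$cohort[tr] == k]
          Xk <- X[rows_k, , drop = FALSE]
          Xk <- Xk[, apply(Xk, 2, function(c) length(unique(c)) > 1), drop = FALSE]
          gwas_marginal(subset_panel(panel, samples = rows_k),
                        covariates = Xk, source = k)
        })
        stats_by_method$meta_ct <- if (length(per) > 1) meta_analyze(per) else per[[1]]
      }

      for (method in methods) {
        if (method %in% c("ct", "meta_ct")) {
          stats <- stats_by_method[[method]]
          # clump once at p_T = 1; thresholding the index SNPs afterwards is
          # equivalent to clumping each restricted set (greedy order is by p)
          full <- clump(stats, p_tr, clump_params(1, params$clump_r2,
                                                  params$clump_window_kb))
          for (pt in p_grid) {
            ssub <- full[full$snp_id %in%
                           stats$snp_id[!is.na(stats$p) & stats$p <= pt], ,
                         drop = FALSE]
            class(ssub) <- class(full)
            rows[[length(rows) + 1]] <- eval_fold_ct(
              panel, ssub, X, y, va, te, r, f, method, pt
            )
          }
        } else { # lasso
          for (pt in p_grid) {
            cand <- stats_comb$snp_id[!is.na(stats_comb$p) & stats_comb$p <= pt]
            if (length(cand) == 0) {
              rows[[length(rows) + 1]] <- fold_row(r, f, method, pt, NA, 0, 0,
                                                   NA, NA)
              next
            }
            fit <- fit_joint_lasso(p_tr, covariates = X[tr, , drop = FALSE],
                                   candidate_snps = cand, seed = seed + r * 100 + f)
            s_te <- compute_score(subset_panel(panel, samples = te), fit$score)
            metric <- if (nrow(fit$score) == 0 || sd(s_te) == 0) {
              # covariate-only model; score carries no information
              0.5
            } else {
              # linear predictor from the lasso's own coefficients
              eta <- fit$covariate_coef[1] +
                X[te, , drop = FALSE] %*% fit$covariate_coef[-1] + s_te
              auc(drop(eta), y[te])
            }
            rows[[length(rows) + 1]] <- fold_row(
              r, f, method, pt, metric, fit$n_entered, fit$n_selected,
              mean(s_te[y[te] == 1]), mean(s_te[y[te] == 0])
            )
          }
        }
      }
    }
  }
  folds <- do.call(rbind, rows)
  summary <- aggregate(
    metric ~ method + p_threshold, data = folds,
    FUN = function(v) c(median = median(v, na.rm = TRUE),
                        iqr = IQR(v, na.rm = TRUE))
  )
  summary <- data.frame(
    method = summary$method, p_threshold = summary$p_threshold,
    median = summary$metric[, "median"], iqr = summary$metric[, "iqr"]
  )
  list(folds = folds, summary = summary, plan_hash = plan_hash)
}

fold_row <- function(r, f, method, pt, metric, entered, selected,
                     mean_case, mean_control) {
  data.frame(
    rep = r, fold = f, method = method, p_threshold = pt,
    metric = metric, n_entered = entered, n_selected = selected,
    mean_score_case = mean_case, mean_score_control = mean_control,
    stringsAsFactors = FALSE
  )
}

eval_fold_ct <- function(panel, score, X, y, va, te, r, f, method, pt) {
  if (nrow(score) == 0) {
    return(fold_row(r, f, method, pt, NA, 0, 0, NA, NA))
  }
  s_va <- compute_score(subset_panel(panel, samples = va), score)
  s_te <- compute_score(subset_panel(panel, samples = te), score)
  metric <- if (sd(s_va) == 0 || sd(s_te) == 0) {
    0.5
  } else {
    model <- refit_score_model(s_va, y[va], X[va, , drop = FALSE])
    pred <- model$predict(s_te, X[te, , drop = FALSE])
    auc(pred, y[te])
  }
  fold_row(r, f, method, pt, metric, nrow(score), nrow(score),
           mean(s_te[y[te] == 1]), mean(s_te[y[te] == 0]))
}
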