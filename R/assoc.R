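#' Marginal per-SNP association scan
#'
#' Fits, for each SNP, one generalized linear model of the phenotype on
#' dosage plus covariates — logistic regression for a binary phenotype,
#' least squares for a continuous one — and reports the Wald effect
#' estimate, standard error and p-value for the dosage term.  Missing
#' dosages are imputed to the SNP mean.  SNPs with (near-)zero dosage
#' variance or failed convergence are flagged in the output rather than
#' dropped.
#'
#' @param panel A [genotype_panel()].
#' @param phenotype Numeric vector aligned with the panel's samples
#'   (binary 0/1 or continuous); defaults to `sample_meta$status`.
#' @param covariates Optional numeric matrix/data frame of covariates
#'   (no intercept column; one is added).
#' @param family `"binary"` or `"continuous"`; `"auto"` picks binary iff
#'   the phenotype has only values 0 and 1.
#' @param source Provenance label stored in the `source` column
#'   (e.g. a cohort name, `"combined"`).
#' @return A `summary_stats` data frame: `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `p`, `n`, `maf`,
#'   `source`, `flag` (`""`, `"zero_variance"`, `"no_convergence"`,
#'   `"separation"`).
#' @export
gwas_marginal <- function(panel, phenotype = NULL, covariates = NULL,
                          family = c("auto", "binary", "continuous"),
                          source = "combined") {
  stop_if_not_panel(panel)
  family <- match.arg(family)
  y <- phenotype %||% panel$sample_meta$status
  stopifnot(length(y) == nrow(panel$dosages))
  ok <- !is.na(y)
  if (family == "auto") {
    family <- if (all(y[ok] %in% c(0, 1))) "binary" else "continuous"
  }
  if (family == "binary" && length(unique(y[ok])) < 2) {
    stop("binary phenotype needs both classes", call. = FALSE)
  }
  X0 <- cbind(`(Intercept)` = 1)
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(covariates))
    stopifnot(nrow(cv) == length(y))
    X0 <- cbind(X0[rep(1, length(y)), , drop = FALSE], cv)
  } else {
    X0 <- X0[rep(1, length(y)), , drop = FALSE]
  }
  if (qr(X0[ok, , drop = FALSE])$rank < ncol(X0)) {
    stop("covariate matrix is rank-deficient", call. = FALSE)
  }
  fam <- if (family == "binary") binomial() else gaussian()
  # base fit without the SNP provides good starting values for every SNP fit
  base <- glm.fit(X0[ok, , drop = FALSE], y[ok], family = fam)
  eta0 <- base$linear.predictors

  m <- ncol(panel$dosages)
  beta <- se <- p <- maf <- rep(NA_real_, m)
  nobs <- rep(NA_integer_, m)
  flag <- rep("", m)
  for (j in seq_len(m)) {
    g <- panel$dosages[, j]
    mu_g <- mean(g, na.rm = TRUE)
    g[is.na(g)] <- mu_g
    gj <- g[ok]
    maf[j] <- min(mu_g / 2, 1 - mu_g / 2)
    nobs[j] <- sum(ok)
    if (var(gj) < 1e-12) {
      flag[j] <- "zero_variance"
      next
    }
    X <- cbind(X0[ok, , drop = FALSE], dosage = gj)
    fit <- tryCatch(
      suppressWarnings(glm.fit(X, y[ok], family = fam, etastart = eta0)),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      flag[j] <- "no_convergence"
      next
    }
    if (family == "binary" && !fit$converged) flag[j] <- "no_convergence"
    cf <- fit$coefficients["dosage"]
    # Wald covariance from the weighted crossproduct
    w <- fit$weights
    XtX <- crossprod(X * sqrt(w))
    vc <- tryCatch(chol2inv(chol(XtX)), error = function(e) NULL)
    if (is.null(vc)) {
      flag[j] <- "separation"
      next
    }
    dispersion <- if (family == "binary") 1 else {
      sum(fit$residuals^2 * w) / fit$df.residual
    }
    sej <- sqrt(vc[ncol(X), ncol(X)] * dispersion)
    if (!is.finite(cf) || !is.finite(sej) || sej > 50) {
      flag[j] <- "separation"
      next
    }
    beta[j] <- cf
    se[j] <- sej
    z <- cf / sej
    p[j] <- if (family == "binary") {
      2 * pnorm(-abs(z))
    } else {
      2 * pt(-abs(z), df = fit$df.residual)
    }
  }
  out <- data.frame(
    snp_id = panel$snp_meta$snp_id,
    chrom = panel$snp_meta$chrom,
    pos = panel$snp_meta$pos,
    effect_allele = panel$snp_meta$effect_allele,
    other_allele = panel$snp_meta$other_allele,
    beta = beta, se = se, p = p, n = nobs, maf = maf,
    source = source, flag = flag,
    stringsAsFactors = FALSE
  )
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools per-cohort summary statistics SNP by SNP as a weighted average
#' of cohort effects with weights equal to the inverse variances:
#' `beta_meta = sum(w_k * beta_k) / sum(w_k)` with `w_k = 1 / v_k`, and
#' pooled variance `1 / sum(w_k)`.  A SNP absent (or flagged) in some
#' cohorts is pooled over the cohorts that do contribute.  Effect alleles
#' must already be harmonized across inputs (see [harmonize_alleles()]).
#'
#' @param stats_list List of `summary_stats` data frames, one per cohort.
#' @return A `summary_stats` data frame with `source = "meta"` and an
#'   extra `k` column counting contributing cohorts.
#' @export
meta_analyze <- function(stats_list) {
  stopifnot(length(stats_list) >= 1)
  usable <- lapply(stats_list, function(s) {
    s <- as.data.frame(s)
    s <- s[!is.na(s$beta) & !is.na(s$se), , drop = FALSE]
    if (any(s$se <= 0)) stop("non-positive standard error", call. = FALSE)
    s
  })
  all_ids <- unique(unlist(lapply(usable, `[[`, "snp_id")))
  if (length(all_ids) == 0) stop("no SNPs with usable estimates", call. = FALSE)
  first <- do.call(rbind, usable)
  first <- first[!duplicated(first$snp_id), ]
  rownames(first) <- first$snp_id

  num <- den <- ntot <- setNames(numeric(length(all_ids)), all_ids)
  k <- setNames(integer(length(all_ids)), all_ids)
  for (s in usable) {
    w <- 1 / s$se^2
    num[s$snp_id] <- num[s$snp_id] + w * s$beta
    den[s$snp_id] <- den[s$snp_id] + w
    ntot[s$snp_id] <- ntot[s$snp_id] + s$n
    k[s$snp_id] <- k[s$snp_id] + 1L
  }
  beta <- num / den
  se <- sqrt(1 / den)
  fm <- first[all_ids, ]
  out <- data.frame(
    snp_id = all_ids,
    chrom = fm$chrom, pos = fm$pos,
    effect_allele = fm$effect_allele, other_allele = fm$other_allele,
    beta = unname(beta), se = unname(se),
    p = 2 * pnorm(-abs(beta / se)),
    n = unname(ntot), maf = fm$maf,
    source = "meta", flag = "", k = unname(k),
    stringsAsFactors = FALSE
  )
  class(out) <- c("summary_stats", "data.frame")
  out
}

is_strand_ambiguous <- function(a1, a2) {
  pair <- paste(pmin(toupper(a1), toupper(a2)), pmax(toupper(a1), toupper(a2)))
  pair %in% c("A T", "C G")
}

#' Harmonize effect alleles between two summary-statistic sets
#'
#' Aligns `stats_b` to `stats_a` over their shared SNPs: where the
#' effect/other alleles are swapped, `stats_b`'s effect sign is flipped
#' and its alleles relabeled; strand-ambiguous (A/T, C/G) SNPs are
#' flagged; SNPs whose allele pairs neither match nor swap are excluded
#' and logged.
#'
#' @param stats_a,stats_b `summary_stats` data frames sharing SNP ids.
#' @return List with `a`, `b` (aligned, same SNPs, same order),
#'   `flipped` (ids sign-flipped in `b`), `ambiguous` (strand-ambiguous
#'   ids), and `excluded` (irreconcilable ids).
#' @export
harmonize_alleles <- function(stats_a, stats_b) {
  a <- as.data.frame(stats_a)
  b <- as.data.frame(stats_b)
  shared <- intersect(a$snp_id, b$snp_id)
  if (length(shared) == 0) stop("no shared SNP ids", call. = FALSE)
  a <- a[match(shared, a$snp_id), ]
  b <- b[match(shared, b$snp_id), ]
  same <- toupper(a$effect_allele) == toupper(b$effect_allele) &
    toupper(a$other_allele) == toupper(b$other_allele)
  swapped <- toupper(a$effect_allele) == toupper(b$other_allele) &
    toupper(a$other_allele) == toupper(b$effect_allele)
  bad <- !(same | swapped)
  if (any(swapped)) {
    b$beta[swapped] <- -b$beta[swapped]
    tmp <- b$effect_allele[swapped]
    b$effect_allele[swapped] <- b$other_allele[swapped]
    b$other_allele[swapped] <- tmp
    if ("maf" %in% names(b)) b$maf[swapped] <- b$maf[swapped] # MAF is folded; unchanged
  }
  amb <- is_strand_ambiguous(a$effect_allele, a$other_allele)
  keep <- !bad
  out_a <- a[keep, ]; out_b <- b[keep, ]
  class(out_a) <- class(out_b) <- c("summary_stats", "data.frame")
  list(
    a = out_a, b = out_b,
    flipped = shared[swapped],
    ambiguous = shared[amb & keep],
    excluded = shared[bad]
  )
}
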