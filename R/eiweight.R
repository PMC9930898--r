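#' Locus structure for gene-prioritization weighting
#'
#' Describes the loci over which leave-one-out SNP weights are computed:
#' each locus has a SNP set `J`, a gene set, a SNP-to-gene incidence
#' (which genes are "related to" each SNP — by construction all genes at
#' the SNP's locus), and per-SNP feature vectors consumed by the
#' prioritization predictor.
#'
#' @param loci A list; each element a list with `id`, `snps` (character),
#'   `genes` (character), `features` (numeric matrix, one row per SNP,
#'   rownames = SNP ids), and optional `snp_genes` (named list mapping
#'   each SNP id to its related genes; default: all genes at the locus).
#' @return A list of class `locus_structure`.
#' @export
locus_structure <- function(loci) {
  loci <- lapply(loci, function(L) {
    stopifnot(!is.null(L$id), length(L$snps) >= 1, length(L$genes) >= 1,
              is.matrix(L$features), nrow(L$features) == length(L$snps))
    if (is.null(rownames(L$features))) rownames(L$features) <- L$snps
    L
  })
  all_snps <- unlist(lapply(loci, `[[`, "snps"))
  if (anyDuplicated(all_snps)) {
    stop("every SNP must belong to exactly one locus", call. = FALSE)
  }
  structure(loci, class = "locus_structure")
}

#' Leave-one-out changes in predicted gene causality
#'
#' For each SNP `j` at a locus, removes that SNP's features from the
#' prediction and records, for every related gene `g`, the change
#' `delta[j, g] = Ei(g) - Ei(g)_{-j}` between the baseline predicted
#' causality and the prediction without SNP `j`.  The baseline is
#' computed once.  With `retrain = TRUE` the predictor is refit from
#' scratch on the reduced SNP set before re-predicting (slower; the
#' default re-predicts with fixed model parameters, which is
#' deterministic and fast).
#'
#' @param predictor A prioritization predictor, e.g. from
#'   [toy_prioritizer()]: a list exposing
#'   `score(locus, drop_snp = NULL)` returning named per-gene
#'   probabilities, and optionally `retrain(drop_snp)` returning a
#'   refitted predictor.
#' @param locus One locus element of a [locus_structure()].
#' @param retrain Refit the predictor for every dropped SNP.
#' @return Numeric matrix `delta` of dimension `|J| x |genes|`
#'   (rownames = SNP ids, colnames = genes); entries for genes unrelated
#'   to a SNP are `NA`.
#' @export
loo_deltas <- function(predictor, locus, retrain = FALSE) {
  base <- predictor$score(locus)
  genes <- locus$genes
  stopifnot(all(genes %in% names(base)))
  snp_genes <- locus$snp_genes %||%
    setNames(rep(list(genes), length(locus$snps)), locus$snps)
  delta <- matrix(NA_real_, length(locus$snps), length(genes),
                  dimnames = list(locus$snps, genes))
  for (j in locus$snps) {
    pred_j <- if (retrain) {
      if (is.null(predictor$retrain)) {
        stop("predictor does not support retraining", call. = FALSE)
      }
      predictor$retrain(j)$score(locus, drop_snp = j)
    } else {
      predictor$score(locus, drop_snp = j)
    }
    gj <- snp_genes[[j]]
    delta[j, gj] <- base[gj] - pred_j[gj]
  }
  delta
}

#' Per-SNP contribution: mean leave-one-out change over related genes
#'
#' `delta_j = sum_{g in G_j} delta[j, g] / |G_j|` — the signed mean, so
#' opposite-signed gene changes can cancel; magnitudes are taken only at
#' the normalization step ([locus_weights()]).
#'
#' @param delta A `|J| x |genes|` matrix from [loo_deltas()] (`NA` for
#'   unrelated genes).
#' @return Named numeric vector `delta_j` over SNPs.
#' @export
snp_contribution <- function(delta) {
  stopifnot(is.matrix(delta))
  out <- rowMeans(delta, na.rm = TRUE)
  if (any(rowSums(!is.na(delta)) == 0)) {
    stop("a SNP has an empty related-gene set", call. = FALSE)
  }
  out
}

#' Locus-normalized SNP weights
#'
#' `w_j = |delta_j| / sum_{j in J} |delta_j|` over the SNPs at one
#' locus.  A locus where every contribution is zero is degenerate: all
#' weights are defined as 0 and the locus is flagged via the
#' `"degenerate"` attribute.
#'
#' @param delta_j Named numeric vector of per-SNP contributions for one
#'   locus.
#' @return Named weights summing to 1 (or all 0 for a degenerate locus).
#' @export
locus_weights <- function(delta_j) {
  stopifnot(length(delta_j) >= 1)
  tot <- sum(abs(delta_j))
  if (tot == 0) {
    w <- setNames(rep(0, length(delta_j)), names(delta_j))
    attr(w, "degenerate") <- TRUE
    return(w)
  }
  w <- abs(delta_j) / tot
  attr(w, "degenerate") <- FALSE
  w
}

#' Compute leave-one-out weights for a whole locus structure
#'
#' Convenience wrapper running [loo_deltas()], [snp_contribution()] and
#' [locus_weights()] across all loci.
#'
#' @inheritParams loo_deltas
#' @param loci A [locus_structure()].
#' @return Data frame: `snp_id`, `locus_id`, `delta`, `weight`,
#'   `degenerate`.
#' @export
ei_weights <- function(predictor, loci, retrain = FALSE) {
  out <- lapply(loci, function(L) {
    d <- snp_contribution(loo_deltas(predictor, L, retrain = retrain))
    w <- locus_weights(d)
    data.frame(
      snp_id = names(d), locus_id = L$id, delta = unname(d),
      weight = as.vector(w), degenerate = attr(w, "degenerate"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Weight-adjusted score file
#'
#' Multiplies each covered SNP's summary-statistic effect by its
#' leave-one-out weight, `beta_j * w_j`, and emits the result as a score
#' file.  SNPs with weight 0 are excluded from the SNP set (they have no
#' influence on any causal-gene prediction), as are stats SNPs without a
#' weight.  Scatter data pairing each SNP's raw and weighted effect is
#' attached for plotting.
#'
#' @param stats A `summary_stats` data frame.
#' @param weights Data frame from [ei_weights()] (`snp_id`, `weight`).
#' @return A [score_file()] with attribute `"scatter"`: data frame
#'   `snp_id`, `beta`, `weighted_beta`, `weight` over all covered SNPs
#'   (including the excluded zero-weight ones).
#' @export
weighted_score_file <- function(stats, weights) {
  s <- as.data.frame(stats)
  w <- weights[match(s$snp_id, weights$snp_id), "weight"]
  covered <- !is.na(w)
  if (!any(covered)) stop("no stats SNPs have weights", call. = FALSE)
  scatter <- data.frame(
    snp_id = s$snp_id[covered],
    beta = s$beta[covered],
    weighted_beta = s$beta[covered] * w[covered],
    weight = w[covered],
    stringsAsFactors = FALSE
  )
  keep <- covered & w > 0
  out <- score_file(
    s$snp_id[keep], s$effect_allele[keep], s$other_allele[keep],
    s$beta[keep] * w[keep], method = "ei_weighted"
  )
  attr(out, "scatter") <- scatter
  out
}

#' Toy additive-logistic gene prioritizer
#'
#' A desk-scale stand-in for a trained gene-prioritization model: gene
#' scores are `plogis(a + b' A_g)` where `A_g` averages the feature
#' vectors of the SNPs related to gene `g`.  The coefficients are fit by
#' logistic regression of planted causal-gene labels on aggregated
#' features across the training loci, so the predictor is deterministic
#' given its inputs and can be refit on reduced SNP sets.  "Dropping" a
#' SNP removes its features from every aggregation.
#'
#' @param training_loci A [locus_structure()] whose locus elements carry
#'   a `causal_gene` field (the planted truth).
#' @param seed Integer seed (the fit itself is deterministic; the seed
#'   only fixes any tie-breaking jitter, kept for the interface
#'   contract).
#' @return A predictor list with `score(locus, drop_snp = NULL)`,
#'   `retrain(drop_snp)` and `coefficients`.
#' @export
toy_prioritizer <- function(training_loci, seed = 1L) {
  build <- function(drop_global = NULL) {
    agg <- function(L, drop_snp = NULL) {
      drop <- union(drop_global, drop_snp)
      keep <- setdiff(L$snps, drop)
      snp_genes <- L$snp_genes %||%
        setNames(rep(list(L$genes), length(L$snps)), L$snps)
      nf <- ncol(L$features)
      res <- vapply(L$genes, function(g) {
        rel <- keep[vapply(keep, function(s) g %in% snp_genes[[s]], logical(1))]
        if (length(rel) == 0) {
          rep(0, nf)
        } else {
          colMeans(L$features[rel, , drop = FALSE])
        }
      }, numeric(nf))
      if (nf == 1) matrix(res, ncol = 1) else t(res)
    }
    X <- do.call(rbind, lapply(training_loci, function(L) agg(L)))
    y <- unlist(lapply(training_loci, function(L) {
      as.integer(L$genes == L$causal_gene)
    }))
    cf <- with_seed(seed, {
      suppressWarnings(
        glm.fit(cbind(1, X), y, family = binomial())$coefficients
      )
    })
    cf[!is.finite(cf)] <- 0
    list(
      coefficients = cf,
      score = function(locus, drop_snp = NULL) {
        A <- agg(locus, drop_snp)
        p <- plogis(drop(cbind(1, A) %*% cf))
        setNames(p, locus$genes)
      },
      retrain = function(drop_snp) build(drop_global = drop_snp)
    )
  }
  build()
}
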