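## Five-model bivariate Bayesian regression over paired cell types, and the
## integrated Bayes factor (iBF) for differential (cell-specific) eQTLs.
##
## Each model's Bayes factor is against the joint null (no eQTL in either
## cell type):
##   A-not-B      BF(yA | gA) * 1
##   B-not-A      1 * BF(yB | gB)
##   A-and-B      BF(yA | gA) * BF(yB | gB)   (independent effects)
##   stable       one shared standardized effect fitted on the stacked data
##                with per-cell-type intercepts
##   A-opposite-B the stable model with the sign of the B design flipped
## The iBF compares the average of the four differential models with the
## stable model; an eQTL with iBF > 0 is flagged differential.

MODEL_NAMES <- c("stable", "A-not-B", "B-not-A", "A-and-B", "A-opposite-B")

#' Fit the five bivariate association models
#'
#' @param yA,yB residual trait vectors for the two cell types (need not be
#'   the same length; residual correlation between paired samples is
#'   ignored).
#' @param gA,gB dosage vectors matching `yA`/`yB`.
#' @param prior a [prior_grid()].
#' @param gene_id,snp_id optional labels carried into the result.
#' @return object of class `bivariate_result`: list with `log10bf` (named
#'   vector over the five models), `ibf`, `differential`, `best_model`,
#'   `gene_id`, `snp_id`.
#' @export
fit_five_models <- function(yA, yB, gA, gB, prior = prior_grid(),
                            gene_id = NA_character_,
                            snp_id = NA_character_) {
  if (stats::var(gA) == 0 || stats::var(gB) == 0) {
    stop("monomorphic genotype", call. = FALSE)
  }
  bfA <- as.numeric(univariate_log10bf(yA, gA, prior))
  bfB <- as.numeric(univariate_log10bf(yB, gB, prior))
  y <- c(yA, yB)
  g <- c(gA, gB)
  groups <- rep(c("A", "B"), c(length(yA), length(yB)))
  flipB <- seq_along(yB) + length(yA)
  stable <- joint_log10bf(y, matrix(g, ncol = 1L), prior, groups = groups)
  opposite <- joint_log10bf(y, matrix(g, ncol = 1L), prior, groups = groups,
                            flip = flipB)
  log10bf <- c(stable = stable, "A-not-B" = bfA, "B-not-A" = bfB,
               "A-and-B" = bfA + bfB, "A-opposite-B" = opposite)
  res <- structure(list(log10bf = log10bf, gene_id = gene_id,
                        snp_id = snp_id),
                   class = "bivariate_result")
  ib <- integrated_bf(res)
  res$ibf <- ib$ibf
  res$differential <- ib$differential
  res$best_model <- ib$best_model
  res
}

#' Integrated Bayes factor for a differential eQTL
#'
#' `iBF = log10(mean(BF_AnotB, BF_BnotA, BF_AandB, BF_AoppB)) -
#' log10(BF_stable)`, with the four differential models weighted uniformly.
#' An eQTL is flagged differential when `iBF > 0` (strictly); the best
#' model is the argmax over the four differential models (reported as
#' "stable" for non-differential results).
#'
#' @param result a `bivariate_result` (or a named numeric vector of the
#'   five log10 BFs).
#' @param weights weights over the four differential models (sum to 1).
#' @return list with `ibf`, `differential`, `best_model`.
#' @export
integrated_bf <- function(result, weights = rep(0.25, 4)) {
  lb <- if (inherits(result, "bivariate_result")) result$log10bf else result
  stopifnot(all(MODEL_NAMES %in% names(lb)))
  diff_models <- setdiff(MODEL_NAMES, "stable")
  ld <- lb[diff_models]
  ibf <- as.numeric(log10_weighted_sum(ld, weights)) - lb[["stable"]]
  differential <- ibf > 0
  best <- if (differential) diff_models[which.max(ld)] else "stable"
  list(ibf = ibf, differential = differential, best_model = best)
}

#' @export
print.bivariate_result <- function(x, ...) {
  cat(sprintf("bivariate_result %s / %s: iBF = %.3f (%s; best %s)\n",
              x$gene_id, x$snp_id, x$ibf,
              if (x$differential) "differential" else "not differential",
              x$best_model))
  print(round(x$log10bf, 3))
  invisible(x)
}

#' Classify discovery eQTLs across two cell types
#'
#' Fits the five bivariate models for every discovery record against the
#' paired traits and summarizes the class composition.  Sample sets must be
#' matched (same individuals) unless `pooled = TRUE`, which acknowledges a
#' pooled-sample approximation across distinct cohorts.
#'
#' @param records `eqtl_records` for the discovery study.
#' @param exprA,exprB samples x genes residual trait matrices for cell
#'   types A and B.
#' @param genoA,genoB `genotype_matrix` objects matching the trait rows.
#' @param prior a [prior_grid()].
#' @param pooled set TRUE when the two sample sets are not the same
#'   individuals.
#' @return data.frame of class `bivariate_batch`: one row per record with
#'   the five log10 BFs, `ibf`, `differential`, `best_model`.
#' @export
classify_bivariate_batch <- function(records, exprA, exprB, genoA, genoB,
                                     prior = prior_grid(), pooled = FALSE) {
  if (!pooled && !identical(rownames(exprA), rownames(exprB))) {
    stop("sample sets differ; set `pooled = TRUE` for the pooled-sample ",
         "approximation", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(records)), function(i) {
    g <- records$gene_id[i]
    s <- records$snp_id[i]
    jA <- match(s, genoA$snp_ids)
    jB <- match(s, genoB$snp_ids)
    fit <- fit_five_models(exprA[, g], exprB[, g],
                           genoA$dosages[, jA], genoB$dosages[, jB],
                           prior, gene_id = g, snp_id = s)
    data.frame(gene_id = g, snp_id = s, t(fit$log10bf), ibf = fit$ibf,
               differential = fit$differential, best_model = fit$best_model,
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bivariate_batch", "data.frame")
  out
}

#' @export
summary.bivariate_batch <- function(object, ...) {
  tab <- table(factor(object$best_model, levels = MODEL_NAMES))
  cat("bivariate class composition:\n")
  print(tab)
  cat(sprintf("differential: %d / %d\n", sum(object$differential),
              nrow(object)))
  invisible(tab)
}
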