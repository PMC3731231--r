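## Cross-study replication, cell-type-specificity calls, binned replication
## curves, exact categorical tests, and the four logistic enrichment models.

#' Call replication and cell-type specificity
#'
#' A discovery eQTL is `replicated` in a target study when the target's
#' log10 BF for the same (gene, SNP) pair is at or above `bf_threshold`;
#' pairs absent from the target table, or below the MAF floor in either
#' study, are `untested` and excluded from all denominators.  With one
#' within-cell-type and one between-cell-type target, each tested record is
#' categorized: `cell-specific` (within-only), `shared`
#' (within-and-between), `between-only`, or `neither`.
#'
#' @param discovery `eqtl_records` with a `maf` column.
#' @param within association table of the within-cell-type target study:
#'   data.frame `gene_id`, `snp_id`, `ubf`, `maf`.
#' @param between same for the between-cell-type target.
#' @param bf_threshold target-study log10 BF replication threshold.
#' @param maf_min minimum MAF required in both studies for a pair to be
#'   testable.
#' @return the discovery records with `within_status`, `between_status`
#'   (replicated / not-replicated / untested) and `category` columns.
#' @export
call_replication <- function(discovery, within, between = NULL,
                             bf_threshold = 1, maf_min = 0.05) {
  status_vs <- function(target) {
    if (is.null(target)) return(rep("untested", nrow(discovery)))
    key <- paste(discovery$gene_id, discovery$snp_id)
    tkey <- paste(target$gene_id, target$snp_id)
    m <- match(key, tkey)
    status <- rep("untested", nrow(discovery))
    tested <- !is.na(m) & discovery$maf >= maf_min &
      target$maf[m] >= maf_min
    status[tested] <- ifelse(target$ubf[m][tested] >= bf_threshold,
                             "replicated", "not-replicated")
    status
  }
  out <- as.data.frame(discovery)
  out$within_status <- status_vs(within)
  out$between_status <- status_vs(between)
  out$category <- ifelse(
    out$within_status == "untested" | out$between_status == "untested",
    NA_character_,
    ifelse(out$within_status == "replicated",
           ifelse(out$between_status == "replicated", "shared",
                  "cell-specific"),
           ifelse(out$between_status == "replicated", "between-only",
                  "neither")))
  out
}

#' Binned success-fraction curve with Wilson intervals
#'
#' Groups observations into `n_bins` equally spaced bins over the range of
#' `x` and reports each bin's success fraction with a 95% Wilson score
#' interval. Empty bins are emitted with `NA` fraction and flagged.
#'
#' @param x numeric covariate (e.g. discovery log10 BF).
#' @param outcome logical/0-1 outcomes.
#' @param n_bins number of bins (>= 2).
#' @return data.frame `bin`, `mid`, `n`, `fraction`, `lo`, `hi`, `empty`.
#' @export
binned_curve <- function(x, outcome, n_bins = 30L) {
  if (n_bins < 2L) stop("`n_bins` must be >= 2", call. = FALSE)
  outcome <- as.numeric(outcome)
  br <- seq(min(x), max(x), length.out = n_bins + 1L)
  bin <- findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  out <- lapply(seq_len(n_bins), function(b) {
    sel <- bin == b
    n <- sum(sel)
    if (n == 0L) {
      return(data.frame(bin = b, mid = (br[b] + br[b + 1]) / 2, n = 0L,
                        fraction = NA_real_, lo = NA_real_, hi = NA_real_,
                        empty = TRUE))
    }
    k <- sum(outcome[sel])
    ci <- wilson_interval(k, n)
    data.frame(bin = b, mid = (br[b] + br[b + 1]) / 2, n = n,
               fraction = k / n, lo = ci[1], hi = ci[2], empty = FALSE)
  })
  do.call(rbind, out)
}

## 95% Wilson score interval for k successes out of n.
wilson_interval <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' Exact McNemar test for paired binary outcomes
#'
#' Exact binomial two-sided p-value on the discordant counts: under the
#' null the `(b10, b01)` split of discordant pairs is Binomial(n_d, 1/2).
#' With no discordant pairs the p-value is 1.
#'
#' @param a,b logical vectors of paired outcomes, or `NULL` when
#'   `counts` is given.
#' @param counts optional length-2 vector `(b10, b01)` of discordant counts.
#' @return list with `p_value`, `b10`, `b01`.
#' @export
mcnemar_test <- function(a = NULL, b = NULL, counts = NULL) {
  if (is.null(counts)) {
    a <- as.logical(a); b <- as.logical(b)
    counts <- c(sum(a & !b), sum(!a & b))
  }
  b10 <- counts[1]; b01 <- counts[2]
  nd <- b10 + b01
  p <- if (nd == 0L) 1 else min(1, 2 * stats::pbinom(min(b10, b01), nd, 0.5))
  list(p_value = p, b10 = b10, b01 = b01)
}

#' Fisher's exact test with the sample odds ratio
#'
#' Two-sided hypergeometric exact p-value (via [stats::fisher.test()]) and
#' the sample odds ratio `(a*d)/(b*c)`.  A zero margin gives `p = 1` and an
#' undefined odds ratio (`NA`).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return list with `odds_ratio` (sample OR) and `p_value`.
#' @export
fisher_test <- function(tab) {
  tab <- matrix(as.numeric(tab), 2L, 2L)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(odds_ratio = NA_real_, p_value = 1))
  }
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  p <- stats::fisher.test(tab)$p.value
  list(odds_ratio = or, p_value = p)
}

#' Fit one of the four logistic enrichment models
#'
#' Logistic regression (IRLS via [stats::glm()]) for the model family used
#' throughout the CRE analysis:
#' \describe{
#'   \item{eq2}{`overlap ~ signed TSS distance + |distance| + expression +
#'     eQTL-vs-background indicator` — CRE overlap enrichment of eQTL SNPs.}
#'   \item{eq3}{`within-replication ~ CRE overlap + distance terms +
#'     log10 BF + tier` — overlap as a predictor of replication.}
#'   \item{eq4}{`overlap ~ distance terms + expression + group`
#'     (background / tier1 / tier2 factor) — plus a Wald test of the
#'     tier2 - tier1 coefficient difference.}
#'   \item{eq5}{`intervening insulator ~ inter-SNP distance + pair
#'     positions + hotspot flag + intervening-TSS flag + pair-source
#'     indicator` — insulators between independently associated SNP pairs.}
#' }
#' Covariates that are constant in the data are dropped (with a note in the
#' fit) rather than producing a rank-deficient design.
#'
#' @param model one of `"eq2"`, `"eq3"`, `"eq4"`, `"eq5"`.
#' @param data data.frame holding the columns the model needs (see above;
#'   outcome column `outcome`, binary).
#' @return object of class `enrichment_fit`: coefficient table (`beta`,
#'   `se`, `z`, `p`), `aic`, `model`, `dropped`, and for eq4
#'   `tier_contrast` (estimate, se, z, p of tier2 - tier1).
#' @export
fit_enrichment <- function(model = c("eq2", "eq3", "eq4", "eq5"), data) {
  model <- match.arg(model)
  spec <- switch(model,
    eq2 = outcome ~ signed_dist + abs_dist + expression + is_eqtl,
    eq3 = outcome ~ overlap + signed_dist + abs_dist + log10bf + tier,
    eq4 = outcome ~ signed_dist + abs_dist + expression + group,
    eq5 = outcome ~ distance + pos_a + pos_b + hotspot_flag + tss_flag +
      is_eqtl_pair)
  vars <- all.vars(spec)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  # drop constant covariates to keep the design full rank
  dropped <- character(0)
  for (v in setdiff(vars, "outcome")) {
    if (length(unique(data[[v]])) < 2L) {
      spec <- stats::update(spec, paste(". ~ . -", v))
      dropped <- c(dropped, v)
    }
  }
  fit <- stats::glm(spec, data = data, family = stats::binomial())
  if (!fit$converged) {
    stop("logistic fit did not converge (separation?)", call. = FALSE)
  }
  cf <- summary(fit)$coefficients
  tab <- data.frame(term = rownames(cf), beta = cf[, 1], se = cf[, 2],
                    z = cf[, 3], p = cf[, 4], row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- list(model = model, coefficients = tab, aic = stats::AIC(fit),
              dropped = dropped, glm = fit)
  if (model == "eq4" && is.factor(data$group)) {
    lv <- levels(data$group)
    t1 <- paste0("group", "tier1"); t2 <- paste0("group", "tier2")
    if (all(c(t1, t2) %in% rownames(cf))) {
      V <- stats::vcov(fit)
      est <- cf[t2, 1] - cf[t1, 1]
      se <- sqrt(V[t2, t2] + V[t1, t1] - 2 * V[t2, t1])
      z <- est / se
      out$tier_contrast <- list(estimate = est, se = se, z = z,
                                p = 2 * stats::pnorm(-abs(z)))
    }
  }
  structure(out, class = "enrichment_fit")
}

#' @export
print.enrichment_fit <- function(x, ...) {
  cat(sprintf("enrichment_fit (%s), AIC = %.1f\n", x$model, x$aic))
  print(x$coefficients, digits = 3)
  if (length(x$dropped)) cat("dropped constant covariates:",
                             paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}
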