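## Random-forest prediction of eQTL replication / cell-type specificity
## from positional and CRE-overlap features, and the GWAS annotation
## transfer experiment.

#' Assemble classifier feature rows
#'
#' One row per eQTL record: discovery log10 BF, signed and absolute TSS
#' distance, mean expression, effect size, MAF, and one boolean overlap
#' column per CRE track (all configured cell types), plus an intervening-
#' insulator flag per insulator track.
#'
#' @param records `eqtl_records` (needs `ubf`, `beta`, `maf`, `gex`,
#'   `tss_dist`, `pos`, `gene_id`, `snp_id`).
#' @param overlaps logical matrix from [overlap_annotation()] whose rows
#'   align with `records`.
#' @param labels binary outcome vector aligned with `records` (e.g. a
#'   replication status or eQTL-vs-background indicator).
#' @param insulator_flags optional logical vector/matrix of intervening-
#'   insulator indicators aligned with `records`.
#' @return data.frame of features with a `label` factor column.
#' @export
assemble_features <- function(records, overlaps, labels,
                              insulator_flags = NULL) {
  stopifnot(nrow(overlaps) == nrow(records),
            length(labels) == nrow(records))
  feat <- data.frame(log10bf = records$ubf,
                     signed_dist = records$tss_dist,
                     abs_dist = abs(records$tss_dist),
                     expression = records$gex,
                     beta = abs(records$beta),
                     maf = records$maf)
  ov <- as.data.frame(overlaps * 1)
  names(ov) <- make.names(paste0("cre_", colnames(overlaps)))
  feat <- cbind(feat, ov)
  if (!is.null(insulator_flags)) {
    iv <- as.data.frame(as.matrix(insulator_flags) * 1)
    names(iv) <- make.names(paste0("ins_",
                                   if (is.null(colnames(insulator_flags)))
                                     seq_len(ncol(iv))
                                   else colnames(insulator_flags)))
    feat <- cbind(feat, iv)
  }
  if (anyNA(feat)) stop("features contain missing values", call. = FALSE)
  feat$label <- factor(as.integer(as.logical(labels)), levels = c(0L, 1L))
  feat
}

## Stratified k-fold assignments preserving the class ratio within +/- 1.
stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

## AUC via the rank (Mann-Whitney) formulation; ties get average ranks.
rank_auc <- function(scores, labels) {
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## ROC points from pooled scores (FPR, TPR at every threshold).
roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  lab <- as.integer(labels[ord] == 1L)
  tpr <- cumsum(lab) / sum(lab)
  fpr <- cumsum(1 - lab) / sum(1 - lab)
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Cross-validated random-forest classification
#'
#' Stratified k-fold cross-validation of a random forest; out-of-fold
#' predicted probabilities are pooled across folds, the ROC/AUC computed by
#' the rank (Mann-Whitney) formulation, accuracy thresholded at probability
#' 0.5, and per-feature permutation importance (mean decrease in
#' out-of-bag accuracy) taken from a forest grown on the full data.
#'
#' @param rows feature data.frame from [assemble_features()].
#' @param k number of folds (default 10).
#' @param n_trees trees per forest (default 500).
#' @param seed integer seed (fold assignment and forests).
#' @param exclude optional regex; matching feature columns are dropped
#'   before training (used by the CRE ablation).
#' @return object of class `rf_report`: `auc`, `accuracy`, `roc`
#'   (data.frame), `importance` (named vector), `oof_prob`, `folds`,
#'   `seed`.
#' @export
cross_validate_rf <- function(rows, k = 10L, n_trees = 500L, seed = 1L,
                              exclude = NULL) {
  labels <- as.integer(as.character(rows$label))
  if (length(unique(labels)) < 2L) {
    stop("need both classes present", call. = FALSE)
  }
  feat <- rows[, setdiff(names(rows), "label"), drop = FALSE]
  if (!is.null(exclude)) {
    feat <- feat[, !grepl(exclude, names(feat)), drop = FALSE]
  }
  folds <- stratified_folds(labels, k, seed)
  oof <- rep(NA_real_, nrow(rows))
  with_seed(seed + 1L, {
    for (f in seq_len(k)) {
      tr <- folds != f
      fit <- randomForest::randomForest(
        x = feat[tr, , drop = FALSE], y = factor(labels[tr], levels = 0:1),
        ntree = n_trees)
      oof[!tr] <- stats::predict(fit, feat[!tr, , drop = FALSE],
                                 type = "prob")[, "1"]
    }
  })
  full <- with_seed(seed + 2L, randomForest::randomForest(
    x = feat, y = factor(labels, levels = 0:1), ntree = n_trees,
    importance = TRUE))
  imp <- randomForest::importance(full, type = 1L)[, 1L]
  acc <- mean((oof >= 0.5) == (labels == 1L))
  structure(list(auc = rank_auc(oof, labels), accuracy = acc,
                 roc = roc_points(oof, labels), importance = imp,
                 oof_prob = oof, folds = folds, seed = seed),
            class = "rf_report")
}

#' @export
print.rf_report <- function(x, ...) {
  cat(sprintf("rf_report: AUC = %.3f, accuracy = %.3f (seed %d)\n",
              x$auc, x$accuracy, x$seed))
  top <- sort(x$importance, decreasing = TRUE)
  cat("top importance:", paste(names(utils::head(top, 4)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Ablate CRE features under shared folds
#'
#' Runs [cross_validate_rf()] twice with identical fold assignments and
#' seeds: once with all features and once with the CRE overlap/insulator
#' columns removed; reports the AUC difference.
#'
#' @inheritParams cross_validate_rf
#' @param cre_pattern regex identifying CRE feature columns.
#' @return list with `with_cre`, `without_cre` (both `rf_report`) and
#'   `delta_auc`.
#' @export
ablate_cre_features <- function(rows, k = 10L, n_trees = 500L, seed = 1L,
                                cre_pattern = "^(cre_|ins_)") {
  with_cre <- cross_validate_rf(rows, k, n_trees, seed)
  without_cre <- cross_validate_rf(rows, k, n_trees, seed,
                                   exclude = cre_pattern)
  list(with_cre = with_cre, without_cre = without_cre,
       delta_auc = with_cre$auc - without_cre$auc)
}

#' GWAS annotation transfer
#'
#' Trains an eQTL-vs-background random forest on a reduced, cell-type-
#' portable CRE feature set, then scores a GWAS SNP list twice: with
#' features computed from the matched cell type's tracks and from an
#' unmatched cell type's tracks.  The paired probability distributions are
#' compared by a two-sided Wilcoxon signed-rank test.
#'
#' @param training feature rows (from [assemble_features()]) with `label`
#'   1 = eQTL, 0 = background; CRE columns must be named `cre_<class>`
#'   (cell-type-agnostic names shared with the application sets).
#' @param gwas_matched,gwas_unmatched feature data.frames for the GWAS
#'   SNPs, with exactly the same feature columns as `training` (minus
#'   `label`), computed from matched and unmatched tracks respectively.
#' @param n_trees trees in the forest.
#' @param seed integer seed.
#' @return list with `prob_matched`, `prob_unmatched`, `p_value`
#'   (Wilcoxon signed-rank, two-sided; 1 when all pairs tie), and
#'   `median_diff`.
#' @export
annotate_gwas <- function(training, gwas_matched, gwas_unmatched,
                          n_trees = 500L, seed = 1L) {
  feat_cols <- setdiff(names(training), "label")
  if (!identical(sort(feat_cols), sort(names(gwas_matched))) ||
      !identical(sort(feat_cols), sort(names(gwas_unmatched)))) {
    stop("feature mismatch between training and application sets",
         call. = FALSE)
  }
  labels <- factor(as.character(training$label), levels = c("0", "1"))
  fit <- with_seed(seed, randomForest::randomForest(
    x = training[, feat_cols, drop = FALSE], y = labels, ntree = n_trees))
  pm <- stats::predict(fit, gwas_matched[, feat_cols, drop = FALSE],
                       type = "prob")[, "1"]
  pu <- stats::predict(fit, gwas_unmatched[, feat_cols, drop = FALSE],
                       type = "prob")[, "1"]
  d <- pm - pu
  p <- if (all(d == 0)) 1 else {
    suppressWarnings(stats::wilcox.test(pm, pu, paired = TRUE)$p.value)
  }
  list(prob_matched = pm, prob_unmatched = pu, p_value = p,
       median_diff = stats::median(d))
}
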