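## Genotype QC and the expression normalization / latent-factor-removal
## pipeline that produces the residual traits used for association.

#' Genotype quality control
#'
#' Removes samples below the sample call-rate threshold, flags low
#' call-rate SNPs as missing, removes SNPs whose genotype counts deviate
#' from Hardy-Weinberg equilibrium (1-df chi-square on rounded dosages at
#' `hwe_alpha`), and mean-imputes remaining missing dosages per SNP.
#'
#' @param raw a `genotype_matrix` whose `dosages` may contain `NA`.
#' @param sample_call_rate_min minimum fraction of non-missing genotypes
#'   per sample.
#' @param snp_call_rate_min minimum fraction of non-missing genotypes per
#'   SNP; below it the whole SNP is set missing (then dropped as
#'   uninformative).
#' @param hwe_alpha HWE chi-square p-value threshold; `0` disables the
#'   filter.
#' @return a filtered `genotype_matrix` with mean-imputed dosages.
#' @export
filter_genotypes <- function(raw, sample_call_rate_min = 0.95,
                             snp_call_rate_min = 0.95, hwe_alpha = 1e-4) {
  for (v in c(sample_call_rate_min, snp_call_rate_min, hwe_alpha)) {
    stopifnot_scalar(v, "threshold", 0, 1)
  }
  dos <- raw$dosages
  keep_s <- rowMeans(!is.na(dos)) >= sample_call_rate_min
  if (!any(keep_s)) stop("all samples removed by call-rate filter",
                         call. = FALSE)
  dos <- dos[keep_s, , drop = FALSE]
  # SNPs below call rate: flagged entirely missing, hence dropped
  low_snp <- colMeans(!is.na(dos)) < snp_call_rate_min
  keep_v <- !low_snp
  # HWE on rounded genotype counts
  if (hwe_alpha > 0) {
    hwe_p <- apply(dos, 2L, function(g) hwe_chisq_p(round(g[!is.na(g)])))
    keep_v <- keep_v & (is.na(hwe_p) | hwe_p >= hwe_alpha)
  }
  dos <- dos[, keep_v, drop = FALSE]
  # mean-impute per SNP
  for (j in seq_len(ncol(dos))) {
    miss <- is.na(dos[, j])
    if (any(miss)) dos[miss, j] <- mean(dos[!miss, j])
  }
  structure(list(sample_ids = raw$sample_ids[keep_s],
                 snp_ids = raw$snp_ids[keep_v],
                 chrom = raw$chrom[keep_v], pos = raw$pos[keep_v],
                 major = raw$major[keep_v], minor = raw$minor[keep_v],
                 maf = colMeans(dos) / 2, dosages = dos),
            class = "genotype_matrix")
}

## 1-df HWE chi-square p-value from rounded genotypes (0/1/2 counts).
hwe_chisq_p <- function(g) {
  n <- length(g)
  if (n == 0L) return(NA_real_)
  obs <- c(sum(g == 0), sum(g == 1), sum(g == 2))
  p <- (2 * obs[3] + obs[2]) / (2 * n)
  if (p == 0 || p == 1) return(NA_real_)
  expc <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((obs - expc)^2 / expc)
  stats::pchisq(stat, df = 1L, lower.tail = FALSE)
}

#' Normalize an expression matrix
#'
#' The array-level pipeline: log2 transform (non-positive entries floored at
#' half the minimum positive value), k-nearest-neighbour imputation of
#' missing entries (nearest traits by Euclidean distance over complete
#' pairs), per-array quantile transform to the average empirical
#' distribution across arrays, then a per-trait transform to standard-normal
#' quantiles `qnorm((rank - 0.5)/n)` with ties broken by average rank.
#' Constant traits are dropped with a warning.
#'
#' @param raw samples x traits numeric matrix (intensity scale).
#' @param knn_k neighbours used for imputation.
#' @param log_transform set `FALSE` if `raw` is already on log scale.
#' @return samples x traits matrix of standard-normal residual quantiles
#'   (stage "quantile"), with attribute `stage`.
#' @export
normalize_expression <- function(raw, knn_k = 10L, log_transform = TRUE) {
  x <- as.matrix(raw)
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("need at least 2 samples and 2 traits", call. = FALSE)
  }
  if (log_transform) {
    minpos <- min(x[x > 0], na.rm = TRUE)
    x[!is.na(x) & x <= 0] <- minpos / 2
    x <- log2(x)
  }
  if (anyNA(x)) x <- knn_impute(x, k = knn_k)
  dn <- dimnames(x)
  x0 <- x                       # pre-quantile values break rank ties below
  x <- quantile_to_average(x)
  dimnames(x) <- dn
  keep <- apply(x0, 2L, function(col) length(unique(col)) > 1L)
  if (!all(keep)) {
    warning(sum(!keep), " constant trait(s) dropped")
    x <- x[, keep, drop = FALSE]
    x0 <- x0[, keep, drop = FALSE]
  }
  # per-trait standard-normal quantiles; ties introduced by the array-level
  # transform are broken by the pre-transform ordering, genuine duplicates
  # keep average ranks
  n <- nrow(x)
  for (j in seq_len(ncol(x))) {
    u <- rank(x[, j], ties.method = "average") +
      rank(x0[, j], ties.method = "average") / (n + 1)
    x[, j] <- qnorm((rank(u, ties.method = "average") - 0.5) / n)
  }
  attr(x, "stage") <- "quantile"
  x
}

## k-NN imputation: a missing (sample, trait) cell takes the mean of that
## sample's values in the k nearest other traits (Euclidean distance over
## completely observed pairs of entries).  Distances and neighbour values
## always come from the original observed entries, never from imputations.
knn_impute <- function(x, k = 10L) {
  p <- ncol(x)
  obs <- x
  colmeans <- colMeans(obs, na.rm = TRUE)
  for (j in which(colSums(is.na(obs)) > 0L)) {
    d <- vapply(seq_len(p), function(l) {
      if (l == j) return(Inf)
      ok <- !is.na(obs[, j]) & !is.na(obs[, l])
      if (!any(ok)) return(Inf)
      sqrt(mean((obs[ok, j] - obs[ok, l])^2))
    }, numeric(1L))
    nn <- order(d)[seq_len(min(k, sum(is.finite(d))))]
    for (i in which(is.na(obs[, j]))) {
      vals <- obs[i, nn]
      x[i, j] <- if (all(is.na(vals))) colmeans[j] else mean(vals, na.rm = TRUE)
    }
  }
  x
}

## Per-array quantile transform to the average empirical distribution:
## every row's sorted values are replaced by the mean sorted profile.
quantile_to_average <- function(x) {
  sorted <- apply(x, 1L, sort)            # ncol(x) x nrow(x)
  ref <- rowMeans(sorted)
  t(apply(x, 1L, function(row) ref[rank(row, ties.method = "first")]))
}

#' Remove expression principal components
#'
#' Computes the PCs of the trait matrix, chooses `k` by the
#' percent-variance-explained difference rule (remove PCs 1..k where `k+1`
#' is the first PC whose PVE drop from the previous PC falls below
#' `pve_delta`), regresses every trait on PCs 1..k, and re-quantile-
#' normalizes the residuals per trait.
#'
#' @param expr samples x traits matrix at stage "quantile".
#' @param pve_delta PVE-difference threshold (> 0); `1` removes nothing.
#' @return list with `residuals` (stage "residual") and `report` (class
#'   `normalization_report`: per-PC PVE, `n_removed`, `pve_delta`).
#' @export
remove_pcs <- function(expr, pve_delta = 0.01) {
  if (pve_delta <= 0) stop("`pve_delta` must be > 0", call. = FALSE)
  x <- as.matrix(expr)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  pve <- pc$sdev^2 / sum(pc$sdev^2)
  drops <- -diff(pve)
  j <- which(drops < pve_delta)
  k <- if (length(j) == 0L) length(drops) else j[1L] - 1L
  if (k > 0L) {
    scores <- pc$x[, seq_len(k), drop = FALSE]
    fit <- stats::lm.fit(cbind(1, scores), x)
    res <- fit$residuals
  } else {
    res <- x
  }
  res <- apply(res, 2L, qnorm_transform)
  dimnames(res) <- dimnames(x)
  attr(res, "stage") <- "residual"
  report <- structure(list(pve = pve, n_removed = k, pve_delta = pve_delta),
                      class = "normalization_report")
  list(residuals = res, report = report)
}

#' @export
print.normalization_report <- function(x, ...) {
  cat(sprintf("normalization_report: %d PC(s) removed (pve_delta = %g)\n",
              x$n_removed, x$pve_delta))
  cat("leading PVE:", paste(sprintf("%.3f", utils::head(x$pve, 5)),
                            collapse = " "), "\n")
  invisible(x)
}

#' Cluster probes of multi-probe genes
#'
#' For each gene, the probes x samples matrix is clustered with a Gaussian
#' mixture (spherical components, BIC over 1..`max_clusters` components,
#' with a conjugate variance prior so singleton clusters have finite BIC).
#' Each cluster's trait is the per-sample mean of its member probes;
#' single-probe genes pass through.
#'
#' @param expr samples x probes matrix (stage "residual").
#' @param probe_to_gene named character vector or data.frame
#'   (`probe_id`, `gene_id`) mapping columns of `expr` to genes.
#' @param max_clusters maximum mixture components per gene (>= 1).
#' @return list `gene_id -> samples x clusters` matrix (cluster columns
#'   named `<gene>_c<j>`).
#' @export
cluster_probes <- function(expr, probe_to_gene, max_clusters = 3L) {
  if (max_clusters < 1L) stop("`max_clusters` must be >= 1", call. = FALSE)
  if (is.data.frame(probe_to_gene)) {
    map <- stats::setNames(probe_to_gene$gene_id, probe_to_gene$probe_id)
  } else {
    map <- probe_to_gene
  }
  x <- as.matrix(expr)
  genes <- unique(map[colnames(x)])
  out <- list()
  for (g in genes) {
    probes <- colnames(x)[map[colnames(x)] == g]
    sub <- x[, probes, drop = FALSE]
    if (length(probes) == 1L) {
      out[[g]] <- matrix(sub, ncol = 1L,
                         dimnames = list(rownames(x), paste0(g, "_c1")))
      next
    }
    cl <- probe_cluster_labels(t(sub), max_clusters)
    traits <- vapply(sort(unique(cl)), function(ci)
      rowMeans(sub[, cl == ci, drop = FALSE]), numeric(nrow(sub)))
    colnames(traits) <- paste0(g, "_c", seq_len(ncol(traits)))
    rownames(traits) <- rownames(x)
    out[[g]] <- traits
  }
  out
}

## GMM labels for a probes x samples matrix.  Probes live on the
## correlation metric d = sqrt(2 (1 - r)) (coherent probes near 0,
## anticorrelated ones near 2); the mixture runs on the leading principal
## coordinate with a fixed variance prior (scale 0.25, i.e. a prior SD of
## half the distance of an uncorrelated pair) so singleton clusters have
## finite BIC but coherent probes are not split.
probe_cluster_labels <- function(pm, max_clusters) {
  p <- nrow(pm)
  r <- suppressWarnings(stats::cor(t(pm)))
  r[!is.finite(r)] <- 1
  d <- stats::as.dist(sqrt(pmax(2 * (1 - r), 0)))  # pmax keeps dim here
  if (max(d) < 1e-6) return(rep(1L, p))  # indistinguishable probes
  coords <- suppressWarnings(stats::cmdscale(d, k = 1L))
  if (is.null(dim(coords)) || ncol(coords) == 0L) return(rep(1L, p))
  g_max <- min(max_clusters, p)
  fit <- try(suppressWarnings(
    mclust::Mclust(coords, G = seq_len(g_max),
                   prior = mclust::priorControl(scale = 0.25),
                   verbose = FALSE)),
    silent = TRUE)
  if (inherits(fit, "try-error") || is.null(fit)) return(rep(1L, p))
  fit$classification
}

#' Per-population quantile normalization
#'
#' Applies the per-trait standard-normal quantile transform within each
#' population separately, then pools the samples; used for multi-population
#' studies so allele-frequency differences between populations cannot
#' masquerade as expression signal.
#'
#' @param expr samples x traits matrix.
#' @param pop_labels population label per sample (>= 2 samples per
#'   population).
#' @return matrix of the same shape.
#' @export
per_population_normalize <- function(expr, pop_labels) {
  x <- as.matrix(expr)
  stopifnot(length(pop_labels) == nrow(x))
  tab <- table(pop_labels)
  if (any(tab < 2L)) stop("every population needs >= 2 samples", call. = FALSE)
  for (p in names(tab)) {
    rows <- pop_labels == p
    x[rows, ] <- apply(x[rows, , drop = FALSE], 2L, qnorm_transform)
  }
  x
}
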