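## LD-block segmentation, tiered discovery of independently associated SNPs
## (allelic heterogeneity), a forward-stepwise/BIC cross-check, and
## permutation-based FDR.

#' Segment a recombination map into LD blocks
#'
#' A new block starts after every inter-SNP interval whose recombination
#' rate is at or above `rate_threshold` (cM/Mb).
#'
#' @param map a [simulate_recomb_map()] result (or any list with
#'   `positions` and `rates`).
#' @param rate_threshold boundary rate in cM/Mb (> 0).
#' @return list of class `ld_block_map`: `block` (integer per SNP,
#'   ascending) and `boundaries` (positions of the boundary intervals).
#' @examples
#' m <- simulate_recomb_map(7, hotspot_every = 3)
#' ld_blocks(m, 0.9)$block
#' @export
ld_blocks <- function(map, rate_threshold = 0.9) {
  if (is.null(map$positions) || length(map$positions) == 0L) {
    stop("empty recombination map", call. = FALSE)
  }
  if (rate_threshold <= 0) stop("`rate_threshold` must be > 0", call. = FALSE)
  is_boundary <- map$rates >= rate_threshold
  block <- cumsum(c(1L, as.integer(is_boundary)))
  structure(list(block = block,
                 boundaries = which(is_boundary)),
            class = "ld_block_map")
}

#' Tiered scan for independently associated cis SNPs at one gene
#'
#' Two-step allelic-heterogeneity discovery: per probe cluster, the most
#' highly associated SNP (largest univariate log10 BF) in each LD block
#' within the cis window becomes a candidate; the best candidate is tier 1;
#' tiers 2..`max_tiers` are added greedily by the largest conditional
#' (multivariate) log10 BF given all previously accepted SNPs, each required
#' to lie in a block distinct from all accepted tiers and to exceed
#' `bf_floor`.  Records are unioned across probe clusters of the gene,
#' keeping the best record per SNP.  Ties for best-in-block break to the
#' lowest genomic coordinate.
#'
#' @param gene one row of a gene-model data.frame.
#' @param traits matrix (samples x probe clusters) of residual traits for
#'   this gene; a plain vector is treated as one cluster.
#' @param geno `genotype_matrix`.
#' @param blocks integer LD-block index per SNP of `geno`.
#' @param prior a [prior_grid()].
#' @param max_tiers maximum number of tiers (default 4).
#' @param bf_floor minimum log10 BF (univariate for tier 1, conditional for
#'   later tiers) for a record to be admitted.
#' @param gex mean expression level to record (per probe cluster, optional).
#' @return data.frame of eQTL records: `gene_id`, `probe_cluster`,
#'   `snp_id`, `pos`, `block`, `tier`, `ubf`, `mbf`, `beta`, `maf`, `gex`,
#'   `tss_dist`. Zero rows when nothing passes `bf_floor`.
#' @export
tier_scan <- function(gene, traits, geno, blocks, prior = prior_grid(),
                      max_tiers = 4L, bf_floor = 0, gex = NULL) {
  if (is.vector(traits)) traits <- matrix(traits, ncol = 1L,
                                          dimnames = list(NULL, "pc1"))
  if (is.null(colnames(traits))) {
    colnames(traits) <- paste0("pc", seq_len(ncol(traits)))
  }
  idx <- cis_snp_index(gene, geno)
  if (length(idx) == 0L) stop("gene has no cis SNPs", call. = FALSE)
  G <- geno$dosages[, idx, drop = FALSE]
  bl <- blocks[idx]
  pos <- geno$pos[idx]
  out <- list()
  for (pc in colnames(traits)) {
    y <- traits[, pc]
    ubf <- ubf_scan(y, G, prior)
    # best SNP per block, ties to the lowest coordinate (order is by
    # position already, which.max takes the first maximum)
    cand <- vapply(split(seq_along(idx), bl), function(ii)
      ii[which.max(ubf[ii])], integer(1L))
    cand <- cand[order(ubf[cand], decreasing = TRUE)]
    accepted <- integer(0)
    recs <- list()
    for (t in seq_len(min(max_tiers, length(cand)))) {
      remaining <- cand[!(bl[cand] %in% bl[accepted])]
      if (length(remaining) == 0L) break
      if (t == 1L) {
        pick <- remaining[1L]
        score <- ubf[pick]
        mbf <- score
      } else {
        # conditional BF = joint(accepted + j) - joint(accepted); the
        # reduced term is shared by every candidate
        reduced <- joint_log10bf(y, G[, accepted, drop = FALSE], prior)
        cond <- vapply(remaining, function(j) {
          joint_log10bf(y, G[, c(accepted, j), drop = FALSE], prior) -
            reduced
        }, numeric(1L))
        pick <- remaining[which.max(cond)]
        score <- max(cond)
        mbf <- score
      }
      if (score < bf_floor) break
      est <- effect_estimate(y, G[, pick])
      recs[[t]] <- data.frame(
        gene_id = gene$gene_id, probe_cluster = pc,
        snp_id = geno$snp_ids[idx[pick]], pos = pos[pick],
        block = bl[pick], tier = t, ubf = ubf[pick], mbf = mbf,
        beta = est$beta, maf = geno$maf[idx[pick]],
        gex = if (is.null(gex)) mean(y) else gex[[pc]],
        tss_dist = pos[pick] - gene$tss,
        stringsAsFactors = FALSE)
      accepted <- c(accepted, pick)
    }
    out[[pc]] <- if (length(recs)) do.call(rbind, recs) else NULL
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(gene_id = character(0), probe_cluster = character(0),
                      snp_id = character(0), pos = integer(0),
                      block = integer(0), tier = integer(0),
                      ubf = numeric(0), mbf = numeric(0), beta = numeric(0),
                      maf = numeric(0), gex = numeric(0),
                      tss_dist = numeric(0), stringsAsFactors = FALSE)
  } else {
    # union across probe clusters: keep the best (largest mbf) per SNP
    res <- res[order(-res$mbf), ]
    res <- res[!duplicated(res$snp_id), ]
    res <- res[order(res$tier, -res$mbf), ]
  }
  rownames(res) <- NULL
  res
}

#' Scan a whole study
#'
#' Runs [tier_scan()] for every gene and stacks the records.
#'
#' @param expr samples x genes matrix of residual traits (or a named list
#'   `gene_id -> samples x clusters` matrix for multi-probe genes).
#' @param geno `genotype_matrix`.
#' @param gene_models gene model data.frame.
#' @param blocks LD-block index per SNP.
#' @inheritParams tier_scan
#' @return an `eqtl_records` data.frame.
#' @export
scan_study <- function(expr, geno, gene_models, blocks,
                       prior = prior_grid(), max_tiers = 4L, bf_floor = 0) {
  recs <- lapply(seq_len(nrow(gene_models)), function(i) {
    gm <- gene_models[i, ]
    traits <- if (is.list(expr)) expr[[gm$gene_id]] else expr[, gm$gene_id]
    if (is.null(traits)) return(NULL)
    tier_scan(gm, traits, geno, blocks, prior, max_tiers, bf_floor)
  })
  out <- do.call(rbind, recs)
  class(out) <- c("eqtl_records", "data.frame")
  out
}

#' @export
print.eqtl_records <- function(x, ...) {
  cat(sprintf("eqtl_records: %d records, %d genes, tiers %s\n",
              nrow(x), length(unique(x$gene_id)),
              paste(sort(unique(x$tier)), collapse = "/")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Forward stepwise regression with BIC
#'
#' Greedy forward selection of cis SNPs for one trait: at each step the SNP
#' whose addition most improves the Bayesian Information Criterion enters
#' the model; selection stops when no SNP improves BIC.  Each SNP enters
#' with the same design used by the Bayesian association models — an
#' additive dosage term plus a dominance indicator — and is charged two
#' parameters in the BIC.
#'
#' @param y trait vector.
#' @param cis_genotypes dosage matrix (samples x SNPs), column names used as
#'   SNP identifiers.
#' @param dominance include the per-SNP dominance column (default TRUE,
#'   matching the association model family).
#' @return integer vector of selected column indices, in selection order
#'   (possibly empty).
#' @export
forward_stepwise_bic <- function(y, cis_genotypes, dominance = TRUE) {
  G <- as.matrix(cis_genotypes)
  if (ncol(G) < 1L) stop("need at least one cis SNP", call. = FALSE)
  n <- length(y)
  Dm <- if (dominance) {
    matrix(dominance_indicator(G), nrow = n)
  } else NULL
  per_snp <- if (dominance) 2L else 1L
  selected <- integer(0)
  # BIC of gaussian lm: n*log(RSS/n) + k*log(n) (+ const)
  bic_of <- function(cols) {
    X <- cbind(1, G[, cols, drop = FALSE],
               if (dominance) Dm[, cols, drop = FALSE])
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    n * log(rss / n) + (per_snp * length(cols) + 1L) * log(n)
  }
  current <- bic_of(integer(0))
  repeat {
    rest <- setdiff(seq_len(ncol(G)), selected)
    if (length(rest) == 0L) break
    bics <- vapply(rest, function(j) bic_of(c(selected, j)), numeric(1L))
    best <- which.min(bics)
    if (bics[best] >= current) break
    selected <- c(selected, rest[best])
    current <- bics[best]
  }
  selected
}

#' Permutation-based FDR for tiered eQTL discovery
#'
#' One shared sample permutation is applied to the whole expression matrix
#' (identically across genes), the full tiered scan is re-run, and per tier
#' the FDR at each log10 BF cutoff `c` is estimated as
#' `min(1, N_perm(c) / N_obs(c))`, then monotonized to be non-increasing in
#' `c`.  A permuted count of zero is floored at one before the ratio — a
#' single permutation cannot certify an FDR below its own resolution, so
#' the tail estimate stays conservative.  With `n_perm > 1`, permuted
#' counts are averaged over permutations.
#'
#' @inheritParams scan_study
#' @param seed integer seed for the permutation(s).
#' @param n_perm number of permutations (default 1).
#' @param cutoffs log10 BF cutoff grid; defaults to `seq(0, 10, 0.25)`.
#' @param observed optional precomputed observed `eqtl_records` (from
#'   [scan_study()] with `bf_floor = 0`); computed when missing.
#' @return an object of class `fdr_table`: data.frame with `tier`,
#'   `cutoff`, `n_obs`, `n_perm`, `fdr`, plus the observed records in
#'   `attr(, "observed")`.
#' @export
permutation_fdr <- function(expr, geno, gene_models, blocks,
                            prior = prior_grid(), seed = 1L, n_perm = 1L,
                            max_tiers = 4L, cutoffs = seq(0, 10, 0.25),
                            observed = NULL) {
  if (n_perm < 1L) stop("`n_perm` must be >= 1", call. = FALSE)
  if (is.null(observed)) {
    observed <- scan_study(expr, geno, gene_models, blocks, prior,
                           max_tiers, bf_floor = 0)
  }
  n <- nrow(if (is.list(expr)) expr[[1]] else expr)
  perm_counts <- with_seed(seed, {
    counts <- 0
    for (p in seq_len(n_perm)) {
      ord <- sample.int(n)
      pexpr <- if (is.list(expr)) {
        lapply(expr, function(m) m[ord, , drop = FALSE])
      } else {
        expr[ord, , drop = FALSE]
      }
      prec <- scan_study(pexpr, geno, gene_models, blocks, prior,
                         max_tiers, bf_floor = 0)
      counts <- counts + count_by_cutoff(prec, cutoffs)
    }
    counts / n_perm
  })
  obs_counts <- count_by_cutoff(observed, cutoffs)
  tiers <- sort(unique(observed$tier))
  tab <- do.call(rbind, lapply(tiers, function(t) {
    n_obs <- obs_counts[as.character(t), ]
    n_prm <- if (as.character(t) %in% rownames(perm_counts)) {
      perm_counts[as.character(t), ]
    } else rep(0, length(cutoffs))
    # conservative: a permuted count of zero is floored at one — the
    # estimate cannot resolve FDRs below the permutation's resolution
    fdr <- ifelse(n_obs > 0, pmin(1, pmax(n_prm, 1) / n_obs), 1)
    # monotonize (non-increasing in the cutoff), but cutoffs with no
    # observed associations stay at the undefined-as-1 convention
    fdr <- cummin(fdr)
    fdr[n_obs == 0] <- 1
    data.frame(tier = t, cutoff = cutoffs, n_obs = as.numeric(n_obs),
               n_perm = as.numeric(n_prm), fdr = fdr)
  }))
  structure(tab, class = c("fdr_table", "data.frame"), observed = observed)
}

## Records with BF >= cutoff, tabulated per tier; tier 1 is judged on the
## univariate BF, later tiers on the conditional BF.
count_by_cutoff <- function(records, cutoffs) {
  tiers <- sort(unique(records$tier))
  if (length(tiers) == 0L) tiers <- 1L
  out <- matrix(0, nrow = length(tiers), ncol = length(cutoffs),
                dimnames = list(as.character(tiers), NULL))
  for (t in tiers) {
    score <- ifelse(records$tier == t,
                    ifelse(records$tier == 1L, records$ubf, records$mbf),
                    NA_real_)
    score <- score[records$tier == t]
    out[as.character(t), ] <- vapply(cutoffs, function(c.)
      sum(score >= c.), numeric(1L))
  }
  out
}

#' log10 BF cutoff achieving a target FDR
#'
#' The smallest cutoff in the table whose (monotonized) FDR estimate is at
#' or below `target`; `Inf` when the target is never reached.
#'
#' @param tab an `fdr_table`.
#' @param tier tier to look up.
#' @param target target FDR (default 0.10).
#' @return numeric cutoff (possibly `Inf`).
#' @export
fdr_cutoff <- function(tab, tier = 1L, target = 0.10) {
  tt <- tab[tab$tier == tier & tab$fdr <= target & tab$n_obs > 0, ]
  if (nrow(tt) == 0L) return(Inf)
  min(tt$cutoff)
}

#' @export
print.fdr_table <- function(x, ...) {
  cat("Permutation FDR table\n")
  for (t in sort(unique(x$tier))) {
    cat(sprintf("  tier %d: FDR-10%% cutoff = %s\n", t,
                format(fdr_cutoff(x, t, 0.10))))
  }
  invisible(x)
}
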