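## Synthetic study generator.
##
## Emits genotypes with LD-block structure, expression traits with planted
## tiered cis-eQTLs and latent confounders across two "cell types", CRE
## interval tracks that are partly cell-type specific and enriched (or
## depleted) around planted causal SNPs, and a machine-readable truth table
## used by the recovery tests.  All draws are governed by explicit seeds and
## never touch the caller's RNG stream.

#' Simulate a recombination map with periodic hotspots
#'
#' SNP positions are evenly spaced; every `hotspot_every`-th inter-SNP
#' interval carries `hotspot_rate` (cM/Mb), all others `background_rate`.
#' Intervals at or above the LD-block rate threshold later become block
#' boundaries.
#'
#' @param n_snps number of SNPs (>= 2).
#' @param spacing inter-SNP spacing in bp (> 0).
#' @param hotspot_every place a hotspot at every this-many-th interval.
#' @param hotspot_rate recombination rate at hotspots, cM/Mb.
#' @param background_rate rate elsewhere, cM/Mb (>= 0).
#' @param chromosome chromosome name.
#' @param offset 0-based position of the first SNP.
#' @return an object of class `recomb_map`: list with `chromosome`,
#'   `positions` (0-based, strictly increasing) and `rates`
#'   (length `n_snps - 1`).
#' @export
simulate_recomb_map <- function(n_snps, spacing = 2000L, hotspot_every = 10L,
                                hotspot_rate = 2.0, background_rate = 0.1,
                                chromosome = "chr1", offset = 0L) {
  if (n_snps < 2) stop("`n_snps` must be >= 2", call. = FALSE)
  if (spacing <= 0) stop("`spacing` must be positive", call. = FALSE)
  if (background_rate < 0 || hotspot_rate < 0) {
    stop("rates must be non-negative", call. = FALSE)
  }
  positions <- offset + spacing * seq_len(n_snps)
  rates <- rep(background_rate, n_snps - 1L)
  idx <- seq_along(rates)
  rates[idx %% hotspot_every == 0L] <- hotspot_rate
  structure(list(chromosome = chromosome, positions = positions,
                 rates = rates),
            class = "recomb_map")
}

#' Simulate dosage genotypes with block-exchangeable LD
#'
#' Haplotypes are drawn per LD block by comonotone copying: within a block,
#' each haplotype carries a shared latent uniform; each SNP's allele is the
#' thresholded shared uniform with probability `theta = within_block_r2^(1/4)`
#' and an independent draw otherwise.  For SNPs of equal MAF this yields a
#' pairwise dosage correlation of `theta^2 = sqrt(within_block_r2)`, i.e.
#' r-squared approximately `within_block_r2`; blocks are independent.
#' Dosages are the sums of two haplotypes and recoded so the counted allele
#' is the minor one.
#'
#' @param n_samples number of individuals (> 0).
#' @param map a [simulate_recomb_map()] result.
#' @param maf_range `(low, high)` with `0 < low <= high <= 0.5`; per-SNP MAFs
#'   are drawn uniformly on this range.
#' @param within_block_r2 target within-block r-squared in `[0, 1]`.
#' @param seed integer seed.
#' @param rate_threshold cM/Mb rate at which an interval becomes a block
#'   boundary.
#' @param max_retries resampling attempts for SNPs that come out
#'   monomorphic.
#' @return an object of class `genotype_matrix`: list with `sample_ids`,
#'   `snp_ids`, `chrom`, `pos`, `major`, `minor`, `maf`, and the
#'   `n_samples x n_snps` matrix `dosages` (values in `[0, 2]`).
#' @export
simulate_genotypes <- function(n_samples, map, maf_range = c(0.05, 0.5),
                               within_block_r2 = 0.8, seed = 1L,
                               rate_threshold = 0.9, max_retries = 10L) {
  if (n_samples <= 0) stop("`n_samples` must be positive", call. = FALSE)
  if (!inherits(map, "recomb_map")) stop("`map` must be a recomb_map", call. = FALSE)
  lo <- maf_range[1]; hi <- maf_range[2]
  if (!(lo > 0 && lo <= hi && hi <= 0.5)) {
    stop("`maf_range` must satisfy 0 < low <= high <= 0.5", call. = FALSE)
  }
  stopifnot_scalar(within_block_r2, "within_block_r2", 0, 1)
  p <- length(map$positions)
  blocks <- ld_blocks(map, rate_threshold)$block
  theta <- within_block_r2^(1 / 4)
  nh <- 2L * n_samples

  with_seed(seed, {
    mafs <- runif(p, lo, hi)
    draw_snp <- function(j, u_block) {
      copy <- runif(nh) < theta
      ifelse(copy, u_block < mafs[j], runif(nh) < mafs[j])
    }
    hap <- matrix(0L, nrow = nh, ncol = p)
    for (b in unique(blocks)) {
      idx <- which(blocks == b)
      u <- runif(nh)
      for (j in idx) hap[, j] <- draw_snp(j, u)
    }
    dos <- hap[seq_len(n_samples), , drop = FALSE] +
      hap[n_samples + seq_len(n_samples), , drop = FALSE]
    for (j in seq_len(p)) {
      tries <- 0L
      while (stats::var(dos[, j]) == 0 && tries < max_retries) {
        a <- draw_snp(j, runif(nh))
        dos[, j] <- a[seq_len(n_samples)] + a[n_samples + seq_len(n_samples)]
        tries <- tries + 1L
      }
      if (stats::var(dos[, j]) == 0) {
        stop(sprintf("SNP %d monomorphic after %d retries", j, max_retries),
             call. = FALSE)
      }
    }
    freq <- colMeans(dos) / 2
    flip <- freq > 0.5
    dos[, flip] <- 2 - dos[, flip]
    major <- ifelse(flip, "G", "A")
    minor <- ifelse(flip, "A", "G")
    snp_ids <- sprintf("%s_snp%04d", map$chromosome, seq_len(p))
    sample_ids <- sprintf("s%04d", seq_len(n_samples))
    dimnames(dos) <- list(sample_ids, snp_ids)
    structure(list(sample_ids = sample_ids, snp_ids = snp_ids,
                   chrom = rep(map$chromosome, p), pos = map$positions,
                   major = major, minor = minor,
                   maf = colMeans(dos) / 2, dosages = dos),
              class = "genotype_matrix")
  })
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs on %s, MAF %.3f-%.3f\n",
              nrow(x$dosages), ncol(x$dosages), x$chrom[1],
              min(x$maf), max(x$maf)))
  invisible(x)
}

## Bind several per-chromosome genotype matrices into one.
bind_genotypes <- function(gts) {
  dos <- do.call(cbind, lapply(gts, `[[`, "dosages"))
  structure(list(sample_ids = gts[[1]]$sample_ids,
                 snp_ids = unlist(lapply(gts, `[[`, "snp_ids")),
                 chrom = unlist(lapply(gts, `[[`, "chrom")),
                 pos = unlist(lapply(gts, `[[`, "pos")),
                 major = unlist(lapply(gts, `[[`, "major")),
                 minor = unlist(lapply(gts, `[[`, "minor")),
                 maf = unlist(lapply(gts, `[[`, "maf")),
                 dosages = dos),
            class = "genotype_matrix")
}

#' Lay out synthetic gene models
#'
#' Genes are tiled along chromosomes with alternating strand.  The TSS is
#' `start` on the plus strand and `end` on the minus strand; the cis window
#' used downstream is TSS/TES plus/minus 1 Mb.
#'
#' @param n_genes number of genes.
#' @param genes_per_chrom genes placed per chromosome.
#' @param gene_spacing distance between consecutive gene starts, bp.
#' @param gene_length gene body length, bp.
#' @param first_start 0-based start of the first gene on each chromosome.
#' @return data.frame with `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `tss`, `tes`.
#' @export
simulate_gene_models <- function(n_genes, genes_per_chrom = 25L,
                                 gene_spacing = 1200000L,
                                 gene_length = 20000L,
                                 first_start = 150000L) {
  if (n_genes < 1) stop("`n_genes` must be >= 1", call. = FALSE)
  chrom_i <- (seq_len(n_genes) - 1L) %/% genes_per_chrom + 1L
  within <- (seq_len(n_genes) - 1L) %% genes_per_chrom
  start <- first_start + within * gene_spacing
  end <- start + gene_length
  strand <- ifelse(seq_len(n_genes) %% 2L == 1L, "+", "-")
  data.frame(gene_id = sprintf("gene%04d", seq_len(n_genes)),
             chrom = paste0("chr", chrom_i),
             strand = strand, start = start, end = end,
             tss = ifelse(strand == "+", start, end),
             tes = ifelse(strand == "+", end, start),
             stringsAsFactors = FALSE)
}

#' Build recombination maps with a SNP cluster at every gene
#'
#' Places `snps_per_gene` evenly spaced SNPs centred on each gene body and
#' concatenates the clusters into one map per chromosome.  Within a
#' cluster, every `hotspot_every`-th interval is a hotspot; the gaps
#' between clusters always carry `hotspot_rate`, so SNPs of different
#' genes never share an LD block.
#'
#' @inheritParams simulate_recomb_map
#' @param gene_models a [simulate_gene_models()] data.frame.
#' @param snps_per_gene SNPs per gene cluster (>= 2).
#' @return named list of `recomb_map` objects, one per chromosome.
#' @export
simulate_gene_snp_maps <- function(gene_models, snps_per_gene = 50L,
                                   spacing = 2000L, hotspot_every = 10L,
                                   hotspot_rate = 2.0,
                                   background_rate = 0.1) {
  if (snps_per_gene < 2L) stop("`snps_per_gene` must be >= 2", call. = FALSE)
  chroms <- unique(gene_models$chrom)
  maps <- lapply(chroms, function(ch) {
    gms <- gene_models[gene_models$chrom == ch, ]
    gms <- gms[order(gms$start), ]
    pos <- integer(0)
    rates <- numeric(0)
    for (i in seq_len(nrow(gms))) {
      mid <- (gms$start[i] + gms$end[i]) %/% 2L
      p <- mid - (snps_per_gene %/% 2L) * spacing +
        spacing * seq_len(snps_per_gene)
      r <- rep(background_rate, snps_per_gene - 1L)
      idx <- seq_along(r)
      r[idx %% hotspot_every == 0L] <- hotspot_rate
      if (length(pos) > 0L) rates <- c(rates, hotspot_rate)  # gap boundary
      pos <- c(pos, p)
      rates <- c(rates, r)
    }
    if (any(diff(pos) <= 0)) {
      stop("gene clusters overlap; increase gene spacing or reduce the ",
           "SNP cluster span", call. = FALSE)
    }
    structure(list(chromosome = ch, positions = pos, rates = rates),
              class = "recomb_map")
  })
  names(maps) <- chroms
  maps
}

#' LD blocks across several per-chromosome maps
#'
#' Concatenates per-chromosome block indices with offsets so block ids are
#' globally unique (blocks never span chromosomes).
#'
#' @param maps named list of `recomb_map` objects.
#' @param rate_threshold cM/Mb boundary threshold.
#' @return integer vector of block indices, ordered as the maps' SNPs.
#' @export
combined_ld_blocks <- function(maps, rate_threshold = 0.9) {
  per <- lapply(maps, function(m) ld_blocks(m, rate_threshold)$block)
  offs <- cumsum(c(0, utils::head(vapply(per, max, numeric(1)), -1L)))
  unlist(mapply(`+`, per, offs, SIMPLIFY = FALSE), use.names = FALSE)
}

## The cis window: [min(tss, tes) - 1 Mb, max(tss, tes) + 1 Mb].
cis_window <- function(gene, size = 1e6) {
  c(min(gene$tss, gene$tes) - size, max(gene$tss, gene$tes) + size)
}

## Index of SNPs cis to a gene row.
cis_snp_index <- function(gene, geno, size = 1e6) {
  w <- cis_window(gene, size)
  which(geno$chrom == gene$chrom & geno$pos >= w[1] & geno$pos <= w[2])
}

#' Plant tiered, class-labelled eQTLs
#'
#' Chooses causal SNPs for a set of genes: the tier-1 SNP from one LD block
#' near the TSS, additional tiers from distinct blocks, with a bivariate
#' class drawn for each gene (applied to all its tiers).
#'
#' @param gene_models output of [simulate_gene_models()].
#' @param geno a `genotype_matrix` covering the genes' chromosomes.
#' @param blocks integer vector: LD-block index per SNP of `geno`
#'   (see [ld_blocks()]; block indices must be comparable within a
#'   chromosome).
#' @param genes gene ids to receive an eQTL (default: all).
#' @param n_tiers tiers planted per gene (1-4).
#' @param beta additive effect per dosage, in trait-SD units; recycled
#'   across genes.
#' @param classes bivariate class per gene, recycled; one of `"stable"`,
#'   `"A-not-B"`, `"B-not-A"`, `"A-and-B"`, `"A-opposite-B"`.
#' @param seed integer seed.
#' @return a `planted_truth` data.frame: `gene_id`, `snp_id`, `tier`,
#'   `beta`, `class`, `cell_types`.
#' @export
plant_eqtls <- function(gene_models, geno, blocks, genes = gene_models$gene_id,
                        n_tiers = 1L, beta = 0.5, classes = "stable",
                        seed = 1L) {
  stopifnot(n_tiers >= 1L, n_tiers <= 4L)
  rows <- with_seed(seed, {
    out <- list()
    beta <- rep_len(beta, length(genes))
    classes <- rep_len(classes, length(genes))
    for (i in seq_along(genes)) {
      gm <- gene_models[gene_models$gene_id == genes[i], ]
      idx <- cis_snp_index(gm, geno)
      if (length(idx) == 0L) {
        stop(sprintf("gene %s has no cis SNPs", genes[i]), call. = FALSE)
      }
      # prefer SNPs near the TSS so tiers sit in nearby but distinct blocks
      ord <- idx[order(abs(geno$pos[idx] - gm$tss))]
      bl <- blocks[ord]
      chosen <- integer(0)
      used_blocks <- integer(0)
      for (t in seq_len(n_tiers)) {
        cand <- ord[!(bl %in% used_blocks)]
        if (length(cand) == 0L) break
        pick <- sample(cand[seq_len(min(5L, length(cand)))], 1L)
        chosen <- c(chosen, pick)
        used_blocks <- c(used_blocks, blocks[pick])
        bl <- blocks[ord]
      }
      out[[i]] <- data.frame(gene_id = genes[i],
                             snp_id = geno$snp_ids[chosen],
                             tier = seq_along(chosen),
                             beta = beta[i], class = classes[i],
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  rows$cell_types <- c("stable" = "A+B", "A-not-B" = "A", "B-not-A" = "B",
                       "A-and-B" = "A+B", "A-opposite-B" = "A+B")[rows$class]
  class(rows) <- c("planted_truth", "data.frame")
  rows
}

#' Effect size achieving a target cis heritability
#'
#' Returns the additive effect per dosage such that the SNP explains a
#' fraction `r2` of the trait variance, given the dosage variance and the
#' non-genetic variance (noise plus confounders).
#'
#' @param r2 target proportion of variance explained, in `[0, 1)`.
#' @param var_g dosage variance of the causal SNP.
#' @param other_var total non-genetic variance (default 1).
#' @return numeric effect size.
#' @export
beta_for_r2 <- function(r2, var_g, other_var = 1) {
  stopifnot_scalar(r2, "r2", 0, 1 - 1e-12)
  sqrt(r2 / (1 - r2) * other_var / var_g)
}

## Per-cell-type effect sizes implied by a bivariate class.
class_betas <- function(class, beta) {
  switch(class,
         "stable" = c(A = beta, B = beta),
         "A-not-B" = c(A = beta, B = 0),
         "B-not-A" = c(A = 0, B = beta),
         "A-and-B" = c(A = beta, B = beta / 2),
         "A-opposite-B" = c(A = beta, B = -beta),
         stop("unknown bivariate class: ", class, call. = FALSE))
}

#' Simulate expression traits with planted eQTLs and confounders
#'
#' Each trait is `sum(beta_t * dosage_t) + confounder loadings + Gaussian
#' noise`, with per-cell-type betas realized literally from the planted
#' bivariate class (A-not-B: `beta_B = 0`; A-opposite-B: `beta_B = -beta_A`;
#' stable: `beta_A = beta_B`; A-and-B: `beta_B = beta_A / 2`).  Latent
#' confounders are sample-level Gaussian factors with Gaussian loadings
#' shared across genes, so principal-component removal can recover them.
#'
#' @param genotypes_by_celltype named list of `genotype_matrix` objects
#'   (one per cell type; may be the same object for paired designs).
#' @param gene_models gene model data.frame.
#' @param eqtl_plan a `planted_truth` data.frame from [plant_eqtls()], or
#'   `NULL` for an all-null simulation.
#' @param n_confounders number of latent factors.
#' @param confounder_var_frac total variance contributed by the factors, in
#'   units of the (unit) noise variance.
#' @param noise_sd residual noise SD.
#' @param seed integer seed.
#' @return list with `expression` (named list of samples x genes matrices)
#'   and `truth` (the plan, annotated with realized per-cell-type betas).
#' @export
simulate_expression <- function(genotypes_by_celltype, gene_models,
                                eqtl_plan = NULL, n_confounders = 3L,
                                confounder_var_frac = 0.2, noise_sd = 1,
                                seed = 1L) {
  cts <- names(genotypes_by_celltype)
  if (is.null(cts) || any(cts == "")) {
    stop("`genotypes_by_celltype` must be a named list", call. = FALSE)
  }
  if (!is.null(eqtl_plan)) {
    for (r in seq_len(nrow(eqtl_plan))) {
      gm <- gene_models[gene_models$gene_id == eqtl_plan$gene_id[r], ]
      g0 <- genotypes_by_celltype[[1]]
      j <- match(eqtl_plan$snp_id[r], g0$snp_ids)
      if (is.na(j)) stop("planted SNP not found: ", eqtl_plan$snp_id[r],
                         call. = FALSE)
      w <- cis_window(gm)
      if (g0$chrom[j] != gm$chrom || g0$pos[j] < w[1] || g0$pos[j] > w[2]) {
        stop(sprintf("planted SNP %s outside cis window of %s",
                     eqtl_plan$snp_id[r], eqtl_plan$gene_id[r]),
             call. = FALSE)
      }
    }
  }
  ng <- nrow(gene_models)
  with_seed(seed, {
    # loadings shared across cell types so confounders are study-level
    lambda <- matrix(rnorm(ng * n_confounders,
                           sd = if (n_confounders > 0)
                             sqrt(confounder_var_frac / max(1, n_confounders))
                           else 0),
                     nrow = ng)
    expr <- lapply(cts, function(ct) {
      geno <- genotypes_by_celltype[[ct]]
      n <- nrow(geno$dosages)
      Fmat <- matrix(rnorm(n * n_confounders), nrow = n)
      Y <- matrix(rnorm(n * ng, sd = noise_sd), nrow = n)
      if (n_confounders > 0) Y <- Y + Fmat %*% t(lambda)
      colnames(Y) <- gene_models$gene_id
      rownames(Y) <- geno$sample_ids
      if (!is.null(eqtl_plan)) {
        # cell types named "A"/"B" map to the planted classes directly;
        # other labels map by position
        suffix <- if (ct %in% c("A", "B")) ct else {
          if (ct == cts[1]) "A" else "B"
        }
        for (r in seq_len(nrow(eqtl_plan))) {
          b <- class_betas(eqtl_plan$class[r], eqtl_plan$beta[r])[[suffix]]
          if (b != 0) {
            j <- match(eqtl_plan$snp_id[r], geno$snp_ids)
            Y[, eqtl_plan$gene_id[r]] <- Y[, eqtl_plan$gene_id[r]] +
              b * geno$dosages[, j]
          }
        }
      }
      Y
    })
    names(expr) <- cts
    truth <- eqtl_plan
    if (!is.null(truth)) {
      truth$beta_A <- vapply(seq_len(nrow(truth)), function(r)
        class_betas(truth$class[r], truth$beta[r])[["A"]], numeric(1))
      truth$beta_B <- vapply(seq_len(nrow(truth)), function(r)
        class_betas(truth$class[r], truth$beta[r])[["B"]], numeric(1))
    }
    list(expression = expr, truth = truth)
  })
}

#' Simulate cell-type-labelled CRE tracks
#'
#' Background intervals are placed uniformly along each chromosome at a
#' density giving a SNP-coverage rate of about `background_rate` (with the
#' 500 bp overlap padding applied downstream).  A fraction
#' `specific_fraction` of background intervals exist in exactly one cell
#' type; the rest are shared.  Activating intervals additionally cover each
#' planted causal SNP of the matched cell type(s) with probability
#' `eqtl_enrichment * background_rate`; repressive intervals cover causal
#' SNPs at `background_rate / eqtl_enrichment` (depletion); the insulator
#' (CTCF-like) track is neutral background.  Background intervals of the
#' activating and repressive classes avoid causal SNPs so the planted
#' enrichment is exact.
#'
#' @param gene_models gene models (used for the genome span; must be
#'   non-empty).
#' @param celltypes character vector of cell-type labels.
#' @param truth `planted_truth` (may be NULL: pure background tracks).
#' @param snp_map data.frame `snp_id`, `chrom`, `pos` for causal placement.
#' @param classes CRE classes to emit.
#' @param specific_fraction fraction of background intervals specific to one
#'   cell type, in `[0, 1]`.
#' @param eqtl_enrichment fold enrichment of activating coverage at causal
#'   SNPs (>= 1).
#' @param background_rate baseline SNP coverage probability.
#' @param width interval width, bp.
#' @param seed integer seed.
#' @return list with `tracks` (data.frame `track_id`, `cell_type`, `class`,
#'   `chrom`, `start`, `end`, 0-based half-open) and `truth` with
#'   `in_activating` / `in_repressive` membership flags added.
#' @export
simulate_cre_tracks <- function(gene_models, celltypes, truth = NULL,
                                snp_map = NULL,
                                classes = c("activating", "repressive",
                                            "insulator"),
                                specific_fraction = 0.3, eqtl_enrichment = 3,
                                background_rate = 0.15, width = 1000L,
                                seed = 1L) {
  if (is.null(gene_models) || nrow(gene_models) == 0L) {
    stop("empty gene set", call. = FALSE)
  }
  stopifnot_scalar(specific_fraction, "specific_fraction", 0, 1)
  if (eqtl_enrichment < 1) stop("`eqtl_enrichment` must be >= 1", call. = FALSE)

  causal <- NULL
  if (!is.null(truth) && nrow(truth) > 0L) {
    if (is.null(snp_map)) stop("`snp_map` required when truth is given",
                               call. = FALSE)
    m <- match(truth$snp_id, snp_map$snp_id)
    causal <- data.frame(chrom = snp_map$chrom[m], pos = snp_map$pos[m],
                         cell_types = truth$cell_types,
                         stringsAsFactors = FALSE)
  }

  chroms <- unique(gene_models$chrom)
  spans <- vapply(chroms, function(ch)
    max(gene_models$end[gene_models$chrom == ch]) + 1e6, numeric(1))

  with_seed(seed, {
    rows <- list()
    flags <- list()
    for (cls in classes) {
      # baseline intervals; exclusion zone around causal SNPs for the
      # classes whose causal coverage is planted explicitly
      excl_pad <- width + 600L
      for (ci in seq_along(chroms)) {
        ch <- chroms[ci]
        n_bg <- round(background_rate * spans[ci] / width)
        starts <- sort(round(runif(n_bg, 0, spans[ci] - width)))
        if (!is.null(causal) && cls %in% c("activating", "repressive")) {
          cc <- causal[causal$chrom == ch, ]
          if (nrow(cc) > 0L) {
            bad <- vapply(starts, function(s)
              any(cc$pos >= s - excl_pad & cc$pos < s + width + excl_pad),
              logical(1L))
            starts <- starts[!bad]
          }
        }
        if (length(starts) > 0L) {
          spec <- runif(length(starts)) < specific_fraction
          own_ct <- sample(celltypes, length(starts), replace = TRUE)
          for (k in seq_along(starts)) {
            cts_here <- if (spec[k]) own_ct[k] else celltypes
            rows[[length(rows) + 1L]] <- data.frame(
              cell_type = cts_here, class = cls, chrom = ch,
              start = starts[k], end = starts[k] + width,
              stringsAsFactors = FALSE)
          }
        }
      }
      # planted coverage at causal SNPs
      if (!is.null(causal) && cls %in% c("activating", "repressive")) {
        p_cov <- if (cls == "activating") {
          min(1, eqtl_enrichment * background_rate)
        } else {
          background_rate / eqtl_enrichment
        }
        hit <- runif(nrow(causal)) < p_cov
        flags[[cls]] <- hit
        for (k in which(hit)) {
          cts_here <- if (specific_fraction == 0) {
            celltypes
          } else {
            matched <- strsplit(causal$cell_types[k], "+", fixed = TRUE)[[1]]
            cts <- celltypes[seq_along(celltypes) %in%
                               match(matched, c("A", "B"))]
            if (length(cts) == 0L) celltypes else cts
          }
          s <- causal$pos[k] - sample(seq_len(width - 1L), 1L)
          rows[[length(rows) + 1L]] <- data.frame(
            cell_type = cts_here, class = cls, chrom = causal$chrom[k],
            start = s, end = s + width, stringsAsFactors = FALSE)
        }
      }
    }
    tracks <- do.call(rbind, rows)
    tracks$track_id <- paste(tracks$class, tracks$cell_type, sep = "_")
    tracks <- tracks[order(tracks$track_id, tracks$chrom, tracks$start),
                     c("track_id", "cell_type", "class", "chrom",
                       "start", "end")]
    rownames(tracks) <- NULL
    if (!is.null(truth)) {
      truth$in_activating <- if (!is.null(flags$activating))
        flags$activating else FALSE
      truth$in_repressive <- if (!is.null(flags$repressive))
        flags$repressive else FALSE
    }
    list(tracks = tracks, truth = truth)
  })
}

#' Simulate a GWAS SNP list
#'
#' Draws SNP positions either inside a given track's intervals (emulating
#' GWAS hits that sit in matched-cell-type regulatory elements) or uniformly
#' over the genome span.
#'
#' @param tracks CRE tracks data.frame.
#' @param n number of SNPs.
#' @param inside_track track_id to sample inside, or `NULL` for uniform
#'   background positions.
#' @param gene_models used for the genome span when `inside_track` is NULL.
#' @param seed integer seed.
#' @return data.frame `snp_id`, `chrom`, `pos`.
#' @export
simulate_gwas_snps <- function(tracks, n, inside_track = NULL,
                               gene_models = NULL, seed = 1L) {
  with_seed(seed, {
    if (!is.null(inside_track)) {
      tt <- tracks[tracks$track_id == inside_track, ]
      if (nrow(tt) == 0L) stop("no intervals in track ", inside_track,
                               call. = FALSE)
      pick <- sample(nrow(tt), n, replace = TRUE)
      pos <- tt$start[pick] +
        floor(runif(n) * (tt$end[pick] - tt$start[pick]))
      data.frame(snp_id = sprintf("gwas%04d", seq_len(n)),
                 chrom = tt$chrom[pick], pos = as.integer(pos),
                 stringsAsFactors = FALSE)
    } else {
      chroms <- unique(gene_models$chrom)
      ch <- sample(chroms, n, replace = TRUE)
      span <- vapply(ch, function(c.)
        max(gene_models$end[gene_models$chrom == c.]) + 1e6, numeric(1))
      data.frame(snp_id = sprintf("gwas%04d", seq_len(n)),
                 chrom = ch, pos = as.integer(floor(runif(n) * span)),
                 stringsAsFactors = FALSE)
    }
  })
}
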