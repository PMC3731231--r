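## Interval machinery: CRE track handling, padded SNP-CRE overlap,
## intervening-insulator logic, background SNP sets and SNP pairs.
##
## All coordinates are 0-based half-open (BED convention); SNPs are points
## at their 0-based position.  IRanges does the heavy lifting internally
## (converted to 1-based closed at the boundary of each helper).

## internal: data.frame intervals -> IRanges per chromosome (list).
as_iranges_by_chrom <- function(iv) {
  split_idx <- split(seq_len(nrow(iv)), iv$chrom)
  lapply(split_idx, function(ii)
    IRanges::IRanges(start = iv$start[ii] + 1L, end = iv$end[ii]))
}

#' Merge replicate interval tracks
#'
#' Takes the union of intervals sharing a track id; intervals that touch at
#' a shared half-open boundary (`[a,b)`, `[b,c)`) merge into one.
#'
#' @param tracks data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `track_id`, `cell_type`, `class`.
#' @return data.frame of the same shape with disjoint sorted intervals.
#' @export
merge_replicates <- function(tracks) {
  if (any(tracks$start >= tracks$end)) {
    stop("malformed interval: start >= end", call. = FALSE)
  }
  keys <- if ("track_id" %in% names(tracks)) tracks$track_id else ""
  out <- lapply(unique(keys), function(k) {
    tt <- tracks[keys == k, , drop = FALSE]
    per_chrom <- lapply(unique(tt$chrom), function(ch) {
      sub <- tt[tt$chrom == ch, ]
      ir <- IRanges::reduce(IRanges::IRanges(sub$start + 1L, sub$end))
      df <- data.frame(chrom = ch, start = IRanges::start(ir) - 1L,
                       end = IRanges::end(ir), stringsAsFactors = FALSE)
      if ("track_id" %in% names(tracks)) df$track_id <- k
      for (col in intersect(c("cell_type", "class"), names(tracks))) {
        df[[col]] <- sub[[col]][1L]
      }
      df
    })
    do.call(rbind, per_chrom)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Padded SNP-interval overlap
#'
#' A SNP overlaps a track when its position lies in `[start - pad,
#' end + pad)` for some interval: containment, or within `pad` bp of an
#' element boundary.
#'
#' @param snps data.frame with `chrom`, `pos` (0-based points).
#' @param track data.frame of intervals (`chrom`, `start`, `end`).
#' @param pad boundary padding in bp (default 500, >= 0).
#' @return logical vector, one entry per SNP row.
#' @export
snp_overlaps <- function(snps, track, pad = 500L) {
  if (pad < 0) stop("`pad` must be >= 0", call. = FALSE)
  out <- logical(nrow(snps))
  if (nrow(track) == 0L) return(out)
  padded <- data.frame(chrom = track$chrom,
                       start = track$start - pad, end = track$end + pad)
  ir_by_chrom <- as_iranges_by_chrom(padded)
  for (ch in unique(snps$chrom)) {
    rows <- which(snps$chrom == ch)
    ir <- ir_by_chrom[[ch]]
    if (is.null(ir)) next
    pts <- IRanges::IRanges(snps$pos[rows] + 1L, snps$pos[rows] + 1L)
    out[rows] <- IRanges::overlapsAny(pts, ir)
  }
  out
}

#' Intervening-insulator test
#'
#' TRUE when the midpoint `floor((start + end)/2)` of some insulator
#' interval lies strictly between the SNP and the TSS.  A degenerate span
#' (`snp == tss`) is FALSE by convention.
#'
#' @param snp_pos SNP position (0-based).
#' @param tss_pos TSS position (0-based).
#' @param insulator data.frame of intervals on the same chromosome
#'   (`start`, `end`; a `chrom` column, if present, must already be
#'   filtered to the SNP's chromosome).
#' @return logical scalar.
#' @export
intervening_insulator <- function(snp_pos, tss_pos, insulator) {
  if (snp_pos == tss_pos) return(FALSE)
  if (nrow(insulator) == 0L) return(FALSE)
  mids <- floor((insulator$start + insulator$end) / 2)
  lo <- min(snp_pos, tss_pos)
  hi <- max(snp_pos, tss_pos)
  any(mids > lo & mids < hi)
}

#' Background SNP set with one gene assignment per SNP
#'
#' Every SNP cis to at least one gene (within 1 Mb of a TSS/TES, or inside
#' the gene) appears exactly once, assigned uniformly at random to one of
#' the genes it is cis to; SNPs cis to no gene are excluded.
#'
#' @param geno `genotype_matrix` (or data.frame `snp_id`, `chrom`, `pos`).
#' @param gene_models gene model data.frame.
#' @param seed integer seed for the random assignments.
#' @return data.frame `snp_id`, `chrom`, `pos`, `gene_id`.
#' @export
background_snps <- function(geno, gene_models, seed = 1L) {
  snp_df <- if (inherits(geno, "genotype_matrix")) {
    data.frame(snp_id = geno$snp_ids, chrom = geno$chrom, pos = geno$pos,
               stringsAsFactors = FALSE)
  } else geno
  cis_genes <- vector("list", nrow(snp_df))
  for (i in seq_len(nrow(gene_models))) {
    gm <- gene_models[i, ]
    w <- cis_window(gm)
    hit <- which(snp_df$chrom == gm$chrom &
                   snp_df$pos >= w[1] & snp_df$pos <= w[2])
    for (s in hit) cis_genes[[s]] <- c(cis_genes[[s]], gm$gene_id)
  }
  keep <- which(lengths(cis_genes) > 0L)
  assigned <- with_seed(seed, vapply(keep, function(s) {
    gs <- cis_genes[[s]]
    if (length(gs) == 1L) gs else sample(gs, 1L)
  }, character(1L)))
  data.frame(snp_id = snp_df$snp_id[keep], chrom = snp_df$chrom[keep],
             pos = snp_df$pos[keep], gene_id = assigned,
             stringsAsFactors = FALSE)
}

#' Build eQTL and background SNP pairs
#'
#' eQTL pairs are the (tier 1, tier 2) SNPs of every gene with a qualifying
#' second tier; background pairs are two distinct random cis SNPs for each
#' eligible gene.  Each pair is annotated with the inter-SNP distance and
#' flags for an intervening recombination hotspot and an intervening
#' (other-gene) TSS, both via the midpoint rule.
#'
#' @param records `eqtl_records` (tier 1 and 2 rows used).
#' @param geno `genotype_matrix`.
#' @param gene_models gene model data.frame.
#' @param hotspot_intervals data.frame `chrom`, `start`, `end` of hotspot
#'   intervals (recombination-map intervals at or above the LD-block rate
#'   threshold).
#' @param seed integer seed for background pair sampling.
#' @return data.frame `gene_id`, `pos_a`, `pos_b`, `chrom`, `distance`,
#'   `hotspot_flag`, `tss_flag`, `source` ("eqtl" or "background").
#' @export
build_snp_pairs <- function(records, geno, gene_models, hotspot_intervals,
                            seed = 1L) {
  pair_row <- function(gene_id, chrom, pa, pb, source) {
    gm <- gene_models[gene_models$gene_id == gene_id, ]
    hs <- hotspot_intervals[hotspot_intervals$chrom == chrom, , drop = FALSE]
    other_tss <- gene_models$tss[gene_models$chrom == chrom &
                                   gene_models$gene_id != gene_id]
    lo <- min(pa, pb); hi <- max(pa, pb)
    hflag <- if (nrow(hs) > 0L) {
      mids <- floor((hs$start + hs$end) / 2)
      any(mids > lo & mids < hi)
    } else FALSE
    tflag <- any(other_tss > lo & other_tss < hi)
    data.frame(gene_id = gene_id, chrom = chrom, pos_a = pa, pos_b = pb,
               distance = abs(pa - pb), hotspot_flag = hflag,
               tss_flag = tflag, source = source, stringsAsFactors = FALSE)
  }
  out <- list()
  for (g in unique(records$gene_id)) {
    rr <- records[records$gene_id == g, ]
    t1 <- rr[rr$tier == 1L, ]
    t2 <- rr[rr$tier == 2L, ]
    if (nrow(t1) && nrow(t2) && t1$pos[1] != t2$pos[1]) {
      gm <- gene_models[gene_models$gene_id == g, ]
      out[[length(out) + 1L]] <- pair_row(g, gm$chrom, t1$pos[1], t2$pos[1],
                                          "eqtl")
    }
  }
  bg <- with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(gene_models))) {
      gm <- gene_models[i, ]
      idx <- cis_snp_index(gm, geno)
      if (length(idx) < 2L) next
      pick <- sample(idx, 2L)
      rows[[length(rows) + 1L]] <- pair_row(gm$gene_id, gm$chrom,
                                            geno$pos[pick[1]],
                                            geno$pos[pick[2]], "background")
    }
    rows
  })
  res <- do.call(rbind, c(out, bg))
  rownames(res) <- NULL
  res
}

#' Hotspot intervals of a recombination map
#'
#' The inter-SNP intervals whose rate is at or above the LD-block rate
#' threshold, as 0-based half-open intervals between the flanking SNPs.
#'
#' @param map a `recomb_map`.
#' @param rate_threshold cM/Mb threshold.
#' @return data.frame `chrom`, `start`, `end`.
#' @export
hotspot_intervals <- function(map, rate_threshold = 0.9) {
  i <- which(map$rates >= rate_threshold)
  data.frame(chrom = rep(map$chromosome, length(i)),
             start = map$positions[i], end = map$positions[i + 1L],
             stringsAsFactors = FALSE)
}

#' Annotate SNPs against every track
#'
#' @param snps data.frame `snp_id`, `chrom`, `pos`.
#' @param tracks CRE tracks data.frame (with `track_id`).
#' @param pad boundary padding, bp.
#' @return logical matrix, SNPs x tracks (columns named by track id).
#' @export
overlap_annotation <- function(snps, tracks, pad = 500L) {
  ids <- unique(tracks$track_id)
  out <- matrix(FALSE, nrow = nrow(snps), ncol = length(ids),
                dimnames = list(snps$snp_id, ids))
  for (tid in ids) {
    out[, tid] <- snp_overlaps(snps, tracks[tracks$track_id == tid, ], pad)
  }
  out
}
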