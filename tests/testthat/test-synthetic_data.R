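test_that("recombination map places hotspots by construction", {
  m <- simulate_recomb_map(7, hotspot_every = 3, hotspot_rate = 2.0,
                           background_rate = 0.1)
  expect_equal(m$rates, c(0.1, 0.1, 2.0, 0.1, 0.1, 2.0))
  expect_true(all(diff(m$positions) > 0))
  expect_equal(length(m$rates), length(m$positions) - 1L)

  # degenerate: hotspot rate equal to background -> one block downstream
  m2 <- simulate_recomb_map(7, hotspot_every = 3, hotspot_rate = 0.1,
                            background_rate = 0.1)
  expect_equal(max(ld_blocks(m2, 0.9)$block), 1L)

  expect_error(simulate_recomb_map(7, spacing = 0), "positive")
  expect_error(simulate_recomb_map(1), ">= 2")
})

test_that("genotype simulator respects MAF range, determinism and LD knobs", {
  map <- simulate_recomb_map(50)
  g0 <- simulate_genotypes(500, map, maf_range = c(0.1, 0.5),
                           within_block_r2 = 0, seed = 2)
  C <- cor(g0$dosages)
  expect_lt(mean(abs(C[upper.tri(C)])), 0.1)
  expect_true(all(g0$dosages >= 0 & g0$dosages <= 2))
  expect_true(all(g0$maf > 0 & g0$maf <= 0.5))
  expect_equal(g0$maf, colMeans(g0$dosages) / 2, tolerance = 1e-12)

  # maf_range (0.5, 0.5): realized frequency within binomial noise
  g5 <- simulate_genotypes(500, map, maf_range = c(0.5, 0.5), seed = 3)
  expect_true(all(g5$maf >= 0.4 & g5$maf <= 0.6))

  # same seed, same draw; different seed differs
  g0b <- simulate_genotypes(500, map, maf_range = c(0.1, 0.5),
                            within_block_r2 = 0, seed = 2)
  expect_identical(g0$dosages, g0b$dosages)
  expect_error(simulate_genotypes(0, map), "positive")

  # within-block correlation rises with the r2 knob, cross-block stays flat
  g8 <- simulate_genotypes(500, map, maf_range = c(0.3, 0.5),
                           within_block_r2 = 0.8, seed = 2)
  bl <- ld_blocks(map, 0.9)$block
  C8 <- cor(g8$dosages)
  same <- outer(bl, bl, "==") & upper.tri(C8)
  expect_gt(mean(C8[same]^2), 0.3)
  expect_lt(mean(C8[!same & upper.tri(C8)]^2), 0.05)
})

test_that("null expression shows no trait-dosage association", {
  st <- make_study(n_genes = 30, n_samples = 200, r2 = 0)
  sim <- simulate_expression(list(A = st$geno), st$gm, NULL,
                             n_confounders = 0, confounder_var_frac = 0,
                             seed = 9)
  Y <- sim$expression$A
  maxr <- vapply(seq_len(nrow(st$gm)), function(i) {
    idx <- eqtlcre:::cis_snp_index(st$gm[i, ], st$geno)
    max(abs(cor(Y[, st$gm$gene_id[i]], st$geno$dosages[, idx])))
  }, numeric(1))
  expect_lt(max(maxr), 0.35)       # per-gene max over ~50 SNPs at n=200
  expect_lt(median(maxr), 0.25)
})

test_that("planted effects realize the requested R2 and class signs", {
  st <- make_study(n_genes = 20, n_samples = 500, r2 = 0.5,
                   n_confounders = 0, confounder_var_frac = 0)
  st$truth$beta <- beta_for_r2(0.5,
    apply(st$geno$dosages[, match(st$truth$snp_id, st$geno$snp_ids),
                          drop = FALSE], 2, var), other_var = 1)
  sim <- simulate_expression(list(A = st$geno), st$gm, st$truth,
                             n_confounders = 0, confounder_var_frac = 0,
                             seed = 11)
  r2 <- vapply(seq_len(nrow(st$truth)), function(i) {
    g <- st$geno$dosages[, match(st$truth$snp_id[i], st$geno$snp_ids)]
    summary(lm(sim$expression$A[, st$truth$gene_id[i]] ~ g))$r.squared
  }, numeric(1))
  expect_true(all(abs(r2 - 0.5) < 0.1))

  # A-opposite-B: fitted slopes have opposite signs in the two cell types
  st2 <- make_study(n_genes = 10, n_samples = 300, r2 = 0.3,
                    classes = "A-opposite-B")
  sim2 <- simulate_expression(list(A = st2$geno, B = st2$geno), st2$gm,
                              st2$truth, n_confounders = 0,
                              confounder_var_frac = 0, seed = 12)
  signs <- vapply(seq_len(nrow(st2$truth)), function(i) {
    g <- st2$geno$dosages[, match(st2$truth$snp_id[i], st2$geno$snp_ids)]
    bA <- coef(lm(sim2$expression$A[, st2$truth$gene_id[i]] ~ g))[2]
    bB <- coef(lm(sim2$expression$B[, st2$truth$gene_id[i]] ~ g))[2]
    sign(bA) == -sign(bB)
  }, logical(1))
  expect_true(all(signs))

  # planted SNP outside the cis window errors
  bad <- st$truth[1, ]
  bad$gene_id <- st$gm$gene_id[10]  # SNP belongs to gene 1's cluster
  expect_error(
    simulate_expression(list(A = st$geno), st$gm, bad, 0, 0, seed = 1),
    "cis window")
})

test_that("CRE tracks honour specificity and enrichment settings", {
  st <- make_study(n_genes = 20, n_samples = 100, r2 = 0.2, seed = 5)
  snp_map <- data.frame(snp_id = st$geno$snp_ids, chrom = st$geno$chrom,
                        pos = st$geno$pos)
  # specific_fraction = 0: tracks identical across cell types
  cre0 <- simulate_cre_tracks(st$gm, c("A", "B"), st$truth, snp_map,
                              specific_fraction = 0, eqtl_enrichment = 3,
                              seed = 6)
  tA <- cre0$tracks[cre0$tracks$cell_type == "A",
                    c("class", "chrom", "start", "end")]
  tB <- cre0$tracks[cre0$tracks$cell_type == "B",
                    c("class", "chrom", "start", "end")]
  rownames(tA) <- rownames(tB) <- NULL
  expect_identical(tA, tB)

  # eqtl_enrichment = 1: causal vs background overlap within 2 SE
  cre1 <- simulate_cre_tracks(st$gm, c("A", "B"), st$truth, snp_map,
                              specific_fraction = 0.3, eqtl_enrichment = 1,
                              seed = 7)
  act <- cre1$tracks[cre1$tracks$track_id == "activating_A", ]
  causal <- snp_map[match(st$truth$snp_id, snp_map$snp_id), ]
  bgs <- snp_map[sample(setdiff(seq_len(nrow(snp_map)),
                                match(st$truth$snp_id, snp_map$snp_id)),
                        500), ]
  f1 <- mean(snp_overlaps(causal, act)); n1 <- nrow(causal)
  f0 <- mean(snp_overlaps(bgs, act)); n0 <- nrow(bgs)
  se <- sqrt(f1 * (1 - f1) / n1 + f0 * (1 - f0) / n0)
  expect_lt(abs(f1 - f0), max(2 * se, 0.02))

  expect_error(simulate_cre_tracks(st$gm[0, ], c("A", "B")), "empty gene")

  # determinism
  cre1b <- simulate_cre_tracks(st$gm, c("A", "B"), st$truth, snp_map,
                               specific_fraction = 0.3, eqtl_enrichment = 1,
                               seed = 7)
  expect_identical(cre1$tracks, cre1b$tracks)
})

test_that("truth rows are unique, tiered, and cis to their genes", {
  st <- make_study(n_genes = 25, n_samples = 100, r2 = 0.2, n_tiers = 2,
                   seed = 8)
  tr <- st$truth
  expect_false(any(duplicated(paste(tr$gene_id, tr$snp_id))))
  for (g in unique(tr$gene_id)) {
    tt <- tr$tier[tr$gene_id == g]
    expect_false(any(duplicated(tt)))
    # tiers sit in distinct LD blocks
    bl <- st$blocks[match(tr$snp_id[tr$gene_id == g], st$geno$snp_ids)]
    expect_false(any(duplicated(bl)))
  }
  m <- match(tr$snp_id, st$geno$snp_ids)
  for (i in seq_len(nrow(tr))) {
    gmrow <- st$gm[st$gm$gene_id == tr$gene_id[i], ]
    w <- eqtlcre:::cis_window(gmrow)
    expect_true(st$geno$pos[m[i]] >= w[1] && st$geno$pos[m[i]] <= w[2])
  }
})
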