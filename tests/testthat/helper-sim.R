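# Shared fixture builder: a small synthetic study with per-gene SNP
# clusters, built fresh in code at test time.
make_study <- function(n_genes = 30, n_samples = 200, snps_per_gene = 50,
                       r2 = 0.2, classes = "stable", n_tiers = 1,
                       n_confounders = 3, confounder_var_frac = 0.2,
                       signal_genes = NULL, seed = 1) {
  gm <- eqtlcre::simulate_gene_models(n_genes, genes_per_chrom = 25)
  maps <- eqtlcre::simulate_gene_snp_maps(gm, snps_per_gene)
  blocks <- eqtlcre::combined_ld_blocks(maps, 0.9)
  gts <- lapply(seq_along(maps), function(ci)
    eqtlcre::simulate_genotypes(n_samples, maps[[ci]], c(0.1, 0.5), 0.8,
                                seed = seed + ci))
  geno <- eqtlcre:::bind_genotypes(gts)
  truth <- NULL
  if (r2 > 0) {
    genes <- if (is.null(signal_genes)) gm$gene_id else signal_genes
    truth <- eqtlcre::plant_eqtls(gm, geno, blocks, genes = genes,
                                  n_tiers = n_tiers, beta = 1,
                                  classes = classes, seed = seed + 50)
    vg <- apply(geno$dosages[, match(truth$snp_id, geno$snp_ids),
                             drop = FALSE], 2, var)
    truth$beta <- eqtlcre::beta_for_r2(r2, vg,
                                       other_var = 1 + confounder_var_frac)
  }
  list(gm = gm, maps = maps, blocks = blocks, geno = geno, truth = truth,
       seed = seed)
}

# Residual traits for one cell type of a study.
make_residuals <- function(study, celltype = "A", geno = study$geno,
                           n_confounders = 3, confounder_var_frac = 0.2,
                           seed = study$seed + 70) {
  gl <- list(geno)
  names(gl) <- celltype
  sim <- eqtlcre::simulate_expression(gl, study$gm, study$truth,
                                      n_confounders, confounder_var_frac,
                                      noise_sd = 1, seed = seed)
  q <- eqtlcre::normalize_expression(sim$expression[[celltype]],
                                     log_transform = FALSE)
  eqtlcre::remove_pcs(q, 0.01)$residuals
}
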