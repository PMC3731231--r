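---
title: "Methods: Bayes-factor cis-eQTL mapping and CRE integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayes-factor cis-eQTL mapping and CRE integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, numerical choices and design decisions
behind `eqtlcre`: what each stage computes, which knobs matter, what the
synthetic-data generator does and does not emulate, and consequently what a
passing test suite does and does not demonstrate about real data.

## The association model

Every association statistic in the package comes from one conjugate Bayesian
linear model. For a residual expression trait $y$ and a SNP with dosage $g$
(mean-imputed, in $[0,2]$), the alternative is

$$ y_i = \mu + \beta_a g_i + \beta_d d_i + \varepsilon_i,
   \qquad \varepsilon_i \sim N(0, \sigma^2), $$

where $d_i = 1$ when the dosage is closest to the heterozygote. The
intercept gets a flat prior, the residual variance the Jeffreys limit
$p(\sigma^2) \propto 1/\sigma^2$, and the effects a scaled prior
$\beta \mid \sigma \sim N(0, \sigma^2 D)$ with
$D = \mathrm{diag}(\sigma_a^2, \sigma_d^2)$. Integrating $\mu$, $\beta$ and
$\sigma^2$ in closed form gives the Bayes factor against the intercept-only
null:

$$ \mathrm{BF} = |I + M D|^{-1/2}
   \left( \frac{A - u^\top (M + D^{-1})^{-1} u}{A} \right)^{-(n-1)/2}, $$

with $A = \|y_c\|^2$, $M = X_c^\top X_c$, $u = X_c^\top y_c$ on the
centred data. Because the effect prior is scaled by $\sigma$, the BF is
invariant to location and scale changes of $y$ and to allele relabelling
$g \to 2-g$.

**Prior grid.** The BF is averaged (uniform weights, log-sum-exp) over
$\sigma_a \in \{0.05, 0.1, 0.2, 0.4\}$ trait-SD units with
$\sigma_d = \sigma_a/4$ — the documented defaults of the tool family this
model comes from; the grid is exposed via `prior_grid()`. Averaging over
scales is what makes a single BF usable across small and large effects.

**Conditional BFs.** Evidence for a focal SNP given an accepted set is the
ratio of the joint-model BF (all SNPs, each with additive + dominance
columns, shared grid) to the BF of the model without the focal SNP. For a
single SNP this reduces exactly to the univariate BF.

**Verification.** The closed form is checked against a Monte-Carlo
estimator built from an exact importance identity: draw $\sigma^2$ from the
*null* posterior (inverse gamma), draw $\beta$ from its conditional prior,
and average the bare likelihood ratio. The estimator shares no algebra with
the closed-form integral, so agreement (within 0.05 log10 units at $10^6$
draws) is a genuine cross-check.

## Preprocessing

The expression pipeline is: log2 (flooring non-positive entries at half the
minimum positive value), $k$-NN imputation ($k = 10$; a missing cell takes
the mean of its sample's values in the $k$ nearest traits), a per-array
quantile transform to the average empirical distribution, a per-trait
transform to standard-normal quantiles $\Phi^{-1}((r - 0.5)/n)$, removal of
leading expression principal components, and a final per-trait
re-normalization. Rank ties introduced by the array-level transform are
broken by the pre-transform ordering so each trait is an exact permutation
of the quantile set; genuine duplicates keep average ranks.

The number of PCs removed follows the PVE-difference rule: PCs are removed
up to (but not including) the first PC whose drop in percent variance
explained from its predecessor falls below `pve_delta` (default 0.01,
config-exposed). With `pve_delta = 1` nothing is removed. Because the
synthetic confounders enter as sample-level factors with Gaussian loadings
shared across genes, PC removal recovers them; this is the latent-factor
assumption built into the generator, and real hidden structure need not be
so benign.

**Probe clustering.** Genes measured by several probes are split into probe
clusters, each modelled independently downstream. A Gaussian mixture over
2–5 probes embedded in hundreds of sample-dimensions is not identifiable,
so probes are placed on the correlation metric $d = \sqrt{2(1 - r)}$
(coherent pairs near 0, uncorrelated pairs at $\sqrt 2$, anticorrelated
pairs near 2), projected onto the leading principal coordinate, and
clustered with `mclust` (BIC over 1..`max_clusters`, default 3). A fixed
variance prior (`priorControl(scale = 0.25)`, i.e. a prior SD of half an
uncorrelated pair's distance) keeps singleton clusters at finite BIC
without splitting coherent pairs: on constructed cases an $r = +0.9$ pair
stays together and an $r = -0.9$ pair separates.

## Tiered discovery and permutation FDR

LD blocks are runs of SNPs delimited by inter-SNP intervals whose
recombination rate reaches `rate_threshold` (default 0.9 cM/Mb,
config-exposed). Discovery is two-step per probe cluster: the best SNP per
block by univariate BF becomes a candidate; the top candidate is tier 1;
tiers 2–4 are added greedily by conditional BF given everything already
accepted, each in a fresh block, each above `bf_floor`. Ties for
best-in-block break to the lowest coordinate. Records are unioned across a
gene's probe clusters.

FDR comes from one sample permutation applied identically across all genes
(more are supported; counts are averaged). At cutoff $c$,
$\widehat{\mathrm{FDR}}(c) = \min(1, N_{\mathrm{perm}}(c)/N_{\mathrm{obs}}(c))$
per tier, monotonized to be non-increasing in $c$; tier-1 records are
scored by univariate BF and later tiers by conditional BF. Two edge rules:
a cutoff with no observed associations reports FDR 1, and a permuted count
of zero is floored at one before the ratio — a single permutation cannot
certify an FDR below its own resolution, and without the floor a lone
chance exceedance of the permutation maximum would define a spurious
"FDR 0" cutoff on null data. The operating threshold for everything
downstream is the smallest cutoff at or below the target FDR (default
10%).

**Stepwise cross-check.** The alternative count of independent SNPs per
gene is greedy forward selection by BIC over all cis SNPs. Each SNP enters
with the same additive + dominance design used by the Bayes factors and is
charged two parameters; with a 1-df additive-only design (available as
`dominance = FALSE`) the stepwise arm admits a lone SNP at roughly
$\alpha \approx 0.02$ and accumulates chance inclusions that make its
counts systematically exceed the tier scan's. The 2-df, model-consistent
design is the package's default and is what the tier-agreement statistic
uses.

## Replication and cell-type specificity

A discovery record is *replicated* in a target study when the target's
log10 BF for the same gene–SNP pair reaches `bf_threshold` (default 1);
pairs absent from the target, or below `maf_min` (default 0.05) in either
study, are *untested* and never enter denominators. With a within-cell-type
and a between-cell-type target, tested records are categorized as
cell-specific (within-only), shared, between-only, or neither. Replication
curves bin records by discovery BF (30 equal-width bins) with Wilson 95%
intervals.

Paired categorical contrasts use an exact binomial McNemar test on the
discordant counts (two-sided, capped at 1); unpaired contrasts use Fisher's
exact test with the sample odds ratio reported. The four logistic
enrichment models share one fitting routine (`stats::glm`, IRLS; Wald $Z$
and two-tailed normal $p$): CRE overlap for eQTL vs background SNPs,
within-cell-type replication on CRE overlap, the three-level
background/tier1/tier2 contrast (with a Wald test of the tier difference),
and intervening insulators for tier1–tier2 SNP pairs vs random cis pairs,
controlling for inter-SNP distance, pair positions, intervening hotspots
and intervening TSSs. Covariates that are constant in a given data set are
dropped rather than producing a rank-deficient design; position covariates
enter as signed TSS distance plus its absolute value.

## The bivariate five-model classifier

For paired traits $(y_A, y_B)$ and one SNP, five models are scored against
the joint null: *A-not-B* and *B-not-A* (the univariate BF in one cell
type), *A-and-B* (the product of the two univariate BFs — independent
effects), *stable* (one shared standardized effect fitted on the stacked
data with per-cell-type intercepts), and *A-opposite-B* (the stable model
with the B design sign-flipped). The integrated Bayes factor is

$$ \mathrm{iBF} = \log_{10}\!\Big(\tfrac14 \textstyle\sum_{m \ne \text{stable}}
   \mathrm{BF}_m\Big) - \log_{10} \mathrm{BF}_{\text{stable}}, $$

with uniform weights over the four differential configurations
(configurable); an eQTL is flagged differential when $\mathrm{iBF} > 0$ and
then labelled by the largest differential BF. Swapping the cell-type labels
exchanges A-not-B and B-not-A exactly and leaves the symmetric models
unchanged.

Two properties of this construction should be kept in mind. Power differs
across models: planted A-and-B effects are frequently absorbed by the
stable model (both fit the mean structure; stable pays one Occam factor,
A-and-B two), and this confusion is expected. And the $\mathrm{iBF} > 0$
rule is liberal: under the joint null every BF has expectation one, and the
average of four correlated, right-skewed BFs exceeds the stable BF for a
substantial minority of null genes. The flag is therefore a *ranking*
device — the suite checks that planted cell-specific genes flag at 90%+
while the null rate stays far below — and analyses that need a calibrated
error rate should threshold iBF by a permutation-style reference rather
than at zero. Residual correlation
between paired samples is ignored in the likelihood (independent-residual
approximation), which overstates evidence slightly when the same
individuals contribute both cell types.

## Interval conventions

All coordinates are 0-based half-open (BED native); SNPs are points at
their 0-based position. Overlap uses a symmetric pad of 500 bp:
$[\text{start} - \text{pad}, \text{end} + \text{pad})$, so a SNP exactly
$\text{pad}$ bases past an element's end does not overlap. The
intervening-insulator rule asks whether an element midpoint
$\lfloor (\text{start} + \text{end})/2 \rfloor$ lies strictly between SNP
and TSS; a degenerate span is false. Replicate tracks merge by interval
union, with half-open adjacency collapsing. Everything is backed by
IRanges and tested against $O(nm)$ brute-force scans.

## Random-forest specificity prediction

Feature rows combine discovery statistics (log10 BF, signed and absolute
TSS distance, |effect|, MAF, mean expression) with one boolean column per
CRE track in both cell types. Cross-validation is stratified (class ratio
preserved within one sample per fold), out-of-fold probabilities are
pooled, AUC uses the rank (Mann–Whitney) formulation — identical to
trapezoidal ROC integration — and accuracy is thresholded at 0.5.
Permutation importance is the forest's mean decrease in out-of-bag accuracy
under single-feature permutation. The CRE ablation re-runs the identical
folds without CRE columns and reports $\Delta$AUC. Forest size defaults to
500 trees; results stabilize well below that at these row counts.

The GWAS transfer experiment trains an eQTL-vs-background forest on a
reduced, cell-type-portable feature set (per-class overlap flags), scores a
GWAS SNP list once with matched-cell-type tracks and once with
unmatched-cell-type tracks, and compares the paired probabilities with a
two-sided Wilcoxon signed-rank test. The negative training set is sampled
from background SNPs, matched in size to the positives by default.

## The synthetic generator

The generator produces what the analysis assumes and little more:

* **Genotypes.** Haplotypes are drawn per LD block by comonotone copying:
  within a block each haplotype carries a shared latent uniform, and each
  SNP copies the thresholded shared uniform with probability
  $\theta = (r^2_{\text{target}})^{1/4}$. For equal MAFs the pairwise
  dosage $r^2$ equals the target; with MAFs drawn from a range, realized
  within-block $r^2$ is materially lower than the target while remaining
  far above the cross-block level — blocks, not exact $r^2$, are what the
  downstream statistics consume. Blocks are
  independent; there is no inter-block decay, no phasing realism, no
  admixture.
* **Gene layout.** Genes tile chromosomes at 1.2 Mb spacing with a 50-SNP,
  ~100 kb cluster centred on each gene, so each 1 Mb cis window contains
  exactly its own cluster and recombination hotspots at every 10th
  interval (5 blocks per gene). Planted tiers always sit in distinct
  blocks near the TSS.
* **Expression.** Traits are sums of planted dosage effects, shared latent
  factors and Gaussian noise. Bivariate classes are realized literally
  (A-not-B sets $\beta_B = 0$; A-opposite-B sets $\beta_B = -\beta_A$;
  A-and-B uses $\beta_B = \beta_A/2$). Effect sizes are free parameters —
  the source material reports no usable effect-size distribution — and
  tests state them as target cis-$R^2$ via `beta_for_r2()`.
* **CRE tracks.** Background intervals (1 kb) are placed uniformly at a
  density giving ~15% SNP coverage; a configurable fraction exists in
  exactly one cell type. Activating elements additionally cover planted
  causal SNPs of the matched cell type(s) at `eqtl_enrichment`-fold the
  background rate; repressive elements cover them at background/fold
  (depletion); the insulator track is neutral. Background activating and
  repressive intervals avoid causal SNPs so the planted enrichment is
  exact rather than approximate.
* **Scales.** The documented study conditions are 200 genes, 50 cis SNPs
  per gene, two cell types and 200 samples per cohort; recovery checks run
  at 100 genes (tier 1), 50 genes (allelic heterogeneity, $n = 300$), 250
  genes (bivariate, 50 per class) and a 120-gene three-cohort pipeline for
  the classifier stages, and the byte-determinism check uses a 40-gene
  configuration — determinism is scale-free.

Passing tests on these data show that the machinery is correct and
calibrated under its own assumptions: block-structured LD, Gaussian
additive traits, benign latent factors, literal class definitions and
exactly planted enrichment. They do not show robustness to trans effects,
non-Gaussian expression, population structure, probe artefacts, LD leakage
across block boundaries, or CRE boundary imprecision in real annotation.

## Degenerate inputs and tie rules

Monomorphic dosage vectors are errors everywhere (the generator resamples
and then fails loudly). Constant traits are dropped with a warning during
normalization. Collinear conditioning sets are errors in the conditional
BF. Best-in-block ties break to the lowest coordinate; the differential
flag uses a strict inequality so an exact five-way BF tie is not
differential; a SNP coinciding with the TSS has no intervening insulator;
zero discordant pairs give McNemar $p = 1$; a zero-margin table gives
Fisher $p = 1$ with an undefined odds ratio; identical matched and
unmatched feature sets give identical probabilities and Wilcoxon $p = 1$.

## Reproducibility

Every stochastic operation takes an explicit integer seed and restores the
caller's RNG state. Identical configuration plus seed yields byte-identical
output files, which the test suite asserts by comparing two full pipeline
runs as raw bytes.
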