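---
title: "Methods: trans-eQTL discovery, mediation and interpretation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trans-eQTL discovery, mediation and interpretation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its statistical machinery: the
models each stage fits, the tunable parameters and their defaults, what the
synthetic cohort generator does and does not emulate, the numerical choices,
and the known limitations.

## The discovery model

Trans-eQTL mapping asks whether a variant's dosage associates with the
expression of a *distant* gene — on another chromosome, or more than
`trans_min_bp` (default 5 Mb) from the gene's TSS on the same chromosome.
Cis associations use a `cis_window_bp` window (default 1 Mb) around the TSS.
Pairs between 1 and 5 Mb are tested in neither mode; this buffer avoids
counting long-range cis regulation as trans.

### Normalization

Expression is prepared the way large eQTL consortia prepare it:

1. **Detection filter.** Genes nonzero in fewer than `min_nonzero_samples`
   samples are removed. Rank-based transforms turn an all-zero gene into
   pure tie-breaking noise that can associate with anything, so undetected
   genes must go first.
2. **Quantile normalization** across samples (the `limma` tie rule: tied
   values receive the mean of the reference quantiles they span).
3. **Inverse normal transform** per gene: rank *k* of *n* maps to
   `qnorm((k − 3/8)/(n + 1/4))`. The Blom offset 3/8 is a convention, not a
   substantive choice; it is exposed (`offset`) because other pipelines use
   0 or 1/2. Ties get average ranks. Per-gene (across samples) application
   is the eQTL standard; the alternative (per sample across genes) changes
   the marginal being normalized and is not implemented.

After the transform every gene is standard normal in rank, which is also
what justifies the colocalization prior variance below.

### Covariates

Hidden expression factors are the top principal components of the
normalized expression matrix. This is a deliberate, documented surrogate
for Bayesian hidden-factor models (PEER): both estimate the dominant
inter-sample covariation — batch, cell-type composition, technical noise —
that would otherwise both mask real trans effects and, worse, induce
spurious gene–gene correlation. The factor count is capped at
`floor(n/10)` to avoid overfitting small cohorts (a 50-factor model is
reasonable at n ≈ 1400, not at n = 200). Genotype PCs (top PCs of
standardized dosage) absorb population structure; categorical sample
covariates are expanded to centered indicators. Assembly fails loudly on
rank deficiency, naming the collinear columns.

### The scan

The engine residualizes expression and dosage against `[1, C]` once
(Frisch–Waugh) and converts residual correlations to OLS t statistics,
`t = r·sqrt(df/(1−r²))` with `df = n − ncol(C) − 2`, so a genes × variants
scan is two matrix products rather than a per-pair `lm()`. On covariate-free
toys it reproduces the textbook simple-regression t-test to machine
precision (tested). Monomorphic variants are skipped with a logged count.

### Multiple testing

Three schemes are provided:

- **Pooled BH** over all trans tests; candidates at `alpha` (working lists
  at 0.25 and 0.05).
- **Hierarchical gene-level**: per gene, Šidák-correct the minimum p for
  the gene's test count (`1 − (1−p)^m`, computed via `expm1` for small p),
  then BH across genes.
- **Permutation gene-level**: per gene, compare the observed minimum p to
  minima under sample-label permutations of the covariate-residualized
  expression; empirical p `(1 + #{perm ≤ obs})/(n_perm + 1)`; BH across
  genes. One shared permutation per iteration serves all genes — each
  permutation costs one matrix product, and per-gene marginals are
  unchanged. A beta-tail approximation accelerator was considered and left
  out: at desk scale the exact permutation loop is affordable.

**Order of FDR and LD pruning.** Greedy pruning visits records in ascending
p, so the pruned list contains each LD clump's *minimum* p. Computing BH on
that selected subset is anti-conservative: on 50 signal-free cohorts, 22%
yielded at least one pooled-FDR-0.05 trans call, versus 4% when BH runs on
the full record list. The pipeline therefore applies BH to all trans
records first and prunes the significant candidates into independent
signals afterwards (`order = "fdr_then_prune"`, the default); the reverse
order remains available for comparison. Pruning itself is greedy per gene —
a record survives unless its variant exceeds `r² > 0.6` with a
different variant already kept *for that gene* — so one variant can remain
the independent signal for several trans genes, which is precisely the
structure a hotspot describes. A global mode (`per_gene = FALSE`) treats
records of an already-kept variant as kept.

### Split-half replication

The cohort is split into two disjoint equal folds (randomly, or by an
explicit `folds` argument for stratified designs); the full trans pipeline
runs per fold and the overlap is |A ∩ B| / min(|A|, |B|). Intersection over
the smaller list is the documented convention; any overlap statistic needs
a denominator and the smaller list bounds the achievable intersection.

## Colocalization

Per variant, the Wakefield approximate Bayes factor from `(beta, se)` under
a `N(0, W)` effect prior. `W = 0.15²` is the standard choice for a
quantitative trait with unit variance — guaranteed here by the inverse
normal transform; for GWAS traits on other scales `W` is exposed.
Posteriors over the five hypotheses enumerate single-causal-variant
configurations in log space (log-sum-exp throughout; the H3 term uses a
guarded `log(exp(a) − exp(b))` that degrades to −Inf for a single variant).
Priors are the conventional `p1 = p2 = 1e-4`, `p12 = 1e-5`. The region for
a cis–trans pair is the LD-partner set of the independent trans-eSNP
(r² > 0.6) rather than a fixed window, matching how the pairs are formed;
pairs with fewer than two shared variants are skipped (the posterior is
degenerate there). Agreement with brute-force enumeration over all
configurations is tested to 1e-9 for regions up to six variants.

## Mediation

For each colocalized (SNP, cis gene, trans gene) triple, two OLS fits —
`y_cis ~ g + C` and `y_trans ~ g + y_cis + C`, no exposure–mediator
interaction — and quasi-Bayesian Monte Carlo: `n_sims` draws from the
asymptotic normal of each fit's slope block, ACME draw = a·b, direct
effect = c′, total = a·b + c′ (an identity in the linear no-interaction
model). Drawing only the slope block makes the estimate invariant to
constant shifts of any input, which the full-coefficient draw (including
the intercept) is not. The two-sided Monte-Carlo p is floored at
`1/(n_sims+1)`; the per-pair threshold 0.05 is applied uncorrected, as is
common for these screens, with a BH option (`adjust = "BH"`). Collinear
dosage and mediator (|r| > 0.999) abort with a non-identifiability error.

The b = 0 calibration of the screen holds on unconfounded data (false-flag
fraction ≤ 2α, tested); shared hidden factors confound the mediator–outcome
edge, which is exactly why the screen should receive the same covariates as
the scan.

## Hotspots and co-expression statistics

Independent trans-eSNPs with ≥ 3 distinct target genes are hotspots. The
co-regulation statistic is the mean absolute Pearson correlation over
target pairs, compared with `n_random` resampled gene sets in which each
target is replaced by a random gene from the same mean-expression bin
(deciles by default; the bin multiset of every draw equals the targets' bin
multiset by construction, asserted per draw). Empirical p uses the +1
correction. Both per-hotspot p-values and a pooled summary (mean across
hotspots vs the null of per-draw means) are reported.

All co-expression statistics — hotspot co-regulation and the
mediated-vs-colocalized-vs-random pair contrast — are computed on
**covariate-residualized** normalized expression (the pipeline's `residual`
matrix). On unadjusted expression the shared hidden factors inflate
correlations among *random* genes, so the resampled null creeps toward the
planted signal and the empirical p becomes a coin flip around the
interesting range; after residualization the planted hotspots sit at the
resampling floor across seeds. This mirrors the common practice of
computing co-expression on covariate-adjusted residuals.

## Hi-C contact enrichment

Positions map to fixed 100-kb bins (`floor(pos/resolution)`, 0-based
half-open; genes anchored at the TSS — the anchor is a convention, and TSS
is the same anchor the scan windows use). Interchromosomal eSNP–eGene pairs
contribute their normalized contact frequency; zeros are discarded (the
interchromosomal matrix is sparse and zeros carry no rank information), and
the null draws bins uniformly with the observed chromosome-pair composition
(the observed chromosome pairs recycled in order). The comparison is a
one-sided Wilcoxon rank-sum test — robust to the heavy-tailed contact
distribution and invariant to global rescaling of the matrix, so any
normalization constant cancels. A KS alternative was considered and
rejected as the default because location shift, not shape, is the question.

## GWAS integration

Loci are defined by iterative greedy clumping: the smallest-p variant below
`5e-8` indexes a locus; variants at `r² > 0.6` join it and leave the pool.
QTL records are prefiltered to nominal `p < 1e-5` (trans lists are small,
so the usual genome-wide QTL threshold would leave nothing to colocalize),
intersected with locus members by variant id (equivalent to interval
intersection under this locus definition), and colocalized per (gene,
locus); calls require PP4 > 0.6. Gene-set enrichment uses Fisher's exact
test with the sample odds ratio ad/bc (the quantity usually reported), the
Haldane–Anscombe 0.5 correction when a cell is zero, and Woolf log-normal
confidence intervals. The kME (module membership) contrast is a two-sample
Wilcoxon rank-sum on externally supplied kME values — co-expression network
construction is out of scope by design.

## The synthetic cohort generator

The generator plants the statistical structure the analyses assume, with
full ground-truth export:

- **Genotypes.** Hardy–Weinberg dosages with template-haplotype LD blocks:
  each block has one allele frequency and a per-haplotype template allele
  that members copy with probability `sqrt(ld_within_block_r)`, giving
  pairwise within-block dosage correlation equal to the configured value
  (exact copies at 1, independence at 0). Defaults: MAF uniform on
  (0.05, 0.5), blocks of 10 at correlation 0.8 — r² ≈ 0.64, comfortably
  above the 0.6 pruning/clumping threshold, as in a dense common-variant
  panel.
- **Expression.** Shared hidden factors (5 factors, loading sd 0.5) plus
  unit noise, then planted effects: cis targets gain `a·g`; trans targets
  gain `b·y_cis + c·g`, inheriting the realized mediator (so mediated
  targets carry the mediator's noise, as a real cascade would). Planted cis
  genes are relocated next to their variant and trans targets to another
  chromosome, so planted labels always match the scan windows. Default
  effect sizes a = b = c = 1 put planted trans signals at roughly 10% of
  expression variance at n = 500 — strong but within the range reported
  for replicable trans effects.
- **Hotspots** are mediated fan-outs: one variant, one cis mediator, four
  trans targets sharing it — which both satisfies the ≥ 3-target
  definition and makes targets genuinely co-regulated.
- **Hi-C.** Poisson baseline (mean 5) over all interchromosomal bin pairs;
  pairs linked by planted interchromosomal trans effects get the mean
  multiplied by `hic_enrichment_factor`. Poisson is a tractable stand-in
  for a normalized contact distribution; the rank-based enrichment test
  does not depend on the marginal family.
- **GWAS.** Causal variants (shared with planted trans effects) get latent
  |z| ~ N(8, 1); other variants follow the conditional single-causal
  approximation `z_j = Σ r_jc·z_c + ε`, `ε ~ N(0, sqrt(1 − max r²))`, with
  `se = 1/sqrt(2·n·maf·(1−maf))` and two-sided normal p. The conditional
  (rather than unit) noise makes a strongly planted causal variant the
  deterministic minimum p of its block.
- **Determinism.** All randomness flows from one root seed through named
  substreams per artifact, so regenerating one artifact does not perturb
  the others; every stage is bit-identical across runs at a fixed seed
  (tested).

What the generator does **not** emulate: realistic human LD maps and
recombination, population structure beyond global PCs, sex chromosomes,
read-count noise models (expression is Gaussian on the post-normalization
scale), distance-decay in Hi-C, and polygenic GWAS backgrounds. Passing
tests therefore demonstrate the statistical machinery is correct and
calibrated under the stated generative model — not that the pipeline is
robust to every artefact of real sequencing data.

## Problem sizes and calibration checks

The reference synthetic study uses 500 samples, 4 chromosomes × 10 Mb,
2,000 variants, 500 genes, with 20 cis, 20 mediated-trans and 10
direct-trans effects, 5 hotspots (4 targets each), 5× contact enrichment
and 5 GWAS-causal trans variants. Calibration runs 50 signal-free cohorts
at n = 200 with the same genome. These sizes keep the full suite and the
acceptance script within minutes on one CPU while leaving every stage with
hundreds of thousands of tests to correct over. Uniformity of null p-values
is checked by KS on a thinned subsample (one variant per second LD block):
KS assumes independent observations, and per-pair p-values within an LD
block are mechanically dependent.

## Known limitations

- PEER is emulated by expression PCs; factor rotations that PEER's priors
  would resolve differently are not reproduced.
- The permutation FDR's shared-permutation scheme preserves per-gene
  marginals but not the joint distribution across genes; gene-level BH is
  unaffected.
- Single-causal-variant colocalization only; allelic heterogeneity within
  a region (SuSiE-style multi-causal models) is out of scope.
- Mediation assumes sequential ignorability given the covariates; no
  sensitivity analysis is provided.
- The Hi-C test conditions on non-zero contacts; systematic zero-inflation
  differences between observed and random bins would not be detected.
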