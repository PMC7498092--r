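---
title: "Methods: kinship-aware cis/trans eQTL mapping with feqtl"
author: "feqtl authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinship-aware cis/trans eQTL mapping with feqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`feqtl` implements a complete all-pairs cis/trans eQTL analysis for small,
pedigree-structured cohorts: genotype QC (MAF filter, LD tag-SNP
blocking), RNA-seq normalisation and filtering, a pedigree additive
relationship matrix used as the error covariance of a generalized least
squares (GLS) scan under linear-dosage and genotype-factor ANOVA models,
a per-SNP genotype-permutation validation of the low-p-value excess,
orthonormalized visualization coordinates, and surplus-based gene-category
enrichment of top trans associations. A synthetic-data generator with
planted effects makes the whole chain testable without access to animal
data. This vignette explains each model, the tunable parameters, the
numerical choices, and what the synthetic experiments do and do not
demonstrate.

# The association models

For gene $i$ and SNP $j$ the linear model is
$$ y_i = \alpha + \beta g_j + C\gamma + \varepsilon,\qquad
   \varepsilon \sim (0,\ \sigma^2 A), $$
where $y_i$ is log2 CPM expression, $g_j \in \{0,1,2\}$ counts minor
alleles, $C$ is the covariate design (intercept; breed with 2 levels and
batch with 5 levels, treatment-coded; RIN and age in days as numeric
covariates) and $A$ is the pedigree numerator relationship matrix.
Following the matrix-scan tradition, $A$ is taken as the error covariance
verbatim rather than estimated as a variance-component mixture; this is an
approximation (the true residual covariance is
$\sigma_g^2 A + \sigma_e^2 I$) whose consequences are discussed under
*Limitations*.

Computationally, all sample-indexed quantities are whitened by $L^{-1}$
with $LL^\top = A$ (lower Cholesky), residualized against the whitened
design through its QR decomposition, and scaled to unit norm. The inner
product of the two prepared vectors is the partial correlation $r$, and

* linear: $t = r\sqrt{df/(1-r^2)}$ with $df = n - k - 1$ ($k$ = design
  columns), two-sided p from the t distribution; the slope is reported on
  the original scale.
* ANOVA: indicator columns for the observed genotype classes minus one
  replace the dosage; the nested-model F statistic on
  $(q,\; n - k - q)$ df is computed from the explained fraction of the
  unit-norm residualized expression, $q$ = observed classes − 1. Pairs
  with a single observed class, dosages collinear with the covariates, or
  zero-variance expression are emitted as untestable with a reason code,
  keeping the record count at exactly genes × SNPs.

The batched implementation computes whitening, residualization and row
normalisation once per chunk of genes and obtains all statistics by
matrix products; tests assert equality with per-pair GLS `lm()`/`anova()`
fits to 1e-8. Results are independent of the chunk size up to
floating-point rounding (the chunk shape changes the BLAS call sequence,
so last-bit differences between chunkings are expected and the contract
is equality within 1e-10).

Pairs are **cis** when the SNP position falls within
`cis_distance` (default $10^6$ bp, inclusive) of the gene interval
$[\mathrm{start}, \mathrm{end}]$ on the same chromosome — the interval
anchor, not the TSS, matching the matrix-scan convention — else
**trans**. Benjamini–Hochberg FDR is applied separately within each
(model × cis/trans) partition, because reported eQTL tables carry their
own FDR scale per partition; joint adjustment across models would mix
dependent test families with different calibration.

## Orthonormalized visualization

Raw expression-vs-dosage plots can look unimpressive for highly
significant pairs when covariates carry much of the variance. Plotting
instead the centered, scaled, whitened and covariate-orthogonalized
unit-norm vectors (`orthonormalizeForViz()`) displays exactly the
association the scan tested: the inner product of the two plotted vectors
*is* the partial correlation behind the reported t statistic (asserted to
1e-10 in tests).

# Genotype QC

* **MAF filter**: minor allele frequency computed on all samples jointly;
  threshold 0.3, boundary inclusive (a threshold that removes
  underpowered SNPs naturally keeps the boundary case). Dosages are first
  re-oriented so that 2 marks the minor-allele homozygote.
* **LD blocking**: one left-to-right pass per chromosome; the current
  block absorbs the next SNP iff its squared Pearson correlation with
  *every* member is at least 0.9 (all-pairwise rule). Blocks never span
  chromosomes; the first member by position tags the block. The pass
  restarts at chromosome boundaries only, not at large physical gaps.
* **Missing genotypes** are not supported: the loader rejects anything
  outside {0,1,2} with a clear message. Mean imputation is noted as
  future work.

# Expression preparation

Counts are subset to the union of the user's differential-expression list
and mitochondrial list (when given), filtered to genes with at least
`min_reads` (5) in at least `min_samples` (11 — the size of the smaller
breed group, so a gene expressed in only one group survives), then
TMM-normalised (edgeR's `calcNormFactors`, factors geometric-mean-centred
to 1) and converted to $\log_2((c + 0.5)/\mathrm{effective\ library} \cdot 10^6)$.
Genes with any observation more than `z_max` (3) sd from the gene mean on
this normalized scale are removed. The z-rule is two-sided ("further than
3 sd from the mean"); "a single outlying value" is read as *at least one*
(the conservative removal criterion), and constant genes (sd = 0) are
kept with z defined as 0. The test suite checks the TMM implementation
against an independent step-by-step transcription of the published
recipe (upper-quartile reference, 30%/5% double trim,
precision-weighted mean).

# Kinship

The additive relationship matrix is built by the tabular method:
$a_{ii} = 1 + a_{s_i d_i}/2$, $a_{ij} = (a_{j s_i} + a_{j d_i})/2$, with
unknown parents contributing 0, after truncating the pedigree to 4
parent-steps from each study animal (per-animal horizon; ancestors at the
horizon become founders). The scan is invariant to a global scaling of
the error covariance (asserted in tests), so the choice of $A$ over
$A/2$ (kinship proper) is immaterial. Gene-dropping Monte-Carlo agreement
and the textbook closed forms (parent–offspring 0.5, full sibs 0.5,
offspring-of-full-sibs diagonal 1.25) are asserted in tests. A ridge of
$10^{-8} \times$ mean diagonal is added before Cholesky for numerical
positive-definiteness; it bounds exactness of the "identity covariance is
a no-op" property at about $10^{-8}$, far below any quantity of interest.

# Permutation validation

The observed excess of small p-values is validated by shuffling each
SNP's dosages across samples independently (preserving each SNP's dosage
multiset) and re-running the full two-model scan — 1000 iterations by
default, with per-iteration seeds derived as `seed + iteration` so
results are independent of scheduling. Per iteration and partition the
count of $p < 0.01$ and the 1st/10th/100th smallest p-values are saved;
the observed count is summarised by a one-sided normal-approximation tail
probability, and each saved rank by the empirical fraction of iterations
whose k-th smallest p-value is strictly below the observed one.

Two properties of this null are worth stating plainly. First, per-SNP
shuffling destroys LD, so the null describes independent-SNP data — a
property of the procedure, not a bug. Second, shuffling also destroys the
alignment between genotypes and the pedigree: in a related cohort the
observed genotypes are themselves A-structured, whitening removes part of
their variance, and the observed low-p count therefore sits
*systematically low* in the permutation distribution even under the null.
LD acts similarly on the spread: correlated tests make the observed
low-p count more variable than the LD-free shuffle null. Exchangeability
between observed and shuffled data is therefore exact only for an
unrelated cohort with independent SNPs, which is the design the package's
null-case calibration experiment uses, while the planted-signal
experiment (whose effect is an order of magnitude above these biases)
keeps the full pedigree and LD structure.

# Enrichment

The top trans set is chosen as the $k$ pairs with smallest p-values in
the linear-trans partition, with $k$ defaulting to the *surplus*:
$\max(0, \#\{p<\alpha\} - \alpha N)$, the observed count of low p-values
minus the count a uniform distribution would produce. Ties are broken by
(snp_id, gene_id) order for determinism. Each category's 2×2 Fisher table
counts **pairs with multiplicity** against a deduplicated gene-set
background — deliberately mirroring published trans-eQTL enrichment
tables whose "N genes" column counts eQTLs, not unique genes. The test is
two-sided so depletion registers as well. Note the multiplicity inflates
the nominal Fisher sample size; the package reports the construction
as-is and leaves deduplicated variants to the caller (pass
`unique(top$gene_id)`).

QTL-region annotation extends each SNP by a 100 kb flank on both sides
(inclusive interval arithmetic via GenomicRanges) and intersects genes
without extension.

# The synthetic-data generator

The generator emulates the study design the analysis assumes:

* **Cohort**: 11 + 27 animals from two breeds, each breed descending from
  its own founder pool through 4 generations with reused parent pairs
  (full sibs occur), so breed is confounded with pedigree clusters as in
  real two-breed designs. A founders-only switch yields an unrelated
  cohort ($A = I$).
* **Genotypes**: founder alleles drawn per LD block at frequencies in
  [`target_maf_min` + 0.05, 0.5] with a small between-breed frequency
  offset, then transmitted by Mendelian sampling. All SNPs of a block
  share one meiosis draw (complete within-block linkage) and block copies
  differ from the seed SNP only by rare founder-allele flips
  (`ld_flip_prob`, default 0.01), so within-block dosage $R^2$ stays
  above 0.9 *and* every offspring dosage is Mendelian-consistent with its
  parents — flipping dosages per sample, the obvious alternative, would
  violate Mendelian transmission. Genes are placed uniformly over the
  genomic span the SNPs cover, so cis pairs arise at a realistic rate.
* **Counts**: negative-binomial on a log2 link; the linear predictor sums
  a per-gene baseline (log2 CPM uniform on [5, 10], i.e. moderately to
  highly expressed genes), planted genotype effects, per-gene covariate
  effects (breed/batch/RIN/age coefficients drawn with sds 0.5/0.3/0.2/0.1
  log2 units), an optional polygenic term with covariance
  $\sigma_p^2 A$ ($\sigma_p$ default 0.25 log2 units) and lognormal
  library-size offsets (mean $2 \times 10^6$). Dispersion defaults to
  0.08, a typical biological CV for purebred animals. None of these
  magnitudes is asserted — they are config-exposed defaults chosen to be
  realistic, not estimates of any particular data set.
* **Planted effects**: `effect_size_sd` is the planted $|\beta|$ in units
  of the per-gene residual sd of log2 expression, where the residual sd
  counts shot noise, overdispersion *and* the polygenic component —
  "an effect at 2 residual sd" then means exactly that for the scan.
  Cis pairs relocate their target gene to within 0.5 Mb of the SNP; trans
  pairs force different chromosomes. Effects are dosage-linear by
  default; a configurable fraction are carrier-shift ("dominant")
  effects, the case the ANOVA model exists for. For
  category-enrichment experiments the generator can designate a fraction
  of genes as a category and allocate trans targets with a configurable
  preference (weight `target_category_bias`); the allocation is
  stratified (exact expected counts) rather than independently sampled,
  which removes a variance source irrelevant to the hypothesis under
  test.
* **Determinism**: every stage derives its own seed from the global seed,
  so identical configurations reproduce byte-identical outputs and
  stages can be re-run in isolation.

What passing synthetic tests shows — and does not. The generator
produces Mendelian LD-blocked genotypes, NB counts and pedigree
covariance, so the experiments demonstrate correctness of the statistics,
calibration under the generator's null, and power/recovery at planted
effect sizes. They do not demonstrate robustness to features real data
add: genotyping error and missingness, expression outliers beyond NB
tails, population structure not captured by a 4-generation pedigree,
cryptic batch-genotype confounding, or reference/annotation artefacts.

# Experiment dimensions

The packaged experiments use deliberately modest sizes so the entire
suite runs in minutes on one core, while keeping each check's power high:
null calibration at 200 genes × 500 independent SNPs (~10^5 tests —
tight enough that a 3-binomial-sd band on the p<0.01 fraction is a
demanding check); permutation validation at 50 genes × 80 SNPs × 200
iterations; planted-pair recovery at 200 genes × 200 SNPs with 4 cis + 4
trans effects over 20 replicates (cis partitions then hold ~800 pairs,
so the top-1% criterion is not degenerate against 4 planted cis pairs);
enrichment at 250 genes × 500 SNPs with 80 trans effects and a 30%
category at 3× preference, where the Fisher z-margin is ~4 se. The
full-scale 1425 × 19179 contract is checked as arithmetic, not executed.

# Known limitations

* Taking $A$ as the error covariance verbatim (rather than REML-estimating
  $\sigma_g^2 A + \sigma_e^2 I$) over-corrects when the true polygenic
  fraction is small; under the generator's defaults this produces a mild
  conservative shift visible in permutation percentiles. It reproduces
  the analysis design faithfully; a mixed-model scan is out of scope.
* The ANOVA model at n = 38 with 2 numerator df is noticeably less
  powerful than the linear model for dosage-linear effects and its
  p-value distribution reacts more strongly to distributional violations
  — the reason the enrichment pipeline consumes the linear-trans
  partition.
* Fisher tables mixing pair multiplicities with gene-set backgrounds
  overstate the effective sample size; treat the p-values as ordering
  evidence, not literal error rates.
* The LD generator produces near-copy blocks, not realistic decay, and
  the pedigree generator produces balanced generations; both are
  verifiable simplifications, not models of any real population.
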