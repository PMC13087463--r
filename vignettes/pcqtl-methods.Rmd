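---
title: "Multi-gene cis-QTL mapping on cluster principal components: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-gene cis-QTL mapping on cluster principal components: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `pcqtl`, the
assumptions behind them, the tunable parameters and their defaults,
what the synthetic-cohort generator does and does not emulate, and the
design choices made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The model in brief

A *cis*-regulatory variant can shift the expression of several
neighboring genes at once. When the per-gene effects are weak, a
single-gene eQTL scan — a regression of one gene's expression on one
variant's dosage — has low power at every gene even though the
aggregate effect is strong. `pcqtl` pools neighboring, co-expressed
genes into clusters and maps QTLs on the principal components of the
cluster's expression. A shared effect that is invisible per gene
accumulates along the PC axis it aligns with.

## 2. Cluster calling

Expression is first residualized on user-supplied covariates (latent
expression factors, genotype PCs, technical covariates) by per-gene
OLS; no shrinkage, since covariates are assumed few relative to
samples. Residualization is idempotent and the residuals are exactly
orthogonal to every covariate row.

Per chromosome, Spearman's rank correlation is computed for every gene
pair (ranks with average ties, then Pearson on ranks; two-sided
p-values from the t approximation). A pair is significant at
`p < 0.05 / C(N, 2)` with `N` the number of expressed genes on the
chromosome — a deliberately conservative Bonferroni divisor. Both
positive and negative correlations count. Constant expression vectors
have undefined correlations and never contribute significant pairs.

Clusters are maximal runs of contiguous genes found by a stepwise
sliding window: window sizes from 50 down to 2, scanned left to right
within each size; a window of `n` genes with `m` significant pairs is
recorded iff `0.7 * C(n, 2) <= m` and none of its genes is already
clustered. The formal inequality (at least 70%) is used rather than a
strict ">" reading: with `n = 2`, `0.7 <= 1` accepts a single
significant pair, which is what makes pair clusters possible at all.
Cluster membership is therefore unique within a context and every gene
sits in the largest accepted window covering it. An optional gene
blacklist (e.g. cross-mappable genes) flags clusters rather than
removing them.

Null clusters — the background for enrichment — are windows of 2–5
contiguous genes none of which belongs to a cluster, sampled so the
size distribution matches the relative size distribution of the called
clusters. Matching is by proportion at a configurable total (the
count-vs-proportion reading was open; proportions compose better when
the candidate pool is small), sampled without replacement per size
stratum and reproducible under a seed.

## 3. PC phenotypes and normalized shared variance

PCA is performed on per-gene standardized residualized expression,
i.e. an eigendecomposition of the gene-gene correlation matrix. On
this scale the squared correlation-scale loading of PC1 on gene *i*,
`l_i^2 = (v_i * sqrt(lambda_1))^2`, equals the fraction of gene *i*'s
variance explained by PC1, and the normalized shared variance

```
(sum_i l_i^2 - 1) / (n - 1) * 100
```

is exactly 0 for mutually uncorrelated genes (`lambda_1 = 1`) and
exactly 100 for perfectly correlated ones (`lambda_1 = n`). Working on
the covariance scale instead would break both endpoints whenever gene
variances differ, which is why standardization is built in rather than
optional. Input matrices are assumed already inverse-normal per gene
(the GTEx convention); the simulator applies the same transform.

All `n` PCs are emitted as phenotypes — subtle effects can load on a
low-variance PC (see §7) — with phenotype id `cluster:PCk`, anchored
at the cluster span for the BED dialect. PC signs are arbitrary; they
are fixed so the gene with the largest |loading| loads positively,
which makes outputs reproducible without affecting mapping (the scan
is sign-invariant).

## 4. Fine-mapping

Each phenotype (gene expression or PC) is fine-mapped on
individual-level dosages of all variants with MAF ≥ 0.05 (inclusive
floor) within ±1 Mb of the cluster span — the same variant set for
eQTL and pcQTL phenotypes of a cluster, so their credible sets are
comparable.

The fine-mapper is a sum-of-single-effects model fitted by iterative
Bayesian stepwise selection: L = 10 additive single effects, each a
Bayesian regression with a uniform prior over variants and a
`N(0, V_l)` effect prior. Per iteration each effect is re-fitted to
the residual of the others; `V_l` is re-estimated by maximizing the
single-effect marginal likelihood (Brent on log V, with the point-null
`V = 0` kept when it wins); the residual variance is re-estimated each
sweep. Convergence is declared when the evidence lower bound moves by
less than `1e-3` (the ELBO is asserted non-decreasing in the tests);
`max_iter = 100`, with a non-convergence flag rather than an error.

Per effect, the 95% credible set is the smallest variant set by
descending posterior weight reaching cumulative 0.95. A set is kept
iff its purity — the minimum absolute dosage correlation among
members, computed on the analysis cohort itself, no external LD panel
— is at least 0.5; single-variant sets have purity 1. Duplicate sets
across effects collapse to the higher-purity instance (the reference
behavior is silent here; collapsing avoids double-counting one signal
as two). The PIP identity `pip_j = 1 - prod_l (1 - alpha_lj)` holds
exactly over all L effects.

Calibration uses a genotype-shuffle null: permuting the
individual-to-genotype matching per phenotype removes real
associations while preserving LD and phenotype distributions; the
identical workflow should then yield (almost) no purity-filtered
credible sets. The acceptance suite bounds the null rate at 0.05 sets
per phenotype — "approximately zero" against a positive-control rate
above 1 — because the purity filter admits a small, nonzero
false-signal rate on LD-structured nulls.

## 5. Nominal scans, permutation FDR, aFC

Nominal scans are per-variant simple OLS with two-sided t p-values.
Phenotype-level empirical p-values come from B = 1000 permutations of
the phenotype: the direct estimate `(1 + #{perm min-p <= obs})/(B+1)`
and a maximum-likelihood Beta fit to the permutation min-p values
whose tail probability interpolates below the 1/B resolution (the
FastQTL/tensorQTL scheme). If the Beta fit fails, the direct p is
substituted and flagged. Storey q-values with smoother-estimated pi0
(natural cubic spline over lambda, evaluated at 0.95) give
phenotype-level FDR; below 10 phenotypes pi0 is fixed at 1, which is
exactly Benjamini-Hochberg. The three pooled conditions — eQTL alone,
pcQTL alone, joint — are separate q-value runs; significance is
q < 0.05.

Allelic fold change is estimated from expression on a positive linear
scale under the allelic model `E[e|g] = c (2 - g + g k)/2`, by least
squares on the log scale with `log c` profiled out and `log2 k`
optimized on `[-log2 100, log2 100]` (the conventional cap). The
estimate flips sign exactly under a ref/alt swap. The reference
implementations compute aFC from normalized expression through their
own internal transform, which is not documented; this estimator is a
stated decision and magnitude comparisons to published aFCs are
qualitative only.

A credible set's effect on gene A is the PIP-weighted mean
`sum_i PIP_i log2(aFC_iA) / sum_i PIP_i` over its members, using the
per-effect posterior weights of that set. Across the cluster's genes,
`max |log2 aFC|` measures the largest single-gene effect and the
coefficient of variation of |log2 aFC| measures concentration: CV 0 is
perfectly distributed, large CV is one-gene-dominated. CV uses the
sample standard deviation (n−1): the source convention is unstated,
and this matches `sd()` everywhere else in the package; the convention
is frozen in the tests.

QTL-to-TSS distances are strand-signed (`variant − TSS` on +,
`TSS − variant` on −, so upstream is negative on both strands), taken
over every lead variant of a group × every transcript TSS, reporting
the signed value of the minimum-absolute pair (consistent with a
symmetric distance axis; the min-of-signed reading would collapse to
the most-upstream pair instead). Near-TSS means |d| < 250 bp.

## 6. Colocalization, groups, novelty

Each QTL signal is reduced to its per-variant log Bayes factor row
(the fitted single-effect lbf of its credible set's effect); GWAS
signals use Wakefield approximate Bayes factors with effect prior sd
0.15 (quantitative-trait default; configurable). For a pair of
signals over their common variant index the five hypothesis sums are
enumerated — H0 none, H1/H2 one signal only, H3 two distinct causal
variants (`S1*S2 - S4`), H4 one shared variant — with priors
`p1 = p2 = 1e-4`, `p12 = 5e-6` (standard defaults; the source is
silent) and log-sum-exp throughout, since lbf spikes overflow naive
sums. The result is symmetric in its arguments and sums to 1.

Credible-set groups are the connected components of the undirected
graph with QTL credible sets as nodes and edges where PP_H4 ≥ 0.75.
GWAS signals are *not* graph nodes; they are linked post hoc
(per-tissue: eQTL-linked if any eQTL reaches 0.75; pcQTL-only if a
pcQTL reaches it and no eQTL does; unique hits collapse by
variant-trait pair across tissues). A pcQTL credible set is **novel**
iff its group contains no eQTL credible set.

## 7. The synthetic world

`simulate_cohort()` draws: two AR(1) latent Gaussian haplotypes per
sample thresholded at per-variant allele frequencies (neighbor LD
`ld_decay = 0.9`, MAF uniform on [0.05, 0.5], 150 variants, 500
samples — the target tissues have N > 400); a gene cluster
`gene_g = loading_g (factor + shared_effect * g_causal) +
private_effect_g * g_private + noise`, inverse-normal transformed per
gene; uncorrelated background genes around the cluster (so the
Bonferroni divisor and null-window sampling are exercised); covariates
mixed into all genes; a positive linear-scale channel generated
through the allelic model with stated per-gene aFCs; and an
independent GWAS cohort (n = 10,000, target z = 8) sharing or not
sharing the causal variant. One global seed drives fixed substreams
per stage.

Preset worlds:

* `shared_strong` — factor variance 0.2, noise 0.4 (pairwise r ≈ 0.33,
  PC1 shared variance near where real correlated clusters sit), one
  causal variant with effect 0.5 on the shared axis. Detected by both
  routes; the expected outcome is a "both" group.
* `single_gene_strong` — one gene with a 0.6-SD private effect
  (aFC 1.5): the classic concentrated eQTL (high max |aFC|, high CV).
* `distributed_weak` — per-gene effects of 0.18 SD from one variant in
  an inverse-sign pattern (+, +, −, −) on four genes with factor
  variance 0.35 / noise 0.65. The design was stated as "PC1 detects";
  implementation showed that with all-positive effects the shared
  factor sits in PC1's sampling denominator, so any seed strong enough
  for PC1 also lights up single genes — across calibration grids the
  joint event "PC detects and every gene misses" plateaued near 45%.
  With inverse signs the effect lands on a *contrast* PC in which the
  factor cancels, the per-gene z stays ≈ 2.3 while the PC z roughly
  doubles, and the joint event clears a majority of seeds. This is
  also the mechanism of the motivating real example (a low-variance PC
  capturing inverse variation between two neighboring genes). The
  0.18-SD value is the calibration the preset definition itself calls
  for at n = 500.
* `null` — no factor, no genetic effect: no clusters, no credible
  sets.

What the generator does **not** emulate: realistic human LD maps
(AR(1) has no block boundaries or recombination hotspots), allele
frequency spectra, expression count noise or mappability artifacts,
trans-effects, or multi-tissue sharing. A green end-to-end test
therefore establishes internal consistency of the statistical
machinery under a plausible cohort — not performance on real GTEx
data, whose headline counts depend on protected genotypes and
genome-scale multiplicity.

## 8. Numerical choices and degenerate inputs

* Coordinates: BED is 0-based half-open on disk, VCF 1-based; every
  internal position is 1-based; converters sit only at the readers
  and writers.
* Missing genotypes: mean-imputed per variant; variants over 10%
  missing are dropped. (The upstream tools' handling is undocumented;
  this matches common QTL practice.)
* GWAS given only z and n: `se = 1/sqrt(n)`, `beta = z*se` — only z
  and n enter the Wakefield ABFs up to scale.
* MAF floor and the count-filter threshold are inclusive; the TPM
  threshold is strict (`> 0.1`), mirroring the stated wording; the
  "at least 20%" sample-share comparisons are `>=`.
* Zero-variance variant columns get lbf 0 and minimal posterior
  weight; zero-variance genes are an error at PCA (impossible after
  the expression filter) and undefined-correlation pairs are never
  significant.
* Beta permutation fit: Nelder-Mead on log shapes from a
  method-of-moments start; failure falls back to the direct p with a
  flag.
* Ties in min-|distance| and credible-set ordering resolve to the
  first occurrence in a deterministic order.

## 9. Known limitations

* The fine-mapper asserts statistical equivalence to the reference
  sum-of-single-effects implementation (recovery, calibration,
  exchangeability), not bitwise equality; prior-variance optimizer
  internals differ.
* Summary-statistic fine-mapping, functional priors, >10 effects,
  multi-trait colocalization and proportional tests are out of scope.
* aFC requires a positive linear-scale channel; it is not derivable
  from inverse-normal expression, so real-data use needs the
  upstream linear matrices.
* The enrichment module consumes annotation resources as plain
  tables; it does not compute enhancer predictions, GO propagation,
  or variant consequences.
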