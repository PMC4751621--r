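---
title: "Regional heritability mapping: models, choices, and what the simulations show"
author: "rhmscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional heritability mapping: models, choices, and what the simulations show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rhmscan)
```

## The problem

Single-SNP association scans miss loci whose effect is spread over several
variants, or whose causal variant is poorly tagged by any one genotyped SNP.
Regional heritability mapping (RHM) instead asks how much trait variance a
short genomic *region* explains: the genome is tiled with windows of
consecutive genotyped SNPs, and each window contributes a random genetic
effect whose covariance is a relationship matrix built from the window's
markers. A window with a real contribution raises the restricted likelihood
relative to a genome-wide polygenic model, however the signal is distributed
across the window's SNPs — including the case where the causal variant
itself was never genotyped and only its LD partners carry the signal.

`rhmscan` implements the full pipeline — quality control, phenotype
preparation, relationship matrices, REML variance components, the window
scan with fine mapping, a kinship-aware single-SNP scan (SSGWAS) for
comparison, and significance thresholds — plus a gene-dropping simulator so
every stage can be exercised and calibrated without access to restricted
cohort data.

## Models

### Phenotype preparation

Within each cohort the raw trait is adjusted for sex, age and age squared by
ordinary least squares, and the residuals are rank-transformed to the
standard normal, `qnorm((rank - 0.5)/n)` with average ranks for ties; the
cohorts are then merged. Age squared is used uncentered (centering changes
coefficients, not residuals). The (rank − 0.5)/n offset is the default; the
Blom offset 3/8 is available through `rank_inverse_normal(offset = 3/8)`.
Per-cohort processing means each cohort contributes an exactly
standard-normal sample, so cohort-level location/scale differences cannot
masquerade as genetic signal.

### Relationship matrices

With dosages $g \in \{0, 0.5, 1\}$ (allele-B fraction) and allele-B
frequency $p_k$ estimated from the analysis sample, the marker-based
relationship between individuals $i \ne j$ over a SNP set of size $m$ is

$$f_{ij} = \frac{2}{m_{ij}} \sum_k \frac{(g_{ik}-p_k)(g_{jk}-p_k)}{p_k(1-p_k)},$$

summed over SNPs non-missing in both individuals ($m_{ij}$ of them;
pairwise-complete sums are unbiased under missingness at random). The
diagonal uses the homozygosity-corrected form

$$f_{ii} = 1 + \frac{Obs(\#hom)_i - E(\#hom)_i}{m_i - E(\#hom)_i},
\qquad E(\#hom)_i = \sum_k \bigl(1 - 2p_k(1-p_k)\bigr),$$

so self-relationship reads $1 + \hat F_i$ with $\hat F_i$ an inbreeding
estimate, and the variance attached to a random effect with this covariance
is an additive genetic variance. The observed and expected homozygosity are
aggregated per individual before the ratio is taken. Two consequences worth
knowing: (1) the off-diagonal part of a matrix over a union of disjoint SNP
sets is exactly the $m$-weighted average of the per-set matrices, but the
diagonal correction, being a ratio, is not additive over SNP sets; (2) the
whole construction is invariant to relabeling the A/B alleles at any SNP.
The same formula serves the whole-genome matrix $G_w$ (all post-QC
autosomal SNPs — the scanned window's SNPs are *not* removed) and each
regional matrix $G_r$.

Sampling noise can leave small negative eigenvalues; `bend_psd()` raises
eigenvalues below a floor (default $10^{-6}$) and reconstructs, and is a
strict no-op on matrices that are already PSD. The scan bends $G_w$ once
up front; regional matrices are used as-is because the residual term keeps
the fitted covariance positive definite, and any Cholesky failure during a
window fit is treated as a rejected optimizer step.

### Variance components and the scan

The null model is $y = \mu + a + e$ with $\mathrm{var}(a) = \sigma^2_w G_w$;
the full model for a window adds $r$ with $\mathrm{var}(r) = \sigma^2_r G_r$.
Both are fitted by REML, maximizing

$$\ell_R = -\tfrac12\left[\log|V| + \log|X'V^{-1}X| + y'Py\right] + c,$$

with $X$ the intercept column. Fitting choices:

* Single-structure models (the null, and the SSGWAS polygenic fit) are
  solved in the eigenbasis of $G_w$: for a fixed variance ratio the scale
  profiles out in closed form, leaving a 1-D Brent search over the
  log-ratio. Eigenvalues within $10^{-12}$ of zero are treated as exact
  zeros — leaving the numerical noise in corrupts the profile at extreme
  ratios.
* Two-component models use Nelder-Mead over the two log variance ratios
  with the residual scale profiled out, warm-started from the null
  solution. Ratios are clamped to $e^{\pm 15}$: beyond that a component is
  numerically absent (heritability within $3\times10^{-7}$ of 0 or 1) and
  the dense solves lose accuracy to ill-conditioning.
* A boundary pass re-solves the model with any near-zero component pinned
  at exactly zero and keeps the better restricted likelihood; variances
  below $10^{-10}\,\mathrm{var}(y)$ are reported as 0.
* Each window's LRT is $\max(0,\, 2(\ell_{full} - \ell_{null}))$ with the
  null likelihood re-evaluated through the same dense code path, so route
  differences cannot produce spurious negative LRTs.

The scan also applies an exact boundary screen: at the null solution the
REML score for $\sigma^2_r$, $\tfrac12\,(y'PG_rPy - \mathrm{tr}(PG_r))$,
costs $O(n^2)$ per window once $V^{-1}$ is cached from the null eigen
decomposition. Windows with a non-positive score (plus two probe
evaluations as insurance against non-monotone profiles) have their REML
solution on the boundary $\sigma^2_r = 0$ and an exact LRT of 0, so the
optimizer run is skipped. This is an exact shortcut, not an approximation,
and it is what makes genome scans affordable: most windows in any scan are
null.

Heritabilities are reported as $h^2_r = \sigma^2_r/\sigma^2_p$ and
$h^2_w = \sigma^2_w/\sigma^2_p$ with
$\sigma^2_p = \sigma^2_w + \sigma^2_r + \sigma^2_e$, and the scan summary
averages $h^2_w$ across windows (with its standard error across windows).

### The null law of the boundary LRT

$\sigma^2_r$ is tested on its boundary, so the LRT is not $\chi^2_1$. The
package's default maps the statistic through the survival function of a
chi-square with 0.5 degrees of freedom, the fractional-df calibration in
long-standing use for regional variance-component scans; the theoretical
boundary mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ is available via
`lrt_to_neg_log10_p(method = "mixture")`. The fractional-df map is the
default because it reproduces the reference LRT→p conversions of published
regional scans to ~0.01–0.08 on the $-\log_{10}p$ scale, where the mixture
deviates by up to ~0.3; for large statistics the two differ by roughly
$\log_{10}2 \approx 0.3$, the mixture being more conservative. The test
suite reports both calibrations against null simulations: empirical LRT
quantiles sit below $\chi^2_1$ quantiles, and the fractional-df map is at
most mildly anti-conservative relative to the mixture.

A caution the test suite quantifies: null simulations show the scan's LRT
following the boundary mixture closely, which makes the fractional-df map
anti-conservative at the shallow tails of small scans; combined with the
halved test count, the genome-wide threshold construction controls the
family-wise error at 5% only to the extent that overlapping windows are
strongly dependent. In the simulator (adjacent-window LRT correlation
≈ 0.3) the realized family-wise error of a null genome scan is closer to
10% than 5%. The construction is retained because it is the method's
standard form; users wanting strict control can use the mixture mapping
and/or unhalved counts.

### Thresholds

Genome-wide thresholds are Bonferroni at family-wise $\alpha = 0.05$;
suggestive thresholds are the level at which one false positive per scan is
expected ($1/m$). For overlapping-window scans the raw window count is
halved to approximate the number of independent tests — each SNP sits in
two windows at 50% overlap — and the halved count is used verbatim even
when fractional (5,373/2 = 2,686.5), which is what reproduces the reference
thresholds 4.73 and 3.43 exactly. Summaries round to two decimals; all
machine-readable output keeps full precision. By default the pipeline
derives $m$ from the tests it actually performed; published counts can be
pinned through `paper_counts`.

### SSGWAS

The comparison method fits the polygenic null once and score-tests each SNP:
$T = [\tilde g' \hat V^{-1}(y-\hat\mu)]^2 / (\tilde g' \hat V^{-1}\tilde g)$
against $\chi^2_1$, with $\tilde g$ the centered dosage and missing dosages
mean-imputed for the test only. With $\hat\sigma^2_w = 0$ this reduces
exactly to the classical regression score test. The exact
$\hat V^{-1}$-weighted form is used (rather than a residual-based
approximation); the cached eigen decomposition makes the whole scan one
matrix product plus column sums.

## The simulator

`simulate_cohort()` produces the structures the model assumes, so that
recovery and calibration are checkable against known truth:

* **Genotypes.** Founder haplotypes draw each SNP's allele from a
  configurable MAF law (default uniform on [0.01, 0.5] with a 5% rare tail
  down to 0.001). Local LD is first-order copying: adjacent markers share a
  latent uniform with probability `ld_decay` (default 0.9), so marginal
  frequencies are exact while neighbouring markers correlate; the induced
  $r^2$ between neighbours depends on how similar their frequencies are,
  which makes tagging realistically variable. Families are two parents plus
  a configurable sibship, filled by gene-dropping with recombination
  between adjacent SNPs (default ≈ one crossover per chromosome); the rest
  of the sample are unrelated singletons. Missing calls are uniform, and a
  configurable number of SNPs is overwritten with heterozygote-free draws
  to emulate assay failures that violate HWE.
* **Phenotypes.** Trait = per-cohort covariate part (sex, age, age²) +
  regional part (equal-weight sum of standardized causal dosages) +
  polygenic part (independent normal weights on all non-causal SNPs) +
  normal residual. The polygenic part is residualized in-sample against the
  regional parts, and the residual against both, before each component is
  scaled to its exact empirical target variance — without this, LD-induced
  and finite-sample covariance between components perturbs the realized
  fractions by a few percent at cohort scale. `truth` records the realized
  fractions, which equal the targets by construction.
  Causal dosages come from the pre-missingness matrix, and
  `drop_causal_snps` removes the causal SNPs from the emitted data while
  keeping their effect — the ungenotyped-causal-variant scenario.
* **Determinism.** Everything derives from R's Mersenne-Twister stream
  seeded once from `config$seed` (genotypes) and `config$seed + 1`
  (phenotypes); identical configs are bit-identical.

Defaults mirror a three-cohort family study of 2,246 adults; tests override
sizes downward per scenario. What the simulator does *not* emulate:
realistic human LD maps and recombination hotspots, demographic history,
selection, assortative mating, X-chromosome inheritance, genotyping batch
effects correlated with cohort, or trait architectures with
dominance/epistasis. Passing tests therefore demonstrate internal
correctness and calibration of the estimator under the model's own
assumptions, not performance on any particular real cohort.

## Study scales used by the checks

The reference analysis ran ~2,250 individuals by 268,651 SNPs; REML scans
at that scale are cluster work. The package's checks keep the model and
pipeline identical and shrink the data, with these one-time choices:

* *Parameter recovery*: 50 replicates at n = 1,000, 5,000 SNPs (10
  chromosomes), one 100-SNP region with $h^2_r = 0.05$ on $h^2_w = 0.45$.
  Regional estimates carry a small downward bias (~0.015 here) because the
  window is 2% of this reduced genome and family covariance absorbs part of
  the regional variance into $\sigma^2_w$; at the reference scale the
  window is 0.04% of the genome and the effect is negligible.
* *Family-wise error*: 20 null scans at n = 300, 1,000 SNPs, 19 windows.
* *Score-test size*: 5,000 independent null SNPs at n = 400 (`ld_decay` 0
  so the per-SNP binomial reference applies).
* *Ungenotyped causal variants*: n = 1,000, 1,000 SNPs, one region with 20
  causal SNPs carrying $h^2_r = 0.15$, causal SNPs dropped from the emitted
  data. After the drop, imperfect tagging leaves roughly half the regional
  variance visible, so the emitted-data signal (~7%) and the
  signal-to-threshold ratio match the strongest fine-mapped region of the
  reference analysis at less than half its sample size; 20 causal SNPs
  (rather than a handful) keep the tagged fraction stable across seeds.

## Known limitations

* Dense REML is $O(n^3)$ per likelihood evaluation; n in the low thousands
  is the practical ceiling for genome scans on one core.
* The whole-genome matrix retains each scanned window's SNPs (matching the
  reference procedure); at small genome sizes this shrinks regional
  estimates, as quantified above.
* Fixed effects beyond the intercept are assumed absorbed upstream by the
  per-cohort adjustment; the variance-component models fit an intercept
  only.
* The exact HWE test conditions on allele counts; for extremely large
  samples the enumeration is $O(\min(n_A, n_B))$ per SNP, which is fine at
  cohort scale.
* `h2_region + h2_poly` near 1 leaves little residual variance and the
  profile search near its clamp; the simulator rejects configurations at or
  above 1.
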