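---
title: "Gene-based SNP-set association testing from GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-based SNP-set association testing from GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geneSAT)
```

## The model

geneSAT tests genes (or arbitrary genomic intervals) for association with a
trait using only GWAS summary statistics and an external genotype reference
panel. For a gene with $m$ variants, let $z_1,\dots,z_m$ be the per-variant
Z-scores, $z_j = \ln(\mathrm{OR}_j)/\mathrm{SE}_j$, oriented to each
variant's effect allele, and let $R$ be the $m \times m$ Pearson
correlation matrix of the corresponding reference-panel dosages (the LD
matrix). Under the null of no association the vector $z$ is asymptotically
$\mathrm{MVN}(0, R)$: the LD of the panel stands in for the correlation of
the Z-statistics.

Three SNP-set statistics are computed per gene:

* **Sum (burden) test**: $B = \sum_j z_j$, with null
  $B \sim N(0, \mathbf{1}^\top R \mathbf{1})$. Most powerful when effects
  share a direction and have similar sizes.
* **Squared-sum test**: $Q = \sum_j z_j^2$, whose null is the weighted sum
  $\sum_k \lambda_k \chi^2_1$ with $\lambda_k$ the eigenvalues of $R$.
  Robust to mixed effect directions.
* **Adaptive test**: $T = \min_{\rho \in [0,1]} P(Q_\rho)$ where
  $Q_\rho = (1-\rho) Q + \rho B^2$. $\rho = 0$ recovers the squared-sum
  test, $\rho = 1$ the burden test; the reported p-value accounts for the
  minimization over $\rho$.

The null of every $Q_\rho$ is a weighted chi-square: writing
$A_\rho = (1-\rho) I + \rho J$, the weights are the eigenvalues of
$A_\rho^{1/2} R\, A_\rho^{1/2}$, so the weight total at grid point $\rho$
is $(1-\rho)\,m + \rho\, \mathbf{1}^\top R \mathbf{1}$ (a conservation law
the tests assert).

## Numerical machinery

**Weighted chi-square tails** (`quadFormPvalue`) are computed by numerical
inversion of the characteristic function (an Imhof-type oscillatory
integral). The integrand is analytic, with a known value at the origin, an
oscillation frequency bounded by $(q + \sum_k w_k)/2$, and amplitude
decaying like $u^{-(1+m/2)}$; a composite Simpson rule sized to the
oscillation count evaluates it in one vectorized pass, with the quadrature
error estimated by halving the resolution and the truncated tail bounded
analytically. Two situations are special-cased: equal weights collapse to
an exact scaled chi-square, and weights below $10^{-10}$ of the largest
are dropped (their contribution is negligible but they stretch the
truncation range enormously). When the inversion cannot resolve the value
— estimated error comparable to the result, or p below $10^{-12}$ where
cancellation dominates — the Liu moment-matching approximation (scaled
non-central chi-square matched on skewness) is used and the method is
recorded per gene.

**The adaptive p-value** is obtained by a one-dimensional integration that
is exact for $z \sim \mathrm{MVN}(0,R)$. Conditioning on the standardized
burden $u = \mathbf{1}^\top z / \sqrt{\mathbf{1}^\top R \mathbf{1}}$, the
conditional law of $z$ is Gaussian with mean proportional to $u$ and
covariance $\Sigma_e = R - R\mathbf{1}\mathbf{1}^\top R / \mathbf{1}^\top
R \mathbf{1}$, so $Q \mid u^2{=}x$ is a *non-central* weighted chi-square
whose noncentralities grow linearly in $x$ (plus a deterministic
null-space shift). The event "every $Q_\rho$ stays below its $T$-level
quantile" reduces to an upper bound on $Q$ for $\rho < 1$ and a range
bound on $x$ for $\rho = 1$; integrating the conditional CDF over the
1-df density of $x$ gives $P(\min_\rho p_\rho \le T)$ without the
moment-matching of the classical minimum-p machinery. The conditional CDF
is tabulated on 21 nodes and interpolated with a monotone (Hyman) spline
before the outer quadrature. Per-$\rho$ quantiles come from a secant
inversion of the survival function seeded by the Liu quantile; below
$T < 10^{-3}$ the Liu quantiles and survival curves are used directly —
in that regime genome-wide decisions depend only on the order of
magnitude, and the reported p is clamped into the always-valid sandwich
$[T, |\mathrm{grid}| \cdot T]$.

A Monte-Carlo estimator (draws from $\mathrm{MVN}(0,R)$ via a square-root
factor with diagonal jitter at most $10^{-8}$,
$\hat p = (1 + \#\{T^* \le T\})/(N+1)$) serves as an independent
cross-check in the test suite and as a runtime fallback when integration
diagnostics fail; the method used is recorded in the results table. The
draw-level event $T^* \le T$ is evaluated by threshold inversion — some
$Q_\rho$ exceeding the exact $T$-level quantile of its own null — so no
per-draw tail evaluations are needed.

**The $\rho$ grid** defaults to the 11-point squared grid
$(0, 0.01, 0.04, \dots, 0.81, 1)$, denser near 0 where the optimum
typically lies for polygenic signals; any grid in $[0,1]$ may be supplied.

## Preprocessing choices

* **QC order is fixed** (autosomes → INFO → strand-ambiguous →
  non-biallelic → duplicate rsID) so the per-rule removal counts in the
  QC report are reproducible. The INFO rule defaults to *keeping*
  variants with INFO ≥ 0.9 — the standard imputation-quality filter —
  with `info_mode = "drop_above_literal"` available for sensitivity
  analyses; records with missing INFO are retained.
* **Z-scores** use $\ln(\mathrm{OR})/\mathrm{SE}$, the standard
  transformation for case-control summary statistics.
* **Gene membership** is inclusive on both interval ends (TSS–TES), with
  an optional symmetric padding (default 0 bp). Variants in overlapping
  genes count for every gene containing them: the per-gene tests are
  marginal, so sharing is harmless.
* **Harmonization** matches by position and allele pair against the
  panel, flips the Z sign when the effect allele is the panel reference
  allele, and drops incompatible pairs. Strand-complement rescue is
  deliberately not attempted; strand-ambiguous (A/T, C/G) variants are
  already removed upstream, where the ambiguity is detectable.
* **Perfect-LD pruning** removes the later-position SNP of any pair with
  $|r| \ge$ `r_max` (default 0.9999), scanning in position order against
  the already-kept set; the operation is a projection (idempotent), and
  genes falling below 2 SNPs are dropped with a reason.
* **Bundles** persist processed per-chromosome gene sets as delimited
  text (SNP tables plus LD matrices in long format, 17 significant
  digits) with an md5 manifest, so a round trip is bit-exact and runs are
  auditable.

## The synthetic-data generator

The generator produces every input the pipeline consumes, with known
ground truth:

* **LD structures**: AR(1) ($r^{|i-j|}$), equal blocks, or identity.
* **Z-scores**: $\mathrm{MVN}(\delta, R)$ via square-root factorization;
  $\delta = 0$ gives null genes, a constant per-SNP shift gives signal
  genes.
* **Genotype panels**: a latent-Gaussian threshold model — two correlated
  standard-normal vectors per individual thresholded at the MAF quantile
  and summed to a diploid dosage. The realized dosage correlation is
  *attenuated* relative to the latent target (dichotomization loses
  information); the pipeline estimates LD from the realized panel exactly
  as it would from real data, so calibration experiments are honest about
  this attenuation rather than correcting it.
* **Summary statistics**: per-gene Z-vectors drawn under the *realized*
  panel LD, converted to (OR, SE) via $\mathrm{OR} = e^{z \cdot
  \mathrm{SE}}$ with SE drawn uniformly in 0.02–0.08 (typical of
  well-powered meta-analyses), effect alleles randomly oriented to panel
  REF or ALT to exercise harmonization, and INFO drawn in 0.92–1.
* **Counts**: NB draws with log-uniform baseline means (20–500 by
  default), shared dispersion, per-sample size multipliers and per-gene
  true log2 fold changes.

What the generator does not emulate: realistic allele-frequency spectra,
coalescent haplotype structure, population stratification, imputation
error correlated with INFO, or phenotype-level ascertainment. Passing
calibration and power tests on these synthetics therefore demonstrates
the statistical machinery is correct under its stated model, not that
real-data results are immune to those upstream artifacts.

Default study sizes used by the test suite: type-I calibration uses 2,000
null genes (AR(1) $r = 0.5$, $m = 10$); the end-to-end experiment scans
50 genes with one signal gene ($\delta = 2$ per SNP) over 100 replicates
with a 200-sample panel; DE recovery uses 500 genes at 20 samples per
group. These sizes give binomial/Monte-Carlo noise well below the margins
being asserted while keeping the suite desk-scale.

## The differential-expression stage

The expression stage is a deliberately simplified negative-binomial
pipeline: total-count filter (≥ 10 across samples), median-of-ratios size
factors rescaled to geometric mean 1, a per-gene NB GLM with log link and
log size factors as offset, dispersion from pooled within-condition
moments floored at $10^{-8}$ (a fixed-dispersion mode supports exact
synthetic tests), a Wald test on the condition coefficient reported in
log2 units, and Benjamini–Hochberg adjustment. There is no dispersion
shrinkage, no outlier (Cook's distance) handling and no fold-change
shrinkage; at very small sample sizes the moment dispersions run liberal,
which the null-calibration test quantifies (KS distance to uniform at
$n = 10$ per group). The stage orders effects correctly and recovers
fold changes, which is what the integration report needs from it; users
wanting publication-grade expression analysis should substitute a
shrinkage-based tool and feed its table to `integrateResults()`.

A note on normalization and global shifts: median-of-ratios attributes a
fold change shared by *all* genes to sequencing depth. The parameter
recovery experiment therefore supplies the generator's known (unit) size
factors; real designs rely on most genes being null, as usual.

## Pipeline thresholds

Discovery uses a Bonferroni family-wise threshold
$\alpha_{fw}/\#\{\text{genes tested}\}$ (a nominal family size can be
configured instead, e.g. 20,000 genes giving $2.5\times10^{-6}$ at
$\alpha_{fw} = 0.05$). Replication retests only discovery-significant
genes against the replication summary statistics re-harmonized to the
same panel, at an unadjusted $\alpha = 0.05$ with a *strict* inequality
($p < \alpha$), so a boundary p-value of exactly 0.05 does not replicate;
both choices are configurable. The integrated report joins the three
stages by gene and flags genes passing discovery, replication and
expression simultaneously.

## Degenerate inputs and tie-breaks

Single-SNP genes make all three statistics coincide (handled in closed
form); all-zero Z gives p = 1 everywhere. Monomorphic panel variants are
dropped before LD estimation; missing genotypes use pairwise-complete
correlations. Eigenvalues are clipped at zero after symmetric
eigendecomposition and matrices symmetrized as $(R + R^\top)/2$.
Assignment ties at equal positions are broken by rsID; pruning keeps the
earlier-position SNP. Every stochastic routine takes an explicit seed and
restores the ambient RNG stream on exit.

## Worked example

```{r example, eval = FALSE}
td <- tempdir()
fx <- simulateSumstats(list(
  seed = 42, n_genes = 20, m_per_gene = 8,
  ld = list(type = "ar1", r = 0.5),
  delta = c(rep(0, 9), 2, rep(0, 10)),   # one signal gene
  panel_n = 200), file.path(td, "fixture"))

cfg <- list(discovery_sumstats = fx$sumstats, genes = fx$genes,
            panel_vcf = fx$panel, column_map = fx$column_map)
disc <- runDiscovery(cfg)
subset(disc$scan$results, significant)
```

## Known limitations

The LD panel must match the GWAS population; mismatch biases $R$ and
hence every p-value (the classic limitation of summary-statistic
methods). Genome-build liftover, meta-analysis across cohorts,
covariate-adjusted or conditional analyses, and haplotype-based LD are
out of scope. Far-tail p-values (beyond ~$10^{-12}$) rely on moment
matching and should be read as orders of magnitude.
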