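---
title: "Hologenomic variance decomposition: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hologenomic variance decomposition: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hologreml)
```

## The statistical model

`hologreml` decomposes the variance of a quantitative trait measured on a
cohort with SNP genotypes and taxon (ASV) relative abundances. The working
model for individual $i$ is

$$ y = Xb + g + e, \qquad g \sim N(0, K\sigma^2_k), \qquad
   e \sim N(0, I\sigma^2_e), $$

where $X$ holds fixed covariates (intercept, rearing batch, genetic
principal components, any numeric covariate) and $K$ is a similarity
kernel. With the genomic relationship matrix (GRM)

$$ g_{ij} = \frac{1}{N}\sum_{v=1}^{N}
   \frac{(x_{iv}-2\bar p_v)(x_{jv}-2\bar p_v)}{2\bar p_v(1-\bar p_v)}, $$

the ratio $\sigma^2_k/(\sigma^2_k+\sigma^2_e)$ is the SNP heritability
$h^2$; with the microbial relationship matrix (MRM), built as the average
cross-product of per-taxon standardized abundances, it is the
microbiability $m^2$. The GRM is invariant to which allele is counted,
because both the centering term and the variance denominator are symmetric
under $x \to 2-x$; we count the alternate allele with its observed
frequency. Missing dosages are mean-imputed to $2\bar p_v$ (the GCTA
convention), which makes them contribute exactly zero after centering.

The MRM standardizes each taxon with the *population* variance divisor
($1/n$ rather than $1/(n-1)$). This is a deliberate choice: it forces
$\mathrm{tr}(M)/n = 1$ exactly, so the kernel is on the same scale as a
GRM and $\sigma^2_k$ reads directly as a share of phenotypic variance. The
MRM is built from relative abundances as given (no reclosure after taxon
filtering), and because each taxon is standardized, $m^2$ is invariant to
rescaling the whole table.

## REML estimation

`reml_fit()` computes the *exact* profile restricted likelihood rather than
iterating AI-REML updates. The data are rotated onto the orthogonal
complement of $X$ (the definition of REML), the projected kernel is
eigendecomposed once, and for a candidate ratio $r$ the total variance
$\sigma^2_t = \sigma^2_k + \sigma^2_e$ has a closed-form maximizer. That
leaves a one-dimensional profile likelihood in $r$ on $[0,1]$, maximized
by a 21-point coarse grid followed by golden-section refinement on the
bracketing interval; the grid guards against the (rare) multimodal
profile. At desk scale (hundreds to a few thousand individuals) this is
simpler and more reliable than Newton-type iterations, and it cannot
diverge.

Numerical choices worth knowing:

* eigenvalues of the projected kernel are clamped at zero (relationship
  matrices are PSD in exact arithmetic; clamping absorbs roundoff);
* estimates are clamped to $[0,1]$ and flagged `boundary` rather than
  allowing negative components — a boundary fit is returned `converged`;
* the standard error of the ratio comes from the numerical curvature of
  the profile likelihood at the optimum, and is `NA` at a boundary, where
  the quadratic approximation is meaningless;
* a kernel numerically equal to the identity is rejected: the random
  effect would be indistinguishable from the residual.

### The permutation null for microbiability

An MRM built from a few hundred taxa is a high-dimensional kernel, and a
REML estimate against it can be inflated by chance alignment. `permute_m2()`
reorders the phenotype (together with its covariate rows) against the
kernel, refits, and reports the one-sided add-one p-value
$p = (1 + \#\{m^2_{perm} \ge m^2_{obs}\})/(n_{perm}+1)$, which can never be
zero. Because boundary clamping puts a point mass of null estimates at
exactly zero, an observed estimate of zero ties with most permutations and
yields $p$ near 1: the null distribution of $p$ is *super-uniform*
(conservative), never anti-conservative. The test suite checks validity —
$P(p \le \alpha) \le \alpha$ plus Monte-Carlo slack — rather than exact
uniformity for this reason.

## Mixed-model GWAS and significance thresholds

`lmm_gwas()` fits $y = W\alpha + x\beta + u + \varepsilon$ per SNP with the
variance components estimated once under the null and reused for every
variant (the EMMAX approximation; per-SNP re-estimation is available via
`exact = TRUE` and agrees closely at these scales). After whitening by the
null-fit covariance, each SNP is tested by generalized least squares. Two
p-values are reported: the 1-df likelihood-ratio p at the null variance
components (the headline `p_value`) and a Wald p using the $t$ reference
with per-SNP residual variance. The Wald path reduces *algebraically* to
ordinary least squares when the kernel is the identity, which the tests
exploit as an exactness check.

The genome-wide threshold is $\alpha/M_{\text{eff}}$ and the suggestive
threshold $1/M_{\text{eff}}$, where `simple_m_eff()` computes the effective
test count per block of consecutive SNPs as the minimal number of leading
eigenvalues of the SNP correlation matrix reaching 99.5% of its trace
(`c = 0.995`, `block_size = 1000` — the convention of the eigenvalue-based
correction this implements). With $M_{\text{eff}} = 150{,}802$ these
formulas give $3.32\times10^{-7}$ and $6.63\times10^{-6}$.

## Expression, eQTL and SMR

Expression preprocessing keeps genes with $\ge$ 0.1 TPM *and* $\ge$ 6 raw
reads in $\ge$ 20% of samples, then computes trimmed-mean-of-M (TMM)
between-sample factors (reference column nearest the mean upper quartile;
30% trim on log-ratios, 5% on average abundance; precision-weighted mean;
factors normalized to geometric mean 1). The implementation is written
from the TMM definition and is cross-checked against an independent
implementation in the test suite to $10^{-6}$.

For regression the package uses $\log_2(\text{TMM-scaled CPM}+1)$,
standardized per gene — a deliberate, documented transform choice. Hidden
expression factors are represented by the leading expression principal
components (`expression_pcs()`), a transparent stand-in for latent-factor
models; the number of components is the analyst's choice and enters as an
ordinary covariate matrix.

cis eQTL are variants within $\pm$1 Mb of the TSS (inclusive boundaries;
TSS is strand-aware: feature start on +, end on −). Per-gene multiplicity
is handled by permutation of the expression vector: the empirical p
compares the observed minimum nominal p against permuted minima, again with
the add-one rule (200 permutations by default — direct permutation rather
than a beta-tail approximation, a deliberate simplification at desk
scale). trans eQTL are variants on another chromosome or beyond $\pm$5 Mb
of the TSS with MAF > 5%, nominal p only. The two maps are disjoint by
construction, and variants falling between the cis window and the trans
exclusion belong to neither.

`smr_test()` treats the top eQTL as an instrumental variable:
$b_{xy} = b_{gwas}/b_{eqtl}$ and
$T_{SMR} = z_e^2 z_g^2/(z_e^2+z_g^2) \sim \chi^2_1$. The statistic is
bounded by $\min(z_e^2, z_g^2)$ — a weak instrument caps the attainable
evidence — and tends to $z_g^2$ as the instrument strengthens. A zero
eQTL effect leaves $b_{xy}$ undefined and is flagged, with $T = 0$.

## Taxon–phenotype association

Detection rate (the fraction of samples where a taxon is nonzero) drives a
three-way coding, applied to relative abundances as given:

| detection | coding | correlation |
|---|---|---|
| $\ge$ 60% | abundance with zeros recoded to `NA` | Spearman (or Pearson under `pearson-high`) |
| 30–60% | presence/absence | Spearman |
| < 30% | excluded | — |

Zeros in the high-detection stratum are treated as detection failures, not
true absences, hence the recode-to-missing with pairwise deletion. The two
method policies exist because rank-based correlation is the natural choice
against an ordinal grade while product-moment is conventional against
continuous biochemical traits; `rank` is the default. Benjamini–Hochberg
q-values are computed within each taxonomic level, mirroring per-level
reporting; an estimate requires at least 10 complete pairs (not a
literature constant — a package guard against meaningless correlations).
Alpha diversity (Shannon, Gini–Simpson) is delegated to `vegan` on
row-renormalized abundances.

## The synthetic cohort generator

The generator exists so that every estimator above can be validated against
known truths without any external data. Its defaults encode the study
conditions used throughout the validation suite:

* **Genotypes** — a Gaussian copula: within blocks of 100 consecutive
  SNPs, two AR(1) latent haplotype processes with autocorrelation
  `ld_rho = 0.3` are thresholded at each SNP's allele-frequency quantile;
  per-SNP frequencies are uniform on [0.05, 0.5]. The AR(1) copula is a
  modelling choice (real LD maps are not simulated); it produces the
  qualitative feature that matters — redundancy among nearby SNPs that
  effective-test counting must detect.
* **Microbiome** — zero-inflated log-normal: each taxon gets a detection
  rate from a profile mixing 25% near-core taxa (rate 0.95), 35%
  intermediate (0.55) and 40% rare (0.20) — the left-skewed prevalence
  shape 16S gut surveys show — and detected abundances are log-normal
  around a taxon baseline (SD 2 across taxa, overdispersion 1.5 within),
  rows closed to 1.
* **Phenotype** — batch fixed effects (2 batches, effect SD 0.5) plus
  Gaussian effects on 200 standardized causal SNPs, Gaussian effects on
  all varying taxa, and Gaussian noise. Each random component is rescaled
  so its *realized* sample variance equals its configured fraction
  (`h2_true`, `m2_true`, remainder) — recovery studies then compare
  estimates against a truth that holds in the generated sample, not just
  in expectation. Cross-component sample covariances of order
  $1/\sqrt n$ remain. The ordinal grade is the tertile coding of the
  latent trait, standing in for a three-level histology score; both the
  latent and ordinal traits are exposed, since either convention can be
  used downstream.
* **Expression** — negative-binomial counts (size 10) around
  $\exp(\text{baseline} + \beta \cdot \text{standardized dosage})$ for
  planted cis/trans effects.
* **Seeding** — one master seed; each table draws from a child stream
  `(seed * 1009 + stream) mod (2^31 - 1)`, so bundles are bit-identical
  under a fixed configuration and tables are decoupled.

What the generator does *not* emulate: real LD maps and allele-frequency
spectra, phylogenetic structure among taxa, spatial structure along the
gut, genotype–microbiome covariance (heritable taxa), and
genotype-by-environment effects. Passing recovery tests therefore show the
estimators are correct *under the model they assume*, not that real-data
estimates are unconfounded.

## Validation protocol sizes

The recovery studies used by the tests and the acceptance script are sized
to run on a single CPU in a couple of minutes while keeping the
Monte-Carlo error of a 30-replicate mean near 0.02: heritability recovery
uses 30 cohorts of n = 600 with 2,000 SNPs and 200 causal; microbiability
recovery 30 cohorts of n = 600 with 300 ASVs (1,000 SNPs for the PC
covariates); the permutation null one cohort of n = 500 with 200
permutations; the GWAS calibration 500 × 2,000. The REML optimizer is
checked against a 1,001-point grid evaluation of an independently coded
restricted likelihood on 20 random instances of n = 30.

## Known limitations

* Single-kernel fits only: $h^2$ and $m^2$ are estimated in separate
  models (genetics enters the $m^2$ model through PC covariates), so
  kernel-correlated signal is not partitioned jointly.
* The ordinal grade is analyzed as a quantitative trait; no threshold
  model or saddlepoint correction is provided.
* The eQTL permutation scheme permutes expression against genotypes and
  covariates jointly, which assumes exchangeability after covariate
  adjustment.
* SMR is the single-instrument statistic only — no heterogeneity (HEIDI)
  test, no conditional analysis, no colocalization posterior.
* `run_pipeline()` orchestrates the synthetic preset end to end; analyses
  of real files compose the exported readers and stage functions directly.
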