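---
title: "Methods: ratio phenotypes, the p-gain, and how this package validates them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ratio phenotypes, the p-gain, and how this package validates them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratioqtl)
```

## The model

For two circulating proteins measured on a log scale (Olink NPX units), the
package assumes the linear generative model

$$\log(P_i) = \alpha_i + \beta_i\,\mathrm{SNP} + \gamma_i\,W + \varepsilon_i,
\qquad i \in \{1, 2\},$$

where SNP is the effect-allele dosage (0/1/2), $W$ is unidentified
non-genetic variance shared by both proteins, and $\varepsilon_i$ is
protein-specific noise. Because NPX differences are log-ratios,

$$\log(P_1/P_2) = (\alpha_1-\alpha_2) + (\beta_1-\beta_2)\,\mathrm{SNP}
  + (\gamma_1-\gamma_2)\,W + (\varepsilon_1-\varepsilon_2).$$

The ratio association is stronger than either single-protein association in
two regimes: opposite-signed betas (the genetic contrast is
$|\beta_1| + |\beta_2|$) and comparable nonzero gammas (the shared variance
cancels). When betas *and* gammas are both shared, the ratio cancels
everything and is null — a useful negative control. These four regimes are
exactly the `scenario_preset()` options.

The improvement is measured by the p-gain,
$\min(p_1, p_2)/p_\text{ratio}$, held on the $\log_{10}$ scale throughout:
$\log_{10}(\text{p-gain}) = (-\log_{10} p_3) - \max(-\log_{10} p_1,
-\log_{10} p_2)$. No raw p-value is ever materialized anywhere in the
package; at biobank sample sizes $-\log_{10} p$ exceeds 3,000, far past
double-precision underflow ($p \approx 10^{-308}$).

## Key parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `sample_max_missing`, `protein_max_missing` | 0.2, 0.2 | completeness filter before network estimation; samples first, then proteins — the order changes the result and is fixed |
| `alpha` (GGM edges) | 0.05 | family-wise level over all $\binom{p}{2}$ pairs; with 1,463 proteins the per-test cut prints as $4.7\times10^{-8}$ |
| `geno/mind` missingness | 0.1 | per-variant / per-sample dosage missingness cuts |
| `maf_min`, `mac_min` | 0.01, 100 | minor-allele frequency / count floors |
| `hwe_p_min` | $10^{-15}$ | exact Hardy–Weinberg p floor |
| `pgain_alpha` | 0.05 | critical p-gain $1/(2\alpha) = 10$ per test, $\times$ the number of tests for Bonferroni |
| `genomewide_alpha` | $5\times10^{-8}$ | single-test genome-wide level, divided by the number of ratios in a scan |
| `pgain_base` | $10^{7}$ | genome-wide critical p-gain per ratio, multiplied by the number of ratios |
| cis / novelty / pruning windows | 1 Mb | strict inequalities: cis means *less than* 1 Mb from the nearest gene edge; novel means *more distant than* 1 Mb from any known pQTL of either protein |

All thresholds live in `default_config()` and can be overridden from a flat
`key: value` file (a YAML subset; no YAML parser is assumed in the
environment).

## Numerical choices

* **Extreme-tail p-values.** The two-sided t p-value is the regularized
  incomplete beta $I_x(\nu/2, 1/2)$ at $x = \nu/(\nu+t^2)$, evaluated on the
  log scale via `pbeta(log.p = TRUE)`. The test suite pins this against a
  frozen 66-point grid computed with 60-digit arbitrary-precision arithmetic
  (worst relative error in $-\log_{10} p$ below $10^{-9}$, against a
  tolerance of $10^{-6}$) and against the naive computation wherever the
  naive one does not underflow.
* **Shrinkage partial correlations.** The sample correlation matrix is shrunk
  toward the identity with the analytic Schäfer–Strimmer intensity
  $\lambda = \sum_{i\ne j}\widehat{\mathrm{Var}}(r_{ij}) / \sum_{i\ne j}
  r_{ij}^2$ (clipped to $[0,1]$), inverted, and standardized. At $\lambda=0$
  this reduces to direct inversion, verified to $10^{-10}$ against both
  brute-force inversion and full-conditional regression residuals. The
  reference implementation this mirrors (GeneNet) additionally fits an
  empirical-Bayes null; significance here is via Fisher's
  $z = \operatorname{atanh}(\hat\rho)\sqrt{n-3-(p-2)}$ instead, a documented
  deviation.
* **Exact HWE.** The heterozygote-count distribution conditional on allele
  counts is computed in log space with log-sum-exp normalization, so cohorts
  of any size are safe; configurations tied with the observed probability are
  included with a $10^{-10}$ relative tolerance (plink convention, no mid-p).
* **OLS.** Complete cases per test; the dosage coefficient follows QR
  pivoting, zero residual variance maps to a $-\log_{10}p = \infty$ sentinel,
  and a dosage that is constant in the analysis set is an error, not a
  silent NA.
* **Tie-breaks.** Distance pruning orders by strength, then position, then
  variant id, making the lead set invariant to input order (tested over
  permutations). Ratio orientation follows lexicographic protein order.
* **Degenerate inputs.** A ratio whose difference is constant is rejected
  rather than transformed; an all-missing protein cannot be
  minimum-imputed; an empty QC result reports the per-filter tally.

## The inverse-normal transform

Phenotypes are mapped to normal quantiles with the Blom offset,
$\Phi^{-1}\!\big((\mathrm{rank}-3/8)/(m+1/4)\big)$, average ranks for ties,
missing values left missing. The transform is applied **within each cohort**
(discovery and replication separately) to avoid leakage across the split.
Minimum imputation happens on the NPX scale before any transform, and only
for the network-estimation stage; association tests use per-test complete
cases without imputation.

## What the synthetic generator does and does not emulate

`generate_cohort()` draws genotypes per variant as Binomial(2, MAF)
(Hardy–Weinberg, no LD), shared factors and residuals as Gaussians,
covariates as age ~ U(40, 70), sex ~ Bernoulli(0.5), PCs ~ N(0, 1) with
zero default loadings, and missingness completely at random. The cohort
split is by assignment (first `n_discovery` samples), emulating the
discovery/replication interface of an ancestry-based split without modeling
population structure.

It does **not** emulate: LD between variants, relatedness or stratification,
non-Gaussian or heteroskedastic noise, limit-of-detection (left-censored)
missingness, plate/batch effects, or epitope artifacts. A green end-to-end
test therefore establishes that the statistical machinery is correct under
the stated model — not that the pipeline is robust to those real-data
complications.

Preset effect sizes are fixed once: $\beta = 0.2$ per allele
(opposite-beta scenario), $\beta = 0.3$ with $\gamma = 2$ for the
shared-factor scenario, MAF 0.3, residual sd 1. The shared-factor loading
must exceed the residual sd for the ratio to beat the single protein — the
ratio doubles the residual variance while removing $\gamma^2$ of shared
variance per protein — which is why $\gamma = 2$ rather than a smaller
value; with these choices both planted signals clear a
1,000-candidate Bonferroni p-gain threshold with power near 1 at
n = 4,000.

## Null calibration of the p-gain

The critical value $1/(2\alpha) = 10$ is a **bound**, not an exact quantile:
under the two-random-proteins null the simulated exceedance of p-gain 10 is
about 0.06–0.09% at n = 1,000 (10,000 replicates), far below the nominal 5%,
and stays below the bound across protein correlations
$\rho \in \{0, 0.3, 0.6\}$. The conservativeness comes from the positive
dependence of the three test statistics through the shared phenotypes. The
simulation exposes $\rho$ so both readings of "random proteins"
(independent or correlated) are testable; no parameter was adjusted to move
the exceedance toward 5%.

## Design choices where the design was open

* **Number of latent factors**: the model allows any `n_factors`; presets use
  one. Nothing in the desk-scale validation depends on the count.
* **Replication denominators**: discovery significance uses
  $10\times$ (candidates tested), replication uses $10\times$ (discovery-
  significant count), mirroring the published instances; both are parameters.
* **Fisher sidedness**: the enrichment test reports one-sided (upper tail)
  and two-sided p-values; for the worked cytokine-pair table the one-sided p
  meets the printed `< 0.002` bound while the two-sided p is 0.00204.
* **QC attribution**: a variant failing several filters is counted in each
  filter's tally; removal is the union, and removed + retained always equals
  the input count.

## Known limitations

Colocalization and fine-mapping of rQTL loci are out of scope, as are
BGEN/VCF dosage input, mixed models, X-chromosome handling, and any network
visualization. The regional-refinement workflow is represented by re-running
the ratio GWAS on a windowed variant subset rather than by separate
imputation machinery. The enrichment resampler draws distinct unordered
pairs uniformly from the stated protein universe; it does not preserve
degree structure of the query set.
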