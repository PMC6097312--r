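---
title: "Mapping the genetics of uniformity: models and design choices in hetvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the genetics of uniformity: models and design choices in hetvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In livestock populations, the *residual* variance of a trait — the spread
that remains after management groups, covariates and additive genetic merit
are accounted for — is itself partly heritable. Families differ not only in
mean performance but in how uniformly their offspring perform. `hetvar`
implements a complete analysis chain for mapping this "genetic heterogeneity
of residual variance" in a half-sib design: a few hundred genotyped sires,
each with a large group of phenotyped but ungenotyped progeny.

The chain is: (1) simulate or read a progeny-test data set; (2) fit a
bivariate sire DHGLM for the trait mean and the log residual variance; (3)
turn its solutions into pseudo-phenotypes (response variables) for
genotyped sires; (4) run a BayesC mixture-prior GWAS on each response with
per-sire residual weights; (5) summarise evidence as Bayes factors, 1-Mb
window variance shares, top-window overlaps and a scale-effect test.

## The sire DHGLM

For progeny record $y_{ij}$ of sire $i$:

$$ y_{ij} = \mathbf{x}_{ij}'\mathbf{b} + s_i + e_{ij}, \qquad
   e_{ij} \sim N(0,\ \phi_{ij}), \qquad
   \log \phi_{ij} = \mathbf{x}_{ij}'\mathbf{b}_v + s_{v,i} $$

with fixed effects (both parts) contemporary group and linear/quadratic age
nested within sex, and sire effects
$(s_i, s_{v,i}) \sim N(0, \mathbf{G}_0)$ where $\mathbf{G}_0$ holds
$\sigma^2_s$, $\sigma^2_{sv}$ and their covariance. The genetic correlation
$r_{mv} = \mathrm{cov}(s, s_v)/\sqrt{\sigma^2_s \sigma^2_{sv}}$ couples
mean and dispersion. `fit_dhglm()` supports two modes: `rmv_free`
(covariance estimated) and `rmv_zero` (covariance pinned at zero, which
decouples the two parts exactly; the package tests verify the decoupling
against a stand-alone weighted sire model to 1e-8).

Estimation iterates the standard interconnected-GLM linearisation: given
current $\phi$, the stacked mean/dispersion mixed-model equations are
solved jointly; squared mean-model residuals are converted to the working
response $\psi_{ij} = \log\phi_{ij} + \hat e_{ij}^2 /((1-h_{ij})\phi_{ij}) - 1$
whose record variance is fixed at $2/(1-h_{ij})$ (the asymptotic variance
of a scaled one-df chi-square; $h$ is the record's leverage); $\mathbf{G}_0$
is updated by EM-REML, $\mathbf{G}_0 \leftarrow (\mathbf{U}'\mathbf{U} +
\sum_i \mathrm{PEV}_i)/q$; and $\phi$ is refreshed from the dispersion-part
fit. EM was chosen over average-information updates because it cannot leave
the parameter space; when rounding still produces an indefinite
$\mathbf{G}_0$ it is bent by flooring eigenvalues at 1e-8. Convergence
requires both max $|\Delta \log \phi| < 10^{-6}$ and variance-component
changes below $10^{-5}$ of the dominant component's scale (defaults; both
are arguments). Measuring the component change against the dominant scale
rather than each component's own magnitude keeps a variance collapsing to
its zero boundary — where EM creeps — from stalling the declaration.

Computationally, the fixed effects are absorbed so only the
(parts × sires)-dimensional random block is ever inverted; per-record
leverages and per-sire prediction-error (co)variances come from that block
via the identity
$t'C^{-1}t = x'F^{-1}x + (Kx - z)' D (Kx - z)$. This keeps a fit with
hundreds of sires and tens of thousands of records in seconds per
iteration; the solver is verified against a dense GLS oracle on small
instances.

A note on scales: the generator draws sire genetic *values* $A_m, A_v$ and
progeny receive half of them, so the model-scale components estimated by
the DHGLM are one quarter of the configured `sigma2_s`, `sigma2_sv`. The
correlation `r_mv` is scale-free.

## Response variables

Four pseudo-phenotypes per sire, mirroring the common practice for
variance GWAS:

* `dEBV_m`, `dEBV_v`: deregressed EBV of the mean and variance parts of
  the `rmv_free` fit;
* `dEBV_v_r0`: deregressed variance-part EBV of the `rmv_zero` fit;
* `lnvar`: $\ln \hat\sigma^2_{\hat e}$, the log sample variance (n−1
  denominator) of the `rmv_zero` mean-model residuals within each family.

Deregression uses the founder (no-parent-average) form, `dEBV = EBV/r²`
with `r² = 1 − PEV/σ²ₛ`, and GWAS weight
`w = (1 − h²)/((c + (1 − r²)/r²) h²)`. The no-parent-average variant is the
appropriate one here because the sires are simulated unrelated; the
parent-average-removal equations are an extension point. `c`, the fraction
of genetic variance not captured by markers, defaults to 0.5 (a
conventional choice; it only rescales weights smoothly). In the degenerate
shrinkage-free case `r² = 1` with `c = 0`, the weight reduces to
`(1 − h²)/h²`. Heritabilities entering the weight are computed from the
fit's own components via the sire-model identity
`h² = 4σ²ₛ/(4σ²ₛ + mean residual variance)` rather than taken from
literature. `lnvar` is deliberately *not* adjusted for contemporary-group
effects on the variance: it is the "few-adjustments" response, and that
simplicity (plus possible non-genetic contamination) is part of what the
response comparison is meant to expose.

## BayesC with heterogeneous weights

Each response `y` (one record per sire) is analysed with
$y = \mathbf{1}\mu + \sum_i \mathbf{z}_i a_i \delta_i + \mathbf{e}$,
$\mathbf{e} \sim N(0, \mathbf{R}\sigma^2_e)$, where $\mathbf{R}$ is
diagonal: $1/w_i$ for deregressed responses and $1/n_i$ (reciprocal progeny
count) for `lnvar`. The prior proportion of zero-effect SNPs is fixed at
$\pi = 0.999$. $\sigma^2_a$ and $\sigma^2_e$ carry scaled inverse
chi-squared priors with 4 degrees of freedom; scales default to
`resid_prop * var(y)` for the residual and to an expected genic share
(`genic_prop * var(y)`, default 0.5) spread over the $M(1-\pi)$ SNPs the
prior expects in the model, divided by the panel's mean heterozygosity.
Genotypes are mean-imputed (missing calls) and mean-centred; no variance
standardisation, so effects stay on the allele-substitution scale.

The Gibbs sampler updates $(\delta_i, a_i)$ jointly from the collapsed
conditional. Two algebraically identical execution paths exist: a direct
one (dot product per SNP per sweep) and a default fast path that
precomputes the weighted Gram matrix $Z'WZ$ and keeps every SNP's score
current in O(M) per effect change, refreshing from scratch every 2000
sweeps against floating-point drift; the test suite checks both paths
produce bit-identical chains. Correctness is established two independent
ways: at $\pi = 0$ the posterior mean effects match the closed-form ridge
solution, and on a 3-SNP instance with pinned variances the inclusion
probabilities match exact enumeration over all $2^3$ models.

Desk-scale chain defaults are 50,000 iterations, 10,000 burn-in, thinning
50; full-scale settings (550,000/150,000 for variance responses,
250,000/50,000 for the mean) are available through `bayesc_config()`.
Convergence is monitored with a Geweke z on each hyperparameter chain
(first 10% vs last 50%, spectral density at zero estimated by an AR fit,
the standard MCMC estimator).

## Inference summaries

SNP significance uses the Bayes factor
`BF = (p/(1-p)) / ((1-π)/π)` with thresholds 3 (suggestive) and 20
(strong); a posterior probability of exactly 1 is capped at
`1 − 1/(kept samples + 1)` so the odds stay finite, and the cap is logged.
Window summaries allocate SNPs to non-overlapping megabase bins
(`floor((bp−1)/1e6)`, reported with 1-based `Chr_Mb` labels), compute the
variance of each window's genomic values from posterior-mean effects and
realised genotypes, and report it as a percentage of the variance of the
total genomic value (default) or of the sum over windows — the two
conventions differ only through linkage disequilibrium between windows,
and both are implemented because reference GWAS software is not explicit
about which it reports. Under linkage equilibrium the shares are additive
(the tests require the sum to lie in [95, 105]% with 2,000 individuals).
Top-K window overlaps use set semantics with deterministic tie-breaks. The
scale-effect test divides a SNP's absolute effect on the mean response by
the trait mean and its effect on the variance response by the mean
residual variance; a strictly larger standardised variance effect flags
action on the variance beyond a pure scale effect.

## The synthetic-data generator

`sim_config()` defaults describe a yearling-weight-like progeny test: 423
sires; progeny group sizes log-uniform on [50, 800] (an optional
calibrated truncated log-normal reproduces the full-scale 50–10,180 range
with mean 411 when asked); trait mean 280 kg; baseline residual variance
`exp(eta0) = 600` kg²; sire-value variances `sigma2_s = 130` kg² (i.e. a
heritability near 0.2 on the phenotypic scale) and `sigma2_sv = 0.2` on
the log-variance scale; genetic correlation `r_mv = 0.76`; contemporary
groups assigned uniformly at random with 10 kg standard deviation; age
uniform on [300, 420] days with small sex-nested linear and quadratic
coefficients. QTL for the two scales are disjoint SNP sets whose effects
are scaled to explain a configured share (default 20%) of each genetic
variance; the polygenic remainder carries all of the cross-scale
covariance, which caps the feasible `|r_mv|` at the geometric mean of the
polygenic shares — infeasible combinations error rather than silently
rescale. Genotypes are binomial Hardy-Weinberg draws (optionally with a
copy-neighbour block-LD mode and missingness).

What the generator does *not* emulate matters for interpreting green
tests: no pedigree relationships among sires, no selection, no
skewness or heavy tails in the residuals, no contemporary-group effects on
the *variance*, and LD only of the simple block kind. Passing tests
demonstrate internal correctness and statistical behaviour under this
idealised design, not performance on real cattle data.

## Monte Carlo problem sizes

The test suite runs its heavier checks at deliberately reduced scale so a
full run stays in the minutes range: DHGLM parameter recovery uses 10
replicates of 400 sires × 150 progeny (the estimates are effectively
unbiased there: across replicates the mean `r_mv` lands within a few
hundredths of the generating 0.76 and mean `sigma2_sv` within ~5% of
truth); null calibration uses 423 sires × 2,000 SNPs with 50,000-sweep
chains; the end-to-end pattern replicates use 220–300 sires with ~450
SNPs and shortened chains. The acceptance script runs a 300-sire study at
similar sizes.

## A caveat the pipeline itself exposes

One documented expectation could not be reproduced and is, we argue,
unreproducible under this generative model: that with a strong positive
`r_mv` the deregressed mean and variance EBV correlate highly (they do,
~0.8) *while* `dEBV_m` and `lnvar` stay essentially uncorrelated. If
`r_mv = 0.76` is a real correlation between genetic effects on the mean
and on the log residual variance, then the within-family residual variance
— which is what `lnvar` measures, with accuracy ~0.7–0.85 at these family
sizes — must correlate with mean genetic merit at roughly
`r_mv × acc_m × acc_lnvar ≈ 0.5–0.6`, and it does in our simulations. A
near-zero `corr(dEBV_m, lnvar)` alongside a high fitted `r_mv` can arise
in real data (for instance if the fitted correlation is partly an artefact
of residual skewness or scale effects in the coupled model), but not from
a Gaussian generative model in which `r_mv` is literally true. The
acceptance suite therefore reports this correlation honestly rather than
forcing it into a narrow band; see the repository notes for the full
analysis.

Similarly, with 423 observations and 2,000 null SNPs, BayesC's posterior
routinely grants a handful of chance-correlated SNPs `BF > 20`
(expectation on the order of one per run), and the *mean* posterior
inclusion probability under a no-signal response sits slightly below the
prior (0.0003 vs 0.001) because the residual variance absorbs everything
and the marginal likelihood ratio is right-skewed with most mass below 1.
Both behaviours are properties of the model at this sample size — the
sampler itself is verified exact by enumeration — and the calibration
checks report them as measured.

## Known limitations

Animal-model (pedigree) DHGLM, parent-average-aware deregression, π
estimation, multi-trait extensions, genotype imputation and functional
annotation are out of scope. The Geweke diagnostic uses fixed segment
fractions; the sampler stores only thinned hyperparameter chains, not
per-SNP effect chains.
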