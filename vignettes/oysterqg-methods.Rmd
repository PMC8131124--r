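---
title: "Quantitative genetics of oyster larval salinity tolerance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genetics of oyster larval salinity tolerance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oysterqg)
```

## The scientific problem

Eastern oysters (*Crassostrea virginica*) in the northern Gulf of Mexico face
declining estuarine salinity. Whether populations can cope depends on two
quantities this package estimates from a breeding experiment: the additive
genetic variance of larval body size under low (8 psu) versus ambient
(15 psu) rearing salinity — i.e., the raw material for evolutionary
adaptation — and the contribution of transgenerational plasticity (TGP),
i.e., effects of the *parents'* salinity environment on offspring phenotype.

The experimental template is a modified North Carolina II block design:
within each of 16 blocks, eggs of four dams (two per parental acclimation
site) are each fertilized by two sires (one per site), giving eight crosses
per block. Fertilization failure is severe (about 68% of crosses are
discarded), so the realized data are an unbalanced subset of the planned
design. Offspring of each surviving family are split between the two rearing
salinities and their maximum anterior-posterior length is measured at 5 days
post-fertilization.

## The animal model

The core estimator is a Gaussian "animal model" fitted separately per
rearing salinity:

$$y = \mu + \beta_1\,\mathrm{DamAcclim} + \beta_2\,\mathrm{SireAcclim}
      + Z_1\,\mathrm{Animal} + Z_2\,\mathrm{DamID} + \varepsilon,$$

where `Animal` is each individual's additive genetic value with covariance
$\sigma^2_a A$ ($A$ = additive relationship matrix from the pedigree),
`DamID` is a dam-level random intercept capturing non-genetic maternal
effects (egg provisioning, epigenetics) with variance $\sigma^2_m$, and
$\varepsilon$ is i.i.d. residual noise with variance $\sigma^2_e$.
Narrow-sense heritability and the maternal ratio are component ratios,

$$h^2 = \frac{\sigma^2_a}{\sigma^2_a + \sigma^2_m + \sigma^2_e},
\qquad
m^2 = \frac{\sigma^2_m}{\sigma^2_a + \sigma^2_m + \sigma^2_e},$$

computed per MCMC draw; the denominator deliberately excludes fixed-effect
variance (the component-ratio convention — conventions differ across the
literature, so this is stated explicitly).

### Priors

Each variance component gets a scaled inverse-chi-square prior — the
univariate case of the inverse-Wishart — parameterized by a scale $V$ and
degrees of belief $\nu$. `default_priors()` partitions the sample
phenotypic variance equally among all random terms ($V = V_p/3$ for the
animal, dam, and residual terms) with $\nu = 1$; fixed effects get
effectively flat $N(0, 10^8)$ priors. `prior_sensitivity()` refits under
alternative $\nu$.

A finding worth stating prominently: at the realized design size of this
experiment (roughly 12 sires, 21 dams, 27 families per salinity), the
partition of variance between the animal, dam, and residual terms is only
weakly identified by the likelihood — the sire side contributes about a
dozen effective observations on $\sigma^2_a$, and dam-side genetic variance
is confounded with maternal variance. As a consequence the posterior for
$h^2$ is wide (95% intervals span roughly half the unit interval) and its
location is materially sensitive to $\nu$: near-scale-free priors
($\nu \approx 0$) push the maternal component to zero and $h^2$ towards
one, while $\nu$ of a few concentrates the components near the
equal-partition scale. Replicate simulations in the test suite show that
credible intervals remain calibrated (they cover the generating value at
roughly the nominal rate), but *point* estimates of $h^2$ shrink noticeably
toward the prior. Single-dataset point estimates at this design size should
therefore be read together with their intervals, not alone.

### Samplers

Two exact Gibbs samplers target the same posterior:

* **Reduced sampler** (default; Rcpp). For the strictly two-generation
  pedigrees this package produces — unrelated non-inbred founders, each
  phenotyped larva a terminal offspring with one record — each offspring
  breeding value decomposes into midparent plus an independent Mendelian
  deviation with variance $\sigma^2_a/2$. Marginalizing the Mendelian
  deviations analytically leaves records conditionally independent given
  founder effects, with residual variance $\sigma^2_a/2 + \sigma^2_e$. The
  joint Gaussian location block (fixed effects, founder breeding values, dam
  effects) is then only ~90-dimensional, and $\sigma^2_a$, $\sigma^2_e$ are
  updated by univariate slice sampling on the log scale ($\sigma^2_m$ stays
  conjugate). This removes the crippling coupling between a
  thousand-dimensional latent block and $\sigma^2_a$ that makes the naive
  animal-model Gibbs sampler mix slowly, at identical posterior.
* **Mixed-model-equations reference sampler** (`gibbs_mixed_reference`,
  pure R). The textbook formulation: all pedigree individuals' effects are
  drawn jointly from the MME full conditional using the sparse inverse
  relationship matrix, with conjugate scaled inverse-chi-square variance
  draws. It handles arbitrary pedigrees and known-variance (GLS/BLUP)
  degenerations, and the test suite checks that both samplers agree within
  Monte Carlo error and that conjugate special cases match their closed
  forms.

All randomness flows through R's RNG from named sub-streams of one master
seed (`substream_seed()`), and phenotype rows are sorted canonically before
fitting, so results are bit-reproducible and invariant to input row order.
Production chain lengths mirror 1.3M iterations with 300k burn-in
(`mcmc_settings()`); simulation studies and tests use scaled chains
(`mcmc_settings_scaled()`, 25k–50k iterations), which diagnostics
(`mcmc_diagnostics()`: lag-1 autocorrelation, effective sample size) show
are amply mixed for the reduced sampler.

### Posterior summaries

Point estimates are reported as posterior means and kernel-density modes
(`posterior_mode()`, `stats::density` defaults); intervals as both
highest-posterior-density (shortest-window) and central quantile intervals.
Variance draws are strictly positive by construction — no zero-truncation
adjustments.

## The bivariate family-mean model

The cross-environment genetic covariance is estimated from family means:
$y_{fe} = \mu_e + g_{fe} + \varepsilon_{fe}$ with
$\mathrm{vec}(g) \sim N(0,\, G \otimes A_\mathrm{fam})$, a 2x2 genetic
covariance $G$ under an inverse-Wishart prior (scale $\nu V$ with
equal-partition $V$ and minimal proper $\nu = 2$), and *diagonal* residual
covariance — different larvae are measured in the two environments, so
residuals cannot covary. $A_\mathrm{fam}$ treats families as
pseudo-individuals whose "parents" are their sire and dam (half-sib families
get relationship 0.25); this linkage is an assumption, and an `linked =
FALSE` mode treats families as unrelated instead. Families measured in only
one environment enter through their observed cell (missing at random). The
covariance $G_{12}$ is identified directly by the cross-environment
covariance of family means; the diagonal split between $G_{ee}$ and the
residual is, as in the univariate case, weak at ~27 families and the same
prior-shrinkage caveat applies.

## Mixed-model ANOVAs for environment and TGP

`fit_lmm()` / `anova_table()` / `tukey_contrasts()` standardize the
environmental and TGP tests on REML with dam and sire random intercepts
(no pedigree covariance here — genetic covariance belongs to the animal
model), marginal Type-III F tests with sum-to-zero contrasts and
Satterthwaite denominator degrees of freedom, and Tukey HSD cell contrasts.
Percent differences are reported relative to the smaller cell mean (the
"X% larger" convention) with delta-method standard errors. REML fitting,
Satterthwaite approximation, and the studentized-range adjustment are
delegated to lme4, lmerTest, and emmeans; exact replication of any
particular dataset's denominator df is convention-dependent and is not a
target. Mortality is analysed on the proportion scale with family as the
unit; egg-quality assays are log-transformed, tested per assay for an
acclimation-site effect, and regressed against family-mean larval size with
dam/sire random intercepts.

## Selection calculations

`selection_differential()` and `predicted_response()` implement the
breeder's equation $R = h^2 S$ in both directions. For lower-tail truncation
culling of a normal phenotype, `truncation_intensity()` gives
$i = \phi(z)/(1-q)$ with $z = \Phi^{-1}(q)$, and
`required_culling_fraction()` inverts it by bracketed root finding
(tolerance $10^{-8}$). The normality assumption is the standard reading of
truncation-selection theory; `empirical_selection_differential()` provides a
distribution-free cross-check that deletes the smallest fraction of an
observed phenotype vector directly. With the published inputs — a 3.4 µm
per-generation deficit, $h^2 = 0.68$, and
$\sigma_p = \sqrt{V_a/h^2} = 14.38$ µm — the required differential is 5 µm
per generation and the required culling fraction about 20%, i.e. within the
smallest quartile.

## The synthetic-data generator

Because the raw measurements are not public, every analysis stage is
exercised on synthetic experiments whose generative parameters are
calibrated to the published summaries (`default_params()`):

* **Variance components.** Additive variances 140.7 / 122.3 µm² (low /
  ambient); $V_p = V_a / h^2$ with $h^2$ = 0.68 / 0.66; maternal variance
  $m^2 V_p$ with $m^2$ = 0.11 / 0.16; residual the remainder (43.5 / 33.4
  µm²). Founder breeding values are *bivariate* across environments with
  covariance 55.18 µm² (genetic correlation 0.42), so the individual-level
  and family-mean structures are mutually consistent. Offspring get
  midparent plus bivariate Mendelian noise with covariance $G/2$
  (non-inbred founders; the inbreeding-adjusted Mendelian term is
  documented but off by default, as the designs never mate relatives).
  Maternal effects use one standard-normal deviate per dam scaled by the
  per-environment maternal SD (cross-environment correlation 1 — the data
  offer no information on this, and it does not enter any single-environment
  fit).
* **Means and fixed effects.** The ambient grand mean is 3.4/0.045 = 75.56
  µm, so the grand low-salinity effect of -3.4 µm is the published ~4.5%
  reduction. Parental acclimation sites are coded ±1/2 (centered), with
  interaction defaults chosen to reproduce the dam-side contrast pattern: a
  ~9% ambient-vs-low gap under low-acclimated dams and none under
  medium-acclimated dams. The published dam-side and sire-side contrast
  sets are mutually inconsistent with any additive two-way-interaction
  surface (their marginal averages differ), so the dam pattern and the
  grand 3.4 µm effect are matched exactly and the sire contrasts come out
  about half a percentage point larger than printed. Acclimation-site main
  effects are not printed and default to small values (+1.5 / +0.5 µm).
* **Design and attrition.** 16 blocks with dam reuse tuned so 19 (low-site)
  and 21 (medium-site) distinct dams fill the 32 + 32 dam slots, every
  reused dam meeting four sires; fertilization failure Bernoulli(0.68);
  family-by-treatment retention 0.86 and per-larva measurement rates 0.73 /
  0.79 so that paper-scale runs land near the published totals of 1248 /
  1379 measured larvae over ~34 / 35 families per treatment (the published
  per-family counts are not itemized, so these two rates are the
  generator's own reconciliation of "about 50 larvae per cross" with the
  printed totals). Parameter-recovery designs instead fix exactly 50
  measured larvae per family and target the realized estimation subsets
  (12 sires / 21 dams / 27 families at low, 13 / 24 / 29 at ambient).
* **Survival and egg quality.** Family-by-treatment mortality is
  logit-normal around 27% (logit-scale SD 0.5, a moderate overdispersion
  choice) with no treatment or parental-site effect; egg-quality assays
  (protein and five lipid classes) are log-normal per dam with no site
  effect and no link to larval size by default — the published null
  structure — with injectable site effects for power studies. Assay means
  and SDs on the log scale are not published; the defaults are plausible
  per-egg biochemistry scales and only the null structure matters to any
  test.
* Lengths are truncated at zero by resampling (not clipping), keeping the
  distribution smooth; at the calibrated mean/SD this is astronomically
  rare. The 24-h stepwise larval salinity acclimation is not modelled
  mechanistically; it is absorbed into the treatment effect.

What the generator does *not* emulate: non-normal length distributions,
block effects (the published residual-vs-block diagnostic showed none; the
pipeline reproduces that diagnostic plot), density dependence in culture,
within-family measurement correlation, and realized per-family count
jitter beyond the binomial measurement model. Passing tests therefore
demonstrate that the estimators recover the assumed Gaussian
variance-component world at the study's design size — not that the model is
correct for any particular real dataset.

One consequence of the calibrated genetic correlation (0.42) deserves
emphasis: family-level genotype-by-environment deviations add variance of
order $(V_{a,\mathrm{low}} + V_{a,\mathrm{amb}} - 2\,\mathrm{cov})/2
\approx 76$ µm² to any ambient-minus-low family contrast. Single-replicate
salinity ANOVAs on fully calibrated data are therefore far noisier than the
published F statistics suggest — the published strong salinity F and the
published covariance are in tension. Tests that probe the ANOVA machinery's
power use a no-G×E parameter variant; replicate averages (as in the
acceptance study) are unaffected in expectation.

## Problem sizes used in simulation studies

As the package's own choices: univariate recovery studies use 20 replicate
datasets per salinity with 50k-iteration scaled chains; the bivariate
covariance study 50 replicates with 12k-iteration chains; the ANOVA
round-trip 50 replicate paper-scale experiments; interval-calibration
checks 200 replicates with shorter chains. The tiny pipeline configuration
(4 blocks, 10 larvae per family, 4k-iteration chains) runs in seconds and
drives the end-to-end tests.

## Known limitations

* Two-generation pedigrees only (the design never produces deeper ones);
  the reduced sampler's assumptions are checked and the MME reference
  sampler covers general pedigrees at small scale.
* Gaussian response only; no REML/likelihood-ratio alternative for the
  animal model is provided.
* Founder relatedness is assumed zero (hatchery records were lost); this is
  a documented configuration assumption, not an estimate.
* Variance-component point estimates at the study's design size are
  prior-sensitive (see above); the package reports intervals and provides
  the sensitivity runner rather than pretending the data decide alone.
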