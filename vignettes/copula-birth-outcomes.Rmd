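---
title: "Joint modelling of low birth weight and preterm birth with copbirth"
author: "copbirth authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modelling of low birth weight and preterm birth with copbirth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copbirth)
```

## The model

Low birth weight (lbw, birth weight below 2.5 kg) and preterm birth (ptb,
gestation under 37 completed weeks) are strongly dependent binary outcomes:
analysing them separately discards information about how the risks co-occur.
`copbirth` fits a **copula distributional regression** — a bivariate probit
model in its default configuration — in which *three* distribution
parameters each get their own predictor:

$$
\Phi^{-1}(\mu_{ji}) \;=\; \mathbf{x}_i^\top\boldsymbol\beta_j
 + s_{1j}(\mathrm{age}_i) + s_{2j}(\mathrm{county}_i), \qquad j = 1, 2,
$$
$$
\operatorname{atanh}(\theta_i) \;=\; \mathbf{z}_i^\top\boldsymbol\beta_\theta ,
$$

where $\mu_{ji} = P(Y_{ji} = 1)$ are the margin probabilities and
$\theta_i \in (-1, 1)$ is the record-level dependence parameter of a
Gaussian copula $C$.  The joint cell probabilities follow from the copula:

$$
p_{11} = C(\mu_1, \mu_2; \theta), \quad
p_{10} = \mu_1 - p_{11}, \quad
p_{01} = \mu_2 - p_{11}, \quad
p_{00} = 1 - \mu_1 - \mu_2 + p_{11}.
$$

With probit margins and the Gaussian copula this is exactly the latent
bivariate-normal model $Y_j = 1\{Z_j \le \eta_j\}$,
$\operatorname{corr}(Z_1, Z_2) = \theta$, so $\theta$ is the **tetrachoric
correlation** between the latent propensities.  A notational subtlety: the
copula's arguments for a Bernoulli outcome are taken to be the success
probabilities $\mu_j$ themselves (the latent-threshold convention), which is
the only reading under which
$p_{11} = \Phi_2(\eta_1, \eta_2; \theta)$ reproduces the bivariate probit.

Besides the Gaussian family, Clayton, Joe, Gumbel, Frank,
Farlie–Gumbel–Morgenstern and Plackett copulas are available, each with the
link that maps its natural parameter range to the real line (atanh for
$(-1,1)$, log for $(0,\infty)$, $\log(\theta - 1)$ for $(1,\infty)$,
identity for Frank).  Clayton, Joe, Gumbel and Plackett as implemented
cover positive dependence only; rotated/survival variants are out of scope.
Margins may instead use logit or cloglog links.

## Smooth terms

* **Age** enters through a rank-10 penalized thin-plate regression spline
  (1-D radial basis, eigen-truncated, bending-energy penalty).  The basis
  dimension `k = 10` is a conventional default chosen to be well above the
  2–3 effective degrees of freedom such age effects typically need; the
  penalty, not `k`, controls the fitted complexity.
* **County** enters through a Markov random field smooth: a region
  indicator basis penalized by the adjacency-graph Laplacian
  ($\beta^\top L \beta = \sum_{i \sim j} (\beta_i - \beta_j)^2$), so
  neighbouring counties shrink toward each other.  The full-rank basis is
  kept (about 100 regions is small).  Isolated regions simply carry a zero
  penalty row, with a warning about the extra connected component.
* Every smooth carries a sum-to-zero constraint absorbed into the basis by
  centering reparameterization; intercepts live in the parametric block, so
  dummy coefficients keep their reference-level interpretation
  (ethnicity = White, educ = Primary, firstbirth/smoke = No,
  marital = Unmarried).

Basis/penalty pairs are constructed with `mgcv::smoothCon`, which makes the
penalized margins exactly comparable to an `mgcv::gam` fit with the same
smoothing parameters — a property the test suite exploits as an independent
cross-check of the fitting engine.

## Estimation

The penalized log-likelihood

$$
\ell_p(\boldsymbol\beta)
 = \sum_i \log p_{y_{1i} y_{2i}}(\mu_{1i}, \mu_{2i}, \theta_i)
 - \tfrac12 \sum_s \lambda_s \boldsymbol\beta_s^\top S_s \boldsymbol\beta_s
$$

is maximized by a damped Newton iteration with analytic gradient and
Hessian (closed-form copula partials for the Gaussian family; analytic
first partials with high-accuracy differenced second partials for the other
families), Hessian ridging when indefinite, and step halving that never
accepts a decrease in $\ell_p$.  Start values come from univariate
penalized margin fits with the dependence predictor started at 0.
Convergence requires a gradient max-norm below $10^{-5}$ and a positive
definite penalized Hessian; anything else is flagged, never silently
accepted (`conv_check()`).

**Smoothing parameters** are selected by minimizing
$\mathrm{AIC}(\lambda) = -2\hat\ell + 2\,\mathrm{edf}(\lambda)$ with
$\mathrm{edf} = \operatorname{tr}\{(\mathcal{H} + S_\lambda)^{-1}
\mathcal{H}\}$ ($\mathcal{H}$ the unpenalized negative Hessian at the
optimum), using a Nelder–Mead search over $\log\lambda$ warm-started from
the best point of a coarse grid ($\log_{10}\lambda \in \{-2, 0, 2, 4\}$).
AIC over effective degrees of freedom was chosen because it is the
criterion the model-selection workflow already reports; a
marginal-likelihood (REML-type) scheme would be a reasonable alternative
but is deliberately not claimed.

**Uncertainty** uses the Bayesian posterior covariance
$V_p = (\mathcal{H} + S_\lambda)^{-1}$.  Intervals for nonlinear
functionals — joint and conditional probabilities, per-record $\theta$, the
overall mean $\theta$ — are percentile intervals over
$\boldsymbol\beta^* \sim N(\hat{\boldsymbol\beta}, V_p)$ draws
(default 1000, seed recorded in the output), which avoids delta-method
bias in ratios like $P(Y_1 = 1 \mid Y_2 = 1) = p_{11}/\mu_2$.

The "overall" dependence is reported as the observation mean of the
per-record $\hat\theta_i$; since the dependence predictor is
covariate-dependent there is no single $\theta$, so per-pattern values are
always reported alongside.

## Numerical choices

* Gaussian copula CDF: a vectorized Genz/Drezner–Wesolowsky-type algorithm
  (20-node Gauss–Legendre on the arcsine-transformed integral for
  $|\theta| \le 0.925$, tail expansion beyond), accurate to about
  $10^{-14}$; validated in the tests against nested adaptive quadrature of
  the bivariate normal density.
* $\theta$ is confined to $10^{-7}$ inside its open bounds and dependence
  predictors are capped at $|\eta| \le 15$, preventing overflow near the
  comonotone boundary.
* Margin probabilities are clipped to $[10^{-12}, 1 - 10^{-12}]$; cell
  probabilities below $-10^{-8}$ raise an error (they indicate an invalid
  $\theta$ or an implementation fault), while rounding noise in
  $[-10^{-12}, 0)$ is clipped and the table renormalized.
* Frank near $\theta = 0$ and Plackett near $\theta = 1$ use second-order
  series expansions of the CDF and its partials to avoid 0/0.
* Missing data: complete cases, with a message counting dropped records.

## The synthetic cohort

The real North Carolina natality data are restricted-license, so the
package ships a generator (`default_truth()`, `make_county_graph()`,
`generate_births()`) that emulates their structure and makes every stage
testable end to end:

* 20,000 records by default; covariates drawn independently with round
  plausible frequencies (58/15/22/5% White/Hispanic/Black/Other;
  15/55/30% primary/secondary/tertiary education; 42% first births, 60%
  married, 12% smokers).  Only the *age-group shares* are calibrated to
  published figures (about 12% under 20, about 11% aged 35+, via a
  truncated normal, mean 27.05, sd 6.35, on [13, 50]); the other
  frequencies are configurable placeholders.
* Parametric truth equals the published point estimates for all three
  equations; the age effects are a smoothed hinge rising after age 30 (lbw)
  and a centered quadratic U (ptb), both centered over the age
  distribution; county effects are intrinsic GMRF draws on a 10×10 lattice
  (sd 0.15), mimicking ~100 spatially smooth county effects.
* Outcomes are generated through the latent bivariate-Gaussian route
  (exactly the Gaussian copula with probit margins); for other families the
  pair is sampled by conditional inversion of the copula and thresholded at
  the margins.
* Implied event rates land around 8% (lbw) and 10% (ptb), inside plausible
  perinatal ranges, with profile-specific rates spanning roughly 1–30%.

What passing tests on this cohort do **not** show: robustness to real-data
features the generator omits — correlated covariates, informative
missingness, county-level sample-size imbalance beyond multinomial noise,
irregular county adjacency, or misspecified link/copula families.
Conclusions about the real data would need the real data.

## Problem sizes used in the checks

The statistical acceptance checks use sizes chosen to make Monte-Carlo
noise small relative to the tested effect while keeping a laptop-scale run:
parameter recovery uses 20 replicates at n = 4,000 with the full 100-county
design; interval coverage uses 100 replicates at n = 2,000 with a 20-county
lattice; smooth-recovery consistency compares n = 2,000 against n = 20,000;
link selection uses 20 replicates at n = 20,000 with parametric margins.
The study-scale analysis scripts run at n = 20,000 with all terms.

## Known limitations

* Only one-parameter copulas; no rotations, no mixed or continuous margins.
* Smoothing-parameter selection by AIC/Nelder–Mead can be slow for many
  smooths (each objective evaluation is a penalized Newton fit, though
  warm-started) and, like any edf-based criterion, may undersmooth slightly
  relative to REML-type selection.
* The dependence equation is parametric in the examples; smooths are
  supported there too but interact with the weak identification of
  covariate-dependent dependence at low event rates — expect wide
  intervals.
* Per-record probabilities near 0 or 1 are clipped, so extreme profiles
  carry a small deterministic bias on the order of the clip (1e-12).

## A short session

```{r example, eval = FALSE}
county <- make_county_graph(10, 10, spatial_sd = 0.15, seed = 1)
dat <- generate_births(default_truth(n = 20000), county, seed = 2)

spec <- cdr_spec(
  lbw ~ ethnicity + educ + firstbirth + marital + smoke + s(age) +
    mrf(county),
  ptb ~ ethnicity + educ + firstbirth + marital + smoke + s(age) +
    mrf(county),
  ~ educ)
fit <- fit_cdr(dat, spec, graph = county$graph)
conv_check(fit)
summary(fit)

average_theta(fit)                      # overall tetrachoric correlation
predict_quantity(fit,
  data.frame(ethnicity = "White", educ = "Tertiary", firstbirth = 0,
             marital = 1, smoke = 0, age = 26, county = "45"),
  "cond_1_given_2")                     # P(lbw = 1 | ptb = 1)
plot_smooth(fit, "eq2:s(age)")          # U-shaped age effect with band
```

The numbered scripts under `analysis/` run the same pipeline end to end
(simulate → fit → dependence → profile probabilities → figures) and write
their tables under `results/`.
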