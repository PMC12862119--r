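# copbirth

Joint modelling of two binary birth outcomes — low birth weight (lbw,
weight < 2.5 kg) and preterm birth (ptb, gestation < 37 weeks) — with a
**copula distributional regression**. The two outcomes are strongly
interdependent; modelling them jointly quantifies how risks co-occur for a
given maternal profile, which separate univariate regressions cannot do.

## The model

Each margin is Bernoulli with a probit (optionally logit/cloglog) link, and
the pair is coupled by a one-parameter copula whose dependence parameter has
its own predictor:

    Φ⁻¹(μⱼ) = xᵀβⱼ + s₁ⱼ(age) + s₂ⱼ(county),   j = 1, 2
    atanh(θ) = zᵀβ_θ

with p₁₁ = C(μ₁, μ₂; θ) and the other cells by the margin identities.
With the Gaussian copula and probit links this is the classical bivariate
probit: θ is the tetrachoric correlation between the latent propensities.
Age enters via penalized thin-plate regression splines; county via a Markov
random field smooth penalized by the adjacency-graph Laplacian. Estimation
is penalized maximum likelihood (damped Newton, analytic derivatives) with
AIC-based smoothing-parameter selection; intervals come from posterior
simulation under the penalized-Hessian-inverse covariance. Clayton, Joe,
Gumbel, Frank, FGM and Plackett copulas are also available.

Because the motivating natality data are restricted-license, the package
includes a synthetic-cohort generator (`default_truth()`,
`make_county_graph()`, `generate_births()`) reproducing the data structure:
20,000 records, ~100 counties on a connected lattice with GMRF spatial
effects, published point estimates as parametric truth, a flat-then-rising
age effect for lbw and a U-shaped one for ptb, and realistic event rates.

## Worked example

```r
library(copbirth)
county <- make_county_graph(10, 10, spatial_sd = 0.15, seed = 1)
dat <- generate_births(default_truth(n = 20000), county, seed = 2)

spec <- cdr_spec(
  lbw ~ ethnicity + educ + firstbirth + marital + smoke + s(age) + mrf(county),
  ptb ~ ethnicity + educ + firstbirth + marital + smoke + s(age) + mrf(county),
  ~ educ)
fit <- fit_cdr(dat, spec, graph = county$graph)
average_theta(fit)
```

The same pipeline, staged, lives in `analysis/01_simulate.R` …
`analysis/05_figures.R`; each stage prints a short report and writes its
tables under `results/`. On the default seed the run prints:

```
event rates: lbw 8.2%, ptb 11.0%, both 4.4%
overall theta-hat = 0.716, 95% interval (0.693, 0.737)
Kendall's tau at the mean theta = 0.508
       pattern     theta     lower     upper
   (reference) 0.5191459 0.4352270 0.5892014
  educSecondary 0.7282452 0.6976335 0.7550186
  educTertiary 0.7933069 0.7563339 0.8248848
preferred margins: probit
```

The overall θ̂ is the observation mean of the per-record tetrachoric
correlation (here generated around 0.71): higher-educated mothers show
stronger dependence by construction of the simulation truth. Stage 4
reports profile probabilities, e.g. for the representative mother (26,
White, tertiary-educated, married, non-smoking) a ~3.7% lbw and ~4.9% ptb
marginal probability, P(lbw | ptb) ≈ 41% against P(lbw | full term) ≈ 1.8%,
and stage 5 maps P(lbw, ptb) by county (1.4–4.0% non-smoking vs 3.1–7.6%
smoking for the representative profile).

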