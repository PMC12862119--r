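# Shared oracles and fixtures, independent of the implementation paths they
# check.

# central finite differences of a scalar function
fd_grad <- function(fun, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    (fun(xp) - fun(xm)) / (2 * h)
  }, 0)
}

# bivariate standard normal CDF by nested adaptive quadrature of the density
quad_binorm <- function(u, v, rho, rel.tol = 1e-9) {
  xu <- qnorm(u); yv <- qnorm(v)
  dens <- function(y, x) {
    s2 <- 1 - rho^2
    exp(-(x^2 - 2 * rho * x * y + y^2) / (2 * s2)) / (2 * pi * sqrt(s2))
  }
  outer_f <- function(xs) vapply(xs, function(x)
    integrate(dens, -8.5, yv, x = x, rel.tol = rel.tol)$value, 0)
  integrate(outer_f, -8.5, xu, rel.tol = rel.tol)$value
}

# interior theta values for property grids, per family
family_thetas <- list(
  gaussian = c(-0.9, -0.4, 0.05, 0.5, 0.95),
  fgm      = c(-0.9, -0.4, 0.05, 0.5, 0.95),
  clayton  = c(0.1, 0.5, 1.2, 3, 7),
  joe      = c(1.05, 1.4, 2, 3.5, 6),
  gumbel   = c(1.05, 1.4, 2, 3.5, 6),
  frank    = c(-8, -2, 0.3, 3, 10),
  plackett = c(0.15, 0.6, 1.4, 4, 12))

all_families <- names(family_thetas)

# random interior theta draws for a family
draw_thetas <- function(family, n) {
  switch(family,
    gaussian = runif(n, -0.999, 0.999),
    fgm      = runif(n, -0.999, 0.999),
    clayton  = exp(runif(n, log(0.05), log(8))),
    joe      = 1 + exp(runif(n, log(0.05), log(5))),
    gumbel   = 1 + exp(runif(n, log(0.05), log(5))),
    frank    = { t <- runif(n, -14, 14); t[abs(t) < 0.01] <- 0.5; t },
    plackett = exp(runif(n, -2.5, 2.5)))
}

# small three-equation design bundle for likelihood tests
toy_dm <- function(n = 50, seed = 1, link1 = "probit", link2 = "probit",
                   family = "gaussian") {
  set.seed(seed)
  d <- data.frame(x = rnorm(n), w = rbinom(n, 1, 0.4),
                  y1 = rbinom(n, 1, 0.4), y2 = rbinom(n, 1, 0.35))
  spec <- cdr_spec(y1 ~ x + w, y2 ~ x, ~ w,
                   link1 = link1, link2 = link2, copula = family)
  eq1 <- copbirth:::.build_equation(spec$margin1, d)
  eq2 <- copbirth:::.build_equation(spec$margin2, d)
  eqt <- copbirth:::.build_equation(spec$theta_formula, d)
  list(dm = list(X1 = eq1$X, X2 = eq2$X, Xt = eqt$X, y1 = eq1$y, y2 = eq2$y,
                 link1 = link1, link2 = link2, cspec = spec$copula,
                 pens = list(), free_theta = TRUE, fix_theta_eta = NULL),
       spec = spec, data = d,
       p = ncol(eq1$X) + ncol(eq2$X) + ncol(eqt$X))
}

# a safe random coefficient vector for a toy_dm (moderate dependence)
toy_beta <- function(tm, seed = 2, scale = 0.3) {
  set.seed(seed)
  rnorm(tm$p, 0, scale)
}

# default profile used in prediction tests (representative mother)
representative_profile <- function(county_id = "5") {
  data.frame(ethnicity = "White", educ = "Tertiary", firstbirth = 0,
             marital = 1, smoke = 0, age = 26, county = county_id,
             stringsAsFactors = FALSE)
}

# truth with a degenerate (fixed) covariate profile so that every record
# shares one (mu1, mu2, theta)
fixed_profile_truth <- function(n = 1e5) {
  tr <- default_truth(n = n, spatial_sd = 0)
  tr$covariate_dist <- list(
    ethnicity = c(White = 0, Hispanic = 0, Black = 1, Other = 0),
    educ = c(Primary = 0, Secondary = 1, Tertiary = 0),
    firstbirth = 1, marital = 0, smoke = 1)
  tr$age_range <- c(26 - 1e-9, 26 + 1e-9)
  tr
}
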