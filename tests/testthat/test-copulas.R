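test_that("Gaussian copula matches closed form and quadrature", {
  sp <- copula_spec("gaussian")
  # independence and boundary behaviour
  expect_equal(copula_cdf(0.3, 0.4, sp, 0), 0.12, tolerance = 1e-12)
  expect_equal(copula_cdf(0.5, 1, sp, 0.74), 0.5, tolerance = 1e-12)
  expect_equal(copula_cdf(0, 0.8, sp, 0.74), 0, tolerance = 1e-15)
  # closed form C(1/2, 1/2; rho) = 1/4 + asin(rho)/(2 pi)
  expect_equal(copula_cdf(0.5, 0.5, sp, 0.74), 0.25 + asin(0.74) / (2 * pi),
               tolerance = 1e-10)
  expect_equal(copula_cdf(0.5, 0.5, sp, 0.74), 0.38259, tolerance = 1e-5)
  # independent nested-quadrature oracle at a few points
  for (pt in list(c(0.3, 0.6, 0.5), c(0.85, 0.2, -0.7), c(0.5, 0.5, 0.96))) {
    expect_equal(copula_cdf(pt[1], pt[2], sp, pt[3]),
                 quad_binorm(pt[1], pt[2], pt[3]), tolerance = 1e-7)
  }
})

test_that("all families obey copula boundary and monotonicity laws", {
  g <- seq(0.05, 0.95, by = 0.1)
  for (fam in all_families) {
    sp <- copula_spec(fam)
    for (th in family_thetas[[fam]]) {
      expect_equal(copula_cdf(g, rep(1, length(g)), sp, th), g,
                   tolerance = 1e-9, label = paste(fam, "C(u,1)=u"))
      expect_equal(copula_cdf(rep(0, length(g)), g, sp, th), rep(0, length(g)),
                   label = paste(fam, "C(0,v)=0"))
      Cm <- outer(g, g, function(u, v) copula_cdf(u, v, sp, th))
      # componentwise nondecreasing
      expect_true(all(diff(Cm) >= -1e-12), label = paste(fam, "monotone u"))
      expect_true(all(t(diff(t(Cm))) >= -1e-12),
                  label = paste(fam, "monotone v"))
      # rectangle inequality (2-increasing) on all adjacent sub-rectangles
      rect <- Cm[-1, -1] - Cm[-1, -ncol(Cm)] - Cm[-nrow(Cm), -1] +
        Cm[-nrow(Cm), -ncol(Cm)]
      expect_true(all(rect >= -1e-10), label = paste(fam, "2-increasing"))
      # Frechet-Hoeffding bounds
      FH_lo <- outer(g, g, function(u, v) pmax(u + v - 1, 0))
      FH_hi <- outer(g, g, pmin)
      expect_true(all(Cm >= FH_lo - 1e-10 & Cm <= FH_hi + 1e-10),
                  label = paste(fam, "Frechet bounds"))
    }
  }
})

test_that("theta links are monotone bijections with exact round trips", {
  for (fam in all_families) {
    sp <- copula_spec(fam)
    ths <- sort(draw_thetas(fam, 1000))
    etas <- theta_to_eta(ths, sp)
    expect_true(all(diff(etas) > 0), label = paste(fam, "monotone link"))
    expect_equal(eta_to_theta(etas, sp), ths, tolerance = 1e-12,
                 label = paste(fam, "round trip"))
  }
  sp <- copula_spec("gaussian")
  expect_identical(theta_to_eta(0, sp), 0)
  # atanh(0.74) = 0.5 log(1.74/0.26)
  expect_equal(theta_to_eta(0.74, sp), 0.5 * log(1.74 / 0.26),
               tolerance = 1e-12)
  expect_equal(theta_to_eta(0.74, sp), 0.95048, tolerance = 1e-5)
  # tertiary-education dependence predictor: tanh(0.670 + 0.374)
  expect_equal(eta_to_theta(1.044, sp), tanh(1.044), tolerance = 1e-12)
  expect_equal(eta_to_theta(1.044, sp), 0.7795, tolerance = 1e-4)
})

test_that("theta values at or beyond the bounds raise a domain error", {
  expect_error(copula_cdf(0.5, 0.5, copula_spec("gaussian"), 1.2),
               "gaussian")
  expect_error(copula_cdf(0.5, 0.5, copula_spec("clayton"), -0.5),
               "clayton")
  expect_error(theta_to_eta(1, copula_spec("fgm")), "admissible")
  expect_error(kendall_tau(copula_spec("gumbel"), 0.8), "gumbel")
})

test_that("cell probabilities obey the table identities and Frechet bounds", {
  sp <- copula_spec("gaussian")
  cp <- cell_probs(0.3, 0.4, sp, 0)
  expect_equal(unlist(cp), c(p11 = 0.12, p10 = 0.18, p01 = 0.28, p00 = 0.42),
               tolerance = 1e-10)
  # comonotone limit: p11 -> min(mu1, mu2)
  expect_equal(cell_probs(0.3, 0.4, sp, 1 - 1e-9)$p11, 0.3,
               tolerance = 1e-5)
  cp2 <- cell_probs(0.5, 0.5, sp, 0.74)
  expect_equal(cp2$p11, 0.25 + asin(0.74) / (2 * pi), tolerance = 1e-9)
  expect_equal(cp2$p10, 0.5 - cp2$p11, tolerance = 1e-12)
  expect_equal(cp2$p01, cp2$p10, tolerance = 1e-12)
  # random triples per family
  set.seed(42)
  for (fam in all_families) {
    spf <- copula_spec(fam)
    n <- 2000
    mu1 <- runif(n, 0.01, 0.99); mu2 <- runif(n, 0.01, 0.99)
    th <- draw_thetas(fam, n)
    cp <- cell_probs(mu1, mu2, spf, th)
    expect_true(all(abs(rowSums(cp) - 1) < 1e-12), label = paste(fam, "sum"))
    expect_true(all(cp >= 0), label = paste(fam, "nonneg"))
    expect_true(all(cp$p11 <= pmin(mu1, mu2) + 1e-9 &
                      cp$p11 >= pmax(mu1 + mu2 - 1, 0) - 1e-9),
                label = paste(fam, "Frechet"))
  }
})

test_that("Kendall's tau matches closed forms and the integral route", {
  gsp <- copula_spec("gaussian")
  expect_identical(kendall_tau(gsp, 0), 0)
  expect_equal(kendall_tau(gsp, 1 - 1e-9), 1, tolerance = 1e-3)
  expect_equal(kendall_tau(gsp, 0.74), 2 / pi * asin(0.74), tolerance = 1e-12)
  # closed form vs the generic numeric double-integral route
  expect_equal(copbirth:::.kendall_tau_numeric(gsp, 0.74),
               2 / pi * asin(0.74), tolerance = 1e-3)
  expect_equal(copbirth:::.kendall_tau_numeric(copula_spec("clayton"), 2),
               2 / (2 + 2), tolerance = 1e-3)
  expect_equal(copbirth:::.kendall_tau_numeric(copula_spec("gumbel"), 2.5),
               1 - 1 / 2.5, tolerance = 1e-3)
  # Monte-Carlo oracle for the Gaussian closed form
  set.seed(7)
  n <- 2e5
  th <- 0.74
  z1 <- rnorm(n); z2 <- th * z1 + sqrt(1 - th^2) * rnorm(n)
  i <- sample(n); j <- sample(n)
  conc <- sign((z1 - z1[i]) * (z2 - z2[i]))
  expect_equal(kendall_tau(gsp, th), mean(conc[conc != 0]),
               tolerance = 0.01)
})

test_that("copula first partials agree with finite differences everywhere", {
  set.seed(11)
  h <- 1e-6
  for (fam in all_families) {
    for (th in family_thetas[[fam]][c(2, 4)]) {
      u <- runif(5, 0.05, 0.95); v <- runif(5, 0.05, 0.95)
      d <- copbirth:::.copula_derivs1(u, v, fam, rep(th, 5))
      core <- function(uu, vv, tt) copbirth:::.copula_cdf_core(uu, vv, fam, tt)
      expect_equal(d$Cu, (core(u + h, v, th) - core(u - h, v, th)) / (2 * h),
                   tolerance = 1e-5, label = paste(fam, "Cu"))
      expect_equal(d$Cv, (core(u, v + h, th) - core(u, v - h, th)) / (2 * h),
                   tolerance = 1e-5, label = paste(fam, "Cv"))
      expect_equal(d$Ct, (core(u, v, th + h) - core(u, v, th - h)) / (2 * h),
                   tolerance = 1e-4, label = paste(fam, "Ct"))
    }
  }
})
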