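#' Lattice county graph with spatially smooth effects
#'
#' Builds a connected nx x ny lattice graph (default 10 x 10, i.e. 100
#' regions, mirroring the 100 North Carolina counties) and draws one
#' spatially smooth region effect per margin from an intrinsic Gaussian
#' Markov random field whose precision is proportional to the graph
#' Laplacian (generalized-inverse sampling), centered to mean zero and
#' scaled to \code{spatial_sd}.
#'
#' @param nx,ny Lattice dimensions; \code{nx * ny >= 4}.
#' @param spatial_sd Marginal standard deviation of each county effect
#'   vector (0 gives exactly zero effects).
#' @param seed Integer seed for the GMRF draws.
#' @return A list of class \code{"county_sim"}: \code{graph}
#'   (\code{\link{region_graph}}), \code{spatial1}, \code{spatial2}
#'   (named effect vectors) and \code{coords} (lattice coordinates for
#'   mapping).
#' @export
make_county_graph <- function(nx = 10, ny = 10, spatial_sd = 0.15,
                              seed = 1) {
  if (nx * ny < 4) stop("need at least 4 regions", call. = FALSE)
  ids <- as.character(seq_len(nx * ny))
  edges <- NULL
  for (r in 0:(ny - 1)) for (c0 in 0:(nx - 1)) {
    i <- r * nx + c0 + 1
    if (c0 < nx - 1) edges <- rbind(edges, c(ids[i], ids[i + 1]))
    if (r < ny - 1) edges <- rbind(edges, c(ids[i], ids[i + nx]))
  }
  graph <- region_graph(ids, edges)
  coords <- cbind(x = rep(0:(nx - 1), ny), y = rep(0:(ny - 1), each = nx))
  rownames(coords) <- ids
  set.seed(seed)
  structure(list(graph = graph,
                 spatial1 = .sample_gmrf(graph, spatial_sd),
                 spatial2 = .sample_gmrf(graph, spatial_sd),
                 coords = coords, spatial_sd = spatial_sd, seed = seed),
            class = "county_sim")
}

# intrinsic GMRF draw: x = V_+ diag(1/sqrt(ev_+)) z over the positive
# eigenspace of the Laplacian, then centered and rescaled
.sample_gmrf <- function(graph, spatial_sd) {
  ids <- graph$region_ids
  n <- length(ids)
  if (spatial_sd == 0) {
    x <- rep(0, n); names(x) <- ids; return(x)
  }
  L <- graph_laplacian(graph)
  e <- eigen(L, symmetric = TRUE)
  pos <- e$values > 1e-8 * max(e$values)
  z <- rnorm(sum(pos))
  x <- drop(e$vectors[, pos, drop = FALSE] %*% (z / sqrt(e$values[pos])))
  x <- x - mean(x)
  x <- x * spatial_sd / stats::sd(x)
  names(x) <- ids
  x
}

#' Default simulation truth for the synthetic birth cohort
#'
#' Parametric coefficients default to the point estimates of the published
#' North Carolina analysis: the two probit margin equations (low birth
#' weight and preterm birth) and the atanh-linked dependence equation in
#' maternal education.  The true age effects follow the reported shapes —
#' flat to about age 30 then rising for low birth weight, and a U shape for
#' preterm birth — each centered to mean zero over the age distribution so
#' the intercepts keep their printed interpretation.  Maternal age is drawn
#' from a truncated normal calibrated so that about 12\% of mothers are
#' under 20 and about 11\% are 35 or older.
#'
#' @param n Number of records (default 20000, the study sample size).
#' @param spatial_sd Standard deviation of the county effects.
#' @return A list of class \code{"sim_truth"} with elements \code{beta1},
#'   \code{beta2}, \code{beta_theta} (named coefficient vectors),
#'   \code{f1_age}, \code{f2_age} (centered functions of age),
#'   \code{covariate_dist}, \code{age_range}, \code{n}, \code{spatial_sd}.
#' @export
default_truth <- function(n = 20000, spatial_sd = 0.15) {
  beta1 <- c("(Intercept)" = -1.611, ethnicityHispanic = -0.033,
             ethnicityBlack = 0.376, ethnicityOther = 0.250,
             educSecondary = 0.047, educTertiary = -0.042,
             firstbirthYes = 0.129, maritalMarried = -0.087,
             smokeYes = 0.427)
  beta2 <- c("(Intercept)" = -1.253, ethnicityHispanic = -0.029,
             ethnicityBlack = 0.283, ethnicityOther = 0.119,
             educSecondary = -0.021, educTertiary = -0.103,
             firstbirthYes = -0.010, maritalMarried = -0.084,
             smokeYes = 0.162)
  beta_theta <- c("(Intercept)" = 0.670, educSecondary = 0.205,
                  educTertiary = 0.374)
  # age distribution: truncated normal giving ~12% under 20, ~11% >= 35
  age_mean <- 27.05; age_sd <- 6.35; age_range <- c(13, 50)
  dens <- function(a) dnorm(a, age_mean, age_sd) /
    diff(pnorm(age_range, age_mean, age_sd))
  f1_raw <- function(a) 0.010 * pmax(a - 30, 0)^1.5      # flat then rising
  f2_raw <- function(a) 0.0022 * (a - 27)^2              # U shape
  c1 <- integrate(function(a) f1_raw(a) * dens(a),
                  age_range[1], age_range[2])$value
  c2 <- integrate(function(a) f2_raw(a) * dens(a),
                  age_range[1], age_range[2])$value
  structure(list(
    beta1 = beta1, beta2 = beta2, beta_theta = beta_theta,
    f1_age = function(a) f1_raw(a) - c1,
    f2_age = function(a) f2_raw(a) - c2,
    covariate_dist = list(
      ethnicity = c(White = 0.58, Hispanic = 0.15, Black = 0.22,
                    Other = 0.05),
      educ = c(Primary = 0.15, Secondary = 0.55, Tertiary = 0.30),
      firstbirth = 0.42, marital = 0.60, smoke = 0.12),
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    n = n, spatial_sd = spatial_sd, copula = "gaussian"),
    class = "sim_truth")
}

# truncated normal age draw on truth$age_range
.draw_age <- function(n, truth) {
  lo <- pnorm(truth$age_range[1], truth$age_mean, truth$age_sd)
  hi <- pnorm(truth$age_range[2], truth$age_mean, truth$age_sd)
  qnorm(runif(n, lo, hi), truth$age_mean, truth$age_sd)
}

# linear predictors for given covariates under the truth
.truth_eta <- function(d, truth, county) {
  eta_par <- function(beta) {
    beta[["(Intercept)"]] +
      beta[["ethnicityHispanic"]] * (d$ethnicity == "Hispanic") +
      beta[["ethnicityBlack"]] * (d$ethnicity == "Black") +
      beta[["ethnicityOther"]] * (d$ethnicity == "Other") +
      beta[["educSecondary"]] * (d$educ == "Secondary") +
      beta[["educTertiary"]] * (d$educ == "Tertiary") +
      beta[["firstbirthYes"]] * d$firstbirth +
      beta[["maritalMarried"]] * d$marital +
      beta[["smokeYes"]] * d$smoke
  }
  eta1 <- eta_par(truth$beta1) + truth$f1_age(d$age)
  eta2 <- eta_par(truth$beta2) + truth$f2_age(d$age)
  if (!is.null(county)) {
    eta1 <- eta1 + unname(county$spatial1[d$county])
    eta2 <- eta2 + unname(county$spatial2[d$county])
  }
  etat <- truth$beta_theta[["(Intercept)"]] +
    truth$beta_theta[["educSecondary"]] * (d$educ == "Secondary") +
    truth$beta_theta[["educTertiary"]] * (d$educ == "Tertiary")
  list(eta1 = eta1, eta2 = eta2, etat = etat)
}

#' Generate a synthetic birth cohort
#'
#' Draws covariates independently per record from the truth's covariate
#' distributions, assembles the three linear predictors, and generates the
#' outcome pair through the latent bivariate-Gaussian route
#' (\eqn{Y_j = 1\{Z_j \le \eta_j\}} with corr(\eqn{Z_1, Z_2}) =
#' \eqn{\theta_i}), which is exactly the Gaussian copula with probit
#' margins.  For non-Gaussian copulas the pair is sampled by conditional
#' inversion of the copula and thresholded at the margin probabilities.
#'
#' @param truth A \code{\link{default_truth}}-style object.
#' @param county A \code{\link{make_county_graph}} result, or \code{NULL}
#'   for no spatial term.
#' @param n Number of records (defaults to \code{truth$n}).
#' @param seed Integer seed; identical seeds give identical tables.
#' @param copula Copula family used for outcome generation.
#' @return A data frame (\code{lbw}, \code{ptb}, covariates, \code{county})
#'   with attributes \code{eta1}, \code{eta2}, \code{theta} holding the
#'   record-level truth.
#' @export
generate_births <- function(truth, county = NULL, n = truth$n, seed = 1,
                            copula = truth$copula) {
  set.seed(seed)
  cd <- truth$covariate_dist
  d <- data.frame(
    ethnicity = sample(names(cd$ethnicity), n, TRUE, cd$ethnicity),
    educ = sample(names(cd$educ), n, TRUE, cd$educ),
    firstbirth = rbinom(n, 1, cd$firstbirth),
    marital = rbinom(n, 1, cd$marital),
    smoke = rbinom(n, 1, cd$smoke),
    age = .draw_age(n, truth),
    stringsAsFactors = FALSE)
  d$county <- if (!is.null(county))
    sample(county$graph$region_ids, n, TRUE) else "1"
  eta <- .truth_eta(d, truth, county)
  cspec <- copula_spec(copula)
  theta <- eta_to_theta(eta$etat, cspec)
  mu1 <- inverse_link(eta$eta1, "probit")
  mu2 <- inverse_link(eta$eta2, "probit")
  if (abs(max(abs(theta)) - 1) < 1e-6 && copula %in% c("gaussian", "fgm"))
    warning("theta at the dependence boundary: outcomes nearly degenerate",
            call. = FALSE)
  if (copula == "gaussian") {
    z1 <- rnorm(n); z2 <- theta * z1 + sqrt(1 - theta^2) * rnorm(n)
    d$lbw <- as.integer(z1 <= eta$eta1)
    d$ptb <- as.integer(z2 <= eta$eta2)
  } else {
    uu <- .copula_conditional_sample(n, cspec, theta)
    d$lbw <- as.integer(uu$u1 <= mu1)
    d$ptb <- as.integer(uu$u2 <= mu2)
  }
  d <- d[, c("lbw", "ptb", "ethnicity", "educ", "firstbirth", "marital",
             "smoke", "age", "county")]
  attr(d, "eta1") <- eta$eta1
  attr(d, "eta2") <- eta$eta2
  attr(d, "theta") <- theta
  attr(d, "seed") <- seed
  d
}

# sample (U1, U2) from the copula by inverting the conditional CDF
# C_{2|1}(v | u) = dC/du with vectorized bisection
.copula_conditional_sample <- function(n, cspec, theta) {
  u1 <- runif(n)
  w <- runif(n)
  lo <- rep(1e-12, n); hi <- rep(1 - 1e-12, n)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    val <- .copula_derivs1(u1, mid, cspec$family, theta)$Cu
    up <- val < w
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  list(u1 = u1, u2 = (lo + hi) / 2)
}
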