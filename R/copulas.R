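#' Copula specification for a bivariate binary model
#'
#' Defines the copula family coupling the two Bernoulli margins, the link
#' used to map the dependence parameter theta onto the real line, and the
#' admissible open interval for theta.  Seven one-parameter families are
#' supported; Clayton, Joe, Gumbel and Plackett (as implemented) cover
#' positive dependence only, matching their natural parameter ranges.
#'
#' @param family One of \code{"gaussian"}, \code{"clayton"}, \code{"joe"},
#'   \code{"gumbel"}, \code{"frank"}, \code{"fgm"}, \code{"plackett"}.
#' @return An object of class \code{"copula_spec"} with elements
#'   \code{family}, \code{link_name} and \code{theta_bounds} (open interval).
#' @details The theta link is determined by the family: \code{atanh} for
#'   Gaussian and FGM (theta in (-1,1)), \code{log} for Clayton and Plackett
#'   (theta > 0), \code{log(theta - 1)} for Joe and Gumbel (theta > 1), and
#'   the identity for Frank (theta real, theta = 0 handled as the
#'   independence limit).  Linear predictors on the link scale are capped at
#'   |eta| <= 15 to avoid overflow.
#' @export
#' @examples
#' sp <- copula_spec("gaussian")
#' copula_cdf(0.5, 0.5, sp, 0.74)
copula_spec <- function(family = c("gaussian", "clayton", "joe", "gumbel",
                                   "frank", "fgm", "plackett")) {
  family <- match.arg(family)
  info <- switch(family,
    gaussian = list(link = "atanh",       bounds = c(-1, 1)),
    fgm      = list(link = "atanh",       bounds = c(-1, 1)),
    clayton  = list(link = "log",         bounds = c(0, Inf)),
    plackett = list(link = "log",         bounds = c(0, Inf)),
    joe      = list(link = "log_shifted", bounds = c(1, Inf)),
    gumbel   = list(link = "log_shifted", bounds = c(1, Inf)),
    frank    = list(link = "identity_bounded", bounds = c(-Inf, Inf)))
  structure(list(family = family, link_name = info$link,
                 theta_bounds = info$bounds),
            class = "copula_spec")
}

#' @export
print.copula_spec <- function(x, ...) {
  cat("Copula family:", x$family, "\n")
  cat("  theta link:  ", x$link_name, "\n")
  cat("  theta bounds: (", x$theta_bounds[1], ", ", x$theta_bounds[2], ")\n",
      sep = "")
  invisible(x)
}

# numerical guard distance from the open theta bounds
.THETA_EPS <- 1e-7
.ETA_CAP <- 15

.check_theta <- function(theta, spec) {
  b <- spec$theta_bounds
  bad <- !is.finite(theta) | theta <= b[1] | theta >= b[2]
  if (spec$family == "frank") bad <- !is.finite(theta)
  if (any(bad))
    stop(sprintf(
      "theta = %g outside the admissible range (%g, %g) for the %s copula",
      theta[which(bad)[1]], b[1], b[2], spec$family), call. = FALSE)
  invisible(TRUE)
}

# keep theta strictly inside the open bounds for numerical stability
.clamp_theta <- function(theta, spec) {
  b <- spec$theta_bounds
  lo <- if (is.finite(b[1])) b[1] + .THETA_EPS else -tanh(.ETA_CAP) * 0 - 3e6
  hi <- if (is.finite(b[2])) b[2] - .THETA_EPS else 3e6
  if (spec$family %in% c("gaussian", "fgm")) {
    lo <- -1 + .THETA_EPS; hi <- 1 - .THETA_EPS
  }
  pmin(pmax(theta, lo), hi)
}

## ---------------------------------------------------------------------------
## Bivariate standard normal CDF, vectorized.
##
## Genz/Drezner-Wesolowsky style algorithm: for |rho| <= 0.925 Gauss-Legendre
## quadrature of the arcsine-transformed single integral; for larger |rho|
## the complementary tail expansion.  Absolute accuracy around 1e-15 in the
## central range and better than 1e-10 near |rho| = 1.
## ---------------------------------------------------------------------------

.gl20_x <- c(0.9931285991850949, 0.9639719272779138, 0.9122344282513259,
             0.8391169718222188, 0.7463319064601508, 0.6360536807265150,
             0.5108670019508271, 0.3737060887154196, 0.2277858511416451,
             0.07652652113349733)
.gl20_w <- c(0.01761400713915212, 0.04060142980038694, 0.06267204833410906,
             0.08327674157670475, 0.1019301198172404, 0.1181945319615184,
             0.1316886384491766, 0.1420961093183821, 0.1491729864726037,
             0.1527533871307259)

#' Bivariate standard normal CDF
#'
#' \code{pbinorm(h, k, rho)} returns \eqn{P(X \le h, Y \le k)} for a standard
#' bivariate normal pair with correlation \code{rho}; all arguments are
#' recycled to a common length.
#'
#' @param h,k Upper integration limits.
#' @param rho Correlation(s) in \[-1, 1\].
#' @return Numeric vector of probabilities.
#' @export
pbinorm <- function(h, k, rho) {
  n <- max(length(h), length(k), length(rho))
  h <- rep_len(as.numeric(h), n); k <- rep_len(as.numeric(k), n)
  r <- rep_len(as.numeric(rho), n)
  out <- numeric(n)

  inf_h <- h == Inf; inf_k <- k == Inf
  ninf <- h == -Inf | k == -Inf
  out[ninf] <- 0
  out[inf_h & !ninf] <- pnorm(k[inf_h & !ninf])
  out[inf_k & !ninf & !inf_h] <- pnorm(h[inf_k & !ninf & !inf_h])
  main <- !(inf_h | inf_k | ninf)
  if (!any(main)) return(out)

  hm <- h[main]; km <- k[main]; rm <- r[main]
  res <- numeric(length(hm))

  ctr <- abs(rm) <= 0.925
  if (any(ctr)) res[ctr] <- .pbinorm_central(hm[ctr], km[ctr], rm[ctr])
  if (any(!ctr)) res[!ctr] <- .pbinorm_tail(hm[!ctr], km[!ctr], rm[!ctr])
  out[main] <- pmin(pmax(res, 0), 1)
  out
}

# |rho| <= 0.925: Phi(h)Phi(k) + (1/2pi) int_0^{asin rho}
#   exp(-(h^2+k^2-2hk sin t)/(2 cos^2 t)) dt, 20-node Gauss-Legendre
.pbinorm_central <- function(h, k, r) {
  hk <- h * k
  hs <- (h * h + k * k) / 2
  asr <- asin(r) / 2
  acc <- 0
  for (i in seq_along(.gl20_x)) {
    for (s in c(-1, 1)) {
      sn <- sin(asr * (1 + s * .gl20_x[i]))
      acc <- acc + .gl20_w[i] * exp((sn * hk - hs) / (1 - sn * sn))
    }
  }
  acc * asr / (2 * pi) + pnorm(h) * pnorm(k)
}

# |rho| > 0.925: Genz tail expansion.  By X -> -X, Y -> -Y symmetry the
# upper-orthant routine evaluated at (-h, -k) equals the CDF at (h, k).
.pbinorm_tail <- function(h, k, r) {
  dh <- -h
  dk <- ifelse(r < 0, k, -k)          # Genz sign flip folded in
  hk <- ifelse(r < 0, -1, 1) * dh * (-k)
  bvn <- numeric(length(h))

  as_ <- (1 - r) * (1 + r)
  a <- sqrt(as_)
  bs <- (dh - dk)^2
  cc <- (4 - hk) / 8
  dd <- (12 - hk) / 16
  asr <- -(bs / as_ + hk) / 2
  ok <- asr > -100
  bvn[ok] <- (a * exp(asr) * (1 - cc * (bs - as_) * (1 - dd * bs / 5) / 3 +
                                cc * dd * as_ * as_ / 5))[ok]
  ok2 <- -hk < 100
  if (any(ok2)) {
    b <- sqrt(bs)
    sp <- sqrt(2 * pi) * pnorm(-b / a)
    bvn[ok2] <- bvn[ok2] - (exp(-hk / 2) * sp * b *
                              (1 - cc * bs * (1 - dd * bs / 5) / 3))[ok2]
  }
  a2 <- a / 2
  for (i in seq_along(.gl20_x)) {
    for (s in c(-1, 1)) {
      xs <- (a2 + a2 * s * .gl20_x[i])^2
      rs <- sqrt(1 - xs)
      asr2 <- -(bs / xs + hk) / 2
      ok3 <- asr2 > -100
      if (any(ok3)) {
        sp <- 1 + cc * xs * (1 + dd * xs)
        ep <- exp(-hk * (1 - rs) / (2 * (1 + rs))) / rs
        bvn[ok3] <- bvn[ok3] + (a2 * .gl20_w[i] * exp(asr2) * (ep - sp))[ok3]
      }
    }
  }
  bvn <- -bvn / (2 * pi)
  pos <- r > 0
  out <- numeric(length(h))
  out[pos] <- bvn[pos] + pnorm(-pmax(dh, dk)[pos])
  if (any(!pos)) {
    bneg <- -bvn[!pos]
    adj <- ifelse(dk[!pos] > dh[!pos],
                  pnorm(dk[!pos]) - pnorm(dh[!pos]), 0)
    out[!pos] <- bneg + adj
  }
  pmin(pmax(out, 0), 1)
}

## ---------------------------------------------------------------------------
## Copula CDFs and analytic partial derivatives
## ---------------------------------------------------------------------------

#' Copula CDF
#'
#' Evaluates \eqn{C(u, v; \theta)} for the family in \code{spec}.  Arguments
#' are recycled; boundary values of \code{u}, \code{v} in \{0, 1\} obey the
#' uniform-margin conditions exactly.
#'
#' @param u,v Probabilities in \[0, 1\].
#' @param spec A \code{\link{copula_spec}}.
#' @param theta Dependence parameter(s), strictly inside
#'   \code{spec$theta_bounds}.
#' @return Numeric vector of copula values.
#' @export
copula_cdf <- function(u, v, spec, theta) {
  stopifnot(inherits(spec, "copula_spec"))
  if (any(u < 0 | u > 1 | v < 0 | v > 1, na.rm = TRUE))
    stop("u and v must lie in [0, 1]", call. = FALSE)
  .check_theta(theta, spec)
  n <- max(length(u), length(v), length(theta))
  u <- rep_len(u, n); v <- rep_len(v, n); theta <- rep_len(theta, n)
  C <- .copula_cdf_core(u, v, spec$family, theta)
  # enforce exact boundary behaviour
  C[u == 0 | v == 0] <- 0
  C[u == 1] <- v[u == 1]
  C[v == 1] <- pmin(u, 1)[v == 1]
  C
}

.copula_cdf_core <- function(u, v, family, theta) {
  ui <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  vi <- pmin(pmax(v, 1e-12), 1 - 1e-12)
  switch(family,
    gaussian = pbinorm(qnorm(ui), qnorm(vi), theta),
    clayton = {
      S <- ui^(-theta) + vi^(-theta) - 1
      S^(-1 / theta)
    },
    joe = {
      x <- (1 - ui)^theta; y <- (1 - vi)^theta
      1 - (x + y - x * y)^(1 / theta)
    },
    gumbel = {
      A <- (-log(ui))^theta + (-log(vi))^theta
      exp(-A^(1 / theta))
    },
    frank = {
      small <- abs(theta) < 1e-5
      out <- numeric(length(ui))
      if (any(small)) {
        us <- ui[small]; vs <- vi[small]; ts <- theta[small]
        out[small] <- us * vs * (1 + ts * (1 - us) * (1 - vs) / 2)
      }
      if (any(!small)) {
        ub <- ui[!small]; vb <- vi[!small]; tb <- theta[!small]
        E <- expm1(-tb)
        out[!small] <- -log1p(expm1(-tb * ub) * expm1(-tb * vb) / E) / tb
      }
      out
    },
    fgm = ui * vi * (1 + theta * (1 - ui) * (1 - vi)),
    plackett = {
      near1 <- abs(theta - 1) < 1e-6
      out <- numeric(length(ui))
      if (any(near1)) {
        us <- ui[near1]; vs <- vi[near1]; ts <- theta[near1]
        out[near1] <- us * vs * (1 + (ts - 1) * (1 - us) * (1 - vs))
      }
      if (any(!near1)) {
        ub <- ui[!near1]; vb <- vi[!near1]; tb <- theta[!near1]
        S <- 1 + (tb - 1) * (ub + vb)
        R <- sqrt(S^2 - 4 * ub * vb * tb * (tb - 1))
        out[!near1] <- (S - R) / (2 * (tb - 1))
      }
      out
    },
    stop("unknown copula family: ", family))
}

# Analytic first partial derivatives dC/du, dC/dv, dC/dtheta.
# Returns list(C, Cu, Cv, Ct); u, v assumed strictly inside (0,1).
.copula_derivs1 <- function(u, v, family, theta) {
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  v <- pmin(pmax(v, 1e-12), 1 - 1e-12)
  switch(family,
    gaussian = {
      x <- qnorm(u); y <- qnorm(v)
      s2 <- 1 - theta^2; s <- sqrt(s2)
      C <- pbinorm(x, y, theta)
      Cu <- pnorm((y - theta * x) / s)
      Cv <- pnorm((x - theta * y) / s)
      Ct <- exp(-(x^2 - 2 * theta * x * y + y^2) / (2 * s2)) / (2 * pi * s)
      list(C = C, Cu = Cu, Cv = Cv, Ct = Ct)
    },
    clayton = {
      S <- u^(-theta) + v^(-theta) - 1
      C <- S^(-1 / theta)
      Cu <- u^(-theta - 1) * S^(-1 / theta - 1)
      Cv <- v^(-theta - 1) * S^(-1 / theta - 1)
      dS <- -(u^(-theta) * log(u) + v^(-theta) * log(v))
      Ct <- C * (log(S) / theta^2 - dS / (theta * S))
      list(C = C, Cu = Cu, Cv = Cv, Ct = Ct)
    },
    joe = {
      x <- (1 - u)^theta; y <- (1 - v)^theta
      T <- x + y - x * y
      C <- 1 - T^(1 / theta)
      Cu <- T^(1 / theta - 1) * (1 - u)^(theta - 1) * (1 - y)
      Cv <- T^(1 / theta - 1) * (1 - v)^(theta - 1) * (1 - x)
      lx <- log1p(-u); ly <- log1p(-v)
      Tt <- x * (1 - y) * lx + y * (1 - x) * ly
      Ct <- -T^(1 / theta) * (-log(T) / theta^2 + Tt / (theta * T))
      list(C = C, Cu = Cu, Cv = Cv, Ct = Ct)
    },
    gumbel = {
      a <- -log(u); b <- -log(v)
      A <- a^theta + b^theta
      C <- exp(-A^(1 / theta))
      Cu <- C * A^(1 / theta - 1) * a^(theta - 1) / u
      Cv <- C * A^(1 / theta - 1) * b^(theta - 1) / v
      ala <- ifelse(a^theta > 0, a^theta * log(a), 0)
      blb <- ifelse(b^theta > 0, b^theta * log(b), 0)
      At <- ala + blb
      Ct <- -C * A^(1 / theta) * (-log(A) / theta^2 + At / (theta * A))
      list(C = C, Cu = Cu, Cv = Cv, Ct = Ct)
    },
    frank = {
      n <- max(length(u), length(v), length(theta))
      u <- rep_len(u, n); v <- rep_len(v, n); theta <- rep_len(theta, n)
      small <- abs(theta) < 1e-5
      C <- Cu <- Cv <- Ct <- numeric(n)
      if (any(small)) {
        us <- u[small]; vs <- v[small]; ts <- theta[small]
        C[small] <- us * vs * (1 + ts * (1 - us) * (1 - vs) / 2)
        Cu[small] <- vs + ts * vs * (1 - vs) * (1 - 2 * us) / 2
        Cv[small] <- us + ts * us * (1 - us) * (1 - 2 * vs) / 2
        Ct[small] <- us * vs * (1 - us) * (1 - vs) / 2
      }
      if (any(!small)) {
        ub <- u[!small]; vb <- v[!small]; tb <- theta[!small]
        E <- expm1(-tb); Eu <- expm1(-tb * ub); Ev <- expm1(-tb * vb)
        D <- 1 + Eu * Ev / E
        C[!small] <- -log(D) / tb
        Cu[!small] <- exp(-tb * ub) * Ev / (D * E)
        Cv[!small] <- exp(-tb * vb) * Eu / (D * E)
        dEu <- -ub * exp(-tb * ub); dEv <- -vb * exp(-tb * vb)
        dE <- -exp(-tb)
        dD <- ((dEu * Ev + Eu * dEv) * E - Eu * Ev * dE) / E^2
        Ct[!small] <- log(D) / tb^2 - dD / (tb * D)
      }
      list(C = C, Cu = Cu, Cv = Cv, Ct = Ct)
    },
    fgm = {
      C <- u * v * (1 + theta * (1 - u) * (1 - v))
      Cu <- v * (1 + theta * (1 - v) * (1 - 2 * u))
      Cv <- u * (1 + theta * (1 - u) * (1 - 2 * v))
      Ct <- u * v * (1 - u) * (1 - v)
      list(C = C, Cu = Cu, Cv = Cv, Ct = Ct)
    },
    plackett = {
      n <- max(length(u), length(v), length(theta))
      u <- rep_len(u, n); v <- rep_len(v, n); theta <- rep_len(theta, n)
      near1 <- abs(theta - 1) < 1e-6
      C <- Cu <- Cv <- Ct <- numeric(n)
      if (any(near1)) {
        us <- u[near1]; vs <- v[near1]; ts <- theta[near1]
        C[near1] <- us * vs * (1 + (ts - 1) * (1 - us) * (1 - vs))
        Cu[near1] <- vs * (1 + (ts - 1) * (1 - vs) * (1 - 2 * us))
        Cv[near1] <- us * (1 + (ts - 1) * (1 - us) * (1 - 2 * vs))
        Ct[near1] <- us * vs * (1 - us) * (1 - vs)
      }
      if (any(!near1)) {
        ub <- u[!near1]; vb <- v[!near1]; tb <- theta[!near1]
        S <- 1 + (tb - 1) * (ub + vb)
        R <- sqrt(S^2 - 4 * ub * vb * tb * (tb - 1))
        C[!near1] <- (S - R) / (2 * (tb - 1))
        Cu[!near1] <- 0.5 * (1 - (S - 2 * vb * tb) / R)
        Cv[!near1] <- 0.5 * (1 - (S - 2 * ub * tb) / R)
        dRdt <- (S * (ub + vb) - 2 * ub * vb * (2 * tb - 1)) / R
        Ct[!near1] <- ((ub + vb - dRdt) * (tb - 1) - (S - R)) /
          (2 * (tb - 1)^2)
      }
      list(C = C, Cu = Cu, Cv = Cv, Ct = Ct)
    },
    stop("unknown copula family: ", family))
}

# Second partial derivatives.  Gaussian: fully analytic.  Other families:
# central differences of the analytic first partials (step 1e-6, clamped
# inside the unit square / theta bounds).
.copula_derivs2 <- function(u, v, spec, theta) {
  family <- spec$family
  u <- pmin(pmax(u, 1e-10), 1 - 1e-10)
  v <- pmin(pmax(v, 1e-10), 1 - 1e-10)
  d1 <- .copula_derivs1(u, v, family, theta)
  if (family == "gaussian") {
    x <- qnorm(u); y <- qnorm(v)
    s2 <- 1 - theta^2; s <- sqrt(s2)
    zx <- (y - theta * x) / s
    zy <- (x - theta * y) / s
    phi2 <- d1$Ct                       # bivariate normal density at (x, y)
    Cuu <- dnorm(zx) * (-theta / s) / dnorm(x)
    Cvv <- dnorm(zy) * (-theta / s) / dnorm(y)
    Cuv <- dnorm(zx) / (s * dnorm(y))
    Cut <- phi2 * (-(x - theta * y) / s2) / dnorm(x)
    Cvt <- phi2 * (-(y - theta * x) / s2) / dnorm(y)
    Q <- (x^2 - 2 * theta * x * y + y^2) / s2
    dQ <- (-2 * x * y * s2 + (x^2 - 2 * theta * x * y + y^2) * 2 * theta) / s2^2
    Ctt <- phi2 * (theta / s2 - dQ / 2)
    return(c(d1, list(Cuu = Cuu, Cuv = Cuv, Cvv = Cvv,
                      Cut = Cut, Cvt = Cvt, Ctt = Ctt)))
  }
  hu <- 1e-6
  up <- pmin(u + hu, 1 - 1e-10); um <- pmax(u - hu, 1e-10)
  vp <- pmin(v + hu, 1 - 1e-10); vm <- pmax(v - hu, 1e-10)
  du <- up - um; dv <- vp - vm
  b <- spec$theta_bounds
  ht <- pmax(1e-6, 1e-6 * abs(theta))
  tp <- theta + ht; tm <- theta - ht
  if (is.finite(b[1])) tm <- pmax(tm, b[1] + .THETA_EPS / 2)
  if (is.finite(b[2])) tp <- pmin(tp, b[2] - .THETA_EPS / 2)
  dt <- tp - tm
  fup <- .copula_derivs1(up, v, family, theta)
  fum <- .copula_derivs1(um, v, family, theta)
  fvp <- .copula_derivs1(u, vp, family, theta)
  fvm <- .copula_derivs1(u, vm, family, theta)
  ftp <- .copula_derivs1(u, v, family, tp)
  ftm <- .copula_derivs1(u, v, family, tm)
  c(d1, list(
    Cuu = (fup$Cu - fum$Cu) / du,
    Cuv = (fvp$Cu - fvm$Cu) / dv,
    Cvv = (fvp$Cv - fvm$Cv) / dv,
    Cut = (ftp$Cu - ftm$Cu) / dt,
    Cvt = (ftp$Cv - ftm$Cv) / dt,
    Ctt = (ftp$Ct - ftm$Ct) / dt))
}

## ---------------------------------------------------------------------------
## theta links
## ---------------------------------------------------------------------------

#' Map the dependence parameter to / from the linear predictor scale
#'
#' \code{theta_to_eta} applies the family's link (e.g. atanh for the
#' Gaussian copula) and \code{eta_to_theta} inverts it.  The round trip is
#' the identity to machine precision for theta strictly inside the bounds.
#'
#' @param theta Dependence parameter(s) strictly inside the open bounds.
#' @param eta Real linear predictor value(s); capped at |eta| <= 15.
#' @param spec A \code{\link{copula_spec}}.
#' @return Numeric vector.
#' @export
theta_to_eta <- function(theta, spec) {
  .check_theta(theta, spec)
  switch(spec$link_name,
    atanh = atanh(theta),
    log = log(theta),
    log_shifted = log(theta - 1),
    identity_bounded = theta)
}

#' @rdname theta_to_eta
#' @export
eta_to_theta <- function(eta, spec) {
  eta <- pmin(pmax(eta, -.ETA_CAP), .ETA_CAP)
  th <- switch(spec$link_name,
    atanh = tanh(eta),
    log = exp(eta),
    log_shifted = 1 + exp(eta),
    identity_bounded = eta)
  .clamp_theta(th, spec)
}

# dtheta/deta and d2theta/deta2 on the capped eta scale
.dtheta_deta <- function(eta, spec) {
  eta <- pmin(pmax(eta, -.ETA_CAP), .ETA_CAP)
  switch(spec$link_name,
    atanh = 1 / cosh(eta)^2,
    log = exp(eta),
    log_shifted = exp(eta),
    identity_bounded = rep_len(1, length(eta)))
}

.d2theta_deta2 <- function(eta, spec) {
  eta <- pmin(pmax(eta, -.ETA_CAP), .ETA_CAP)
  switch(spec$link_name,
    atanh = -2 * tanh(eta) / cosh(eta)^2,
    log = exp(eta),
    log_shifted = exp(eta),
    identity_bounded = rep_len(0, length(eta)))
}

## ---------------------------------------------------------------------------
## 2x2 cell probabilities
## ---------------------------------------------------------------------------

#' Joint cell probabilities for two Bernoulli margins under a copula
#'
#' Builds the 2x2 table \eqn{P(Y_1 = y_1, Y_2 = y_2)} from the margin
#' success probabilities and the copula:
#' \eqn{p_{11} = C(\mu_1, \mu_2; \theta)}, \eqn{p_{10} = \mu_1 - p_{11}},
#' \eqn{p_{01} = \mu_2 - p_{11}}, \eqn{p_{00} = 1 - \mu_1 - \mu_2 + p_{11}}.
#' Tiny negative cells (rounding noise below 1e-12 in magnitude) are clipped
#' to zero and the table renormalized; anything below -1e-8 signals an
#' inadmissible theta or an implementation fault and raises an error.
#'
#' @param mu1,mu2 Margin probabilities in (0, 1).
#' @param spec A \code{\link{copula_spec}}.
#' @param theta Dependence parameter(s).
#' @return A data frame with columns \code{p11}, \code{p10}, \code{p01},
#'   \code{p00}, one row per input element.
#' @export
cell_probs <- function(mu1, mu2, spec, theta) {
  stopifnot(inherits(spec, "copula_spec"))
  if (any(mu1 <= 0 | mu1 >= 1 | mu2 <= 0 | mu2 >= 1))
    stop("mu1 and mu2 must lie strictly inside (0, 1)", call. = FALSE)
  n <- max(length(mu1), length(mu2), length(theta))
  mu1 <- rep_len(mu1, n); mu2 <- rep_len(mu2, n); theta <- rep_len(theta, n)
  p11 <- copula_cdf(mu1, mu2, spec, theta)
  p10 <- mu1 - p11
  p01 <- mu2 - p11
  p00 <- 1 - mu1 - mu2 + p11
  m <- cbind(p11 = p11, p10 = p10, p01 = p01, p00 = p00)
  worst <- min(m)
  if (worst < -1e-8)
    stop(sprintf(paste0(
      "negative cell probability %.3e: copula evaluation is numerically ",
      "invalid for (mu1, mu2, theta) = (%.4f, %.4f, %.4f)"),
      worst, mu1[which(m < -1e-8, arr.ind = TRUE)[1, 1]],
      mu2[which(m < -1e-8, arr.ind = TRUE)[1, 1]],
      theta[which(m < -1e-8, arr.ind = TRUE)[1, 1]]), call. = FALSE)
  m[m < 0] <- 0
  m <- m / rowSums(m)
  as.data.frame(m)
}

## ---------------------------------------------------------------------------
## Kendall's tau
## ---------------------------------------------------------------------------

#' Kendall's tau for a copula family
#'
#' Closed forms where available (Gaussian: \eqn{(2/\pi)\arcsin\theta};
#' Clayton: \eqn{\theta/(\theta+2)}; Gumbel: \eqn{1 - 1/\theta}; FGM:
#' \eqn{2\theta/9}; Frank: via the Debye function), otherwise Gauss-Legendre
#' evaluation of \eqn{\tau = 1 - 4\int\!\!\int \partial_u C\,\partial_v C
#' \,du\,dv}.
#'
#' @param spec A \code{\link{copula_spec}}.
#' @param theta Scalar dependence parameter.
#' @return Kendall's tau in (-1, 1).
#' @export
kendall_tau <- function(spec, theta) {
  stopifnot(inherits(spec, "copula_spec"), length(theta) == 1)
  .check_theta(theta, spec)
  switch(spec$family,
    gaussian = 2 / pi * asin(theta),
    clayton = theta / (theta + 2),
    gumbel = 1 - 1 / theta,
    fgm = 2 * theta / 9,
    frank = {
      if (abs(theta) < 1e-8) return(0)
      debye1 <- integrate(function(t) t / expm1(t), 0, theta,
                          rel.tol = 1e-10)$value / theta
      1 + 4 * (debye1 - 1) / theta
    },
    .kendall_tau_numeric(spec, theta))
}

# tau = 1 - 4 int int Cu * Cv du dv, 64x64 Gauss-Legendre on (0,1)^2
.kendall_tau_numeric <- function(spec, theta) {
  gl <- .gauss_legendre_01(64)
  uu <- rep(gl$x, each = 64); vv <- rep(gl$x, times = 64)
  ww <- rep(gl$w, each = 64) * rep(gl$w, times = 64)
  d <- .copula_derivs1(uu, vv, spec$family, rep_len(theta, length(uu)))
  1 - 4 * sum(ww * d$Cu * d$Cv)
}

# Gauss-Legendre nodes/weights on (0,1) via the Golub-Welsch eigenproblem
.gauss_legendre_01 <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b; J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(x = (x + 1) / 2, w = w / 2)
}
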