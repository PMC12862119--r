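#' Model specification for the bivariate copula regression
#'
#' Collects the three model equations — one linear predictor per margin and
#' one for the dependence parameter — together with the margin links and the
#' copula family.  Formulas use \code{s(x)} (optionally \code{s(x, k = )})
#' for a penalized thin-plate regression spline and \code{mrf(region)} for a
#' Markov random field smooth over a supplied adjacency graph; all other
#' terms are parametric with dummy coding.
#'
#' @param margin1,margin2 Formulas with the binary responses on the left,
#'   e.g. \code{lbw ~ ethnicity + smoke + s(age) + mrf(county)}.
#' @param theta_formula Right-hand-side formula for the dependence
#'   predictor (default intercept only).
#' @param link1,link2 Margin links: \code{"probit"}, \code{"logit"} or
#'   \code{"cloglog"}.
#' @param copula Copula family name passed to \code{\link{copula_spec}}.
#' @return An object of class \code{"cdr_spec"}.
#' @export
cdr_spec <- function(margin1, margin2, theta_formula = ~1,
                     link1 = c("probit", "logit", "cloglog"),
                     link2 = c("probit", "logit", "cloglog"),
                     copula = "gaussian") {
  link1 <- match.arg(link1); link2 <- match.arg(link2)
  out <- list(margin1 = margin1, margin2 = margin2,
              theta_formula = theta_formula,
              link1 = link1, link2 = link2,
              copula = copula_spec(copula))
  y1 <- all.vars(margin1[[2]]); y2 <- all.vars(margin2[[2]])
  if (identical(y1, y2))
    stop("the two margin outcomes must be distinct variables", call. = FALSE)
  class(out) <- "cdr_spec"
  out
}

## ---------------------------------------------------------------------------
## Link functions
## ---------------------------------------------------------------------------

#' Inverse link for a Bernoulli margin
#'
#' probit: \eqn{\Phi(\eta)}; logit: \eqn{1/(1+e^{-\eta})}; cloglog:
#' \eqn{1 - \exp(-e^{\eta})}.  Results are clipped to
#' \code{[1e-12, 1 - 1e-12]}.
#'
#' @param eta Linear predictor value(s).
#' @param link One of \code{"probit"}, \code{"logit"}, \code{"cloglog"}.
#' @return Probabilities.
#' @export
inverse_link <- function(eta, link = c("probit", "logit", "cloglog")) {
  link <- match.arg(link)
  mu <- switch(link,
    probit = pnorm(eta),
    logit = plogis(eta),
    cloglog = -expm1(-exp(eta)))
  pmin(pmax(mu, 1e-12), 1 - 1e-12)
}

# dmu/deta and d2mu/deta2
.link_d1 <- function(eta, link) {
  switch(link,
    probit = dnorm(eta),
    logit = { m <- plogis(eta); m * (1 - m) },
    cloglog = exp(eta - exp(eta)))
}
.link_d2 <- function(eta, link) {
  switch(link,
    probit = -eta * dnorm(eta),
    logit = { m <- plogis(eta); m * (1 - m) * (1 - 2 * m) },
    cloglog = exp(eta - exp(eta)) * (1 - exp(eta)))
}

## ---------------------------------------------------------------------------
## Per-equation design construction
## ---------------------------------------------------------------------------

# parse one model formula into parametric + smooth blocks
.build_equation <- function(formula, data, graph = NULL, xlevels = NULL,
                            smooth_templates = NULL) {
  tf <- stats::terms(formula)
  labels <- attr(tf, "term.labels")
  has_resp <- attr(tf, "response") == 1
  y <- NULL
  if (has_resp) {
    yname <- all.vars(formula[[2]])
    y <- data[[yname]]
    if (is.null(y)) stop("response not found in data: ", yname, call. = FALSE)
    if (!all(y %in% c(0, 1)))
      stop("response '", yname, "' must be coded 0/1", call. = FALSE)
  } else yname <- NULL

  par_terms <- character(0)
  smooth_calls <- list()
  for (lb in labels) {
    if (grepl("^(s|mrf)\\(", lb)) {
      smooth_calls[[length(smooth_calls) + 1]] <- str2lang(lb)
    } else par_terms <- c(par_terms, lb)
  }

  pb <- build_parametric(data, par_terms, xlevels = xlevels)
  X <- pb$X
  col_labels <- pb$labels
  smooths <- list()
  for (cl in smooth_calls) {
    kind <- as.character(cl[[1]])
    var <- as.character(cl[[2]])
    if (!var %in% names(data))
      stop("smooth covariate not found in data: ", var, call. = FALSE)
    lab <- paste0(kind, "(", var, ")")
    if (!is.null(smooth_templates) && lab %in% names(smooth_templates)) {
      term <- smooth_templates[[lab]]
      B <- eval_smooth(term, data[[var]])
    } else if (kind == "s") {
      k <- if (!is.null(cl$k)) eval(cl$k) else 10
      term <- build_tprs(data[[var]], k = k, label = lab)
      term$var <- var
      B <- term$basis
    } else {
      if (is.null(graph))
        stop("mrf() term requires an adjacency graph", call. = FALSE)
      term <- build_mrf(data[[var]], graph, label = lab)
      term$var <- var
      B <- term$basis
    }
    idx <- ncol(X) + seq_len(ncol(B))
    X <- cbind(X, B)
    col_labels <- c(col_labels, paste0(lab, ".", seq_len(ncol(B))))
    smooths[[lab]] <- list(term = term, idx = idx, label = lab)
  }
  colnames(X) <- col_labels
  list(X = X, y = y, yname = yname, labels = col_labels,
       par_idx = seq_along(pb$labels), par_labels = pb$labels,
       xlevels = pb$xlevels, smooths = smooths, formula = formula,
       par_terms = par_terms)
}

# design rows for new profiles, using construction-time state
.eq_design <- function(eq, newdata) {
  pb <- build_parametric(newdata, eq$par_terms, xlevels = eq$xlevels)
  X <- pb$X
  for (sm in eq$smooths) {
    if (!sm$term$var %in% names(newdata))
      stop("profile is missing covariate: ", sm$term$var, call. = FALSE)
    X <- cbind(X, eval_smooth(sm$term, newdata[[sm$term$var]]))
  }
  X
}

# warn on exactly collinear design columns, naming the first offender
.check_rank <- function(X, eqname) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_col <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning(sprintf(
      "design for %s is rank deficient: column(s) %s are collinear",
      eqname, paste(drop_col, collapse = ", ")), call. = FALSE)
  }
}

## ---------------------------------------------------------------------------
## Penalized log-likelihood, gradient and Hessian
## ---------------------------------------------------------------------------

# dm: list(X1, X2, Xt, y1, y2, link1, link2, cspec, pens)
# pens: list of list(S, eq, idx)  -- idx within the stacked coefficient vector
# beta stacked (b1, b2, bt); if fix_theta_eta is numeric, bt absent and
# eta_theta is that constant.

.split_beta <- function(beta, dm) {
  p1 <- ncol(dm$X1); p2 <- ncol(dm$X2)
  b1 <- beta[seq_len(p1)]
  b2 <- beta[p1 + seq_len(p2)]
  bt <- if (dm$free_theta) beta[p1 + p2 + seq_len(ncol(dm$Xt))] else NULL
  list(b1 = b1, b2 = b2, bt = bt)
}

#' Penalized log-likelihood of the copula model
#'
#' Evaluates \eqn{\ell_p(\beta) = \sum_i \log p_{y_{1i} y_{2i}} -
#' \frac12 \sum_s \lambda_s \beta_s' S_s \beta_s} for a stacked coefficient
#' vector, optionally with its analytic gradient and Hessian.  Exposed
#' mainly for testing; \code{\link{fit_cdr}} drives it.
#'
#' @param beta Stacked coefficients (margin 1, margin 2, dependence).
#' @param dm Internal design bundle as built by \code{\link{fit_cdr}}
#'   (returned in \code{fit$dm}).
#' @param lambdas Smoothing parameter vector (one per penalty; recycled).
#' @param want \code{"loglik"}, \code{"grad"} or \code{"hess"} —
#'   each level includes the previous ones.
#' @return List with \code{loglik} (penalized), \code{loglik_unpen},
#'   and optionally \code{grad} and \code{hess} (penalized), plus
#'   \code{hess_unpen} when \code{want = "hess"}.
#' @export
penalized_loglik <- function(beta, dm, lambdas, want = "grad") {
  sp <- .split_beta(beta, dm)
  eta1 <- drop(dm$X1 %*% sp$b1)
  eta2 <- drop(dm$X2 %*% sp$b2)
  etat <- if (dm$free_theta) drop(dm$Xt %*% sp$bt) else
    rep_len(dm$fix_theta_eta, length(eta1))
  mu1 <- inverse_link(eta1, dm$link1)
  mu2 <- inverse_link(eta2, dm$link2)
  theta <- eta_to_theta(etat, dm$cspec)

  need_hess <- want == "hess"
  d <- if (need_hess) .copula_derivs2(mu1, mu2, dm$cspec, theta)
       else .copula_derivs1(mu1, mu2, dm$cspec$family, theta)

  y1 <- dm$y1; y2 <- dm$y2
  sgn <- ifelse(y1 == y2, 1, -1)
  add_u <- (y1 == 1 & y2 == 0) - (y1 == 0 & y2 == 0)
  add_v <- (y2 == 1 & y1 == 0) - (y1 == 0 & y2 == 0)
  addc <- (y1 == 1 & y2 == 0) * mu1 + (y2 == 1 & y1 == 0) * mu2 +
    (y1 == 0 & y2 == 0) * (1 - mu1 - mu2)
  p <- sgn * d$C + addc
  if (any(!is.finite(p))) {
    i <- which(!is.finite(p))[1]
    stop(sprintf(
      "non-finite cell probability at record %d (mu1=%.4g, mu2=%.4g, theta=%.4g)",
      i, mu1[i], mu2[i], theta[i]), call. = FALSE)
  }
  p <- pmax(p, 1e-300)
  ll <- sum(log(p))

  lambdas <- rep_len(lambdas, length(dm$pens))
  pen <- 0
  for (s in seq_along(dm$pens)) {
    ps <- dm$pens[[s]]
    bs <- beta[ps$idx]
    pen <- pen + lambdas[s] * drop(crossprod(bs, ps$S %*% bs))
  }
  out <- list(loglik = ll - pen / 2, loglik_unpen = ll)
  if (want == "loglik") return(out)

  h1p <- .link_d1(eta1, dm$link1)
  h2p <- .link_d1(eta2, dm$link2)
  tp1 <- .dtheta_deta(etat, dm$cspec)

  dpdm1 <- sgn * d$Cu + add_u
  dpdm2 <- sgn * d$Cv + add_v
  dpdth <- sgn * d$Ct
  g1 <- dpdm1 * h1p / p
  g2 <- dpdm2 * h2p / p
  gt <- dpdth * tp1 / p

  grad <- c(crossprod(dm$X1, g1), crossprod(dm$X2, g2),
            if (dm$free_theta) crossprod(dm$Xt, gt))
  for (s in seq_along(dm$pens)) {
    ps <- dm$pens[[s]]
    grad[ps$idx] <- grad[ps$idx] - lambdas[s] * drop(ps$S %*% beta[ps$idx])
  }
  out$grad <- grad
  if (!need_hess) return(out)

  h1pp <- .link_d2(eta1, dm$link1)
  h2pp <- .link_d2(eta2, dm$link2)
  tp2 <- .d2theta_deta2(etat, dm$cspec)

  w11 <- (sgn * d$Cuu * h1p^2 + dpdm1 * h1pp) / p - g1^2
  w22 <- (sgn * d$Cvv * h2p^2 + dpdm2 * h2pp) / p - g2^2
  w12 <- (sgn * d$Cuv * h1p * h2p) / p - g1 * g2
  H11 <- crossprod(dm$X1 * w11, dm$X1)
  H22 <- crossprod(dm$X2 * w22, dm$X2)
  H12 <- crossprod(dm$X1 * w12, dm$X2)
  if (dm$free_theta) {
    w1t <- (sgn * d$Cut * h1p * tp1) / p - g1 * gt
    w2t <- (sgn * d$Cvt * h2p * tp1) / p - g2 * gt
    wtt <- (sgn * d$Ctt * tp1^2 + dpdth * tp2) / p - gt^2
    H1t <- crossprod(dm$X1 * w1t, dm$Xt)
    H2t <- crossprod(dm$X2 * w2t, dm$Xt)
    Htt <- crossprod(dm$Xt * wtt, dm$Xt)
    H <- rbind(cbind(H11, H12, H1t),
               cbind(t(H12), H22, H2t),
               cbind(t(H1t), t(H2t), Htt))
  } else {
    H <- rbind(cbind(H11, H12), cbind(t(H12), H22))
  }
  out$hess_unpen <- H
  Hp <- H
  for (s in seq_along(dm$pens)) {
    ps <- dm$pens[[s]]
    Hp[ps$idx, ps$idx] <- Hp[ps$idx, ps$idx] - lambdas[s] * ps$S
  }
  out$hess <- Hp
  out
}

## ---------------------------------------------------------------------------
## Newton inner loop
## ---------------------------------------------------------------------------

.newton_fit <- function(beta, dm, lambdas, control) {
  iter <- 0
  fval <- penalized_loglik(beta, dm, lambdas, want = "hess")
  trace <- NULL
  repeat {
    iter <- iter + 1
    g <- fval$grad
    H <- -fval$hess               # negative penalized Hessian
    ridge <- 0
    ch <- NULL
    repeat {
      ch <- tryCatch(chol(H + diag(ridge, nrow(H))), error = function(e) NULL)
      if (!is.null(ch)) break
      ridge <- if (ridge == 0) 1e-7 * mean(abs(diag(H))) + 1e-10 else ridge * 100
      if (ridge > 1e10 * (mean(abs(diag(H))) + 1)) break
    }
    if (is.null(ch)) {            # fall back to steepest ascent
      step <- g / sqrt(sum(g^2) + 1e-12)
    } else {
      step <- backsolve(ch, forwardsolve(t(ch), g))
    }
    t_ <- 1
    repeat {
      cand <- beta + t_ * step
      fc <- tryCatch(penalized_loglik(cand, dm, lambdas, want = "loglik"),
                     error = function(e) NULL)
      if (!is.null(fc) && is.finite(fc$loglik) &&
          fc$loglik >= fval$loglik - 1e-12) break
      t_ <- t_ / 2
      if (t_ < 1e-10) break
    }
    if (t_ < 1e-10) break         # no ascent step found
    beta <- beta + t_ * step
    fval <- penalized_loglik(beta, dm, lambdas, want = "hess")
    gmax <- max(abs(fval$grad))
    trace <- rbind(trace, c(iter = iter, loglik_pen = fval$loglik,
                            grad_max = gmax, step = t_))
    if (gmax < control$tol || iter >= control$maxit) break
  }
  gmax <- max(abs(fval$grad))
  pd <- !inherits(tryCatch(chol(-fval$hess), error = function(e) e), "error")
  list(beta = beta, fval = fval, iter = iter, grad_max = gmax,
       hess_pd = pd,
       converged = gmax < control$conv_tol && pd,
       trace = trace)
}

# effective degrees of freedom: trace of (Hn + S_lambda)^{-1} Hn
.edf <- function(fval, dm, lambdas) {
  Hn <- -fval$hess_unpen
  Hp <- -fval$hess
  Fm <- tryCatch(solve(Hp, Hn), error = function(e) {
    solve(Hp + diag(1e-8 * mean(abs(diag(Hp))), nrow(Hp)), Hn)
  })
  edf_i <- diag(Fm)
  lambdas <- rep_len(lambdas, length(dm$pens))
  per_smooth <- vapply(dm$pens, function(ps) sum(edf_i[ps$idx]), 0)
  list(total = sum(edf_i), per_coef = edf_i, per_smooth = per_smooth)
}

#' Control parameters for \code{\link{fit_cdr}}
#'
#' @param tol Gradient max-norm at which the Newton iteration stops.
#' @param conv_tol Gradient max-norm below which the fit is flagged
#'   converged (with a positive-definite penalized Hessian).
#' @param maxit Maximum Newton iterations per inner fit.
#' @param outer_maxit Maximum objective evaluations of the smoothing
#'   parameter search.
#' @param lambda_grid Coarse common-log-lambda grid tried before the
#'   derivative-free refinement.
#' @param verbose Print per-iteration progress.
#' @return A list of control values.
#' @export
cdr_control <- function(tol = 1e-7, conv_tol = 1e-5, maxit = 100,
                        outer_maxit = 100, lambda_grid = c(-2, 0, 2, 4),
                        verbose = FALSE) {
  list(tol = tol, conv_tol = conv_tol, maxit = maxit,
       outer_maxit = outer_maxit, lambda_grid = lambda_grid,
       verbose = verbose)
}

## ---------------------------------------------------------------------------
## Main fitting routine
## ---------------------------------------------------------------------------

#' Fit the bivariate copula distributional regression
#'
#' Penalized maximum likelihood for the three-equation model: two Bernoulli
#' margins joined by a one-parameter copula whose dependence parameter has
#' its own linear predictor.  Smoothing parameters are either fixed or
#' selected by minimizing AIC (based on effective degrees of freedom) over
#' log-lambda with a Nelder-Mead search started from the best point of a
#' coarse grid.  Standard errors derive from the inverse penalized Hessian
#' (Bayesian posterior covariance).
#'
#' @param data Data frame with the outcomes and covariates; rows with
#'   missing values in model variables are dropped (with a message).
#' @param spec A \code{\link{cdr_spec}}.
#' @param graph A \code{\link{region_graph}} if any equation has an
#'   \code{mrf()} term.
#' @param lambda \code{"auto"} (default) or a numeric vector of fixed
#'   smoothing parameters, one per smooth (margin-1 smooths, margin-2
#'   smooths, dependence-equation smooths, in formula order).
#' @param fix_theta_eta Optional numeric: freeze the dependence predictor at
#'   this value on the link scale (e.g. 0 for independence) instead of
#'   estimating the dependence equation.
#' @param control See \code{\link{cdr_control}}.
#' @return An object of class \code{"cdr_fit"}: stacked \code{coefficients},
#'   posterior covariance \code{Vp}, \code{lambdas}, \code{edf} (total and
#'   per smooth), unpenalized \code{loglik}, per-record \code{fitted}
#'   (mu1, mu2, theta), convergence diagnostics, and the design bundle
#'   needed for prediction.
#' @export
fit_cdr <- function(data, spec, graph = NULL, lambda = "auto",
                    fix_theta_eta = NULL, control = cdr_control()) {
  stopifnot(inherits(spec, "cdr_spec"))
  vars <- unique(c(all.vars(spec$margin1), all.vars(spec$margin2),
                   all.vars(spec$theta_formula)))
  vars <- intersect(vars, names(data))
  cc <- stats::complete.cases(data[, vars, drop = FALSE])
  if (any(!cc)) {
    message(sum(!cc), " record(s) with missing model variables dropped")
    data <- data[cc, , drop = FALSE]
  }

  eq1 <- .build_equation(spec$margin1, data, graph)
  eq2 <- .build_equation(spec$margin2, data, graph)
  eqt <- .build_equation(spec$theta_formula, data, graph)
  .check_rank(eq1$X, "margin 1"); .check_rank(eq2$X, "margin 2")
  if (ncol(eqt$X) > 1) .check_rank(eqt$X, "dependence equation")

  free_theta <- is.null(fix_theta_eta)
  p1 <- ncol(eq1$X); p2 <- ncol(eq2$X); pt <- if (free_theta) ncol(eqt$X) else 0
  pens <- list()
  for (sm in eq1$smooths)
    pens[[length(pens) + 1]] <- list(S = sm$term$penalty, idx = sm$idx,
                                     label = paste0("eq1:", sm$label))
  for (sm in eq2$smooths)
    pens[[length(pens) + 1]] <- list(S = sm$term$penalty, idx = p1 + sm$idx,
                                     label = paste0("eq2:", sm$label))
  if (free_theta)
    for (sm in eqt$smooths)
      pens[[length(pens) + 1]] <- list(S = sm$term$penalty,
                                       idx = p1 + p2 + sm$idx,
                                       label = paste0("theta:", sm$label))

  dm <- list(X1 = eq1$X, X2 = eq2$X, Xt = eqt$X,
             y1 = eq1$y, y2 = eq2$y,
             link1 = spec$link1, link2 = spec$link2,
             cspec = spec$copula, pens = pens,
             free_theta = free_theta, fix_theta_eta = fix_theta_eta)

  # start values: univariate penalized margin fits, dependence at eta = 0
  b1 <- .start_margin(eq1, spec$link1, pens, 0, control)
  b2 <- .start_margin(eq2, spec$link2, pens, p1, control)
  beta0 <- c(b1, b2, if (free_theta) rep(0, pt))

  n_pen <- length(pens)
  auto <- identical(lambda, "auto") && n_pen > 0
  lam <- if (auto) rep(1, n_pen) else
    if (n_pen > 0) rep_len(as.numeric(lambda), n_pen) else numeric(0)

  if (auto) {
    # inner fit cache for warm starts
    warm <- beta0
    n_eval <- 0
    objective <- function(loglam) {
      n_eval <<- n_eval + 1
      lm_ <- exp(loglam)
      ft <- .newton_fit(warm, dm, lm_, control)
      warm <<- ft$beta
      ed <- .edf(ft$fval, dm, lm_)
      aic <- -2 * ft$fval$loglik_unpen + 2 * ed$total
      if (control$verbose)
        cat(sprintf("  lambda eval %d: log-lam = (%s), AIC = %.3f\n",
                    n_eval, paste(sprintf("%.2f", loglam), collapse = ", "),
                    aic))
      aic
    }
    grid_vals <- vapply(control$lambda_grid * log(10),
                        function(g) objective(rep(g, n_pen)), 0)
    best <- control$lambda_grid[which.min(grid_vals)] * log(10)
    opt <- stats::optim(rep(best, n_pen), objective, method = "Nelder-Mead",
                        control = list(maxit = control$outer_maxit,
                                       reltol = 1e-4,
                                       warn.1d.NelderMead = FALSE))
    lam <- exp(opt$par)
    beta0 <- warm
  }

  ft <- .newton_fit(beta0, dm, lam, control)
  fval <- ft$fval
  ed <- if (n_pen > 0) .edf(fval, dm, lam) else {
    list(total = p1 + p2 + pt, per_coef = rep(1, p1 + p2 + pt),
         per_smooth = numeric(0))
  }

  Hp <- -fval$hess
  Vp <- tryCatch(chol2inv(chol(Hp)), error = function(e) {
    warning("penalized Hessian not positive definite; ",
            "covariance computed with a small ridge", call. = FALSE)
    solve(Hp + diag(1e-7 * mean(abs(diag(Hp))) + 1e-10, nrow(Hp)))
  })

  sp <- .split_beta(ft$beta, dm)
  eta1 <- drop(eq1$X %*% sp$b1); eta2 <- drop(eq2$X %*% sp$b2)
  etat <- if (free_theta) drop(eqt$X %*% sp$bt) else
    rep_len(fix_theta_eta, nrow(eq1$X))
  fitted <- data.frame(mu1 = inverse_link(eta1, spec$link1),
                       mu2 = inverse_link(eta2, spec$link2),
                       theta = eta_to_theta(etat, spec$copula))

  labels <- c(paste0("eq1:", eq1$labels), paste0("eq2:", eq2$labels),
              if (free_theta) paste0("theta:", eqt$labels))
  beta <- ft$beta
  names(beta) <- labels
  dimnames(Vp) <- list(labels, labels)
  names(ed$per_smooth) <- vapply(pens, `[[`, "", "label")
  if (n_pen > 0) names(lam) <- names(ed$per_smooth)

  structure(list(
    coefficients = beta, Vp = Vp, lambdas = lam,
    edf = ed$total, edf_per_smooth = ed$per_smooth,
    edf_per_coef = ed$per_coef,
    loglik = fval$loglik_unpen, loglik_pen = fval$loglik,
    fitted = fitted, n = nrow(eq1$X),
    converged = ft$converged, grad_max = ft$grad_max,
    hess_pd = ft$hess_pd, iterations = ft$iter, trace = ft$trace,
    spec = spec, dm = dm, eq1 = eq1, eq2 = eq2, eqt = eqt,
    free_theta = free_theta, fix_theta_eta = fix_theta_eta),
    class = "cdr_fit")
}

# univariate penalized binary regression Newton for margin start values
.start_margin <- function(eq, link, pens, offset_idx, control) {
  X <- eq$X; y <- eq$y
  p <- ncol(X)
  Ss <- list()
  for (ps in pens) {
    local <- ps$idx - offset_idx
    if (all(local >= 1 & local <= p)) Ss[[length(Ss) + 1]] <-
        list(S = ps$S, idx = local)
  }
  beta <- c(stats::qnorm(pmin(pmax(mean(y), 0.02), 0.98)), rep(0, p - 1))
  if (link == "logit") beta[1] <- stats::qlogis(pmin(pmax(mean(y), 0.02), 0.98))
  for (it in 1:50) {
    eta <- drop(X %*% beta)
    mu <- inverse_link(eta, link)
    d1 <- .link_d1(eta, link)
    g <- (y / mu - (1 - y) / (1 - mu)) * d1
    w <- d1^2 * (y / mu^2 + (1 - y) / (1 - mu)^2)
    grad <- drop(crossprod(X, g))
    H <- crossprod(X * w, X)
    for (s in Ss) {
      grad[s$idx] <- grad[s$idx] - drop(s$S %*% beta[s$idx])
      H[s$idx, s$idx] <- H[s$idx, s$idx] + s$S
    }
    step <- tryCatch(solve(H + diag(1e-8, p), grad), error = function(e) grad)
    beta <- beta + step
    if (max(abs(grad)) < 1e-6) break
  }
  beta
}

## ---------------------------------------------------------------------------
## Methods and diagnostics
## ---------------------------------------------------------------------------

#' @export
logLik.cdr_fit <- function(object, ...) {
  structure(object$loglik, df = object$edf, class = "logLik")
}

#' Information criteria with effective degrees of freedom
#'
#' AIC = \eqn{-2\ell + 2\,\mathrm{edf}};
#' BIC = \eqn{-2\ell + \log(n)\,\mathrm{edf}}, where \eqn{\ell} is the
#' unpenalized log-likelihood at the penalized optimum and edf the total
#' effective degrees of freedom.
#'
#' @param model A \code{"cdr_fit"}.
#' @return Named numeric vector \code{c(AIC = , BIC = )}.
#' @export
information_criteria <- function(model) {
  stopifnot(inherits(model, "cdr_fit"))
  c(AIC = -2 * model$loglik + 2 * model$edf,
    BIC = -2 * model$loglik + log(model$n) * model$edf)
}

#' @export
AIC.cdr_fit <- function(object, ..., k = 2) {
  -2 * object$loglik + k * object$edf
}

#' @export
BIC.cdr_fit <- function(object, ...) {
  unname(information_criteria(object)["BIC"])
}

#' Convergence diagnostics
#'
#' Reports the gradient max-norm at the optimum, the smallest eigenvalue of
#' the negative penalized Hessian, iteration counts and the selected
#' smoothing parameters.
#'
#' @param model A \code{"cdr_fit"}.
#' @return Invisibly, a list of the reported quantities.
#' @export
conv_check <- function(model) {
  stopifnot(inherits(model, "cdr_fit"))
  Hp <- -penalized_loglik(model$coefficients, model$dm,
                          if (length(model$lambdas)) model$lambdas else 0,
                          want = "hess")$hess
  ev <- eigen(Hp, symmetric = TRUE, only.values = TRUE)$values
  out <- list(converged = model$converged,
              grad_max = model$grad_max,
              min_eigen = min(ev),
              iterations = model$iterations,
              lambdas = model$lambdas,
              edf = model$edf)
  cat("Converged:               ", out$converged, "\n")
  cat("Gradient max-norm:       ", format(out$grad_max, digits = 4), "\n")
  cat("Smallest -Hessian eigen: ", format(out$min_eigen, digits = 4), "\n")
  cat("Newton iterations:       ", out$iterations, "\n")
  if (length(out$lambdas))
    cat("Smoothing parameters:    ",
        paste(sprintf("%s = %.4g", names(out$lambdas), out$lambdas),
              collapse = ", "), "\n")
  cat("Total edf:               ", format(out$edf, digits = 5), "\n")
  invisible(out)
}

#' @export
print.cdr_fit <- function(x, ...) {
  cat("Copula distributional regression fit\n")
  cat("  copula:", x$spec$copula$family,
      "| links:", x$spec$link1, "/", x$spec$link2, "\n")
  cat("  n =", x$n, "| coefficients =", length(x$coefficients),
      "| edf =", format(x$edf, digits = 5), "\n")
  cat("  log-likelihood =", format(x$loglik, digits = 8),
      "| AIC =", format(AIC(x), digits = 8), "\n")
  cat("  converged:", x$converged,
      "( max|grad| =", format(x$grad_max, digits = 3), ")\n")
  invisible(x)
}
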