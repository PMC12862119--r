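#' Predict joint, marginal and conditional probabilities with intervals
#'
#' Computes a model-based quantity for one or more covariate profiles:
#' plug-in point estimates from the fitted per-profile
#' \eqn{(\mu_1, \mu_2, \theta)} through the copula cell probabilities, and
#' percentile intervals from posterior simulation — coefficient draws
#' \eqn{\beta^* \sim N(\hat\beta, V_p)} propagated through the same
#' nonlinear map.  Conditional probabilities are ratios of cells, e.g.
#' \eqn{P(Y_1 = 1 \mid Y_2 = 1) = p_{11}/\mu_2}.
#'
#' Every call verifies the cell-probability identities (cells sum to one
#' and conditional times marginal equals joint, both to 1e-12) and refuses
#' conditioning events with probability below 1e-10.
#'
#' @param model A \code{\link{fit_cdr}} result.
#' @param profile Data frame of covariate profiles (one row per profile).
#' @param quantity One of \code{"marg1"}, \code{"marg2"}, \code{"joint11"},
#'   \code{"joint10"}, \code{"joint01"}, \code{"joint00"},
#'   \code{"cond_1_given_2"}, \code{"cond_1_given_not2"},
#'   \code{"cond_2_given_1"}, \code{"theta"}, \code{"tau"}.
#' @param level Interval coverage (default 0.95).
#' @param n_sim Number of posterior draws (default 1000).
#' @param seed Seed for the posterior draws (recorded in the output).
#' @return Data frame with columns \code{quantity}, \code{estimate},
#'   \code{lower}, \code{upper}; attribute \code{"seed"} records the draw
#'   seed.
#' @export
predict_quantity <- function(model, profile,
                             quantity = c("marg1", "marg2", "joint11",
                                          "joint10", "joint01", "joint00",
                                          "cond_1_given_2",
                                          "cond_1_given_not2",
                                          "cond_2_given_1", "theta", "tau"),
                             level = 0.95, n_sim = 1000, seed = 1) {
  stopifnot(inherits(model, "cdr_fit"))
  quantity <- match.arg(quantity)
  if (!model$converged)
    warning("model not flagged converged; predictions may be unreliable",
            call. = FALSE)
  stopifnot(level > 0, level < 1)

  X1 <- .eq_design(model$eq1, profile)
  X2 <- .eq_design(model$eq2, profile)
  Xt <- .eq_design(model$eqt, profile)
  est <- .quantity_from_beta(model$coefficients, model, X1, X2, Xt, quantity)

  draws <- .posterior_draws(model, n_sim, seed)
  qsim <- apply(draws, 1, function(b)
    .quantity_from_beta(b, model, X1, X2, Xt, quantity, check = FALSE))
  if (is.null(dim(qsim))) qsim <- matrix(qsim, nrow = 1)
  alpha <- (1 - level) / 2
  ci <- t(apply(qsim, 1, stats::quantile, probs = c(alpha, 1 - alpha)))

  out <- data.frame(quantity = quantity, estimate = est,
                    lower = ci[, 1], upper = ci[, 2], level = level)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  out
}

# evaluate one quantity for a coefficient vector at profile design rows
.quantity_from_beta <- function(beta, model, X1, X2, Xt, quantity,
                                check = TRUE) {
  sp <- .split_beta(beta, model$dm)
  mu1 <- inverse_link(drop(X1 %*% sp$b1), model$spec$link1)
  mu2 <- inverse_link(drop(X2 %*% sp$b2), model$spec$link2)
  etat <- if (model$free_theta) drop(Xt %*% sp$bt) else
    rep_len(model$fix_theta_eta, length(mu1))
  theta <- eta_to_theta(etat, model$spec$copula)
  if (quantity == "theta") return(theta)
  if (quantity == "tau")
    return(vapply(theta, function(t) kendall_tau(model$spec$copula, t), 0))
  cp <- cell_probs(mu1, mu2, model$spec$copula, theta)
  if (check) {
    stopifnot(all(abs(rowSums(cp) - 1) < 1e-12))
    stopifnot(all(abs(cp$p11 / pmax(mu2, 1e-300) * mu2 - cp$p11) < 1e-12))
  }
  switch(quantity,
    marg1 = mu1, marg2 = mu2,
    joint11 = cp$p11, joint10 = cp$p10, joint01 = cp$p01, joint00 = cp$p00,
    cond_1_given_2 = { .check_cond(mu2); cp$p11 / mu2 },
    cond_1_given_not2 = { .check_cond(1 - mu2); cp$p10 / (1 - mu2) },
    cond_2_given_1 = { .check_cond(mu1); cp$p11 / mu1 })
}

.check_cond <- function(pr) {
  if (any(pr < 1e-10))
    stop("conditioning event has probability below 1e-10: ",
         "conditional probability undefined", call. = FALSE)
}

# n_sim x p matrix of coefficient draws from N(beta-hat, Vp)
.posterior_draws <- function(model, n_sim, seed) {
  set.seed(seed)
  p <- length(model$coefficients)
  R <- tryCatch(chol(model$Vp), error = function(e)
    chol(model$Vp + diag(1e-10 * mean(diag(model$Vp)), p)))
  Z <- matrix(rnorm(n_sim * p), n_sim, p)
  sweep(Z %*% R, 2, model$coefficients, `+`)
}

#' Overall dependence summary
#'
#' The "overall" copula parameter is the observation-weighted mean of the
#' per-record \eqn{\hat\theta_i}; its interval comes from posterior
#' simulation of that mean.  Because the dependence equation is covariate-
#' dependent, per-pattern values (one per distinct dependence-predictor
#' row) are reported alongside, with the tetrachoric interpretation under
#' the Gaussian copula.
#'
#' @param model A \code{\link{fit_cdr}} result.
#' @param level Interval coverage.
#' @param n_sim Posterior draws.
#' @param seed Draw seed.
#' @return List with \code{estimate}, \code{lower}, \code{upper},
#'   \code{tau} (Kendall's tau at the mean theta) and \code{per_level}
#'   (data frame of per-pattern theta estimates and intervals).
#' @export
average_theta <- function(model, level = 0.95, n_sim = 1000, seed = 1) {
  stopifnot(inherits(model, "cdr_fit"))
  if (!model$free_theta)
    return(list(estimate = model$fitted$theta[1], lower = NA, upper = NA,
                per_level = NULL))
  Xt <- model$dm$Xt
  bt_idx <- ncol(model$dm$X1) + ncol(model$dm$X2) + seq_len(ncol(Xt))
  cs <- model$spec$copula
  theta_hat <- eta_to_theta(drop(Xt %*% model$coefficients[bt_idx]), cs)
  draws <- .posterior_draws(model, n_sim, seed)[, bt_idx, drop = FALSE]

  patt <- unique(as.data.frame(Xt))
  alpha <- (1 - level) / 2
  mean_draws <- vapply(seq_len(n_sim), function(s)
    mean(eta_to_theta(drop(Xt %*% draws[s, ]), cs)), 0)
  per <- do.call(rbind, lapply(seq_len(nrow(patt)), function(i) {
    xrow <- as.numeric(patt[i, ])
    th <- eta_to_theta(sum(xrow * model$coefficients[bt_idx]), cs)
    ds <- eta_to_theta(drop(draws %*% xrow), cs)
    data.frame(pattern = paste(colnames(Xt)[xrow != 0 &
                                 colnames(Xt) != "(Intercept)"],
                               collapse = "+"),
               theta = th,
               lower = unname(stats::quantile(ds, alpha)),
               upper = unname(stats::quantile(ds, 1 - alpha)))
  }))
  per$pattern[per$pattern == ""] <- "(reference)"
  list(estimate = mean(theta_hat),
       lower = unname(stats::quantile(mean_draws, alpha)),
       upper = unname(stats::quantile(mean_draws, 1 - alpha)),
       tau = kendall_tau(cs, mean(theta_hat)),
       per_level = per)
}

## ---------------------------------------------------------------------------
## Effect tables
## ---------------------------------------------------------------------------

#' Effect tables for the three equations
#'
#' Parametric coefficients with standard errors from the posterior
#' covariance, Z = estimate/SE and two-sided normal p-values; smooth terms
#' summarized by their effective degrees of freedom.
#'
#' @param object A \code{\link{fit_cdr}} result.
#' @param ... Unused.
#' @return A \code{"summary.cdr_fit"}: list of per-equation coefficient
#'   tables (\code{margin1}, \code{margin2}, \code{theta}) and a
#'   \code{smooths} edf table.
#' @export
summary.cdr_fit <- function(object, ...) {
  se <- sqrt(diag(object$Vp))
  mk_table <- function(idx, labels) {
    est <- unname(object$coefficients[idx])
    s <- unname(se[idx])
    z <- est / s
    data.frame(parameter = labels, estimate = est, se = s, z = z,
               p = 2 * stats::pnorm(-abs(z)))
  }
  p1 <- ncol(object$dm$X1); p2 <- ncol(object$dm$X2)
  t1 <- mk_table(object$eq1$par_idx, object$eq1$par_labels)
  t2 <- mk_table(p1 + object$eq2$par_idx, object$eq2$par_labels)
  tt <- if (object$free_theta)
    mk_table(p1 + p2 + object$eqt$par_idx, object$eqt$par_labels) else NULL
  sm <- if (length(object$edf_per_smooth))
    data.frame(term = names(object$edf_per_smooth),
               edf = unname(object$edf_per_smooth),
               lambda = unname(object$lambdas)) else NULL
  structure(list(margin1 = t1, margin2 = t2, theta = tt, smooths = sm,
                 loglik = object$loglik, edf = object$edf, n = object$n,
                 aic = AIC(object), converged = object$converged),
            class = "summary.cdr_fit")
}

#' @export
print.summary.cdr_fit <- function(x, digits = 3, ...) {
  fmt <- function(tb) {
    tb$p <- format.pval(tb$p, digits = digits, eps = 1e-3)
    print(format(tb, digits = digits), row.names = FALSE)
  }
  cat("Margin 1 coefficients:\n"); fmt(x$margin1)
  cat("\nMargin 2 coefficients:\n"); fmt(x$margin2)
  if (!is.null(x$theta)) {
    cat("\nDependence equation coefficients:\n"); fmt(x$theta)
  }
  if (!is.null(x$smooths)) {
    cat("\nSmooth terms:\n")
    print(format(x$smooths, digits = digits), row.names = FALSE)
  }
  cat("\nn =", x$n, " log-likelihood =", format(x$loglik, digits = 8),
      " edf =", format(x$edf, digits = 5),
      " AIC =", format(x$aic, digits = 8), "\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Plots
## ---------------------------------------------------------------------------

#' Plot a fitted smooth with a 95\% posterior band
#'
#' Evaluates the centered smooth contribution on a 200-point grid over the
#' observed covariate range with pointwise percentile bands from posterior
#' simulation.
#'
#' @param model A \code{\link{fit_cdr}} result.
#' @param term Term label, e.g. \code{"eq1:s(age)"} (equation prefix
#'   \code{eq1:}, \code{eq2:} or \code{theta:}).
#' @param n_sim Posterior draws for the band.
#' @param seed Draw seed.
#' @param n_grid Grid size.
#' @param plot Draw on the current device (base graphics)?
#' @param ... Passed to \code{plot}.
#' @return Invisibly, a data frame \code{x}, \code{fit}, \code{lower},
#'   \code{upper}.
#' @export
plot_smooth <- function(model, term, n_sim = 1000, seed = 1, n_grid = 200,
                        plot = TRUE, ...) {
  stopifnot(inherits(model, "cdr_fit"))
  av <- c(paste0("eq1:", names(model$eq1$smooths)),
          paste0("eq2:", names(model$eq2$smooths)),
          if (model$free_theta) paste0("theta:", names(model$eqt$smooths)))
  if (!term %in% av)
    stop("unknown smooth term '", term, "'; available: ",
         paste(av, collapse = ", "), call. = FALSE)
  eqname <- sub(":.*", "", term)
  lab <- sub("^[^:]*:", "", term)
  eq <- switch(eqname, eq1 = model$eq1, eq2 = model$eq2, theta = model$eqt)
  offset <- switch(eqname, eq1 = 0, eq2 = ncol(model$dm$X1),
                   theta = ncol(model$dm$X1) + ncol(model$dm$X2))
  sm <- eq$smooths[[lab]]
  # grid over the construction data range (regions for an MRF term)
  grid <- if (is.null(sm$term$graph))
    seq(sm$term$xrange[1], sm$term$xrange[2], length.out = n_grid) else
      sm$term$graph$region_ids
  B <- eval_smooth(sm$term, grid)
  idx <- offset + sm$idx
  fit <- drop(B %*% model$coefficients[idx])
  draws <- .posterior_draws(model, n_sim, seed)[, idx, drop = FALSE]
  sims <- B %*% t(draws)
  lo <- apply(sims, 1, stats::quantile, 0.025)
  hi <- apply(sims, 1, stats::quantile, 0.975)
  out <- data.frame(x = if (is.null(sm$term$graph)) grid else
                      as.numeric(grid),
                    fit = fit, lower = lo, upper = hi)
  if (plot && is.null(sm$term$graph)) {
    edf_s <- model$edf_per_smooth[term]
    plot(out$x, out$fit, type = "n", ylim = range(out$lower, out$upper),
         xlab = sm$term$var,
         ylab = if (is.na(edf_s)) term else
           sprintf("%s (edf %.2f)", term, edf_s), ...)
    polygon(c(out$x, rev(out$x)), c(out$lower, rev(out$upper)),
            col = "grey85", border = NA)
    lines(out$x, out$fit, lwd = 2)
  }
  invisible(out)
}

#' Map per-region values
#'
#' Renders one value per region on the county graph, either at supplied
#' coordinates or with a spectral layout of the adjacency graph (Laplacian
#' eigenvectors), shading points by value.
#'
#' @param values Named numeric vector (names = region ids).
#' @param graph A \code{\link{region_graph}}.
#' @param coords Optional two-column coordinate matrix with region-id
#'   rownames (e.g. \code{county$coords} from
#'   \code{\link{make_county_graph}}).
#' @param main Title.
#' @param palette Color ramp function.
#' @param plot Draw on the current device?
#' @return Invisibly, a data frame of region, x, y, value.
#' @export
plot_map <- function(values, graph, coords = NULL, main = "",
                     palette = grDevices::hcl.colors, plot = TRUE) {
  ids <- graph$region_ids
  if (is.null(names(values))) names(values) <- ids
  miss <- setdiff(ids, names(values))
  if (length(miss))
    stop("no value supplied for region(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(coords)) {
    L <- graph_laplacian(graph)
    e <- eigen(L, symmetric = TRUE)
    nc <- ncol(e$vectors)
    coords <- e$vectors[, c(nc - 1, nc - 2)]
    rownames(coords) <- ids
  }
  v <- values[ids]
  rngv <- range(v)
  cols <- if (diff(rngv) < 1e-15) rep(palette(2)[1], length(v)) else
    palette(100)[1 + round(99 * (v - rngv[1]) / diff(rngv))]
  out <- data.frame(region = ids, x = coords[ids, 1], y = coords[ids, 2],
                    value = unname(v))
  if (plot) {
    plot(out$x, out$y, type = "n", axes = FALSE, xlab = "", ylab = "",
         main = main)
    for (e_ in seq_len(nrow(graph$edges))) {
      a <- graph$edges[e_, 1]; b <- graph$edges[e_, 2]
      segments(coords[a, 1], coords[a, 2], coords[b, 1], coords[b, 2],
               col = "grey80")
    }
    points(out$x, out$y, pch = 21, bg = cols, cex = 2)
  }
  invisible(out)
}
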