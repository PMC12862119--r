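#' Region adjacency graph
#'
#' A light container for the county neighbourhood structure used by the
#' Markov random field smooth: an ordered roster of region identifiers and
#' an edge list of unordered adjacent pairs.
#'
#' @param region_ids Character (or coercible) vector of unique region labels.
#' @param edges Two-column matrix or data frame of region id pairs; self
#'   loops are rejected, duplicate pairs collapsed.
#' @return An object of class \code{"region_graph"} with elements
#'   \code{region_ids}, \code{edges} (two-column character matrix) and
#'   \code{n_components}.
#' @export
region_graph <- function(region_ids, edges) {
  region_ids <- as.character(region_ids)
  if (anyDuplicated(region_ids))
    stop("region_ids must be unique", call. = FALSE)
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stop("edges must have two columns", call. = FALSE)
  storage.mode(edges) <- "character"
  if (any(edges[, 1] == edges[, 2]))
    stop("self-loops are not allowed in the adjacency structure",
         call. = FALSE)
  unknown <- setdiff(c(edges), region_ids)
  if (length(unknown))
    stop("edge endpoints not in region roster: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  # canonical order, drop duplicates
  sw <- edges[, 1] > edges[, 2]
  edges[sw, ] <- edges[sw, 2:1]
  edges <- unique(edges)
  g <- structure(list(region_ids = region_ids, edges = edges),
                 class = "region_graph")
  g$n_components <- .graph_components(g)
  if (g$n_components > 1)
    warning(sprintf(
      "adjacency graph has %d connected components; isolated blocks keep a zero penalty row",
      g$n_components), call. = FALSE)
  g
}

#' @export
print.region_graph <- function(x, ...) {
  cat("Region graph:", length(x$region_ids), "regions,",
      nrow(x$edges), "edges,", x$n_components, "connected component(s)\n")
  invisible(x)
}

# number of connected components (iterative label propagation)
.graph_components <- function(graph) {
  ids <- graph$region_ids
  comp <- seq_along(ids)
  names(comp) <- ids
  e1 <- match(graph$edges[, 1], ids)
  e2 <- match(graph$edges[, 2], ids)
  repeat {
    new <- comp
    m <- pmin(comp[e1], comp[e2])
    # propagate the smaller label across each edge
    for (j in seq_along(e1)) {
      if (new[e1[j]] > m[j]) new[e1[j]] <- m[j]
      if (new[e2[j]] > m[j]) new[e2[j]] <- m[j]
    }
    if (identical(new, comp)) break
    comp <- new
  }
  length(unique(comp))
}

#' Graph Laplacian of a region graph
#'
#' Returns the combinatorial Laplacian L with L_ii = degree(i) and
#' L_ij = -1 for adjacent regions, with dimnames equal to the region roster.
#' Used as the MRF penalty: \eqn{\beta' L \beta = \sum_{i \sim j}
#' (\beta_i - \beta_j)^2}.
#'
#' @param graph A \code{\link{region_graph}}.
#' @return A square numeric matrix.
#' @export
graph_laplacian <- function(graph) {
  ids <- graph$region_ids
  n <- length(ids)
  L <- matrix(0, n, n, dimnames = list(ids, ids))
  i <- match(graph$edges[, 1], ids)
  j <- match(graph$edges[, 2], ids)
  for (e in seq_along(i)) {
    L[i[e], j[e]] <- L[i[e], j[e]] - 1
    L[j[e], i[e]] <- L[j[e], i[e]] - 1
    L[i[e], i[e]] <- L[i[e], i[e]] + 1
    L[j[e], j[e]] <- L[j[e], j[e]] + 1
  }
  L
}

#' Read a region adjacency edge list
#'
#' Plain-text format: one comma-separated pair \code{"idA,idB"} per line.
#' Blank lines and lines starting with \code{#} are skipped.
#'
#' @param path File path.
#' @param region_ids Optional roster; defaults to the ids seen in the file.
#' @return A \code{\link{region_graph}}.
#' @export
read_adjacency <- function(path, region_ids = NULL) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  parts <- strsplit(trimws(lines[keep]), ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad))
    stop(sprintf("malformed adjacency line %d: '%s' (expected 'idA,idB')",
                 keep[bad[1]], lines[keep[bad[1]]]), call. = FALSE)
  edges <- do.call(rbind, parts)
  edges <- trimws(edges)
  if (is.null(region_ids))
    region_ids <- sort(unique(c(edges)))
  region_graph(region_ids, edges)
}

#' Write a region adjacency edge list
#'
#' @param graph A \code{\link{region_graph}}.
#' @param path Output file path.
#' @export
write_adjacency <- function(graph, path) {
  writeLines(paste(graph$edges[, 1], graph$edges[, 2], sep = ","), path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Smooth term construction (thin wrappers over mgcv::smoothCon so that the
## bases and penalties are exactly those a gam() fit would use)
## ---------------------------------------------------------------------------

#' Penalized thin-plate regression spline term
#'
#' Builds the rank-\code{k} 1-D thin-plate regression spline basis for a
#' continuous covariate together with its wiggliness (bending energy)
#' penalty, with the sum-to-zero identifiability constraint absorbed by
#' reparameterization, so every basis column sums to zero over the data.
#' After constraint absorption the penalty null space is the linear trend
#' (dimension 1).
#'
#' @param x Numeric covariate values (construction data).
#' @param k Basis dimension before constraint (default 10); requires at
#'   least \code{k} distinct values.
#' @param label Term label used in reports.
#' @return An object of class \code{"smooth_term"}: \code{label},
#'   \code{basis} (n x (k-1)), \code{penalty} ((k-1) x (k-1), symmetric
#'   PSD), \code{null_dim}, \code{penalty_scale} (factor applied by the
#'   constructor), \code{constraint = "sum-to-zero (centered)"} and the
#'   underlying constructor state used for prediction.
#' @export
build_tprs <- function(x, k = 10, label = "s(x)") {
  x <- as.numeric(x)
  if (k < 3) stop("k must be at least 3", call. = FALSE)
  if (length(unique(x)) < k)
    stop(sprintf(
      "only %d distinct covariate values: reduce the basis dimension k below that",
      length(unique(x))), call. = FALSE)
  dat <- data.frame(x = x)
  sm <- mgcv::smoothCon(mgcv::s(x, bs = "tp", k = k), data = dat,
                        absorb.cons = TRUE)[[1]]
  .smooth_term(sm, label = label, var = "x",
               null_dim = 1L, extra = list(xrange = range(x)))
}

#' Markov random field smooth term
#'
#' Builds the region-indicator basis and graph-Laplacian penalty for a
#' spatially smooth region effect: adjacent regions are shrunk toward each
#' other, with the sum-to-zero constraint absorbed.  The penalty null space
#' after constraint has dimension (number of connected components - 1);
#' isolated regions simply carry a zero penalty row.
#'
#' @param region Vector of region ids, one per record; every value must
#'   appear in \code{graph$region_ids}.
#' @param graph A \code{\link{region_graph}}.
#' @param label Term label used in reports.
#' @return A \code{"smooth_term"}; see \code{\link{build_tprs}}.
#' @export
build_mrf <- function(region, graph, label = "mrf(region)") {
  region <- as.character(region)
  missing_ids <- setdiff(unique(region), graph$region_ids)
  if (length(missing_ids))
    stop("regions present in data but absent from the adjacency graph: ",
         paste(sort(missing_ids), collapse = ", "), call. = FALSE)
  L <- graph_laplacian(graph)
  dat <- data.frame(x = factor(region, levels = graph$region_ids))
  sm <- mgcv::smoothCon(mgcv::s(x, bs = "mrf", xt = list(penalty = L)),
                        data = dat, absorb.cons = TRUE)[[1]]
  .smooth_term(sm, label = label, var = "x",
               null_dim = graph$n_components - 1L,
               extra = list(graph = graph))
}

# common smooth_term packaging
.smooth_term <- function(sm, label, var, null_dim, extra = NULL) {
  out <- c(list(label = label, var = var,
                basis = sm$X,
                penalty = sm$S[[1]],
                penalty_scale = if (is.null(sm$S.scale)) 1 else sm$S.scale,
                null_dim = null_dim,
                constraint = "sum-to-zero (centered)",
                sm = sm), extra)
  class(out) <- "smooth_term"
  out
}

#' @export
print.smooth_term <- function(x, ...) {
  cat("Smooth term", x$label, ":", ncol(x$basis), "basis columns,",
      "penalty null dim", x$null_dim, "\n")
  invisible(x)
}

#' Evaluate a smooth term's basis at new covariate values
#'
#' @param term A \code{"smooth_term"}.
#' @param x New covariate values (numeric for TPRS, region ids for MRF).
#' @return Design matrix rows matching the constrained basis.
#' @export
eval_smooth <- function(term, x) {
  stopifnot(inherits(term, "smooth_term"))
  if (!is.null(term$graph)) {
    x <- as.character(x)
    bad <- setdiff(unique(x), term$graph$region_ids)
    if (length(bad))
      stop("unknown region id(s) at prediction time: ",
           paste(sort(bad), collapse = ", "), call. = FALSE)
    nd <- data.frame(x = factor(x, levels = term$graph$region_ids))
  } else {
    nd <- data.frame(x = as.numeric(x))
  }
  mgcv::PredictMat(term$sm, nd)
}

## ---------------------------------------------------------------------------
## Parametric (dummy-coded) design block
## ---------------------------------------------------------------------------

# canonical reference levels for the birth-cohort covariates
.canonical_levels <- list(
  ethnicity = c("White", "Hispanic", "Black", "Other"),
  educ = c("Primary", "Secondary", "Tertiary"))
.yesno_vars <- c("firstbirth", "smoke")

# coerce a covariate column to a factor with fixed reference level
.as_model_factor <- function(x, name, levels = NULL) {
  if (name %in% names(.canonical_levels)) {
    lev <- .canonical_levels[[name]]
    x <- factor(as.character(x), levels = lev)
    if (anyNA(x))
      stop(sprintf("unknown level in '%s' (expected one of %s)",
                   name, paste(lev, collapse = ", ")), call. = FALSE)
    return(x)
  }
  if (name == "marital") {
    x <- as.character(x)
    x[x %in% c("0", "No", "Unmarried")] <- "Unmarried"
    x[x %in% c("1", "Yes", "Married")] <- "Married"
    return(factor(x, levels = c("Unmarried", "Married")))
  }
  if (name %in% .yesno_vars || all(x %in% c(0, 1, "0", "1", "No", "Yes"))) {
    x <- as.character(x)
    x[x %in% c("0", "No")] <- "No"
    x[x %in% c("1", "Yes")] <- "Yes"
    return(factor(x, levels = c("No", "Yes")))
  }
  if (!is.null(levels)) {
    f <- factor(as.character(x), levels = levels)
    if (anyNA(f))
      stop(sprintf("unknown level '%s' in '%s' at prediction time",
                   setdiff(unique(as.character(x)), levels)[1], name),
           call. = FALSE)
    return(f)
  }
  factor(x)
}

#' Parametric design block with fixed reference levels
#'
#' Dummy (indicator) coding of categorical and binary covariates with the
#' reference levels fixed as ethnicity = White, educ = Primary,
#' firstbirth/marital/smoke = No; continuous covariates enter untouched.
#'
#' @param data Data frame holding the covariates.
#' @param terms Character vector of covariate names.
#' @param xlevels Optional list of factor levels recorded at construction
#'   time (used at prediction; unseen levels raise an error).
#' @return A list with \code{X} (design matrix including intercept),
#'   \code{labels} (column names) and \code{xlevels}.
#' @export
build_parametric <- function(data, terms, xlevels = NULL) {
  cols <- list()
  labels <- "(Intercept)"
  X <- matrix(1, nrow(data), 1)
  lev_out <- list()
  for (nm in terms) {
    if (!nm %in% names(data))
      stop("covariate not found in data: ", nm, call. = FALSE)
    x <- data[[nm]]
    if (is.numeric(x) && !(nm %in% .yesno_vars) &&
        !all(x %in% c(0, 1))) {
      X <- cbind(X, x)
      labels <- c(labels, nm)
      next
    }
    f <- .as_model_factor(x, nm, levels = xlevels[[nm]])
    lev_out[[nm]] <- levels(f)
    M <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(M) <- paste0(nm, levels(f)[-1])
    X <- cbind(X, M)
    labels <- c(labels, colnames(M))
  }
  colnames(X) <- labels
  list(X = X, labels = labels, xlevels = lev_out)
}
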