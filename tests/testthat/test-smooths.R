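make_lattice <- function(nx, ny) {
  ids <- as.character(seq_len(nx * ny))
  edges <- NULL
  for (r in 0:(ny - 1)) for (c0 in 0:(nx - 1)) {
    i <- r * nx + c0 + 1
    if (c0 < nx - 1) edges <- rbind(edges, c(ids[i], ids[i + 1]))
    if (r < ny - 1) edges <- rbind(edges, c(ids[i], ids[i + nx]))
  }
  region_graph(ids, edges)
}

test_that("region graphs validate input and report structure", {
  g <- region_graph(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  expect_equal(g$n_components, 1)
  expect_error(region_graph(c("a", "b"), rbind(c("a", "a"))), "self-loop")
  expect_error(region_graph(c("a", "b"), rbind(c("a", "z"))), "roster")
  expect_warning(region_graph(c("a", "b", "c"), rbind(c("a", "b"))),
                 "components")
})

test_that("graph Laplacian matches its definition", {
  g <- region_graph(c("1", "2", "3"), rbind(c("1", "2"), c("2", "3")))
  L <- graph_laplacian(g)
  expect_equal(unname(L),
               rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)))
  # beta' L beta = sum over edges of squared differences, random beta
  g2 <- make_lattice(4, 3)
  L2 <- graph_laplacian(g2)
  set.seed(3)
  for (i in 1:5) {
    b <- rnorm(12)
    edge_sum <- sum((b[as.integer(g2$edges[, 1])] -
                       b[as.integer(g2$edges[, 2])])^2)
    expect_equal(drop(t(b) %*% L2 %*% b), edge_sum, tolerance = 1e-12)
  }
  # constant vector in the null space of a connected graph
  expect_equal(drop(t(rep(2, 12)) %*% L2 %*% rep(2, 12)), 0,
               tolerance = 1e-12)
  # rank = regions - components
  ev <- eigen(L2, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(ev > 1e-8), 12 - 1)
})

test_that("adjacency files round trip and malformed lines are located", {
  g <- make_lattice(3, 3)
  f <- tempfile(fileext = ".txt")
  write_adjacency(g, f)
  g2 <- read_adjacency(f)
  expect_equal(sort(g2$region_ids), sort(g$region_ids))
  expect_equal(nrow(g2$edges), nrow(g$edges))
  writeLines(c("1,2", "2;3", "3,4"), f)
  expect_error(read_adjacency(f), "line 2")
})

test_that("TPRS basis is centered, PSD-penalized, linear in the null space", {
  set.seed(1)
  x <- runif(300, 13, 50)
  st <- build_tprs(x, k = 10)
  expect_equal(ncol(st$basis), 9)
  expect_lt(max(abs(colSums(st$basis))), 1e-8)
  expect_equal(st$penalty, t(st$penalty), tolerance = 1e-12)
  ev <- eigen(st$penalty, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
  expect_equal(st$null_dim, 1)
  # linear function: representable with zero penalty; lambda -> infinity
  # collapses any fit to the least-squares straight line
  B <- cbind(1, st$basis)
  p <- ncol(B)
  S <- matrix(0, p, p); S[-1, -1] <- st$penalty
  y <- 2 + 3 * x
  b <- solve(crossprod(B) + 1e8 * S, crossprod(B, y))
  expect_lt(max(abs(B %*% b - y)), 1e-6)
  expect_lt(drop(t(b[-1]) %*% st$penalty %*% b[-1]), 1e-10)
  y2 <- sin(x / 6)
  b2 <- solve(crossprod(B) + 1e9 * S, crossprod(B, y2))
  ols <- fitted(lm(y2 ~ x))
  expect_lt(max(abs(drop(B %*% b2) - ols)), 1e-4)
  expect_error(build_tprs(rep(1:5, 10), k = 10), "distinct")
})

test_that("TPRS penalty quadratic form approximates bending energy", {
  x <- seq(0, pi, length.out = 30)
  st <- build_tprs(x, k = 20)
  B <- cbind(1, st$basis)
  p <- ncol(B)
  S <- matrix(0, p, p); S[-1, -1] <- st$penalty
  y <- sin(3 * x)
  b <- solve(crossprod(B) + 1e-9 * S, crossprod(B, y))
  grid <- seq(min(x), max(x), length.out = 4001)
  fg <- drop(cbind(1, eval_smooth(st, grid)) %*% b)
  h <- grid[2] - grid[1]
  bend <- sum((diff(fg, differences = 2) / h^2)^2) * h
  qf <- drop(t(b[-1]) %*% st$penalty %*% b[-1]) * st$penalty_scale
  expect_equal(qf, bend, tolerance = 0.05)
})

test_that("MRF term reproduces the Laplacian quadratic form", {
  g <- make_lattice(3, 3)
  set.seed(2)
  reg <- sample(g$region_ids, 150, replace = TRUE)
  mt <- build_mrf(reg, g)
  expect_equal(ncol(mt$basis), 8)     # 9 regions - 1 constraint
  expect_lt(max(abs(colSums(mt$basis))), 1e-8)
  expect_equal(mt$null_dim, 0)        # connected graph
  Fm <- eval_smooth(mt, g$region_ids)
  L <- graph_laplacian(g)
  for (i in 1:5) {
    b <- rnorm(8)
    f <- drop(Fm %*% b)
    expect_equal(drop(t(b) %*% mt$penalty %*% b) * mt$penalty_scale,
                 drop(t(f) %*% L %*% f), tolerance = 1e-10)
  }
  expect_error(build_mrf(c(reg, "not-a-county"), g), "not-a-county")
  expect_error(eval_smooth(mt, "99"), "unknown region")
})

test_that("parametric block uses the fixed reference coding", {
  d <- data.frame(ethnicity = c("Black", "White", "Hispanic"),
                  educ = c("Tertiary", "Primary", "Secondary"),
                  firstbirth = c(1, 0, 0), marital = c(0, 0, 1),
                  smoke = c(1, 0, 0), age = c(30, 25, 40))
  pb <- build_parametric(d, c("ethnicity", "educ", "firstbirth", "marital",
                              "smoke", "age"))
  expect_equal(pb$labels,
               c("(Intercept)", "ethnicityHispanic", "ethnicityBlack",
                 "ethnicityOther", "educSecondary", "educTertiary",
                 "firstbirthYes", "maritalMarried", "smokeYes", "age"))
  # record with ethnicity Black: 1 only in the Black dummy
  expect_equal(unname(pb$X[1, c("ethnicityBlack", "ethnicityHispanic",
                                "ethnicityOther")]), c(1, 0, 0))
  # all-reference record: all dummies 0
  expect_equal(unname(pb$X[2, -c(1, 10)]), rep(0, 8))
  # 3-level educ gives exactly two columns
  expect_equal(sum(startsWith(pb$labels, "educ")), 2)
  expect_error(build_parametric(data.frame(ethnicity = "Martian"),
                                "ethnicity"), "Martian|unknown")
})
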