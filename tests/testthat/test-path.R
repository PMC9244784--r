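test_that("a null edge has a near-zero coefficient", {
  set.seed(1)
  n <- 2000
  dd <- data.frame(A = rnorm(n), B = rnorm(n))
  fit <- fit_path(dd, path_spec(data.frame(from = "A", to = "B")))
  cf <- fit$coefficients$coef[1]
  expect_lt(abs(cf), 3 / sqrt(n))
  expect_lt(fit$r2[["B"]], 0.01)
})

test_that("a saturated recursive model fits perfectly", {
  set.seed(2)
  n <- 500
  dd <- data.frame(X = rnorm(n))
  dd$M <- 0.5 * dd$X + rnorm(n)
  dd$Y <- 0.3 * dd$X + 0.4 * dd$M + rnorm(n)
  spec <- path_spec(data.frame(
    from = c("X", "X", "M"), to = c("M", "Y", "Y")))
  fit <- fit_path(dd, spec)
  expect_equal(fit$df, 0)
  expect_equal(fit$chi_square, 0, tolerance = 1e-8)
  # implied correlations reproduce observed exactly
  expect_equal(fit$implied, fit$observed, tolerance = 1e-10)
})

test_that("chain coefficients are recovered and match the OLS oracle", {
  set.seed(3)
  n <- 10000
  X <- rnorm(n)
  M <- 0.6 * X + rnorm(n, 0, sqrt(1 - 0.36))
  Y <- 0.5 * M + rnorm(n, 0, sqrt(1 - 0.25))
  dd <- data.frame(X = X, M = M, Y = Y)
  spec <- path_spec(data.frame(from = c("X", "M"), to = c("M", "Y")))
  fit <- fit_path(dd, spec)
  cxm <- fit$coefficients$coef[fit$coefficients$from == "X"]
  cmy <- fit$coefficients$coef[fit$coefficients$from == "M"]
  expect_equal(cxm, 0.6, tolerance = 0.03)
  expect_equal(cmy, 0.5, tolerance = 0.03)
  # equation-wise standardized OLS oracle
  o1 <- unname(coef(lm(scale(M) ~ scale(X)))[2])
  o2 <- unname(coef(lm(scale(Y) ~ scale(M)))[2])
  expect_equal(cxm, o1, tolerance = 1e-10)
  expect_equal(cmy, o2, tolerance = 1e-10)
})

test_that("multi-parent equations equal standardized multiple regression", {
  set.seed(4)
  n <- 800
  dd <- data.frame(A = rnorm(n), B = rnorm(n))
  dd$C <- 0.4 * dd$A - 0.3 * dd$B + rnorm(n)
  spec <- path_spec(data.frame(from = c("A", "B"), to = c("C", "C")))
  fit <- fit_path(dd, spec)
  oracle <- coef(lm(scale(C) ~ scale(A) + scale(B), data = dd))[-1]
  got <- fit$coefficients$coef[match(c("A", "B"),
                                     fit$coefficients$from)]
  expect_equal(got, unname(oracle), tolerance = 1e-10)
})

test_that("indirect effects follow the product-of-paths rule", {
  set.seed(5)
  n <- 300
  X <- rnorm(n); M <- 0.6 * X + rnorm(n); Y <- 0.5 * M + rnorm(n)
  dd <- data.frame(X = X, M = M, Y = Y)
  spec <- path_spec(data.frame(from = c("X", "M"), to = c("M", "Y")))
  fit <- fit_path(dd, spec)
  eff <- indirect_effects(fit, "X", "Y")
  a <- fit$coefficients$coef[fit$coefficients$from == "X"]
  b <- fit$coefficients$coef[fit$coefficients$from == "M"]
  expect_equal(eff$indirect, a * b, tolerance = 1e-12)
  expect_equal(eff$direct, 0)
  # no path at all
  expect_equal(indirect_effects(fit, "Y", "X")$total, 0)
})

test_that("matrix-based effects equal brute-force path enumeration", {
  set.seed(6)
  vars <- c("A", "B", "C", "D", "E", "F")
  edges <- data.frame(
    from = c("A", "A", "B", "B", "C", "D", "C", "A"),
    to   = c("B", "C", "C", "D", "D", "E", "E", "F"))
  spec <- path_spec(edges)
  n <- 400
  dd <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  names(dd) <- vars
  # induce dependence along the DAG
  dd$B <- 0.5 * dd$A + rnorm(n)
  dd$C <- 0.3 * dd$A + 0.4 * dd$B + rnorm(n)
  dd$D <- 0.2 * dd$B + 0.3 * dd$C + rnorm(n)
  dd$E <- 0.6 * dd$D + 0.2 * dd$C + rnorm(n)
  dd$F <- 0.4 * dd$A + rnorm(n)
  fit <- fit_path(dd, spec)
  # exhaustive DFS over all directed paths, products of coefficients
  B <- fit$B
  enumerate <- function(src, tgt) {
    total <- 0
    walk <- function(node, prod) {
      if (node == tgt) { total <<- total + prod; return(invisible()) }
      nxt <- spec$edges$to[spec$edges$from == node]
      for (v in nxt) walk(v, prod * B[v, node])
    }
    nxt <- spec$edges$to[spec$edges$from == src]
    for (v in nxt) walk(v, B[v, src])
    total
  }
  for (tgt in c("D", "E")) {
    eff <- indirect_effects(fit, "A", tgt)
    expect_equal(eff$total, enumerate("A", tgt), tolerance = 1e-12)
  }
})

test_that("total effect equals the reduced-form coefficient on clean data", {
  set.seed(7)
  n <- 50000
  X <- rnorm(n)
  M <- 0.6 * X + rnorm(n, 0, 1e-3)
  Y <- 0.5 * M + 0.2 * X + rnorm(n, 0, 1e-3)
  dd <- data.frame(X = X, M = M, Y = Y)
  spec <- path_spec(data.frame(from = c("X", "M", "X"),
                               to = c("M", "Y", "Y")))
  fit <- fit_path(dd, spec)
  eff <- indirect_effects(fit, "X", "Y")
  reduced <- unname(coef(lm(scale(Y) ~ scale(X)))[2])
  expect_equal(eff$total, reduced, tolerance = 1e-4)
  expect_equal(eff$total, eff$direct + eff$indirect, tolerance = 1e-12)
})

test_that("cyclic specifications and collinear parents are errors", {
  expect_error(path_spec(data.frame(from = c("A", "B"), to = c("B", "A"))),
               "cycle")
  set.seed(8)
  n <- 100
  A <- rnorm(n)
  dd <- data.frame(A = A, B = A, C = rnorm(n))  # B duplicates A
  spec <- path_spec(data.frame(from = c("A", "B"), to = c("C", "C")))
  expect_error(fit_path(dd, spec), "collinearity.*C")
})

test_that("stratified path analysis skips above-optimal N by design", {
  g <- generate_dataset(generator_config(n_studies = 60L, seed = 19,
                                         missing_rates = c(
                                           et = 0.3, nue = 0.5, soc = 0,
                                           an = 0, ap = 0, ak = 0,
                                           mat = 0, map_mm = 0)))
  optima <- find_optima_all(g$dataset)
  fits <- path_analysis(g$dataset, optima)
  expect_true(fits$W_minus$converged)
  expect_true(fits$W_plus$converged)
  expect_true(fits$N_minus$converged)
  expect_false(fits$N_plus$converged)
  expect_true(all(fits$W_minus$r2 >= 0 & fits$W_minus$r2 <= 1))
})

test_that("path specs round-trip through YAML and JSON config", {
  edges <- data.frame(from = c("x", "m"), to = c("m", "y"))
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(lapply(seq_len(nrow(edges)), function(i)
    list(from = edges$from[i], to = edges$to[i])), yml)
  sp <- read_path_spec(yml)
  expect_equal(sp$edges$from, edges$from)
  jsn <- tempfile(fileext = ".json")
  jsonlite::write_json(edges, jsn)
  sp2 <- read_path_spec(jsn)
  expect_equal(sp2$edges$to, edges$to)
  unlink(c(yml, jsn))
})
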