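test_that("a perfectly separating binary feature gives a depth-1 tree", {
  X <- data.frame(f = c(rep(0, 10), rep(1, 10)))
  y <- c(rep(2, 10), rep(5, 10))
  tree <- grow_tree(X, y, min_leaf = 2)
  expect_false(tree$root$is_leaf)
  expect_true(tree$root$left$is_leaf)
  expect_true(tree$root$right$is_leaf)
  expect_equal(mean((predict(tree, X) - y)^2), 0)
})

test_that("constant response yields a single leaf", {
  X <- data.frame(a = rnorm(20), b = rnorm(20))
  y <- rep(3.5, 20)
  tree <- grow_tree(X, y)
  expect_true(tree$root$is_leaf)
  expect_equal(predict(tree, X), rep(3.5, 20))
  rk <- rank_features(tree)
  expect_true(all(rk$importance == 0))
})

test_that("root split equals exhaustive search over feature/threshold pairs", {
  set.seed(42)
  n <- 50
  X <- data.frame(x1 = runif(n), x2 = runif(n), x3 = rnorm(n))
  y <- 2 * (X$x2 > 0.6) + 0.5 * X$x1 + rnorm(n, 0, 0.3)
  tree <- grow_tree(X, y, min_leaf = 5)
  # brute force: all features, all midpoints, SSE reduction
  best <- list(gain = -Inf)
  for (j in seq_along(X)) {
    xs <- sort(unique(X[[j]]))
    for (k in seq_len(length(xs) - 1)) {
      thr <- (xs[k] + xs[k + 1]) / 2
      l <- y[X[[j]] <= thr]
      r <- y[X[[j]] > thr]
      if (length(l) < 5 || length(r) < 5) next
      gain <- sum((y - mean(y))^2) -
        (sum((l - mean(l))^2) + sum((r - mean(r))^2))
      if (gain > best$gain) best <- list(gain = gain, j = j, thr = thr)
    }
  }
  expect_equal(tree$root$feature, names(X)[best$j])
  expect_equal(tree$root$threshold, best$thr, tolerance = 1e-12)
})

test_that("every split strictly reduces total risk", {
  set.seed(7)
  n <- 200
  X <- data.frame(a = runif(n), b = runif(n))
  y <- sin(6 * X$a) + rnorm(n, 0, 0.2)
  tree <- grow_tree(X, y, min_leaf = 5, max_depth = 6)
  check <- function(node) {
    if (node$is_leaf) return(invisible())
    expect_gt(node$gain_risk, 0)
    expect_equal(node$risk - (node$left$risk + node$right$risk),
                 node$gain_risk, tolerance = 1e-10)
    expect_equal(node$left$n_node + node$right$n_node, node$n_node)
    check(node$left)
    check(node$right)
  }
  check(tree$root)
})

test_that("categorical features split by response-ordered partition", {
  X <- data.frame(g = rep(c("a", "b", "c", "d"), each = 8),
                  stringsAsFactors = FALSE)
  y <- rep(c(1, 5, 1.2, 5.3), each = 8)
  tree <- grow_tree(X, y, min_leaf = 4)
  expect_false(tree$root$is_leaf)
  expect_setequal(tree$root$categories, c("a", "c"))
  # unseen category routed deterministically
  p <- predict(tree, data.frame(g = "zz"))
  expect_true(is.finite(p))
})

test_that("importance follows the risk-change-per-branch-node formula", {
  set.seed(9)
  n <- 150
  X <- data.frame(f1 = runif(n), f2 = runif(n), noise = runif(n))
  y <- 3 * (X$f1 > 0.5) + 1.5 * (X$f2 > 0.3) + rnorm(n, 0, 0.1)
  tree <- grow_tree(X, y, min_leaf = 5, max_depth = 5)
  rk <- rank_features(tree)
  # independent traversal accumulating risk changes
  acc <- c(f1 = 0, f2 = 0, noise = 0)
  nb <- 0
  walk <- function(node) {
    if (node$is_leaf) return(invisible())
    acc[node$feature] <<- acc[node$feature] +
      (node$risk - node$left$risk - node$right$risk)
    nb <<- nb + 1
    walk(node$left)
    walk(node$right)
  }
  walk(tree$root)
  for (f in names(acc)) {
    expect_equal(rk$importance[rk$feature == f], acc[[f]] / nb,
                 tolerance = 1e-12)
  }
  # only-splitting features carry importance
  d1 <- grow_tree(data.frame(u = c(rep(0, 8), rep(1, 8)),
                             v = rnorm(16)),
                  c(rep(1, 8), rep(4, 8)), min_leaf = 4)
  rk1 <- rank_features(d1)
  expect_gt(rk1$importance[rk1$feature == "u"], 0)
  expect_equal(rk1$importance[rk1$feature == "v"], 0)
})

test_that("signal features dominate the ranking across seeded replicates", {
  hits <- 0
  reps <- 100
  for (s in seq_len(reps)) {
    set.seed(s)
    n <- 150
    X <- data.frame(f1 = runif(n), f2 = runif(n), n1 = runif(n),
                    n2 = runif(n), n3 = runif(n))
    y <- 2.5 * (X$f1 > 0.5) + 2 * X$f2 + rnorm(n, 0, 0.3)
    rk <- rank_features(grow_tree(X, y, min_leaf = 10, max_depth = 5))
    if (all(c("f1", "f2") %in% rk$feature[1:2])) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.95)
})

test_that("cross-validation folds are balanced, exhaustive and seeded", {
  set.seed(1)
  n <- 103
  X <- data.frame(a = runif(n))
  y <- X$a + rnorm(n, 0, 0.1)
  cv1 <- cross_validate(X, y, k = 10, seed = 5)
  sizes <- sort(as.numeric(table(cv1$folds)))
  expect_equal(sizes, c(rep(10, 7), rep(11, 3)))
  expect_equal(length(cv1$folds), n)
  cv2 <- cross_validate(X, y, k = 10, seed = 5)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$fold_mse, cv2$fold_mse)
  # leave-one-out
  cvl <- cross_validate(X[1:12, , drop = FALSE], y[1:12], k = 12,
                        seed = 2, min_leaf = 2)
  expect_equal(as.numeric(table(cvl$folds)), rep(1, 12))
  expect_error(cross_validate(X[1:5, , drop = FALSE], y[1:5], k = 10),
               "exceeds")
})

test_that("median/mode imputation preserves row count and drops empty cols", {
  X <- data.frame(a = c(1, NA, 3), b = c("x", "y", NA),
                  c = c(NA, NA, NA), stringsAsFactors = FALSE)
  expect_warning(imp <- impute_features(X), "all-missing")
  expect_equal(nrow(imp$X), 3)
  expect_false("c" %in% names(imp$X))
  expect_equal(imp$X$a, c(1, 2, 3))
  expect_false(anyNA(imp$X$b))
})

test_that("trees serialize to JSON", {
  X <- data.frame(f = c(rep(0, 6), rep(1, 6)))
  y <- c(rep(1, 6), rep(2, 6))
  tree <- grow_tree(X, y, min_leaf = 2)
  path <- tempfile(fileext = ".json")
  write_tree_json(tree, path)
  parsed <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_false(parsed$leaf)
  expect_equal(parsed$feature, "f")
  unlink(path)
})

test_that("root split agrees with an independent CART implementation", {
  skip_if_not_installed("rpart")
  set.seed(55)
  n <- 120
  X <- data.frame(a = runif(n), b = runif(n), c = rnorm(n))
  y <- 2 * (X$a > 0.4) + X$b + rnorm(n, 0, 0.2)
  tree <- grow_tree(X, y, min_leaf = 5, max_depth = 3)
  rp <- rpart::rpart(y ~ ., data = cbind(X, y = y),
                     control = rpart::rpart.control(
                       minsplit = 10, minbucket = 5, cp = 0,
                       maxdepth = 1, xval = 0))
  expect_equal(tree$root$feature,
               as.character(rp$frame$var[1]))
  expect_equal(tree$root$threshold,
               unname(rp$splits[1, "index"]), tolerance = 1e-8)
})
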