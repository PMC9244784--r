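#' Impute missing feature values
#'
#' Numeric columns are filled with the (training) median, categorical
#' columns with the (training) mode; statistics can be reused so test
#' folds are imputed from training-split values only. Columns that are
#' entirely missing are dropped with a warning. Never changes the number
#' of rows.
#'
#' @param X Feature data frame.
#' @param stats Optional imputation statistics from a previous call.
#' @return List: `X` (imputed), `stats`.
#' @export
impute_features <- function(X, stats = NULL) {
  X <- as.data.frame(X, stringsAsFactors = FALSE)
  if (is.null(stats)) {
    stats <- list()
    drop <- character(0)
    for (cl in names(X)) {
      v <- X[[cl]]
      if (all(is.na(v))) {
        drop <- c(drop, cl)
        next
      }
      stats[[cl]] <- if (is.numeric(v)) {
        stats::median(v, na.rm = TRUE)
      } else {
        tt <- sort(table(v), decreasing = TRUE)
        names(tt)[1]
      }
    }
    if (length(drop) > 0L) {
      warning("dropping all-missing feature(s): ",
              paste(drop, collapse = ", "), call. = FALSE)
      X <- X[setdiff(names(X), drop)]
    }
  } else {
    X <- X[intersect(names(X), names(stats))]
  }
  for (cl in names(X)) {
    v <- X[[cl]]
    v[is.na(v)] <- stats[[cl]]
    X[[cl]] <- v
  }
  list(X = X, stats = stats)
}

node_sse <- function(y) sum((y - mean(y))^2)

# Best split of one numeric feature by exhaustive midpoint scan using
# prefix sums; ties resolved toward the lowest threshold (strict-gain scan
# in ascending order).
best_split_numeric <- function(x, y, min_leaf) {
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]
  n <- length(ys)
  cs <- cumsum(ys)
  cq <- cumsum(ys^2)
  tot_s <- cs[n]
  tot_q <- cq[n]
  ks <- which(xs[-n] < xs[-1])
  ks <- ks[ks >= min_leaf & (n - ks) >= min_leaf]
  if (length(ks) == 0L) return(NULL)
  sse_l <- cq[ks] - cs[ks]^2 / ks
  sse_r <- (tot_q - cq[ks]) - (tot_s - cs[ks])^2 / (n - ks)
  sse_parent <- tot_q - tot_s^2 / n
  gains <- sse_parent - (sse_l + sse_r)
  best <- which.max(gains)  # first maximum -> lowest threshold on ties
  list(gain = gains[best],
       threshold = (xs[ks[best]] + xs[ks[best] + 1]) / 2)
}

# Categorical split: categories ordered by mean response, then scanned as
# an ordered variable (optimal for squared-error regression).
best_split_categorical <- function(x, y, min_leaf) {
  x <- as.character(x)
  mu <- tapply(y, x, mean)
  lev <- names(sort(mu))
  if (length(lev) < 2L) return(NULL)
  xr <- match(x, lev)
  sp <- best_split_numeric(as.numeric(xr), y, min_leaf)
  if (is.null(sp)) return(NULL)
  list(gain = sp$gain, categories = lev[seq_len(floor(sp$threshold))])
}

grow_node <- function(X, y, min_leaf, max_depth, depth, n_root) {
  n <- length(y)
  risk <- node_sse(y) / n_root
  node <- list(
    is_leaf = TRUE, prediction = mean(y), n_node = n, risk = risk
  )
  if (depth >= max_depth || n < 2L * min_leaf || node_sse(y) < 1e-12) {
    return(node)
  }
  best <- NULL
  for (j in seq_along(X)) {
    v <- X[[j]]
    sp <- if (is.numeric(v)) {
      best_split_numeric(v, y, min_leaf)
    } else {
      best_split_categorical(v, y, min_leaf)
    }
    if (!is.null(sp) && sp$gain > 1e-12 &&
        (is.null(best) || sp$gain > best$gain)) {
      best <- sp
      best$feature <- names(X)[j]
      best$j <- j
    }
  }
  if (is.null(best)) return(node)
  v <- X[[best$j]]
  go_left <- if (is.numeric(v)) v <= best$threshold else
    as.character(v) %in% best$categories
  node$is_leaf <- FALSE
  node$feature <- best$feature
  node$threshold <- if (is.numeric(v)) best$threshold else NA_real_
  node$categories <- if (is.numeric(v)) NULL else best$categories
  if (!is.numeric(v)) {
    node$right_categories <- setdiff(unique(as.character(v)),
                                     best$categories)
  }
  node$gain_risk <- best$gain / n_root
  node$left <- grow_node(X[go_left, , drop = FALSE], y[go_left],
                         min_leaf, max_depth, depth + 1L, n_root)
  node$right <- grow_node(X[!go_left, , drop = FALSE], y[!go_left],
                          min_leaf, max_depth, depth + 1L, n_root)
  node
}

#' Grow a regression tree by greedy variance reduction
#'
#' CART-style binary splitting minimizing node risk (mean squared error
#' weighted by node fraction). Numeric splits are placed at midpoints
#' between sorted distinct values; categorical features (including a
#' high-cardinality study identifier) are split by response-ordered
#' partitioning. Splitting stops at `min_leaf`, `max_depth` or zero gain.
#' Ties are broken deterministically toward the lowest feature index, then
#' the lowest threshold. Missing feature values are imputed by the
#' training median/mode.
#'
#' @param X Feature data frame (numeric and/or categorical columns).
#' @param y Numeric response.
#' @param min_leaf Minimum observations per leaf (default 5).
#' @param max_depth Maximum depth (default 12).
#' @return A list of class `ws_tree` with the root node, feature names,
#'   imputation statistics and `n` (training size).
#' @export
grow_tree <- function(X, y, min_leaf = 5L, max_depth = 12L) {
  stopifnot(is.numeric(y), nrow(as.data.frame(X)) == length(y))
  imp <- impute_features(X)
  X <- imp$X
  n <- length(y)
  if (n < 2L * min_leaf && stats::var(y) > 0) {
    # still legal: the root simply stays a leaf
  }
  root <- grow_node(X, y, as.integer(min_leaf), as.integer(max_depth),
                    0L, n)
  structure(list(root = root, features = names(X),
                 impute_stats = imp$stats, n = n,
                 min_leaf = as.integer(min_leaf),
                 max_depth = as.integer(max_depth)),
            class = "ws_tree")
}

predict_node <- function(node, X, idx, out) {
  if (node$is_leaf || length(idx) == 0L) {
    out[idx] <- node$prediction
    return(out)
  }
  v <- X[[node$feature]][idx]
  go_left <- if (!is.null(node$categories)) {
    as.character(v) %in% node$categories
  } else {
    v <= node$threshold
  }
  # unseen categories: route toward the larger training child (tie: left)
  if (!is.null(node$categories)) {
    unseen <- !(as.character(v) %in%
                  c(node$categories, node$right_categories))
    go_left[unseen] <- node$left$n_node >= node$right$n_node
  }
  out <- predict_node(node$left, X, idx[go_left], out)
  predict_node(node$right, X, idx[!go_left], out)
}

#' Predict from a grown regression tree
#' @param object A `ws_tree`.
#' @param newdata Feature data frame.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.ws_tree <- function(object, newdata, ...) {
  imp <- impute_features(newdata, stats = object$impute_stats)
  X <- imp$X
  predict_node(object$root, X, seq_len(nrow(X)),
               numeric(nrow(X)))
}

#' Seeded k-fold cross-validation of the regression tree
#'
#' Randomly divides the data into `k` subsets of similar size (fold sizes
#' differ by at most one; every observation is tested exactly once), grows
#' a tree on each training portion (imputation statistics from the
#' training split only) and evaluates squared error on the held-out fold.
#'
#' @param X Feature data frame.
#' @param y Numeric response.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param min_leaf,max_depth Tree hyperparameters.
#' @return List: `fold_mse` (length `k`), `mse` (mean over folds),
#'   `folds` (assignment vector).
#' @export
cross_validate <- function(X, y, k = 10L, seed = 1L, min_leaf = 5L,
                           max_depth = 12L) {
  n <- length(y)
  if (k > n) stop("k (", k, ") exceeds number of observations (", n, ")",
                  call. = FALSE)
  set.seed(seed)
  folds <- sample(rep(seq_len(k), length.out = n))
  X <- as.data.frame(X, stringsAsFactors = FALSE)
  fold_mse <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    tree <- grow_tree(X[tr, , drop = FALSE], y[tr],
                      min_leaf = min_leaf, max_depth = max_depth)
    pred <- predict(tree, X[!tr, , drop = FALSE])
    mean((y[!tr] - pred)^2)
  }, numeric(1))
  list(fold_mse = fold_mse, mse = mean(fold_mse), folds = folds)
}

count_branch_nodes <- function(node) {
  if (node$is_leaf) return(0L)
  1L + count_branch_nodes(node$left) + count_branch_nodes(node$right)
}

accumulate_importance <- function(node, acc) {
  if (node$is_leaf) return(acc)
  acc[node$feature] <- acc[node$feature] +
    (node$risk - node$left$risk - node$right$risk)
  acc <- accumulate_importance(node$left, acc)
  accumulate_importance(node$right, acc)
}

#' Risk-change predictor importance ranking
#'
#' Importance of a feature is the sum over its splits of the change in
#' risk (parent risk minus the two child risks) divided by the number of
#' branch nodes in the tree. Unused features score 0. Ties are broken by
#' feature order.
#'
#' @param tree A `ws_tree`.
#' @return Tibble (`feature`, `importance`, `rank`) sorted by decreasing
#'   importance, with attributes `top15` and `bottom5`.
#' @export
rank_features <- function(tree) {
  stopifnot(inherits(tree, "ws_tree"))
  acc <- stats::setNames(rep(0, length(tree$features)), tree$features)
  acc <- accumulate_importance(tree$root, acc)
  nb <- count_branch_nodes(tree$root)
  imp <- if (nb > 0L) acc / nb else acc
  ord <- order(-imp, seq_along(imp))
  out <- tibble::tibble(
    feature = names(imp)[ord],
    importance = unname(imp[ord]),
    rank = seq_along(imp)
  )
  attr(out, "top15") <- utils::head(out, 15L)
  attr(out, "bottom5") <- utils::tail(out, 5L)
  attr(out, "n_branch_nodes") <- nb
  out
}

tree_to_list <- function(node) {
  if (node$is_leaf) {
    return(list(leaf = TRUE, prediction = node$prediction,
                n = node$n_node, risk = node$risk))
  }
  list(leaf = FALSE, feature = node$feature,
       threshold = node$threshold, categories = node$categories,
       n = node$n_node, risk = node$risk, gain_risk = node$gain_risk,
       left = tree_to_list(node$left), right = tree_to_list(node$right))
}

#' Serialize a regression tree to JSON
#' @param tree A `ws_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(tree, path) {
  jsonlite::write_json(tree_to_list(tree$root), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
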