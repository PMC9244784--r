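#' Define a recursive path-model specification
#'
#' A path specification is a directed acyclic edge list over observed
#' variables. Variables that are never a target are exogenous; every edge
#' target is endogenous.
#'
#' @param edges Two-column data frame (`from`, `to`) of directed edges.
#' @return A list of class `ws_path_spec` with `edges`, `variables`
#'   (topologically ordered), `exogenous`, `endogenous`.
#' @export
path_spec <- function(edges) {
  edges <- as.data.frame(edges)
  stopifnot(all(c("from", "to") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  vars <- unique(c(edges$from, edges$to))
  # Kahn topological sort; failure means a cycle
  remaining <- edges
  order <- character(0)
  pool <- vars
  while (length(pool) > 0L) {
    sinks_in <- unique(remaining$to)
    sources <- setdiff(pool, sinks_in)
    if (length(sources) == 0L) {
      stop("path specification error: edge graph contains a cycle",
           call. = FALSE)
    }
    order <- c(order, sources)
    pool <- setdiff(pool, sources)
    remaining <- remaining[!(remaining$from %in% sources), , drop = FALSE]
  }
  endo <- unique(edges$to)
  structure(list(
    edges = edges,
    variables = order,
    exogenous = setdiff(vars, endo),
    endogenous = order[order %in% endo]
  ), class = "ws_path_spec")
}

#' Read a path specification from a YAML or JSON edge list
#'
#' The file holds a list of `from`/`to` pairs (or a two-column table).
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A `ws_path_spec`.
#' @export
read_path_spec <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  }
  if (!is.data.frame(raw)) raw <- dplyr::bind_rows(lapply(raw, tibble::as_tibble))
  path_spec(raw)
}

#' Default a-priori path specification for the wheat synthesis
#'
#' Climate (MAT), initial soil nutrients (SOC, AK, AP) and management
#' (water, N input) act on the yield response ratio; yield response feeds
#' the WP response, and both feed the NUE response.
#'
#' @param predictors Exogenous variable names.
#' @param responses The three response-ratio variables, in causal order.
#' @return A `ws_path_spec`.
#' @export
default_path_spec <- function(
    predictors = c("mat", "soc", "ak", "ap", "water_mm", "n_kg_ha"),
    responses = c("rr_y", "rr_wp", "rr_nue")) {
  ij <- which(upper.tri(diag(length(responses))), arr.ind = TRUE)
  edges <- rbind(
    expand.grid(from = predictors, to = responses,
                stringsAsFactors = FALSE),
    data.frame(from = responses[ij[, "row"]], to = responses[ij[, "col"]])
  )
  path_spec(edges)
}

#' Fit a recursive path model by equation-wise standardized OLS
#'
#' All variables are standardized to zero mean and unit variance; for a
#' recursive model with uncorrelated errors, each endogenous variable's
#' path coefficients are exactly its standardized multiple-regression
#' coefficients on its parents (the maximum-likelihood solution for this
#' model class). The model-implied covariance is assembled from the path
#' coefficients and residual variances, and the overall fit statistic is
#' chi-square = (n - 1) * F_ML against the observed correlations.
#'
#' @param data Data frame containing the spec variables (complete cases
#'   are used; an error is raised if too few remain).
#' @param spec A [path_spec()].
#' @return A list of class `ws_path_fit`: `coefficients` tibble
#'   (`from`, `to`, `coef`), `r2` (named, per endogenous variable),
#'   `resid_var`, `chi_square`, `df`, `p_model`, `n`, `converged`, plus the
#'   `B` matrix and observed/implied correlation matrices.
#' @export
fit_path <- function(data, spec) {
  stopifnot(inherits(spec, "ws_path_spec"))
  vars <- spec$variables
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars) > 0L) {
    stop("data lacks path variable(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  dd <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  n <- nrow(dd)
  p <- length(vars)
  if (n <= p) {
    stop("insufficient data: ", n, " complete cases for ", p,
         " variables", call. = FALSE)
  }
  Z <- scale(as.matrix(dd))
  S <- stats::cor(as.matrix(dd))
  B <- matrix(0, p, p, dimnames = list(vars, vars))
  psi <- stats::setNames(rep(1, p), vars)
  r2 <- stats::setNames(rep(NA_real_, length(spec$endogenous)),
                        spec$endogenous)
  coefs <- list()
  for (v in spec$endogenous) {
    parents <- spec$edges$from[spec$edges$to == v]
    Rpp <- S[parents, parents, drop = FALSE]
    rpy <- S[parents, v]
    ok <- tryCatch({
      beta <- solve(Rpp, rpy)
      TRUE
    }, error = function(e) FALSE)
    if (!ok || kappa(Rpp) > 1e10) {
      stop("collinearity error among parents of ", v, ": ",
           paste(parents, collapse = ", "), call. = FALSE)
    }
    beta <- drop(solve(Rpp, rpy))
    B[v, parents] <- beta
    r2[v] <- sum(beta * rpy)
    psi[v] <- 1 - r2[v]
    coefs[[v]] <- tibble::tibble(from = parents, to = v,
                                 coef = unname(beta))
  }
  # exogenous block keeps its observed correlations
  Psi <- diag(psi)
  dimnames(Psi) <- list(vars, vars)
  ex <- spec$exogenous
  Psi[ex, ex] <- S[ex, ex]
  IB <- solve(diag(p) - B)
  Sigma <- IB %*% Psi %*% t(IB)
  dimnames(Sigma) <- list(vars, vars)
  f_ml <- as.numeric(
    determinant(Sigma, logarithm = TRUE)$modulus +
      sum(diag(S %*% solve(Sigma))) -
      determinant(S, logarithm = TRUE)$modulus - p
  )
  f_ml <- max(f_ml, 0)
  q <- length(ex)
  n_free <- nrow(spec$edges) + length(spec$endogenous) + q * (q + 1) / 2
  df <- p * (p + 1) / 2 - n_free
  chi_square <- (n - 1) * f_ml
  structure(list(
    coefficients = dplyr::bind_rows(coefs),
    r2 = r2,
    resid_var = psi[spec$endogenous],
    chi_square = chi_square,
    df = df,
    p_model = if (df > 0) stats::pchisq(chi_square, df,
                                        lower.tail = FALSE) else NA_real_,
    n = n,
    converged = TRUE,
    B = B,
    observed = S,
    implied = Sigma,
    spec = spec
  ), class = "ws_path_fit")
}

#' @export
print.ws_path_fit <- function(x, ...) {
  cat(sprintf("<ws_path_fit> n = %d, chi-square = %.4f (df = %d%s)\n",
              x$n, x$chi_square, x$df,
              if (x$df > 0) sprintf(", p = %.3f", x$p_model) else ""))
  print(x$coefficients)
  invisible(x)
}

#' Direct, indirect and total effects in a fitted path model
#'
#' The indirect effect is the sum over all directed paths of length two or
#' more from `source` to `target` of the product of edge coefficients; the
#' total effect adds the direct edge (if any). Computed from the coefficient
#' matrix via (I - B)^{-1} = I + B + B^2 + ...
#'
#' @param fit A `ws_path_fit`.
#' @param source,target Variable names.
#' @return Named list: `direct`, `indirect`, `total`.
#' @export
indirect_effects <- function(fit, source, target) {
  stopifnot(inherits(fit, "ws_path_fit"), fit$converged)
  vars <- fit$spec$variables
  stopifnot(source %in% vars, target %in% vars)
  B <- fit$B
  total_mat <- solve(diag(length(vars)) - B) - diag(length(vars))
  dimnames(total_mat) <- dimnames(B)
  total <- total_mat[target, source]
  direct <- B[target, source]
  list(direct = direct, indirect = total - direct, total = total)
}

#' Path models per input-level stratum
#'
#' Fits the path model separately within the below-optimal water (W-),
#' above-optimal water (W+) and below-optimal N (N-) strata. The
#' above-optimal N stratum (N+) is reported as non-converged by design:
#' data paucity at above-optimal N rates does not support a stable model,
#' so a placeholder with `converged = FALSE` is returned instead of a
#' forced fit.
#'
#' @param dataset A [ws_dataset()].
#' @param optima Per-region optima from [find_optima_all()].
#' @param spec A [path_spec()]; default [default_path_spec()].
#' @return Named list of `ws_path_fit` objects (element `N_plus` is a
#'   non-converged placeholder).
#' @export
path_analysis <- function(dataset, optima, spec = default_path_spec()) {
  lv <- classify(dataset, optima)
  eff_y <- compute_rr(dataset, "yield")
  eff_wp <- compute_rr(dataset, "wp")
  eff_nue <- compute_rr(dataset, "nue")
  dd <- tibble::tibble(
    obs_id = dataset$obs_id,
    mat = dataset$mat, soc = dataset$soc, ak = dataset$ak,
    ap = dataset$ap,
    water_mm = dataset$water_mm, n_kg_ha = dataset$n_kg_ha,
    rr_y = eff_y$rr[match(dataset$obs_id, eff_y$obs_id)],
    rr_wp = eff_wp$rr[match(dataset$obs_id, eff_wp$obs_id)],
    rr_nue = eff_nue$rr[match(dataset$obs_id, eff_nue$obs_id)]
  )
  strata <- list(
    W_minus = lv$water_level == "W_minus",
    W_plus = lv$water_level == "W_plus",
    N_minus = lv$n_level == "N_minus"
  )
  placeholder <- function(n, note) structure(list(
    coefficients = tibble::tibble(from = character(0), to = character(0),
                                  coef = numeric(0)),
    r2 = NULL, resid_var = NULL, chi_square = NA_real_, df = NA_integer_,
    p_model = NA_real_, n = n, converged = FALSE, note = note,
    B = NULL, observed = NULL, implied = NULL, spec = spec
  ), class = "ws_path_fit")
  fits <- lapply(names(strata), function(s) {
    sub <- dd[strata[[s]], , drop = FALSE]
    tryCatch(fit_path(sub, spec),
             error = function(e) placeholder(nrow(sub),
                                             conditionMessage(e)))
  })
  names(fits) <- names(strata)
  fits$N_plus <- placeholder(sum(lv$n_level == "N_plus"),
                             "not fitted by design (data paucity)")
  fits
}
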