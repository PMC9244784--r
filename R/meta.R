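#' Log response ratios for a paired-observation dataset
#'
#' Computes the per-pair log response ratio rr = ln(treatment) - ln(control)
#' for the requested outcome, with the replicate-based weight
#' w = (rep_t * rep_c) / (rep_t + rep_c) (falling back to 1 where replicate
#' counts are missing). Water productivity uses directly extracted `wp_t` /
#' `wp_c` where present, else yield / (10 * ET); N use efficiency requires
#' directly extracted `nue_t` / `nue_c` (an unfertilized control has no
#' defined yield-per-kg-N). Pairs that cannot be computed are excluded with
#' a reason, never silently dropped.
#'
#' @param dataset A [ws_dataset()].
#' @param outcome One of `"yield"`, `"wp"`, `"nue"`.
#' @return A tibble of effect sizes (`obs_id`, `study_id`, `region`,
#'   `outcome`, `rr`, `weight`) with an `excluded` attribute: a tibble of
#'   (`obs_id`, `reason`) for pairs that were dropped.
#' @export
compute_rr <- function(dataset, outcome = c("yield", "wp", "nue")) {
  outcome <- match.arg(outcome)
  get0c <- function(nm) {
    if (nm %in% names(dataset)) dataset[[nm]] else rep(NA_real_, nrow(dataset))
  }
  tv <- switch(outcome,
    yield = dataset$y_t,
    wp = {
      v <- get0c("wp_t")
      et <- get0c("et_t")
      ifelse(is.na(v) & !is.na(et) & et > 0,
             water_productivity_safe(dataset$y_t, et), v)
    },
    nue = get0c("nue_t")
  )
  cv <- switch(outcome,
    yield = dataset$y_c,
    wp = {
      v <- get0c("wp_c")
      et <- get0c("et_c")
      ifelse(is.na(v) & !is.na(et) & et > 0,
             water_productivity_safe(dataset$y_c, et), v)
    },
    nue = get0c("nue_c")
  )
  reason <- rep(NA_character_, nrow(dataset))
  reason[is.na(tv)] <- "missing treatment value"
  reason[is.na(reason) & is.na(cv)] <- "missing control value"
  reason[is.na(reason) & (tv <= 0 | cv <= 0)] <- "nonpositive value"
  keep <- is.na(reason)

  rep_t <- get0c("rep_t")
  rep_c <- get0c("rep_c")
  weight <- ifelse(!is.na(rep_t) & !is.na(rep_c) & rep_t > 0 & rep_c > 0,
                   rep_t * rep_c / (rep_t + rep_c), 1)

  eff <- tibble::tibble(
    obs_id = dataset$obs_id[keep],
    study_id = dataset$study_id[keep],
    region = dataset$region[keep],
    outcome = outcome,
    rr = log(tv[keep]) - log(cv[keep]),
    weight = weight[keep]
  )
  attr(eff, "excluded") <- tibble::tibble(
    obs_id = dataset$obs_id[!keep], reason = reason[!keep]
  )
  eff
}

water_productivity_safe <- function(y, et) {
  ifelse(!is.na(et) & et > 0, y / (10 * et), NA_real_)
}

# ---- REML machinery ------------------------------------------------------
#
# Model: rr_ij = mu + u_i + e_ij, u_i ~ N(0, tau2), e_ij ~ N(0, sigma2/w_ij),
# studies i, observations j. With lambda = tau2/sigma2 the per-study
# sufficient statistics S_i = sum w, T_i = sum w*rr, Q_i = sum w*rr^2 give
# (Woodbury):
#   A(l)  = sum S_i/(1+l S_i)         ~ X'V^{-1}X * sigma2
#   B(l)  = sum T_i/(1+l S_i)         ~ X'V^{-1}y * sigma2
#   R(l)  = sum (Q_i - l T_i^2/(1+l S_i)) - B^2/A   ~ y'Py * sigma2
# and the restricted -2 log-likelihood, with sigma2 profiled out in closed
# form (sigma2_hat = R/(N-1)), reduces to the 1-D criterion
#   f(l) = (N-1) log R(l) + sum log(1+l S_i) + log A(l).
# f is minimized over l >= 0 by safeguarded bisection on its numerical
# derivative. All functions below are vectorized across replicates (rows)
# so the cluster bootstrap refits in bulk.

reml_profile_crit <- function(lambda, S, T_, Q, N) {
  denom <- 1 + lambda * S
  A <- rowSums(S / denom)
  B <- rowSums(T_ / denom)
  Rq <- rowSums(Q - lambda * T_^2 / denom) - B^2 / A
  Rq <- pmax(Rq, 1e-300)
  (N - 1) * log(Rq) + rowSums(log(denom)) + log(A)
}

reml_solve_lambda <- function(S, T_, Q, N, lambda_hi = 1e6, iters = 60L) {
  nrep <- nrow(S)
  grad <- function(lam) {
    h <- 1e-6 * (lam + 1e-3)
    (reml_profile_crit(lam + h, S, T_, Q, N) -
       reml_profile_crit(pmax(lam - h, 0), S, T_, Q, N)) / (2 * h)
  }
  lo <- rep(0, nrep)
  hi <- rep(lambda_hi, nrep)
  at_zero <- grad(lo) >= 0          # criterion already increasing at 0
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    g <- grad(mid)
    up <- g < 0
    lo <- ifelse(up, mid, lo)
    hi <- ifelse(up, hi, mid)
  }
  lam <- (lo + hi) / 2
  lam[at_zero] <- 0
  lam
}

reml_study_stats <- function(rr, weight, study_id) {
  f <- factor(study_id, levels = unique(study_id))
  list(
    S = as.numeric(tapply(weight, f, sum)),
    T_ = as.numeric(tapply(weight * rr, f, sum)),
    Q = as.numeric(tapply(weight * rr^2, f, sum)),
    n = as.numeric(tapply(rr, f, length)),
    study = levels(f)
  )
}

# Fit from per-replicate stat matrices; returns mu, tau2, sigma2, se rows.
reml_fit_stats <- function(S, T_, Q, n) {
  N <- rowSums(n)
  m <- rowSums(!is.na(S) & S > -Inf) # ncol unless padded; S always finite
  lam <- reml_solve_lambda(S, T_, Q, N)
  one_study <- rowSums(S > 0) == 1L
  lam[one_study] <- 0
  denom <- 1 + lam * S
  A <- rowSums(S / denom)
  B <- rowSums(T_ / denom)
  Rq <- rowSums(Q - lam * T_^2 / denom) - B^2 / A
  sigma2 <- pmax(Rq, 0) / pmax(N - 1, 1)
  degenerate <- sigma2 < 1e-14
  lam[degenerate] <- 0
  tau2 <- lam * sigma2
  mu <- B / A
  # recompute A at final lambda for the SE
  denom <- 1 + lam * S
  A <- rowSums(S / denom)
  se <- sqrt(sigma2 / A)
  list(mu = mu, tau2 = tau2, sigma2 = sigma2, se = se, N = N)
}

#' Pool effect sizes by restricted maximum likelihood
#'
#' Fits the study-level random-effects model
#' rr_ij = mu + u_study(i) + e_ij with Var(u) = tau2 and
#' Var(e_ij) = sigma2 / w_ij by REML: sigma2 is profiled out in closed form
#' and the remaining one-dimensional restricted likelihood in
#' tau2/sigma2 is maximized by safeguarded bisection on its derivative
#' (tau2 projected to >= 0). The pooled estimate is the generalized
#' least-squares mean under the fitted variances.
#'
#' @param effects A tibble with columns `rr`, `weight`, `study_id` (as
#'   produced by [compute_rr()] or [simulate_effects()]).
#' @param subgroup Optional label stored on the result.
#' @param tau2_fixed Constrain the between-study variance instead of
#'   estimating it; only `0` is supported (the fixed-effect solution: the
#'   pooled estimate becomes the inverse-variance weighted mean).
#' @return A one-row tibble: `subgroup`, `n_obs`, `n_studies`, `pooled_rr`,
#'   `se`, `tau2`, `sigma2`, `ci_low`, `ci_high` (Wald), `percent_change`
#'   (= (exp(pooled_rr) - 1) * 100), `converged`.
#' @export
fit_reml <- function(effects, subgroup = "overall", tau2_fixed = NULL) {
  stopifnot(all(c("rr", "weight", "study_id") %in% names(effects)))
  if (nrow(effects) < 2L) {
    stop("insufficient data: need at least 2 effect sizes, got ",
         nrow(effects), call. = FALSE)
  }
  if (any(!is.finite(effects$rr))) {
    stop("non-finite effect sizes present", call. = FALSE)
  }
  if (any(effects$weight <= 0)) {
    stop("weights must be positive", call. = FALSE)
  }
  st <- reml_study_stats(effects$rr, effects$weight, effects$study_id)
  if (!is.null(tau2_fixed)) {
    if (tau2_fixed != 0) {
      stop("only tau2_fixed = 0 (fixed-effect model) is supported",
           call. = FALSE)
    }
    w <- effects$weight
    mu <- sum(w * effects$rr) / sum(w)
    sigma2 <- sum(w * (effects$rr - mu)^2) / (nrow(effects) - 1)
    se <- sqrt(sigma2 / sum(w))
    return(tibble::tibble(
      subgroup = subgroup, n_obs = nrow(effects),
      n_studies = length(st$study), pooled_rr = mu, se = se,
      tau2 = 0, sigma2 = sigma2,
      ci_low = mu - stats::qnorm(0.975) * se,
      ci_high = mu + stats::qnorm(0.975) * se,
      percent_change = (exp(mu) - 1) * 100, converged = TRUE
    ))
  }
  fit <- reml_fit_stats(matrix(st$S, 1), matrix(st$T_, 1),
                        matrix(st$Q, 1), matrix(st$n, 1))
  pooled <- fit$mu[1]
  se <- fit$se[1]
  tibble::tibble(
    subgroup = subgroup,
    n_obs = nrow(effects),
    n_studies = length(st$study),
    pooled_rr = pooled,
    se = se,
    tau2 = fit$tau2[1],
    sigma2 = fit$sigma2[1],
    ci_low = pooled - stats::qnorm(0.975) * se,
    ci_high = pooled + stats::qnorm(0.975) * se,
    percent_change = (exp(pooled) - 1) * 100,
    converged = TRUE
  )
}

#' Cluster-bootstrap bias-corrected confidence interval for the pooled effect
#'
#' Resamples studies (clusters) with replacement, refits the REML pooling
#' model on each resample, and returns the bias-corrected (BC) percentile
#' 95% interval. Observation-level resampling is available behind
#' `cluster = FALSE`. Reproducible from `seed`.
#'
#' @param effects Effect-size tibble (`rr`, `weight`, `study_id`).
#' @param n_iter Number of bootstrap iterations (default 4999).
#' @param seed Integer seed.
#' @param level Coverage level (default 0.95).
#' @param cluster Resample studies (`TRUE`, default) or observations.
#' @return A list: `ci_low`, `ci_high`, `pooled_rr`, `method`
#'   (`"bc"` or `"percentile"`), `boot` (the replicate pooled estimates).
#' @export
bootstrap_ci <- function(effects, n_iter = 4999L, seed = 1L, level = 0.95,
                         cluster = TRUE) {
  point <- fit_reml(effects)$pooled_rr
  set.seed(seed)
  st <- reml_study_stats(effects$rr, effects$weight, effects$study_id)
  m <- length(st$study)
  if (cluster && m >= 2L) {
    M <- matrix(sample.int(m, n_iter * m, replace = TRUE), nrow = n_iter)
    fit <- reml_fit_stats(
      matrix(st$S[M], nrow = n_iter), matrix(st$T_[M], nrow = n_iter),
      matrix(st$Q[M], nrow = n_iter), matrix(st$n[M], nrow = n_iter)
    )
    boot <- fit$mu
  } else {
    n <- nrow(effects)
    boot <- vapply(seq_len(n_iter), function(b) {
      ii <- sample.int(n, n, replace = TRUE)
      st_b <- reml_study_stats(effects$rr[ii], effects$weight[ii],
                               paste0(effects$study_id[ii], "#", ii))
      reml_fit_stats(matrix(st_b$S, 1), matrix(st_b$T_, 1),
                     matrix(st_b$Q, 1), matrix(st_b$n, 1))$mu[1]
    }, numeric(1))
  }
  boot <- boot[is.finite(boot)]
  alpha <- (1 - level) / 2
  if (length(unique(boot)) == 1L) {
    return(list(ci_low = boot[1], ci_high = boot[1], pooled_rr = point,
                method = "degenerate", boot = boot))
  }
  prop_below <- mean(boot < point)
  if (prop_below <= 0 || prop_below >= 1) {
    warning("bias correction degenerate; falling back to plain percentile",
            call. = FALSE)
    qq <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE)
    return(list(ci_low = qq[1], ci_high = qq[2], pooled_rr = point,
                method = "percentile", boot = boot))
  }
  z0 <- stats::qnorm(prop_below)
  p_lo <- stats::pnorm(2 * z0 + stats::qnorm(alpha))
  p_hi <- stats::pnorm(2 * z0 + stats::qnorm(1 - alpha))
  qq <- stats::quantile(boot, c(p_lo, p_hi), names = FALSE)
  list(ci_low = qq[1], ci_high = qq[2], pooled_rr = point, method = "bc",
       boot = boot)
}

#' Subgroup meta-analysis summaries
#'
#' Pools effect sizes overall, by region, or by water/N input level
#' (above/below the regional optimum). Subgroups with fewer than
#' `min_effects` effect sizes are reported as not estimable rather than
#' fitted.
#'
#' @param dataset A [ws_dataset()].
#' @param outcome `"yield"`, `"wp"` or `"nue"`.
#' @param grouping `"overall"`, `"region"`, `"water_level"` or `"n_level"`.
#' @param optima Optional precomputed per-region optima
#'   (see [find_optima_all()]); computed from `dataset` when needed.
#' @param min_effects Minimum effect sizes for a subgroup to be estimated.
#' @param boot_iter Bootstrap iterations for the confidence interval; 0
#'   (default) reports the Wald interval from [fit_reml()].
#' @param seed Seed for the bootstrap.
#' @return A tibble with one row per subgroup (`estimable = FALSE` rows
#'   carry `NA` estimates).
#' @export
subgroup_summary <- function(dataset, outcome = "yield",
                             grouping = c("overall", "region",
                                          "water_level", "n_level"),
                             optima = NULL, min_effects = 3L,
                             boot_iter = 0L, seed = 1L) {
  grouping <- match.arg(grouping)
  eff <- compute_rr(dataset, outcome)
  if (grouping %in% c("water_level", "n_level")) {
    if (is.null(optima)) optima <- find_optima_all(dataset)
    lv <- classify(dataset, optima)
    eff$water_level <- lv$water_level[match(eff$obs_id, dataset$obs_id)]
    eff$n_level <- lv$n_level[match(eff$obs_id, dataset$obs_id)]
  }
  labels <- switch(grouping,
    overall = rep("overall", nrow(eff)),
    region = eff$region,
    water_level = eff$water_level,
    n_level = eff$n_level
  )
  out <- lapply(split(seq_len(nrow(eff)), labels), function(ii) {
    sub <- eff[ii, , drop = FALSE]
    lab <- labels[ii[1]]
    if (nrow(sub) < max(min_effects, 2L) ||
        length(unique(sub$study_id)) < 1L) {
      return(tibble::tibble(
        subgroup = lab, n_obs = nrow(sub), n_studies =
          length(unique(sub$study_id)),
        pooled_rr = NA_real_, se = NA_real_, tau2 = NA_real_,
        sigma2 = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        percent_change = NA_real_, converged = NA, estimable = FALSE
      ))
    }
    res <- fit_reml(sub, subgroup = lab)
    if (boot_iter > 0L) {
      ci <- bootstrap_ci(sub, n_iter = boot_iter, seed = seed)
      res$ci_low <- ci$ci_low
      res$ci_high <- ci$ci_high
    }
    res$estimable <- TRUE
    res
  })
  dplyr::bind_rows(out)
}
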