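# Small fixture builders used across test files.

tiny_obs <- function(n = 3, region = "North", study_id = "S001",
                     water = 300, nrate = 180, y_t = 6000, y_c = 4500) {
  tibble::tibble(
    study_id = rep_len(study_id, n),
    region = rep_len(region, n),
    water_mm = rep_len(water, n),
    n_kg_ha = rep_len(nrate, n),
    y_t = rep_len(y_t, n),
    y_c = rep_len(y_c, n)
  )
}

noise_free_config <- function(seed = 11, n_studies = 40L) {
  generator_config(
    n_studies = n_studies,
    tau2_study = 0, sigma2_resid = 0,
    soil_effect = c(soc = 0, ap = 0, ak = 0),
    missing_rates = c(et = 0, nue = 0, soc = 0, an = 0, ap = 0, ak = 0,
                      mat = 0, map_mm = 0),
    seed = seed
  )
}

# Independent REML oracle: builds the full marginal covariance matrix per
# candidate (tau2, sigma2) and evaluates the textbook restricted
# log-likelihood; maximized by nested grid refinement. Deliberately naive.
reml_oracle_grid <- function(rr, weight, study_id,
                             tau2_range = c(0, 0.5),
                             sigma2_range = c(1e-4, 0.5),
                             levels = 4, pts = 21) {
  n <- length(rr)
  X <- matrix(1, n, 1)
  studies <- unique(study_id)
  Zmat <- outer(study_id, studies, "==") * 1
  restricted_ll <- function(tau2, sigma2) {
    V <- tau2 * (Zmat %*% t(Zmat)) + diag(sigma2 / weight)
    Vi <- solve(V)
    XtVi <- t(X) %*% Vi
    A <- XtVi %*% X
    beta <- solve(A, XtVi %*% rr)
    r <- rr - X %*% beta
    -0.5 * (determinant(V, logarithm = TRUE)$modulus +
              determinant(A, logarithm = TRUE)$modulus +
              t(r) %*% Vi %*% r)[1]
  }
  t_rng <- tau2_range
  s_rng <- sigma2_range
  best <- c(NA, NA)
  for (lv in seq_len(levels)) {
    tg <- seq(t_rng[1], t_rng[2], length.out = pts)
    sg <- seq(s_rng[1], s_rng[2], length.out = pts)
    ll <- outer(tg, sg, Vectorize(restricted_ll))
    ij <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    best <- c(tg[ij[1]], sg[ij[2]])
    t_step <- diff(t_rng) / (pts - 1)
    s_step <- diff(s_rng) / (pts - 1)
    t_rng <- c(max(0, best[1] - t_step), best[1] + t_step)
    s_rng <- c(max(1e-6, best[2] - s_step), best[2] + s_step)
  }
  list(tau2 = best[1], sigma2 = best[2])
}
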