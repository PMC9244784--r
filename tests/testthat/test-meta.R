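test_that("log response ratio identities hold", {
  d <- ws_dataset(tiny_obs(3, y_t = 5000, y_c = 5000))
  eff <- compute_rr(d, "yield")
  expect_equal(eff$rr, rep(0, 3))
  d2 <- ws_dataset(tiny_obs(2, y_t = exp(1) * 4000, y_c = 4000))
  expect_equal(compute_rr(d2, "yield")$rr, rep(1, 2))
})

test_that("percent change is the exact inverse log transform", {
  # a pooled log ratio of ln(1.40) = 0.3365 means a 40% increase
  eff <- tibble::tibble(study_id = rep(c("a", "b"), 3),
                        rr = log(1.40), weight = 1)
  f <- fit_reml(eff)
  expect_equal(f$percent_change, 40, tolerance = 1e-10)
  expect_equal(log(1 + f$percent_change / 100), f$pooled_rr,
               tolerance = 1e-12)
})

test_that("pairs that cannot be computed are excluded with a reason", {
  obs <- tiny_obs(3)
  obs$nue_t <- c(30, NA, 25)
  obs$nue_c <- c(20, 22, NA)
  d <- ws_dataset(obs)
  eff <- compute_rr(d, "nue")
  expect_equal(nrow(eff), 1L)
  exc <- attr(eff, "excluded")
  expect_equal(nrow(exc), 2L)
  expect_setequal(exc$reason,
                  c("missing treatment value", "missing control value"))
})

test_that("WP ratios fall back to yield over 10*ET when not extracted", {
  obs <- tiny_obs(2, y_t = 6000, y_c = 4500)
  obs$et_t <- c(400, 420)
  obs$et_c <- c(350, 360)
  d <- ws_dataset(obs)
  eff <- compute_rr(d, "wp")
  expect_equal(eff$rr[1],
               log((6000 / (10 * 400)) / (4500 / (10 * 350))))
})

test_that("single-study and zero-dispersion fits are exact", {
  eff <- tibble::tibble(study_id = "s1", rr = c(0.1, 0.4, 0.7),
                        weight = 1)
  f <- fit_reml(eff)
  expect_equal(f$pooled_rr, 0.4)
  expect_equal(f$tau2, 0)
  effc <- tibble::tibble(study_id = rep(c("a", "b", "c"), 2), rr = 0.25,
                         weight = c(1, 2, 3, 1, 2, 3))
  fc <- fit_reml(effc)
  expect_equal(fc$pooled_rr, 0.25)
  expect_equal(fc$tau2, 0)
})

test_that("REML matches a grid-search restricted-likelihood maximizer", {
  set.seed(101)
  eff <- simulate_effects(10, c(3, 6), mu = 0.3, tau2 = 0.04,
                          sigma2 = 0.02)
  f <- fit_reml(eff)
  oracle <- reml_oracle_grid(eff$rr, eff$weight, eff$study_id)
  expect_lt(abs(f$tau2 - oracle$tau2), 1e-4)
  expect_lt(abs(f$sigma2 - oracle$sigma2), 1e-4)
})

test_that("REML agrees with an independent mixed-model fit", {
  skip_if_not_installed("lme4")
  set.seed(7)
  eff <- simulate_effects(15, c(2, 6), mu = 0.2, tau2 = 0.06,
                          sigma2 = 0.03, weights = c(1, 2, 0.5))
  f <- fit_reml(eff)
  m <- lme4::lmer(rr ~ 1 + (1 | study_id), data = eff, weights = weight,
                  REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(f$pooled_rr, unname(lme4::fixef(m)[1]), tolerance = 1e-6)
  expect_equal(f$tau2, vc$vcov[1], tolerance = 1e-6)
  expect_equal(f$sigma2, vc$vcov[2], tolerance = 1e-6)
})

test_that("pooled estimate is invariant to rescaling all weights", {
  set.seed(5)
  eff <- simulate_effects(8, 4, mu = 0.3, tau2 = 0.05, sigma2 = 0.02,
                          weights = c(1, 3))
  f1 <- fit_reml(eff)
  eff2 <- eff
  eff2$weight <- eff2$weight * 7.3
  f2 <- fit_reml(eff2)
  expect_equal(f1$pooled_rr, f2$pooled_rr, tolerance = 1e-8)
  expect_equal(f1$tau2, f2$tau2, tolerance = 1e-8)
})

test_that("constraining tau2 to zero gives the weighted mean", {
  set.seed(6)
  eff <- simulate_effects(6, 3, mu = 0.3, tau2 = 0.05, sigma2 = 0.02,
                          weights = c(1, 2, 4))
  f0 <- fit_reml(eff, tau2_fixed = 0)
  expect_equal(f0$pooled_rr,
               sum(eff$weight * eff$rr) / sum(eff$weight))
  expect_error(fit_reml(eff, tau2_fixed = 0.1), "tau2_fixed = 0")
})

test_that("too few effects is an explicit error", {
  expect_error(fit_reml(tibble::tibble(study_id = "a", rr = 0.1,
                                       weight = 1)),
               "insufficient data")
})

test_that("bootstrap intervals are reproducible and degenerate safely", {
  set.seed(2)
  eff <- simulate_effects(12, 4, mu = 0.3, tau2 = 0.04, sigma2 = 0.02)
  ci1 <- bootstrap_ci(eff, n_iter = 199, seed = 77)
  ci2 <- bootstrap_ci(eff, n_iter = 199, seed = 77)
  expect_identical(ci1$ci_low, ci2$ci_low)
  expect_identical(ci1$ci_high, ci2$ci_high)
  # all-identical effects collapse to a point interval
  effc <- tibble::tibble(study_id = rep(c("a", "b", "c"), 2), rr = 0.4,
                         weight = 1)
  cic <- bootstrap_ci(effc, n_iter = 99, seed = 1)
  expect_equal(cic$ci_low, fit_reml(effc)$pooled_rr)
  expect_equal(cic$ci_high, cic$ci_low)
})

test_that("observation-level resampling is available behind the flag", {
  set.seed(3)
  eff <- simulate_effects(8, 4, mu = 0.3, tau2 = 0.02, sigma2 = 0.02)
  ci <- bootstrap_ci(eff, n_iter = 99, seed = 5, cluster = FALSE)
  expect_true(ci$ci_low < ci$ci_high)
})

test_that("subgroup summaries have one row per subgroup", {
  obs <- rbind(tiny_obs(5, region = "North", study_id = "S1"),
               tiny_obs(4, region = "East", study_id = "S2",
                        y_t = 7000, y_c = 5000))
  obs$y_t <- obs$y_t * exp(rnorm(nrow(obs), 0, 0.05))
  d <- ws_dataset(obs)
  overall <- subgroup_summary(d, "yield", "overall")
  expect_equal(nrow(overall), 1L)
  expect_equal(overall$n_obs, 9L)
  by_region <- subgroup_summary(d, "yield", "region")
  expect_equal(nrow(by_region), 2L)
  expect_setequal(by_region$subgroup, c("North", "East"))
})

test_that("small subgroups are reported as not estimable", {
  obs <- rbind(tiny_obs(6, region = "North", study_id = "S1"),
               tiny_obs(2, region = "East", study_id = "S2"))
  obs$y_t <- obs$y_t * exp(seq(0.01, 0.08, length.out = 8))
  d <- ws_dataset(obs)
  by_region <- subgroup_summary(d, "yield", "region", min_effects = 3)
  east <- by_region[by_region$subgroup == "East", ]
  expect_false(east$estimable)
  expect_true(is.na(east$pooled_rr))
})

test_that("noise-free regional effects are recovered exactly", {
  # two regions with known deterministic response ratios 0.2 and 0.4
  obs <- rbind(
    tiny_obs(6, region = "North", study_id = "S1",
             y_t = 5000 * exp(0.2), y_c = 5000),
    tiny_obs(6, region = "East", study_id = "S2",
             y_t = 5000 * exp(0.4), y_c = 5000)
  )
  obs$study_id <- rep(c("S1", "S1b", "S2", "S2b"), each = 3)
  d <- ws_dataset(obs)
  by_region <- subgroup_summary(d, "yield", "region")
  expect_equal(by_region$pooled_rr[by_region$subgroup == "North"], 0.2,
               tolerance = 1e-10)
  expect_equal(by_region$pooled_rr[by_region$subgroup == "East"], 0.4,
               tolerance = 1e-10)
})
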