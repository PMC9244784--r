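test_that("water productivity follows the 1 mm/ha = 10 m3 conversion", {
  expect_equal(water_productivity(1800, 100), 1.8)
  expect_equal(water_productivity(0, 250), 0)
  expect_equal(water_productivity(2 * 1800, 100),
               2 * water_productivity(1800, 100))
  expect_error(water_productivity(1000, 0), "et must be > 0")
})

test_that("NUE is yield per kg of applied N", {
  expect_equal(nue(1000, 100), 10)
  expect_equal(nue(0, 50), 0)
  expect_equal(nue(6500, 195), 33.33, tolerance = 1e-3)
  expect_error(nue(5000, 0), "n must be > 0")
})

test_that("a strictly increasing response puts the optimum in the top bin", {
  obs <- tiny_obs(6, region = "North", study_id = "S1")
  obs$water_mm <- c(100, 150, 200, 250, 300, 350)
  obs$y_t <- c(4000, 4500, 5000, 5500, 6000, 6500)
  d <- ws_dataset(obs)
  opt <- find_optima(d, "North", bin_w = 50)
  expect_equal(opt$optw, 375)  # center of the [350, 400) bin
  expect_equal(opt$w_max, 350)
})

test_that("a single observation defines its own optimal bin", {
  d <- ws_dataset(tiny_obs(1, region = "East", water = 320))
  opt <- find_optima(d, "East", bin_w = 50)
  expect_equal(opt$optw, 325)
  expect_error(find_optima(d, "North"), "insufficient data")
})

test_that("ties go to the lowest input bin", {
  obs <- tiny_obs(4, region = "North", study_id = "S1")
  obs$water_mm <- c(120, 220, 320, 420)
  obs$y_t <- c(5000, 6000, 6000, 5500)
  d <- ws_dataset(obs)
  expect_equal(find_optima(d, "North", bin_w = 50)$optw, 225)
})

test_that("noise-free generated optima are recovered within half a bin", {
  g <- generate_dataset(noise_free_config(seed = 21, n_studies = 80L))
  opt <- find_optima_all(g$dataset, bin_w = 50, bin_n = 30)
  for (r in opt$region) {
    expect_lt(abs(opt$optw[opt$region == r] -
                    g$truth$config$w_opt_true[[r]]), 50)
  }
  # the N optimum is confounded by the (random) water inputs within each N
  # bin; pinning water at its optimum isolates the N response
  cfg_n <- noise_free_config(seed = 22, n_studies = 80L)
  cfg_n$w_range <- c(0.999, 1.001)
  g2 <- generate_dataset(cfg_n)
  opt2 <- find_optima_all(g2$dataset, bin_w = 50, bin_n = 30)
  for (r in opt2$region) {
    expect_lte(abs(opt2$optn[opt2$region == r] -
                     g2$truth$config$n_opt_true[[r]]), 15)
  }
})

test_that("optimum finding is invariant to observation order", {
  g <- generate_dataset(generator_config(n_studies = 20L, seed = 13))
  d <- g$dataset
  opt1 <- find_optima_all(d)
  set.seed(1)
  opt2 <- find_optima_all(d[sample(nrow(d)), ])
  expect_equal(as.data.frame(opt1), as.data.frame(opt2))
})

test_that("classification is strict-above with boundary below", {
  obs <- tiny_obs(3, region = "North", study_id = "S1")
  obs$water_mm <- c(275, 276, 100)
  obs$n_kg_ha <- c(0, 200, 105)
  d <- ws_dataset(obs)
  optima <- tibble::tibble(region = "North", optw = 275, optn = 105,
                           w_max = 276, n_max = 200)
  lv <- classify(d, optima)
  expect_equal(lv$water_level, c("W_minus", "W_plus", "W_minus"))
  expect_equal(lv$n_level, c("N_minus", "N_plus", "N_minus"))
  # every observation gets exactly one label pair
  expect_equal(sum(lv$water_level == "W_plus") +
                 sum(lv$water_level == "W_minus"), nrow(d))
})

test_that("saving potential matches hand-evaluated formulas", {
  obs <- tiny_obs(3, region = "North", study_id = "S1")
  obs$water_mm <- c(600, 500, 800)
  d <- ws_dataset(obs)
  optima <- tibble::tibble(region = "North", optw = 500, optn = 150,
                           w_max = 800, n_max = 180)
  sp <- saving_potential(d, optima, "water")
  # per-observation: (100, 0, 300) mm; relative (12.5, 0, 37.5)%
  expect_equal(sp$mean_abs, mean(c(100, 0, 300)))
  expect_equal(sp$min_abs, 0)
  expect_equal(sp$max_abs, 300)
  expect_equal(sp$mean_rel, mean(c(12.5, 0, 37.5)))
  expect_equal(sp$n_above, 2L)
})

test_that("no overuse means zero saving potential", {
  obs <- tiny_obs(4, region = "East", water = 200)
  d <- ws_dataset(obs)
  optima <- tibble::tibble(region = "East", optw = 300, optn = 500,
                           w_max = 200, n_max = 180)
  sp <- saving_potential(d, optima, "water")
  expect_equal(sp$mean_rel, 0)
  expect_equal(sp$n_above, 0L)
})

test_that("mean relative saving averages per-observation ratios", {
  g <- generate_dataset(generator_config(n_studies = 25L, seed = 31))
  d <- g$dataset
  optima <- find_optima_all(d)
  sp <- saving_potential(d, optima, "nitrogen")
  for (r in optima$region) {
    x <- d$n_kg_ha[d$region == r]
    opt <- optima$optn[optima$region == r]
    nmax <- optima$n_max[optima$region == r]
    direct <- mean(pmax(x - opt, 0) / nmax * 100)
    expect_equal(sp$mean_rel[sp$region == r], direct, tolerance = 1e-12)
  }
})

test_that("perfectly linear cells recover slope, intercept and r2 = 1", {
  obs <- tiny_obs(8, region = "North", study_id = "S1")
  obs$water_mm <- seq(100, 450, by = 50)
  x <- obs$water_mm / 1000
  obs$y_t <- (2 * x + 1) * 1000  # yield t/ha = 2x + 1
  d <- ws_dataset(obs)
  optima <- tibble::tibble(region = "North", optw = 1000, optn = 1000,
                           w_max = 450, n_max = 180)
  lr <- suppressWarnings(level_regressions(d, optima))
  row <- lr[lr$outcome == "yield" & lr$level == "W_minus" &
              lr$scope == "North", ]
  expect_equal(row$slope, 2, tolerance = 1e-10)
  expect_equal(row$intercept, 1, tolerance = 1e-10)
  expect_equal(row$r2, 1, tolerance = 1e-10)
})

test_that("regression cells match the closed-form normal equations", {
  set.seed(17)
  obs <- tiny_obs(10, region = "East", study_id = "S1")
  obs$water_mm <- runif(10, 100, 300)
  obs$y_t <- 3000 + 8 * obs$water_mm + rnorm(10, 0, 200)
  d <- ws_dataset(obs)
  optima <- tibble::tibble(region = "East", optw = 1000, optn = 1000,
                           w_max = 300, n_max = 180)
  lr <- level_regressions(d, optima, x_scale = 1 / 1000)
  row <- lr[lr$outcome == "yield" & lr$level == "W_minus" &
              lr$scope == "East", ]
  x <- obs$water_mm / 1000
  y <- obs$y_t / 1000
  slope_cf <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(row$slope, slope_cf, tolerance = 1e-10)
  expect_equal(row$intercept, mean(y) - slope_cf * mean(x),
               tolerance = 1e-10)
})

test_that("degenerate regressor variance is flagged, not fitted", {
  obs <- tiny_obs(5, region = "North", water = 250)
  d <- ws_dataset(obs)
  optima <- tibble::tibble(region = "North", optw = 1000, optn = 1000,
                           w_max = 250, n_max = 180)
  lr <- level_regressions(d, optima)
  row <- lr[lr$outcome == "yield" & lr$level == "W_minus" &
              lr$scope == "North", ]
  expect_false(row$defined)
})
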