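#' Water productivity
#'
#' Grain yield per unit of evapotranspired water. Yield enters in kg/ha and
#' ET in mm; since 1 mm of water over 1 ha is 10 m^3, the result in kg/m^3
#' is y / (10 * et).
#'
#' @param y Yield, kg/ha.
#' @param et Total evapotranspiration, mm (> 0).
#' @return Water productivity, kg/m^3.
#' @export
#' @examples
#' water_productivity(1800, 100) # 1.8 kg m^-3
water_productivity <- function(y, et) {
  if (any(!is.na(et) & et <= 0)) {
    stop("et must be > 0", call. = FALSE)
  }
  y / (10 * et)
}

#' Fertilizer nitrogen use efficiency
#'
#' Grain yield per kg of applied N fertilizer. Unfertilized arms (n = 0)
#' have no defined NUE and are a domain error.
#'
#' @param y Yield, kg/ha.
#' @param n N fertilizer applied, kg/ha (> 0).
#' @return NUE, kg grain per kg N.
#' @export
nue <- function(y, n) {
  if (any(!is.na(n) & n <= 0)) {
    stop("n must be > 0 (unfertilized arms have no defined NUE)",
         call. = FALSE)
  }
  y / n
}

bin_center <- function(x, width) (floor(x / width) + 0.5) * width

# Lowest-input bin center whose mean treatment yield attains the maximum
# over bins (ties broken toward lower input; float tolerance 1e-8 relative).
optimal_bin <- function(input, yield, width) {
  ctr <- bin_center(input, width)
  means <- tapply(yield, ctr, mean)
  centers <- as.numeric(names(means))
  mx <- max(means)
  ok <- means >= mx - 1e-8 * max(abs(mx), 1)
  opt <- min(centers[ok])
  list(opt = opt, in_opt = ctr == opt)
}

#' Region-wise optimal input levels
#'
#' Operationalizes "the minimal input that produced maximum yields": treated
#' observations are binned by input level (equal-width bins), and the
#' optimum is the center of the lowest-input bin whose mean treatment yield
#' attains the maximum over bins. Companion yield/WP/NUE values are means
#' within the optimal bin; `w_max`/`n_max` are the regional sample maxima.
#'
#' @param dataset A [ws_dataset()].
#' @param region One of the four region labels.
#' @param bin_w Water bin width, mm (default 50).
#' @param bin_n N bin width, kg/ha (default 30).
#' @return One-row tibble: `region`, `n`, `optw`, `optn`, `w_max`, `n_max`,
#'   `yield_at_optw_t`, `wp_at_optw`, `nue_at_optw`, `n_at_optw`,
#'   `yield_at_optn_t`, `water_at_optn`.
#' @export
find_optima <- function(dataset, region, bin_w = 50, bin_n = 30) {
  sub <- dataset[dataset$region == region &
                   !is.na(dataset$water_mm) & !is.na(dataset$y_t), ,
                 drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("insufficient data: no usable observations in region ", region,
         call. = FALSE)
  }
  ow <- optimal_bin(sub$water_mm, sub$y_t, bin_w)
  on_ <- optimal_bin(sub$n_kg_ha, sub$y_t, bin_n)
  wp_col <- if ("wp_t" %in% names(sub)) sub$wp_t else
    water_productivity_safe(sub$y_t, if ("et_t" %in% names(sub))
      sub$et_t else NA_real_)
  nue_col <- if ("nue_t" %in% names(sub)) sub$nue_t else NA_real_
  mean_or_na <- function(v, sel) {
    v <- v[sel]
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }
  tibble::tibble(
    region = region,
    n = nrow(sub),
    optw = ow$opt,
    optn = on_$opt,
    w_max = max(sub$water_mm),
    n_max = max(sub$n_kg_ha),
    yield_at_optw_t = mean(sub$y_t[ow$in_opt]) / 1000,
    wp_at_optw = mean_or_na(wp_col, ow$in_opt),
    nue_at_optw = mean_or_na(nue_col, ow$in_opt),
    n_at_optw = mean(sub$n_kg_ha[ow$in_opt]),
    yield_at_optn_t = mean(sub$y_t[on_$in_opt]) / 1000,
    water_at_optn = mean(sub$water_mm[on_$in_opt])
  )
}

#' Optima for every region present in a dataset
#' @inheritParams find_optima
#' @return A tibble with one row per region.
#' @export
find_optima_all <- function(dataset, bin_w = 50, bin_n = 30) {
  dplyr::bind_rows(lapply(sort(unique(dataset$region)), function(r)
    find_optima(dataset, r, bin_w = bin_w, bin_n = bin_n)))
}

#' Classify observations as above/below the regional optimal input
#'
#' An observation is `W_plus` iff its water input strictly exceeds the
#' regional optimum, else `W_minus`; the same rule gives `N_plus`/`N_minus`
#' for nitrogen. Inputs exactly at the optimum are "below-or-equal", so the
#' optimum itself is never counted as overuse.
#'
#' @param dataset A [ws_dataset()].
#' @param optima Per-region optima from [find_optima_all()].
#' @return Tibble with `obs_id`, `region`, `water_level`, `n_level`.
#' @export
classify <- function(dataset, optima) {
  ii <- match(dataset$region, optima$region)
  if (anyNA(ii)) {
    stop("no optima available for region(s): ",
         paste(unique(dataset$region[is.na(ii)]), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    obs_id = dataset$obs_id,
    region = dataset$region,
    water_level = ifelse(dataset$water_mm > optima$optw[ii],
                         "W_plus", "W_minus"),
    n_level = ifelse(dataset$n_kg_ha > optima$optn[ii],
                     "N_plus", "N_minus")
  )
}

#' Water or nitrogen saving potential by region
#'
#' For each observation above the regional optimum the absolute saving is
#' input minus optimum (mm or kg/ha) and the relative saving is that excess
#' over the regional maximum input, in percent; observations at or below
#' the optimum contribute zero savings (hence the minimum is 0 whenever any
#' such observation exists). Summaries are the mean/min/max over all
#' observations of the region, with relative values averaged per
#' observation (never a ratio of means).
#'
#' @param dataset A [ws_dataset()].
#' @param optima Per-region optima from [find_optima_all()].
#' @param kind `"water"` or `"nitrogen"`.
#' @return Tibble with one row per region: `region`, `kind`, `n`,
#'   `n_above`, `mean_abs`, `min_abs`, `max_abs`, `mean_rel`, `min_rel`,
#'   `max_rel`.
#' @export
saving_potential <- function(dataset, optima,
                             kind = c("water", "nitrogen")) {
  kind <- match.arg(kind)
  input <- if (kind == "water") dataset$water_mm else dataset$n_kg_ha
  rows <- lapply(optima$region, function(r) {
    sel <- dataset$region == r & !is.na(input)
    x <- input[sel]
    opt <- if (kind == "water") optima$optw[optima$region == r] else
      optima$optn[optima$region == r]
    xmax <- if (kind == "water") optima$w_max[optima$region == r] else
      optima$n_max[optima$region == r]
    abs_sav <- pmax(x - opt, 0)
    rel_sav <- if (xmax > 0) abs_sav / xmax * 100 else rep(0, length(x))
    n_above <- sum(x > opt)
    if (length(x) == 0L || n_above == 0L) {
      abs_sav <- 0
      rel_sav <- 0
    }
    tibble::tibble(
      region = r, kind = kind, n = length(x), n_above = n_above,
      mean_abs = mean(abs_sav), min_abs = min(abs_sav),
      max_abs = max(abs_sav),
      mean_rel = mean(rel_sav), min_rel = min(rel_sav),
      max_rel = max(rel_sav)
    )
  })
  dplyr::bind_rows(rows)
}

#' Linear input-response regressions within input-level strata
#'
#' Ordinary least squares of each outcome (yield in t/ha, WP in kg/m^3, NUE
#' in kg/kg) on the scaled input within each (outcome, level, region) cell
#' and over all regions ("Total"). The regressor is input * `x_scale`;
#' the default 1/1000 expresses water in metres and N in t/ha so slopes are
#' of order 1.
#'
#' @param dataset A [ws_dataset()].
#' @param optima Per-region optima from [find_optima_all()].
#' @param x_scale Input scaling applied before regression (default 1/1000).
#' @param alpha Significance threshold used only for the `significant` flag
#'   (cells with p >= alpha are flagged, not suppressed).
#' @param min_n Minimum observations per cell (default 3).
#' @return Tibble: `outcome`, `level`, `scope`, `n`, `slope`, `intercept`,
#'   `r2`, `p_value`, `significant`, `defined`.
#' @export
level_regressions <- function(dataset, optima, x_scale = 1 / 1000,
                              alpha = 0.05, min_n = 3L) {
  lv <- classify(dataset, optima)
  wp_col <- if ("wp_t" %in% names(dataset)) dataset$wp_t else
    water_productivity_safe(dataset$y_t,
                            if ("et_t" %in% names(dataset))
                              dataset$et_t else NA_real_)
  nue_col <- if ("nue_t" %in% names(dataset)) dataset$nue_t else
    rep(NA_real_, nrow(dataset))
  outcomes <- list(
    yield = dataset$y_t / 1000,
    wp = wp_col,
    nue = nue_col
  )
  levels_def <- list(
    W_minus = list(lab = lv$water_level == "W_minus", x = dataset$water_mm),
    W_plus = list(lab = lv$water_level == "W_plus", x = dataset$water_mm),
    N_minus = list(lab = lv$n_level == "N_minus", x = dataset$n_kg_ha),
    N_plus = list(lab = lv$n_level == "N_plus", x = dataset$n_kg_ha)
  )
  scopes <- c("Total", sort(unique(dataset$region)))
  out <- list()
  for (oc in names(outcomes)) {
    for (lev in names(levels_def)) {
      for (sc in scopes) {
        sel <- levels_def[[lev]]$lab &
          (sc == "Total" | dataset$region == sc) &
          !is.na(outcomes[[oc]]) & !is.na(levels_def[[lev]]$x)
        n_cell <- sum(sel)
        if (n_cell < min_n) next
        x <- levels_def[[lev]]$x[sel] * x_scale
        y <- outcomes[[oc]][sel]
        if (stats::sd(x) < 1e-12) {
          out[[length(out) + 1L]] <- tibble::tibble(
            outcome = oc, level = lev, scope = sc, n = n_cell,
            slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
            p_value = NA_real_, significant = NA, defined = FALSE
          )
          next
        }
        fit <- stats::lm(y ~ x)
        sm <- summary(fit)
        pv <- sm$coefficients["x", "Pr(>|t|)"]
        out[[length(out) + 1L]] <- tibble::tibble(
          outcome = oc, level = lev, scope = sc, n = n_cell,
          slope = unname(stats::coef(fit)["x"]),
          intercept = unname(stats::coef(fit)["(Intercept)"]),
          r2 = sm$r.squared, p_value = pv,
          significant = pv < alpha, defined = TRUE
        )
      }
    }
  }
  dplyr::bind_rows(out)
}
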