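#' Value of saved irrigation water
#'
#' 1 mm of water over 1 ha is 10 m^3, so the per-hectare value of a water
#' saving is ws_mm * 10 * price.
#'
#' @param ws_mm Water saving, mm.
#' @param p_water Water price, yuan/m^3.
#' @return Value, yuan/ha.
#' @export
#' @examples
#' water_saving_value(49, 0.30) # 147.00 yuan/ha
water_saving_value <- function(ws_mm, p_water) {
  stopifnot(all(ws_mm >= 0), all(p_water >= 0))
  ws_mm * 10 * p_water
}

#' Value of saved nitrogen fertilizer
#'
#' @param ns_kg N saving, kg/ha.
#' @param p_n N fertilizer price, yuan/kg.
#' @return Value, yuan/ha.
#' @export
nitrogen_saving_value <- function(ns_kg, p_n) {
  stopifnot(all(ns_kg >= 0), all(p_n >= 0))
  ns_kg * p_n
}

#' Value of avoided greenhouse-gas emissions
#'
#' @param gwp_save_kg Avoided emissions, kg CO2 eq/ha.
#' @param p_carbon_per_t Carbon price, yuan per tonne CO2.
#' @return Value, yuan/ha.
#' @export
carbon_value <- function(gwp_save_kg, p_carbon_per_t) {
  stopifnot(all(gwp_save_kg >= 0), all(p_carbon_per_t >= 0))
  gwp_save_kg * p_carbon_per_t / 1000
}

#' Totals, carbon share and regional scale-up of saving values
#'
#' total = input-saving value + carbon value; the carbon share is the
#' carbon value relative to the INPUT-saving value (in %); the regional
#' total scales the per-hectare total by the regional area.
#'
#' @param value_input Input-saving value, yuan/ha.
#' @param value_carbon Carbon co-benefit value, yuan/ha.
#' @param area_ha Regional area, ha.
#' @return Tibble: `total`, `carbon_share_pct` (`NA` when `value_input`
#'   is 0: the share is undefined, not zero), `region_total`.
#' @export
econ_totals <- function(value_input, value_carbon, area_ha) {
  stopifnot(all(value_carbon >= 0), all(area_ha >= 0))
  tibble::tibble(
    total = value_input + value_carbon,
    carbon_share_pct = ifelse(value_input > 0,
                              100 * value_carbon / value_input, NA_real_),
    region_total = (value_input + value_carbon) * area_ha
  )
}

#' Regional water- or nitrogen-saving valuation table
#'
#' End-to-end valuation per region from physical savings, prices, avoided
#' emissions and areas. Values are kept at full precision internally;
#' `round_report = TRUE` rounds per-hectare values to 2 decimals and
#' region totals to integer yuan, the conventional reporting layout.
#'
#' @param params Tibble with `region`, `area_ha`, `p_carbon_yuan_t`,
#'   `gwp_save_kg_ha`, and either (`ws_mm`, `p_water_yuan_m3`) for water or
#'   (`ns_kg_ha`, `p_n_yuan_kg`) for nitrogen.
#' @param kind `"water"` or `"nitrogen"`.
#' @param round_report Round for reporting (default FALSE).
#' @return Tibble: `region`, `kind`, `saving_phys`, `value_input`,
#'   `value_carbon`, `total`, `carbon_share_pct`, `region_total`.
#' @export
econ_table <- function(params, kind = c("water", "nitrogen"),
                       round_report = FALSE) {
  kind <- match.arg(kind)
  value_input <- if (kind == "water") {
    water_saving_value(params$ws_mm, params$p_water_yuan_m3)
  } else {
    nitrogen_saving_value(params$ns_kg_ha, params$p_n_yuan_kg)
  }
  value_carbon <- carbon_value(params$gwp_save_kg_ha,
                               params$p_carbon_yuan_t)
  tt <- econ_totals(value_input, value_carbon, params$area_ha)
  saving_phys <- if (kind == "water") params$ws_mm else params$ns_kg_ha
  out <- tibble::tibble(
    region = params$region,
    kind = kind,
    saving_phys = saving_phys,
    value_input = value_input,
    value_carbon = value_carbon,
    total = tt$total,
    carbon_share_pct = tt$carbon_share_pct,
    region_total = tt$region_total
  )
  if (round_report) {
    # report convention: per-ha components rounded to 2 d.p. first, then
    # totals, shares and regional scale-ups derived from the rounded values
    vi <- round(out$value_input, 2)
    vc <- round(out$value_carbon, 2)
    out$value_input <- vi
    out$value_carbon <- vc
    out$total <- round(vi + vc, 2)
    out$carbon_share_pct <- ifelse(vi > 0, round(100 * vc / vi, 2),
                                   NA_real_)
    out$region_total <- round(out$total * params$area_ha)
  }
  out
}
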