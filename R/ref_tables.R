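# Published regional synthesis values for Chinese wheat production.
# These tables are INPUTS to the valuation and scaling steps (prices,
# areas, saving potentials, per-hectare impact scores); the package's own
# estimators reproduce their structure from raw paired observations.

#' Published regional water-optimum summary
#'
#' Region-wise optimal total water input (OPTW, mm), companion N input,
#' yield, WP and NUE at the optimum, and water saving potential (absolute
#' mm and % of the regional maximum input).
#'
#' @return Tibble, one row per region plus an `Average` row.
#' @export
reference_optima_water <- function() {
  tibble::tibble(
    region = c("Center", "East", "North", "Northwest", "Average"),
    n = c(201L, 292L, 404L, 424L, 330L),
    optw_mm = c(316, 359, 289, 557, 380),
    n_input_kg_ha = c(205, 197, 191, 322, 229),
    yield_t_ha = c(7.4, 7.6, 6.5, 5.1, 6.7),
    wp_kg_m3 = c(2.1, 1.9, 1.7, 1.5, 1.8),
    nue_kg_kg = c(27.1, 31.6, 33.2, 26.3, 30.0),
    wsp_mean_mm = c(49, 95, 73, 76, 73),
    wsp_min_mm = c(0, 0, 0, 0, 0),
    wsp_max_mm = c(141, 352, 385, 192, 268),
    wsp_mean_pct = c(11, 13, 11, 10, 11),
    wsp_min_pct = c(0, 0, 0, 0, 0),
    wsp_max_pct = c(31, 50, 57, 26, 41)
  )
}

#' Published regional nitrogen-optimum summary
#'
#' Region-wise optimal N input (OPTN, kg/ha), companion water input, yield,
#' WP and NUE at the optimum, and N saving potential.
#'
#' @return Tibble, one row per region plus an `Average` row.
#' @export
reference_optima_nitrogen <- function() {
  tibble::tibble(
    region = c("Center", "East", "North", "Northwest", "Average"),
    n = c(201L, 292L, 404L, 424L, 330L),
    optn_kg_ha = c(240, 240, 195, 270, 236),
    water_input_mm = c(257, 308, 293, 322, 295),
    yield_t_ha = c(7.4, 7.6, 6.5, 5.1, 6.7),
    wp_kg_m3 = c(2.1, 1.9, 1.7, 1.5, 1.8),
    nue_kg_kg = c(27.1, 31.6, 33.2, 26.3, 30.0),
    nsp_mean_kg = c(44, 10, 68, 60, 46),
    nsp_min_kg = c(0, 0, 0, 0, 0),
    nsp_max_kg = c(120, 60, 314, 255, 187),
    nsp_mean_pct = c(12, 3, 13, 11, 10),
    nsp_min_pct = c(0, 0, 0, 0, 0),
    nsp_max_pct = c(33, 20, 62, 49, 41)
  )
}

#' Published per-hectare impact scores of regional water and N input
#'
#' Eight impact-category scores per hectare for each region (GWP kg CO2 eq,
#' PED MJ, AP kg SO2 eq, ADP kg antimony eq, EP kg P3O4 eq, RI kg PM2.5 eq,
#' POFP kg NMVOC eq, ETx CTUe). Per-tonne columns are derived from these
#' and the regional yields by [per_tonne()].
#'
#' @return Tibble, one row per region.
#' @export
reference_impacts_per_ha <- function() {
  tibble::tibble(
    region = c("Center", "East", "North", "Northwest"),
    GWP = c(1634.37, 1620.24, 1772.94, 1541.81),
    PED = c(17087.05, 17030.01, 19386.30, 16839.85),
    AP = c(9.69, 9.53, 10.53, 9.14),
    ADP = c(0.04, 0.04, 0.04, 0.04),
    EP = c(3.66, 3.50, 3.66, 3.16),
    RI = c(1.73, 1.75, 1.99, 1.73),
    POFP = c(2.04, 1.94, 2.21, 1.90),
    ETx = c(383.99, 360.04, 407.90, 349.76)
  )
}

#' Published water-saving economics inputs by region
#'
#' Irrigation water price (yuan/m^3), mean water saving (mm), regional
#' carbon price (yuan/t CO2), avoided GWP from saved water (kg CO2/ha) and
#' irrigated wheat area (ha).
#'
#' @return Tibble, one row per region.
#' @export
reference_econ_water <- function() {
  tibble::tibble(
    region = c("Center", "East", "North", "Northwest"),
    p_water_yuan_m3 = c(0.30, 0.15, 0.42, 0.46),
    ws_mm = c(49, 95, 73, 76),
    p_carbon_yuan_t = c(20.51, 29.80, 61.98, 6.11),
    gwp_save_kg_ha = c(93.34, 180.97, 139.06, 144.78),
    area_ha = c(2102596, 2227713, 1422983, 1464135)
  )
}

#' Published nitrogen-saving economics inputs by region
#'
#' N fertilizer price (yuan/kg), mean N saving (kg/ha), regional carbon
#' price (yuan/t CO2), avoided GWP from saved N (kg CO2/ha) and wheat area
#' (ha).
#'
#' @return Tibble, one row per region.
#' @export
reference_econ_nitrogen <- function() {
  tibble::tibble(
    region = c("Center", "East", "North", "Northwest"),
    p_n_yuan_kg = c(4.48, 4.13, 4.30, 4.31),
    ns_kg_ha = c(44, 10, 68, 60),
    p_carbon_yuan_t = c(20.51, 29.80, 61.98, 6.11),
    gwp_save_kg_ha = c(131.86, 29.97, 179.81, 137.85),
    area_ha = c(5673670, 3934430, 2764270, 2929640)
  )
}
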