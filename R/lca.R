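#' Impact categories and their units
#'
#' The eight life-cycle impact categories used for water/N input
#' characterization: global warming potential, primary energy demand,
#' acidification, abiotic depletion, eutrophication, respiratory
#' inorganics, photochemical oxidant formation and ecotoxicity.
#'
#' @return Named character vector: category -> unit.
#' @export
lca_categories <- function() {
  c(GWP = "kg CO2 eq", PED = "MJ", AP = "kg SO2 eq",
    ADP = "kg antimony eq", EP = "kg P3O4 eq", RI = "kg PM2.5 eq",
    POFP = "kg NMVOC eq", ETx = "CTUe")
}

#' Read a characterization-factor matrix from CSV
#'
#' Layout: a header row (`substance`, `unit`, then the eight category
#' columns), a units row (substance cell `"unit"`) declaring each
#' category's unit, then one row per substance with its inventory unit and
#' factors. Exactly the eight canonical categories must be present with
#' their fixed units.
#'
#' @param path CSV path.
#' @return A list of class `ws_factor_matrix`: `factors` (matrix, substance
#'   x category), `substance_units` (named), `category_units` (named).
#' @export
read_factor_matrix <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  cats <- setdiff(names(raw), c("substance", "unit"))
  expected <- lca_categories()
  if (!setequal(cats, names(expected))) {
    stop("factor matrix must have exactly the 8 categories: ",
         paste(names(expected), collapse = ", "), call. = FALSE)
  }
  unit_row <- raw[raw$substance == "unit", , drop = FALSE]
  if (nrow(unit_row) != 1L) {
    stop("factor matrix needs one unit row (substance column = 'unit')",
         call. = FALSE)
  }
  cat_units <- unlist(unit_row[names(expected)])
  bad <- names(expected)[cat_units != expected]
  if (length(bad) > 0L) {
    stop("category unit mismatch for: ",
         paste(sprintf("%s (got %s, want %s)", bad, cat_units[bad],
                       expected[bad]), collapse = "; "), call. = FALSE)
  }
  body <- raw[raw$substance != "unit", , drop = FALSE]
  fm <- as.matrix(vapply(names(expected),
                         function(cl) as.numeric(body[[cl]]),
                         numeric(nrow(body))))
  if (nrow(body) == 1L) fm <- matrix(fm, nrow = 1,
                                     dimnames = list(NULL, names(expected)))
  rownames(fm) <- body$substance
  structure(list(
    factors = fm,
    substance_units = stats::setNames(body$unit, body$substance),
    category_units = expected
  ), class = "ws_factor_matrix")
}

#' Read per-kg-N emission/background coefficients from CSV
#'
#' Columns: `substance`, `unit`, `per_kg_n` (field emission plus
#' production/transport burden per kg N fertilizer), `per_m3_water`
#' (burden per m^3 of irrigation water provision).
#'
#' @param path CSV path.
#' @return Tibble as described.
#' @export
read_emission_coefs <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Build a per-hectare inventory from input rates
#'
#' The system boundary covers production and transport of N fertilizer,
#' field emissions from its application (e.g. N2O, NH3, nitrate leaching)
#' and provision of irrigation water; it excludes the production and use of
#' irrigation facilities, machinery and equipment.
#'
#' @param region Region label (metadata only).
#' @param n_kg_ha N fertilizer rate, kg/ha.
#' @param irrigation_m3_ha Irrigation water, m^3/ha.
#' @param coefs Coefficient table from [read_emission_coefs()].
#' @return A list of class `ws_inventory`: `region`, `amounts` (named,
#'   kg or MJ per ha), `units` (named).
#' @export
build_inventory <- function(region, n_kg_ha, irrigation_m3_ha, coefs) {
  stopifnot(n_kg_ha >= 0, irrigation_m3_ha >= 0)
  amounts <- coefs$per_kg_n * n_kg_ha +
    coefs$per_m3_water * irrigation_m3_ha
  structure(list(
    region = region,
    amounts = stats::setNames(amounts, coefs$substance),
    units = stats::setNames(coefs$unit, coefs$substance)
  ), class = "ws_inventory")
}

#' Characterize an inventory into impact-category scores
#'
#' score_c = sum over substances of amount_s * factor_{s,c}. Substances
#' absent from the factor matrix contribute zero and are listed in the
#' `unmatched` attribute; a unit disagreement between inventory and factor
#' matrix is an error naming the substance.
#'
#' @param inv A `ws_inventory`.
#' @param fm A `ws_factor_matrix`.
#' @return Named numeric vector of per-hectare scores (one per category)
#'   with attribute `unmatched`.
#' @export
characterize <- function(inv, fm) {
  stopifnot(inherits(inv, "ws_inventory"),
            inherits(fm, "ws_factor_matrix"))
  subs <- names(inv$amounts)
  matched <- subs[subs %in% rownames(fm$factors)]
  unmatched <- setdiff(subs, matched)
  for (s in matched) {
    if (!is.na(fm$substance_units[s]) && !is.na(inv$units[s]) &&
        fm$substance_units[s] != inv$units[s]) {
      stop("unit mismatch for substance ", shQuote(s), ": inventory ",
           inv$units[s], " vs factor matrix ", fm$substance_units[s],
           call. = FALSE)
    }
  }
  scores <- if (length(matched) > 0L) {
    drop(inv$amounts[matched] %*% fm$factors[matched, , drop = FALSE])
  } else {
    stats::setNames(rep(0, ncol(fm$factors)), colnames(fm$factors))
  }
  structure(scores, unmatched = unmatched)
}

#' Scale per-hectare scores to per-tonne of grain
#'
#' @param score_per_ha Named per-category scores (per ha).
#' @param yield_t_ha Regional grain yield, t/ha (> 0).
#' @return Per-tonne scores.
#' @export
#' @examples
#' per_tonne(c(GWP = 1541.81), 5.1) # 302.32 kg CO2 eq / t
per_tonne <- function(score_per_ha, yield_t_ha) {
  if (any(yield_t_ha <= 0)) stop("yield must be > 0", call. = FALSE)
  score_per_ha / yield_t_ha
}

#' Express regional scores relative to a reference region
#'
#' @param results Data frame with columns `region` and one column per
#'   category (e.g. the per-ha impact table).
#' @param category Category column name.
#' @param reference_region Region whose score is the 100% reference.
#' @return Tibble `region`, `ratio_pct` (100 * score / reference score).
#' @export
region_ratio <- function(results, category, reference_region) {
  ref <- results[[category]][results$region == reference_region]
  if (length(ref) != 1L || is.na(ref) || ref <= 0) {
    stop("reference score for ", reference_region,
         " must be a single positive value", call. = FALSE)
  }
  tibble::tibble(
    region = results$region,
    ratio_pct = 100 * results[[category]] / ref
  )
}

#' Full impact table for regional input rates
#'
#' Builds inventories from per-region N and irrigation rates, characterizes
#' them, and scales per-tonne by regional yield.
#'
#' @param inputs Tibble with `region`, `n_kg_ha`, `irrigation_m3_ha`,
#'   `yield_t_ha`.
#' @param coefs Emission coefficients ([read_emission_coefs()]).
#' @param fm Factor matrix ([read_factor_matrix()]).
#' @return Tibble: `region`, `yield_t_ha`, then `<cat>_per_ha` and
#'   `<cat>_per_t` for each category.
#' @export
impact_table <- function(inputs, coefs, fm) {
  rows <- lapply(seq_len(nrow(inputs)), function(i) {
    inv <- build_inventory(inputs$region[i], inputs$n_kg_ha[i],
                           inputs$irrigation_m3_ha[i], coefs)
    sc <- characterize(inv, fm)
    pt <- per_tonne(sc, inputs$yield_t_ha[i])
    out <- tibble::tibble(region = inputs$region[i],
                          yield_t_ha = inputs$yield_t_ha[i])
    for (cat in names(lca_categories())) {
      out[[paste0(cat, "_per_ha")]] <- unname(sc[cat])
      out[[paste0(cat, "_per_t")]] <- unname(pt[cat])
    }
    out
  })
  dplyr::bind_rows(rows)
}
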