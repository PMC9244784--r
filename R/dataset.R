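# Canonical column set. Everything beyond the mandatory six is optional;
# unknown extra columns are kept verbatim as candidate features for the
# tree-based ranking.
.ws_mandatory <- c("study_id", "water_mm", "n_kg_ha", "y_t", "y_c")
.ws_numeric_cols <- c(
  "year", "mat", "map_mm", "soc", "an", "ap", "ak",
  "water_mm", "n_kg_ha", "y_t", "y_c", "et_t", "et_c",
  "rep_t", "rep_c", "split_n_stages", "irrigation_events",
  "wp_t", "wp_c", "nue_t", "nue_c"
)

#' Construct a paired-observation dataset
#'
#' Validates a table of paired treatment/control wheat observations and
#' attaches provenance metadata. One row is one treatment/control pair: the
#' treatment arm received irrigation and/or nitrogen fertilizer, the control
#' arm neither. Yields are stored internally in kg/ha.
#'
#' @param observations A data frame with at least `study_id`, `water_mm`
#'   (total water input, mm), `n_kg_ha` (total N fertilizer, kg/ha), `y_t`,
#'   `y_c` (treatment/control grain yield, kg/ha) and either `region` or
#'   `province`. Optional columns include climate (`mat`, `map_mm`), initial
#'   soil nutrients (`soc`, `an`, `ap`, `ak`), evapotranspiration (`et_t`,
#'   `et_c`), replicate counts (`rep_t`, `rep_c`), directly extracted water
#'   productivity (`wp_t`, `wp_c`) and N use efficiency (`nue_t`, `nue_c`),
#'   `wheat_type`, `split_n_stages`, `irrigation_events`. Any further columns
#'   are retained as extra features. Missing values are `NA`, never sentinel
#'   numbers.
#' @param provenance Free-text description of where the observations came
#'   from.
#' @return A tibble of class `ws_dataset` with attribute `provenance`.
#' @export
ws_dataset <- function(observations, provenance = "unspecified") {
  obs <- tibble::as_tibble(observations)
  missing_cols <- setdiff(.ws_mandatory, names(obs))
  if (!("region" %in% names(obs)) && !("province" %in% names(obs))) {
    missing_cols <- c(missing_cols, "region|province")
  }
  if (length(missing_cols) > 0L) {
    stop("dataset schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!("region" %in% names(obs))) {
    obs$region <- region_of(obs$province)
  }
  if (!all(obs$region %in% wheat_regions())) {
    bad <- setdiff(unique(obs$region), wheat_regions())
    stop("unknown region label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if ("province" %in% names(obs)) {
    implied <- region_of(obs$province)
    if (!all(implied == obs$region)) {
      stop("region column inconsistent with province mapping at row(s): ",
           paste(utils::head(which(implied != obs$region), 5L),
                 collapse = ", "),
           call. = FALSE)
    }
  }
  if (!("obs_id" %in% names(obs))) {
    obs$obs_id <- sprintf("obs%04d", seq_len(nrow(obs)))
  }
  if (anyDuplicated(obs$obs_id)) {
    stop("obs_id values must be unique", call. = FALSE)
  }
  bad_pos <- which(
    (!is.na(obs$y_t) & obs$y_t <= 0) | (!is.na(obs$y_c) & obs$y_c <= 0)
  )
  if (length(bad_pos) > 0L) {
    stop("nonpositive yield at row(s): ",
         paste(utils::head(bad_pos, 5L), collapse = ", "), call. = FALSE)
  }
  bad_inp <- which(
    (!is.na(obs$water_mm) & obs$water_mm < 0) |
      (!is.na(obs$n_kg_ha) & obs$n_kg_ha < 0)
  )
  if (length(bad_inp) > 0L) {
    stop("negative water or N input at row(s): ",
         paste(utils::head(bad_inp, 5L), collapse = ", "), call. = FALSE)
  }
  structure(obs, class = c("ws_dataset", class(obs)),
            provenance = provenance)
}

#' Read a paired-observation dataset from CSV
#'
#' Reads an RFC-4180 CSV (header row, UTF-8, empty cells or "NA" for missing
#' values), coerces the recognised columns to their types, and validates the
#' result. Rows whose recognised numeric columns fail coercion are rejected
#' with their row numbers.
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector mapping internal column
#'   names to the file's column names, e.g. `c(y_t = "yield_trt")`.
#' @param yield_unit Unit of the yield columns in the file: `"kg_ha"`
#'   (default) or `"t_ha"` (values are multiplied by 1000 on read).
#' @param provenance Provenance string stored on the dataset; defaults to the
#'   file path.
#' @return A `ws_dataset` tibble.
#' @export
read_dataset <- function(path, schema = NULL,
                         yield_unit = c("kg_ha", "t_ha"),
                         provenance = path) {
  yield_unit <- match.arg(yield_unit)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), check.names = FALSE)
  if (!is.null(schema)) {
    for (internal in names(schema)) {
      ext <- schema[[internal]]
      if (!ext %in% names(raw)) {
        stop("schema error: mapped column ", shQuote(ext),
             " not found in file", call. = FALSE)
      }
      names(raw)[names(raw) == ext] <- internal
    }
  }
  num_cols <- intersect(.ws_numeric_cols, names(raw))
  bad_rows <- integer(0)
  for (cl in num_cols) {
    v <- raw[[cl]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad_rows <- union(bad_rows, which(!is.na(v) & is.na(coerced)))
      raw[[cl]] <- coerced
    }
  }
  if (length(bad_rows) > 0L) {
    bad_rows <- sort(bad_rows)
    warning("rejecting ", length(bad_rows),
            " row(s) failing numeric coercion: rows ",
            paste(utils::head(bad_rows, 10L), collapse = ", "),
            call. = FALSE)
    raw <- raw[-bad_rows, , drop = FALSE]
  }
  if (yield_unit == "t_ha") {
    raw$y_t <- raw$y_t * 1000
    raw$y_c <- raw$y_c * 1000
  }
  ws_dataset(raw, provenance = provenance)
}

#' Write a dataset to CSV
#'
#' Inverse of [read_dataset()]: values round-trip exactly as written
#' (integers and text bit-exact, decimals value-exact via full-precision
#' formatting).
#'
#' @param dataset A `ws_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Number of studies and observations in a dataset
#' @param dataset A `ws_dataset`.
#' @return Named list with `n_studies` and `n_obs`.
#' @export
dataset_counts <- function(dataset) {
  list(n_studies = length(unique(dataset$study_id)),
       n_obs = nrow(dataset))
}

#' @export
print.ws_dataset <- function(x, ...) {
  cnt <- dataset_counts(x)
  cat(sprintf("<ws_dataset> %d observations from %d studies (%s)\n",
              cnt$n_obs, cnt$n_studies,
              paste(sort(unique(x$region)), collapse = ", ")))
  NextMethod()
}
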