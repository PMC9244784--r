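#' Province-to-region classification for Chinese wheat production
#'
#' Wheat studies are grouped into four production regions. The mapping covers
#' the 25 provinces (and province-level municipalities) with published field
#' studies; provinces outside the table (e.g. Tibet) are deliberately
#' unmapped because no studies exist for them.
#'
#' @return A tibble with columns `province` and `region`.
#' @export
#' @examples
#' region_map()
region_map <- function() {
  tibble::tibble(
    province = c(
      "Gansu", "Ningxia", "Qinghai", "Shaanxi", "Xinjiang",
      "Beijing", "Jilin", "Hebei", "Heilongjiang", "Inner Mongolia",
      "Liaoning", "Shanxi", "Tianjin",
      "Guangdong", "Guangxi", "Henan", "Hubei", "Hunan",
      "Anhui", "Fujian", "Jiangsu", "Jiangxi", "Shandong", "Zhejiang",
      "Shanghai"
    ),
    region = c(
      rep("Northwest", 5L),
      rep("North", 8L),
      rep("Center", 5L),
      rep("East", 7L)
    )
  )
}

#' The four wheat production regions
#' @return Character vector of the region labels, in canonical order.
#' @export
wheat_regions <- function() c("Center", "East", "North", "Northwest")

#' Classify a province into its wheat production region
#'
#' Matching is case-insensitive after trimming surrounding whitespace.
#'
#' @param province Character vector of province names.
#' @return Character vector of regions (`Center`, `East`, `North`,
#'   `Northwest`), same length as `province`.
#' @export
#' @examples
#' region_of(c("Gansu", "Shandong"))
region_of <- function(province) {
  stopifnot(is.character(province))
  rm_tbl <- region_map()
  key <- tolower(trimws(province))
  idx <- match(key, tolower(rm_tbl$province))
  if (anyNA(idx)) {
    bad <- unique(province[is.na(idx)])
    stop(
      "unmapped province(s): ", paste(shQuote(bad), collapse = ", "),
      "; only the 25 provinces with published wheat studies are classified",
      call. = FALSE
    )
  }
  rm_tbl$region[idx]
}
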