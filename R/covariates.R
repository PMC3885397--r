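#' Derived sampling covariates
#'
#' Seasons, latitudinal bands and 5-cm length classes are derived from month,
#' latitude and fork length. Season 1 spans the year boundary (October--March,
#' the austral spawning season); season is a function of month only, pooling
#' across years. Lengths exactly on a class boundary belong to the lower
#' class, consistent with closed labels "46-50", "51-55".
#'
#' @name covariates
NULL

#' Season from month
#'
#' @param month Integer month 1--12.
#' @param levels 2 (1 = Oct--Mar, 2 = Apr--Sep) or 4 (1 = Jan--Mar,
#'   2 = Apr--Jun, 3 = Jul--Sep, 4 = Oct--Dec).
#' @return Integer season codes.
#' @export
#' @examples
#' season_of_month(11)            # 1 (spawning season)
#' season_of_month(11, levels = 4) # 4 (Oct-Dec)
season_of_month <- function(month, levels = 2) {
  if (any(is.na(month)) || any(month < 1 | month > 12 | month != round(month))) {
    bad <- which(is.na(month) | month < 1 | month > 12 | month != round(month))
    stop("month out of range 1-12 at position(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (levels == 2) {
    ifelse(month >= 10 | month <= 3, 1L, 2L)
  } else if (levels == 4) {
    ((month - 1) %/% 3) + 1L
  } else {
    stop("season levels must be 2 or 4", call. = FALSE)
  }
}

#' Latitudinal band from latitude
#'
#' Bands are numbered from the north: band 1 is latitudes less than the first
#' edge (default < 23 degrees S), band 2 between the edges (23--29), band 3
#' south of the second edge (> 29). A latitude exactly on an edge joins the
#' band to its south (band k covers [edge_k-1, edge_k)), so 23 falls in the
#' 23--29 band.
#'
#' @param latitude_degS Positive degrees south.
#' @param edges_degS Strictly increasing interior edges, default `c(23, 29)`.
#' @return Integer band index, 1 (north) to `length(edges_degS) + 1` (south).
#' @export
latitude_band <- function(latitude_degS, edges_degS = c(23, 29)) {
  if (is.unsorted(edges_degS, strictly = TRUE)) {
    stop("band edges must be strictly increasing", call. = FALSE)
  }
  findInterval(latitude_degS, edges_degS) + 1L
}

#' Length class from fork length
#'
#' Closed 5-cm classes labelled "46-50", "51-55", etc.: class k covers
#' (lower - 1, lower + width - 1] where lower runs 1, 6, 11, ... for the
#' default width of 5, so a fish of exactly 50.0 cm falls in "46-50" and one
#' of 50.5 cm in "51-55".
#'
#' @param fork_length_cm Fork lengths (cm), positive.
#' @param width_cm Class width, default 5.
#' @return List with `lower` (numeric lower label), `label` ("46-50") and
#'   `midpoint` (48 for "46-50").
#' @export
length_class <- function(fork_length_cm, width_cm = 5) {
  if (width_cm <= 0) stop("length class width must be positive", call. = FALSE)
  if (any(fork_length_cm <= 0, na.rm = TRUE)) {
    stop("fork lengths must be positive", call. = FALSE)
  }
  # ceiling to the class upper bound: upper = width * ceiling(L / width)
  upper <- width_cm * ceiling(fork_length_cm / width_cm)
  lower <- upper - width_cm + 1
  list(lower = lower,
       label = paste0(lower, "-", upper),
       midpoint = lower + (width_cm - 1) / 2)
}
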