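#' City-average daily deposition over reporting stations
#'
#' Collapses station-level records to one city-level daily series by the
#' arithmetic mean over the stations that reported on each date. Dates on
#' which no station reported are absent from the output (treated as
#' missing downstream).
#'
#' @param records Tibble with columns `date`, `station`, `deposition`
#'   (grains/1000 mm2, >= 0); `(date, station)` must be unique.
#'
#' @return A tibble with columns `date`, `deposition`, dates strictly
#'   increasing.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   date = rep(as.Date("2015-08-01"), 2), station = c("A", "B"),
#'   deposition = c(0, 10)
#' )
#' average_stations(rec) # mean 5
average_stations <- function(records) {
  stop_if_not_cols(records, c("date", "station", "deposition"), "`records`")
  if (nrow(records) == 0) abort("`records` is empty")
  if (anyDuplicated(records[c("date", "station")])) {
    abort("duplicated (date, station) in `records`")
  }
  if (any(records$deposition < 0, na.rm = TRUE)) {
    abort("`deposition` must be >= 0")
  }
  records %>%
    filter(!is.na(.data$deposition)) %>%
    group_by(.data$date) %>%
    summarise(deposition = mean(.data$deposition), .groups = "drop") %>%
    arrange(.data$date)
}

#' Trailing moving average of a daily series
#'
#' The value at date t is the mean of the depositions on days
#' t - window + 1, ..., t (the current day and the previous window - 1
#' days). The first `window - 1` dates carry `NA` rather than an average
#' over fewer days, so every non-missing value is a mean of exactly
#' `window` days. `window = 1` returns the input.
#'
#' @param series Tibble with columns `date`, `deposition`, dates strictly
#'   increasing and consecutive.
#' @param window Window length in days (integer >= 1).
#'
#' @return A tibble with columns `date`, `deposition` (the windowed values).
#' @export
#' @examples
#' s <- tibble::tibble(
#'   date = as.Date("2015-08-01") + 0:3, deposition = c(1, 2, 4, 8)
#' )
#' moving_average(s, 2) # NA, 1.5, 3, 6
moving_average <- function(series, window) {
  stop_if_not_cols(series, c("date", "deposition"), "`series`")
  window <- as.integer(window)
  if (is.na(window) || window < 1) abort("`window` must be an integer >= 1")
  if (window > nrow(series)) abort("`window` exceeds series length")
  if (window == 1L) return(as_tibble(series[c("date", "deposition")]))
  x <- series$deposition
  cs <- cumsum(c(0, x))
  out <- (cs[(window + 1):length(cs)] - cs[1:(length(cs) - window)]) / window
  tibble(date = series$date,
         deposition = c(rep(NA_real_, window - 1L), out))
}

#' Detect pollen seasons by cumulative bounds
#'
#' For each calendar year the season starts on the first date whose running
#' cumulative deposition reaches `lower_frac` of the annual total and ends
#' on the first date reaching `upper_frac` (defaults 2.5% and 97.5%), so
#' the season contains at least `upper_frac - lower_frac` of the annual
#' pollen.
#'
#' @param series Tibble with columns `date`, `deposition`; may span several
#'   years.
#' @param lower_frac,upper_frac Cumulative start/end fractions,
#'   0 < lower_frac < upper_frac < 1.
#'
#' @return A tibble with one row per year: `year`, `start_date`,
#'   `end_date`, `annual_total`, `season_total`.
#' @export
#' @examples
#' s <- tibble::tibble(
#'   date = as.Date("2015-01-01") + 0:99, deposition = rep(1, 100)
#' )
#' detect_season(s) # starts day 3, ends day 98
detect_season <- function(series, lower_frac = 0.025, upper_frac = 0.975) {
  stop_if_not_cols(series, c("date", "deposition"), "`series`")
  if (!(lower_frac > 0 && lower_frac < upper_frac && upper_frac < 1)) {
    abort("need 0 < lower_frac < upper_frac < 1")
  }
  series <- arrange(series, .data$date)
  years <- as.integer(format(series$date, "%Y"))
  purrr::map_dfr(sort(unique(years)), function(y) {
    yr <- series[years == y, ]
    dep <- ifelse(is.na(yr$deposition), 0, yr$deposition)
    total <- sum(dep)
    if (total <= 0) {
      abort(sprintf("no pollen season: annual deposition sum is 0 in %d", y))
    }
    cs <- cumsum(dep)
    i0 <- which(cs >= lower_frac * total)[1]
    i1 <- which(cs >= upper_frac * total)[1]
    tibble(
      year = y, start_date = yr$date[i0], end_date = yr$date[i1],
      annual_total = total,
      season_total = cs[i1] - if (i0 > 1) cs[i0 - 1] else 0
    )
  })
}
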