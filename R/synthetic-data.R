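#' Seasonal shape parameters for one pollen year
#'
#' Describes the deterministic city-level seasonal curve for one calendar
#' year: a Gaussian bump in day-of-year scaled so that the expected
#' city-mean annual deposition sum equals `total_grains`, plus the
#' coefficient of variation of multiplicative station-level noise.
#'
#' @param year Calendar year.
#' @param peak_day Day-of-year of the seasonal maximum.
#' @param spread_days Seasonal width (standard deviation of the bump, days,
#'   > 0). The central 95% of the season spans roughly `3.9 * spread_days`
#'   days.
#' @param total_grains Annual city-mean pollen sum (grains/1000 mm2, >= 0).
#' @param station_noise_cv Coefficient of variation of the multiplicative
#'   lognormal station-day noise (>= 0). 0 makes all stations identical.
#'
#' @return A one-row tibble of class `season_shape`.
#' @export
#' @examples
#' season_shape(2015, peak_day = 239, spread_days = 10, total_grains = 3017)
season_shape <- function(year, peak_day, spread_days, total_grains,
                         station_noise_cv = 0.2) {
  if (spread_days <= 0) abort("`spread_days` must be > 0")
  if (total_grains < 0) abort("`total_grains` must be >= 0")
  if (station_noise_cv < 0) abort("`station_noise_cv` must be >= 0")
  out <- tibble(
    year = as.integer(year), peak_day = peak_day,
    spread_days = spread_days, total_grains = total_grains,
    station_noise_cv = station_noise_cv
  )
  class(out) <- c("season_shape", class(out))
  out
}

#' Dose-response parameters of the patient-count generator
#'
#' The generator draws daily patient counts whose expectation follows the
#' shifted-logarithm curve `f(x) = a * log(x + c) + d` of the trailing
#' `window_days`-day mean deposition `x`, clipped at zero. Defaults are the
#' coefficients of the published Beijing Artemisia fit and its 3-day
#' exposure window.
#'
#' @param a Scale (patients per log-unit of deposition).
#' @param c Deposition shift (grains/1000 mm2, > 0).
#' @param d Offset (patients).
#' @param window_days Trailing exposure window length (integer >= 1).
#'
#' @return A one-row tibble of class `response_params`.
#' @export
response_params <- function(a = 8.33, c = 8.53, d = -13.85, window_days = 3L) {
  if (c <= 0) abort("`c` must be > 0")
  if (window_days < 1) abort("`window_days` must be >= 1")
  out <- tibble(a = a, c = c, d = d, window_days = as.integer(window_days))
  class(out) <- c("response_params", class(out))
  out
}

#' Rest-day calendar
#'
#' Builds a daily calendar flagging rest days (weekends, plus any supplied
#' holidays) on which patient counts are excluded from modelling because
#' hospital capacity differs from weekdays.
#'
#' @param years Integer vector of calendar years to cover.
#' @param holidays Optional `Date` vector of additional rest days; must fall
#'   within `years`.
#' @param weekends_are_rest Flag Saturdays and Sundays as rest days
#'   (default `TRUE`).
#'
#' @return A tibble with columns `date`, `is_rest_day`.
#' @export
#' @examples
#' cal <- make_calendar(2015)
#' sum(cal$is_rest_day)
make_calendar <- function(years, holidays = as.Date(character()),
                          weekends_are_rest = TRUE) {
  years <- sort(unique(as.integer(years)))
  holidays <- as.Date(holidays)
  if (length(holidays) > 0 &&
      !all(as.integer(format(holidays, "%Y")) %in% years)) {
    abort("all `holidays` must fall within the listed `years`")
  }
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  dates <- dates[as.integer(format(dates, "%Y")) %in% years]
  wd <- as.POSIXlt(dates)$wday
  tibble(
    date = dates,
    is_rest_day = (weekends_are_rest & wd %in% c(0L, 6L)) | dates %in% holidays
  )
}

year_dates <- function(year) {
  seq(as.Date(sprintf("%d-01-01", year)),
      as.Date(sprintf("%d-12-31", year)), by = "day")
}

#' Generate one year of station-level pollen deposition records
#'
#' Daily station values are a deterministic unimodal (Gaussian-bump)
#' city-level curve, scaled so the expected city-mean annual sum equals
#' `total_grains`, multiplied by independent lognormal station-day noise
#' with unit mean and the stated coefficient of variation.
#'
#' @param shape A [season_shape()].
#' @param n_stations Number of monitoring stations (integer >= 1).
#' @param seed Integer seed; identical seeds give identical output.
#'
#' @return A tibble with columns `date`, `station`, `deposition`
#'   (grains/1000 mm2), one row per station per day of the year.
#' @export
#' @examples
#' rec <- generate_pollen_series(season_shape(2015, 239, 10, 3000), 4, seed = 1)
#' dplyr::count(rec, station)
generate_pollen_series <- function(shape, n_stations, seed) {
  if (!inherits(shape, "season_shape")) abort("`shape` must be a season_shape")
  if (n_stations < 1) abort("`n_stations` must be >= 1")
  dates <- year_dates(shape$year)
  doy <- seq_along(dates)
  w <- dnorm(doy, mean = shape$peak_day, sd = shape$spread_days)
  base <- shape$total_grains * w / sum(w)

  cv <- shape$station_noise_cv
  grid <- tidyr::expand_grid(
    station = sprintf("S%02d", seq_len(n_stations)),
    date = dates
  ) %>%
    mutate(base = rep(base, times = n_stations))
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    withr_seed(substream_seed(seed, "pollen"), {
      noise <- rlnorm(nrow(grid), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    })
  } else {
    noise <- 1
  }
  grid %>%
    mutate(deposition = .data$base * noise) %>%
    select("date", "station", "deposition") %>%
    arrange(.data$date, .data$station)
}

# set.seed scoped to an expression, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  eval.parent(substitute(expr))
}

#' Generate daily patient counts from a city-mean deposition series
#'
#' For each day the expected count is `mu = max(0, a * log(x_w + c) + d)`
#' where `x_w` is the trailing `window_days`-day mean deposition; realized
#' counts are Poisson draws with mean `mu` (or `mu` itself with
#' `noise = FALSE`). Counts are produced for every day with a defined
#' windowed exposure; rest-day exclusion happens downstream in
#' [select_samples()]. The first `window_days - 1` days of the series have
#' no full window and carry `NA` counts.
#'
#' @param city_series Tibble with columns `date`, `deposition` (city mean).
#' @param response A [response_params()].
#' @param seed Integer seed.
#' @param noise If `FALSE`, return the (possibly non-integer) expected
#'   counts instead of Poisson draws.
#'
#' @return A tibble with columns `date`, `patients`.
#' @export
generate_patient_counts <- function(city_series, response, seed, noise = TRUE) {
  stop_if_not_cols(city_series, c("date", "deposition"), "`city_series`")
  if (!inherits(response, "response_params")) {
    abort("`response` must be a response_params")
  }
  xw <- moving_average(city_series, response$window_days)$deposition
  mu <- pmax(0, response$a * log(xw + response$c) + response$d)
  patients <- mu
  ok <- !is.na(mu)
  if (noise) {
    withr_seed(substream_seed(seed, "patients"), {
      patients[ok] <- rpois(sum(ok), mu[ok])
    })
  }
  tibble(date = city_series$date, patients = patients)
}

#' Full synthetic study design
#'
#' Bundles the per-year seasonal shapes, the response parameters and the
#' calendar specification of a multi-year, multi-station surveillance
#' study. The defaults emulate a three-year, four-station design with
#' unimodal late-summer seasons that start on different days but end
#' consistently in mid-September, annual totals of 4845, 3017 and 3008
#' grains/1000 mm2, and patient counts driven by the default
#' [response_params()] curve of the 3-day trailing mean.
#'
#' @param shapes A tibble of stacked [season_shape()] rows, one per year.
#' @param response A [response_params()].
#' @param n_stations Number of stations.
#' @param holidays Optional extra rest days passed to [make_calendar()].
#'
#' @return A list of class `study_design`.
#' @export
study_design <- function(shapes = NULL, response = response_params(),
                         n_stations = 4L, holidays = as.Date(character())) {
  if (is.null(shapes)) {
    shapes <- bind_rows(
      season_shape(2014, peak_day = 225, spread_days = 17, total_grains = 4845),
      season_shape(2015, peak_day = 239, spread_days = 10, total_grains = 3017),
      season_shape(2016, peak_day = 236, spread_days = 12, total_grains = 3008)
    )
  }
  if (anyDuplicated(shapes$year)) abort("one season_shape per year")
  structure(
    list(shapes = shapes, response = response,
         n_stations = as.integer(n_stations), holidays = holidays),
    class = "study_design"
  )
}

#' Generate a complete synthetic study dataset
#'
#' Draws station-level pollen records, city-driven daily patient counts and
#' the rest-day calendar for every year of the design. Patient counts are
#' generated from the city-mean series (the average over stations), so the
#' downstream pipeline can recover the generating exposure window.
#'
#' @param design A [study_design()].
#' @param seed Integer master seed; split into named substreams for pollen
#'   and patients so either can be regenerated independently.
#'
#' @return A list of class `pollen_study` with tibbles `pollen`
#'   (`date`, `station`, `deposition`), `patients` (`date`, `patients`) and
#'   `calendar` (`date`, `is_rest_day`).
#' @export
#' @examples
#' study <- generate_study_dataset(study_design(), seed = 1)
#' lapply(study, nrow)
generate_study_dataset <- function(design = study_design(), seed = 1L) {
  if (!inherits(design, "study_design")) abort("`design` must be a study_design")
  years <- design$shapes$year
  if (length(design$holidays) > 0 &&
      !all(as.integer(format(design$holidays, "%Y")) %in% years)) {
    abort("holiday dates must fall within the design years")
  }
  pollen <- purrr::map_dfr(seq_len(nrow(design$shapes)), function(i) {
    sh <- design$shapes[i, ]
    class(sh) <- c("season_shape", class(tibble()))
    generate_pollen_series(sh, design$n_stations,
                           seed = substream_seed(seed, paste0("year", sh$year)))
  })
  city <- average_stations(pollen)
  patients <- purrr::map_dfr(years, function(y) {
    cs <- filter(city, as.integer(format(.data$date, "%Y")) == y)
    generate_patient_counts(cs, design$response,
                            seed = substream_seed(seed, paste0("pat", y)))
  })
  structure(
    list(pollen = pollen, patients = patients,
         calendar = make_calendar(years, holidays = design$holidays)),
    class = "pollen_study"
  )
}

#' @export
print.pollen_study <- function(x, ...) {
  yrs <- sort(unique(as.integer(format(x$pollen$date, "%Y"))))
  cat(sprintf(
    "<pollen_study> %d station-day pollen records (%d stations), %d patient days, years %s\n",
    nrow(x$pollen), dplyr::n_distinct(x$pollen$station), nrow(x$patients),
    paste(yrs, collapse = ", ")
  ))
  invisible(x)
}

#' Write a synthetic study dataset to CSV files
#'
#' Writes `pollen.csv` (date, station, deposition), `patients.csv`
#' (date, patients) and `calendar.csv` (date, is_rest_day) with ISO-8601
#' dates.
#'
#' @param study A `pollen_study` from [generate_study_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_study_csv <- function(study, dir) {
  if (!inherits(study, "pollen_study")) abort("`study` must be a pollen_study")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("pollen.csv", "patients.csv", "calendar.csv"))
  readr::write_csv(study$pollen, paths[1])
  readr::write_csv(study$patients, paths[2])
  readr::write_csv(study$calendar, paths[3])
  invisible(paths)
}

#' Read study CSV files
#'
#' Readers for the CSV dialect written by [write_study_csv()].
#'
#' @param path File path.
#' @return A tibble with the corresponding columns.
#' @name read_study_csv
NULL

#' @rdname read_study_csv
#' @export
read_pollen_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    date = readr::col_date(), station = readr::col_character(),
    deposition = readr::col_double()
  ))
}

#' @rdname read_study_csv
#' @export
read_patients_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    date = readr::col_date(), patients = readr::col_double()
  ))
}

#' @rdname read_study_csv
#' @export
read_calendar_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    date = readr::col_date(), is_rest_day = readr::col_logical()
  ))
}
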