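#' Run the full grading pipeline
#'
#' End-to-end analysis from raw records to the grading scale: station
#' averaging, season detection by cumulative bounds, moving-average
#' exposure construction per candidate window, eligible-pair selection
#' (in-season, non-rest-day, complete), Spearman window selection,
#' shifted-log dose-response fitting, threshold derivation (deposition
#' percentiles + patient quantiles + minimum substitution), scale building
#' and per-day classification. Every exclusion between raw input and the
#' fitted pair set is accounted for in `exclusion_log`.
#'
#' @param pollen Tibble `date`, `station`, `deposition`.
#' @param patients Tibble `date`, `patients`.
#' @param calendar Tibble `date`, `is_rest_day`, or `NULL` for no rest-day
#'   exclusion.
#' @param candidates Candidate window lengths (default 1:4).
#' @param season_fracs Cumulative season bounds (default `c(0.025, 0.975)`).
#' @param percentile_fractions,patient_fractions,minimum_fraction Passed to
#'   [threshold_set()].
#' @param in_season_only Restrict modelling pairs to detected seasons
#'   (default `TRUE`).
#' @param round_thresholds Passed to [build_scale()].
#'
#' @return An object of class `grading_report`: a list with `city_series`,
#'   `seasons`, `window_selection`, `samples` (pairs at the chosen window),
#'   `fit`, `thresholds`, `final_thresholds`, `scale`, `classified` (per-day
#'   levels over the chosen-window series) and `exclusion_log`.
#' @export
#' @examples
#' study <- generate_study_dataset(study_design(), seed = 1)
#' report <- run_pipeline(study$pollen, study$patients, study$calendar)
#' report$scale
run_pipeline <- function(pollen, patients, calendar = NULL,
                         candidates = 1:4, season_fracs = c(0.025, 0.975),
                         percentile_fractions = c(0.25, 0.5, 0.75),
                         patient_fractions = c(0.25, 0.5, 0.75),
                         minimum_fraction = 0.10,
                         in_season_only = TRUE,
                         round_thresholds = TRUE) {
  if (any(season_fracs <= 0 | season_fracs >= 1) ||
      season_fracs[1] >= season_fracs[2]) {
    abort("`season_fracs` must satisfy 0 < lower < upper < 1")
  }
  city <- average_stations(pollen)
  seasons <- detect_season(city, season_fracs[1], season_fracs[2])
  seasons_used <- if (in_season_only) seasons else NULL

  by_window <- windowed_samples(city, patients, seasons_used, calendar,
                                candidates)
  selection <- select_window(by_window)
  w <- chosen_window(selection)
  samples <- by_window[[as.character(w)]]

  fit <- fit_log_curve(samples)
  thresholds <- threshold_set(samples, percentile_fractions,
                              patient_fractions, minimum_fraction)
  final_thresholds <- substitute_minimum(thresholds)
  scale <- build_scale(final_thresholds, fit,
                       round_thresholds = round_thresholds)

  exposure <- moving_average(city, w)
  classified <- classify_series(scale, exposure)

  n_patient_days <- sum(!is.na(patients$patients))
  log <- tibble(
    stage = c("station-day records", "city-series days",
              "patient days (non-missing)",
              sprintf("eligible pairs (window %d)", w)),
    n = c(nrow(pollen), nrow(city), n_patient_days, nrow(samples))
  )

  structure(
    list(city_series = city, seasons = seasons,
         window_selection = selection, samples = samples, fit = fit,
         thresholds = thresholds, final_thresholds = final_thresholds,
         scale = scale, classified = classified, exclusion_log = log),
    class = "grading_report"
  )
}

#' @export
print.grading_report <- function(x, ...) {
  cat("== Pollen grading pipeline report ==\n\n")
  cat("Pollen seasons (cumulative bounds):\n")
  print(x$seasons)
  cat("\n")
  print(x$window_selection)
  cat("\n")
  print(x$fit)
  cat("\nFinal thresholds:\n")
  print(x$final_thresholds)
  cat("\n")
  print(x$scale)
  cat("\nRecord accounting:\n")
  print(as.data.frame(x$exclusion_log), row.names = FALSE)
  invisible(x)
}

#' Validate pipeline input tables
#'
#' Schema and sanity checks on the three input tables: required columns,
#' non-negative depositions and counts, duplicated `(date, station)` keys,
#' and date continuity of the city series. Never mutates its inputs; all
#' problems are reported together rather than raised.
#'
#' @param pollen,patients,calendar Input tibbles as for [run_pipeline()];
#'   `patients` and `calendar` may be `NULL` to skip their checks.
#'
#' @return A tibble with columns `table`, `row`, `rule`, `message`; zero
#'   rows when all inputs are clean.
#' @export
validate_inputs <- function(pollen, patients = NULL, calendar = NULL) {
  problems <- list()
  add <- function(table, row, rule, message) {
    problems[[length(problems) + 1]] <<-
      tibble(table = table, row = as.integer(row), rule = rule,
             message = message)
  }

  need <- c("date", "station", "deposition")
  if (!all(need %in% names(pollen))) {
    add("pollen", NA, "schema",
        paste("missing columns:",
              paste(setdiff(need, names(pollen)), collapse = ", ")))
  } else {
    bad <- which(!is.na(pollen$deposition) & pollen$deposition < 0)
    for (i in bad) {
      add("pollen", i, "non-negative deposition",
          sprintf("deposition %g < 0", pollen$deposition[i]))
    }
    dup <- which(duplicated(pollen[c("date", "station")]))
    for (i in dup) {
      add("pollen", i, "unique (date, station)",
          sprintf("duplicate record for %s / %s",
                  pollen$date[i], pollen$station[i]))
    }
    dates <- sort(unique(pollen$date))
    if (length(dates) > 1) {
      gaps <- which(diff(dates) > 1)
      for (g in gaps) {
        add("pollen", NA, "date continuity",
            sprintf("gap between %s and %s", dates[g], dates[g + 1]))
      }
    }
  }

  if (!is.null(patients)) {
    if (!all(c("date", "patients") %in% names(patients))) {
      add("patients", NA, "schema", "missing columns: date, patients")
    } else {
      bad <- which(!is.na(patients$patients) & patients$patients < 0)
      for (i in bad) {
        add("patients", i, "non-negative counts",
            sprintf("patients %g < 0", patients$patients[i]))
      }
      dup <- which(duplicated(patients$date))
      for (i in dup) {
        add("patients", i, "unique date",
            sprintf("duplicate date %s", patients$date[i]))
      }
    }
  }

  if (!is.null(calendar) &&
      !all(c("date", "is_rest_day") %in% names(calendar))) {
    add("calendar", NA, "schema", "missing columns: date, is_rest_day")
  }

  if (length(problems) == 0) {
    tibble(table = character(), row = integer(), rule = character(),
           message = character())
  } else {
    bind_rows(problems)
  }
}

#' Plot a city series with detected seasons
#'
#' Daily city-mean deposition with detected season windows shaded; a quick
#' visual check that the cumulative bounds bracket the seasonal mass.
#'
#' @param city_series Tibble `date`, `deposition`.
#' @param seasons A [detect_season()] table.
#' @return A ggplot object.
#' @export
plot_season_series <- function(city_series, seasons) {
  ggplot2::ggplot(city_series,
                  ggplot2::aes(x = .data$date, y = .data$deposition)) +
    ggplot2::geom_rect(
      data = seasons, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_date, xmax = .data$end_date,
                   ymin = -Inf, ymax = Inf),
      fill = "goldenrod", alpha = 0.2
    ) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = NULL, y = "city-mean deposition (grains/1000 mm²)")
}
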