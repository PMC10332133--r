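#' Empirical deposition percentiles
#'
#' Percentiles of the windowed deposition distribution under the
#' linear-interpolation convention (type 7 order-statistic interpolation).
#'
#' @param exposures Numeric vector of deposition values (>= 4 values).
#' @param fractions Percentile fractions in (0, 1); default 25/50/75%.
#'
#' @return A tibble with columns `fraction`, `deposition`, monotone in the
#'   fraction.
#' @export
#' @examples
#' deposition_percentiles(c(1, 2, 3, 4), fractions = 0.25) # 1.75
deposition_percentiles <- function(exposures, fractions = c(0.25, 0.5, 0.75)) {
  exposures <- exposures[!is.na(exposures)]
  if (length(exposures) < 4) abort("need at least 4 exposure values")
  if (any(fractions <= 0 | fractions >= 1)) {
    abort("`fractions` must lie in (0, 1)")
  }
  tibble(
    fraction = fractions,
    deposition = unname(quantile(exposures, probs = fractions, type = 7))
  )
}

#' Deposition thresholds at patient quantiles
#'
#' Sorts the paired samples by ascending exposure and returns, for each
#' patient fraction q, the smallest exposure at which the running
#' cumulative patient sum reaches at least q of the total: the deposition
#' value "when q of patients appeared".
#'
#' @param samples Paired-sample tibble with columns `exposure`, `patients`;
#'   total patients must be > 0.
#' @param fractions Patient fractions in (0, 1); default 25/50/75%.
#'
#' @return A tibble with columns `fraction`, `deposition`, nondecreasing in
#'   the fraction.
#' @export
#' @examples
#' s <- tibble::tibble(exposure = c(10, 20, 30), patients = c(5, 5, 10))
#' patient_quantile_thresholds(s, c(0.25, 0.5)) # 10, 20
patient_quantile_thresholds <- function(samples,
                                        fractions = c(0.25, 0.5, 0.75)) {
  stop_if_not_cols(samples, c("exposure", "patients"), "`samples`")
  if (any(fractions <= 0 | fractions >= 1)) {
    abort("`fractions` must lie in (0, 1)")
  }
  s <- samples %>%
    filter(!is.na(.data$exposure), !is.na(.data$patients)) %>%
    arrange(.data$exposure)
  total <- sum(s$patients)
  if (total <= 0) abort("total patient count must be > 0")
  cum <- cumsum(s$patients)
  tibble(
    fraction = fractions,
    deposition = vapply(fractions, function(q) {
      s$exposure[which(cum >= q * total)[1]]
    }, numeric(1))
  )
}

#' Bundle basic grading thresholds
#'
#' Computes the two basic threshold series from the eligible paired
#' samples: deposition percentiles of the exposure distribution and
#' deposition values at patient quantiles, together with the patient
#' fraction nominally attached to the substituted minimum threshold.
#'
#' @param samples Paired-sample tibble (`exposure`, `patients`).
#' @param percentile_fractions Fractions for [deposition_percentiles()].
#' @param patient_fractions Fractions for [patient_quantile_thresholds()].
#' @param minimum_fraction Nominal patient fraction attached to the
#'   substituted minimum threshold (default 0.10).
#'
#' @return An object of class `threshold_set` with elements `percentiles`,
#'   `patient_quantiles` (both tibbles) and `minimum_fraction`.
#' @export
threshold_set <- function(samples,
                          percentile_fractions = c(0.25, 0.5, 0.75),
                          patient_fractions = c(0.25, 0.5, 0.75),
                          minimum_fraction = 0.10) {
  structure(
    list(
      percentiles = deposition_percentiles(samples$exposure,
                                           percentile_fractions),
      patient_quantiles = patient_quantile_thresholds(samples,
                                                      patient_fractions),
      minimum_fraction = minimum_fraction
    ),
    class = "threshold_set"
  )
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("Deposition percentiles:\n")
  print(x$percentiles)
  cat("Patient-quantile thresholds:\n")
  print(x$patient_quantiles)
  invisible(x)
}

#' Substitute the season-start minimum threshold
#'
#' The lowest patient-quantile threshold starts only once the first
#' patient fraction has appeared and so can miss the early pollen season.
#' When the 25th deposition percentile lies below the 25%-patient
#' threshold, it is substituted as a new minimum threshold with a nominal
#' patient fraction of `minimum_fraction`, giving a four-threshold set;
#' otherwise the patient-quantile set is returned unchanged with a
#' warning.
#'
#' @param thresholds A [threshold_set()].
#'
#' @return A tibble with columns `patient_fraction`, `threshold`, `source`
#'   (`"deposition_percentile"` or `"patient_quantile"`), sorted by
#'   threshold.
#' @export
substitute_minimum <- function(thresholds) {
  if (!inherits(thresholds, "threshold_set")) {
    abort("`thresholds` must be a threshold_set")
  }
  pq <- arrange(thresholds$patient_quantiles, .data$fraction)
  base <- tibble(
    patient_fraction = pq$fraction, threshold = pq$deposition,
    source = "patient_quantile"
  )
  p25 <- thresholds$percentiles$deposition[
    thresholds$percentiles$fraction == 0.25
  ]
  if (length(p25) != 1) {
    warn("no 25th deposition percentile available; minimum not substituted")
    return(base)
  }
  if (p25 >= base$threshold[1]) {
    warn(paste0(
      "25th deposition percentile (", format(p25), ") is not below the ",
      "lowest patient-quantile threshold; minimum not substituted"
    ))
    return(base)
  }
  bind_rows(
    tibble(patient_fraction = thresholds$minimum_fraction, threshold = p25,
           source = "deposition_percentile"),
    base
  ) %>%
    arrange(.data$threshold)
}

#' Build the five-level pollen deposition grading scale
#'
#' Partitions the deposition axis into five half-open, right-closed levels
#' `(0, T1], (T1, T2], (T2, T3], (T3, T4], (T4, Inf)` from four strictly
#' increasing thresholds, and annotates each level with its
#' patient-increment band: the interval of `f'(x) = a / (x + c)` values
#' (additional patients per one-grain deposition increase) spanned by the
#' level. Bands are contiguous, non-overlapping and decreasing across
#' levels; band edges are the derivative evaluated at the thresholds.
#' Displayed band edges are truncated (not rounded) to two decimals; full
#' precision is kept in the numeric columns.
#'
#' @param thresholds Four strictly increasing positive deposition values,
#'   or the tibble returned by [substitute_minimum()].
#' @param fit A [dose_response_fit()] with `a > 0`.
#' @param round_thresholds Round thresholds half-up to integers for the
#'   published-style scale (default `TRUE`); full-precision thresholds are
#'   kept in the `threshold_raw` attribute.
#'
#' @return An object of class `grading_scale`: a five-row tibble with
#'   columns `level`, `lower`, `upper`, `interval`, `band_lower`,
#'   `band_upper`, `band` (the truncated display label).
#' @export
#' @examples
#' fit <- dose_response_fit(8.33, 8.53, -13.85)
#' build_scale(c(11, 27, 59, 119), fit)
build_scale <- function(thresholds, fit, round_thresholds = TRUE) {
  if (is.data.frame(thresholds)) thresholds <- thresholds$threshold
  raw <- as.numeric(thresholds)
  if (length(raw) != 4) abort("need exactly 4 thresholds")
  thr <- if (round_thresholds) round_half_up(raw) else raw
  if (any(thr <= 0) || any(diff(thr) <= 0)) {
    abort("thresholds must be strictly increasing and positive")
  }
  if (!inherits(fit, "dose_response_fit")) {
    abort("`fit` must be a dose_response_fit")
  }
  if (!is.na(fit$a) && fit$a <= 0) abort("`fit` must have a > 0")

  dthr <- derivative(fit, thr)
  lower <- c(0, thr)
  upper <- c(thr, Inf)
  band_lower <- c(dthr, 0)
  band_upper <- c(Inf, dthr)
  band <- c(
    sprintf("≥%.2f", truncate2(dthr[1])),
    sprintf("[%.2f, %.2f)", truncate2(dthr[2:4]), truncate2(dthr[1:3])),
    sprintf("<%.2f", truncate2(dthr[4]))
  )
  interval <- c(
    sprintf("(%g, %g]", lower[1:4], upper[1:4]),
    sprintf("(%g, ∞)", lower[5])
  )
  out <- tibble(
    level = 1:5, lower = lower, upper = upper, interval = interval,
    band_lower = band_lower, band_upper = band_upper, band = band
  )
  structure(out, class = c("grading_scale", class(out)),
            threshold_raw = raw, fit = fit)
}

#' @export
print.grading_scale <- function(x, ...) {
  cat("Pollen deposition grading scale",
      "(additional patients per one-grain increase)\n")
  df <- as.data.frame(x)[c("level", "interval", "band")]
  names(df) <- c("Level", "Deposition interval", "Patient increment")
  print(df, row.names = FALSE)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.grading_scale <- function(x, ...) as_tibble(x)

#' Classify deposition values into scale levels
#'
#' Maps each positive deposition value to the unique level whose half-open
#' interval contains it; an upper boundary belongs to the lower level
#' (right-closed convention). Zero and negative values are rejected: no
#' level's interval contains them.
#'
#' @param scale A [build_scale()] result.
#' @param x Deposition values (> 0, grains/1000 mm2).
#'
#' @return Integer vector of levels in 1..5.
#' @export
#' @examples
#' sc <- build_scale(c(11, 27, 59, 119), dose_response_fit(8.33, 8.53, -13.85))
#' classify(sc, c(11, 80, 1e6)) # 1, 4, 5
classify <- function(scale, x) {
  if (!inherits(scale, "grading_scale")) {
    abort("`scale` must be a grading_scale")
  }
  if (any(is.na(x)) || any(x <= 0)) {
    abort("deposition values must be positive (x = 0 lies outside the scale)")
  }
  thr <- scale$upper[1:4]
  as.integer(1L + rowSums(outer(x, thr, `>`)))
}

#' Classify a daily series into scale levels
#'
#' Per-date classification of a (windowed) city deposition series; dates
#' with missing or non-positive exposure get `NA` level.
#'
#' @param scale A [build_scale()] result.
#' @param exposure_series Tibble with columns `date`, `deposition`.
#'
#' @return A tibble with columns `date`, `exposure`, `level`.
#' @export
classify_series <- function(scale, exposure_series) {
  stop_if_not_cols(exposure_series, c("date", "deposition"),
                   "`exposure_series`")
  ok <- !is.na(exposure_series$deposition) & exposure_series$deposition > 0
  level <- rep(NA_integer_, nrow(exposure_series))
  if (any(ok)) level[ok] <- classify(scale, exposure_series$deposition[ok])
  tibble(date = exposure_series$date,
         exposure = exposure_series$deposition, level = level)
}

#' @exportS3Method ggplot2::autoplot
autoplot.grading_scale <- function(object, xmax = NULL, ...) {
  fit <- attr(object, "fit")
  thr <- object$upper[1:4]
  if (is.null(xmax)) xmax <- 2 * thr[4]
  grid <- tibble(x = seq(0.5, xmax, length.out = 400))
  grid$increment <- derivative(fit, grid$x)
  bands <- tibble(
    xmin = object$lower, xmax_ = pmin(object$upper, xmax),
    level = factor(object$level)
  )
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = bands,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax_,
                   ymin = -Inf, ymax = Inf, fill = .data$level),
      alpha = 0.25
    ) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$x, y = .data$increment)) +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::labs(
      x = "windowed pollen deposition (grains/1000 mm²)",
      y = "additional patients per grain", fill = "level"
    )
}
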