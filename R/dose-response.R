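#' Spearman rank correlation with significance flag
#'
#' Rank-based correlation with average-rank tie handling, reported together
#' with an (approximate) p-value and a significance flag at the 0.01 level,
#' the level conventionally footnoted in correlation tables of this kind.
#'
#' @param x,y Numeric vectors of equal length >= 3; ties allowed.
#'
#' @return A one-row tibble: `rho`, `p_value`, `n`, `significant_01`.
#' @export
#' @examples
#' spearman_rho(1:5, c(2, 1, 4, 3, 5))
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 3) abort("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) abort("`x` and `y` must be complete")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    abort("Spearman correlation undefined for a constant sequence")
  }
  rho <- cor(x, y, method = "spearman")
  p <- cor.test(x, y, method = "spearman", exact = FALSE)$p.value
  tibble(rho = rho, p_value = p, n = length(x), significant_01 = p < 0.01)
}

#' Build paired samples for each candidate exposure window
#'
#' Convenience wrapper producing the input of [select_window()]: for every
#' candidate window length it computes the trailing moving average of the
#' city series and selects the eligible pairs with the same season and
#' calendar exclusions.
#'
#' @param city_series Tibble with columns `date`, `deposition`.
#' @param patients Tibble with columns `date`, `patients`.
#' @param seasons,calendar Passed to [select_samples()].
#' @param candidates Integer vector of window lengths (default 1:4).
#'
#' @return A named list (names = window length) of paired-sample tibbles.
#' @export
windowed_samples <- function(city_series, patients, seasons = NULL,
                             calendar = NULL, candidates = 1:4) {
  if (any(candidates < 1)) abort("candidate windows must be >= 1")
  out <- purrr::map(candidates, function(w) {
    select_samples(moving_average(city_series, w), patients, seasons, calendar)
  })
  setNames(out, as.character(candidates))
}

#' Select the exposure window by Spearman rank correlation
#'
#' Computes the Spearman correlation between patient counts and windowed
#' deposition for each candidate window and chooses the window attaining
#' the maximum rho; ties are broken toward the shorter window (less
#' smoothing). A candidate with constant exposure is flagged and excluded
#' from the argmax rather than treated as fatal.
#'
#' @param samples_by_window Named list (names = window length in days) of
#'   paired-sample tibbles with columns `exposure`, `patients`, e.g. from
#'   [windowed_samples()]. Each candidate needs >= 3 pairs.
#'
#' @return An object of class `window_selection`: the correlation table
#'   (`window`, `rho`, `p_value`, `n`, `significant_01`, `flagged`) with
#'   attribute `chosen_window`. `tidy()` returns the table.
#' @export
select_window <- function(samples_by_window) {
  if (is.null(names(samples_by_window)) ||
      anyNA(suppressWarnings(as.integer(names(samples_by_window))))) {
    abort("`samples_by_window` must be named by integer window length")
  }
  tab <- purrr::map_dfr(names(samples_by_window), function(nm) {
    s <- samples_by_window[[nm]]
    stop_if_not_cols(s, c("exposure", "patients"), "each sample set")
    if (nrow(s) < 3) abort(sprintf("window %s has fewer than 3 pairs", nm))
    flagged <- length(unique(s$exposure)) < 2 ||
      length(unique(s$patients)) < 2
    if (flagged) {
      tibble(window = as.integer(nm), rho = NA_real_, p_value = NA_real_,
             n = nrow(s), significant_01 = NA, flagged = TRUE)
    } else {
      spearman_rho(s$exposure, s$patients) %>%
        mutate(window = as.integer(nm), flagged = FALSE) %>%
        select("window", "rho", "p_value", "n", "significant_01", "flagged")
    }
  }) %>%
    arrange(.data$window)
  usable <- filter(tab, !.data$flagged)
  if (nrow(usable) == 0) abort("all candidate windows have constant series")
  chosen <- min(usable$window[usable$rho == max(usable$rho)])
  structure(tab, class = c("window_selection", class(tab)),
            chosen_window = chosen)
}

#' @export
print.window_selection <- function(x, ...) {
  cat("Exposure-window selection (Spearman rho vs. patient counts)\n")
  print(as_tibble(x), ...)
  cat(sprintf("Chosen window: %d day(s)\n", chosen_window(x)))
  invisible(x)
}

#' Chosen window of a `window_selection`
#' @param selection A [select_window()] result.
#' @return Integer window length.
#' @export
chosen_window <- function(selection) attr(selection, "chosen_window")

#' @exportS3Method generics::tidy
tidy.window_selection <- function(x, ...) as_tibble(x)

#' Construct a shifted-logarithm dose-response fit object
#'
#' Represents the curve `f(x) = a * log(x + c) + d` mapping windowed pollen
#' deposition to the expected daily number of allergic patients. Usually
#' produced by [fit_log_curve()], but can be built directly from known
#' coefficients (e.g. a published fit) for prediction and scale building.
#'
#' @param a Scale (patients per log-unit).
#' @param c Shift (grains/1000 mm2, > 0).
#' @param d Offset (patients).
#' @param r_squared Coefficient of determination in `[0, 1]` (optional).
#' @param n Number of samples fitted (optional).
#' @param data Optional paired-sample tibble the fit was computed from.
#' @param degenerate Flag for a flat-response (a ~ 0) fit.
#'
#' @return An object of class `dose_response_fit`.
#' @export
#' @examples
#' fit <- dose_response_fit(a = 8.33, c = 8.53, d = -13.85)
#' predict(fit, c(0, 11))
#' derivative(fit, 11)
dose_response_fit <- function(a, c, d, r_squared = NA_real_, n = NA_integer_,
                              data = NULL, degenerate = FALSE) {
  if (!is.na(c) && c <= 0) abort("`c` must be > 0")
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    abort("`r_squared` must be in [0, 1]")
  }
  structure(
    list(a = a, c = c, d = d, r_squared = r_squared,
         n = as.integer(n), data = data, degenerate = degenerate),
    class = "dose_response_fit"
  )
}

# Closed-form inner least squares: given shift cc, regress y on log(x + cc).
# Returns c(a, d, sse).
profile_ls <- function(x, y, cc) {
  L <- log(x + cc)
  lbar <- mean(L)
  ybar <- mean(y)
  sxx <- sum((L - lbar)^2)
  if (sxx == 0) return(c(a = 0, d = ybar, sse = sum((y - ybar)^2)))
  a <- sum((L - lbar) * (y - ybar)) / sxx
  d <- ybar - a * lbar
  c(a = a, d = d, sse = sum((y - (a * L + d))^2))
}

#' Fit the shifted-logarithm dose-response curve
#'
#' Least-squares estimation of `(a, c, d)` in
#' `patients ~ a * log(exposure + c) + d`. The nonlinear shift `c` is
#' profiled over a coarse log-spaced grid (0.01 to 1000), the linear inner
#' problem for `(a, d)` solved in closed form at each grid point, and the
#' profile objective then polished by one-dimensional Brent refinement on
#' `log(c)` around the best grid point. This avoids the initialization sensitivity of a joint
#' nonlinear search; the inner problem is exactly linear given `c`.
#'
#' @param samples Paired-sample tibble with columns `exposure` (>= 0) and
#'   `patients`; >= 4 rows with >= 3 distinct exposures.
#' @param c_grid Profile grid for the shift parameter.
#'
#' @return A [dose_response_fit()] with `r_squared = 1 - SSE/SST` and the
#'   data attached. A constant patient series yields a degenerate flat fit
#'   (`a = 0`, `r_squared = 0`) with a warning.
#' @export
#' @examples
#' x <- seq(1, 200, length.out = 50)
#' y <- 8.33 * log(x + 8.53) - 13.85
#' s <- tibble::tibble(exposure = x, patients = y)
#' fit_log_curve(s)
fit_log_curve <- function(samples,
                          c_grid = 10^seq(-2, 3, length.out = 121)) {
  stop_if_not_cols(samples, c("exposure", "patients"), "`samples`")
  x <- samples$exposure
  y <- samples$patients
  if (length(x) < 4) abort("need at least 4 paired samples")
  if (any(x < 0)) abort("exposures must be >= 0")
  if (length(unique(x)) < 3) abort("need at least 3 distinct exposure values")

  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    warn("constant patient counts: degenerate flat fit (a = 0)")
    return(dose_response_fit(a = 0, c = c_grid[1], d = mean(y),
                             r_squared = 0, n = length(y),
                             data = as_tibble(samples), degenerate = TRUE))
  }

  sse_grid <- vapply(c_grid, function(cc) profile_ls(x, y, cc)[["sse"]],
                     numeric(1))
  i <- which.min(sse_grid)
  lo <- log(c_grid[max(1L, i - 1L)])
  hi <- log(c_grid[min(length(c_grid), i + 1L)])
  opt <- optimize(function(lc) profile_ls(x, y, exp(lc))[["sse"]],
                  interval = c(lo, hi), tol = 1e-10)
  cc <- exp(opt$minimum)
  est <- profile_ls(x, y, cc)
  dose_response_fit(
    a = est[["a"]], c = cc, d = est[["d"]],
    r_squared = max(0, 1 - est[["sse"]] / sst), n = length(y),
    data = as_tibble(samples), degenerate = abs(est[["a"]]) < 1e-10
  )
}

#' Predicted expected patient count
#'
#' Evaluates `f(x) = a * log(x + c) + d` of a fitted (or constructed)
#' dose-response curve. Strictly increasing in `x` when `a > 0`.
#'
#' @param object A [dose_response_fit()].
#' @param x Deposition values (grains/1000 mm2); requires `x + c > 0`.
#' @param ... Unused.
#' @return Numeric vector of expected patient counts.
#' @export
predict.dose_response_fit <- function(object, x, ...) {
  if (any(x <= -object$c)) abort("`x` must exceed -c (log domain)")
  object$a * log(x + object$c) + object$d
}

#' First derivative of the dose-response curve
#'
#' `f'(x) = a / (x + c)`: the expected additional patients per one-grain
#' increase in windowed deposition. Strictly positive and strictly
#' decreasing in `x` when `a > 0`, reflecting the slowing increase of
#' patient numbers at high deposition.
#'
#' @param fit A [dose_response_fit()].
#' @param x Deposition values (grains/1000 mm2); requires `x + c > 0`.
#' @return Numeric vector of patient increments per grain/1000 mm2.
#' @export
#' @examples
#' derivative(dose_response_fit(8.33, 8.53, -13.85), c(11, 27, 59, 119))
derivative <- function(fit, x) {
  if (!inherits(fit, "dose_response_fit")) {
    abort("`fit` must be a dose_response_fit")
  }
  if (any(x <= -fit$c)) abort("`x` must exceed -c (log domain)")
  fit$a / (x + fit$c)
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("Shifted-log dose-response fit: f(x) = a*ln(x + c) + d\n")
  cat(sprintf("  a = %.4g, c = %.4g, d = %.4g\n", x$a, x$c, x$d))
  if (!is.na(x$r_squared)) cat(sprintf("  R-squared = %.3f", x$r_squared))
  if (!is.na(x$n)) cat(sprintf("  (n = %d)", x$n))
  cat("\n")
  if (isTRUE(x$degenerate)) cat("  [degenerate flat fit]\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dose_response_fit <- function(x, ...) {
  tibble(term = c("a", "c", "d"), estimate = c(x$a, x$c, x$d))
}

#' @exportS3Method generics::glance
glance.dose_response_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, n = x$n, degenerate = isTRUE(x$degenerate))
}

#' @exportS3Method ggplot2::autoplot
autoplot.dose_response_fit <- function(object, ...) {
  if (is.null(object$data)) abort("fit carries no data to plot")
  xr <- range(object$data$exposure)
  grid <- tibble(exposure = seq(max(xr[1], 0), xr[2], length.out = 200))
  grid$patients <- predict(object, grid$exposure)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$exposure, y = .data$patients)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = grid, colour = "firebrick", linewidth = 1) +
    ggplot2::labs(
      x = "windowed pollen deposition (grains/1000 mm²)",
      y = "daily allergic patients",
      title = sprintf("f(x) = %.2f ln(x + %.2f) %+.2f",
                      object$a, object$c, object$d)
    )
}
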