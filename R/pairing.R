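#' Select eligible (exposure, patient count) sample pairs
#'
#' Builds the paired samples used for dose-response modelling. A date is
#' retained when it (i) falls within a detected pollen season, (ii) is not
#' a rest day or holiday, and (iii) has a non-missing value in both the
#' exposure and the patient series. Pairing is same-day: any exposure lag
#' is expressed through the moving-average window, not here.
#'
#' @param exposure_series Tibble with columns `date`, `deposition`
#'   (typically a [moving_average()] of the city series).
#' @param patients Tibble with columns `date`, `patients`.
#' @param seasons Season table from [detect_season()], or `NULL` to skip
#'   the in-season filter.
#' @param calendar Tibble with columns `date`, `is_rest_day`, or `NULL` to
#'   skip the rest-day filter.
#'
#' @return A tibble with columns `date`, `exposure`, `patients`, sorted by
#'   date. An empty result triggers a warning, not an error.
#' @export
select_samples <- function(exposure_series, patients, seasons = NULL,
                           calendar = NULL) {
  stop_if_not_cols(exposure_series, c("date", "deposition"),
                   "`exposure_series`")
  stop_if_not_cols(patients, c("date", "patients"), "`patients`")
  out <- exposure_series %>%
    select("date", exposure = "deposition") %>%
    inner_join(select(patients, "date", "patients"), by = "date") %>%
    filter(!is.na(.data$exposure), !is.na(.data$patients))
  if (!is.null(seasons)) {
    stop_if_not_cols(seasons, c("start_date", "end_date"), "`seasons`")
    in_season <- purrr::reduce(
      purrr::map(seq_len(nrow(seasons)), function(i) {
        out$date >= seasons$start_date[i] & out$date <= seasons$end_date[i]
      }),
      `|`, .init = rep(FALSE, nrow(out))
    )
    out <- out[in_season, ]
  }
  if (!is.null(calendar)) {
    stop_if_not_cols(calendar, c("date", "is_rest_day"), "`calendar`")
    rest <- calendar$date[calendar$is_rest_day]
    out <- filter(out, !.data$date %in% rest)
  }
  out <- arrange(out, .data$date)
  if (nrow(out) == 0) warn("no eligible paired samples after exclusions")
  out
}
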