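test_that("pollen generator respects degenerate and noiseless cases", {
  zero <- generate_pollen_series(
    season_shape(2015, 239, 10, total_grains = 0), n_stations = 2, seed = 1
  )
  expect_true(all(zero$deposition == 0))

  quiet <- generate_pollen_series(
    season_shape(2015, 239, 10, 3000, station_noise_cv = 0),
    n_stations = 4, seed = 1
  )
  per_day <- tapply(quiet$deposition, quiet$date, function(v) diff(range(v)))
  expect_true(all(per_day == 0))
  # conservation: city-mean annual sum equals the configured total
  city <- average_stations(quiet)
  expect_equal(sum(city$deposition), 3000, tolerance = 1e-10)
})

test_that("pollen generator validates its parameters", {
  expect_error(season_shape(2015, 239, spread_days = 0, total_grains = 10))
  expect_error(season_shape(2015, 239, 10, total_grains = -1))
  expect_error(generate_pollen_series(
    season_shape(2015, 239, 10, 10), n_stations = 0, seed = 1
  ))
})

test_that("noisy city-mean annual sums are unbiased for the configured total", {
  sums <- vapply(1:20, function(s) {
    rec <- generate_pollen_series(
      season_shape(2015, 239, 10, 3000, station_noise_cv = 0.2),
      n_stations = 4, seed = s
    )
    sum(average_stations(rec)$deposition)
  }, numeric(1))
  expect_lt(abs(mean(sums) - 3000) / 3000, 0.05)
})

test_that("generators are deterministic under a fixed seed", {
  a <- generate_pollen_series(season_shape(2015, 239, 10, 3000), 4, seed = 7)
  b <- generate_pollen_series(season_shape(2015, 239, 10, 3000), 4, seed = 7)
  expect_identical(a, b)

  s1 <- generate_study_dataset(study_design(), seed = 11)
  s2 <- generate_study_dataset(study_design(), seed = 11)
  expect_identical(s1$pollen, s2$pollen)
  expect_identical(s1$patients, s2$patients)

  d1 <- file.path(tempdir(), "study_a")
  d2 <- file.path(tempdir(), "study_b")
  p1 <- write_study_csv(s1, d1)
  p2 <- write_study_csv(s2, d2)
  for (i in seq_along(p1)) {
    expect_identical(readLines(p1[i]), readLines(p2[i]))
  }
})

test_that("patient counts follow the shifted-log mean of the windowed series", {
  # flat response: a = 0 makes every day's mean equal d
  flat <- generate_patient_counts(
    toy_series(rep(50, 10)), response_params(a = 0, d = 5, window_days = 1),
    seed = 1, noise = FALSE
  )
  expect_equal(flat$patients, rep(5, 10))

  # deterministic mode reproduces the curve at a known windowed exposure
  det <- generate_patient_counts(
    toy_series(rep(11, 5)), response_params(), seed = 1, noise = FALSE
  )
  expect_true(all(is.na(det$patients[1:2]))) # no full 3-day window yet
  expect_equal(det$patients[3:5], rep(8.33 * log(11 + 8.53) - 13.85, 3))

  # Poisson draws: sample mean within 3 standard errors of the curve mean
  n <- 1000
  mu <- 8.33 * log(11 + 8.53) - 13.85
  counts <- generate_patient_counts(
    toy_series(rep(11, n + 2)), response_params(), seed = 7
  )
  realized <- counts$patients[-(1:2)]
  expect_lt(abs(mean(realized) - mu), 3 * sqrt(mu / n))
})

test_that("realized counts match the curve mean across deposition deciles", {
  resp <- response_params()
  pooled <- dplyr::bind_rows(lapply(1:20, function(s) {
    rec <- generate_pollen_series(season_shape(2015, 239, 10, 3000), 4, seed = s)
    city <- average_stations(rec)
    counts <- generate_patient_counts(city, resp, seed = s + 500)
    xw <- moving_average(city, resp$window_days)$deposition
    tibble::tibble(xw = xw, y = counts$patients)
  })) |>
    dplyr::filter(!is.na(xw), xw > 1) # drop off-season near-zero mass
  pooled$decile <- dplyr::ntile(pooled$xw, 10)
  by_dec <- dplyr::summarise(
    dplyr::group_by(pooled, decile),
    obs = mean(y),
    expect = mean(pmax(0, resp$a * log(xw + resp$c) + resp$d)),
    se = sqrt(mean(pmax(0, resp$a * log(xw + resp$c) + resp$d)) / dplyr::n()),
    .groups = "drop"
  )
  expect_true(all(abs(by_dec$obs - by_dec$expect) < 4 * by_dec$se))
})

test_that("study dataset covers every station-day and validates years", {
  study <- generate_study_dataset(study_design(), seed = 2)
  days <- sum(vapply(2014:2016, function(y) {
    as.integer(as.Date(sprintf("%d-12-31", y)) - as.Date(sprintf("%d-01-01", y))) + 1L
  }, integer(1)))
  expect_identical(nrow(study$pollen), days * 4L)
  expect_identical(nrow(study$patients), days)
  expect_identical(nrow(study$calendar), days)

  expect_error(
    generate_study_dataset(
      study_design(holidays = as.Date("2020-10-01")), seed = 1
    ),
    "within the design years"
  )
})

test_that("noise-free default design recovers the generating 3-day window", {
  study <- generate_study_dataset(study_design(), seed = 3)
  city <- average_stations(study$pollen)
  patients <- generate_patient_counts(city, response_params(), seed = 1,
                                      noise = FALSE)
  bw <- suppressWarnings(windowed_samples(
    city, patients, detect_season(city), study$calendar
  ))
  expect_identical(chosen_window(select_window(bw)), 3L)
})
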