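test_that("deposition percentiles use linear order-statistic interpolation", {
  expect_equal(
    deposition_percentiles(1:5, 0.5)$deposition, 3
  )
  expect_equal(
    deposition_percentiles(1:4, 0.25)$deposition, 1.75
  )
  expect_equal(
    deposition_percentiles(rep(7, 10))$deposition, rep(7, 3)
  )
  p <- deposition_percentiles(rlnorm(100, 3, 1))
  expect_true(all(diff(p$deposition) >= 0))
  expect_error(deposition_percentiles(1:3), "at least 4")
})

test_that("patient-quantile thresholds scan the cumulative patient mass", {
  s <- tibble::tibble(exposure = c(10, 20, 30), patients = c(5, 5, 10))
  expect_equal(
    patient_quantile_thresholds(s, c(0.25, 0.5, 0.75))$deposition,
    c(10, 20, 30)
  )
  # all patients at one exposure: that value at every fraction
  mass <- tibble::tibble(exposure = c(5, 42, 80), patients = c(0, 12, 0))
  expect_equal(
    patient_quantile_thresholds(mass)$deposition, rep(42, 3)
  )
  expect_error(
    patient_quantile_thresholds(
      tibble::tibble(exposure = 1:3, patients = rep(0, 3))
    ),
    "> 0"
  )
})

test_that("patient-quantile thresholds match the brute-force scan oracle", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(3:20, 1)
    s <- tibble::tibble(
      exposure = round(runif(n, 0, 100), 1),
      patients = rpois(n, 6)
    )
    if (sum(s$patients) == 0) s$patients[1] <- 1
    for (q in c(0.1, 0.25, 0.5, 0.75, 0.9)) {
      expect_equal(
        patient_quantile_thresholds(s, q)$deposition,
        oracle_patient_quantile(s$exposure, s$patients, q)
      )
    }
  }
})

published_threshold_set <- function(p25 = 10.5) {
  structure(
    list(
      percentiles = tibble::tibble(fraction = 0.25, deposition = p25),
      patient_quantiles = tibble::tibble(
        fraction = c(0.25, 0.5, 0.75), deposition = c(27, 59, 119)
      ),
      minimum_fraction = 0.10
    ),
    class = "threshold_set"
  )
}

test_that("minimum substitution prepends the deposition percentile", {
  final <- substitute_minimum(published_threshold_set())
  expect_equal(final$threshold, c(10.5, 27, 59, 119))
  expect_equal(final$patient_fraction, c(0.10, 0.25, 0.5, 0.75))
  expect_equal(final$source[1], "deposition_percentile")

  # precondition branches: percentile not below the lowest quantile
  expect_warning(eq <- substitute_minimum(published_threshold_set(p25 = 27)),
                 "not below")
  expect_equal(eq$threshold, c(27, 59, 119))
  expect_warning(gt <- substitute_minimum(published_threshold_set(p25 = 40)),
                 "not below")
  expect_equal(gt$threshold, c(27, 59, 119))
})

test_that("threshold_set derives both series from paired samples", {
  set.seed(3)
  s <- tibble::tibble(exposure = rlnorm(80, 3, 1), patients = rpois(80, 8))
  ts <- threshold_set(s)
  expect_equal(ts$percentiles$deposition,
               unname(quantile(s$exposure, c(0.25, 0.5, 0.75))))
  expect_equal(ts$patient_quantiles$deposition,
               sapply(c(0.25, 0.5, 0.75),
                      function(q) oracle_patient_quantile(s$exposure,
                                                          s$patients, q)))
})

test_that("the five-level scale reproduces the published intervals and bands", {
  scale <- build_scale(c(10.5, 27, 59, 119), printed_fit())
  expect_equal(nrow(scale), 5)
  expect_equal(scale$lower, c(0, 11, 27, 59, 119)) # 10.5 rounds half-up to 11
  expect_equal(scale$upper, c(11, 27, 59, 119, Inf))
  expect_equal(scale$interval[1], "(0, 11]")
  expect_equal(scale$interval[5], "(119, ∞)")
  expect_equal(scale$band[1], "≥0.42")
  expect_equal(scale$band[2], "[0.23, 0.42)")
  expect_equal(scale$band[3], "[0.12, 0.23)")
  expect_equal(scale$band[4], "[0.06, 0.12)")
  expect_equal(scale$band[5], "<0.06")

  # bands tile contiguously; edges are derivative evaluations at thresholds
  expect_equal(scale$band_lower[1:4], scale$band_upper[2:5])
  expect_equal(scale$band_upper[2:5],
               derivative(printed_fit(), c(11, 27, 59, 119)))
  expect_true(all(diff(scale$band_lower) < 0))

  expect_error(build_scale(c(11, 27, 27, 119), printed_fit()), "increasing")
  expect_error(build_scale(c(11, 27, 59, 119),
                           dose_response_fit(-1, 1, 0)), "a > 0")
})

test_that("classification uses right-closed intervals and is monotone", {
  scale <- build_scale(c(11, 27, 59, 119), printed_fit())
  expect_identical(classify(scale, 11), 1L)   # boundary belongs below
  expect_identical(classify(scale, 80), 4L)
  expect_identical(classify(scale, 1e6), 5L)
  expect_error(classify(scale, 0), "positive")

  x <- sort(rlnorm(200, 3, 1.5))
  lv <- classify(scale, x)
  expect_true(all(diff(lv) >= 0))
  expect_true(all(lv %in% 1:5))

  series <- toy_series(c(5, NA, 80, 0, 200))
  cl <- classify_series(scale, series)
  expect_equal(cl$level, c(1L, NA, 4L, NA, 5L))
})
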