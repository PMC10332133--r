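# Independent brute-force oracles used to cross-check the implementation.

# Classical rank formula 1 - 6*sum(d^2)/(n(n^2-1)); exact when there are no
# ties, which is how it is used in the tests.
oracle_spearman <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Trailing k-day mean by explicit looping.
oracle_trailing_mean <- function(values, window) {
  n <- length(values)
  out <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    if (t >= window) out[t] <- mean(values[(t - window + 1):t])
  }
  out
}

# Deposition threshold at patient fraction q by an explicit cumulative scan
# over exposure-sorted pairs.
oracle_patient_quantile <- function(exposure, patients, q) {
  o <- order(exposure)
  exposure <- exposure[o]
  patients <- patients[o]
  total <- sum(patients)
  acc <- 0
  for (i in seq_along(exposure)) {
    acc <- acc + patients[i]
    if (acc >= q * total) return(exposure[i])
  }
  exposure[length(exposure)]
}

# Small daily series builder.
toy_series <- function(values, start = as.Date("2015-08-01")) {
  tibble::tibble(date = start + seq_along(values) - 1, deposition = values)
}

printed_fit <- function() dose_response_fit(a = 8.33, c = 8.53, d = -13.85)
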