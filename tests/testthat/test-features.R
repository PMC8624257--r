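# Time-domain feature extractors.

test_that("hand-computed values on the [1, -2, 3] window", {
  w <- matrix(rep(c(1, -2, 3), 8), nrow = 8, byrow = TRUE)
  expect_equal(amplitude_features(w, "IEMG"), rep(6, 8))
  expect_equal(amplitude_features(w, "MAV"), rep(2, 8))
  expect_equal(amplitude_features(w, "SSI"), rep(14, 8))
  expect_equal(amplitude_features(w, "WL"), rep(8, 8))
  expect_equal(amplitude_features(w, "VAR"), rep(7, 8))  # uncentered, /(N-1)
  expect_equal(amplitude_features(w, "AAC"), rep(8 / 3, 8))
})

test_that("constant windows collapse the difference features", {
  w <- matrix(-1.5, 8, 50)
  expect_equal(amplitude_features(w, "RMS"), rep(1.5, 8))
  expect_equal(amplitude_features(w, "MAV"), rep(1.5, 8))
  expect_equal(amplitude_features(w, "WL"), rep(0, 8))
  expect_equal(amplitude_features(w, "AAC"), rep(0, 8))
  expect_equal(amplitude_features(w, "DASDV"), rep(0, 8))
})

test_that("threshold feature semantics on the alternating window", {
  w <- matrix(rep(c(1, -1, 1, -1), 8), nrow = 8, byrow = TRUE)
  expect_equal(threshold_features(w, "ZC", 0.5), rep(3, 8))
  expect_equal(threshold_features(w, "WAMP", 0.5), rep(3, 8))
  expect_equal(threshold_features(w, "MYOP", 0.5), rep(1, 8))

  # unreachable thresholds zero every count; SSC thresholds a product of
  # differences (mV^2), so its unreachable proxy is the square
  big <- 2 * max(abs(w)) + 1
  for (f in c("ZC", "WAMP", "MYOP"))
    expect_equal(threshold_features(w, f, big), rep(0, 8))
  expect_equal(threshold_features(w, "SSC", (2 * max(abs(w)))^2 + 1),
               rep(0, 8))

  # boundary semantics at threshold 0 on a constant signal
  cw <- matrix(2, 8, 10)
  expect_equal(threshold_features(cw, "ZC", 0), rep(0, 8))
  expect_equal(threshold_features(cw, "WAMP", 0), rep(9, 8))
  expect_error(threshold_features(cw, "WAMP", -1), "non-negative")
})

test_that("amplitude features obey the scaling laws", {
  set.seed(31)
  for (rep_i in 1:20) {
    x <- matrix(rnorm(8 * 60), 8)
    k <- runif(1, 0.5, 4)
    for (f in c("IEMG", "MAV", "RMS", "WL", "AAC", "DASDV"))
      expect_equal(amplitude_features(k * x, f),
                   k * amplitude_features(x, f), tolerance = 1e-10)
    for (f in c("VAR", "SSI"))
      expect_equal(amplitude_features(k * x, f),
                   k^2 * amplitude_features(x, f), tolerance = 1e-10)
    for (f in c("ZC", "WAMP", "MYOP", "SSC"))
      expect_equal(threshold_features(k * x, f, 0),
                   threshold_features(x, f, 0))
  }
})

test_that("count features stay integer-valued within their ranges", {
  set.seed(32)
  N <- 40
  for (rep_i in 1:25) {
    x <- matrix(rnorm(8 * N, sd = 2), 8)
    thr <- runif(1, 0, 3)
    zc <- threshold_features(x, "ZC", thr)
    wamp <- threshold_features(x, "WAMP", thr)
    ssc <- threshold_features(x, "SSC", thr)
    myop <- threshold_features(x, "MYOP", thr)
    expect_true(all(zc == round(zc) & zc >= 0 & zc <= N - 1))
    expect_true(all(wamp == round(wamp) & wamp >= 0 & wamp <= N - 1))
    expect_true(all(ssc == round(ssc) & ssc >= 0 & ssc <= N - 2))
    expect_true(all(myop >= 0 & myop <= 1))
  }
})

test_that("LOG clamps exact zeros instead of overflowing", {
  w <- matrix(c(0, 1, 2, 0, 3, 1), 1)
  w8 <- matrix(rep(as.numeric(w), 8), nrow = 8, byrow = TRUE)
  v <- amplitude_features(w8, "LOG")
  expect_true(all(is.finite(v)))
  expect_true(all(v > 0))
})

test_that("the R-factor threshold grid matches its definition", {
  tc <- threshold_grid(3.3, 0, 10, 0.5)
  expect_length(tc$thresholds, 21L)
  expect_equal(max(tc$thresholds), 33.0)
  expect_equal(unique(round(diff(tc$thresholds), 10)), 1.65)

  expect_equal(threshold_grid(5, 0, 0, 1)$thresholds, 0)
  expect_equal(threshold_grid(1, 1, 3, 1)$thresholds, c(1, 2, 3))
  expect_error(threshold_grid(-1), "positive")
  expect_error(threshold_grid(1, 5, 2), "R_min")
  expect_error(threshold_grid(1, 0, 1, 0), "R_step")
})

test_that("MAVSLP differences consecutive windows and drops the first", {
  expect_equal(as.numeric(mavslp(matrix(c(2, 5, 4), ncol = 1))), c(3, -1))
  m <- matrix(rnorm(12), 4, 3)
  expect_equal(mavslp(m[nrow(m):1, ]), -mavslp(m)[nrow(mavslp(m)):1, ])
  expect_warning(out <- mavslp(matrix(1, 1, 3)), "at least 2")
  expect_equal(nrow(out), 0L)
})

test_that("AR estimation recovers known processes", {
  set.seed(33)
  x <- as.numeric(stats::filter(rnorm(5000), 0.5, method = "recursive"))
  m1 <- ar_model(x, 1)
  expect_lt(abs(m1$coefficients[1] - 0.5), 0.05)
  m2 <- ar_model(x, 2)
  expect_lt(abs(m2$coefficients[2]), 0.1)

  wn <- rnorm(5000)
  expect_lt(abs(ar_model(wn, 1)$coefficients[1]), 0.1)

  expect_warning(z <- ar_model(rep(0, 100), 3), "degenerate")
  expect_equal(z$coefficients, rep(0, 3))
  expect_equal(z$cepstral, rep(0, 3))
  expect_error(ar_model(rnorm(5), 10), "exceed")
  expect_error(ar_model(rnorm(100), 11), "order")
})

test_that("cepstral recursion matches its identities and the FFT oracle", {
  expect_identical(cepstral_from_ar(0.5), -0.5)
  expect_equal(cepstral_from_ar(numeric(0)), numeric(0))
  expect_equal(cepstral_from_ar(c(0, 0, 0)), c(0, 0, 0))

  a <- c(0.5, -0.2)
  cc <- cepstral_from_ar(a)
  expect_equal(cc[1], -0.5)
  expect_equal(cc[2], 0.325)  # -a2 - (1 - 1/2) a1 c1
  expect_equal(cc, oracle_cepstrum_fft(a), tolerance = 1e-8)

  set.seed(34)
  for (p in c(3, 5)) {
    a <- rnorm(p, sd = 0.15)
    expect_equal(cepstral_from_ar(a), oracle_cepstrum_fft(a),
                 tolerance = 1e-7)
  }
})

test_that("feature matrices have the documented shapes and labels", {
  ds <- tiny_dataset(c("rest", "spread"), n_sessions = 2, trial_duration = 5)
  fm <- extract_features(ds, "MAV")
  expect_equal(nrow(fm), 2 * 2 * 476)
  expect_length(attr(fm, "value_cols"), 8L)
  expect_named(fm, c("subject_id", "session_id", "posture_id",
                     "window_start", sprintf("ch%d_MAV", 1:8)))

  hud <- extract_features(ds, "HUDGINS", shift_ms = 250)
  expect_length(attr(hud, "value_cols"), 32L)
  du <- extract_features(ds, "DU", shift_ms = 250)
  expect_length(attr(du, "value_cols"), 48L)
  ar3 <- extract_features(ds, "AR", order = 3, shift_ms = 250)
  expect_length(attr(ar3, "value_cols"), 24L)

  mav <- extract_features(ds, "MAV", shift_ms = 250)
  slp <- extract_features(ds, "MAVSLP", shift_ms = 250)
  n_trials <- nrow(ds$manifest)
  expect_equal(nrow(slp), nrow(mav) - n_trials)
  expect_false(any(slp$window_start == 0))
})

test_that("mixed sampling rates are rejected", {
  ds <- tiny_dataset(c("rest", "spread"), n_sessions = 2, trial_duration = 1)
  ds$recordings[[1]]$sampling_rate <- 1000
  expect_error(extract_features(ds, "MAV"), "mixed sampling rates")
})
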