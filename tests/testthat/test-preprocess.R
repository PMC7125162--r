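make_sensor <- function(t, x, y = x, z = x, subject = "S01") {
  tibble::tibble(subject_id = subject, timestamp_s = t,
                 ax_g = x, ay_g = y, az_g = z)
}

demod_amp <- function(y, t, f) {
  mid <- t > max(t) * 0.25 & t < max(t) * 0.75
  2 * Mod(mean(y[mid] * exp(-2i * pi * f * t[mid])))
}

test_that("constant input (pure gravity) is removed by the band-pass", {
  fs <- 62.5
  t <- seq(0, 60, by = 1 / fs)
  out <- bandpass(make_sensor(t, rep(1, length(t))))
  mid <- t > 10 & t < 50
  expect_lt(max(abs(out$ax_g[mid])), 1e-3)
})

test_that("in-band and out-of-band tones match the analytic magnitude response", {
  fs <- 62.5
  t <- seq(0, 120, by = 1 / fs)
  # 5 Hz passes essentially unchanged, at zero lag
  out5 <- bandpass(make_sensor(t, sin(2 * pi * 5 * t)))
  a5 <- demod_amp(out5$ax_g, t, 5)
  expect_equal(a5, bandpass_gain(5), tolerance = 0.02)
  cc <- stats::ccf(out5$ax_g, sin(2 * pi * 5 * t), lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # 30 Hz is attenuated below the analytic bound
  out30 <- bandpass(make_sensor(t, sin(2 * pi * 30 * t)))
  expect_lt(demod_amp(out30$ax_g, t, 30), bandpass_gain(30))
})

test_that("filtering twice attenuates out-of-band tones strictly more than once", {
  fs <- 62.5
  t <- seq(0, 120, by = 1 / fs)
  for (f in c(0.05, 25)) {
    once <- bandpass(make_sensor(t, sin(2 * pi * f * t)))
    twice <- bandpass(once)
    expect_lt(demod_amp(twice$ax_g, t, f), demod_amp(once$ax_g, t, f))
  }
})

test_that("a too-low Nyquist rate is rejected", {
  t <- seq(0, 10, by = 1 / 30)
  expect_error(bandpass(make_sensor(t, sin(t))), "Nyquist")
})

test_that("resampling is the identity on data already on the 60 Hz grid", {
  t <- seq(0, 10 - 1 / 60, by = 1 / 60)
  x <- rnorm(length(t))
  out <- resample_to_grid(make_sensor(t, x))
  expect_equal(out$timestamp_s, t, tolerance = 1e-12)
  expect_equal(out$ax_g, x, tolerance = 1e-12)
})

test_that("linear interpolation reproduces affine signals exactly", {
  fs <- 62.5
  t <- seq(0, 30, by = 1 / fs)
  out <- resample_to_grid(make_sensor(t, 2 + 0.5 * t))
  expect_equal(out$ax_g, 2 + 0.5 * out$timestamp_s, tolerance = 1e-9)
})

test_that("60 seconds of 62.5 Hz input resamples to exactly 3600 samples", {
  fs <- 62.5
  t <- seq(0, 60, by = 1 / fs)   # includes the right edge
  out <- resample_to_grid(make_sensor(t, sin(t)))
  minute0 <- out$timestamp_s < 60 - 1e-9
  expect_equal(sum(minute0), 3600)
})

test_that("windowing keeps annotated active minutes and logs the rest by reason", {
  # 10-minute session on the exact 60 Hz grid: minutes 3 and 7 unannotated,
  # minute 5 flat (annotated); expected 7 kept, {unannotated: 2, low_variance: 1}
  withr::local_seed(1)
  t <- seq(0, 600 - 1 / 60, by = 1 / 60)
  x <- rnorm(length(t), 0, 0.2)
  flat <- t >= 300 & t < 360
  sensor <- make_sensor(t, ifelse(flat, 0, x),
                        ifelse(flat, 0, rnorm(length(t), 0, 0.2)),
                        ifelse(flat, 0, rnorm(length(t), 0, 0.2)))
  ann <- tibble::tibble(subject_id = "S01", minute_index = 0:9,
                        motor_state = c(1L, 1L, 1L, NA, 1L, 1L, 1L, NA, 1L, 1L),
                        brady_item = 1L, dys_item = 0L, activity = "sitting")
  w <- window_and_label(sensor, ann)
  expect_equal(nrow(w), 7)
  log <- discard_log(w)
  expect_equal(sum(log$reason == "unannotated"), 2)
  expect_equal(sum(log$reason == "low_variance"), 1)
  expect_equal(log$minute[log$reason == "low_variance"], 5L)
  # every kept window is exactly 3600 x 3 with the minute's label
  expect_true(all(vapply(w$values, function(v) all(dim(v) == c(3600, 3)),
                         logical(1))))
  expect_true(all(w$label == 1))
})

test_that("a white-noise minute just above the variance threshold is kept", {
  withr::local_seed(2)
  t <- seq(0, 60 - 1 / 60, by = 1 / 60)
  sensor <- make_sensor(t, rnorm(3600, 0, sqrt(0.02)),
                        rnorm(3600, 0, sqrt(0.02)), rnorm(3600, 0, sqrt(0.02)))
  ann <- tibble::tibble(subject_id = "S01", minute_index = 0L,
                        motor_state = 0L, brady_item = 3L, dys_item = 0L,
                        activity = "sitting")
  w <- window_and_label(sensor, ann)
  expect_equal(nrow(w), 1)
})

test_that("kept plus discarded minutes account for every session minute", {
  cohort <- tiny_cohort(3, 12, seed = 41)
  w <- preprocess_cohort(cohort)
  log <- discard_log(w)
  for (s in unique(cohort$annotations$subject_id)) {
    n_session <- sum(cohort$annotations$subject_id == s)
    n_kept <- sum(w$subject_id == s)
    n_disc <- sum(log$subject_id == s)
    expect_equal(n_kept + n_disc, n_session)
  }
})

test_that("filter-then-resample and resample-then-filter agree on band-limited signals", {
  withr::local_seed(3)
  fs <- 62.5
  n <- round(120 * fs)
  dt <- (1 / fs) * (1 + runif(n, -0.02, 0.02))
  t <- cumsum(dt) - dt[1]
  x <- sin(2 * pi * 1 * t) + 0.5 * sin(2 * pi * 3 * t) + 0.3 * sin(2 * pi * 7 * t)
  sensor <- make_sensor(t, x)
  a <- resample_to_grid(bandpass(sensor))
  b <- bandpass(resample_to_grid(sensor))
  joined <- dplyr::inner_join(a, b, by = c("subject_id", "timestamp_s"))
  mid <- joined$timestamp_s > 20 & joined$timestamp_s < 100
  rms_diff <- sqrt(mean((joined$ax_g.x[mid] - joined$ax_g.y[mid])^2))
  rms_sig <- sqrt(mean(joined$ax_g.x[mid]^2))
  expect_lt(rms_diff / rms_sig, 0.02)
})

test_that("window containers round-trip through the CSV layout", {
  dir <- withr::local_tempdir()
  w <- preprocess_cohort(tiny_cohort(2, 5, seed = 43))
  write_windows(w, dir)
  back <- read_windows(dir)
  expect_equal(back$subject_id, w$subject_id)
  expect_equal(back$label, w$label)
  expect_equal(back$values, w$values)
  expect_equal(discard_log(back), discard_log(w))
})
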