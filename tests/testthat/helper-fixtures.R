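# Fixtures built in code: tiny cohorts, spectrally separable window sets,
# hand-sized networks for gradient checks.

# Class signatures with every movement component silenced (gravity + noise
# only, or pure gravity when noise is also 0).
zero_signatures <- function() {
  sig <- motorstate:::default_class_signatures()
  sig$OFF$voluntary_amp_g <- 0
  sig$OFF$tremor_amp_g <- 0
  sig$OFF$tremor_burst_prob <- 0
  sig$ON$voluntary_amp_g <- 0
  sig$DYS$dyskinesia_amp_g <- 0
  sig$gait$amp_g <- 0
  sig$gait$harmonic_amp_g <- 0
  sig
}

# A window_set of synthetic one-minute windows whose three classes live in
# disjoint spectral bands (and, optionally, on distinct axes), linearly
# separable in band power. Labels cycle 0,1,2 within each subject.
make_separable_windows <- function(n_subjects = 3, per_class = 5,
                                   rate_hz = 60, axis_cue = FALSE,
                                   noise_sd = 0.05, seed = 42) {
  withr::local_seed(seed)
  t <- seq(0, 60 - 1 / rate_hz, by = 1 / rate_hz)
  freqs <- c(5, 1.5, 3)      # OFF tremor-like, ON voluntary, DYS mid-band
  amps <- c(0.4, 0.4, 0.8)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    minute <- 0L
    for (rep in seq_len(per_class)) {
      for (cls in 0:2) {
        f <- freqs[cls + 1] * runif(1, 0.92, 1.08)
        sig <- amps[cls + 1] * sin(2 * pi * f * t + runif(1, 0, 2 * pi))
        v <- matrix(rnorm(length(t) * 3, 0, noise_sd), ncol = 3)
        if (axis_cue) {
          v[, cls + 1] <- v[, cls + 1] + sig
        } else {
          dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
          v <- v + outer(sig, dir)
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject_id = sprintf("F%02d", s), minute = minute,
          start_s = minute * 60, label = as.numeric(cls),
          activity = "sitting", origin = "original", values = list(v))
        minute <- minute + 1L
      }
    }
  }
  motorstate:::new_window_set(dplyr::bind_rows(rows))
}

# Windows that are separable in RAW input space: each class is a fixed
# deterministic template (fixed phase) plus small noise, so distance- and
# margin-based learners on the flattened 10,800-vector can separate them.
# (Random-phase spectral fixtures are separable in band power but look
# nearly orthogonal to raw-input methods.)
make_template_windows <- function(n_subjects = 4, per_class = 5,
                                  rate_hz = 60, noise_sd = 0.05, seed = 44) {
  withr::local_seed(seed)
  t <- seq(0, 60 - 1 / rate_hz, by = 1 / rate_hz)
  templates <- list(
    cbind(0.4 * sin(2 * pi * 5 * t), 0.2 * cos(2 * pi * 5 * t), 0),
    cbind(0.4 * sin(2 * pi * 1.5 * t), 0, 0.3 * sin(2 * pi * 1.5 * t)),
    cbind(0.8 * sin(2 * pi * 3 * t), 0.5 * sin(2 * pi * 3 * t + 1), 0))
  rows <- list()
  for (s in seq_len(n_subjects)) {
    minute <- 0L
    for (rep in seq_len(per_class)) {
      for (cls in 0:2) {
        v <- templates[[cls + 1]] +
          matrix(rnorm(length(t) * 3, 0, noise_sd), ncol = 3)
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject_id = sprintf("T%02d", s), minute = minute,
          start_s = minute * 60, label = as.numeric(cls),
          activity = "sitting", origin = "original", values = list(v))
        minute <- minute + 1L
      }
    }
  }
  motorstate:::new_window_set(dplyr::bind_rows(rows))
}

# Mean spectral power of a window (summed over axes) within a band, via the
# raw periodogram.
band_power <- function(v, band, rate_hz = 60) {
  n <- nrow(v)
  freqs <- (seq_len(n %/% 2)) * rate_hz / n
  sel <- freqs >= band[1] & freqs <= band[2]
  sum(vapply(1:3, function(j) {
    p <- Mod(stats::fft(v[, j] - mean(v[, j])))^2 / n
    sum(p[seq_len(n %/% 2)][sel])
  }, numeric(1)))
}

# Hand-sized network (2 conv blocks + 2 fc layers) for gradient checking.
tiny_net <- function(seed = 1) {
  withr::local_seed(seed)
  spec <- list(input_channels = 2L, input_len = 12L,
               kernels = c(4L, 3L), strides = c(2L, 1L))
  # lengths: 12 -> 5 -> 3
  ch <- c(3L, 4L)
  cin <- c(2L, 3L)
  blocks <- lapply(1:2, function(i) {
    fan <- cin[i] * spec$kernels[i]
    list(W = matrix(rnorm(ch[i] * fan, 0, 0.5), nrow = ch[i]),
         b = rnorm(ch[i], 0, 0.1),
         gamma = runif(ch[i], 0.5, 1.5), beta = rnorm(ch[i], 0, 0.1),
         rmean = rep(0, ch[i]), rvar = rep(1, ch[i]))
  })
  flat <- 3L * 4L
  fc <- list(
    list(W = matrix(rnorm(5 * flat, 0, 0.3), nrow = 5), b = rnorm(5, 0, 0.1)),
    list(W = matrix(rnorm(3 * 5, 0, 0.3), nrow = 3), b = rnorm(3, 0, 0.1)))
  list(params = list(blocks = blocks, fc = fc), spec = spec)
}

# Tiny simulated cohort for fast integration tests.
tiny_cohort <- function(n_subjects = 3, minutes = 8, seed = 7, ...) {
  simulate_cohort(sim_config(n_subjects = n_subjects,
                             session_minutes_range = rep(minutes, 2),
                             seed = seed, ...))
}
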