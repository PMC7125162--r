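#' Configuration for the synthetic wrist-IMU cohort simulator
#'
#' Builds the parameter set from which [simulate_cohort()] generates raw
#' tri-axial wrist acceleration streams plus minute-level expert annotations.
#' Defaults emulate the recording conditions of a shadowed free-living study
#' day: a 30-subject cohort, multi-hour sessions (mean around 7.5 h),
#' a nominal 62.5 Hz sampling rate with timing jitter, minute-level motor
#' states (OFF/ON/DYS coded 0/1/2) following a persistent Markov chain, and
#' class-conditioned motion signatures built from amplitude-modulated
#' sinusoids: OFF carries little voluntary movement plus intermittent
#' 4–6 Hz rest-tremor bursts, ON moderate 0.5–3 Hz voluntary movement, and
#' DYS high-amplitude irregular 1–4 Hz oscillation. Walking adds a gait
#' harmonic; a slowly drifting gravity vector and white sensor noise are
#' always present. Severity items are coupled to the state by a fixed
#' monotone map plus bounded integer noise so the downstream correlation
#' analysis has a recoverable ground truth.
#'
#' @param n_subjects Number of subjects in the cohort.
#' @param session_minutes_range Length-2 integer vector; each subject's
#'   session length in minutes is drawn uniformly from this range.
#' @param sampling_rate_hz Nominal sensor sampling rate (Hz).
#' @param jitter_frac Per-interval uniform timing jitter as a fraction of the
#'   nominal period (`0.02` = +/-2 %).
#' @param class_transition 3x3 row-stochastic per-minute transition matrix
#'   over the states OFF, ON, DYS.
#' @param class_signatures Named list of per-class spectral parameters; see
#'   the default for the expected fields (band limits in Hz, amplitudes in G).
#' @param activity_transition Row-stochastic per-minute transition matrix
#'   over the eight activity categories.
#' @param gravity_drift_scale Magnitude of the orientation random walk of the
#'   gravity direction (per sqrt(second)).
#' @param noise_sd_g White sensor noise standard deviation in G.
#' @param dropout_prob Probability that a minute is unrecorded (no samples).
#' @param unannotated_prob Probability that a recorded minute has no motor
#'   state annotation.
#' @param clip_g Sensor clipping range in G (accelerations saturate at
#'   +/- `clip_g`).
#' @param initial_state Fixed initial motor state (0/1/2) for every subject,
#'   or NULL (default) to draw it from the chain's stationary distribution.
#' @param seed RNG seed; identical configurations give bit-identical cohorts.
#' @return A `sim_config` list, validated.
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 2, session_minutes_range = c(5, 8), seed = 1)
#' cohort <- simulate_cohort(cfg)
sim_config <- function(n_subjects = 30,
                       session_minutes_range = c(120, 780),
                       sampling_rate_hz = 62.5,
                       jitter_frac = 0.02,
                       class_transition = default_class_transition(),
                       class_signatures = default_class_signatures(),
                       activity_transition = default_activity_transition(),
                       gravity_drift_scale = 0.02,
                       noise_sd_g = 0.02,
                       dropout_prob = 0.05,
                       unannotated_prob = 0.05,
                       clip_g = 8,
                       initial_state = NULL,
                       seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    session_minutes_range = as.integer(session_minutes_range),
    sampling_rate_hz = sampling_rate_hz,
    jitter_frac = jitter_frac,
    class_transition = class_transition,
    class_signatures = class_signatures,
    activity_transition = activity_transition,
    gravity_drift_scale = gravity_drift_scale,
    noise_sd_g = noise_sd_g,
    dropout_prob = dropout_prob,
    unannotated_prob = unannotated_prob,
    clip_g = clip_g,
    initial_state = if (is.null(initial_state)) NULL else
      as.integer(initial_state),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_subjects, "subjects,",
      paste(x$session_minutes_range, collapse = "-"), "min sessions,",
      x$sampling_rate_hz, "Hz, seed", x$seed, "\n")
  invisible(x)
}

# Sticky chain with a prescribed stationary distribution:
# P = stay * I + (1 - stay) * 1 pi', whose stationary law is exactly pi.
sticky_chain <- function(pi, stay, labels) {
  pi <- pi / sum(pi)
  n <- length(pi)
  m <- (1 - stay) * matrix(pi, n, n, byrow = TRUE) + stay * diag(n)
  dimnames(m) <- list(labels, labels)
  m
}

# Minute-level motor-state persistence with the three-state mix observed in
# free-living daytime recordings of fluctuating patients
# (roughly OFF 27 %, ON 41 %, DYS 32 %).
default_class_transition <- function() {
  sticky_chain(c(0.27, 0.41, 0.32), stay = 0.90, labels = names(MOTOR_STATES))
}

# Activity mix of a shadowed daytime session: mostly sitting, substantial
# walking, little motor testing, almost no sleep.
default_activity_transition <- function() {
  pi <- c(sitting = 0.574, lying = 0.084, walking = 0.185, standing = 0.053,
          sleeping = 0.005, testing = 0.012, other = 0.034, unknown = 0.053)
  sticky_chain(pi[ACTIVITIES], stay = 0.90, labels = ACTIVITIES)
}

# Amplitudes in G chosen so that wrist movement is physiologic (~0.1-0.6 G)
# and the 0.01 G^2 low-variance screen removes roughly the fifth of minutes
# it removes on real recordings (still, bradykinetic minutes without tremor).
default_class_signatures <- function() {
  list(
    OFF = list(voluntary_band_hz = c(0.5, 3), voluntary_amp_g = 0.08,
               tremor_band_hz = c(4, 6), tremor_amp_g = 0.35,
               tremor_burst_prob = 0.8),
    ON  = list(voluntary_band_hz = c(0.5, 3), voluntary_amp_g = 0.30),
    DYS = list(dyskinesia_band_hz = c(1, 4), dyskinesia_amp_g = 0.60,
               n_components = 4),
    gait = list(band_hz = c(1.8, 2.2), amp_g = 0.25, harmonic_amp_g = 0.12),
    activity_scale = c(sitting = 0.9, lying = 0.7, walking = 1, standing = 1,
                       sleeping = 0.35, testing = 1.2, other = 1, unknown = 1)
  )
}

validate_sim_config <- function(cfg) {
  assert_that(cfg$n_subjects >= 0, "n_subjects must be non-negative")
  assert_that(length(cfg$session_minutes_range) == 2 &&
                cfg$session_minutes_range[1] <= cfg$session_minutes_range[2] &&
                cfg$session_minutes_range[1] >= 1,
              "session_minutes_range must be an increasing pair of minutes >= 1")
  assert_that(cfg$sampling_rate_hz > 2 * 20,
              "sampling_rate_hz must exceed twice the 20 Hz filter cutoff")
  for (nm in c("class_transition", "activity_transition")) {
    m <- cfg[[nm]]
    assert_that(is.matrix(m) && nrow(m) == ncol(m),
                paste(nm, "must be a square matrix"))
    assert_that(all(m >= 0) && all(abs(rowSums(m) - 1) < 1e-9),
                paste(nm, "rows must be non-negative and sum to 1 (within 1e-9)"))
  }
  if (!is.null(cfg$initial_state)) {
    assert_that(cfg$initial_state %in% 0:2, "initial_state must be 0, 1 or 2")
  }
  probs <- c(cfg$jitter_frac, cfg$dropout_prob, cfg$unannotated_prob)
  assert_that(all(probs >= 0 & probs <= 1), "probabilities must lie in [0, 1]")
  assert_that(cfg$noise_sd_g >= 0 && cfg$gravity_drift_scale >= 0 && cfg$clip_g > 0,
              "noise, drift and clip parameters must be non-negative")
  invisible(cfg)
}

# Simulate one Markov chain path of length n from a row-stochastic matrix.
markov_path <- function(trans, n, init = NULL) {
  k <- nrow(trans)
  out <- integer(n)
  out[1] <- if (is.null(init)) sample.int(k, 1) else init
  if (n > 1) {
    for (i in 2:n) out[i] <- sample.int(k, 1, prob = trans[out[i - 1], ])
  }
  out
}

# Sum of amplitude-modulated sinusoids projected on random 3D directions.
# t: sample times within the minute; returns an n x 3 matrix.
am_sinusoids <- function(t, band, amp, n_components = 2) {
  out <- matrix(0, length(t), 3)
  for (j in seq_len(n_components)) {
    f <- runif(1, band[1], band[2])
    phase <- runif(1, 0, 2 * pi)
    fam <- runif(1, 0.1, 0.3)
    env <- 0.5 + 0.5 * sin(2 * pi * fam * t + runif(1, 0, 2 * pi))
    dir <- rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    s <- amp * env * sin(2 * pi * f * t + phase)
    out <- out + outer(s, dir)
  }
  out
}

# Class-conditioned motion signature for one minute (n x 3, in G).
class_signature_signal <- function(t, state, activity, sig) {
  scale <- sig$activity_scale[[activity]] %||% 1
  x <- matrix(0, length(t), 3)
  if (state == 0L) {              # OFF: sparse movement + tremor bursts
    s <- sig$OFF
    x <- x + am_sinusoids(t, s$voluntary_band_hz, s$voluntary_amp_g * scale, 2)
    if (runif(1) < s$tremor_burst_prob) {
      tc <- runif(1, min(t), max(t))
      w <- runif(1, 5, 15)
      env <- exp(-((t - tc) / w)^2)
      f <- runif(1, s$tremor_band_hz[1], s$tremor_band_hz[2])
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      x <- x + outer(s$tremor_amp_g * env * sin(2 * pi * f * t + runif(1, 0, 2 * pi)), dir)
    }
  } else if (state == 1L) {       # ON: moderate voluntary movement
    s <- sig$ON
    x <- x + am_sinusoids(t, s$voluntary_band_hz, s$voluntary_amp_g * scale, 3)
  } else {                        # DYS: high-amplitude irregular oscillation
    s <- sig$DYS
    x <- x + am_sinusoids(t, s$dyskinesia_band_hz, s$dyskinesia_amp_g * scale,
                          s$n_components)
  }
  if (activity == "walking") {
    g <- sig$gait
    f <- runif(1, g$band_hz[1], g$band_hz[2])
    ph <- runif(1, 0, 2 * pi)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    x <- x + outer(g$amp_g * sin(2 * pi * f * t + ph) +
                     g$harmonic_amp_g * sin(2 * pi * 2 * f * t + ph), dir)
  }
  x
}

# Severity items coupled to the motor state by a fixed monotone map plus
# bounded integer-rounded noise. brady is high in OFF and 0 in DYS; dys is
# 0 in OFF/ON and positive in DYS (choreatic dyskinesia defines DYS).
severity_items <- function(states) {
  n <- length(states)
  brady_base <- c(3, 1, 0)[states + 1L]
  brady <- clamp(brady_base + round(rnorm(n, 0, 0.5)), 0, 4)
  brady[states == 2L] <- 0L
  dys <- integer(n)
  in_dys <- states == 2L
  dys[in_dys] <- clamp(3 + round(rnorm(sum(in_dys), 0, 0.5)), 1, 4)
  list(brady = as.integer(brady), dys = as.integer(dys))
}

#' Simulate a synthetic cohort of wrist-IMU recordings with annotations
#'
#' Generates, per subject, a raw timestamped tri-axial acceleration stream
#' (irregular sampling around the nominal rate, session gaps where minutes
#' dropped out, values clipped to the sensor range) and a minute-level
#' annotation track (motor state 0/1/2 or missing, bradykinesia item 0–4,
#' dyskinesia item 0–4, activity category). Identical configurations produce
#' bit-identical cohorts.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `imu_cohort`: a list with tibbles `sensor`
#'   (columns `subject_id`, `timestamp_s`, `ax_g`, `ay_g`, `az_g`) and
#'   `annotations` (columns `subject_id`, `minute_index`, `motor_state`,
#'   `brady_item`, `dys_item`, `activity`), plus the config as attribute.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  old <- .Random.seed_exists()
  on.exit(old(), add = TRUE)
  set.seed(config$seed)

  sensor_list <- vector("list", config$n_subjects)
  annot_list <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    subj <- sprintf("S%02d", i)
    sim <- simulate_subject(config)
    sensor_list[[i]] <- dplyr::mutate(sim$sensor, subject_id = subj, .before = 1)
    annot_list[[i]] <- dplyr::mutate(sim$annotations, subject_id = subj, .before = 1)
  }
  empty_sensor <- tibble::tibble(subject_id = character(),
                                 timestamp_s = numeric(), ax_g = numeric(),
                                 ay_g = numeric(), az_g = numeric())
  empty_ann <- tibble::tibble(subject_id = character(),
                              minute_index = integer(),
                              motor_state = integer(), brady_item = integer(),
                              dys_item = integer(), activity = character())
  cohort <- structure(
    list(sensor = dplyr::bind_rows(c(list(empty_sensor), sensor_list)),
         annotations = dplyr::bind_rows(c(list(empty_ann), annot_list))),
    config = config,
    class = "imu_cohort"
  )
  cohort
}

# Save/restore the global RNG state so simulation is seed-local.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    saved <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", saved, envir = globalenv())
  } else {
    function() suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }
}

simulate_subject <- function(cfg) {
  n_min <- if (cfg$session_minutes_range[1] == cfg$session_minutes_range[2]) {
    cfg$session_minutes_range[1]
  } else {
    sample(seq(cfg$session_minutes_range[1], cfg$session_minutes_range[2]), 1)
  }
  init <- if (is.null(cfg$initial_state)) {
    # start from the chain's stationary law so state frequencies are
    # stationary from the first minute
    sample.int(3, 1, prob = pmax(stationary_distribution(cfg$class_transition), 0))
  } else cfg$initial_state + 1L
  states <- markov_path(cfg$class_transition, n_min, init = init) - 1L
  acts <- ACTIVITIES[markov_path(cfg$activity_transition, n_min)]
  items <- severity_items(states)
  recorded <- rbinom(n_min, 1, 1 - cfg$dropout_prob) == 1
  annotated <- rbinom(n_min, 1, 1 - cfg$unannotated_prob) == 1

  fs <- cfg$sampling_rate_hz
  period <- 1 / fs
  # gravity direction random walk, shared across the session
  g_dir <- c(0, 0, 1)

  # Contiguous runs of recorded minutes become continuous sample streams
  # filling each run right up to its final minute boundary: with <= 2 %
  # interval jitter the last raw sample then always falls past the last
  # 60 Hz grid point of the minute, so resampling covers it completely.
  runs <- rle(recorded)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1
  seg_list <- list()
  for (r in seq_along(runs$values)) {
    mins <- run_start[r]:run_end[r]
    if (!runs$values[r]) {
      g_dir <- drift_gravity(g_dir, cfg$gravity_drift_scale, 60 * length(mins))
      next
    }
    t0 <- (mins[1] - 1) * 60
    t_end <- run_end[r] * 60
    n_samp <- ceiling((t_end - t0) / period) + 2
    dt <- period * (1 + runif(n_samp, -cfg$jitter_frac, cfg$jitter_frac))
    ts <- t0 + cumsum(dt) - dt[1]
    ts <- ts[ts < t_end]
    minute_of <- floor(ts / 60) + 1L
    move <- matrix(0, length(ts), 3)
    for (m in mins) {
      idx <- which(minute_of == m)
      if (length(idx)) {
        move[idx, ] <- class_signature_signal(ts[idx], states[m], acts[m],
                                              cfg$class_signatures)
      }
    }
    gmat <- gravity_track(g_dir, cfg$gravity_drift_scale, ts - ts[1])
    g_dir <- gmat[nrow(gmat), ]
    noise <- matrix(rnorm(length(ts) * 3, 0, cfg$noise_sd_g), ncol = 3)
    acc <- clamp(move + gmat + noise, -cfg$clip_g, cfg$clip_g)
    seg_list[[length(seg_list) + 1]] <- tibble::tibble(
      timestamp_s = ts, ax_g = acc[, 1], ay_g = acc[, 2], az_g = acc[, 3])
  }
  sensor <- if (length(seg_list)) dplyr::bind_rows(seg_list) else
    tibble::tibble(timestamp_s = numeric(), ax_g = numeric(),
                   ay_g = numeric(), az_g = numeric())

  annotations <- tibble::tibble(
    minute_index = seq_len(n_min) - 1L,
    motor_state = ifelse(annotated, states, NA_integer_),
    brady_item = ifelse(annotated, items$brady, NA_integer_),
    dys_item = ifelse(annotated, items$dys, NA_integer_),
    activity = ifelse(annotated, acts, "unknown")
  )
  annotations$motor_state <- as.integer(annotations$motor_state)
  annotations$brady_item <- as.integer(annotations$brady_item)
  annotations$dys_item <- as.integer(annotations$dys_item)
  list(sensor = sensor, annotations = annotations)
}

# Unit gravity direction after a random walk over `seconds` seconds.
drift_gravity <- function(dir, scale, seconds) {
  if (scale == 0) return(dir)
  step <- rnorm(3, 0, scale * sqrt(seconds))
  d <- dir + step
  d / sqrt(sum(d^2))
}

# Per-sample gravity vectors (n x 3, 1 G magnitude) along a random walk.
gravity_track <- function(dir0, scale, t_rel) {
  n <- length(t_rel)
  if (scale == 0) return(matrix(rep(dir0, each = n), ncol = 3))
  dt <- diff(c(0, t_rel))
  steps <- matrix(rnorm(n * 3, 0, scale), ncol = 3) * sqrt(pmax(dt, 0))
  walk <- apply(steps, 2, cumsum)
  if (n == 1) walk <- matrix(walk, ncol = 3)
  d <- sweep(walk, 2, dir0, `+`)
  d / sqrt(rowSums(d^2))
}

#' @export
print.imu_cohort <- function(x, ...) {
  ns <- length(unique(x$sensor$subject_id))
  cat("<imu_cohort>", ns, "subjects,",
      nrow(x$sensor), "samples,", nrow(x$annotations), "annotated minutes\n")
  invisible(x)
}

#' Stationary distribution of a row-stochastic transition matrix
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalized to
#' sum to 1. Used to check that simulated state frequencies match the
#' configured Markov chain.
#'
#' @param trans Row-stochastic square matrix.
#' @return Numeric vector of stationary probabilities.
#' @export
stationary_distribution <- function(trans) {
  e <- eigen(t(trans))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}
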