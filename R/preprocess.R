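#' Specification of the zero-phase band-pass filter
#'
#' The raw acceleration streams are mildly filtered before windowing: a
#' 0.1 Hz lower cutoff removes sensor drift and the gravity component, a
#' 20 Hz upper cutoff removes high-frequency noise. The filter is applied
#' forward and backward (zero phase, no group delay). It is realized as a
#' cascade of an order-`order` Butterworth high-pass at `low_cut_hz` and an
#' order-`order` Butterworth low-pass at `high_cut_hz`; with cutoffs this far
#' apart the cascade's magnitude response is the band-pass product response,
#' and the cascade stays numerically stable at any sampling rate (a direct
#' 8th-order band-pass polynomial does not).
#'
#' @param low_cut_hz Lower cutoff (Hz), default 0.1.
#' @param high_cut_hz Upper cutoff (Hz), default 20.
#' @param order Butterworth order per section and per direction, default 4.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(low_cut_hz = 0.1, high_cut_hz = 20, order = 4) {
  assert_that(low_cut_hz > 0 && high_cut_hz > low_cut_hz,
              "need 0 < low_cut_hz < high_cut_hz")
  assert_that(order >= 1, "order must be >= 1")
  structure(list(low_cut_hz = low_cut_hz, high_cut_hz = high_cut_hz,
                 order = as.integer(order)),
            class = "filter_spec")
}

#' Analytic squared magnitude response of the zero-phase band-pass
#'
#' Closed-form amplitude gain of the forward-backward cascade at frequency
#' `f_hz`: the product of the high-pass and low-pass Butterworth power
#' responses (one factor of |H|^2 per section because the signal passes each
#' section twice).
#'
#' @param f_hz Frequency or frequencies in Hz.
#' @param spec A [filter_spec()].
#' @return Amplitude gain(s) in (0, 1].
#' @export
bandpass_gain <- function(f_hz, spec = filter_spec()) {
  n2 <- 2 * spec$order
  (1 / (1 + (spec$low_cut_hz / f_hz)^n2)) *
    (1 / (1 + (f_hz / spec$high_cut_hz)^n2))
}

# Assign contiguous-segment ids: a new segment starts wherever the gap
# between consecutive timestamps exceeds `gap_s` seconds.
segment_ids <- function(timestamps, gap_s = 0.5) {
  if (length(timestamps) == 0) return(integer(0))
  cumsum(c(TRUE, diff(timestamps) > gap_s))
}

#' Zero-phase band-pass filter a raw recording
#'
#' Filters each axis of each contiguous session segment independently (the
#' filter never runs across recording gaps). Segments too short to filter
#' (fewer than `3 * order + 1` samples) are dropped and logged.
#'
#' @param sensor Tibble with columns `subject_id`, `timestamp_s`, `ax_g`,
#'   `ay_g`, `az_g` (an `imu_cohort$sensor` or a single recording).
#' @param spec A [filter_spec()].
#' @param gap_s Gap (seconds) above which the stream is split into segments.
#' @return The filtered tibble (same columns), with a `dropped_segments`
#'   attribute listing segments too short to filter.
#' @export
bandpass <- function(sensor, spec = filter_spec(), gap_s = 0.5) {
  stopifnot(all(c("subject_id", "timestamp_s", "ax_g", "ay_g", "az_g")
                %in% names(sensor)))
  dropped <- list()
  out <- sensor |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(df, key) {
      assert_that(!is.unsorted(df$timestamp_s, strictly = TRUE),
                  "timestamps must be strictly increasing within a subject")
      df$`..seg` <- segment_ids(df$timestamp_s, gap_s)
      pieces <- split(df, df$`..seg`)
      kept <- lapply(pieces, function(p) {
        n <- nrow(p)
        rate <- 1 / stats::median(diff(p$timestamp_s))
        if (n < 3 * spec$order + 1) {
          dropped[[length(dropped) + 1]] <<- tibble::tibble(
            subject_id = key$subject_id, start_s = p$timestamp_s[1],
            n_samples = n, reason = "too_short")
          return(NULL)
        }
        assert_that(spec$high_cut_hz < rate / 2,
                    sprintf("upper cutoff %.3g Hz is not below Nyquist (%.3g Hz)",
                            spec$high_cut_hz, rate / 2))
        hp <- signal::butter(spec$order, spec$low_cut_hz / (rate / 2), type = "high")
        lp <- signal::butter(spec$order, spec$high_cut_hz / (rate / 2), type = "low")
        for (col in c("ax_g", "ay_g", "az_g")) {
          # removing the segment mean first shortens the start-up transient
          # of the very low cutoff; the mean lies in the stop band anyway
          x <- p[[col]] - mean(p[[col]])
          p[[col]] <- signal::filtfilt(lp, signal::filtfilt(hp, x))
        }
        p
      })
      dplyr::bind_rows(kept) |> dplyr::select(-"..seg")
    }) |>
    dplyr::ungroup()
  attr(out, "dropped_segments") <- dplyr::bind_rows(dropped)
  out
}

#' Resample a recording onto a uniform grid by linear interpolation
#'
#' Each contiguous segment is interpolated onto the grid `k / rate_hz`
#' seconds (aligned to the session clock, so minute boundaries fall on grid
#' points). A full 60 s segment yields exactly `60 * rate_hz` samples.
#'
#' @param sensor Filtered tibble as produced by [bandpass()].
#' @param rate_hz Target rate; default 60 Hz.
#' @param gap_s Gap (seconds) above which the stream is split into segments.
#' @return Tibble with the same columns on the uniform grid.
#' @export
resample_to_grid <- function(sensor, rate_hz = 60, gap_s = 0.5) {
  period <- 1 / rate_hz
  sensor |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(df, key) {
      assert_that(!is.unsorted(df$timestamp_s, strictly = TRUE),
                  "timestamps must be strictly increasing within a subject")
      df$`..seg` <- segment_ids(df$timestamp_s, gap_s)
      pieces <- split(df, df$`..seg`)
      res <- lapply(pieces, function(p) {
        if (nrow(p) < 2) return(NULL)
        t0 <- ceiling(p$timestamp_s[1] / period - 1e-9) * period
        t1 <- p$timestamp_s[nrow(p)]
        if (t0 > t1) return(NULL)
        grid <- seq(t0, t1 + 1e-9, by = period)
        grid <- grid[grid <= t1 + 1e-9]
        tibble::tibble(
          timestamp_s = grid,
          ax_g = approx(p$timestamp_s, p$ax_g, grid, rule = 2)$y,
          ay_g = approx(p$timestamp_s, p$ay_g, grid, rule = 2)$y,
          az_g = approx(p$timestamp_s, p$az_g, grid, rule = 2)$y)
      })
      dplyr::bind_rows(res)
    }) |>
    dplyr::ungroup()
}

#' Cut a resampled recording into labelled one-minute windows
#'
#' Minute `k` covers `[60k, 60(k+1))` seconds (half-open, 0-based). A minute
#' becomes a candidate window only if all `60 * rate_hz` grid samples are
#' present; incomplete minutes are logged as `dropout`. Candidate minutes
#' without a motor-state annotation are discarded as `unannotated`; minutes
#' whose per-axis variances sum to less than `variance_threshold` (in G^2,
#' computed on the filtered 60 Hz data) are discarded as `low_variance`.
#' Kept windows carry the minute's integer motor state as a float label plus
#' the annotated activity.
#'
#' @param sensor Filtered, resampled tibble ([bandpass()] then
#'   [resample_to_grid()]).
#' @param annotations Annotation tibble (see [simulate_cohort()]).
#' @param rate_hz Grid rate, default 60 Hz.
#' @param variance_threshold Minimum sum of per-axis variances, default 0.01.
#' @return A `window_set`: a tibble with columns `subject_id`, `minute`,
#'   `start_s`, `label`, `activity`, `origin` (`"original"`) and the
#'   list-column `values` (each a 3600 x 3 numeric matrix), with the
#'   discard bookkeeping in `attr(, "discard_log")` (columns `subject_id`,
#'   `minute`, `reason`).
#' @export
window_and_label <- function(sensor, annotations, rate_hz = 60,
                             variance_threshold = 0.01) {
  n_expect <- as.integer(60 * rate_hz)
  period <- 1 / rate_hz
  discards <- list()
  rows <- list()
  for (s in unique(sensor$subject_id)) {
    sub <- sensor[sensor$subject_id == s, ]
    ann <- annotations[annotations$subject_id == s, ]
    minute <- floor(sub$timestamp_s / 60 + 1e-9)
    counts <- table(minute)
    all_minutes <- if (nrow(ann)) ann$minute_index else
      as.integer(names(counts))
    for (m in sort(unique(c(all_minutes, as.integer(names(counts)))))) {
      n_here <- if (as.character(m) %in% names(counts))
        counts[[as.character(m)]] else 0L
      if (n_here < n_expect) {
        discards[[length(discards) + 1]] <- tibble::tibble(
          subject_id = s, minute = as.integer(m), reason = "dropout")
        next
      }
      a <- ann[ann$minute_index == m, ]
      state <- if (nrow(a)) a$motor_state[1] else NA_integer_
      if (is.na(state)) {
        discards[[length(discards) + 1]] <- tibble::tibble(
          subject_id = s, minute = as.integer(m), reason = "unannotated")
        next
      }
      idx <- which(minute == m)
      vals <- cbind(sub$ax_g[idx], sub$ay_g[idx], sub$az_g[idx])
      if (sum(apply(vals, 2, var)) < variance_threshold) {
        discards[[length(discards) + 1]] <- tibble::tibble(
          subject_id = s, minute = as.integer(m), reason = "low_variance")
        next
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = s, minute = as.integer(m), start_s = m * 60,
        label = as.numeric(state),
        activity = if (nrow(a)) a$activity[1] else "unknown",
        origin = "original",
        values = list(unname(vals)))
    }
  }
  windows <- if (length(rows)) dplyr::bind_rows(rows) else empty_window_set()
  log <- if (length(discards)) dplyr::bind_rows(discards) else
    tibble::tibble(subject_id = character(), minute = integer(),
                   reason = character())
  new_window_set(windows, discard_log = log)
}

empty_window_set <- function() {
  tibble::tibble(subject_id = character(), minute = integer(),
                 start_s = numeric(), label = numeric(),
                 activity = character(), origin = character(),
                 values = list())
}

new_window_set <- function(tbl, discard_log = NULL) {
  attr(tbl, "discard_log") <- discard_log %||% attr(tbl, "discard_log") %||%
    tibble::tibble(subject_id = character(), minute = integer(),
                   reason = character())
  class(tbl) <- unique(c("window_set", class(tbl)))
  tbl
}

#' Discard bookkeeping of a window set
#'
#' @param windows A `window_set` from [window_and_label()].
#' @return Tibble with one row per discarded minute and its reason
#'   (`dropout`, `unannotated` or `low_variance`).
#' @export
discard_log <- function(windows) {
  attr(windows, "discard_log") %||%
    tibble::tibble(subject_id = character(), minute = integer(),
                   reason = character())
}

#' Run the full preprocessing chain on a cohort
#'
#' [bandpass()] at the native rate, [resample_to_grid()] to 60 Hz, then
#' [window_and_label()]. Filtering precedes resampling.
#'
#' @inheritParams window_and_label
#' @param cohort An `imu_cohort`.
#' @param spec A [filter_spec()].
#' @return A `window_set` (see [window_and_label()]).
#' @export
preprocess_cohort <- function(cohort, spec = filter_spec(), rate_hz = 60,
                              variance_threshold = 0.01) {
  cohort$sensor |>
    bandpass(spec) |>
    resample_to_grid(rate_hz) |>
    window_and_label(cohort$annotations, rate_hz, variance_threshold)
}
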