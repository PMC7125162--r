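# expCNN: the expected value of the class index under the softmax triple,
# an ordinal motor-state score from 0 (OFF) via 1 (ON) to 2 (DYS), plus
# LOESS-smoothed per-subject day curves.

#' Expected-value aggregation of softmax outputs (expCNN)
#'
#' `expCNN = 0 * p(OFF) + 1 * p(ON) + 2 * p(DYS)`, computed per prediction
#' row. Inputs must be normalized probability triples.
#'
#' @param predictions Tibble with columns `p_off`, `p_on`, `p_dys` (e.g.
#'   from [predict.motor_ensemble()]).
#' @param tolerance Allowed deviation of each row sum from 1.
#' @return The tibble with an `expcnn` column appended (values in `[0, 2]`).
#' @export
#' @examples
#' expcnn(tibble::tibble(p_off = 0.2, p_on = 0.3, p_dys = 0.5))$expcnn  # 1.3
expcnn <- function(predictions, tolerance = 1e-6) {
  stopifnot(all(c("p_off", "p_on", "p_dys") %in% names(predictions)))
  p <- as.matrix(predictions[, c("p_off", "p_on", "p_dys")])
  if (any(p < -tolerance) || any(abs(rowSums(p) - 1) > tolerance)) {
    rlang::abort("softmax rows must be non-negative and sum to 1",
                 class = "motorstate_error")
  }
  dplyr::mutate(predictions, expcnn = unname(p[, 2] + 2 * p[, 3]))
}

#' LOESS-smooth a time series without bridging recording gaps
#'
#' Locally weighted polynomial regression (tricube weights) evaluated at the
#' input times, fitted separately on each contiguous run of points:
#' smoothing never bridges gaps longer than `max_gap_min` minutes. Runs too
#' short to fit (`< degree + 2` points) pass through unsmoothed. Output is
#' clipped to `clip`.
#'
#' @param time Numeric times (seconds).
#' @param value Numeric values.
#' @param span LOESS span as a fraction of the run's points, default 0.25.
#' @param degree Local polynomial degree, default 2.
#' @param max_gap_min Gap (minutes) above which runs are smoothed
#'   independently, default 10.
#' @param clip Length-2 clipping range, or NULL for none. Default `c(0, 2)`.
#' @return Numeric vector of smoothed values, same length and order.
#' @export
loess_smooth <- function(time, value, span = 0.25, degree = 2,
                         max_gap_min = 10, clip = c(0, 2)) {
  assert_that(span > 0 && span <= 1, "span must lie in (0, 1]")
  assert_that(degree %in% 0:2, "degree must be 0, 1 or 2")
  stopifnot(length(time) == length(value))
  if (length(time) == 0) return(numeric(0))
  ord <- order(time)
  t_s <- time[ord]; v_s <- value[ord]
  seg <- cumsum(c(TRUE, diff(t_s) > max_gap_min * 60))
  out <- numeric(length(t_s))
  for (g in unique(seg)) {
    idx <- which(seg == g)
    if (length(idx) < degree + 2) {
      out[idx] <- v_s[idx]
      next
    }
    # span must cover enough points for the local polynomial
    n <- length(idx)
    eff_span <- max(span, min(1, (degree + 2) / n + 1e-9))
    # short runs can make the local design near-singular; loess then falls
    # back to a pseudoinverse, which is the behaviour we want — quietly
    fit <- suppressWarnings(
      loess(y ~ x, data = data.frame(x = t_s[idx], y = v_s[idx]),
            span = eff_span, degree = degree,
            family = "gaussian", surface = "direct"))
    out[idx] <- suppressWarnings(
      predict(fit, newdata = data.frame(x = t_s[idx])))
  }
  if (!is.null(clip)) out <- clamp(out, clip[1], clip[2])
  out[order(ord)]
}

#' Per-subject expCNN day curves with LOESS smoothing
#'
#' Computes [expcnn()] if not already present and appends a LOESS-smoothed
#' value per prediction time, per subject.
#'
#' @param predictions Prediction tibble with `subject_id`, `start_s` and
#'   either `expcnn` or the three softmax columns.
#' @inheritParams loess_smooth
#' @return A `motor_day_curves` tibble: `subject_id`, `start_s`, `expcnn`,
#'   `smoothed`, sorted by subject and time.
#' @export
day_curve <- function(predictions, span = 0.25, degree = 2,
                      max_gap_min = 10, clip = c(0, 2)) {
  if (!"expcnn" %in% names(predictions)) predictions <- expcnn(predictions)
  out <- predictions |>
    dplyr::select("subject_id", "start_s", "expcnn") |>
    dplyr::arrange(.data$subject_id, .data$start_s) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(smoothed = loess_smooth(.data$start_s, .data$expcnn,
                                          span = span, degree = degree,
                                          max_gap_min = max_gap_min,
                                          clip = clip)) |>
    dplyr::ungroup()
  class(out) <- unique(c("motor_day_curves", class(out)))
  attr(out, "span") <- span
  out
}

#' Per-subject mean and spread of the unsmoothed expCNN score
#'
#' The descriptive summary used to characterize a patient's day: the
#' arithmetic mean and the population (divide-by-n) standard deviation of
#' the raw expCNN points. A mean near 0 with low spread reads as a
#' predominantly bradykinetic day; a high mean as a predominantly
#' dyskinetic one; a large spread flags a severe fluctuator.
#'
#' @param curves A tibble with `subject_id` and `expcnn` columns (e.g. from
#'   [day_curve()] or [expcnn()]).
#' @return Tibble `subject_id`, `mean_expcnn`, `sd_expcnn`, `n`.
#' @export
subject_summary <- function(curves) {
  curves |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(mean_expcnn = mean(.data$expcnn),
                     sd_expcnn = pop_sd(.data$expcnn),
                     n = dplyr::n(), .groups = "drop")
}

#' Plot per-subject expCNN day curves
#'
#' Unsmoothed expCNN points plus the LOESS day curve, one facet per
#' subject — the package's day-profile visualization.
#'
#' @param object A `motor_day_curves` tibble from [day_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.motor_day_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$start_s / 3600)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$expcnn), alpha = 0.3, size = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), linewidth = 0.8,
                       colour = "#2166ac") +
    ggplot2::facet_wrap(~subject_id) +
    ggplot2::scale_y_continuous(limits = c(0, 2),
                                breaks = 0:2, labels = c("OFF", "ON", "DYS")) +
    ggplot2::labs(x = "time (h)", y = "expCNN") +
    ggplot2::theme_minimal()
}

#' Write per-subject day-curve CSVs
#'
#' One `daycurve_<subject>.csv` per subject (columns `start_s`, `expcnn`,
#' `smoothed`) plus `daycurve_summary.json` with each subject's mean and
#' population SD.
#'
#' @param curves A `motor_day_curves` tibble.
#' @param dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
write_day_curves <- function(curves, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (s in unique(curves$subject_id)) {
    p <- file.path(dir, sprintf("daycurve_%s.csv", s))
    readr::write_csv(dplyr::select(curves[curves$subject_id == s, ],
                                   "start_s", "expcnn", "smoothed"), p)
    paths <- c(paths, p)
  }
  sm <- subject_summary(curves)
  jp <- file.path(dir, "daycurve_summary.json")
  jsonlite::write_json(sm, jp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, jp))
}
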