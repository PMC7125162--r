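# Training-set augmentation: uniform-SO(3) rotations emulate arbitrary wrist
# poses; sliding windows with float-label interpolation multiply the sample
# count roughly twelvefold on gap-free data.

#' Draw a rotation matrix uniformly from SO(3)
#'
#' Quaternion method: four iid standard normals, normalized, converted to a
#' rotation matrix. The result is orthonormal with determinant +1 and the
#' distribution is the Haar (uniform) measure on SO(3).
#'
#' @param n Number of rotations to draw.
#' @return A 3 x 3 matrix if `n = 1`, else a list of such matrices. Uses the
#'   current RNG stream; seed with `set.seed()` for reproducibility.
#' @export
random_rotation <- function(n = 1) {
  draws <- lapply(seq_len(n), function(i) {
    q <- rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           nrow = 3, byrow = TRUE)
  })
  if (n == 1) draws[[1]] else draws
}

check_rotation <- function(rotation) {
  assert_that(is.matrix(rotation) && all(dim(rotation) == c(3, 3)),
              "rotation must be a 3 x 3 matrix")
  assert_that(max(abs(crossprod(rotation) - diag(3))) < 1e-9,
              "rotation must be orthonormal (R'R = I within 1e-9)")
  assert_that(abs(det(rotation) - 1) < 1e-9,
              "rotation must be proper (determinant +1)")
  invisible(rotation)
}

#' Rotate the acceleration vectors of one or more windows
#'
#' Applies a fixed rotation to every 3-vector row of each window's values.
#' Labels, activities and subjects are unchanged; the `origin` field gains
#' `"rotated"` (so `"original"` becomes `"rotated"` and `"slid"` becomes
#' `"slid+rotated"`).
#'
#' @param windows A `window_set` tibble.
#' @param rotation A 3 x 3 proper orthonormal matrix, or a list with one
#'   matrix per window.
#' @return The rotated `window_set`.
#' @export
rotate_window <- function(windows, rotation) {
  rots <- if (is.list(rotation)) rotation else
    rep(list(rotation), nrow(windows))
  assert_that(length(rots) == nrow(windows),
              "need one rotation, or one per window")
  lapply(rots, check_rotation)
  windows$values <- purrr::map2(windows$values, rots,
                                function(v, r) v %*% t(r))
  windows$origin <- dplyr::case_match(windows$origin,
                                      "original" ~ "rotated",
                                      "slid" ~ "slid+rotated",
                                      .default = windows$origin)
  new_window_set(windows)
}

#' Sliding-window augmentation with float-label interpolation
#'
#' For every pair of gap-free consecutive kept minutes (labels L1, L2), new
#' one-minute windows are extracted from the 120 s span at offsets
#' `stride_s, 2 * stride_s, ..., 60 - stride_s` seconds; the window at
#' offset t gets the interpolated float label `(1 - t/60) L1 + (t/60) L2`.
#' Offsets 0 and 60 duplicate the original windows and are not re-emitted,
#' so M gap-free consecutive minutes yield `M + (M - 1) * (60/stride_s - 1)`
#' distinct windows in total.
#'
#' @param windows A `window_set` of original windows.
#' @param stride_s Stride in seconds; must divide 60. Default 5.
#' @param rate_hz Samples per second in the windows (60).
#' @return A `window_set` containing the originals plus the slid windows
#'   (`origin = "slid"`).
#' @export
sliding_windows <- function(windows, stride_s = 5, rate_hz = 60) {
  assert_that(stride_s > 0 && 60 %% stride_s == 0,
              "stride_s must be a positive divisor of 60")
  if (nrow(windows) == 0) return(windows)
  offsets <- seq(stride_s, 60 - stride_s, by = stride_s)
  slid <- windows |>
    dplyr::arrange(.data$subject_id, .data$minute) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_map(function(df, key) {
      is_next <- c(diff(df$minute) == 1L, FALSE)
      pairs <- which(is_next)
      if (!length(pairs)) return(NULL)
      purrr::map_dfr(pairs, function(i) {
        joint <- rbind(df$values[[i]], df$values[[i + 1]])
        purrr::map_dfr(offsets, function(off) {
          r0 <- off * rate_hz
          tibble::tibble(
            subject_id = key$subject_id,
            minute = df$minute[i],
            start_s = df$start_s[i] + off,
            label = (1 - off / 60) * df$label[i] + (off / 60) * df$label[i + 1],
            activity = df$activity[i],
            origin = "slid",
            values = list(joint[(r0 + 1):(r0 + 60 * rate_hz), , drop = FALSE]))
        })
      })
    }) |>
    dplyr::bind_rows()
  out <- dplyr::bind_rows(windows, slid) |>
    dplyr::arrange(.data$subject_id, .data$start_s, .data$origin)
  new_window_set(out, discard_log = discard_log(windows))
}

#' Augment a training set by sliding windows plus per-window rotations
#'
#' The composition used before ensemble training: sliding-window
#' augmentation first, then one independent uniform-SO(3) rotation applied
#' in place to every resulting window (originals included), so the total
#' count on gap-free data is about 12 times the original minute count.
#' Augmentation is for training data only: if any window belongs to a
#' designated test subject the call fails hard rather than leak.
#'
#' @param windows A `window_set` restricted to training subjects.
#' @param test_subjects Character vector of held-out subject ids; any
#'   overlap with `windows` is an error.
#' @param stride_s Sliding stride in seconds (default 5).
#' @param rotate Apply the rotational augmentation (default TRUE).
#' @param seed Integer seed for the rotation draws.
#' @return The augmented `window_set`.
#' @export
augment_training_set <- function(windows, test_subjects = character(),
                                 stride_s = 5, rotate = TRUE, seed = 1L) {
  leaked <- intersect(unique(windows$subject_id), test_subjects)
  if (length(leaked)) {
    rlang::abort(paste0("test subject(s) present in training windows: ",
                        paste(leaked, collapse = ", ")),
                 class = "motorstate_leakage_error")
  }
  if (nrow(windows) == 0) return(windows)
  out <- sliding_windows(windows, stride_s)
  if (rotate) {
    restore <- .Random.seed_exists()
    on.exit(restore(), add = TRUE)
    set.seed(seed)
    out <- rotate_window(out, random_rotation(nrow(out)))
  }
  out
}
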