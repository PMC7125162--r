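#' Configuration of the convolutional motor-state classifier
#'
#' The network maps a one-minute 3600 x 3 window to three logits through
#' seven convolutional blocks (convolution, batch normalization, ReLU) and
#' two fully-connected layers of 512 and 3 nodes. The three accelerometer
#' axes enter as three input channels of a 1-D temporal convolution. With
#' valid padding and the default kernel/stride schedule
#' (8,4), (8,4), (5,3), (4,2), (4,2), (3,1), (2,1) the temporal length
#' shrinks 3600 -> 899 -> 223 -> 73 -> 35 -> 16 -> 14 -> 13, and with the
#' default channel schedule ending at 64 the pre-flatten feature map is
#' 13 x 1 x 64, flattened to an 832-vector.
#'
#' Presets:
#' * `"caption"` (default): channels `c(8, 16, 16, 32, 32, 64, 64)`; the
#'   schedule whose shape arithmetic is self-consistent (13 x 64 = 832).
#' * `"paper-text"`: channels `c(64, 128, 256, 512, 1024, 1024, 1024)`; an
#'   alternative published description of the same network, flatten 13312.
#' * `"reduced"`: channels `c(4, 8, 8, 16, 16, 16, 16)`; a desk-scale
#'   schedule for tests and the synthetic end-to-end experiment.
#'
#' @param preset One of `"caption"`, `"paper-text"`, `"reduced"`; ignored if
#'   `channels` is given.
#' @param channels Integer vector of 7 output-channel counts.
#' @param kernels,strides Integer vectors of 7 temporal kernel sizes and
#'   strides (valid padding).
#' @param fc_sizes Fully-connected layer sizes, default `c(512, 3)`; the
#'   last entry must be 3 (OFF/ON/DYS logits).
#' @param input_len,input_channels Input window shape (3600 samples x 3
#'   axes).
#' @param learning_rate,epochs,batch_size Adam optimizer settings.
#' @param bn_momentum Batch-normalization running-statistics momentum.
#' @param seed Seed for weight initialization and batch shuffling.
#' @return A validated `cnn_config` object.
#' @export
#' @examples
#' cfg <- cnn_config()
#' block_lengths(cfg)   # 899 223 73 35 16 14 13
#' flatten_length(cfg)  # 832
cnn_config <- function(preset = c("caption", "paper-text", "reduced"),
                       channels = NULL,
                       kernels = c(8, 8, 5, 4, 4, 3, 2),
                       strides = c(4, 4, 3, 2, 2, 1, 1),
                       fc_sizes = c(512, 3),
                       input_len = 3600, input_channels = 3,
                       learning_rate = 1e-3, epochs = 10, batch_size = 64,
                       bn_momentum = 0.1, seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(channels)) {
    channels <- switch(preset,
      "caption" = c(8, 16, 16, 32, 32, 64, 64),
      "paper-text" = c(64, 128, 256, 512, 1024, 1024, 1024),
      "reduced" = c(4, 8, 8, 16, 16, 16, 16))
  }
  if (preset == "reduced" && missing(fc_sizes)) fc_sizes <- c(64, 3)
  assert_that(length(channels) == 7 && length(kernels) == 7 &&
                length(strides) == 7, "exactly 7 convolutional blocks required")
  assert_that(fc_sizes[length(fc_sizes)] == 3,
              "the final fully-connected layer must have 3 nodes")
  cfg <- structure(list(
    preset = preset,
    channels = as.integer(channels),
    kernels = as.integer(kernels),
    strides = as.integer(strides),
    fc_sizes = as.integer(fc_sizes),
    input_len = as.integer(input_len),
    input_channels = as.integer(input_channels),
    learning_rate = learning_rate,
    epochs = as.integer(epochs),
    batch_size = as.integer(batch_size),
    bn_momentum = bn_momentum,
    seed = as.integer(seed)), class = "cnn_config")
  lens <- block_lengths(cfg)
  if (any(lens < 1)) {
    rlang::abort(paste0("kernel/stride schedule collapses the window: ",
                        "per-block lengths ", paste(lens, collapse = " ")),
                 class = "motorstate_shape_error")
  }
  cfg
}

#' Per-block temporal output lengths of a CNN configuration
#'
#' Valid-padding length recurrence `L_out = floor((L_in - k) / s) + 1`
#' applied across the seven blocks.
#'
#' @param config A [cnn_config()].
#' @return Integer vector of 7 output lengths.
#' @export
block_lengths <- function(config) {
  L <- config$input_len
  out <- integer(length(config$kernels))
  for (i in seq_along(config$kernels)) {
    L <- floor((L - config$kernels[i]) / config$strides[i]) + 1
    out[i] <- as.integer(L)
  }
  out
}

#' Flattened feature length before the fully-connected head
#'
#' @param config A [cnn_config()].
#' @return `final temporal length * final channel count`.
#' @export
flatten_length <- function(config) {
  lens <- block_lengths(config)
  as.integer(lens[length(lens)] * config$channels[length(config$channels)])
}

#' Closed-form trainable parameter count of a CNN configuration
#'
#' Convolution weights `C_out * C_in * k` plus bias, batch-norm gain and
#' shift per channel, and the fully-connected weights and biases.
#'
#' @param config A [cnn_config()].
#' @return Integer parameter count.
#' @export
n_parameters <- function(config) {
  cin <- c(config$input_channels, config$channels[-7])
  conv <- sum(config$channels * cin * config$kernels + 3 * config$channels)
  sizes <- c(flatten_length(config), config$fc_sizes)
  fc <- sum(sizes[-length(sizes)] * sizes[-1] + sizes[-1])
  as.integer(conv + fc)
}

#' @export
print.cnn_config <- function(x, ...) {
  lens <- block_lengths(x)
  cat("<cnn_config:", x$preset, "> 7 conv blocks\n")
  cat("  channels:", paste(x$channels, collapse = " "), "\n")
  cat("  lengths :", x$input_len, "->", paste(lens, collapse = " -> "), "\n")
  cat("  flatten :", flatten_length(x), " fc:",
      paste(x$fc_sizes, collapse = "/"),
      " params:", n_parameters(x), "\n")
  invisible(x)
}

#' Soft training targets from float labels
#'
#' An integer label becomes a one-hot triple; a fractional label `l`
#' (produced by sliding-window label interpolation) splits its mass
#' linearly: `1 - frac` on `floor(l)` and `frac` on `ceiling(l)`.
#'
#' @param label Numeric vector of labels in `[0, 2]`.
#' @return 3 x n matrix of class probabilities (rows OFF, ON, DYS).
#' @export
#' @examples
#' soft_target(c(1, 1.3, 0.5))
soft_target <- function(label) {
  assert_that(all(label >= 0 & label <= 2), "labels must lie in [0, 2]")
  n <- length(label)
  lo <- floor(label)
  frac <- label - lo
  out <- matrix(0, 3, n)
  for (i in seq_len(n)) {
    out[lo[i] + 1, i] <- out[lo[i] + 1, i] + (1 - frac[i])
    if (frac[i] > 0) out[lo[i] + 2, i] <- frac[i]
  }
  rownames(out) <- names(MOTOR_STATES)
  out
}
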