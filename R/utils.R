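# Internal helpers shared across pipeline stages.

MOTOR_STATES <- c(OFF = 0L, ON = 1L, DYS = 2L)

ACTIVITIES <- c("sitting", "lying", "walking", "standing", "sleeping",
                "testing", "other", "unknown")

#' Derive a per-stage seed from one master seed
#'
#' One master seed reproduces a whole run; each pipeline stage draws from its
#' own stream so that, e.g., changing the number of ensemble members does not
#' shift the simulator's randomness. The derivation is a fixed integer hash of
#' the master seed and the stage name, kept below 2^31.
#'
#' @param master Integer master seed.
#' @param stage Character stage tag (e.g. `"simulate"`, `"augment"`).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(11, "simulate")
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  val <- (abs(as.numeric(master)) * 7919 + h * 104729 + 17) %% 2147483647
  as.integer(max(val, 1))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Population (divide-by-n) standard deviation; the package's descriptive
# convention for day-curve summaries.
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

assert_that <- function(ok, msg) if (!isTRUE(ok)) rlang::abort(msg, class = "motorstate_error")
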