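# R-side wrappers around the compiled network core: weight initialization,
# member training with leakage protection, ensemble aggregation.

# Convert a window_set's list of 3600 x 3 matrices into the (C*L, N) layout
# the compiled core expects (channel index fastest within a column).
windows_to_matrix <- function(windows, config) {
  stopifnot(nrow(windows) > 0)
  dims <- dim(windows$values[[1]])
  assert_that(dims[1] == config$input_len && dims[2] == config$input_channels,
              sprintf("windows are %d x %d but the config expects %d x %d",
                      dims[1], dims[2], config$input_len, config$input_channels))
  vapply(windows$values, function(v) as.vector(t(v)),
         numeric(config$input_len * config$input_channels))
}

cpp_spec <- function(config) {
  list(input_channels = config$input_channels, input_len = config$input_len,
       kernels = config$kernels, strides = config$strides)
}

#' Initialize network weights for a CNN configuration
#'
#' He-normal convolution and fully-connected weights, zero biases, unit
#' batch-norm gains. Shapes are validated against the configuration: a
#' kernel/stride schedule whose valid-padding arithmetic collapses the
#' window is rejected at build time with the per-block lengths.
#'
#' @param config A [cnn_config()].
#' @return A parameter list (blocks and fully-connected layers) consumed by
#'   [train_member()] and [predict_windows()]. Drawn from the current RNG
#'   stream; call `set.seed()` first for reproducibility.
#' @export
build_cnn <- function(config) {
  lens <- c(config$input_len, block_lengths(config))
  cin <- c(config$input_channels, config$channels[-7])
  blocks <- lapply(seq_len(7), function(i) {
    fan_in <- cin[i] * config$kernels[i]
    list(W = matrix(rnorm(config$channels[i] * fan_in, 0, sqrt(2 / fan_in)),
                    nrow = config$channels[i]),
         b = rep(0, config$channels[i]),
         gamma = rep(1, config$channels[i]),
         beta = rep(0, config$channels[i]),
         rmean = rep(0, config$channels[i]),
         rvar = rep(1, config$channels[i]))
  })
  sizes <- c(flatten_length(config), config$fc_sizes)
  fc <- lapply(seq_len(length(sizes) - 1), function(j) {
    list(W = matrix(rnorm(sizes[j + 1] * sizes[j], 0, sqrt(2 / sizes[j])),
                    nrow = sizes[j + 1]),
         b = rep(0, sizes[j + 1]))
  })
  list(blocks = blocks, fc = fc)
}

#' Train one ensemble member on a subject subset
#'
#' Restricts the training windows to `subject_subset`, builds soft targets
#' from the (possibly fractional) labels, and runs mini-batch Adam on the
#' compiled network. Training is deterministic given `seed`. If any window
#' from a designated test subject is present the call fails hard.
#'
#' @param windows A `window_set` of training windows (augmented or not).
#' @param subject_subset Character vector of subjects this member trains on.
#' @param config A [cnn_config()].
#' @param seed Integer seed for initialization and batch shuffling.
#' @param test_subjects Subjects that must not appear (leakage guard).
#' @param verbose Print per-epoch loss.
#' @return A `motor_member` list: `params`, `subjects`, `history` (mean
#'   soft-label cross-entropy per epoch), `seed`, `config`.
#' @export
train_member <- function(windows, subject_subset, config, seed = 1L,
                         test_subjects = character(), verbose = FALSE) {
  leaked <- intersect(unique(windows$subject_id), test_subjects)
  if (length(leaked)) {
    rlang::abort(paste0("test subject(s) present in training windows: ",
                        paste(leaked, collapse = ", ")),
                 class = "motorstate_leakage_error")
  }
  train <- windows[windows$subject_id %in% subject_subset, ]
  assert_that(nrow(train) > 0, "no training windows for this subject subset")
  restore <- .Random.seed_exists()
  on.exit(restore(), add = TRUE)
  set.seed(seed)
  params <- build_cnn(config)
  X <- windows_to_matrix(train, config)
  Y <- soft_target(train$label)
  n <- ncol(X)
  epochs <- config$epochs
  history <- numeric(0)
  if (epochs > 0) {
    shuffle <- vapply(seq_len(epochs), function(e) sample.int(n) - 1L,
                      integer(n))
    fit <- cnn_train_cpp(params, X, Y, cpp_spec(config), epochs,
                         config$batch_size, config$learning_rate,
                         config$bn_momentum, shuffle, verbose)
    params <- fit$params
    history <- fit$history
  }
  structure(list(params = params, subjects = sort(unique(subject_subset)),
                 history = history, seed = seed, config = config),
            class = "motor_member")
}

#' Softmax predictions of one set of network weights
#'
#' Evaluation-mode forward pass (batch-norm running statistics).
#'
#' @param member A `motor_member` from [train_member()].
#' @param windows A `window_set`.
#' @return Tibble `subject_id`, `minute`, `start_s`, `label`, `activity`,
#'   `p_off`, `p_on`, `p_dys`; the three probabilities are non-negative and
#'   sum to one.
#' @export
predict_windows <- function(member, windows) {
  stopifnot(inherits(member, "motor_member"))
  X <- windows_to_matrix(windows, member$config)
  P <- cnn_forward_cpp(member$params, X, cpp_spec(member$config), FALSE)
  tibble::tibble(
    subject_id = windows$subject_id, minute = windows$minute,
    start_s = windows$start_s, label = windows$label,
    activity = windows$activity,
    p_off = P[1, ], p_on = P[2, ], p_dys = P[3, ])
}

#' Train the patient-subset ensemble
#'
#' Each member is trained on a random subset of
#' `min(subset_size, n training subjects)` subjects (subsets drawn without
#' replacement within a member, independently across members), which evens
#' out differing motor-state distributions between patients. Prediction
#' averages the members' softmax outputs.
#'
#' @param windows Training `window_set` (typically after
#'   [augment_training_set()]).
#' @param config A [cnn_config()].
#' @param n_members Number of ensemble members (default 5).
#' @param subset_size Target subjects per member (default 15).
#' @param seed Master seed; member seeds are derived from it.
#' @param test_subjects Leakage guard, as in [train_member()].
#' @param verbose Print progress.
#' @return A `motor_ensemble` object.
#' @export
train_ensemble <- function(windows, config = cnn_config(), n_members = 5,
                           subset_size = 15, seed = 1L,
                           test_subjects = character(), verbose = FALSE) {
  subjects <- sort(unique(windows$subject_id))
  leaked <- intersect(subjects, test_subjects)
  if (length(leaked)) {
    rlang::abort(paste0("test subject(s) present in training windows: ",
                        paste(leaked, collapse = ", ")),
                 class = "motorstate_leakage_error")
  }
  k <- min(subset_size, length(subjects))
  restore <- .Random.seed_exists()
  on.exit(restore(), add = TRUE)
  set.seed(derive_seed(seed, "ensemble-subsets"))
  subsets <- lapply(seq_len(n_members), function(i) sort(sample(subjects, k)))
  members <- lapply(seq_len(n_members), function(i) {
    if (verbose) message("training member ", i, "/", n_members)
    train_member(windows, subsets[[i]], config,
                 seed = derive_seed(seed, paste0("member-", i)),
                 test_subjects = test_subjects, verbose = verbose)
  })
  structure(list(members = members, config = config, seed = seed,
                 subjects = subjects),
            class = "motor_ensemble")
}

#' @export
print.motor_ensemble <- function(x, ...) {
  cat("<motor_ensemble>", length(x$members), "members,",
      length(x$subjects), "training subjects, preset", x$config$preset,
      "(", n_parameters(x$config), "parameters each )\n")
  invisible(x)
}

#' Predict softmax probabilities with an ensemble
#'
#' Mean of the member softmax outputs; the result is again a probability
#' triple per window.
#'
#' @param object A `motor_ensemble`.
#' @param windows A `window_set` to score.
#' @param ... Unused.
#' @return Tibble as in [predict_windows()].
#' @export
predict.motor_ensemble <- function(object, windows, ...) {
  preds <- lapply(object$members, predict_windows, windows = windows)
  out <- preds[[1]]
  if (length(preds) > 1) {
    for (col in c("p_off", "p_on", "p_dys")) {
      out[[col]] <- rowMeans(vapply(preds, `[[`, numeric(nrow(out)), col))
    }
  }
  out
}

#' @describeIn train_ensemble Per-member summary: subjects, final loss.
#' @param x A `motor_ensemble`.
#' @export
tidy.motor_ensemble <- function(x, ...) {
  purrr::map_dfr(seq_along(x$members), function(i) {
    m <- x$members[[i]]
    tibble::tibble(member = i, n_subjects = length(m$subjects),
                   subjects = paste(m$subjects, collapse = ","),
                   epochs = length(m$history),
                   initial_loss = if (length(m$history)) m$history[1] else NA_real_,
                   final_loss = if (length(m$history))
                     m$history[length(m$history)] else NA_real_)
  })
}

#' @describeIn train_ensemble One-row ensemble summary.
#' @export
glance.motor_ensemble <- function(x, ...) {
  tibble::tibble(n_members = length(x$members),
                 n_subjects = length(x$subjects),
                 preset = x$config$preset,
                 n_parameters = n_parameters(x$config),
                 flatten_length = flatten_length(x$config))
}
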