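# Configuration loading and the desk-scale demo runner behind the
# command-line entry point (inst/cli/motorstate).

#' Load and validate a YAML run configuration
#'
#' Reads a key-value configuration file, rejects unknown keys, and
#' materializes every default so the echoed configuration fully describes
#' the run. Recognized top-level keys: `seed`, `n_subjects`,
#' `session_minutes`, `n_members`, `subset_size`, `stride_s`, `augment`,
#' `preset`, `epochs`, `batch_size`, `learning_rate`.
#'
#' @param path Path to a YAML file (empty file = all defaults).
#' @return A named list with every key filled in.
#' @export
load_config <- function(path) {
  defaults <- list(seed = 11L, n_subjects = 8L, session_minutes = 45L,
                   n_members = 2L, subset_size = 15L, stride_s = 5L,
                   augment = TRUE, preset = "reduced", epochs = 6L,
                   batch_size = 64L, learning_rate = 1e-3)
  user <- list()
  if (!is.null(path) && nzchar(path)) {
    if (!file.exists(path)) {
      rlang::abort(paste0("config file not found: ", path),
                   class = "motorstate_io_error")
    }
    user <- yaml::read_yaml(path) %||% list()
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    rlang::abort(paste0("unknown configuration key(s): ",
                        paste(unknown, collapse = ", ")),
                 class = "motorstate_config_error")
  }
  utils::modifyList(defaults, user)
}

#' Run the desk-scale LOSO demonstration experiment
#'
#' Simulates a cohort, runs the full leave-one-subject-out experiment, and
#' (optionally) writes the report to `dir`. One master seed threads through
#' every stage, so two runs with the same configuration are identical.
#'
#' @param seed Master seed (default 11).
#' @param dir Output directory or NULL to skip writing.
#' @param n_subjects,session_minutes Cohort size (default 8 subjects of 45
#'   minutes each).
#' @param config A [cnn_config()]; default the `"reduced"` preset with 8
#'   epochs.
#' @param n_members Ensemble members per fold.
#' @param augment Apply training augmentation.
#' @param verbose Print progress.
#' @return The `motor_experiment` (invisibly if `dir` is given).
#' @export
run_demo <- function(seed = 11L, dir = NULL, n_subjects = 8,
                     session_minutes = 45,
                     config = cnn_config("reduced", epochs = 6),
                     n_members = 2, augment = TRUE, verbose = FALSE) {
  cfg <- sim_config(n_subjects = n_subjects,
                    session_minutes_range = rep(session_minutes, 2),
                    seed = derive_seed(seed, "simulate"))
  cohort <- simulate_cohort(cfg)
  exp <- run_loso_experiment(cohort, config = config, n_members = n_members,
                             augment = augment, seed = seed,
                             verbose = verbose)
  if (!is.null(dir)) {
    write_report(exp, dir)
    return(invisible(exp))
  }
  exp
}
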