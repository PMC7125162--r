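# End-to-end leave-one-subject-out experiment: preprocess -> augment the
# training subjects -> train the ensemble -> score the held-out subject ->
# pool confusion counts, clinimetrics, temporal correlations, activity
# strata and day curves.

#' Run the full LOSO motor-state experiment on a cohort
#'
#' For each fold, the held-out subject's windows never enter augmentation or
#' training (enforced with hard leakage checks). The reference class for
#' categorical scoring is the rater's integer minute label; only original
#' (non-augmented) windows are scored unless `score_augmented = TRUE`, in
#' which case slid/rotated training-style windows of the test subject with
#' integer labels are scored as well.
#'
#' @param cohort An `imu_cohort` from [simulate_cohort()] or [read_cohort()].
#' @param config A [cnn_config()]; default the desk-scale `"reduced"` preset.
#' @param n_members Ensemble members per fold.
#' @param subset_size Subjects per member (capped at the fold's training
#'   cohort size).
#' @param stride_s Sliding-window stride for training augmentation.
#' @param augment Apply training augmentation (default TRUE).
#' @param score_augmented Also score augmented test windows (integer labels
#'   only).
#' @param seed Master seed; all stage seeds derive from it.
#' @param verbose Print per-fold progress.
#' @return A `motor_experiment` list: `confusion` (pooled 3 x 3),
#'   `metrics` (a [clinimetrics()] report), `correlations`
#'   ([temporal_correlations()] tibble), `activity`
#'   ([activity_stratified()] tibble), `day_curves` ([day_curve()] tibble),
#'   `predictions` (per-window tibble with fold, softmax, expcnn,
#'   prediction), and `manifest` (seeds, config, fold assignments, counts).
#' @export
run_loso_experiment <- function(cohort,
                                config = cnn_config("reduced", epochs = 6),
                                n_members = 2,
                                subset_size = 15,
                                stride_s = 5,
                                augment = TRUE,
                                score_augmented = FALSE,
                                seed = 11L,
                                verbose = FALSE) {
  windows <- preprocess_cohort(cohort)
  assert_that(nrow(windows) > 0, "preprocessing produced no windows")
  folds <- loso_folds(windows$subject_id)
  assert_that(nrow(folds) >= 2, "need at least 2 subjects for LOSO")

  fold_preds <- vector("list", nrow(folds))
  for (i in seq_len(nrow(folds))) {
    test_id <- folds$test_subject[i]
    train_ids <- folds$train_subjects[[i]]
    if (verbose) message("fold ", i, "/", nrow(folds), ": test ", test_id)
    train_windows <- windows[windows$subject_id %in% train_ids, ]
    if (augment) {
      train_windows <- augment_training_set(
        train_windows, test_subjects = test_id, stride_s = stride_s,
        seed = derive_seed(seed, paste0("augment-", i)))
    }
    ensemble <- train_ensemble(
      train_windows, config, n_members = n_members,
      subset_size = subset_size,
      seed = derive_seed(seed, paste0("fold-", i)),
      test_subjects = test_id, verbose = verbose)
    test_windows <- windows[windows$subject_id == test_id, ]
    if (score_augmented) {
      test_windows <- sliding_windows(test_windows, stride_s)
      test_windows <- test_windows[test_windows$label ==
                                     round(test_windows$label), ]
    }
    pred <- predict(ensemble, test_windows)
    pred$fold <- i
    fold_preds[[i]] <- pred
  }
  predictions <- dplyr::bind_rows(fold_preds) |> expcnn()
  predictions$prediction <- predicted_class(predictions)
  scored <- predictions[predictions$label == round(predictions$label), ]

  cm <- confusion_matrix3(as.integer(scored$label), scored$prediction)
  metrics <- clinimetrics(cm)
  minute_preds <- dplyr::distinct(
    dplyr::select(scored, "subject_id", "minute", "expcnn"))
  correlations <- temporal_correlations(minute_preds, cohort$annotations)
  activity <- activity_stratified(tibble::tibble(
    activity = scored$activity, reference = as.integer(scored$label),
    prediction = scored$prediction))
  curves <- day_curve(predictions)

  manifest <- list(
    seed = seed,
    config = unclass(config),
    n_members = n_members, subset_size = subset_size,
    stride_s = stride_s, augment = augment,
    score_augmented = score_augmented,
    folds = lapply(seq_len(nrow(folds)), function(i)
      list(fold = i, test = folds$test_subject[i],
           train = folds$train_subjects[[i]])),
    n_subjects = nrow(folds),
    n_windows_scored = nrow(scored),
    discarded = as.list(table(discard_log(windows)$reason)))

  structure(list(confusion = cm, metrics = metrics,
                 correlations = correlations, activity = activity,
                 day_curves = curves, predictions = predictions,
                 manifest = manifest),
            class = "motor_experiment")
}

#' @export
print.motor_experiment <- function(x, ...) {
  cat("<motor_experiment>", x$manifest$n_subjects, "LOSO folds,",
      x$manifest$n_windows_scored, "scored windows\n")
  print(x$metrics)
  invisible(x)
}

#' @describeIn run_loso_experiment Per-class metric battery of the pooled
#'   confusion matrix.
#' @param x A `motor_experiment`.
#' @param ... Unused.
#' @export
tidy.motor_experiment <- function(x, ...) tidy(x$metrics)

#' @describeIn run_loso_experiment One-row overall summary.
#' @export
glance.motor_experiment <- function(x, ...) glance(x$metrics)

#' Write the full experiment report to a directory
#'
#' `report.json` (overall and per-class metrics, correlations, activity
#' table), `confusion.csv`, `correlations.csv`, `activity_table.csv`,
#' per-subject day-curve CSVs, and `run_manifest.json` (seeds, config echo,
#' fold assignments).
#'
#' @param experiment A `motor_experiment`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_report <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(overall = experiment$metrics$overall,
         by_class = experiment$metrics$by_class,
         correlations = experiment$correlations,
         activity = experiment$activity),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  readr::write_csv(as.data.frame(as.table(experiment$confusion)) |>
                     stats::setNames(c("reference", "prediction", "n")),
                   file.path(dir, "confusion.csv"))
  readr::write_csv(experiment$correlations, file.path(dir, "correlations.csv"))
  readr::write_csv(experiment$activity, file.path(dir, "activity_table.csv"))
  write_day_curves(experiment$day_curves, dir)
  jsonlite::write_json(experiment$manifest,
                       file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
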