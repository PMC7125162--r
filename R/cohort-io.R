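# Cohort disk layout:
#   sensor_<subject>.csv       timestamp_s,ax_g,ay_g,az_g
#   annotations_<subject>.csv  minute_index,motor_state,brady_item,dys_item,activity
#   manifest.json              subject list, config echo, seed
# Doubles are written with round-trip precision so read(write(x)) == x exactly.

#' Write a simulated cohort to a directory of CSV files
#'
#' One sensor CSV and one annotation CSV per subject, plus a
#' `manifest.json` echoing the subject list and the simulation seed.
#'
#' @param cohort An `imu_cohort` from [simulate_cohort()] or [read_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest as a tibble (one row per subject with the
#'   file names and row counts).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "imu_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- sort(unique(c(cohort$sensor$subject_id,
                            cohort$annotations$subject_id)))
  rows <- lapply(subjects, function(s) {
    sens <- dplyr::filter(cohort$sensor, .data$subject_id == s)
    ann <- dplyr::filter(cohort$annotations, .data$subject_id == s)
    sf <- sprintf("sensor_%s.csv", s)
    af <- sprintf("annotations_%s.csv", s)
    readr::write_csv(dplyr::select(sens, -"subject_id"), file.path(dir, sf))
    readr::write_csv(dplyr::select(ann, -"subject_id"), file.path(dir, af))
    tibble::tibble(subject_id = s, sensor_file = sf, annotation_file = af,
                   n_samples = nrow(sens), n_minutes = nrow(ann))
  })
  manifest <- dplyr::bind_rows(rows)
  cfg <- attr(cohort, "config")
  jsonlite::write_json(
    list(subjects = subjects,
         seed = if (!is.null(cfg)) cfg$seed else NULL,
         n_subjects = length(subjects),
         files = manifest),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.json` and the per-subject CSVs.
#' @return An `imu_cohort` (see [simulate_cohort()] for the layout).
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) {
    rlang::abort(paste0("no manifest.json found in '", dir, "'"),
                 class = "motorstate_io_error")
  }
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  subjects <- manifest$subjects
  sensor_cols <- readr::cols(
    timestamp_s = readr::col_double(), ax_g = readr::col_double(),
    ay_g = readr::col_double(), az_g = readr::col_double())
  ann_cols <- readr::cols(
    minute_index = readr::col_integer(), motor_state = readr::col_integer(),
    brady_item = readr::col_integer(), dys_item = readr::col_integer(),
    activity = readr::col_character())
  read_one <- function(path, cols, what) {
    out <- tryCatch(
      suppressWarnings(readr::read_csv(path, col_types = cols,
                                       progress = FALSE)),
      error = function(e) rlang::abort(
        paste0("malformed ", what, " CSV '", path, "': ", conditionMessage(e)),
        class = "motorstate_io_error"))
    probs <- readr::problems(out)
    if (nrow(probs) > 0) {
      rlang::abort(sprintf("malformed %s CSV '%s': parse failure at row %d",
                           what, path, probs$row[1]),
                   class = "motorstate_io_error")
    }
    out
  }
  sensor <- dplyr::bind_rows(lapply(subjects, function(s) {
    dplyr::mutate(read_one(file.path(dir, sprintf("sensor_%s.csv", s)),
                           sensor_cols, "sensor"),
                  subject_id = s, .before = 1)
  }))
  annotations <- dplyr::bind_rows(lapply(subjects, function(s) {
    dplyr::mutate(read_one(file.path(dir, sprintf("annotations_%s.csv", s)),
                           ann_cols, "annotation"),
                  subject_id = s, .before = 1)
  }))
  if (length(subjects) == 0) {
    sensor <- tibble::tibble(subject_id = character(), timestamp_s = numeric(),
                             ax_g = numeric(), ay_g = numeric(), az_g = numeric())
    annotations <- tibble::tibble(subject_id = character(),
                                  minute_index = integer(),
                                  motor_state = integer(), brady_item = integer(),
                                  dys_item = integer(), activity = character())
  }
  structure(list(sensor = sensor, annotations = annotations),
            class = "imu_cohort")
}
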