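# Window-container I/O. The container is a directory of plain CSVs:
#   windows_meta.csv   window_id,subject,minute,start_s,label,activity,origin
#                      (label empty = missing)
#   windows_values.csv window_id,row,ax_g,ay_g,az_g   (row 1..3600)
#   discard_log.csv    subject_id,minute,reason

#' Write a window set to a directory of CSV files
#'
#' @param windows A `window_set`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_windows <- function(windows, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- tibble::tibble(
    window_id = seq_len(nrow(windows)),
    subject = windows$subject_id, minute = windows$minute,
    start_s = windows$start_s, label = windows$label,
    activity = windows$activity, origin = windows$origin)
  readr::write_csv(meta, file.path(dir, "windows_meta.csv"))
  values <- purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    v <- windows$values[[i]]
    tibble::tibble(window_id = i, row = seq_len(nrow(v)),
                   ax_g = v[, 1], ay_g = v[, 2], az_g = v[, 3])
  })
  readr::write_csv(values, file.path(dir, "windows_values.csv"))
  readr::write_csv(discard_log(windows), file.path(dir, "discard_log.csv"))
  invisible(dir)
}

#' Read a window set written by [write_windows()]
#'
#' @param dir Directory with the container CSVs.
#' @return A `window_set`.
#' @export
read_windows <- function(dir) {
  meta <- readr::read_csv(
    file.path(dir, "windows_meta.csv"),
    col_types = readr::cols(window_id = "i", subject = "c", minute = "i",
                            start_s = "d", label = "d", activity = "c",
                            origin = "c"), progress = FALSE)
  values <- readr::read_csv(
    file.path(dir, "windows_values.csv"),
    col_types = readr::cols(window_id = "i", row = "i", ax_g = "d",
                            ay_g = "d", az_g = "d"), progress = FALSE)
  vals <- lapply(split(values, values$window_id), function(df) {
    df <- df[order(df$row), ]
    unname(cbind(df$ax_g, df$ay_g, df$az_g))
  })
  log_path <- file.path(dir, "discard_log.csv")
  log <- if (file.exists(log_path)) {
    readr::read_csv(log_path,
                    col_types = readr::cols(subject_id = "c", minute = "i",
                                            reason = "c"), progress = FALSE)
  } else NULL
  out <- tibble::tibble(
    subject_id = meta$subject, minute = meta$minute, start_s = meta$start_s,
    label = meta$label, activity = meta$activity, origin = meta$origin,
    values = unname(vals[as.character(meta$window_id)]))
  new_window_set(out, discard_log = log)
}
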