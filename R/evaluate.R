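# Clinimetric evaluation: cross-validation folds, confusion-matrix
# statistics (one-vs-all), Cohen's kappa, temporal-aggregation correlations,
# activity stratification, committee votes and ICC(2,1) rater reliability.

#' Leave-one-subject-out cross-validation folds
#'
#' One fold per subject; the fold's test set is that single subject and the
#' training set is everyone else.
#'
#' @param subject_ids Character vector of subject ids (duplicates ignored).
#' @return Tibble with columns `fold`, `test_subject`, `train_subjects`
#'   (list-column).
#' @export
loso_folds <- function(subject_ids) {
  ids <- sort(unique(subject_ids))
  tibble::tibble(
    fold = seq_along(ids),
    test_subject = ids,
    train_subjects = lapply(ids, function(s) setdiff(ids, s)))
}

#' Grouped k-fold cross-validation over subjects
#'
#' Subjects are shuffled and split into `k` groups whose sizes differ by at
#' most one; each group is the test set of one fold. Used for the
#' four-patient-group baseline comparison.
#'
#' @param subject_ids Character vector of subject ids.
#' @param k Number of groups, default 4.
#' @param seed Shuffle seed.
#' @return Tibble with `fold`, `test_subjects` and `train_subjects`
#'   list-columns.
#' @export
grouped_folds <- function(subject_ids, k = 4, seed = 1L) {
  ids <- sort(unique(subject_ids))
  assert_that(k >= 2 && k <= length(ids),
              "k must lie between 2 and the number of subjects")
  restore <- .Random.seed_exists()
  on.exit(restore(), add = TRUE)
  set.seed(seed)
  shuffled <- sample(ids)
  groups <- split(shuffled, rep(seq_len(k), length.out = length(ids)))
  tibble::tibble(
    fold = seq_len(k),
    test_subjects = lapply(groups, sort),
    train_subjects = lapply(groups, function(g) setdiff(ids, g)))
}

#' Three-class confusion matrix (reference in rows, prediction in columns)
#'
#' @param reference,prediction Integer vectors with values in `{0, 1, 2}`
#'   (OFF/ON/DYS).
#' @return 3 x 3 integer matrix with dimnames OFF/ON/DYS.
#' @export
confusion_matrix3 <- function(reference, prediction) {
  stopifnot(length(reference) == length(prediction))
  keep <- !is.na(reference) & !is.na(prediction)
  reference <- reference[keep]; prediction <- prediction[keep]
  assert_that(all(reference %in% 0:2) && all(prediction %in% 0:2),
              "labels must be in {0, 1, 2}")
  lv <- names(MOTOR_STATES)
  m <- table(factor(reference, levels = 0:2, labels = lv),
             factor(prediction, levels = 0:2, labels = lv))
  out <- matrix(as.integer(m), 3, 3, dimnames = list(reference = lv,
                                                     prediction = lv))
  out
}

#' Clinimetric statistics of a three-class confusion matrix
#'
#' Overall accuracy, three-class balanced accuracy (macro-averaged recall),
#' Cohen's kappa (observed vs chance agreement from the marginals), and the
#' one-vs-all battery per class: sensitivity, specificity, positive and
#' negative predictive value, balanced accuracy `(sens + spec) / 2`,
#' detection prevalence and true prevalence. Zero-denominator metrics are
#' reported as `NA`, not 0.
#'
#' @param cm 3 x 3 confusion matrix, reference in rows (see
#'   [confusion_matrix3()]).
#' @return A `metrics_report` list with tibbles `overall` and `by_class`;
#'   [tidy()] returns the per-class battery, [glance()] the overall row.
#' @export
clinimetrics <- function(cm) {
  assert_that(is.matrix(cm) && all(dim(cm) == c(3, 3)),
              "cm must be a 3 x 3 matrix")
  assert_that(all(cm >= 0), "confusion counts must be non-negative")
  total <- sum(cm)
  if (total == 0) {
    rlang::abort("empty confusion matrix: metrics undefined",
                 class = "motorstate_error")
  }
  lv <- rownames(cm) %||% names(MOTOR_STATES)
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  per <- purrr::map_dfr(1:3, function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    sens <- safe_div(tp, tp + fn)
    spec <- safe_div(tn, tn + fp)
    tibble::tibble(
      class = lv[i],
      sensitivity = sens,
      specificity = spec,
      ppv = safe_div(tp, tp + fp),
      npv = safe_div(tn, tn + fn),
      balanced_accuracy = (sens + spec) / 2,
      detection_prevalence = (tp + fp) / total,
      prevalence = (tp + fn) / total)
  })
  acc <- sum(diag(cm)) / total
  macro_recall <- mean(per$sensitivity)
  p_chance <- sum(rowSums(cm) * colSums(cm)) / total^2
  kappa <- if (p_chance < 1) (acc - p_chance) / (1 - p_chance) else NA_real_
  out <- list(
    overall = tibble::tibble(accuracy = acc,
                             balanced_accuracy = macro_recall,
                             kappa = kappa, n = total),
    by_class = per,
    confusion = cm)
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> n =", x$overall$n,
      " accuracy =", round(x$overall$accuracy, 3),
      " balanced accuracy =", round(x$overall$balanced_accuracy, 3),
      " kappa =", round(x$overall$kappa, 3), "\n")
  print(x$by_class)
  invisible(x)
}

#' @describeIn clinimetrics Per-class one-vs-all battery as a tibble.
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @export
tidy.metrics_report <- function(x, ...) x$by_class

#' @describeIn clinimetrics One-row overall summary.
#' @export
glance.metrics_report <- function(x, ...) x$overall

#' Correlation of aggregated expCNN with rater severity items
#'
#' For each temporal window size, the window-mean expCNN is mapped onto the
#' two item scales — bradykinesia uses the 0-to-1 portion of the score
#' (`brady_pred = 1 - clip(expCNN, 0, 1)`, so more OFF-like output means
#' more bradykinesia), dyskinesia the 1-to-2 portion
#' (`dys_pred = clip(expCNN, 1, 2) - 1`) — and Pearson-correlated with the
#' window-mean rater item. Windows with no annotated minutes are excluded;
#' a window size with fewer than 3 paired windows, or zero variance on
#' either side, reports `NA`.
#'
#' @param predictions Tibble with `subject_id`, `minute`, `expcnn` (one row
#'   per scored minute).
#' @param annotations Annotation tibble with `subject_id`, `minute_index`,
#'   `brady_item`, `dys_item`.
#' @param window_minutes Aggregation window sizes in minutes; `Inf` means
#'   the whole recording per subject (daily window). Default
#'   `c(1, 5, 30, 60, Inf)`.
#' @return A tibble: `window_minutes`, `item` (`"brady"`/`"dys"`), `r`,
#'   `p_value`, `conf_low`, `conf_high`, `n_windows`.
#' @export
temporal_correlations <- function(predictions, annotations,
                                  window_minutes = c(1, 5, 30, 60, Inf)) {
  stopifnot(all(c("subject_id", "minute", "expcnn") %in% names(predictions)))
  joined <- dplyr::inner_join(
    predictions,
    dplyr::select(annotations, "subject_id", minute = "minute_index",
                  "brady_item", "dys_item"),
    by = c("subject_id", "minute")) |>
    dplyr::filter(!is.na(.data$brady_item), !is.na(.data$dys_item))
  purrr::map_dfr(window_minutes, function(w) {
    grouped <- joined |>
      dplyr::mutate(win = if (is.finite(w)) floor(.data$minute / w) else 0L) |>
      dplyr::group_by(.data$subject_id, .data$win) |>
      dplyr::summarise(expcnn = mean(.data$expcnn),
                       brady_item = mean(.data$brady_item),
                       dys_item = mean(.data$dys_item), .groups = "drop") |>
      dplyr::mutate(brady_pred = 1 - clamp(.data$expcnn, 0, 1),
                    dys_pred = clamp(.data$expcnn, 1, 2) - 1)
    purrr::map_dfr(c("brady", "dys"), function(item) {
      x <- grouped[[paste0(item, "_pred")]]
      y <- grouped[[paste0(item, "_item")]]
      if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
        return(tibble::tibble(window_minutes = w, item = item, r = NA_real_,
                              p_value = NA_real_, conf_low = NA_real_,
                              conf_high = NA_real_, n_windows = length(x)))
      }
      ct <- cor.test(x, y, method = "pearson")
      tibble::tibble(window_minutes = w, item = item,
                     r = unname(ct$estimate), p_value = ct$p.value,
                     conf_low = ct$conf.int[1], conf_high = ct$conf.int[2],
                     n_windows = length(x))
    })
  })
}

#' Balanced accuracy stratified by background activity
#'
#' The activity annotation is never used for training or prediction; this
#' table shows that performance holds up across activities. Per activity:
#' prevalence (percent of scored minutes) and three-class balanced accuracy
#' from the stratum's own confusion matrix (`NA` if a class is absent).
#'
#' @param scored Tibble with columns `activity`, `reference`, `prediction`
#'   (integer labels 0/1/2).
#' @return Tibble `activity`, `n`, `prevalence_pct`, `balanced_accuracy`.
#' @export
activity_stratified <- function(scored) {
  stopifnot(all(c("activity", "reference", "prediction") %in% names(scored)))
  total <- nrow(scored)
  scored |>
    dplyr::group_by(.data$activity) |>
    dplyr::group_modify(function(df, key) {
      cm <- confusion_matrix3(df$reference, df$prediction)
      ba <- tryCatch(clinimetrics(cm)$overall$balanced_accuracy,
                     error = function(e) NA_real_)
      tibble::tibble(n = nrow(df), prevalence_pct = 100 * nrow(df) / total,
                     balanced_accuracy = ba)
    }) |>
    dplyr::ungroup()
}

#' Committee vote over specialist ratings
#'
#' Modal rating over the committee members; a full three-way tie (all
#' ratings distinct) falls back to the median rating.
#'
#' @param ratings Matrix (items x raters) or data frame of ratings on the
#'   0/1/2 scale.
#' @return Integer vector of committee labels, one per item.
#' @export
#' @examples
#' committee_vote(rbind(c(0, 0, 1), c(0, 1, 2)))  # 0, 1
committee_vote <- function(ratings) {
  ratings <- as.matrix(ratings)
  apply(ratings, 1, function(r) {
    tab <- table(r)
    if (max(tab) == 1) as.integer(median(r))
    else as.integer(names(tab)[which.max(tab)])
  })
}

#' Intraclass correlation ICC(2,1): two-way random effects, absolute
#' agreement, single rater
#'
#' Computed from the two-way mean squares of the items-by-raters table:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`, with the
#' consistency F statistic `MSR / MSE` and its degrees of freedom, and a
#' 95% confidence interval from the standard two-way random-effects
#' formulas.
#'
#' @param ratings Matrix or data frame, items in rows, raters in columns
#'   (at least 2 of each).
#' @param conf_level Confidence level, default 0.95.
#' @return One-row tibble: `icc`, `f_statistic`, `df1`, `df2`, `p_value`,
#'   `conf_low`, `conf_high`, `n_items`, `n_raters`.
#' @export
icc21 <- function(ratings, conf_level = 0.95) {
  x <- as.matrix(ratings)
  n <- nrow(x); k <- ncol(x)
  assert_that(n >= 2 && k >= 2, "need at least 2 items and 2 raters")
  assert_that(!anyNA(x), "ratings must be complete")
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_total <- sum((x - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  fv <- msr / mse
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  p <- pf(fv, df1, df2, lower.tail = FALSE)
  # Confidence interval (two-way random, absolute agreement, single rater)
  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  tibble::tibble(icc = icc, f_statistic = fv, df1 = df1, df2 = df2,
                 p_value = p, conf_low = lower, conf_high = upper,
                 n_items = n, n_raters = k)
}

#' Categorical class prediction from softmax columns
#'
#' Argmax of the (ensemble-averaged) softmax triple; exact ties resolve to
#' the lower class index (conservative toward OFF).
#'
#' @param predictions Tibble with `p_off`, `p_on`, `p_dys`.
#' @return Integer vector of predicted classes 0/1/2.
#' @export
predicted_class <- function(predictions) {
  p <- as.matrix(predictions[, c("p_off", "p_on", "p_dys")])
  as.integer(apply(p, 1, which.max) - 1L)
}
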