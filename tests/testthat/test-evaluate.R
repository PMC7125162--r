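test_that("LOSO folds partition subjects with singleton test sets", {
  ids <- c("A", "B", "C")
  f <- loso_folds(ids)
  expect_equal(nrow(f), 3)
  expect_setequal(f$test_subject, ids)
  for (i in 1:3) {
    expect_length(f$train_subjects[[i]], 2)
    expect_length(intersect(f$test_subject[i], f$train_subjects[[i]]), 0)
    expect_setequal(c(f$test_subject[i], f$train_subjects[[i]]), ids)
  }
})

test_that("grouped folds balance group sizes and test each subject once", {
  ids8 <- sprintf("S%02d", 1:8)
  f8 <- grouped_folds(ids8, k = 4, seed = 1)
  expect_true(all(lengths(f8$test_subjects) == 2))
  expect_setequal(unlist(f8$test_subjects), ids8)
  ids30 <- sprintf("S%02d", 1:30)
  f30 <- grouped_folds(ids30, k = 4, seed = 2)
  expect_setequal(lengths(f30$test_subjects), c(8, 8, 7, 7))
  expect_setequal(unlist(f30$test_subjects), ids30)
  expect_identical(grouped_folds(ids30, k = 4, seed = 3),
                   grouped_folds(ids30, k = 4, seed = 3))
})

test_that("a diagonal confusion matrix scores perfectly", {
  cm <- diag(c(10L, 20L, 30L))
  dimnames(cm) <- list(reference = c("OFF", "ON", "DYS"),
                       prediction = c("OFF", "ON", "DYS"))
  rep <- clinimetrics(cm)
  expect_equal(rep$overall$accuracy, 1)
  expect_equal(rep$overall$balanced_accuracy, 1)
  expect_equal(rep$overall$kappa, 1)
  expect_true(all(rep$by_class$sensitivity == 1))
  expect_true(all(rep$by_class$specificity == 1))
})

test_that("all-one-class predictions on a balanced reference score at chance", {
  cm <- matrix(0L, 3, 3)
  cm[, 1] <- c(10L, 10L, 10L)
  rep <- clinimetrics(cm)
  expect_equal(rep$overall$balanced_accuracy, 1 / 3)
  expect_equal(rep$overall$kappa, 0)
  # undefined PPV cells are NA, not zero
  expect_true(is.na(rep$by_class$ppv[2]))
  expect_error(clinimetrics(matrix(0L, 3, 3)), "empty")
})

test_that("clinimetrics equal the pairwise-agreement oracle on random matrices", {
  withr::local_seed(50)
  for (i in 1:50) {
    cm <- random_cm()
    rep <- clinimetrics(cm)
    oracle <- pairwise_metrics(cm)
    expect_equal(rep$overall$accuracy, oracle$accuracy, tolerance = 1e-12)
    expect_equal(rep$overall$kappa, oracle$kappa, tolerance = 1e-12)
    expect_equal(rep$overall$balanced_accuracy, oracle$macro_recall,
                 tolerance = 1e-12)
    for (c in 1:3) {
      expect_equal(rep$by_class$sensitivity[c], oracle$per[[c]]$sens,
                   tolerance = 1e-12)
      expect_equal(rep$by_class$specificity[c], oracle$per[[c]]$spec,
                   tolerance = 1e-12)
      expect_equal(rep$by_class$ppv[c], oracle$per[[c]]$ppv, tolerance = 1e-12)
      expect_equal(rep$by_class$npv[c], oracle$per[[c]]$npv, tolerance = 1e-12)
    }
    expect_equal(sum(rep$by_class$detection_prevalence), 1, tolerance = 1e-12)
  }
})

test_that("per-class metrics are equivariant under joint class relabeling", {
  withr::local_seed(51)
  cm <- random_cm()
  perm <- c(3, 1, 2)
  rep <- clinimetrics(cm)
  rep_p <- clinimetrics(cm[perm, perm])
  expect_equal(rep_p$by_class$sensitivity, rep$by_class$sensitivity[perm])
  expect_equal(rep_p$by_class$specificity, rep$by_class$specificity[perm])
  expect_equal(rep_p$overall$kappa, rep$overall$kappa, tolerance = 1e-12)
  expect_equal(rep_p$overall$balanced_accuracy,
               rep$overall$balanced_accuracy, tolerance = 1e-12)
})

test_that("macro recall of a diagonal-dominant matrix beats any row permutation", {
  cm <- matrix(c(50, 5, 3, 4, 60, 6, 2, 7, 40), 3, 3, byrow = TRUE)
  base <- clinimetrics(cm)$overall$balanced_accuracy
  perms <- list(c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (p in perms) {
    expect_lt(clinimetrics(cm[p, ])$overall$balanced_accuracy, base)
  }
})

test_that("correlations are exact under monotone-linear maps and missing when degenerate", {
  withr::local_seed(54)
  ann <- tibble::tibble(subject_id = rep(sprintf("S%02d", 1:4), each = 30),
                        minute_index = rep(0:29, 4),
                        brady_item = sample(0:4, 120, replace = TRUE),
                        dys_item = 0L)
  # expcnn <= 1 encoding bradykinesia exactly linearly
  pred <- tibble::tibble(subject_id = ann$subject_id, minute = ann$minute_index,
                         expcnn = 1 - ann$brady_item / 4)
  out <- temporal_correlations(pred, ann)
  brady <- out[out$item == "brady", ]
  expect_true(all(abs(brady$r - 1) < 1e-12))
  expect_true(all(brady$p_value < 1e-6))
  # dys side is constant zero -> missing
  expect_true(all(is.na(out$r[out$item == "dys"])))
  # constant predictions -> missing everywhere
  const <- dplyr::mutate(pred, expcnn = 0.5)
  out2 <- temporal_correlations(const, ann)
  expect_true(all(is.na(out2$r)))
})

test_that("aggregation windows shrink the sample count as expected", {
  ann <- tibble::tibble(subject_id = "S01", minute_index = 0:119,
                        brady_item = rep(0:3, 30), dys_item = 0L)
  pred <- tibble::tibble(subject_id = "S01", minute = 0:119,
                         expcnn = runif(120))
  out <- temporal_correlations(pred, ann, window_minutes = c(1, 5, 30, 60, Inf))
  expect_equal(out$n_windows[out$item == "brady"], c(120, 24, 4, 2, 1))
})

test_that("activity strata report prevalence and consistent balanced accuracy", {
  withr::local_seed(52)
  scored <- tibble::tibble(
    activity = rep(c("sitting", "walking"), c(60, 40)),
    reference = sample(0:2, 100, replace = TRUE),
    prediction = sample(0:2, 100, replace = TRUE))
  tab <- activity_stratified(scored)
  expect_equal(sum(tab$prevalence_pct), 100)
  sit <- scored[scored$activity == "sitting", ]
  expect_equal(
    tab$balanced_accuracy[tab$activity == "sitting"],
    clinimetrics(confusion_matrix3(sit$reference,
                                   sit$prediction))$overall$balanced_accuracy)
  solo <- activity_stratified(scored[scored$activity == "walking", ])
  expect_equal(solo$prevalence_pct, 100)
})

test_that("committee votes take the mode with a median tie-break", {
  expect_equal(committee_vote(rbind(c(0, 0, 1))), 0L)
  expect_equal(committee_vote(rbind(c(2, 2, 2))), 2L)
  expect_equal(committee_vote(rbind(c(0, 1, 2))), 1L)
  expect_equal(committee_vote(rbind(c(1, 2, 2), c(0, 0, 2))), c(2L, 0L))
})

test_that("ICC(2,1) matches a full two-way ANOVA variance-components oracle", {
  withr::local_seed(53)
  n <- 30
  truth <- rnorm(n, 1, 0.7)
  ratings <- cbind(truth + rnorm(n, 0, 0.3), truth + rnorm(n, 0.1, 0.3))
  res <- icc21(ratings)
  # oracle: variance components from aov mean squares
  d <- data.frame(y = as.vector(ratings),
                  item = factor(rep(1:n, 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- as.data.frame(summary(stats::aov(y ~ item + rater, d))[[1]])
  msr <- ms["item", "Mean Sq"]; msc <- ms["rater", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]
  k <- 2
  sigma_r <- (msr - mse) / k
  sigma_c <- (msc - mse) / n
  icc_oracle <- sigma_r / (sigma_r + sigma_c + mse)
  expect_equal(res$icc, icc_oracle, tolerance = 1e-10)
  expect_equal(res$f_statistic, msr / mse, tolerance = 1e-10)
  expect_true(res$conf_low < res$icc && res$icc < res$conf_high)
})

test_that("ICC(2,1) is 1 for identical raters and penalizes constant shifts", {
  x <- c(0, 1, 2, 1, 0, 2, 1, 2)
  expect_equal(icc21(cbind(x, x))$icc, 1)
  shifted <- icc21(cbind(x, x + 1))
  expect_lt(shifted$icc, 1)
  expect_error(icc21(cbind(1, 1)), "at least 2")
})

test_that("argmax class prediction breaks ties toward OFF", {
  p <- tibble::tibble(p_off = c(0.4, 1 / 3), p_on = c(0.4, 1 / 3),
                      p_dys = c(0.2, 1 / 3))
  expect_equal(predicted_class(p), c(0L, 0L))
})
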