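# Reference classifiers on the raw flattened windows (no feature
# extraction): linear SVM, kNN (k = 10), random forest, and a
# fully-connected MLP. All consume the 10,800-value flattened window and
# are scored with grouped subject folds on non-augmented data.

#' Baseline classifier comparison on raw windows
#'
#' Trains each requested method on the flattened raw windows of the train
#' subjects of each fold and reports the pooled three-class balanced
#' accuracy per method. Only non-augmented (`origin == "original"`) windows
#' are used. The MLP baseline is a single-hidden-layer network trained with
#' the package's own optimizer (a hidden layer on 10,800 inputs exceeds
#' what `nnet` can fit).
#'
#' @param windows A `window_set` with integer labels.
#' @param folds Fold tibble from [grouped_folds()] (or [loso_folds()], whose
#'   `test_subject` column is accepted too).
#' @param methods Subset of `c("svm", "knn", "rf", "mlp")`.
#' @param knn_k Neighbours for kNN, default 10.
#' @param rf_trees Random-forest trees, default 100.
#' @param mlp_hidden Hidden units of the MLP baseline, default 16.
#' @param mlp_epochs Training epochs of the MLP baseline, default 20.
#' @param seed Seed for the stochastic methods.
#' @return Tibble `method`, `balanced_accuracy`, `n_scored`.
#' @export
run_baselines <- function(windows, folds,
                          methods = c("svm", "knn", "rf", "mlp"),
                          knn_k = 10, rf_trees = 100, mlp_hidden = 16,
                          mlp_epochs = 20, seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  windows <- windows[windows$origin == "original", ]
  assert_that(nrow(windows) > 0, "no original windows to score")
  assert_that(all(windows$label == round(windows$label)),
              "baseline scoring needs integer labels")
  if ("test_subject" %in% names(folds) && !"test_subjects" %in% names(folds)) {
    folds$test_subjects <- as.list(folds$test_subject)
  }
  X <- t(vapply(windows$values, as.vector,
                numeric(length(windows$values[[1]]))))
  y <- factor(windows$label, levels = 0:2)
  subj <- windows$subject_id

  restore <- .Random.seed_exists()
  on.exit(restore(), add = TRUE)

  results <- purrr::map_dfr(methods, function(m) {
    pred <- rep(NA_integer_, length(y))
    for (i in seq_len(nrow(folds))) {
      test_ids <- folds$test_subjects[[i]]
      te <- subj %in% test_ids
      tr <- !te
      if (!any(te) || !any(tr)) next
      set.seed(derive_seed(seed, paste0("baseline-", m, "-", i)))
      pred[te] <- switch(
        m,
        svm = {
          fit <- e1071::svm(X[tr, , drop = FALSE], y[tr],
                            kernel = "linear", scale = FALSE)
          as.integer(as.character(predict(fit, X[te, , drop = FALSE])))
        },
        knn = as.integer(as.character(
          class::knn(X[tr, , drop = FALSE], X[te, , drop = FALSE],
                     y[tr], k = min(knn_k, sum(tr))))),
        rf = {
          fit <- randomForest::randomForest(X[tr, , drop = FALSE], y[tr],
                                            ntree = rf_trees)
          as.integer(as.character(predict(fit, X[te, , drop = FALSE])))
        },
        mlp = mlp_baseline(X[tr, , drop = FALSE], y[tr],
                           X[te, , drop = FALSE], hidden = mlp_hidden,
                           epochs = mlp_epochs,
                           seed = derive_seed(seed, paste0("mlp-", i))))
    }
    ok <- !is.na(pred)
    cm <- confusion_matrix3(as.integer(as.character(y[ok])), pred[ok])
    tibble::tibble(method = m,
                   balanced_accuracy = clinimetrics(cm)$overall$balanced_accuracy,
                   n_scored = sum(ok))
  })
  results
}

# Fully-connected softmax network on the flattened window, trained with the
# package's compiled core (zero conv blocks are not supported there, so the
# flattened input is presented as 1 channel x P samples with a degenerate
# full-width "convolution": a single linear layer, then BN/ReLU, then the
# softmax head).
mlp_baseline <- function(Xtr, ytr, Xte, hidden = 16, epochs = 20, seed = 1L) {
  p <- ncol(Xtr)
  spec <- list(input_channels = 1L, input_len = as.integer(p),
               kernels = as.integer(p), strides = 1L)
  restore <- .Random.seed_exists()
  on.exit(restore(), add = TRUE)
  set.seed(seed)
  params <- list(
    blocks = list(list(
      W = matrix(rnorm(hidden * p, 0, sqrt(2 / p)), nrow = hidden),
      b = rep(0, hidden), gamma = rep(1, hidden), beta = rep(0, hidden),
      rmean = rep(0, hidden), rvar = rep(1, hidden))),
    fc = list(list(W = matrix(rnorm(3 * hidden, 0, sqrt(2 / hidden)), nrow = 3),
                   b = rep(0, 3))))
  Y <- soft_target(as.numeric(as.character(ytr)))
  n <- nrow(Xtr)
  shuffle <- vapply(seq_len(epochs), function(e) sample.int(n) - 1L, integer(n))
  fit <- cnn_train_cpp(params, t(Xtr), Y, spec, epochs, 32L, 1e-3, 0.1,
                       shuffle, FALSE)
  P <- cnn_forward_cpp(fit$params, t(Xte), spec, FALSE)
  as.integer(apply(P, 2, which.max) - 1L)
}
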