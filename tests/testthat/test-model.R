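test_that("the default architecture lands on 13 x 64 = 832 before the head", {
  cfg <- cnn_config()
  expect_equal(block_lengths(cfg), c(899, 223, 73, 35, 16, 14, 13))
  expect_equal(flatten_length(cfg), 832L)
  expect_equal(cfg$input_len, 3600L)
  # the alternative published channel schedule shares the length schedule
  alt <- cnn_config("paper-text")
  expect_equal(block_lengths(alt), block_lengths(cfg))
  expect_equal(flatten_length(alt), 13L * 1024L)
})

test_that("a schedule that collapses the window is rejected with the block lengths", {
  expect_error(cnn_config(strides = c(8, 8, 8, 8, 8, 8, 8)),
               "lengths", class = "motorstate_shape_error")
})

test_that("soft targets split fractional labels linearly", {
  expect_equal(soft_target(1.0)[, 1], c(OFF = 0, ON = 1, DYS = 0))
  expect_equal(soft_target(1.3)[, 1], c(OFF = 0, ON = 0.7, DYS = 0.3))
  expect_equal(soft_target(0.5)[, 1], c(OFF = 0.5, ON = 0.5, DYS = 0))
  expect_equal(soft_target(2)[, 1], c(OFF = 0, ON = 0, DYS = 1))
  expect_equal(colSums(soft_target(runif(20, 0, 2))), rep(1, 20))
  expect_error(soft_target(2.5), "\\[0, 2\\]")
})

test_that("the closed-form parameter count matches the built tensors", {
  for (preset in c("caption", "reduced")) {
    cfg <- cnn_config(preset)
    params <- build_cnn(cfg)
    # count trainable tensors only (batch-norm running stats excluded)
    counted <- sum(vapply(params$blocks, function(b)
      length(b$W) + length(b$b) + length(b$gamma) + length(b$beta),
      numeric(1))) +
      sum(vapply(params$fc, function(f) length(f$W) + length(f$b), numeric(1)))
    expect_equal(n_parameters(cfg), counted)
  }
})

test_that("analytic gradients match finite differences through conv, BN and FC", {
  net <- tiny_net(seed = 4)
  withr::local_seed(4)
  n <- 6
  X <- matrix(rnorm(2 * 12 * n), ncol = n)
  Y <- soft_target(sample(0:2, n, replace = TRUE))
  res <- motorstate:::cnn_loss_grad_cpp(net$params, X, Y, net$spec)
  h <- 1e-6
  loss_at <- function(p) motorstate:::cnn_loss_grad_cpp(p, X, Y, net$spec)$loss
  check_entries <- function(get, set, analytic, label, k = 4) {
    dims <- length(get(net$params))
    for (idx in sort(sample.int(dims, min(k, dims)))) {
      p_plus <- net$params; v <- get(p_plus); v[idx] <- v[idx] + h
      p_plus <- set(p_plus, v)
      p_minus <- net$params; v <- get(p_minus); v[idx] <- v[idx] - h
      p_minus <- set(p_minus, v)
      num <- (loss_at(p_plus) - loss_at(p_minus)) / (2 * h)
      expect_equal(analytic[idx], num, tolerance = 1e-4,
                   label = paste(label, "entry", idx))
    }
  }
  for (b in 1:2) {
    check_entries(function(p) p$blocks[[b]]$W,
                  function(p, v) { p$blocks[[b]]$W[] <- v; p },
                  as.vector(res$blocks[[b]]$W), paste("block", b, "W"))
    check_entries(function(p) p$blocks[[b]]$gamma,
                  function(p, v) { p$blocks[[b]]$gamma <- v; p },
                  as.vector(res$blocks[[b]]$gamma), paste("block", b, "gamma"))
    check_entries(function(p) p$blocks[[b]]$beta,
                  function(p, v) { p$blocks[[b]]$beta <- v; p },
                  as.vector(res$blocks[[b]]$beta), paste("block", b, "beta"))
    check_entries(function(p) p$blocks[[b]]$b,
                  function(p, v) { p$blocks[[b]]$b <- v; p },
                  as.vector(res$blocks[[b]]$b), paste("block", b, "bias"))
  }
  for (f in 1:2) {
    check_entries(function(p) p$fc[[f]]$W,
                  function(p, v) { p$fc[[f]]$W[] <- v; p },
                  as.vector(res$fc[[f]]$W), paste("fc", f, "W"))
  }
})

test_that("an untrained member outputs normalized, roughly uniform probabilities", {
  w <- make_separable_windows(1, 4)
  cfg <- cnn_config("reduced", epochs = 0, seed = 2)
  m <- train_member(w, "F01", cfg, seed = 2)
  pr <- predict_windows(m, w)
  p <- as.matrix(pr[, c("p_off", "p_on", "p_dys")])
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-6)
  expect_true(all(p >= 0))
  expect_true(all(abs(colMeans(p) - 1 / 3) < 0.25))
})

test_that("training separates spectrally distinct classes (oracle-certified fixture)", {
  w <- make_separable_windows(3, 8, seed = 21)
  # certify separability with an independent band-power multinomial logistic
  feats <- data.frame(
    lo = vapply(w$values, band_power, numeric(1), band = c(0.8, 2.2)),
    mid = vapply(w$values, band_power, numeric(1), band = c(2.3, 4)),
    hi = vapply(w$values, band_power, numeric(1), band = c(4.2, 6)),
    y = factor(w$label))
  oracle <- nnet::multinom(y ~ lo + mid + hi, feats, trace = FALSE)
  oracle_acc <- mean(predict(oracle) == feats$y)
  expect_gt(oracle_acc, 0.9)
  # the CNN should do as well on its training data
  cfg <- cnn_config("reduced", epochs = 10, batch_size = 16, seed = 3)
  m <- train_member(w, unique(w$subject_id), cfg, seed = 3)
  expect_lt(m$history[length(m$history)], m$history[1])
  pr <- predict_windows(m, w)
  acc <- mean(predicted_class(pr) == pr$label)
  expect_gt(acc, 0.9)
})

test_that("training is bit-reproducible given a seed", {
  w <- make_separable_windows(1, 3)
  cfg <- cnn_config("reduced", epochs = 2, batch_size = 8)
  m1 <- train_member(w, "F01", cfg, seed = 13)
  m2 <- train_member(w, "F01", cfg, seed = 13)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("a member refuses windows from designated test subjects", {
  w <- make_separable_windows(2, 2)
  expect_error(train_member(w, "F01", cnn_config("reduced", epochs = 1),
                            test_subjects = "F02"),
               class = "motorstate_leakage_error")
  expect_error(train_ensemble(w, cnn_config("reduced", epochs = 1),
                              test_subjects = "F01"),
               class = "motorstate_leakage_error")
})

test_that("ensemble prediction averages member softmax outputs", {
  w <- make_separable_windows(2, 3)
  cfg <- cnn_config("reduced", epochs = 2, batch_size = 16)
  m1 <- train_member(w, unique(w$subject_id), cfg, seed = 1)
  m2 <- train_member(w, unique(w$subject_id), cfg, seed = 2)
  make_ens <- function(members) structure(
    list(members = members, config = cfg, seed = 1,
         subjects = unique(w$subject_id)), class = "motor_ensemble")
  p1 <- predict_windows(m1, w)
  p2 <- predict_windows(m2, w)
  # one member: the ensemble is that member
  expect_equal(predict(make_ens(list(m1)), w), p1)
  # two members: the elementwise mean
  both <- predict(make_ens(list(m1, m2)), w)
  expect_equal(both$p_off, (p1$p_off + p2$p_off) / 2, tolerance = 1e-12)
  expect_equal(both$p_dys, (p1$p_dys + p2$p_dys) / 2, tolerance = 1e-12)
  # K identical members collapse to one
  expect_equal(predict(make_ens(list(m1, m1, m1)), w), p1, tolerance = 1e-12)
  expect_equal(rowSums(as.matrix(both[, c("p_off", "p_on", "p_dys")])),
               rep(1, nrow(both)), tolerance = 1e-6)
})

test_that("every member trains on min(15, n) subjects, never a test subject", {
  w <- make_separable_windows(4, 3)
  cfg <- cnn_config("reduced", epochs = 1, batch_size = 16)
  ens <- train_ensemble(w, cfg, n_members = 3, subset_size = 15, seed = 5)
  for (m in ens$members) expect_length(m$subjects, 4)
  ens2 <- train_ensemble(w, cfg, n_members = 3, subset_size = 2, seed = 5)
  for (m in ens2$members) expect_length(m$subjects, 2)
  td <- tidy(ens)
  expect_equal(nrow(td), 3)
  g <- glance(ens)
  expect_equal(g$n_members, 3)
  expect_equal(g$flatten_length, flatten_length(cfg))
})

test_that("rotation augmentation confers test-time rotation robustness", {
  # classes carry an axis cue that random test rotations destroy unless
  # training itself randomized pose
  train_w <- make_separable_windows(2, 6, axis_cue = TRUE, seed = 31)
  test_w <- make_separable_windows(1, 6, axis_cue = TRUE, seed = 32)
  withr::local_seed(33)
  test_rot <- rotate_window(test_w, random_rotation(nrow(test_w)))
  cfg <- cnn_config("reduced", epochs = 8, batch_size = 16)
  ba <- function(member, ws) {
    pr <- predict_windows(member, ws)
    cm <- confusion_matrix3(as.integer(pr$label), predicted_class(pr))
    clinimetrics(cm)$overall$balanced_accuracy
  }
  plain <- train_member(sliding_windows(train_w), unique(train_w$subject_id),
                        cfg, seed = 34)
  rotated <- train_member(augment_training_set(train_w, seed = 35),
                          unique(train_w$subject_id), cfg, seed = 34)
  drop_plain <- ba(plain, test_w) - ba(plain, test_rot)
  drop_rot <- ba(rotated, test_w) - ba(rotated, test_rot)
  expect_lt(drop_rot, 0.1)
  expect_lt(drop_rot, drop_plain)
})
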