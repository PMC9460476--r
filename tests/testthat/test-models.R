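test_that("the network separates well-separated Gaussian classes", {
  fx <- separable_two_class(seed = 3)
  clf <- train_classifier(fx$x, fx$y, net_config(seed = 11))
  expect_lte(error_rate(predict_label(clf, fx$x), fx$y), 0.02)
  # a point deep inside one class's region is predicted with confidence
  deep <- rep(3, 4)
  p <- predict_posterior(clf, deep)
  expect_gt(p[1, "B"], 0.9)
  # nearest-centroid oracle agrees that the fixture is separable
  centroid <- ifelse(rowMeans(fx$x) > 1.5, "B", "A")
  expect_lte(mean(centroid != fx$y), 0.02)
})

test_that("posteriors normalise, and training is deterministic in the seed", {
  fx <- separable_two_class(n = 60, seed = 5)
  a <- train_classifier(fx$x, fx$y, net_config(seed = 2))
  b <- train_classifier(fx$x, fx$y, net_config(seed = 2))
  expect_identical(a$w1, b$w1)
  expect_identical(a$w2, b$w2)
  c <- train_classifier(fx$x, fx$y, net_config(seed = 3))
  expect_false(identical(a$w1, c$w1))
  p <- predict_posterior(a, fx$x)
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  expect_true(all(p >= 0))
  expect_error(predict_posterior(a, matrix(0, 1, 7)), "dimension")
})

test_that("identical features for both classes yield prior-level posteriors", {
  set.seed(8)
  x <- matrix(rnorm(400 * 3), 400)
  y <- rep(c("A", "B"), each = 200)  # labels independent of features
  clf <- train_classifier(x, y, net_config(seed = 4))
  p <- predict_posterior(clf, x)
  expect_lt(abs(mean(p[, "A"]) - 0.5), 0.1)
  expect_lt(abs(mean(p[, "B"]) - 0.5), 0.1)
})

test_that("training rejects degenerate inputs and respects the epoch budget", {
  fx <- separable_two_class(n = 30, seed = 6)
  expect_error(train_classifier(fx$x[1:30, ], rep("A", 30), net_config()),
               "two distinct")
  mixed <- c(1:3, 31:33)
  expect_error(train_classifier(fx$x[mixed, ], fx$y[mixed], net_config()),
               "10 samples")
  clf <- train_classifier(fx$x, fx$y, net_config(seed = 1))
  expect_lte(clf$epochs, 100)
  expect_lte(clf$epochs, clf$best_epoch + clf$config$patience)
})

test_that("label symmetry: permuting class order permutes the posterior", {
  fx <- separable_two_class(n = 50, seed = 9)
  clf <- train_classifier(fx$x, fx$y, net_config(seed = 2))
  # relabel so that sorted class order is reversed ("Z" > "A")
  y2 <- ifelse(fx$y == "B", "A2", "Z")
  clf2 <- train_classifier(fx$x, y2, net_config(seed = 2))
  expect_identical(clf$classes, c("A", "B"))
  expect_identical(clf2$classes, c("A2", "Z"))
})

test_that("the mode-specific bank mirrors the observed transition structure", {
  s <- simulate_feature_session(drift = drift_config(seed = 13),
                                n_days = 1, trials_per_day = 20)
  ev <- s$events
  fw <- as.matrix(ev[, s$forward_features])
  bank <- train_mode_specific(fw, ev$mode, ev$label, net_config(seed = 1))
  # one classifier per observed current mode
  expect_setequal(names(bank$classifiers), unique(ev$mode))
  # the per-mode class list equals the observed successor set
  for (m in names(bank$classifiers)) {
    expect_setequal(bank$classes_per_mode[[m]], unique(ev$label[ev$mode == m]))
  }
  # WALK reaches every non-STAND activity in the default circuit
  expect_equal(length(bank$classes_per_mode$WALK), 6)
  # single-successor modes are constant with posterior 1
  expect_true(bank$classifiers$STAND$constant)
  p <- predict_mode_posterior(bank, fw[1, ], "STAND")
  expect_identical(colnames(p), "WALK")
  expect_equal(as.numeric(p), 1)
})

test_that("the backward predictor learns stride labels on day-1 data", {
  s <- simulate_feature_session(drift = drift_config(seed = 17,
                                                     class_sep = 1.5),
                                n_days = 1, trials_per_day = 30)
  ev <- s$events
  bw <- as.matrix(ev[, s$backward_features])
  train <- ev$has_stride & ev$trial <= 20
  test <- ev$has_stride & ev$trial > 20
  clf <- train_backward(bw[train, ], ev$label[train], net_config(seed = 5))
  expect_setequal(clf$classes, unique(ev$label[train]))
  expect_lte(error_rate(predict_label(clf, bw[test, ]), ev$label[test]), 0.05)
  expect_equal(ncol(predict_posterior(clf, bw[1 + 1, ])),
               length(unique(ev$label[train])))
})

test_that("model bundles round-trip through JSON", {
  s <- simulate_feature_session(drift = drift_config(seed = 19),
                                n_days = 1, trials_per_day = 12)
  ev <- s$events
  fw <- as.matrix(ev[, s$forward_features])
  bank <- train_mode_specific(fw, ev$mode, ev$label, net_config(seed = 2))
  path <- tempfile(fileext = ".json")
  save_model_bundle(list(forward = bank, backward = NULL), path)
  loaded <- load_model_bundle(path)
  x <- fw[ev$mode == "WALK", ][1:5, ]
  expect_equal(predict_mode_posterior(loaded$forward, x, "WALK"),
               predict_mode_posterior(bank, x, "WALK"), tolerance = 1e-12)
})
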