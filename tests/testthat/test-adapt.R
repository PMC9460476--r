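test_that("entropy matches closed forms and a hand-summed evaluation", {
  expect_equal(entropy(c(1, 0, 0)), 0)
  for (N in c(2, 5, 7)) {
    expect_equal(entropy(rep(1 / N, N)), log(N), tolerance = 1e-12)
  }
  expect_equal(entropy(c(0.7, 0.2, 0.1)), 0.801819, tolerance = 1e-5)
  expect_error(entropy(c(0.5, 0.6)), "sum")
  expect_error(entropy(c(1.2, -0.2)), "non-negative")
})

test_that("the threshold is anchored at five classes and scales with ln N", {
  expect_identical(entropy_threshold(5), 0.6)
  expect_equal(entropy_threshold(1), 0)
  expect_equal(entropy_threshold(2), 0.6 * log(2) / log(5), tolerance = 1e-12)
  expect_equal(entropy_threshold(2), 0.258406, tolerance = 1e-5)
  thr <- vapply(1:8, entropy_threshold, numeric(1))
  expect_true(all(diff(thr) > 0))
  expect_error(entropy_threshold(0), "integer")
})

make_sample <- function(i = 1, label = "WALK", mode = "WALK",
                        backward = rnorm(3)) {
  event_sample(sprintf("e%03d", i), 1, 1, i, mode, label,
               forward = rnorm(4), backward = backward)
}

test_that("entropy selection admits confident samples and rejects vague ones", {
  st <- adaptation_state("entropy")
  p1 <- c(A = 1, B = 0, C = 0)
  st <- entropy_select(st, make_sample(1, label = "A"), p1, 1L)
  expect_length(st$fpool$x, 1)
  expect_identical(st$fpool$label, "A")
  uni <- c(A = 1, B = 1, C = 1) / 3
  st <- entropy_select(st, make_sample(2), uni, 2L)
  expect_length(st$fpool$x, 1)
  log <- audit_log(st)
  expect_identical(log$decision, c("selected", "rejected"))
  # the stored label is the prediction, not the truth
  st2 <- entropy_select(adaptation_state("entropy"),
                        make_sample(3, label = "C"),
                        c(A = 0.97, B = 0.02, C = 0.01), 1L)
  expect_identical(st2$fpool$label, "A")
})

test_that("batch selection counts equal a brute-force gate", {
  set.seed(31)
  post <- random_simplex(100, 5)
  st <- adaptation_state("entropy")
  for (i in 1:100)
    st <- entropy_select(st, make_sample(i),
                         setNames(post[i, ], LETTERS[1:5]), i)
  brute <- sum(apply(post, 1, function(p) -sum(p * log(p))) <
                 0.6 / log(5) * log(5))
  expect_equal(length(st$fpool$x), brute)
  # gate decisions are invariant to class-order permutations
  st_perm <- adaptation_state("entropy")
  for (i in 1:100) {
    perm <- sample(5)
    st_perm <- entropy_select(st_perm, make_sample(i),
                              setNames(post[i, perm], LETTERS[perm]), i)
  }
  expect_equal(audit_log(st_perm)$decision, audit_log(st)$decision)
})

test_that("backward relabeling feeds the forward pool with predicted labels", {
  always_walk <- driftadapt:::prior_classifier(
    c("SIT", "WALK"), c(0, 1))
  st <- adaptation_state("backward")
  n <- 20; skipped <- 0
  for (i in 1:n) {
    has_stride <- i %% 5 != 0
    if (!has_stride) skipped <- skipped + 1
    st <- backward_relabel(st, make_sample(i, label = "SIT",
                                           backward = if (has_stride) rnorm(3)),
                           always_walk, i)
  }
  expect_length(st$fpool$x, n - skipped)
  expect_true(all(st$fpool$label == "WALK"))
  log <- audit_log(st)
  expect_equal(sum(log$decision == "skipped_no_stride"), skipped)
  expect_true(all(log$true_label == "SIT"))
})

test_that("the combined strategy gates only the backward pool", {
  confident <- driftadapt:::prior_classifier(c("A", "B"), c(1, 0))
  vague <- driftadapt:::prior_classifier(c("A", "B"), c(0.5, 0.5))
  st <- adaptation_state("backward_entropy")
  st <- backward_entropy_update(st, make_sample(1), confident, 1L)
  expect_length(st$fpool$x, 1)
  expect_length(st$bpool$x, 1)
  st <- backward_entropy_update(st, make_sample(2), vague, 2L)
  expect_length(st$fpool$x, 2)  # forward update is ungated
  expect_length(st$bpool$x, 1)  # backward pool only below threshold
  log <- audit_log(st)
  expect_identical(log$decision, c("both_pools", "forward_only"))
})

test_that("perfect updates store ground truth unconditionally", {
  st <- adaptation_state("perfect")
  for (i in 1:15) st <- perfect_update(st, make_sample(i, label = "RAMP_ASCENT"), i)
  expect_length(st$fpool$x, 15)
  expect_true(all(st$fpool$label == "RAMP_ASCENT"))
})

test_that("the scheduler retrains after every second trial and resets", {
  s <- simulate_feature_session(drift = drift_config(seed = 23),
                                n_days = 1, trials_per_day = 40)
  ev <- s$events
  fw <- as.matrix(ev[, s$forward_features])
  d1 <- ev$trial <= 20
  bank <- train_mode_specific(fw[d1, ], ev$mode[d1], ev$label[d1],
                              net_config(seed = 1))
  preds <- list(forward = bank, backward = NULL)
  st <- adaptation_state("perfect")
  for (i in which(d1))
    st <- driftadapt:::pool_append_forward(st, fw[i, ], ev$mode[i],
                                           ev$label[i], as.character(i), 0L)
  st$fdirty <- FALSE
  retrains <- integer()
  for (trial in 1:40) {
    for (i in which(ev$trial == trial))
      st <- perfect_update(st, event_sample(as.character(i), 1, trial,
                                            ev$event[i], ev$mode[i],
                                            ev$label[i], fw[i, ]), i)
    before <- st$n_retrains
    out <- maybe_retrain(st, preds, net_config(seed = 1))
    st <- out$state; preds <- out$predictors
    if (st$n_retrains > before) retrains <- c(retrains, trial)
    expect_lt(st$counter, st$interval)
  }
  expect_identical(retrains, seq(2L, 40L, by = 2L))
  expect_equal(st$n_retrains, 20)
})

test_that("the baseline strategy never retrains", {
  st <- adaptation_state("baseline")
  preds <- list(forward = NULL, backward = NULL)
  for (trial in 1:40) {
    out <- maybe_retrain(st, preds, net_config())
    st <- out$state
  }
  expect_equal(st$n_retrains, 0)
  expect_equal(nrow(audit_log(st)), 0)
})

test_that("entropy-selected samples are purer than rejected ones", {
  # with a trained forward predictor on drifting data, the wrong-label
  # fraction among selected samples must undercut that among rejected ones
  sel_err <- rej_err <- numeric(0)
  for (seed in 1:10) {
    s <- small_session(seed = seed, n_days = 2, trials_per_day = 12)
    ev <- s$events
    fw <- as.matrix(ev[, s$forward_features])
    d1 <- ev$day == 1
    bank <- train_mode_specific(fw[d1, ], ev$mode[d1], ev$label[d1],
                                net_config(seed = seed))
    idx <- which(!d1 & ev$mode == "WALK")
    post <- predict_mode_posterior(bank, fw[idx, ], "WALK")
    pred <- colnames(post)[max.col(post)]
    E <- apply(post, 1, entropy)
    gate <- E < entropy_threshold(ncol(post))
    wrong <- pred != ev$label[idx]
    if (any(gate) && any(!gate)) {
      sel_err <- c(sel_err, mean(wrong[gate]))
      rej_err <- c(rej_err, mean(wrong[!gate]))
    }
  }
  expect_gte(length(sel_err), 5)
  expect_lt(mean(sel_err), mean(rej_err))
})
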