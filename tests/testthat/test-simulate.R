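test_that("circuit specification is validated", {
  expect_s3_class(circuit_spec(), "circuit_spec")
  expect_error(circuit_spec(sequence = c("WALK", "SIT")), "begin and end")
  expect_error(circuit_spec(sequence = c("SIT", "WALK", "WALK", "SIT")),
               "consecutive")
  expect_error(circuit_spec(sequence = c("SIT", "WALK", "SIT")), "reachable")
})

test_that("drift configuration enforces its constraints", {
  expect_error(drift_config(var_scale = c(1, -1, 1, 1)), "positive")
  expect_error(drift_config(shift_magnitude = c(0.5, 1, 1, 1)), "day 1")
  expect_error(drift_config(var_scale = c(2, 1, 1, 1)), "day 1")
  bad_cov <- matrix(c(1, 2, 2, 1), 2)  # eigenvalues 3 and -1
  expect_error(drift_config(n_features = 2, cov = bad_cov),
               "positive semi-definite")
  expect_error(drift_config(n_features = 2,
                            cov = matrix(c(1, 0.5, 0.2, 1), 2)),
               "symmetric")
})

test_that("simulated sessions follow the circuit and match the daily scale", {
  s <- simulate_feature_session(drift = drift_config(seed = 11))
  ev <- s$events
  # circuit transitions: collapsing runs of equal labels in any trial must
  # reproduce the circuit segment order
  circuit <- circuit_spec()
  for (tr in c(1, 17, 40)) {
    lab <- ev$label[ev$day == 1 & ev$trial == tr]
    expect_equal(rle(lab)$values, circuit$sequence[-1])
    # mode is the previous event's label, SIT at trial start
    expect_equal(ev$mode[ev$day == 1 & ev$trial == tr],
                 c("SIT", lab[-length(lab)]))
  }
  # daily sample count emulates the recorded scale (~956 +/- 70 per day)
  per_day <- table(ev$day)
  expect_true(all(per_day >= 886 & per_day <= 1026))
  expect_identical(sort(unique(ev$day)), c(1, 2, 3, 7))
})

test_that("identical configuration and seed reproduce the session exactly", {
  a <- simulate_feature_session(drift = drift_config(seed = 4),
                                n_days = 2, trials_per_day = 3)
  b <- simulate_feature_session(drift = drift_config(seed = 4),
                                n_days = 2, trials_per_day = 3)
  expect_identical(a$events, b$events)
  c <- simulate_feature_session(drift = drift_config(seed = 5),
                                n_days = 2, trials_per_day = 3)
  expect_false(identical(a$events, c$events))
})

test_that("zero drift keeps the generator identical across days", {
  s <- simulate_feature_session(
    drift = drift_config(seed = 3, shift_magnitude = rep(0, 4),
                         var_scale = rep(1, 4)),
    n_days = 4, trials_per_day = 12)
  ev <- s$events
  fw <- as.matrix(ev[, s$forward_features])
  # per-class day means differ only by sampling error (4 SE per coordinate)
  for (cl in c("WALK", "STAIR_ASCENT")) {
    sel1 <- ev$label == cl & ev$day == 1
    m1 <- colMeans(fw[sel1, ])
    se1sq <- apply(fw[sel1, ], 2, var) / sum(sel1)
    for (d in c(2, 3, 7)) {
      sel <- ev$label == cl & ev$day == d
      se <- sqrt(se1sq + apply(fw[sel, ], 2, var) / sum(sel))
      expect_true(all(abs(colMeans(fw[sel, ]) - m1) < 4 * se))
    }
  }
})

test_that("a configured day-2 shift is realised in the sample means", {
  d <- 6
  shifts <- list(matrix(0, 7, d), rbind(matrix(0, 2, d),
                                        matrix(rep(c(1, rep(0, d - 1)), 5),
                                               5, d, byrow = TRUE)))
  drift <- drift_config(n_features = d, days = c(1, 2),
                        shift_magnitude = c(0, 1), var_scale = c(1, 1),
                        shifts = shifts, seed = 9)
  s <- simulate_feature_session(drift = drift, n_days = 2,
                                trials_per_day = 40)
  ev <- s$events
  fw <- as.matrix(ev[, s$forward_features])
  sel1 <- ev$label == "WALK" & ev$day == 1
  sel2 <- ev$label == "WALK" & ev$day == 2
  diff <- colMeans(fw[sel2, ]) - colMeans(fw[sel1, ])
  se <- sqrt(apply(fw[sel1, ], 2, var) / sum(sel1) +
               apply(fw[sel2, ], 2, var) / sum(sel2))
  expect_true(all(abs(diff - c(1, rep(0, d - 1))) < 3.5 * se))
})

test_that("class means drift within sampling error of the configured values", {
  drift <- drift_config(seed = 21)
  s <- simulate_feature_session(drift = drift, trials_per_day = 40)
  real <- driftadapt:::realize_drift(drift)
  ev <- s$events
  fw <- as.matrix(ev[, s$forward_features])
  ci <- match("WALK", drift$classes)
  for (di in seq_along(drift$days)) {
    sel <- ev$day == drift$days[di] & ev$label == "WALK"
    expect_gt(sum(sel), 500)
    target <- real$means[ci, ] + real$shifts[[di]][ci, ]
    se <- apply(fw[sel, ], 2, sd) / sqrt(sum(sel))
    expect_true(all(abs(colMeans(fw[sel, ]) - target) < 4 * se))
  }
})

test_that("raw trials place events causally and honour degenerate noise", {
  cfg <- raw_signal_config(seed = 2, mech_noise_sd = 0)
  tr <- simulate_raw_trial(cfg, seed = 5)
  # every event has a full forward window of preceding signal
  expect_true(all(tr$events$time_ms >= 300))
  # fixed-duration strides + zero noise: identical waveforms across strides
  cfg2 <- raw_signal_config(seed = 2, mech_noise_sd = 0,
                            stride_ms = c(1000, 1000))
  circ <- circuit_spec(steps = list(SIT = c(1, 1), STAND = c(1, 1),
                                    WALK = c(3, 3), STAIR_ASCENT = c(2, 2),
                                    STAIR_DESCENT = c(2, 2),
                                    RAMP_ASCENT = c(2, 2),
                                    RAMP_DESCENT = c(2, 2)))
  tr2 <- simulate_raw_trial(cfg2, circ, seed = 5)
  walk_events <- which(tr2$events$label == "WALK")
  mech <- which(tr2$block$roles == "mechanical")[1]
  stride_of <- function(j) {
    i0 <- driftadapt:::time_to_index(tr2$block, tr2$events$time_ms[j])
    tr2$block$data[i0:(i0 + 999), mech]
  }
  w <- walk_events[1:2]
  expect_equal(stride_of(w[1]), stride_of(w[2]), tolerance = 1e-12)
})

test_that("doubling the EMG burst amplitude doubles window MAV", {
  circ <- circuit_spec()
  base <- simulate_raw_trial(raw_signal_config(seed = 3, emg_amplitude = 1),
                             circ, seed = 8)
  loud <- simulate_raw_trial(raw_signal_config(seed = 3, emg_amplitude = 2),
                             circ, seed = 8)
  spec <- window_spec()
  ev_t <- base$events$time_ms[5]
  w1 <- cut_forward_window(base$block, ev_t, spec)
  w2 <- cut_forward_window(loud$block, ev_t, spec)
  emg1 <- emg_features(w1$data[, 1])
  emg2 <- emg_features(w2$data[, 1])
  expect_equal(emg2[["mav"]], 2 * emg1[["mav"]], tolerance = 1e-10)
})

test_that("inverted stride range is rejected", {
  expect_error(raw_signal_config(stride_ms = c(1300, 900)), "min <= max")
})
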