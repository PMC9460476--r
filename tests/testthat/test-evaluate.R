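test_that("error rate is the fraction of misclassified samples", {
  expect_equal(error_rate(c("A", "B"), c("A", "B")), 0)
  expect_equal(error_rate(c("A", "A"), c("B", "B")), 1)
  truth <- c("A", "A", "B", "B", "C", "C", "A", "B")
  pred <- truth; pred[c(3, 7)] <- c("A", "C")
  expect_equal(error_rate(pred, truth), 0.25)
  expect_error(error_rate(character(0), character(0)), "empty")
  expect_error(error_rate("A", c("A", "B")), "length")
})

test_that("the protocol is deterministic and never trains on unpredicted events", {
  s <- small_session(seed = 2)
  cfg <- protocol_config(strategy = "entropy", seed = 5)
  a <- run_protocol(s, cfg)
  b <- run_protocol(s, cfg)
  expect_identical(a$predictions, b$predictions)
  expect_identical(a$per_day_error, b$per_day_error)
  # causality: every pooled test event was predicted at an earlier or equal
  # stream position than its pool entry
  pooled <- data.frame(uid = a$pool$forward_uid, added = a$pool$forward_pos)
  pooled <- pooled[pooled$added > 0, ]  # position 0 = initial training data
  m <- merge(pooled, a$predictions[, c("uid", "pos")], by = "uid")
  expect_equal(nrow(m), nrow(pooled))
  expect_true(all(m$added >= m$pos))
})

test_that("initial training uses only the first half of day 1", {
  s <- small_session(seed = 3)
  res <- run_protocol(s, protocol_config(strategy = "baseline", seed = 1))
  n_day1_trials <- length(unique(s$events$trial[s$events$day == 1]))
  held_out <- unique(res$predictions$trial[res$predictions$day == 1])
  expect_equal(sort(held_out), seq(n_day1_trials / 2 + 1, n_day1_trials))
  # test stream covers everything not used for initial training
  expect_equal(nrow(res$predictions) + res$n_initial, nrow(s$events))
})

test_that("per-activity errors partition the overall error", {
  s <- small_session(seed = 4)
  res <- run_protocol(s, protocol_config(strategy = "baseline", seed = 2))
  tab <- per_activity_errors(res)
  pr <- res$predictions
  for (d in res$days) {
    counts <- table(pr$truth[pr$day == d])
    cells <- unlist(tab[tab$day == d, names(counts)])
    overall <- sum(cells * as.numeric(counts)) / sum(counts)
    expect_equal(overall, res$per_day_error[[paste0("day", d)]],
                 tolerance = 1e-12)
    # per-cell counts agree with a group-by oracle
    for (a in names(counts)) {
      sel <- pr$day == d & pr$truth == a
      expect_equal(sum(sel), as.numeric(counts[[a]]))
      expect_equal(tab[tab$day == d, a], mean(pr$predicted[sel] != a))
    }
  }
})

test_that("baseline equals a single never-updated predictor", {
  s <- small_session(seed = 6)
  res <- run_protocol(s, protocol_config(strategy = "baseline", seed = 9))
  expect_equal(nrow(res$retrain_log), 0)
  ev <- s$events
  fw <- as.matrix(ev[, s$forward_features])
  d1 <- ev$day == 1 & ev$trial <= 5
  net <- net_config(seed = driftadapt:::seed_child(9, 1))
  bank <- train_mode_specific(fw[d1, ], ev$mode[d1], ev$label[d1], net)
  idx <- match(res$predictions$uid,
               sprintf("d%g_t%03d_e%03d", ev$day, ev$trial, ev$event))
  manual <- vapply(seq_along(idx), function(j) {
    i <- idx[j]
    p <- predict_mode_posterior(bank, fw[i, ], ev$mode[i])
    colnames(p)[which.max(p)]
  }, character(1))
  expect_identical(res$predictions$predicted, manual)
})

test_that("PCA drift is fitted on day 1 and mirrors configured shifts", {
  s <- small_session(seed = 7, n_days = 2, trials_per_day = 20,
                     shift = c(0, 1.5, 1.5, 1.5), vscale = c(1, 0.8, 0.8, 0.8))
  pd <- pca_drift(s, activity = "WALK")
  sc1 <- pd$per_day$day1$scores
  v <- apply(sc1, 2, var)
  expect_true(diff(v) <= 1e-9)          # non-increasing component variances
  expect_lt(abs(cov(sc1)[1, 2]), 1e-8)  # uncorrelated day-1 scores
  # the projected day-2 shift equals the loadings applied to the true shift
  real <- driftadapt:::realize_drift(s$drift)
  walk <- match("WALK", s$drift$classes)
  delta <- real$shifts[[2]][walk, ]
  proj_delta <- as.numeric(delta %*% pd$loadings)
  got <- pd$per_day$day2$mean - pd$per_day$day1$mean
  n2 <- nrow(pd$per_day$day2$scores)
  se <- sqrt(diag(pd$per_day$day2$cov) / n2 +
               diag(pd$per_day$day1$cov) / nrow(sc1))
  expect_true(all(abs(got - proj_delta) < 4 * se))
  expect_length(pd$per_day$day1$ellipse$semi_axes, 2)
})

test_that("zero-drift day means coincide in the PCA projection", {
  s <- small_session(seed = 8, n_days = 2, trials_per_day = 20,
                     shift = rep(0, 4), vscale = rep(1, 4))
  pd <- pca_drift(s, activity = "WALK")
  n1 <- nrow(pd$per_day$day1$scores); n2 <- nrow(pd$per_day$day2$scores)
  se <- sqrt(diag(pd$per_day$day1$cov) / n1 + diag(pd$per_day$day2$cov) / n2)
  expect_true(all(abs(pd$per_day$day2$mean - pd$per_day$day1$mean) < 3.5 * se))
})

test_that("aggregation reports means and SDs across runs", {
  runs <- data.frame(run = rep(1:2, each = 2), strategy = "baseline",
                     day = rep(c(1, 2), 2), error = c(0.0, 0.1, 0.2, 0.3))
  agg <- aggregate_runs(runs)
  expect_equal(agg$mean[agg$day == 1], 0.1)
  expect_equal(agg$mean[agg$day == 2], 0.2)
  expect_equal(agg$sd[agg$day == 1], sd(c(0, 0.2)))
  same <- data.frame(run = 1:3, strategy = "s", day = 1, error = 0.25)
  agg2 <- aggregate_runs(same)
  expect_equal(agg2$sd, 0)
  expect_error(aggregate_runs(runs[runs$run == 1, ]), "2 runs")
})

test_that("unknown strategies are rejected up front", {
  expect_error(protocol_config(strategy = "votingx"), "unknown strategy")
})
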