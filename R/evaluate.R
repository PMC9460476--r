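#' Streaming multi-day evaluation protocol configuration
#'
#' @param strategy Adaptation strategy to run: `"baseline"`, `"perfect"`,
#'   `"entropy"`, `"backward"` or `"backward_entropy"`.
#' @param train_fraction Fraction of day-1 trials used for the initial
#'   training (first trials chronologically, default 0.5).
#' @param retrain_interval Retrain interval in trials.
#' @param seed Seed controlling initial training and every retrain.
#' @param net A [net_config()] with the training regimen.
#' @param pool_cap Optional FIFO cap on the training pools.
#' @param random_split Use a random (rather than chronological) day-1 split.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(strategy = "baseline", train_fraction = 0.5,
                            retrain_interval = 2L, seed = 1L,
                            net = net_config(), pool_cap = Inf,
                            random_split = FALSE) {
  strategies <- c("baseline", "perfect", "entropy", "backward",
                  "backward_entropy")
  if (!strategy %in% strategies)
    stop_validation("unknown strategy '%s' (use one of: %s)", strategy,
                    paste(strategies, collapse = ", "))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_validation("train_fraction must lie in (0, 1)")
  if (!is_count(retrain_interval)) stop_validation("retrain_interval must be >= 1")
  structure(list(strategy = strategy, train_fraction = train_fraction,
                 retrain_interval = as.integer(retrain_interval),
                 seed = as.integer(seed), net = net, pool_cap = pool_cap,
                 random_split = isTRUE(random_split)),
            class = "protocol_config")
}

#' Classification error rate
#'
#' The number of wrongly classified samples divided by the total number of
#' samples.
#'
#' @param predictions,truth Equal-length non-empty label vectors.
#' @return Error rate in `[0, 1]`.
#' @export
error_rate <- function(predictions, truth) {
  if (!length(truth)) stop_validation("error_rate of an empty set is undefined")
  if (length(predictions) != length(truth))
    stop_validation("predictions (%d) and truth (%d) differ in length",
                    length(predictions), length(truth))
  mean(predictions != truth)
}

#' Run the streaming multi-day evaluation protocol
#'
#' Trains the forward predictor bank (and, for the backward strategies, the
#' backward predictor) on the initial fraction of day-1 trials, then streams
#' the remaining trials in chronological order. Every event of a trial is
#' first predicted with the current predictors; only afterwards is the trial
#' handed to the adaptation strategy, which may pool samples and retrain on
#' the trial schedule. No event can therefore contribute to any training
#' pool before it has been predicted, and the returned audit trail carries
#' the stream positions needed to verify this.
#'
#' @param dataset A `gait_session` from [simulate_feature_session()] or
#'   [read_session()].
#' @param config A [protocol_config()].
#' @return An object of class `evaluation_result` with per-day forward (and
#'   where applicable backward) error rates, per-day per-activity error
#'   rates, the running per-trial error curve, the prediction table, the
#'   selection audit and the retrain log.
#' @export
run_protocol <- function(dataset, config = protocol_config()) {
  if (!inherits(dataset, "gait_session"))
    stop_validation("dataset must be a gait_session")
  ev <- dataset$events
  days <- sort(unique(ev$day))
  d1 <- days[1L]
  trials1 <- sort(unique(ev$trial[ev$day == d1]))
  if (length(trials1) < 2L) stop_validation("day 1 must contain at least 2 trials")
  n_init <- max(1L, floor(config$train_fraction * length(trials1)))
  init_trials <- if (config$random_split)
    sort(with_local_seed(seed_child(config$seed, 55),
                         sample(trials1, n_init)))
  else trials1[seq_len(n_init)]
  init_mask <- ev$day == d1 & ev$trial %in% init_trials

  fw <- as.matrix(ev[, dataset$forward_features, drop = FALSE])
  bw <- as.matrix(ev[, dataset$backward_features, drop = FALSE])
  uid <- sprintf("d%g_t%03d_e%03d", ev$day, ev$trial, ev$event)

  net <- config$net
  net$seed <- seed_child(config$seed, 1)
  bank <- train_mode_specific(fw[init_mask, , drop = FALSE],
                              ev$mode[init_mask], ev$label[init_mask], net)
  needs_backward <- config$strategy %in% c("backward", "backward_entropy")
  back_clf <- NULL
  if (needs_backward) {
    bsel <- init_mask & ev$has_stride
    bnet <- config$net
    bnet$seed <- seed_child(config$seed, 2)
    back_clf <- train_backward(bw[bsel, , drop = FALSE], ev$label[bsel], bnet)
  }

  state <- adaptation_state(config$strategy, interval = config$retrain_interval,
                            pool_cap = config$pool_cap)
  # seed the pools with the initial training data (stream position 0: these
  # samples are never predicted)
  for (i in which(init_mask))
    state <- pool_append_forward(state, fw[i, ], ev$mode[i], ev$label[i],
                                 uid[i], 0L)
  if (needs_backward)
    for (i in which(init_mask & ev$has_stride))
      state <- pool_append_backward(state, bw[i, ], ev$label[i], uid[i], 0L)
  state$fdirty <- FALSE
  state$bdirty <- FALSE

  predictors <- list(forward = bank, backward = back_clf)
  net_base <- config$net
  net_base$seed <- config$seed

  test_idx <- which(!init_mask)
  ord <- test_idx[order(ev$day[test_idx], ev$trial[test_idx], ev$event[test_idx])]
  trial_key <- paste(ev$day[ord], ev$trial[ord])
  pred <- character(length(ord))
  back_pred <- rep(NA_character_, length(ord))
  pos_of <- integer(length(ord))
  stream_pos <- 0L

  for (tk in unique(trial_key)) {
    rows <- which(trial_key == tk)
    idx <- ord[rows]
    # 1) predict every event of the trial with the current predictors
    for (m in unique(ev$mode[idx])) {
      sel <- rows[ev$mode[idx] == m]
      p <- predict_mode_posterior(predictors$forward, fw[ord[sel], , drop = FALSE], m)
      cls <- predictors$forward$classifiers[[m]]$classes
      pred[sel] <- cls[max.col(p, ties.method = "first")]
    }
    if (needs_backward) {
      sel <- rows[ev$has_stride[idx]]
      if (length(sel))
        back_pred[sel] <- predict_label(predictors$backward,
                                        bw[ord[sel], , drop = FALSE])
    }
    pos_of[rows] <- stream_pos + seq_along(rows)
    stream_pos <- stream_pos + length(rows)

    # 2) hand the predicted trial to the strategy
    for (r in rows) {
      i <- ord[r]
      smp <- event_sample(uid[i], ev$day[i], ev$trial[i], ev$event[i],
                          ev$mode[i], ev$label[i], fw[i, ],
                          if (ev$has_stride[i]) bw[i, ] else NULL)
      state <- switch(config$strategy,
        baseline = state,
        perfect = perfect_update(state, smp, pos_of[r]),
        entropy = {
          post <- predict_mode_posterior(predictors$forward, smp$forward,
                                         smp$mode)
          entropy_select(state, smp, post, pos_of[r])
        },
        backward = backward_relabel(state, smp, predictors$backward, pos_of[r]),
        backward_entropy = backward_entropy_update(state, smp,
                                                   predictors$backward,
                                                   pos_of[r]))
    }
    # 3) scheduler tick at trial end
    res <- maybe_retrain(state, predictors, net_base)
    state <- res$state
    predictors <- res$predictors
  }

  predictions <- data.frame(uid = uid[ord], day = ev$day[ord],
                            trial = ev$trial[ord], event = ev$event[ord],
                            mode = ev$mode[ord], truth = ev$label[ord],
                            predicted = pred, backward_predicted = back_pred,
                            pos = pos_of, stringsAsFactors = FALSE)

  per_day <- vapply(days, function(d) {
    sel <- predictions$day == d
    error_rate(predictions$predicted[sel], predictions$truth[sel])
  }, numeric(1))
  names(per_day) <- paste0("day", days)

  per_day_backward <- NULL
  if (needs_backward) {
    per_day_backward <- vapply(days, function(d) {
      sel <- predictions$day == d & !is.na(predictions$backward_predicted)
      error_rate(predictions$backward_predicted[sel], predictions$truth[sel])
    }, numeric(1))
    names(per_day_backward) <- paste0("day", days)
  }

  running <- do.call(rbind, lapply(split(predictions,
                                         list(predictions$day, predictions$trial),
                                         drop = TRUE), function(g)
    data.frame(day = g$day[1L], trial = g$trial[1L],
               error = error_rate(g$predicted, g$truth),
               n = nrow(g), stringsAsFactors = FALSE)))
  running <- running[order(running$day, running$trial), ]
  rownames(running) <- NULL

  retrain_log <- if (length(state$retrain_log))
    do.call(rbind, lapply(state$retrain_log, function(r)
      data.frame(r, stringsAsFactors = FALSE)))
  else data.frame(retrain = integer(), trained = character(),
                  forward_pool = integer(), backward_pool = integer())

  result <- structure(list(strategy = config$strategy, days = days,
                           per_day_error = per_day,
                           per_day_backward_error = per_day_backward,
                           running = running, predictions = predictions,
                           audit = audit_log(state), retrain_log = retrain_log,
                           pool = list(forward_uid = state$fpool$uid,
                                       forward_pos = state$fpool$pos,
                                       backward_uid = state$bpool$uid,
                                       backward_pos = state$bpool$pos),
                           n_initial = sum(init_mask), config = config),
                      class = "evaluation_result")
  result$per_activity <- per_activity_errors(result)
  result
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("evaluation_result: strategy %s, %d test events, %d retrains\n",
              x$strategy, nrow(x$predictions), nrow(x$retrain_log)))
  cat("  forward error per day:\n")
  print(round(x$per_day_error, 4))
  if (!is.null(x$per_day_backward_error)) {
    cat("  backward error per day:\n")
    print(round(x$per_day_backward_error, 4))
  }
  invisible(x)
}

#' Per-day, per-activity error rates
#'
#' Error rates conditioned on the *true* activity label, one cell per day
#' and activity; cells without samples are `NA`.
#'
#' @param result An `evaluation_result`.
#' @return Data frame with rows = days, columns = activities, plus a `day`
#'   column.
#' @export
per_activity_errors <- function(result) {
  pr <- result$predictions
  acts <- sort(unique(pr$truth))
  out <- data.frame(day = result$days)
  for (a in acts) {
    out[[a]] <- vapply(result$days, function(d) {
      sel <- pr$day == d & pr$truth == a
      if (!any(sel)) NA_real_ else error_rate(pr$predicted[sel], pr$truth[sel])
    }, numeric(1))
  }
  out
}

#' PCA projection of the day-to-day feature drift
#'
#' Fits a principal component analysis on the day-1 forward feature matrix
#' only (centred with the day-1 mean), projects every day onto those
#' components and summarises each day's cloud by its projected mean,
#' covariance and one-standard-deviation ellipse parameters.
#'
#' @param dataset A `gait_session`.
#' @param n_components Number of components retained (default 2).
#' @param activity Optional single activity label to restrict the events to
#'   (e.g. ramp walking); all events when `NULL`.
#' @return An object of class `pca_drift`: list with `loadings`, `center`,
#'   `explained` and a per-day list of `scores`, `mean`, `cov` and
#'   `ellipse` (semi-axes and orientation angle in radians).
#' @export
pca_drift <- function(dataset, n_components = 2L, activity = NULL) {
  ev <- dataset$events
  keep <- rep(TRUE, nrow(ev))
  if (!is.null(activity)) keep <- ev$label == activity
  x <- as.matrix(ev[keep, dataset$forward_features, drop = FALSE])
  day <- ev$day[keep]
  days <- sort(unique(day))
  x1 <- x[day == days[1L], , drop = FALSE]
  if (qr(scale(x1, scale = FALSE))$rank < n_components)
    stop_validation("day-1 feature matrix has rank below %d", n_components)
  pc <- prcomp(x1, center = TRUE, scale. = FALSE)
  loadings <- pc$rotation[, seq_len(n_components), drop = FALSE]
  center <- pc$center
  per_day <- lapply(days, function(d) {
    scores <- sweep(x[day == d, , drop = FALSE], 2L, center, `-`) %*% loadings
    mu <- colMeans(scores)
    cv <- cov(scores)
    ell <- NULL
    if (n_components == 2L) {
      ei <- eigen(cv, symmetric = TRUE)
      ell <- list(semi_axes = sqrt(pmax(ei$values, 0)),
                  angle = atan2(ei$vectors[2L, 1L], ei$vectors[1L, 1L]))
    }
    list(day = d, scores = scores, mean = mu, cov = cv, ellipse = ell)
  })
  names(per_day) <- paste0("day", days)
  structure(list(loadings = loadings, center = center,
                 explained = pc$sdev^2 / sum(pc$sdev^2), per_day = per_day,
                 days = days),
            class = "pca_drift")
}

#' @export
print.pca_drift <- function(x, ...) {
  cat(sprintf("pca_drift: %d components, days %s\n", ncol(x$loadings),
              paste(x$days, collapse = ", ")))
  for (d in names(x$per_day))
    cat(sprintf("  %s: mean (%s)\n", d,
                paste(sprintf("%.3f", x$per_day[[d]]$mean), collapse = ", ")))
  invisible(x)
}

#' Aggregate evaluation runs across seeds or subjects
#'
#' @param runs Data frame with columns `run`, `strategy`, `day`, `error`
#'   (long format, one row per run/strategy/day), as produced by
#'   [compare_strategies()].
#' @return Data frame with per-strategy per-day mean and SD across runs.
#' @export
aggregate_runs <- function(runs) {
  if (length(unique(runs$run)) < 2L)
    stop_validation("aggregation requires at least 2 runs")
  agg <- aggregate(error ~ strategy + day, data = runs,
                   FUN = function(v) c(mean = mean(v), sd = sd(v), n = length(v)))
  out <- data.frame(strategy = agg$strategy, day = agg$day,
                    mean = agg$error[, "mean"], sd = agg$error[, "sd"],
                    n = as.integer(agg$error[, "n"]),
                    stringsAsFactors = FALSE)
  out[order(out$strategy, out$day), ]
}

#' Run several adaptation strategies over seeded simulated sessions
#'
#' For each seed, simulates one multi-day session under the given drift
#' conditions and runs every requested strategy on the identical stream, so
#' strategies are compared pairwise on the same data.
#'
#' @param seeds Integer vector of simulation seeds (one session per seed).
#' @param strategies Character vector of strategy names.
#' @param drift A [drift_config()] template; its seed is replaced per run.
#' @param circuit A [circuit_spec()].
#' @param n_days,trials_per_day Session dimensions.
#' @param net A [net_config()].
#' @param keep_results Keep the full `evaluation_result` objects (memory
#'   permitting) in addition to the summary table.
#' @return List with `errors` (long data frame: run, strategy, day, error,
#'   backward_error) and, when requested, `results` (nested list by seed and
#'   strategy).
#' @export
compare_strategies <- function(seeds = 1:5,
                               strategies = c("baseline", "perfect", "entropy",
                                              "backward", "backward_entropy"),
                               drift = drift_config(), circuit = circuit_spec(),
                               n_days = length(drift$days),
                               trials_per_day = 40L, net = net_config(),
                               keep_results = FALSE) {
  rows <- list()
  results <- if (keep_results) list() else NULL
  for (s in seeds) {
    dr <- drift
    dr$seed <- seed_child(s, 0)
    session <- simulate_feature_session(circuit, dr, n_days = n_days,
                                        trials_per_day = trials_per_day)
    if (keep_results) results[[as.character(s)]] <- list()
    for (st in strategies) {
      cfg <- protocol_config(strategy = st, seed = seed_child(s, 3), net = net)
      res <- run_protocol(session, cfg)
      for (d in res$days) {
        rows[[length(rows) + 1L]] <- data.frame(
          run = s, strategy = st, day = d,
          error = res$per_day_error[[paste0("day", d)]],
          backward_error = if (is.null(res$per_day_backward_error)) NA_real_
                           else res$per_day_backward_error[[paste0("day", d)]],
          stringsAsFactors = FALSE)
      }
      if (keep_results) results[[as.character(s)]][[st]] <- res
    }
  }
  out <- list(errors = do.call(rbind, rows))
  if (keep_results) out$results <- results
  out
}
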