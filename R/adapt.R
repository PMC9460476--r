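#' Posterior entropy
#'
#' Shannon entropy `E = -sum(p_k * log(p_k))` (natural log, `0 * log(0) = 0`)
#' of a posterior probability vector, the confidence measure behind the
#' entropy gate: the lower the entropy, the more confident the prediction.
#'
#' @param p Non-negative probability vector summing to 1 (within 1e-6).
#' @return Entropy in nats, between 0 and `log(length(p))`.
#' @export
entropy <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0)) stop_validation("posterior entries must be non-negative")
  if (abs(sum(p) - 1) > 1e-6)
    stop_validation("posterior must sum to 1 (got %.8f)", sum(p))
  pos <- p[p > 0]
  -sum(pos * log(pos))
}

#' Class-count-scaled entropy threshold
#'
#' The sample-selection threshold `Thr(N) = 0.6 / ln(5) * ln(N)`, anchored so
#' that five classes give exactly 0.6 and scaled with the natural log of the
#' class count so modes with different numbers of reachable activities are
#' gated comparably. `Thr(1) = 0`, and selection uses a strict inequality, so
#' single-class (constant) modes never select.
#'
#' @param n_classes Number of classes `N >= 1`.
#' @param base Threshold value at the reference class count.
#' @param reference_classes Reference class count (default 5).
#' @return The threshold in nats.
#' @export
entropy_threshold <- function(n_classes, base = 0.6, reference_classes = 5L) {
  if (!is_count(n_classes)) stop_validation("n_classes must be an integer >= 1")
  base * (log(n_classes) / log(reference_classes))
}

#' Adaptation state of one strategy run
#'
#' Holds the growing forward and backward training pools, the retrain
#' scheduler counter and the selection/relabel audit log for one strategy.
#' Pools only grow (unless a FIFO cap is set); every pooled sample carries
#' the identity of its source event and the stream position at which it was
#' added, which is what the protocol-causality audit checks.
#'
#' @param strategy One of `"baseline"`, `"perfect"`, `"entropy"`,
#'   `"backward"`, `"backward_entropy"`.
#' @param interval Retrain interval in trials (default 2).
#' @param pool_cap Optional FIFO cap on pool size (default unlimited).
#' @return An object of class `adaptation_state`.
#' @export
adaptation_state <- function(strategy = c("baseline", "perfect", "entropy",
                                          "backward", "backward_entropy"),
                             interval = 2L, pool_cap = Inf) {
  strategy <- match.arg(strategy)
  if (!is_count(interval)) stop_validation("retrain interval must be >= 1")
  if (!is.infinite(pool_cap) && !is_count(pool_cap))
    stop_validation("pool_cap must be a positive integer or Inf")
  structure(list(strategy = strategy, interval = as.integer(interval),
                 counter = 0L, pool_cap = pool_cap,
                 fpool = list(x = list(), mode = character(), label = character(),
                              uid = character(), pos = integer()),
                 bpool = list(x = list(), label = character(),
                              uid = character(), pos = integer()),
                 fdirty = FALSE, bdirty = FALSE,
                 n_retrains = 0L, audit = list(), retrain_log = list()),
            class = "adaptation_state")
}

#' @export
print.adaptation_state <- function(x, ...) {
  cat(sprintf("adaptation_state: strategy %s, forward pool %d, backward pool %d, %d retrains\n",
              x$strategy, length(x$fpool$x), length(x$bpool$x), x$n_retrains))
  invisible(x)
}

pool_append_forward <- function(state, x, mode, label, uid, pos) {
  p <- state$fpool
  k <- length(p$x) + 1L
  p$x[[k]] <- x; p$mode[k] <- mode; p$label[k] <- label
  p$uid[k] <- uid; p$pos[k] <- pos
  if (is.finite(state$pool_cap) && k > state$pool_cap) {
    keep <- (k - state$pool_cap + 1L):k
    p <- list(x = p$x[keep], mode = p$mode[keep], label = p$label[keep],
              uid = p$uid[keep], pos = p$pos[keep])
  }
  state$fpool <- p
  state$fdirty <- TRUE
  state
}

pool_append_backward <- function(state, x, label, uid, pos) {
  p <- state$bpool
  k <- length(p$x) + 1L
  p$x[[k]] <- x; p$label[k] <- label; p$uid[k] <- uid; p$pos[k] <- pos
  if (is.finite(state$pool_cap) && k > state$pool_cap) {
    keep <- (k - state$pool_cap + 1L):k
    p <- list(x = p$x[keep], label = p$label[keep], uid = p$uid[keep],
              pos = p$pos[keep])
  }
  state$bpool <- p
  state$bdirty <- TRUE
  state
}

audit_append <- function(state, uid, rule, E, thr, decision, assigned, truth, pos) {
  state$audit[[length(state$audit) + 1L]] <-
    list(uid = uid, rule = rule, entropy = E, threshold = thr,
         decision = decision, assigned_label = assigned, true_label = truth,
         pos = pos)
  state
}

#' Audit log of an adaptation state as a data frame
#'
#' @param state An [adaptation_state()].
#' @return Data frame with one row per gating decision: event id, rule,
#'   entropy, threshold, decision, assigned label, true label and the stream
#'   position at which the decision was taken.
#' @export
audit_log <- function(state) {
  if (!length(state$audit))
    return(data.frame(uid = character(), rule = character(),
                      entropy = numeric(), threshold = numeric(),
                      decision = character(), assigned_label = character(),
                      true_label = character(), pos = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(state$audit, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
}

#' Construct one gait-event sample
#'
#' The unit record consumed by the adaptation rules: a gait event with its
#' forward feature vector, optional backward (previous-stride) feature
#' vector, current mode and true upcoming activity.
#'
#' @param uid Unique event identifier.
#' @param day,trial,event Position of the event in the session.
#' @param mode Current activity mode at the event.
#' @param label True upcoming activity.
#' @param forward Forward feature vector.
#' @param backward Backward feature vector, or `NULL` for the first event of
#'   a trial (no completed stride).
#' @return A list of class-free event-sample fields.
#' @export
event_sample <- function(uid, day, trial, event, mode, label, forward,
                         backward = NULL) {
  list(uid = uid, day = day, trial = trial, event = event, mode = mode,
       label = label, forward = forward, backward = backward)
}

#' Entropy-gated sample selection
#'
#' Admits the sample's forward features with its *predicted* label into the
#' forward training pool iff the posterior entropy is strictly below the
#' class-count-scaled threshold for the sample's mode. Ties and single-class
#' modes (entropy 0, threshold 0) are rejected.
#'
#' @param state An [adaptation_state()].
#' @param sample An event sample (list with `uid`, `mode`, `label`,
#'   `forward` at minimum).
#' @param posterior Forward-predictor posterior for this sample's mode.
#' @param pos Stream position (events predicted so far) used by the audit.
#' @return The updated state.
#' @export
entropy_select <- function(state, sample, posterior, pos = NA_integer_) {
  labels <- if (is.matrix(posterior)) colnames(posterior) else names(posterior)
  p <- as.numeric(posterior)
  E <- entropy(p)
  thr <- entropy_threshold(length(p))
  predicted <- if (is.null(labels)) as.character(which.max(p)) else labels[which.max(p)]
  selected <- E < thr
  if (selected)
    state <- pool_append_forward(state, sample$forward, sample$mode, predicted,
                                 sample$uid, pos)
  audit_append(state, sample$uid, "entropy_select", E, thr,
               if (selected) "selected" else "rejected", predicted,
               sample$label, pos)
}

#' Backward-prediction relabeling
#'
#' Labels the just-completed stride with the backward predictor and attaches
#' that label to the sample's *forward* features, which join the forward
#' pool unconditionally (no entropy gate on the forward update). Samples
#' without a completed stride (first event of a trial) are skipped and
#' logged.
#'
#' @param state An [adaptation_state()].
#' @param sample An event sample carrying `backward` stride features (or
#'   `NULL`).
#' @param backward_clf The current backward `gait_classifier`.
#' @param pos Stream position for the audit.
#' @return The updated state.
#' @export
backward_relabel <- function(state, sample, backward_clf, pos = NA_integer_) {
  if (is.null(sample$backward) || anyNA(sample$backward))
    return(audit_append(state, sample$uid, "backward_relabel", NA_real_,
                        NA_real_, "skipped_no_stride", NA_character_,
                        sample$label, pos))
  post <- predict_posterior(backward_clf, sample$backward)
  lab <- colnames(post)[which.max(post)]
  state <- pool_append_forward(state, sample$forward, sample$mode, lab,
                               sample$uid, pos)
  audit_append(state, sample$uid, "backward_relabel", NA_real_, NA_real_,
               "relabeled", lab, sample$label, pos)
}

#' Backward relabeling with entropy adaptation of the backward predictor
#'
#' Performs exactly the forward-pool update of [backward_relabel()];
#' additionally, when the backward posterior's entropy is strictly below the
#' threshold for the backward class count, the (stride features,
#' backward-predicted label) pair also joins the backward predictor's own
#' training pool, so both predictors adapt on the retrain schedule.
#'
#' @inheritParams backward_relabel
#' @return The updated state.
#' @export
backward_entropy_update <- function(state, sample, backward_clf,
                                    pos = NA_integer_) {
  if (is.null(sample$backward) || anyNA(sample$backward))
    return(audit_append(state, sample$uid, "backward_entropy", NA_real_,
                        NA_real_, "skipped_no_stride", NA_character_,
                        sample$label, pos))
  post <- predict_posterior(backward_clf, sample$backward)
  lab <- colnames(post)[which.max(post)]
  state <- pool_append_forward(state, sample$forward, sample$mode, lab,
                               sample$uid, pos)
  E <- entropy(as.numeric(post))
  thr <- entropy_threshold(length(backward_clf$classes))
  gated <- E < thr
  if (gated)
    state <- pool_append_backward(state, sample$backward, lab, sample$uid, pos)
  audit_append(state, sample$uid, "backward_entropy", E, thr,
               if (gated) "both_pools" else "forward_only", lab,
               sample$label, pos)
}

#' Ground-truth (perfect-label) update
#'
#' Adds the sample's forward features with its true label to the forward
#' pool unconditionally; the reference strategy an adaptive system is
#' compared against.
#'
#' @inheritParams entropy_select
#' @return The updated state.
#' @export
perfect_update <- function(state, sample, pos = NA_integer_) {
  state <- pool_append_forward(state, sample$forward, sample$mode,
                               sample$label, sample$uid, pos)
  audit_append(state, sample$uid, "perfect", NA_real_, NA_real_, "stored",
               sample$label, sample$label, pos)
}

# Assemble a pool into matrices for retraining.
pool_matrices_forward <- function(state) {
  list(x = do.call(rbind, state$fpool$x), mode = state$fpool$mode,
       label = state$fpool$label)
}

pool_matrices_backward <- function(state) {
  list(x = do.call(rbind, state$bpool$x), label = state$bpool$label)
}

#' Retrain scheduler
#'
#' Called once per completed trial: increments the trial counter and, when
#' it reaches the retrain interval, retrains the strategy's predictors from
#' scratch on the current pools with a fresh derived seed and resets the
#' counter. The baseline strategy never retrains; retrains whose pools have
#' not changed since the previous retrain are skipped. Per-mode class lists
#' are fixed to those observed at initial training; pooled samples whose
#' (pseudo-)label falls outside their mode's class list are excluded from
#' that mode's retrain.
#'
#' @param state An [adaptation_state()].
#' @param predictors List with elements `forward` (a
#'   `mode_specific_predictor`) and optionally `backward` (a
#'   `gait_classifier`).
#' @param config A [net_config()] providing the base seed and regimen.
#' @return List with the updated `state` and `predictors`.
#' @export
maybe_retrain <- function(state, predictors, config = net_config()) {
  state$counter <- state$counter + 1L
  if (state$counter < state$interval)
    return(list(state = state, predictors = predictors))
  state$counter <- 0L
  if (state$strategy == "baseline")
    return(list(state = state, predictors = predictors))

  did <- character()
  if (state$fdirty) {
    pool <- pool_matrices_forward(state)
    cfg <- config
    cfg$seed <- seed_child(config$seed, 7000L + state$n_retrains)
    predictors$forward <- retrain_forward_bank(predictors$forward, pool, cfg)
    state$fdirty <- FALSE
    did <- c(did, "forward")
  }
  if (state$strategy == "backward_entropy" && state$bdirty) {
    pool <- pool_matrices_backward(state)
    cfg <- config
    cfg$seed <- seed_child(config$seed, 9000L + state$n_retrains)
    keep <- pool$label %in% predictors$backward$classes
    if (sum(keep) >= 10L && length(unique(pool$label[keep])) >= 2L) {
      predictors$backward <- train_backward(pool$x[keep, , drop = FALSE],
                                            pool$label[keep], cfg)
      did <- c(did, "backward")
    }
    state$bdirty <- FALSE
  }
  if (length(did)) {
    state$n_retrains <- state$n_retrains + 1L
    state$retrain_log[[length(state$retrain_log) + 1L]] <-
      list(retrain = state$n_retrains, trained = paste(did, collapse = "+"),
           forward_pool = length(state$fpool$x),
           backward_pool = length(state$bpool$x))
  }
  list(state = state, predictors = predictors)
}

# Retrain every mode's classifier on the pooled samples, keeping the class
# lists fixed at those observed in the initial training data.
retrain_forward_bank <- function(bank, pool, config) {
  classifiers <- bank$classifiers
  for (i in seq_along(classifiers)) {
    m <- names(classifiers)[i]
    classes <- bank$classes_per_mode[[m]]
    if (length(classes) < 2L) next  # constant mode stays constant
    sel <- pool$mode == m & pool$label %in% classes
    if (sum(sel) < 10L || length(unique(pool$label[sel])) < 2L) next
    cfg <- config
    cfg$seed <- seed_child(config$seed, i)
    classifiers[[m]] <- train_classifier(pool$x[sel, , drop = FALSE],
                                         pool$label[sel], cfg)
  }
  bank$classifiers <- classifiers
  bank
}
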