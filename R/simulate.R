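#' Gait activity labels
#'
#' The closed set of gait-related activities used throughout the package:
#' sitting, standing, level-ground walking, stair ascent/descent and ramp
#' ascent/descent. Every event's true label and current mode must be a member.
#'
#' @return Character vector of the seven activity labels.
#' @export
activity_levels <- function() {
  c("SIT", "STAND", "WALK", "STAIR_ASCENT", "STAIR_DESCENT",
    "RAMP_ASCENT", "RAMP_DESCENT")
}

#' Activity circuit specification
#'
#' Describes the fixed circuit a subject performs in every trial: the ordered
#' sequence of activities and how many gait events (steps) each activity
#' segment contributes. The default circuit starts seated, stands up, walks,
#' ascends the stairs, walks, descends the ramp, walks (turn), walks back,
#' ascends the ramp, walks, descends the stairs, walks and sits down again.
#' The leading `SIT` entry is the rest state the trial starts from and emits
#' no event of its own.
#'
#' @param sequence Character vector of activity labels. Must begin and end
#'   with `"SIT"`, consecutive entries must differ, and every activity label
#'   must appear.
#' @param steps Named list mapping each activity to an integer range
#'   `c(min, max)` of events emitted per visit of that activity.
#' @return An object of class `circuit_spec`.
#' @export
circuit_spec <- function(sequence = c("SIT", "STAND", "WALK", "STAIR_ASCENT",
                                      "WALK", "RAMP_DESCENT", "WALK",
                                      "RAMP_ASCENT", "WALK", "STAIR_DESCENT",
                                      "WALK", "SIT"),
                         steps = list(SIT = c(1L, 1L), STAND = c(1L, 1L),
                                      WALK = c(2L, 4L),
                                      STAIR_ASCENT = c(2L, 2L),
                                      STAIR_DESCENT = c(2L, 2L),
                                      RAMP_ASCENT = c(2L, 2L),
                                      RAMP_DESCENT = c(2L, 2L))) {
  sequence <- as.character(sequence)
  if (length(sequence) < 2L)
    stop_validation("circuit sequence must contain at least two entries")
  if (!all(sequence %in% activity_levels()))
    stop_validation("circuit sequence contains unknown activity labels: %s",
                    paste(setdiff(sequence, activity_levels()), collapse = ", "))
  if (sequence[1L] != "SIT" || sequence[length(sequence)] != "SIT")
    stop_validation("circuit sequence must begin and end with SIT")
  if (any(sequence[-1L] == sequence[-length(sequence)]))
    stop_validation("consecutive circuit entries must differ (write a contiguous activity as one segment)")
  if (!all(activity_levels() %in% sequence))
    stop_validation("every activity label must be reachable in the circuit")
  missing_steps <- setdiff(unique(sequence[-1L]), names(steps))
  if (length(missing_steps))
    stop_validation("steps range missing for: %s",
                    paste(missing_steps, collapse = ", "))
  for (nm in names(steps)) {
    r <- steps[[nm]]
    if (length(r) != 2L || any(r < 1L) || r[1L] > r[2L])
      stop_validation("steps range for %s must be c(min, max) with 1 <= min <= max", nm)
  }
  structure(list(sequence = sequence, steps = steps), class = "circuit_spec")
}

#' Concept-drift configuration for the feature-level simulator
#'
#' Defines the class-conditional feature distributions and their day-to-day
#' drift. Each activity class has a base mean vector and covariance; on
#' measurement day `d` the mean is shifted by `shift_magnitude[d]` along a
#' fixed per-class unit direction and the covariance is scaled by
#' `var_scale[d]`. The defaults emulate one week of recording on days 1, 2, 3
#' and 7 where the within-day variation is largest on day 1 and the largest
#' mean shift happens between day 1 and day 2, after which the error plateau
#' sets in.
#'
#' @param n_features Feature dimension of the generated vectors.
#' @param classes Activity labels to simulate (default all seven).
#' @param days Numeric day labels; day 1 must come first.
#' @param class_sep Scale of the random class-mean placement, in within-class
#'   standard deviations. Larger values give more separable classes.
#' @param shift_magnitude Per-day mean-shift magnitudes (day 1 must be 0).
#' @param shift_direction How the per-class unit shift direction is chosen:
#'   `"nearest_class"` (default) drifts each class toward its nearest
#'   neighbouring class mean, emulating the loss of specificity that sensor
#'   replacement and skin-condition changes cause; `"random"` drifts along a
#'   fixed random direction.
#' @param var_scale Per-day covariance scale factors (day 1 must be 1, all
#'   must be positive).
#' @param means Optional classes-by-features matrix of base class means;
#'   drawn from the seed when `NULL`.
#' @param cov Optional base covariance matrix shared by all classes
#'   (symmetric positive semi-definite); identity when `NULL`.
#' @param shifts Optional list (one element per day) of classes-by-features
#'   shift matrices overriding the magnitude-times-direction construction.
#' @param seed Integer seed controlling both the randomly placed class
#'   structure and event sampling.
#' @return An object of class `drift_config`.
#' @export
drift_config <- function(n_features = 16L, classes = activity_levels(),
                         days = c(1, 2, 3, 7), class_sep = 1.0,
                         shift_magnitude = c(0, 0.8, 1.0, 1.1),
                         shift_direction = c("nearest_class", "random"),
                         var_scale = c(1, 0.75, 0.65, 0.65),
                         means = NULL, cov = NULL, shifts = NULL, seed = 1L) {
  shift_direction <- match.arg(shift_direction)
  if (!is_count(n_features)) stop_validation("n_features must be a positive integer")
  if (length(shift_magnitude) != length(days) || length(var_scale) != length(days))
    stop_validation("shift_magnitude and var_scale must have one entry per day")
  if (any(var_scale <= 0)) stop_validation("var_scale entries must be positive")
  if (shift_magnitude[1L] != 0 || var_scale[1L] != 1)
    stop_validation("day 1 must use shift 0 and variance scale 1")
  if (!is.null(cov)) {
    if (!isSymmetric(unname(cov)))
      stop_validation("covariance must be symmetric")
    ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < -1e-8 * max(abs(ev), 1)))
      stop_validation("covariance must be positive semi-definite")
  }
  if (!is.null(means) && (nrow(means) != length(classes) || ncol(means) != n_features))
    stop_validation("means must be a %d x %d matrix", length(classes), n_features)
  if (!is.null(shifts) && length(shifts) != length(days))
    stop_validation("shifts must have one matrix per day")
  structure(list(n_features = as.integer(n_features), classes = classes,
                 days = days, class_sep = class_sep,
                 shift_magnitude = shift_magnitude,
                 shift_direction = shift_direction, var_scale = var_scale,
                 means = means, cov = cov, shifts = shifts,
                 seed = as.integer(seed)),
            class = "drift_config")
}

# Realise the class structure (means, shift directions, covariance factor)
# deterministically from the config seed.
realize_drift <- function(drift) {
  k <- length(drift$classes)
  d <- drift$n_features
  pars <- with_local_seed(seed_child(drift$seed, 101), {
    means <- drift$means
    if (is.null(means))
      means <- matrix(rnorm(k * d, sd = drift$class_sep), nrow = k)
    dirs <- if (identical(drift$shift_direction, "nearest_class") && k > 1L) {
      t(vapply(seq_len(k), function(i) {
        dist <- colSums((t(means) - means[i, ])^2)
        dist[i] <- Inf
        v <- means[which.min(dist), ] - means[i, ]
        v / sqrt(sum(v^2))
      }, numeric(d)))
    } else {
      m <- matrix(rnorm(k * d), nrow = k)
      m / sqrt(rowSums(m^2))
    }
    list(means = means, dirs = dirs)
  })
  shifts <- drift$shifts
  if (is.null(shifts))
    shifts <- lapply(drift$shift_magnitude, function(m) m * pars$dirs)
  chol_cov <- if (is.null(drift$cov)) NULL else chol(drift$cov + 1e-10 * diag(d))
  list(means = pars$means, shifts = shifts, chol_cov = chol_cov)
}

# Draw n feature vectors for class index ci on day index di.
draw_class_features <- function(real, drift, ci, di, n) {
  d <- drift$n_features
  z <- matrix(rnorm(n * d), nrow = n)
  if (!is.null(real$chol_cov)) z <- z %*% real$chol_cov
  z <- z * sqrt(drift$var_scale[di])
  sweep(z, 2L, real$means[ci, ] + real$shifts[[di]][ci, ], `+`)
}

# Emit the ordered label sequence for one trial following the circuit.
circuit_trial_labels <- function(circuit) {
  segs <- circuit$sequence[-1L]
  unlist(lapply(segs, function(a) {
    r <- circuit$steps[[a]]
    rep(a, if (r[1L] == r[2L]) r[1L] else sample(seq(r[1L], r[2L]), 1L))
  }), use.names = FALSE)
}

#' Simulate a feature-level multi-day gait session
#'
#' Generates a multi-day stream of gait events whose forward (pre-step) and
#' backward (previous-stride) feature vectors are drawn from class-conditional
#' Gaussian distributions subject to the configured day-to-day drift. Each
#' trial follows the activity circuit; each event carries its current mode
#' (the activity of the previous event, `SIT` at trial start) and its true
#' upcoming activity. The first event of a trial has no completed stride and
#' therefore no backward feature vector.
#'
#' @param circuit A [circuit_spec()].
#' @param drift A [drift_config()] for the forward feature space.
#' @param n_days Number of measurement days to generate (first `n_days`
#'   entries of `drift$days`).
#' @param trials_per_day Number of circuit repetitions per day.
#' @param backward_drift Optional [drift_config()] for the backward (stride)
#'   feature space; derived from `drift` with dimension
#'   `n_backward_features` when `NULL`.
#' @param n_backward_features Dimension of the derived backward feature
#'   space.
#' @param subject Subject identifier stored in the session metadata.
#' @return An object of class `gait_session`: a list with an `events` data
#'   frame (day, trial, event, mode, label, has_stride, then forward and
#'   backward feature columns) plus metadata.
#' @export
simulate_feature_session <- function(circuit = circuit_spec(),
                                     drift = drift_config(),
                                     n_days = length(drift$days),
                                     trials_per_day = 40L,
                                     backward_drift = NULL,
                                     n_backward_features = 12L,
                                     subject = "S01") {
  if (!inherits(circuit, "circuit_spec")) circuit <- do.call(circuit_spec, circuit)
  if (!inherits(drift, "drift_config")) stop_validation("drift must be a drift_config")
  if (!is_count(n_days) || n_days > length(drift$days))
    stop_validation("n_days must be a positive integer <= length(drift$days)")
  if (!is_count(trials_per_day)) stop_validation("trials_per_day must be a positive integer")
  if (is.null(backward_drift))
    backward_drift <- drift_config(n_features = n_backward_features,
                                   classes = drift$classes, days = drift$days,
                                   class_sep = drift$class_sep,
                                   shift_magnitude = drift$shift_magnitude,
                                   var_scale = drift$var_scale,
                                   seed = seed_child(drift$seed, 5))

  real_f <- realize_drift(drift)
  real_b <- realize_drift(backward_drift)
  classes <- drift$classes
  days <- drift$days[seq_len(n_days)]

  events <- with_local_seed(seed_child(drift$seed, 202), {
    rows <- vector("list", n_days * trials_per_day)
    r <- 0L
    for (di in seq_len(n_days)) {
      for (tr in seq_len(trials_per_day)) {
        labels <- circuit_trial_labels(circuit)
        n <- length(labels)
        mode <- c("SIT", labels[-n])
        ci <- match(labels, classes)
        fw <- matrix(NA_real_, n, drift$n_features)
        bw <- matrix(NA_real_, n, backward_drift$n_features)
        for (c_i in unique(ci)) {
          sel <- which(ci == c_i)
          fw[sel, ] <- draw_class_features(real_f, drift, c_i, di, length(sel))
          bw[sel, ] <- draw_class_features(real_b, backward_drift, c_i, di, length(sel))
        }
        bw[1L, ] <- NA_real_  # no completed stride before the first event
        r <- r + 1L
        rows[[r]] <- data.frame(day = days[di], trial = tr,
                                event = seq_len(n), mode = mode,
                                label = labels,
                                has_stride = c(FALSE, rep(TRUE, n - 1L)),
                                fw, bw, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })

  fw_names <- sprintf("f%02d", seq_len(drift$n_features))
  bw_names <- sprintf("b%02d", seq_len(backward_drift$n_features))
  names(events) <- c("day", "trial", "event", "mode", "label", "has_stride",
                     fw_names, bw_names)
  rownames(events) <- NULL
  structure(list(events = events, forward_features = fw_names,
                 backward_features = bw_names, classes = classes,
                 days = days, subject = subject,
                 drift = drift, backward_drift = backward_drift),
            class = "gait_session")
}

#' @export
print.gait_session <- function(x, ...) {
  cat(sprintf("gait_session: subject %s, %d day(s) [%s], %d events\n",
              x$subject, length(x$days), paste(x$days, collapse = ", "),
              nrow(x$events)))
  cat(sprintf("  forward features: %d, backward features: %d, classes: %d\n",
              length(x$forward_features), length(x$backward_features),
              length(x$classes)))
  invisible(x)
}

#' Raw-signal simulator configuration
#'
#' Parameters for [simulate_raw_trial()], which produces continuous
#' multichannel recordings: EMG channels are amplitude-modulated band-limited
#' noise bursts synchronised to strides (spectral content in the 20-450 Hz
#' physiological band so a 20 Hz high-pass retains it), and mechanical
#' channels (segment accelerations/angular velocities and joint angles) are
#' class-dependent smooth stride waveforms plus measurement noise.
#'
#' @param rate Sampling rate in Hz.
#' @param n_emg,n_mech Number of EMG and mechanical channels.
#' @param stride_ms Integer range `c(min, max)` of stride duration in ms.
#' @param emg_amplitude Overall EMG burst amplitude scale.
#' @param emg_band Two-sided EMG carrier band in Hz.
#' @param mech_noise_sd Additive noise SD on mechanical channels.
#' @param seed Seed for the class-dependent waveform/amplitude parameters
#'   (held fixed across trials so classes look consistent).
#' @return An object of class `raw_signal_config`.
#' @export
raw_signal_config <- function(rate = 1000, n_emg = 8L, n_mech = 20L,
                              stride_ms = c(900, 1300), emg_amplitude = 1,
                              emg_band = c(20, 450), mech_noise_sd = 0.1,
                              seed = 1L) {
  if (rate <= 0) stop_validation("sampling rate must be positive")
  if (n_emg < 1L || n_mech < 1L) stop_validation("channel counts must be >= 1")
  if (length(stride_ms) != 2L || any(stride_ms <= 0) || stride_ms[1L] > stride_ms[2L])
    stop_validation("stride_ms must be c(min, max) with 0 < min <= max")
  if (emg_band[1L] <= 0 || emg_band[2L] >= rate / 2)
    stop_validation("emg_band must lie strictly inside (0, Nyquist)")
  structure(list(rate = rate, n_emg = as.integer(n_emg),
                 n_mech = as.integer(n_mech), stride_ms = stride_ms,
                 emg_amplitude = emg_amplitude, emg_band = emg_band,
                 mech_noise_sd = mech_noise_sd, seed = as.integer(seed)),
            class = "raw_signal_config")
}

# Class-dependent waveform parameters, fixed by the config seed.
raw_class_params <- function(config, classes = activity_levels()) {
  k <- length(classes)
  with_local_seed(seed_child(config$seed, 303), {
    list(classes = classes,
         emg_amp = matrix(runif(k * config$n_emg, 0.4, 1.6), nrow = k,
                          dimnames = list(classes, NULL)),
         mech_amp = matrix(runif(k * config$n_mech, 0.5, 2.0), nrow = k,
                           dimnames = list(classes, NULL)),
         mech_phase = matrix(runif(k * config$n_mech, 0, 2 * pi), nrow = k,
                             dimnames = list(classes, NULL)),
         mech_harm = matrix(runif(k * config$n_mech, 0.1, 0.6), nrow = k,
                            dimnames = list(classes, NULL)))
  })
}

#' Simulate one raw multichannel gait trial
#'
#' Produces a continuous recording for one circuit repetition together with
#' its gait-event (initial contact) timestamps and the label track assigning
#' each event its upcoming activity. The first event is placed so that at
#' least a full forward window (300 ms) of signal precedes it.
#'
#' @param config A [raw_signal_config()].
#' @param circuit A [circuit_spec()].
#' @param seed Seed for this trial's random realisation (stride durations,
#'   noise carriers).
#' @return A list with elements `block` (a [signal_block()]), `events`
#'   (data frame of `time_ms`, `label`, `mode`) and `config`.
#' @export
simulate_raw_trial <- function(config = raw_signal_config(),
                               circuit = circuit_spec(), seed = 1L) {
  pars <- raw_class_params(config)
  rate <- config$rate
  with_local_seed(seed_child(seed, 404), {
    labels <- circuit_trial_labels(circuit)
    n_ev <- length(labels)
    durations <- if (config$stride_ms[1L] == config$stride_ms[2L])
      rep(config$stride_ms[1L], n_ev)
    else round(runif(n_ev, config$stride_ms[1L], config$stride_ms[2L]))
    first_at <- max(400, 300 + 50)
    event_ms <- first_at + cumsum(c(0, durations[-n_ev]))
    total_ms <- event_ms[n_ev] + durations[n_ev] + 200
    n <- ceiling(total_ms * rate / 1000)
    t_ms <- (seq_len(n) - 1L) * 1000 / rate

    # stride phase in [0, 1) and active class per sample; flat outside strides
    phase <- rep(0, n)
    cls_idx <- rep(NA_integer_, n)
    for (j in seq_len(n_ev)) {
      s0 <- event_ms[j]
      s1 <- s0 + durations[j]
      sel <- which(t_ms >= s0 & t_ms < s1)
      phase[sel] <- (t_ms[sel] - s0) / durations[j]
      cls_idx[sel] <- match(labels[j], pars$classes)
    }

    # EMG: band-limited white noise carrier, modulated by per-stride bursts
    bf <- signal::butter(4, config$emg_band / (rate / 2), type = "pass")
    emg <- matrix(0, n, config$n_emg)
    env_base <- 0.05
    burst <- exp(-((phase - 0.5)^2) / (2 * 0.12^2))
    for (ch in seq_len(config$n_emg)) {
      carrier <- as.numeric(signal::filtfilt(bf, rnorm(n)))
      amp <- ifelse(is.na(cls_idx), 0, pars$emg_amp[cbind(cls_idx, ch)])
      env <- config$emg_amplitude * (env_base + amp * burst * !is.na(cls_idx))
      emg[, ch] <- env * carrier
    }

    # mechanical: smooth class-dependent stride waveform plus noise
    mech <- matrix(0, n, config$n_mech)
    for (ch in seq_len(config$n_mech)) {
      amp <- ifelse(is.na(cls_idx), 0, pars$mech_amp[cbind(cls_idx, ch)])
      ph <- ifelse(is.na(cls_idx), 0, pars$mech_phase[cbind(cls_idx, ch)])
      hm <- ifelse(is.na(cls_idx), 0, pars$mech_harm[cbind(cls_idx, ch)])
      wave <- amp * (sin(2 * pi * phase + ph) + hm * sin(4 * pi * phase + 2 * ph))
      noise <- if (config$mech_noise_sd > 0) rnorm(n, sd = config$mech_noise_sd) else 0
      mech[, ch] <- wave + noise
    }

    data <- cbind(emg, mech)
    colnames(data) <- c(sprintf("emg%02d", seq_len(config$n_emg)),
                        sprintf("mech%02d", seq_len(config$n_mech)))
    roles <- setNames(c(rep("emg", config$n_emg), rep("mechanical", config$n_mech)),
                      colnames(data))
    block <- signal_block(data, rate = rate, roles = roles, t0 = 0)
    events <- data.frame(time_ms = event_ms, label = labels,
                         mode = c("SIT", labels[-n_ev]),
                         stringsAsFactors = FALSE)
    list(block = block, events = events, config = config)
  })
}
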