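default_config <- function() {
  list(
    seed = 1L,
    simulate = list(n_days = 4L, trials_per_day = 40L,
                    n_forward_features = 16L, n_backward_features = 12L,
                    class_sep = 1.0, days = c(1, 2, 3, 7),
                    shift_magnitude = c(0, 0.8, 1.0, 1.1),
                    var_scale = c(1, 0.75, 0.65, 0.65),
                    rate = 1000, n_emg = 8L, n_mech = 20L,
                    stride_ms = c(900, 1300)),
    signals = list(highpass_cutoff = 20, filter_order = 2,
                   resample_rate = 1000, forward_window_ms = 300,
                   backward_window_ms = 1500, mvc_reference = 1),
    features = list(ar_order = 4L, deadband = 0),
    models = list(hidden = 20L, learning_rate = 0.001, max_epochs = 100L,
                  patience = 3L, validation_fraction = 0.10, batch_size = 32L),
    adapt = list(retrain_interval = 2L, entropy_base = 0.6,
                 entropy_reference_classes = 5L, pool_cap = Inf),
    evaluate = list(train_fraction = 0.5, random_split = FALSE),
    # filled by the config echo written next to outputs; accepted on reload
    package_version = NULL
  )
}

merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop_validation("unknown configuration key%s: %s",
                    if (length(unknown) > 1) "s" else "",
                    paste0(path, unknown, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])))
      defaults[[nm]] <- merge_config(defaults[[nm]], as.list(user[[nm]]),
                                     paste0(path, nm, "."))
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

validate_config <- function(cfg) {
  # constructors perform the detailed checks; validate cross-cutting fields
  net_config(hidden = cfg$models$hidden,
             learning_rate = cfg$models$learning_rate,
             max_epochs = cfg$models$max_epochs,
             patience = cfg$models$patience,
             validation_fraction = cfg$models$validation_fraction,
             batch_size = cfg$models$batch_size, seed = cfg$seed)
  window_spec(cfg$signals$forward_window_ms, cfg$signals$backward_window_ms)
  feature_spec(cfg$features$ar_order, cfg$features$deadband)
  if (!is_count(cfg$adapt$retrain_interval))
    stop_validation("adapt.retrain_interval must be a positive integer")
  if (cfg$evaluate$train_fraction <= 0 || cfg$evaluate$train_fraction >= 1)
    stop_validation("evaluate.train_fraction must lie in (0, 1)")
  cfg
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration file, fills unset values with the
#' package defaults, rejects unknown keys and validates constraints. An
#' empty or missing file yields the full default configuration, whose
#' values are the classical choices for this kind of system (300 ms forward
#' window, 1500 ms stride cap, 20 hidden nodes, Adam step 0.001, 100
#' epochs, 10% validation split, 0.6 entropy threshold at 5 classes,
#' 2-trial retrain interval, 50% day-1 split).
#'
#' @param path Path to a YAML/JSON file, or `NULL` for pure defaults.
#' @return The resolved configuration list (class `run_config`).
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_validation("config file not found: %s", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  cfg <- validate_config(merge_config(default_config(), user))
  structure(cfg, class = c("run_config", "list"))
}

run_config_net <- function(cfg, seed = cfg$seed) {
  net_config(hidden = cfg$models$hidden,
             learning_rate = cfg$models$learning_rate,
             max_epochs = cfg$models$max_epochs,
             patience = cfg$models$patience,
             validation_fraction = cfg$models$validation_fraction,
             batch_size = cfg$models$batch_size, seed = seed)
}

# Echo the resolved configuration next to the outputs for reproducibility.
write_config_echo <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg$package_version <- as.character(utils::packageVersion("driftadapt"))
  yaml::write_yaml(cfg, file.path(dir, "resolved_config.yaml"))
  invisible(cfg)
}

#' Save trained predictors as a portable text bundle
#'
#' Stores the forward bank and optional backward predictor (weights, class
#' lists, standardisation, configuration and seed) as a single JSON
#' descriptor.
#'
#' @param predictors List with `forward` (a `mode_specific_predictor`) and
#'   optionally `backward` (a `gait_classifier`).
#' @param path Output file (JSON).
#' @return `path`, invisibly.
#' @export
save_model_bundle <- function(predictors, path) {
  ser_clf <- function(clf) {
    if (clf$constant) return(list(constant = TRUE, classes = clf$classes,
                                  prior = clf$prior))
    list(constant = FALSE, classes = clf$classes,
         w1 = clf$w1, b1 = clf$b1, w2 = clf$w2, b2 = clf$b2,
         center = unname(clf$standardizer$center),
         scale = unname(clf$standardizer$scale),
         config = unclass(clf$config))
  }
  bundle <- list(format = "driftadapt-model-bundle", version = 1L,
                 forward = lapply(predictors$forward$classifiers, ser_clf),
                 backward = if (!is.null(predictors$backward))
                   ser_clf(predictors$backward) else NULL)
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a predictor bundle written by [save_model_bundle()]
#'
#' @param path Bundle file.
#' @return List with `forward` and (possibly `NULL`) `backward` predictors.
#' @export
load_model_bundle <- function(path) {
  if (!file.exists(path)) stop_validation("bundle not found: %s", path)
  bundle <- jsonlite::read_json(path, simplifyVector = TRUE)
  deser_clf <- function(b) {
    if (isTRUE(b$constant))
      return(prior_classifier(b$classes, as.numeric(b$prior)))
    cfg <- do.call(net_config, b$config)
    structure(list(classes = b$classes, w1 = as.matrix(b$w1),
                   b1 = as.numeric(b$b1), w2 = as.matrix(b$w2),
                   b2 = as.numeric(b$b2),
                   standardizer = list(center = as.numeric(b$center),
                                       scale = as.numeric(b$scale)),
                   config = cfg, constant = FALSE, val_error = NA_real_,
                   epochs = NA_integer_, best_epoch = NA_integer_,
                   n_train = NA_integer_),
              class = "gait_classifier")
  }
  fwd <- lapply(bundle$forward, deser_clf)
  forward <- structure(list(classifiers = fwd,
                            classes_per_mode = lapply(fwd, `[[`, "classes"),
                            config = NULL),
                       class = "mode_specific_predictor")
  backward <- if (length(bundle$backward)) deser_clf(bundle$backward) else NULL
  list(forward = forward, backward = backward)
}

# ---- command-line entry point ----------------------------------------------

parse_cli_args <- function(argv) {
  out <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--"))
      stop_validation("unexpected argument '%s'", a)
    key <- sub("^--", "", a)
    if (i == length(argv) || startsWith(argv[i + 1L], "--"))
      stop_validation("option --%s requires a value", key)
    out[[gsub("-", "_", key)]] <- argv[i + 1L]
    i <- i + 2L
  }
  out
}

cli_usage <- function() {
  paste("usage: driftadapt <subcommand> [--option value ...]",
        "subcommands:",
        "  simulate           --mode {features,raw} --out DIR --seed N [--config FILE]",
        "  extract-features   --in DIR --out DIR [--config FILE]",
        "  train              --features DIR --out FILE [--seed N] [--config FILE]",
        "  evaluate           --data DIR --strategy S --out DIR [--seed N] [--config FILE]",
        "  compare-strategies --out DIR --seeds N [--seed N] [--config FILE]",
        "  pca-drift          --data DIR --out FILE [--activity LABEL]",
        sep = "\n")
}

cli_simulate <- function(opts, cfg) {
  mode <- opts$mode %||% "features"
  seed <- as.integer(opts$seed %||% cfg$seed)
  out <- opts$out %||% stop_validation("simulate requires --out")
  if (mode == "features") {
    drift <- drift_config(n_features = cfg$simulate$n_forward_features,
                          days = cfg$simulate$days,
                          class_sep = cfg$simulate$class_sep,
                          shift_magnitude = cfg$simulate$shift_magnitude,
                          var_scale = cfg$simulate$var_scale, seed = seed)
    session <- simulate_feature_session(circuit_spec(), drift,
                                        n_days = cfg$simulate$n_days,
                                        trials_per_day = cfg$simulate$trials_per_day,
                                        n_backward_features = cfg$simulate$n_backward_features)
    write_session(session, out)
  } else if (mode == "raw") {
    rc <- raw_signal_config(rate = cfg$simulate$rate,
                            n_emg = cfg$simulate$n_emg,
                            n_mech = cfg$simulate$n_mech,
                            stride_ms = cfg$simulate$stride_ms, seed = seed)
    trials <- lapply(seq_len(cfg$simulate$trials_per_day), function(i)
      simulate_raw_trial(rc, circuit_spec(), seed = seed_child(seed, i)))
    write_raw_session(trials, out)
  } else stop_validation("unknown simulate mode '%s'", mode)
  write_config_echo(cfg, out)
  message(sprintf("wrote %s session to %s", mode, out))
  0L
}

cli_extract_features <- function(opts, cfg) {
  input <- opts$`in` %||% opts$in_dir %||% stop_validation("extract-features requires --in")
  out <- opts$out %||% stop_validation("extract-features requires --out")
  raw <- read_raw_session(input)
  spec <- window_spec(cfg$signals$forward_window_ms,
                      cfg$signals$backward_window_ms)
  fspec <- feature_spec(cfg$features$ar_order, cfg$features$deadband)
  rows <- list()
  for (ti in seq_along(raw$trials)) {
    tr <- raw$trials[[ti]]
    block <- tr$block
    if (block$rate != cfg$signals$resample_rate)
      block <- resample_block(block, cfg$signals$resample_rate)
    block <- highpass_emg(block, cfg$signals$highpass_cutoff,
                          cfg$signals$filter_order)
    block <- normalize_mvc(block, cfg$signals$mvc_reference)
    evs <- tr$events
    for (j in seq_len(nrow(evs))) {
      fwin <- cut_forward_window(block, evs$time_ms[j], spec)
      fvec <- build_forward_vector(fwin, fspec)
      bvec <- rep(NA_real_, 6L * sum(block$roles == "mechanical"))
      if (j > 1L) {
        swin <- cut_stride_window(subset_channels(block, "mechanical"),
                                  evs$time_ms[j - 1L], evs$time_ms[j], spec)
        bvec <- build_backward_vector(swin)
      }
      rows[[length(rows) + 1L]] <- c(list(day = 1, trial = ti, event = j,
                                          mode = evs$mode[j],
                                          label = evs$label[j],
                                          has_stride = j > 1L),
                                     as.list(c(fvec, setNames(bvec,
                                       paste0("bw_", seq_along(bvec))))))
    }
  }
  events <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  fw_names <- names(events)[7:(6 + 8 * sum(raw$trials[[1]]$block$roles == "emg") +
                                 6 * sum(raw$trials[[1]]$block$roles == "mechanical"))]
  bw_names <- grep("^bw_", names(events), value = TRUE)
  fw_names <- setdiff(names(events)[-(1:6)], bw_names)
  session <- structure(list(events = events, forward_features = fw_names,
                            backward_features = bw_names,
                            classes = activity_levels(), days = 1,
                            subject = raw$subject, drift = NULL,
                            backward_drift = NULL),
                       class = "gait_session")
  write_session(session, out)
  write_config_echo(cfg, out)
  message(sprintf("extracted features for %d trials to %s",
                  length(raw$trials), out))
  0L
}

cli_train <- function(opts, cfg) {
  input <- opts$features %||% stop_validation("train requires --features")
  out <- opts$out %||% stop_validation("train requires --out")
  seed <- as.integer(opts$seed %||% cfg$seed)
  session <- read_session(input)
  ev <- session$events
  net <- run_config_net(cfg, seed = seed_child(seed, 1))
  fw <- as.matrix(ev[, session$forward_features, drop = FALSE])
  bank <- train_mode_specific(fw, ev$mode, ev$label, net)
  bnet <- run_config_net(cfg, seed = seed_child(seed, 2))
  bsel <- ev$has_stride
  bw <- as.matrix(ev[bsel, session$backward_features, drop = FALSE])
  backward <- train_backward(bw, ev$label[bsel], bnet)
  save_model_bundle(list(forward = bank, backward = backward), out)
  message(sprintf("wrote model bundle to %s", out))
  0L
}

cli_evaluate <- function(opts, cfg) {
  input <- opts$data %||% stop_validation("evaluate requires --data")
  out <- opts$out %||% stop_validation("evaluate requires --out")
  strategy <- opts$strategy %||% "baseline"
  seed <- as.integer(opts$seed %||% cfg$seed)
  session <- read_session(input)
  pc <- protocol_config(strategy = strategy,
                        train_fraction = cfg$evaluate$train_fraction,
                        retrain_interval = cfg$adapt$retrain_interval,
                        seed = seed, net = run_config_net(cfg, seed),
                        pool_cap = cfg$adapt$pool_cap,
                        random_split = cfg$evaluate$random_split)
  res <- run_protocol(session, pc)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(strategy = res$strategy,
                            per_day_error = as.list(res$per_day_error),
                            per_day_backward_error =
                              if (is.null(res$per_day_backward_error)) NULL
                              else as.list(res$per_day_backward_error),
                            n_retrains = nrow(res$retrain_log)),
                       file.path(out, "result.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.csv(res$audit, file.path(out, "audit.csv"), row.names = FALSE)
  write.csv(res$running, file.path(out, "running_error.csv"), row.names = FALSE)
  write.csv(res$per_activity, file.path(out, "per_activity.csv"),
            row.names = FALSE)
  write.csv(res$retrain_log, file.path(out, "retrains.csv"), row.names = FALSE)
  write_config_echo(cfg, out)
  message(sprintf("strategy %s: per-day error %s", strategy,
                  paste(sprintf("%s=%.3f", names(res$per_day_error),
                                res$per_day_error), collapse = " ")))
  0L
}

cli_compare <- function(opts, cfg) {
  out <- opts$out %||% stop_validation("compare-strategies requires --out")
  n_seeds <- as.integer(opts$seeds %||% 5L)
  seed <- as.integer(opts$seed %||% cfg$seed)
  drift <- drift_config(n_features = cfg$simulate$n_forward_features,
                        days = cfg$simulate$days,
                        class_sep = cfg$simulate$class_sep,
                        shift_magnitude = cfg$simulate$shift_magnitude,
                        var_scale = cfg$simulate$var_scale, seed = seed)
  cmp <- compare_strategies(seeds = seed + seq_len(n_seeds) - 1L,
                            drift = drift,
                            n_days = cfg$simulate$n_days,
                            trials_per_day = cfg$simulate$trials_per_day,
                            net = run_config_net(cfg))
  summary <- aggregate_runs(cmp$errors)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write.csv(cmp$errors, file.path(out, "errors_by_run.csv"), row.names = FALSE)
  write.csv(summary, file.path(out, "summary.csv"), row.names = FALSE)
  write_config_echo(cfg, out)
  message(paste(utils::capture.output(print(summary)), collapse = "\n"))
  0L
}

cli_pca_drift <- function(opts, cfg) {
  input <- opts$data %||% stop_validation("pca-drift requires --data")
  out <- opts$out %||% stop_validation("pca-drift requires --out")
  session <- read_session(input)
  pd <- pca_drift(session, n_components = 2L, activity = opts$activity)
  rows <- do.call(rbind, lapply(pd$per_day, function(d)
    data.frame(day = d$day, mean_pc1 = d$mean[1L], mean_pc2 = d$mean[2L],
               semi_axis_1 = d$ellipse$semi_axes[1L],
               semi_axis_2 = d$ellipse$semi_axes[2L],
               angle = d$ellipse$angle)))
  write.csv(rows, out, row.names = FALSE)
  message(sprintf("wrote drift ellipse parameters to %s", out))
  0L
}

#' Command-line entry point
#'
#' Dispatches the `driftadapt` subcommands (`simulate`, `extract-features`,
#' `train`, `evaluate`, `compare-strategies`, `pca-drift`). Installed as a
#' runnable script under `inst/cli/driftadapt`.
#'
#' @param argv Character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit status (0 on success), invisibly.
#' @export
driftadapt_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) {
    message(cli_usage())
    return(invisible(1L))
  }
  cmd <- argv[1L]
  status <- tryCatch({
    opts <- parse_cli_args(argv[-1L])
    cfg <- load_config(opts$config)
    switch(cmd,
           "simulate" = cli_simulate(opts, cfg),
           "extract-features" = cli_extract_features(opts, cfg),
           "train" = cli_train(opts, cfg),
           "evaluate" = cli_evaluate(opts, cfg),
           "compare-strategies" = cli_compare(opts, cfg),
           "pca-drift" = cli_pca_drift(opts, cfg),
           {
             message(sprintf("unknown subcommand '%s'\n%s", cmd, cli_usage()))
             1L
           })
  }, error = function(e) {
    message("driftadapt error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
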