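#' Write a feature-level gait session to disk
#'
#' Serialises a `gait_session` as a JSON manifest (`manifest.json`) plus one
#' CSV per trial. The round trip through [read_session()] restores the
#' session field-for-field.
#'
#' @param dataset A `gait_session`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_session <- function(dataset, path) {
  if (!inherits(dataset, "gait_session"))
    stop_validation("dataset must be a gait_session")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ev <- dataset$events
  key <- unique(ev[, c("day", "trial")])
  files <- sprintf("day%g_trial%03d.csv", key$day, key$trial)
  for (i in seq_len(nrow(key))) {
    sel <- ev$day == key$day[i] & ev$trial == key$trial[i]
    write.csv(ev[sel, , drop = FALSE], file.path(path, files[i]),
              row.names = FALSE)
  }
  manifest <- list(subject = dataset$subject, type = "features",
                   days = dataset$days, classes = dataset$classes,
                   forward_features = dataset$forward_features,
                   backward_features = dataset$backward_features,
                   trials = data.frame(day = key$day, trial = key$trial,
                                       file = files))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a feature-level gait session from disk
#'
#' @param path Directory written by [write_session()].
#' @return A `gait_session`.
#' @export
read_session <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stop_validation("no manifest.json under %s", path)
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  for (field in c("subject", "type", "days", "classes", "forward_features",
                  "backward_features", "trials"))
    if (is.null(manifest[[field]]))
      stop_validation("manifest is missing required field '%s'", field)
  trials <- manifest$trials
  events <- do.call(rbind, lapply(seq_len(nrow(trials)), function(i) {
    f <- file.path(path, trials$file[i])
    if (!file.exists(f)) stop_validation("trial file missing: %s", f)
    read.csv(f, stringsAsFactors = FALSE)
  }))
  needed <- c("day", "trial", "event", "mode", "label", "has_stride",
              manifest$forward_features, manifest$backward_features)
  missing_cols <- setdiff(needed, names(events))
  if (length(missing_cols))
    stop_validation("trial tables are missing columns: %s",
                    paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(c(events$label, events$mode)), manifest$classes)
  if (length(bad))
    stop_validation("trial tables contain labels outside the class list: %s",
                    paste(bad, collapse = ", "))
  events <- events[, needed]
  rownames(events) <- NULL
  structure(list(events = events,
                 forward_features = manifest$forward_features,
                 backward_features = manifest$backward_features,
                 classes = manifest$classes, days = manifest$days,
                 subject = manifest$subject, drift = NULL,
                 backward_drift = NULL),
            class = "gait_session")
}

#' Write a raw multichannel session to disk
#'
#' Serialises raw trials (as produced by [simulate_raw_trial()]) as one CSV
#' per trial (time plus channel columns), one event CSV per trial, and a
#' JSON manifest recording the sampling rate and channel roles.
#'
#' @param trials List of raw trials (each a list with `block` and `events`).
#' @param path Output directory.
#' @param subject Subject identifier.
#' @return `path`, invisibly.
#' @export
write_raw_session <- function(trials, path, subject = "S01") {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  first <- trials[[1L]]$block
  files <- sprintf("trial%03d.csv", seq_along(trials))
  event_files <- sprintf("trial%03d_events.csv", seq_along(trials))
  for (i in seq_along(trials)) {
    bl <- trials[[i]]$block
    df <- data.frame(time_ms = bl$t0 + (seq_len(nrow(bl$data)) - 1L) * 1000 / bl$rate,
                     bl$data, check.names = FALSE)
    write.csv(df, file.path(path, files[i]), row.names = FALSE)
    write.csv(trials[[i]]$events, file.path(path, event_files[i]),
              row.names = FALSE)
  }
  manifest <- list(subject = subject, type = "raw", rate = first$rate,
                   channels = names(first$roles),
                   roles = unname(first$roles),
                   trials = data.frame(trial = seq_along(trials),
                                       file = files, events = event_files))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a raw multichannel session from disk
#'
#' @param path Directory written by [write_raw_session()].
#' @return List with `trials` (each holding `block` and `events`), `rate`
#'   and `subject`.
#' @export
read_raw_session <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stop_validation("no manifest.json under %s", path)
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  for (field in c("subject", "type", "rate", "channels", "roles", "trials"))
    if (is.null(manifest[[field]]))
      stop_validation("manifest is missing required field '%s'", field)
  roles <- setNames(manifest$roles, manifest$channels)
  trials <- lapply(seq_len(nrow(manifest$trials)), function(i) {
    df <- read.csv(file.path(path, manifest$trials$file[i]),
                   check.names = FALSE)
    events <- read.csv(file.path(path, manifest$trials$events[i]),
                       stringsAsFactors = FALSE)
    data <- as.matrix(df[, manifest$channels, drop = FALSE])
    list(block = signal_block(data, rate = manifest$rate, roles = roles,
                              t0 = df$time_ms[1L]),
         events = events)
  })
  list(trials = trials, rate = manifest$rate, subject = manifest$subject)
}
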