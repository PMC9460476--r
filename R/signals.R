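#' Multichannel signal block
#'
#' A time-by-channels sample matrix in physical units with its sampling rate,
#' per-channel roles (`"emg"` or `"mechanical"`) and time origin.
#'
#' @param data Numeric matrix, time in rows, channels in columns.
#' @param rate Sampling rate in Hz (> 0).
#' @param roles Character vector (`"emg"`/`"mechanical"`), one per column;
#'   taken from names when named.
#' @param t0 Time of the first row in ms.
#' @return An object of class `signal_block`.
#' @export
signal_block <- function(data, rate, roles, t0 = 0) {
  data <- as.matrix(data)
  if (!nrow(data)) stop_validation("signal block must contain samples")
  if (rate <= 0) stop_validation("sampling rate must be positive")
  if (length(roles) != ncol(data))
    stop_validation("roles must cover all %d channels", ncol(data))
  if (!all(roles %in% c("emg", "mechanical")))
    stop_validation("channel roles must be 'emg' or 'mechanical'")
  if (anyNA(data)) stop_validation("signal block contains missing values")
  structure(list(data = data, rate = rate,
                 roles = setNames(as.character(roles), colnames(data)),
                 t0 = t0),
            class = "signal_block")
}

#' @export
print.signal_block <- function(x, ...) {
  cat(sprintf("signal_block: %d samples x %d channels (%d emg, %d mechanical), %g Hz, t0 = %g ms\n",
              nrow(x$data), ncol(x$data), sum(x$roles == "emg"),
              sum(x$roles == "mechanical"), x$rate, x$t0))
  invisible(x)
}

#' Subset the channels of a signal block by role
#'
#' @param block A [signal_block()].
#' @param role `"emg"` or `"mechanical"`.
#' @return A `signal_block` containing only the requested channels.
#' @export
subset_channels <- function(block, role = c("mechanical", "emg")) {
  role <- match.arg(role)
  keep <- which(block$roles == role)
  if (!length(keep)) stop_validation("no channels with role '%s'", role)
  signal_block(block$data[, keep, drop = FALSE], rate = block$rate,
               roles = block$roles[keep], t0 = block$t0)
}

#' Event-anchored window specification
#'
#' @param forward_ms Forward window length in ms ending just before a gait
#'   event (default 300).
#' @param backward_ms Maximum backward (stride) window length in ms
#'   (default 1500).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(forward_ms = 300, backward_ms = 1500) {
  if (forward_ms <= 0 || backward_ms <= 0)
    stop_validation("window lengths must be positive")
  if (forward_ms > backward_ms)
    stop_validation("forward window must not exceed the backward maximum")
  structure(list(forward_ms = forward_ms, backward_ms = backward_ms),
            class = "window_spec")
}

#' Zero-lag Butterworth high-pass filter for EMG channels
#'
#' Applies a Butterworth high-pass filter forward and backward (zero net
#' phase) to the EMG channels of a block; mechanical channels pass through
#' untouched. The default removes motion artefact and baseline wander below
#' 20 Hz with a second-order filter.
#'
#' @param block A [signal_block()].
#' @param cutoff Cut-off frequency in Hz; must be below Nyquist.
#' @param order Filter order (of the underlying one-pass filter).
#' @return The filtered `signal_block`.
#' @export
highpass_emg <- function(block, cutoff = 20, order = 2) {
  if (cutoff >= block$rate / 2)
    stop_validation("cutoff (%g Hz) must be below Nyquist (%g Hz)",
                    cutoff, block$rate / 2)
  emg <- which(block$roles == "emg")
  if (!length(emg)) stop_validation("block has no EMG channels")
  bf <- signal::butter(order, cutoff / (block$rate / 2), type = "high")
  out <- block$data
  for (ch in emg) out[, ch] <- as.numeric(signal::filtfilt(bf, block$data[, ch]))
  signal_block(out, rate = block$rate, roles = block$roles, t0 = block$t0)
}

#' Normalise EMG channels to maximal voluntary contraction
#'
#' Divides each EMG channel by its per-channel positive MVC reference value;
#' mechanical channels are untouched.
#'
#' @param block A [signal_block()].
#' @param mvc_reference Positive numeric vector, one value per EMG channel
#'   (recycled if length 1).
#' @return The normalised `signal_block`.
#' @export
normalize_mvc <- function(block, mvc_reference) {
  emg <- which(block$roles == "emg")
  if (!length(emg)) stop_validation("block has no EMG channels")
  if (length(mvc_reference) == 1L) mvc_reference <- rep(mvc_reference, length(emg))
  if (length(mvc_reference) != length(emg))
    stop_validation("mvc_reference must supply one value per EMG channel")
  if (any(!is.finite(mvc_reference)) || any(mvc_reference <= 0))
    stop_validation("MVC reference values must be positive")
  out <- block$data
  out[, emg] <- sweep(out[, emg, drop = FALSE], 2L, mvc_reference, `/`)
  signal_block(out, rate = block$rate, roles = block$roles, t0 = block$t0)
}

#' Resample all channels of a block to a common rate
#'
#' Linear-interpolation resampling of every channel onto a uniform grid at
#' the target rate, preserving the block duration to within one sample
#' period. Output length is `round(n * target_rate / rate)`.
#'
#' @param block A [signal_block()].
#' @param target_rate Target sampling rate in Hz.
#' @return The resampled `signal_block`.
#' @export
resample_block <- function(block, target_rate = 1000) {
  if (target_rate <= 0) stop_validation("target rate must be positive")
  n <- nrow(block$data)
  if (block$rate == target_rate) return(block)
  n_out <- max(1L, round(n * target_rate / block$rate))
  t_in <- (seq_len(n) - 1L) / block$rate
  t_out <- (seq_len(n_out) - 1L) / target_rate
  out <- apply(block$data, 2L, function(col)
    approx(t_in, col, xout = t_out, rule = 2)$y)
  out <- matrix(out, nrow = n_out, dimnames = list(NULL, colnames(block$data)))
  signal_block(out, rate = target_rate, roles = block$roles, t0 = block$t0)
}

# Map a time in ms to the row index of the sample at (or first at/after) it.
time_to_index <- function(block, time_ms) {
  1L + as.integer(round((time_ms - block$t0) * block$rate / 1000))
}

#' Cut the forward prediction window before a gait event
#'
#' Returns exactly `forward_ms * rate / 1000` samples ending one sample
#' before the event time: the window is half-open, the event sample itself is
#' never read (causal prediction).
#'
#' @param block A [signal_block()].
#' @param event_time Event (initial contact) time in ms.
#' @param spec A [window_spec()].
#' @return A `signal_block` holding the window.
#' @export
cut_forward_window <- function(block, event_time, spec = window_spec()) {
  n_win <- as.integer(round(spec$forward_ms * block$rate / 1000))
  i_event <- time_to_index(block, event_time)
  i_start <- i_event - n_win
  if (i_start < 1L || i_event - 1L > nrow(block$data))
    stop_validation("event at %g ms lacks %g ms of preceding signal",
                    event_time, spec$forward_ms)
  signal_block(block$data[i_start:(i_event - 1L), , drop = FALSE],
               rate = block$rate, roles = block$roles,
               t0 = block$t0 + (i_start - 1L) * 1000 / block$rate)
}

#' Cut the previous-stride window ending at a gait event
#'
#' Returns the samples of the completed stride `[previous_event,
#' current_event)`. Strides longer than the backward maximum are truncated to
#' their most recent `backward_ms` milliseconds.
#'
#' @param block A [signal_block()].
#' @param previous_event,current_event Consecutive gait-event times in ms
#'   (strictly increasing).
#' @param spec A [window_spec()].
#' @return A `signal_block` holding the stride window.
#' @export
cut_stride_window <- function(block, previous_event, current_event,
                              spec = window_spec()) {
  if (previous_event >= current_event)
    stop_validation("previous_event must precede current_event")
  i_prev <- time_to_index(block, previous_event)
  i_cur <- time_to_index(block, current_event)
  if (i_prev < 1L || i_cur - 1L > nrow(block$data))
    stop_validation("stride window [%g, %g) outside the block", previous_event,
                    current_event)
  n_max <- as.integer(round(spec$backward_ms * block$rate / 1000))
  i_start <- max(i_prev, i_cur - n_max)
  signal_block(block$data[i_start:(i_cur - 1L), , drop = FALSE],
               rate = block$rate, roles = block$roles,
               t0 = block$t0 + (i_start - 1L) * 1000 / block$rate)
}
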