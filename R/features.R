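#' Feature extraction specification
#'
#' @param ar_order Order of the autoregressive model fitted to each EMG
#'   window (default 4).
#' @param deadband Amplitude deadband used by the zero-crossing and
#'   slope-sign-change counts; 0 counts every crossing.
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(ar_order = 4L, deadband = 0) {
  if (!is_count(ar_order)) stop_validation("ar_order must be a positive integer")
  if (deadband < 0) stop_validation("deadband must be >= 0")
  structure(list(ar_order = as.integer(ar_order), deadband = deadband),
            class = "feature_spec")
}

emg_feature_names <- function(spec = feature_spec()) {
  c("mav", "zc", "ssc", "wl", sprintf("ar%d", seq_len(spec$ar_order)))
}

mechanical_feature_names <- function() {
  c("mean", "sd", "max", "min", "start", "end")
}

# Burg AR fit padded to `order` coefficients. Perfectly predictable series
# (e.g. a pure alternation) drive the Burg residual variance to zero at some
# order; coefficients beyond the last fittable order are 0.
fit_ar_burg <- function(x, order) {
  if (sd(x) == 0) return(rep(0, order))
  for (k in order:1) {
    co <- tryCatch(stats::ar.burg(x, aic = FALSE, order.max = k,
                                  demean = TRUE)$ar,
                   error = function(e) NULL)
    if (!is.null(co)) return(c(co, rep(0, order - length(co))))
  }
  rep(0, order)
}

#' Time-domain EMG features of one window
#'
#' Computes the classical time-domain feature set of a single-channel EMG
#' window: mean absolute value (MAV), zero crossings (ZC), slope sign changes
#' (SSC), waveform length (WL) and the coefficients of a fourth-order
#' autoregressive (AR) model. ZC counts sign changes between consecutive
#' samples whose amplitude step exceeds the deadband; SSC counts slope
#' reversals with the same deadband. AR coefficients are fitted by the Burg
#' method in the prediction convention `x_t = sum(a_i * x_{t-i}) + e_t`.
#'
#' @param window Numeric vector of samples (one channel).
#' @param spec A [feature_spec()].
#' @return Named numeric vector `mav, zc, ssc, wl, ar1..arK`.
#' @export
emg_features <- function(window, spec = feature_spec()) {
  x <- as.numeric(window)
  if (length(x) < max(5L, spec$ar_order + 1L))
    stop_validation("EMG window too short (%d samples)", length(x))
  if (any(!is.finite(x))) stop_validation("EMG window contains non-finite values")
  eps <- spec$deadband
  dx <- diff(x)
  mav <- mean(abs(x))
  wl <- sum(abs(dx))
  zc <- sum(x[-length(x)] * x[-1L] < 0 & abs(dx) > eps)
  mid <- x[c(-1L, -length(x))]
  d1 <- mid - x[seq_len(length(x) - 2L)]
  d2 <- mid - x[3L:length(x)]
  ssc <- sum(d1 * d2 > eps)
  setNames(c(mav, zc, ssc, wl, fit_ar_burg(x, spec$ar_order)),
           emg_feature_names(spec))
}

#' Summary features of one mechanical-channel window
#'
#' The six stride/window summaries used for mechanical sensor channels:
#' mean, standard deviation (population convention, divisor `n`), maximum,
#' minimum, start value and end value. Being summaries, they are invariant
#' to window length, so variable-duration strides yield a fixed dimension.
#'
#' @param window Numeric vector of samples (one channel).
#' @return Named numeric vector `mean, sd, max, min, start, end`.
#' @export
mechanical_features <- function(window) {
  x <- as.numeric(window)
  if (!length(x)) stop_validation("mechanical window is empty")
  if (any(!is.finite(x))) stop_validation("mechanical window contains non-finite values")
  n <- length(x)
  sd_pop <- sqrt(sum((x - mean(x))^2) / n)
  setNames(c(mean(x), sd_pop, max(x), min(x), x[1L], x[n]),
           mechanical_feature_names())
}

#' Assemble the forward feature vector of one event window
#'
#' Concatenates, in channel order, the EMG time-domain features of every EMG
#' channel and the six summary features of every mechanical channel of the
#' forward (pre-event) window. With 8 EMG and 20 mechanical channels this is
#' the default 8 x 8 + 6 x 20 = 184-dimensional vector.
#'
#' @param window A [signal_block()] holding the forward window (all
#'   channels).
#' @param spec A [feature_spec()].
#' @return Named numeric vector, names `<channel>_<feature>`.
#' @export
build_forward_vector <- function(window, spec = feature_spec()) {
  if (!inherits(window, "signal_block"))
    stop_validation("window must be a signal_block")
  cols <- colnames(window$data) %||% sprintf("ch%02d", seq_len(ncol(window$data)))
  out <- lapply(seq_along(window$roles), function(i) {
    f <- if (window$roles[i] == "emg") emg_features(window$data[, i], spec)
         else mechanical_features(window$data[, i])
    setNames(f, paste(cols[i], names(f), sep = "_"))
  })
  unlist(out)
}

#' Assemble the backward (stride) feature vector
#'
#' Concatenates the six summary features of every mechanical channel of a
#' completed-stride window. EMG channels are not part of the backward
#' representation and their presence is an error; subset the block with
#' [subset_channels()] first. With 20 mechanical channels this is the default
#' 120-dimensional vector.
#'
#' @param window A [signal_block()] holding the stride window, mechanical
#'   channels only.
#' @return Named numeric vector, names `<channel>_<feature>`.
#' @export
build_backward_vector <- function(window) {
  if (!inherits(window, "signal_block"))
    stop_validation("window must be a signal_block")
  if (any(window$roles == "emg"))
    stop_validation("backward features use mechanical channels only; drop EMG channels first")
  cols <- colnames(window$data) %||% sprintf("ch%02d", seq_len(ncol(window$data)))
  out <- lapply(seq_len(ncol(window$data)), function(i) {
    f <- mechanical_features(window$data[, i])
    setNames(f, paste(cols[i], names(f), sep = "_"))
  })
  unlist(out)
}
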