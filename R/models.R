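#' Network training configuration
#'
#' Training regimen of the single-hidden-layer softmax networks: 20 hidden
#' rectifier units, Adam with step size 0.001, at most 100 epochs, early
#' stopping when the validation error fails to improve for 3 consecutive
#' epochs, a 10% random validation split and mini-batches of 32.
#'
#' @param hidden Hidden-layer width.
#' @param learning_rate Adam step size.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience in epochs.
#' @param validation_fraction Fraction of samples held out for validation.
#' @param batch_size Mini-batch size.
#' @param seed Seed for weight initialisation, the validation split and
#'   batch shuffling.
#' @return An object of class `net_config`.
#' @export
net_config <- function(hidden = 20L, learning_rate = 0.001, max_epochs = 100L,
                       patience = 3L, validation_fraction = 0.10,
                       batch_size = 32L, seed = 1L) {
  if (!is_count(hidden)) stop_validation("hidden must be a positive integer")
  if (learning_rate <= 0) stop_validation("learning_rate must be positive")
  if (!is_count(max_epochs)) stop_validation("max_epochs must be a positive integer")
  if (!is_count(patience)) stop_validation("patience must be >= 1")
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop_validation("validation_fraction must lie in (0, 1)")
  if (!is_count(batch_size)) stop_validation("batch_size must be a positive integer")
  structure(list(hidden = as.integer(hidden), learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "net_config")
}

# z-score standardisation fitted on the current training pool; constant
# features get unit scale so they pass through unchanged.
fit_standardizer <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2L, sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_standardizer <- function(std, x) {
  sweep(sweep(x, 2L, std$center, `-`), 2L, std$scale, `/`)
}

#' Train a softmax network classifier
#'
#' Trains a single-hidden-layer rectifier network with a softmax output over
#' the distinct labels present in `y`. Features are z-scored on the training
#' data; the standardisation is stored with the model and reapplied at
#' prediction time. Training holds out a random validation fraction, stops
#' early when the validation error has not improved for `patience` epochs and
#' returns the weights of the best validation epoch. Deterministic given
#' `config$seed`.
#'
#' @param x Numeric matrix, samples in rows.
#' @param y Vector of class labels (at least two distinct values).
#' @param config A [net_config()].
#' @return An object of class `gait_classifier`.
#' @export
train_classifier <- function(x, y, config = net_config()) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (nrow(x) != length(y)) stop_validation("x and y lengths differ")
  classes <- sort(unique(y))
  if (length(classes) < 2L)
    stop_validation("training requires at least two distinct labels")
  if (nrow(x) < 10L)
    stop_validation("training requires at least 10 samples")
  std <- fit_standardizer(x)
  fit <- mlp_train_cpp(apply_standardizer(std, x),
                       as.integer(factor(y, levels = classes)) - 1L,
                       length(classes), config$hidden, config$learning_rate,
                       config$max_epochs, config$patience,
                       config$validation_fraction, config$batch_size,
                       config$seed)
  structure(list(classes = classes, w1 = fit$w1, b1 = as.numeric(fit$b1),
                 w2 = fit$w2, b2 = as.numeric(fit$b2),
                 standardizer = std, config = config, constant = FALSE,
                 val_error = fit$val_error, epochs = fit$epochs,
                 best_epoch = fit$best_epoch, n_train = nrow(x)),
            class = "gait_classifier")
}

# Degenerate classifier returning a fixed posterior regardless of input:
# the empirical class frequencies. Used for modes whose training data cannot
# support a network (a single observed successor, or too few samples).
prior_classifier <- function(classes, probs = rep(1 / length(classes),
                                                  length(classes))) {
  structure(list(classes = classes, prior = probs / sum(probs),
                 constant = TRUE, n_train = NA_integer_),
            class = "gait_classifier")
}

# A mode with one observed successor: always that class with posterior 1
# (hence entropy 0).
constant_classifier <- function(class) {
  prior_classifier(class, 1)
}

#' @export
print.gait_classifier <- function(x, ...) {
  if (x$constant)
    cat(sprintf("gait_classifier: constant -> %s\n", x$classes))
  else
    cat(sprintf("gait_classifier: %d classes [%s], %d inputs, val error %.3f (epoch %d/%d)\n",
                length(x$classes), paste(x$classes, collapse = ", "),
                nrow(x$w1), x$val_error, x$best_epoch, x$epochs))
  invisible(x)
}

#' Posterior class probabilities of a classifier
#'
#' @param clf A `gait_classifier`.
#' @param x Numeric vector (one sample) or matrix (samples in rows) with the
#'   training dimension.
#' @return Matrix of posteriors, one row per sample, columns named by class;
#'   rows are non-negative and sum to 1.
#' @export
predict_posterior <- function(clf, x) {
  if (!inherits(clf, "gait_classifier")) stop_validation("clf must be a gait_classifier")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (clf$constant)
    return(matrix(clf$prior, nrow = nrow(x), ncol = length(clf$classes),
                  byrow = TRUE, dimnames = list(NULL, clf$classes)))
  if (ncol(x) != nrow(clf$w1))
    stop_validation("input dimension %d does not match training dimension %d",
                    ncol(x), nrow(clf$w1))
  z <- apply_standardizer(clf$standardizer, x) %*% clf$w1
  z <- sweep(z, 2L, clf$b1, `+`)
  z[z < 0] <- 0
  z <- z %*% clf$w2
  z <- sweep(z, 2L, clf$b2, `+`)
  z <- z - apply(z, 1L, max)
  p <- exp(z)
  p <- p / rowSums(p)
  colnames(p) <- clf$classes
  p
}

#' Predicted labels of a classifier
#'
#' @param clf A `gait_classifier`.
#' @param x Samples as in [predict_posterior()].
#' @return Character vector of argmax labels.
#' @export
predict_label <- function(clf, x) {
  p <- predict_posterior(clf, x)
  clf$classes[max.col(p, ties.method = "first")]
}

#' Train the mode-specific forward predictor bank
#'
#' Groups training events by their current mode and trains one softmax
#' network per mode over that mode's observed successor activities. A mode
#' with a single observed successor gets a constant predictor returning that
#' class with posterior 1. The per-mode class lists are fixed at this initial
#' training and retained across later retrains.
#'
#' @param x Numeric matrix of forward feature vectors, samples in rows.
#' @param modes Character vector of current modes, one per sample.
#' @param y Character vector of true upcoming activities, one per sample.
#' @param config A [net_config()]; each mode trains with a seed derived from
#'   `config$seed` so the bank is reproducible as a whole.
#' @return An object of class `mode_specific_predictor`.
#' @export
train_mode_specific <- function(x, modes, y, config = net_config()) {
  x <- as.matrix(x)
  modes <- as.character(modes)
  y <- as.character(y)
  if (!nrow(x)) stop_validation("no training samples")
  if (nrow(x) != length(modes) || nrow(x) != length(y))
    stop_validation("x, modes and y must agree in length")
  mode_levels <- sort(unique(modes))
  classifiers <- list()
  for (i in seq_along(mode_levels)) {
    m <- mode_levels[i]
    sel <- modes == m
    succ <- sort(unique(y[sel]))
    classifiers[[m]] <- if (length(succ) == 1L) constant_classifier(succ)
    else if (sum(sel) < 10L) {
      # too few samples to fit a network: fall back to class frequencies
      prior_classifier(succ, as.numeric(table(factor(y[sel], levels = succ))))
    } else {
      cfg <- config
      cfg$seed <- seed_child(config$seed, i)
      train_classifier(x[sel, , drop = FALSE], y[sel], cfg)
    }
  }
  structure(list(classifiers = classifiers,
                 classes_per_mode = lapply(classifiers, `[[`, "classes"),
                 config = config),
            class = "mode_specific_predictor")
}

#' @export
print.mode_specific_predictor <- function(x, ...) {
  cat(sprintf("mode_specific_predictor: %d modes\n", length(x$classifiers)))
  for (m in names(x$classifiers)) {
    cl <- x$classifiers[[m]]
    cat(sprintf("  %-14s N=%d%s\n", m, length(cl$classes),
                if (cl$constant) " (constant)" else ""))
  }
  invisible(x)
}

#' Posterior of the forward bank for samples in one mode
#'
#' @param bank A `mode_specific_predictor`.
#' @param x Samples (vector or matrix).
#' @param mode Current mode of the samples.
#' @return Posterior matrix over that mode's class list.
#' @export
predict_mode_posterior <- function(bank, x, mode) {
  clf <- bank$classifiers[[mode]]
  if (is.null(clf))
    stop_validation("no classifier for mode '%s' (unseen in training data)", mode)
  predict_posterior(clf, x)
}

#' Train the backward (previous-stride) predictor
#'
#' A single softmax network over all activity classes, trained on
#' stride-level mechanical feature vectors. Unlike the forward bank it is not
#' mode-specific.
#'
#' @param x Numeric matrix of backward feature vectors.
#' @param y True activity labels.
#' @param config A [net_config()].
#' @return A `gait_classifier`.
#' @export
train_backward <- function(x, y, config = net_config()) {
  train_classifier(x, y, config)
}
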