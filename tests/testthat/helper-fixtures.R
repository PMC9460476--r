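# Shared fixtures, all generated in code.

# Two well-separated Gaussian classes: means differ by 3 SD per coordinate,
# so a nearest-centroid rule is essentially error-free.
separable_two_class <- function(n = 200, d = 4, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * d), n),
             sweep(matrix(rnorm(n * d), n), 2, rep(3, d), `+`))
  list(x = x, y = rep(c("A", "B"), each = n))
}

# A small multi-day feature session for protocol tests.
small_session <- function(seed = 1, n_days = 2, trials_per_day = 10,
                          shift = c(0, 1.0, 1.2, 1.3),
                          vscale = c(1, 0.75, 0.65, 0.65)) {
  simulate_feature_session(
    drift = drift_config(seed = seed, shift_magnitude = shift,
                         var_scale = vscale),
    n_days = n_days, trials_per_day = trials_per_day)
}

# Random posterior vectors on the simplex.
random_simplex <- function(n, k) {
  m <- matrix(rexp(n * k), n)
  m / rowSums(m)
}

# Naive reference implementations of the time-domain features.
naive_td_features <- function(x, eps = 0) {
  n <- length(x)
  mav <- sum(abs(x)) / n
  wl <- 0; zc <- 0; ssc <- 0
  for (i in 1:(n - 1)) {
    wl <- wl + abs(x[i + 1] - x[i])
    if (x[i] * x[i + 1] < 0 && abs(x[i + 1] - x[i]) > eps) zc <- zc + 1
  }
  for (i in 2:(n - 1)) {
    if ((x[i] - x[i - 1]) * (x[i] - x[i + 1]) > eps) ssc <- ssc + 1
  }
  c(mav = mav, zc = zc, ssc = ssc, wl = wl)
}

naive_mech_features <- function(x) {
  n <- length(x)
  c(mean = sum(x) / n, sd = sqrt(sum((x - sum(x) / n)^2) / n),
    max = max(x), min = min(x), start = x[1], end = x[n])
}

make_window_block <- function(n = 300, n_emg = 2, n_mech = 3, rate = 1000,
                              seed = 1) {
  set.seed(seed)
  data <- matrix(rnorm(n * (n_emg + n_mech)), n)
  colnames(data) <- c(sprintf("emg%02d", seq_len(n_emg)),
                      sprintf("mech%02d", seq_len(n_mech)))
  signal_block(data, rate = rate,
               roles = c(rep("emg", n_emg), rep("mechanical", n_mech)))
}
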