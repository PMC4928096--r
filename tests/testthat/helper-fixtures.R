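# Shared fixtures, built in code at test time.

# short renewal recording reused by several files
fixture_renewal <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_ig_renewal(0.8, 1500, 300, seed = 42)
    }
    cache
  }
})

# constant-parameter trajectory on a coarse grid over the fixture
fixture_null_traj <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- constant_parameter_trajectory(
        fixture_renewal(), null_params(1500),
        fit_config(step_delta = 0.5))
    }
    cache
  }
})

# synthetic ECG built from a QRS-like template at known beat times
synthetic_ecg <- function(beat_times, fs = 500, duration = NULL,
                          noise_sd = 0) {
  if (is.null(duration)) duration <- max(beat_times) + 1
  n <- round(duration * fs)
  x <- numeric(n)
  tt <- seq(-0.05, 0.05, by = 1 / fs)
  qrs <- exp(-(tt / 0.012)^2) - 0.35 * exp(-((tt - 0.025) / 0.02)^2)
  for (bt in beat_times) {
    i0 <- round(bt * fs) + 1
    idx <- i0 + seq_along(qrs) - 1 - (length(qrs) %/% 2)
    ok <- idx >= 1 & idx <= n
    x[idx[ok]] <- x[idx[ok]] + qrs[ok]
  }
  if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
  ecg_trace(x, fs)
}

# two-class synthetic feature table: `informative` dimensions separated
# by `sep` pooled SDs, the rest noise
separable_features <- function(n = 64, p = 39, informative = 5, sep = 10,
                               seed = 1) {
  set.seed(seed)
  y <- rep(c("a", "b"), length.out = n)
  X <- matrix(stats::rnorm(n * p), n, p)
  X[y == "b", seq_len(informative)] <-
    X[y == "b", seq_len(informative)] + sep
  colnames(X) <- sprintf("f%02d", seq_len(p))
  list(X = X, y = factor(y))
}
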