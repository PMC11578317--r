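# Shared fixtures built in code.

# A glucose link with the waveform noise switched off (deterministic
# morphology), used for recoverability and monotonicity checks.
noiseless_link <- function() {
  glucose_link(noise_intercept = 0, noise_slope = 0, noise_floor = 1e-9)
}

# Small random regression fixtures on integer grids (exact sums in double,
# so the implementation and the exhaustive oracle agree bit-for-bit).
random_int_fixture <- function(n, d, seed) {
  set.seed(seed)
  list(X = matrix(sample(0:9, n * d, replace = TRUE), n, d),
       y = sample(0:9, n, replace = TRUE))
}

# Deterministic smooth response used for model-fit checks.
smooth_xy <- function(n, d = 3, noise_sd = 0, seed = 1) {
  set.seed(seed)
  X <- matrix(runif(n * d), n, d)
  y <- 5 + 2 * X[, 1] - 1.5 * X[, 2] + X[, 3]^2 + rnorm(n, 0, noise_sd)
  list(X = X, y = y)
}

# Tiny scenario for fast cohort-level tests.
tiny_scenario <- function(n_records = 6L, n_subjects = 1L,
                          glucose_range = c(4.4, 6.4)) {
  scenario_spec("nir_single", n_records, glucose_range,
                n_subjects = n_subjects, duration = 6, sampling_rate = 500)
}

# A recording made of identical concatenated noiseless beats.
concat_beats_record <- function(n_beats, params = beat_params(),
                                sampling_rate = 500) {
  b <- simulate_beat(params, sampling_rate)
  x <- rep(b$intensities, n_beats)
  ppg_record((seq_along(x) - 1) / sampling_rate, x,
             sampling_rate = sampling_rate)
}
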