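## internal helpers shared across modules

# epoch length of the scoring grid, seconds (AASM-style scoring uses 30 s;
# this pipeline inherits 20-s epochs from its clinical scoring convention)
EPOCH_S <- 20

`%||%` <- rlang::`%||%`

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi))
  }
  invisible(x)
}

# derive a child seed stream; keeps results < 2^31 for R's 32-bit integers
child_seed <- function(seed, offset) {
  (as.numeric(seed) * 1000003 + offset) %% 2147483647
}

# 1/f (pink) background noise via spectral shaping of white noise,
# normalised to the requested standard deviation in microvolts
pink_noise <- function(n, sd_uv) {
  if (sd_uv <= 0) return(numeric(n))
  wn <- rnorm(n)
  k <- seq_len(n) - 1
  freq <- pmin(k, n - k)
  freq[1] <- 1
  z <- Re(fft(fft(wn) / sqrt(freq), inverse = TRUE)) / n
  z * sd_uv / sd(z)
}

# amplitude of an f-Hz component measured over the central half of a signal
# (used in tests and filter-response checks; edges avoid filtfilt transients)
sine_amplitude <- function(x, f, fs) {
  n <- length(x)
  i <- seq(round(n * 0.25), round(n * 0.75))
  t <- (i - 1) / fs
  2 * sqrt(mean(x[i] * cos(2 * pi * f * t))^2 +
             mean(x[i] * sin(2 * pi * f * t))^2)
}
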