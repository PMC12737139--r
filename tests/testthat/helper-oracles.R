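# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# literal double-loop-free but direct-summation autocorrelation with the
# per-lag tail normalization, straight from its definition
nacf_direct <- function(y) {
  n <- length(y)
  total <- sum(y^2)
  vapply(0:(n - 1L), function(k) {
    idx <- 1:(n - k)
    num <- sum(y[idx] * y[idx + k])
    num / (sqrt(total) * sqrt(sum(y[idx + k]^2)))
  }, numeric(1))
}

# two-stage grid maximizer: coarse pass, then a 1e-7-step refinement around
# the coarse winner — equivalent to a full 1e-7 grid for unimodal functions
grid_argmax <- function(f, lower, upper, fine_step = 1e-7) {
  coarse <- seq(lower, upper, length.out = 20001L)
  v <- vapply(coarse, f, numeric(1))
  best <- coarse[which.max(v)]
  half <- (upper - lower) / 20000
  lo <- max(lower, best - 2 * half)
  hi <- min(upper, best + 2 * half)
  fine <- seq(lo, hi, by = fine_step)
  fine[which.max(vapply(fine, f, numeric(1)))]
}

# seeded family of smooth unimodal test objectives on [0, 1]
random_unimodal <- function(seed) {
  set.seed(seed)
  m <- stats::runif(1, 0.05, 0.95) # argmax
  p <- stats::runif(1, 1.2, 3)
  a <- stats::runif(1, 0.5, 5)
  list(f = function(x) -a * abs(x - m)^p, argmax = m)
}

# fraction of periodogram power at or below f_hz
low_freq_power_frac <- function(x, fs, f_hz) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))^2
  half <- 2:(n %/% 2 + 1L) # drop DC, keep positive frequencies
  freqs <- (half - 1L) * fs / n
  sum(sp[half][freqs <= f_hz]) / sum(sp[half])
}

make_ecg_pair <- function(seed, kind = "WHITE", snr_db = 5, fs = 360,
                          duration = 10, hr = 72) {
  clean <- synth_ecg(fs, duration, heart_rate_bpm = hr, seed = seed)
  noise <- synth_noise(kind, fs, length(clean$samples), seed = seed + 5000L)
  mix_at_snr(clean, noise, snr_db)
}
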