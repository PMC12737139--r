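# Seeded generators for quasi-periodic test signals and physiological noise.
# Every generator is a pure function of (parameters, seed): the global RNG
# state is saved and restored around each call.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Gaussian bump constants for one heartbeat. Offsets for the slow P and T
# waves scale with the RR interval; the QRS complex keeps a fixed width in
# seconds, as in real ECG. Amplitudes relative to the R peak.
.ecg_waves <- data.frame(
  wave = c("P", "Q", "R", "S", "T"),
  offset_rr = c(-0.22, 0, 0, 0, 0.30), # fraction of RR, added to offset_s
  offset_s = c(0, -0.035, 0, 0.035, 0),
  amplitude = c(0.12, -0.15, 1.00, -0.22, 0.32),
  width_s = c(0.040, 0.012, 0.018, 0.014, 0.060)
)

#' Synthetic ECG-like signal
#'
#' Sum of per-beat Gaussian bumps for the P, Q, R, S and T waves (R
#' dominant) at fixed phase offsets, with beat onsets spaced by RR intervals
#' carrying seeded multiplicative jitter. The waveform is a morphological
#' stand-in for a clinical ECG — quasi-periodic, sharp QRS, slower P/T — not
#' a physiological model. Peak amplitude is normalized to 1.
#'
#' @param fs Sampling rate in Hz (>= 100).
#' @param duration_s Duration in seconds.
#' @param heart_rate_bpm Mean heart rate, 30-240 bpm.
#' @param rr_jitter_frac Multiplicative RR jitter, 0-0.2 (uniform on
#'   `+/- rr_jitter_frac`).
#' @param seed Integer seed; same seed, same signal.
#' @return A [sampled_signal()].
#' @examples
#' ecg <- synth_ecg(360, 10, heart_rate_bpm = 72, seed = 1)
#' @export
synth_ecg <- function(fs, duration_s, heart_rate_bpm = 72, rr_jitter_frac = 0.05,
                      seed = 1L) {
  if (fs < 100) stop("fs must be >= 100 Hz", call. = FALSE)
  if (heart_rate_bpm < 30 || heart_rate_bpm > 240) {
    stop("heart_rate_bpm must be in [30, 240]", call. = FALSE)
  }
  if (rr_jitter_frac < 0 || rr_jitter_frac > 0.2) {
    stop("rr_jitter_frac must be in [0, 0.2]", call. = FALSE)
  }
  n <- as.integer(round(fs * duration_s))
  rr <- 60 / heart_rate_bpm
  with_seed(seed, {
    # R-peak times: first beat centered at rr/2, jittered spacings
    n_beats <- ceiling(duration_s / rr) + 3L
    jit <- 1 + rr_jitter_frac * stats::runif(n_beats, -1, 1)
    r_times <- rr / 2 + c(0, cumsum(rr * jit[-1]))
    t <- (seq_len(n) - 1L) / fs
    x <- numeric(n)
    for (b in r_times) {
      if (b < -0.5 || b > duration_s + 0.5) next
      for (w in seq_len(nrow(.ecg_waves))) {
        center <- b + .ecg_waves$offset_rr[w] * rr + .ecg_waves$offset_s[w]
        width <- .ecg_waves$width_s[w]
        lo <- max(1L, as.integer(floor((center - 5 * width) * fs)))
        hi <- min(n, as.integer(ceiling((center + 5 * width) * fs)) + 1L)
        if (lo > hi) next
        idx <- lo:hi
        x[idx] <- x[idx] +
          .ecg_waves$amplitude[w] * exp(-((t[idx] - center)^2) / (2 * width^2))
      }
    }
    x <- x / max(abs(x))
    sampled_signal(x, fs, sprintf("synthetic ECG %g bpm seed %d", heart_rate_bpm, seed))
  })
}

#' Synthetic physiological noise
#'
#' Seeded emulations of the standard ECG noise taxonomy, all normalized to
#' zero mean and unit power:
#' * `BW` — baseline wander: 2-3 sinusoids below 0.5 Hz plus a slow random
#'   walk;
#' * `EM` — electrode motion: sparse step/transient events convolved with a
#'   short exponential decay kernel;
#' * `MA` — muscle artifact: white noise band-passed to 20 to
#'   `min(100, 0.45 fs)` Hz;
#' * `MIX` — equal-power sum of BW + EM + MA;
#' * `WHITE` — white Gaussian noise.
#'
#' @param kind One of `"BW"`, `"EM"`, `"MA"`, `"MIX"`, `"WHITE"`.
#' @param fs Sampling rate in Hz.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return A [sampled_signal()] with attributes `kind` and `seed`.
#' @export
synth_noise <- function(kind, fs, n, seed = 1L) {
  kind <- toupper(kind)
  kinds <- c("BW", "EM", "MA", "MIX", "WHITE")
  if (!kind %in% kinds) {
    stop(sprintf("unknown noise kind '%s' (use %s)", kind,
                 paste(kinds, collapse = "/")), call. = FALSE)
  }
  n <- as.integer(n)
  raw <- with_seed(seed, switch(
    kind,
    WHITE = stats::rnorm(n),
    BW = {
      t <- (seq_len(n) - 1L) / fs
      n_sin <- sample(2:3, 1L)
      freqs <- stats::runif(n_sin, 0.05, 0.45)
      phases <- stats::runif(n_sin, 0, 2 * pi)
      amps <- stats::runif(n_sin, 0.5, 1)
      s <- numeric(n)
      for (i in seq_len(n_sin)) s <- s + amps[i] * sin(2 * pi * freqs[i] * t + phases[i])
      walk <- cumsum(stats::rnorm(n)) / sqrt(n) # 1/f^2 drift
      s + walk
    },
    EM = {
      rate_hz <- 0.7 # mean transient events per second
      n_events <- max(1L, stats::rpois(1L, rate_hz * n / fs))
      pos <- sample.int(n, n_events, replace = TRUE)
      amp <- stats::rnorm(n_events) * stats::rexp(n_events) # heavy-tailed
      is_step <- stats::runif(n_events) < 0.5
      s <- numeric(n)
      for (i in seq_len(n_events)) {
        if (is_step[i]) {
          s[pos[i]:n] <- s[pos[i]:n] + amp[i]
        } else {
          s[pos[i]] <- s[pos[i]] + amp[i]
        }
      }
      tau <- stats::runif(1L, 0.05, 0.3) # decay time constant, s
      kl <- as.integer(ceiling(5 * tau * fs))
      kernel <- exp(-(0:kl) / (tau * fs))
      # causal convolution with zero initial history
      sm <- stats::filter(c(numeric(kl), s), kernel,
                          method = "convolution", sides = 1)
      as.numeric(sm)[(kl + 1L):(kl + n)]
    },
    MA = {
      hi <- min(100, 0.45 * fs)
      if (hi <= 20) stop("fs too low for the 20 Hz muscle-artifact band", call. = FALSE)
      w <- stats::rnorm(n)
      bp <- signal::butter(4, c(20, hi) / (fs / 2), type = "pass")
      as.numeric(signal::filtfilt(bp, w))
    },
    MIX = {
      parts <- lapply(c("BW", "EM", "MA"), function(k) {
        signal_samples(synth_noise(k, fs, n, seed = seed + match(k, kinds)))
      })
      Reduce(`+`, parts) / sqrt(3)
    }
  ))
  raw <- raw - mean(raw)
  p <- sqrt(mean(raw^2))
  if (p == 0) stop("degenerate zero-power noise draw", call. = FALSE)
  out <- sampled_signal(raw / p, fs, sprintf("%s noise seed %d", kind, seed))
  attr(out, "kind") <- kind
  attr(out, "seed") <- seed
  out
}

#' Mix clean signal and noise at an exact input SNR
#'
#' Scales the noise by `c = sqrt(sum(x^2) / (sum(v^2) * 10^(snr/10)))` so
#' that `snr(clean, clean + c*v)` equals the target exactly (to
#' floating-point accuracy), and returns the full triple.
#'
#' @param clean Clean [sampled_signal()].
#' @param noise Noise [sampled_signal()] of the same length.
#' @param target_snr_db Desired input SNR in dB.
#' @return A `noisy_signal_pair`: list with `clean`, `noise` (scaled),
#'   `noisy`, `input_snr_db`, `noise_kind`, `seed`.
#' @export
mix_at_snr <- function(clean, noise, target_snr_db) {
  x <- signal_samples(clean)
  v <- signal_samples(noise)
  if (length(x) != length(v)) stop("clean and noise lengths differ", call. = FALSE)
  px <- sum(x^2)
  pv <- sum(v^2)
  if (px == 0) stop("clean signal has zero power", call. = FALSE)
  if (pv == 0) stop("noise has zero power", call. = FALSE)
  cc <- sqrt(px / (pv * 10^(target_snr_db / 10)))
  scaled <- cc * v
  fs <- if (inherits(clean, "sampled_signal")) clean$fs else NA_real_
  structure(
    list(
      clean = as_sampled_signal(clean, fs),
      noise = sampled_signal(scaled, fs),
      noisy = sampled_signal(x + scaled, fs,
                             label = sprintf("noisy @ %g dB", target_snr_db)),
      input_snr_db = target_snr_db,
      noise_kind = attr(noise, "kind") %||% NA_character_,
      seed = attr(noise, "seed") %||% NA_integer_
    ),
    class = "noisy_signal_pair"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.noisy_signal_pair <- function(x, ...) {
  cat(sprintf(
    "<noisy_signal_pair> %d samples @ %g Hz, %s noise, input SNR %g dB\n",
    length(x$clean$samples), x$clean$fs, x$noise_kind, x$input_snr_db
  ))
  invisible(x)
}

#' Synthetic fiber-optic cardiorespiratory signal
#'
#' A slow respiration sinusoid plus smaller, sharper cardiac pulses whose
#' amplitude is modulated by the respiration phase — the waveform class
#' produced by multimode-fiber speckle sensing of chest micro-vibrations.
#' Peak amplitude normalized to 1.
#'
#' @param fs Sampling rate in Hz (default 2048, typical for fiber
#'   photodetector front-ends).
#' @param duration_s Duration in seconds.
#' @param heart_rate_bpm Cardiac rate (must exceed `resp_rate_bpm`).
#' @param resp_rate_bpm Respiration rate.
#' @param seed Integer seed (jitters the cardiac pulse times).
#' @return A [sampled_signal()].
#' @export
synth_fiber_cardioresp <- function(fs = 2048, duration_s = 20,
                                   heart_rate_bpm = 72, resp_rate_bpm = 15,
                                   seed = 1L) {
  if (resp_rate_bpm >= heart_rate_bpm) {
    stop("resp_rate_bpm must be below heart_rate_bpm", call. = FALSE)
  }
  if (resp_rate_bpm <= 0) stop("resp_rate_bpm must be positive", call. = FALSE)
  n <- as.integer(round(fs * duration_s))
  t <- (seq_len(n) - 1L) / fs
  f_resp <- resp_rate_bpm / 60
  rr <- 60 / heart_rate_bpm
  with_seed(seed, {
    resp <- sin(2 * pi * f_resp * t)
    n_beats <- ceiling(duration_s / rr) + 3L
    jit <- 1 + 0.03 * stats::runif(n_beats, -1, 1)
    beat_times <- rr / 2 + c(0, cumsum(rr * jit[-1]))
    card <- numeric(n)
    width <- 0.03
    for (b in beat_times) {
      if (b > duration_s + 0.5) break
      mod <- 1 + 0.3 * sin(2 * pi * f_resp * b)
      lo <- max(1L, as.integer(floor((b - 5 * width) * fs)))
      hi <- min(n, as.integer(ceiling((b + 5 * width) * fs)) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      card[idx] <- card[idx] + 0.35 * mod * exp(-((t[idx] - b)^2) / (2 * width^2))
    }
    x <- resp + card
    x <- x / max(abs(x))
    sampled_signal(x, fs, sprintf("fiber cardioresp %g/%g bpm seed %d",
                                  heart_rate_bpm, resp_rate_bpm, seed))
  })
}
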