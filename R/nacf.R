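#' Normalized autocorrelation function (tail-normalized)
#'
#' For a signal \eqn{y(0..N-1)} and lag \eqn{k}:
#' \deqn{\mathrm{NACF}(k) = \frac{\sum_{n=0}^{N-k-1} y(n)\,y(n+k)}
#'   {\sqrt{\sum_{n=0}^{N-1} y^2(n)}\ \sqrt{\sum_{n=0}^{N-k-1} y^2(n+k)}}.}
#' Note the second denominator factor sums only the N-k overlapping tail
#' samples: this is not the textbook biased autocorrelation, and the
#' normalization keeps \eqn{|\mathrm{NACF}(k)| \le 1} by Cauchy-Schwarz with
#' NACF(0) = 1 exactly. Quasi-periodic signals show large peaks at multiples
#' of their period; broadband noise does not — which is what makes the
#' profile usable as a reference-free denoising objective.
#'
#' The raw lagged products are computed via FFT-based correlation
#' (O(N log N)); the per-lag tail normalization is applied exactly.
#'
#' @param signal A [sampled_signal()] or numeric vector (length >= 2, not
#'   identically zero).
#' @param fs Sampling rate, required when `signal` is a bare numeric vector.
#' @return An object of class `nacf_profile`: list with `values` (numeric,
#'   lags 0..N-1), `sample_rate`.
#' @examples
#' p <- nacf(sampled_signal(sin(2 * pi * 5 * (0:999) / 250), fs = 250))
#' p$values[1] # lag 0 == 1
#' @export
nacf <- function(signal, fs = NULL) {
  if (is.numeric(signal) && is.null(fs)) fs <- NA_real_
  y <- signal_samples(signal)
  sr <- if (inherits(signal, "sampled_signal")) signal$fs else fs
  n <- length(y)
  if (n < 2L) stop("signal must have at least 2 samples", call. = FALSE)
  if (!all(is.finite(y))) stop("signal contains non-finite samples", call. = FALSE)
  total <- sum(y^2)
  if (total == 0) stop("all-zero signal: autocorrelation undefined", call. = FALSE)

  # raw autocorrelation r(k) = sum_n y(n) y(n+k) for k = 0..N-1 via FFT
  nfft <- 2^ceiling(log2(2 * n))
  fy <- stats::fft(c(y, numeric(nfft - n)))
  r <- Re(stats::fft(fy * Conj(fy), inverse = TRUE)) / nfft
  r <- r[seq_len(n)]

  # tail energy T(k) = sum_{m=k}^{N-1} y(m)^2
  tail_energy <- rev(cumsum(rev(y^2)))
  vals <- r / (sqrt(total) * sqrt(tail_energy))
  vals[1L] <- 1 # exact by construction
  structure(list(values = vals, sample_rate = sr), class = "nacf_profile")
}

#' @export
print.nacf_profile <- function(x, ...) {
  cat(sprintf("<nacf_profile> %d lags @ %g Hz\n", length(x$values), x$sample_rate))
  invisible(x)
}

#' Non-zero periodic peak (NZOPP) of the autocorrelation profile
#'
#' The largest NACF value over lags in `[exclusion_lag, floor(N/2)]`, where
#' `exclusion_lag = round(min_period_s * sample_rate)` excludes the zero-lag
#' main lobe. For a quasi-periodic signal the peak sits near the fundamental
#' period and approaches 1; for noise it is small. The default
#' `min_period_s = 0.25` s corresponds to a 240 bpm heart-rate ceiling, so
#' any physiological beat period is admissible.
#'
#' @param x An `nacf_profile` from [nacf()], a [sampled_signal()], or a
#'   numeric vector with `fs` given.
#' @param min_period_s Shortest admissible period in seconds (> 0).
#' @param fs Sampling rate when `x` is a bare numeric vector.
#' @return List with `peak_value`, `peak_lag` (samples; smallest lag on
#'   ties), `exclusion_lag`.
#' @export
nzopp <- function(x, min_period_s = 0.25, fs = NULL) {
  profile <- if (inherits(x, "nacf_profile")) x else nacf(x, fs = fs)
  if (!is.finite(profile$sample_rate) || profile$sample_rate <= 0) {
    stop("nzopp needs a valid sampling rate", call. = FALSE)
  }
  if (!is.finite(min_period_s) || min_period_s <= 0) {
    stop("min_period_s must be positive", call. = FALSE)
  }
  n <- length(profile$values)
  excl <- max(1L, as.integer(round(min_period_s * profile$sample_rate)))
  kmax <- n %/% 2L
  if (excl >= kmax) {
    stop(sprintf(
      "signal too short: exclusion lag %d >= floor(N/2) = %d", excl, kmax
    ), call. = FALSE)
  }
  lags <- excl:kmax
  vals <- profile$values[lags + 1L] # values[1] is lag 0
  best <- which.max(vals) # first maximum on ties
  list(
    peak_value = vals[best],
    peak_lag = lags[best],
    exclusion_lag = excl
  )
}
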