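# Reference-based quality metrics. x = clean reference, yin = noisy input,
# yout = denoised estimate; all equal-length numeric vectors or
# sampled_signal objects.

check_pair <- function(a, b) {
  a <- signal_samples(a)
  b <- signal_samples(b)
  if (length(a) != length(b)) {
    stop(sprintf("length mismatch: %d vs %d", length(a), length(b)), call. = FALSE)
  }
  list(a = a, b = b)
}

#' Signal-to-noise ratio (dB)
#'
#' `10 log10( sum(x^2) / sum((yout - x)^2) )`. Returns `Inf` when the
#' estimate equals the reference exactly (zero error), so batch reports
#' never abort on a perfect reconstruction.
#'
#' @param clean Clean reference signal.
#' @param estimate Denoised (or noisy) signal, same length.
#' @return SNR in dB (possibly `Inf`).
#' @examples
#' snr(c(1, 1, 1, 1), c(1, 1, 1, 0)) # 10*log10(4)
#' @export
snr <- function(clean, estimate) {
  p <- check_pair(clean, estimate)
  ps <- sum(p$a^2)
  if (ps == 0) stop("clean reference is identically zero", call. = FALSE)
  pe <- sum((p$b - p$a)^2)
  if (pe == 0) return(Inf)
  10 * log10(ps / pe)
}

#' Root-mean-square error
#'
#' `sqrt(mean((x - yout)^2))`, in signal units.
#'
#' @inheritParams snr
#' @return RMSE (>= 0).
#' @export
rmse <- function(clean, estimate) {
  p <- check_pair(clean, estimate)
  sqrt(mean((p$a - p$b)^2))
}

#' Percentage root-mean-square difference
#'
#' `100 * sqrt( sum((x - yout)^2) / sum(x^2) )`. Dimensionless (percent);
#' invariant to joint rescaling of both signals. Related to SNR by
#' `snr = -20 log10(prd / 100)`.
#'
#' @inheritParams snr
#' @return PRD in percent (>= 0).
#' @export
prd <- function(clean, estimate) {
  p <- check_pair(clean, estimate)
  ps <- sum(p$a^2)
  if (ps == 0) stop("clean reference is identically zero", call. = FALSE)
  100 * sqrt(sum((p$a - p$b)^2) / ps)
}

#' Signal-to-noise-and-distortion ratio (dB)
#'
#' `10 log10( Ps / (Pn + Pd) )` with `Ps = mean(x^2)`,
#' `Pn = mean((yout - x)^2)` and `Pd = mean((yout - yin)^2)`. `Pd` penalizes
#' how far the denoiser moved the signal from its input, so an output that
#' matches the clean reference but differs from the noisy input still gets a
#' finite score.
#'
#' @param clean Clean reference x.
#' @param noisy Noisy input yin.
#' @param denoised Denoised output yout.
#' @return SINAD in dB.
#' @examples
#' sinad(c(1, 1, 1, 1), c(1, 1, 1, -1), c(1, 1, 1, 0))
#' @export
sinad <- function(clean, noisy, denoised) {
  p1 <- check_pair(clean, noisy)
  p2 <- check_pair(clean, denoised)
  x <- p1$a
  yin <- p1$b
  yout <- p2$b
  ps <- mean(x^2)
  pn <- mean((yout - x)^2)
  pd <- mean((yout - yin)^2)
  if (pn + pd == 0) {
    stop("Pn + Pd is zero: SINAD undefined (output equals both reference and input)",
         call. = FALSE)
  }
  10 * log10(ps / (pn + pd))
}

#' Full metrics report for a (clean, noisy, denoised) triple
#'
#' Computes SNR, SINAD, RMSE, PRD and the underlying powers for the
#' denoised output, plus the improvements over the noisy input:
#' `delta_snr_db = snr(x, yout) - snr(x, yin)` and `delta_sinad_db`
#' analogous, with the input SINAD obtained by substituting yin for yout
#' throughout (making its Pd term zero).
#'
#' @inheritParams sinad
#' @return A `metrics_report` object: list with `snr_db`, `sinad_db`,
#'   `rmse`, `prd_percent`, `ps`, `pn`, `pd`, `input_snr_db`,
#'   `input_sinad_db`, `delta_snr_db`, `delta_sinad_db`.
#' @export
delta_metrics <- function(clean, noisy, denoised) {
  x <- signal_samples(clean)
  yin <- signal_samples(noisy)
  yout <- signal_samples(denoised)
  out_snr <- snr(x, yout)
  in_snr <- snr(x, yin)
  out_sinad <- sinad(x, yin, yout)
  in_sinad <- sinad(x, yin, yin) # Pd = 0 by construction
  structure(
    list(
      snr_db = out_snr,
      sinad_db = out_sinad,
      rmse = rmse(x, yout),
      prd_percent = prd(x, yout),
      ps = mean(x^2),
      pn = mean((yout - x)^2),
      pd = mean((yout - yin)^2),
      input_snr_db = in_snr,
      input_sinad_db = in_sinad,
      delta_snr_db = out_snr - in_snr,
      delta_sinad_db = out_sinad - in_sinad
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) if (is.infinite(v)) "inf" else sprintf("%.4f", v)
  cat("<metrics_report>\n")
  cat(sprintf("  SNR:    %s dB (input %s dB, delta %s dB)\n",
              fmt(x$snr_db), fmt(x$input_snr_db), fmt(x$delta_snr_db)))
  cat(sprintf("  SINAD:  %s dB (input %s dB, delta %s dB)\n",
              fmt(x$sinad_db), fmt(x$input_sinad_db), fmt(x$delta_sinad_db)))
  cat(sprintf("  RMSE:   %.6g\n", x$rmse))
  cat(sprintf("  PRD:    %.4f %%\n", x$prd_percent))
  invisible(x)
}
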