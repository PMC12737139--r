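#' Per-layer threshold rule
#'
#' Bundles the threshold lambda and tuning factor alpha attached to one
#' wavelet decomposition level. The tuning factor (units: inverse coefficient
#' amplitude) controls the shape of the layer-dependent threshold function:
#' small alpha gives gentle, smooth shrinkage; large alpha approaches hard
#' thresholding.
#'
#' @param level Decomposition level j (positive integer; 1 = finest detail).
#' @param threshold Threshold lambda_j >= 0, in coefficient-amplitude units.
#' @param tuning Tuning factor alpha_j >= 0.
#' @return A `layer_rule` object (list with `level`, `threshold`, `tuning`).
#' @export
layer_rule <- function(level, threshold, tuning) {
  level <- as.integer(level)
  if (is.na(level) || level < 1L) stop("level must be a positive integer", call. = FALSE)
  if (!is.finite(threshold) || threshold < 0) {
    stop("threshold must be a finite non-negative number", call. = FALSE)
  }
  if (!is.finite(tuning) || tuning < 0) {
    stop("tuning must be a finite non-negative number", call. = FALSE)
  }
  structure(
    list(level = level, threshold = as.numeric(threshold), tuning = as.numeric(tuning)),
    class = "layer_rule"
  )
}

#' @export
print.layer_rule <- function(x, ...) {
  cat(sprintf("<layer_rule> level %d: lambda = %.6g, alpha = %.6g\n",
              x$level, x$threshold, x$tuning))
  invisible(x)
}

#' Adaptive layer-dependent (tanh) threshold function
#'
#' Element-wise shrinkage rule applied to the detail coefficients of one
#' decomposition layer:
#' \deqn{\hat\omega = \mathrm{sgn}(\omega)\,\frac{|\omega|}{2}\,
#'   \left[\tanh\!\big(\alpha(|\omega| - \lambda)\big) + 1\right].}
#' The bracket lies in \[0, 2\], so \eqn{|\hat\omega| \le |\omega|}
#' (shrinkage) for every alpha and lambda. At \eqn{|\omega| = \lambda} the
#' output is exactly \eqn{\omega/2} for any alpha; as alpha grows the rule
#' converges to hard thresholding, while small alpha gives a smooth,
#' soft-like transition that suppresses pseudo-Gibbs ringing.
#'
#' @param w Numeric vector of wavelet coefficients (all finite).
#' @param threshold Threshold lambda >= 0. Alternatively pass a
#'   [layer_rule()] and omit `tuning`.
#' @param tuning Tuning factor alpha >= 0.
#' @return Numeric vector of shrunken coefficients, same length as `w`.
#' @examples
#' aldtf_threshold(c(-2, 0, 2), threshold = 1, tuning = 1)
#' @seealso [soft_threshold()], [hard_threshold()]
#' @export
aldtf_threshold <- function(w, threshold, tuning) {
  if (inherits(threshold, "layer_rule")) {
    rule <- threshold
    threshold <- rule$threshold
    tuning <- rule$tuning
  }
  w <- as.numeric(w)
  if (!all(is.finite(w))) stop("coefficients must all be finite", call. = FALSE)
  if (!is.finite(threshold) || threshold < 0) {
    stop("threshold must be a finite non-negative number", call. = FALSE)
  }
  if (!is.finite(tuning) || tuning < 0) {
    stop("tuning must be a finite non-negative number", call. = FALSE)
  }
  sign(w) * (abs(w) / 2) * (tanh(tuning * (abs(w) - threshold)) + 1)
}

#' Soft thresholding
#'
#' Classical soft shrinkage: \eqn{\hat\omega = \mathrm{sgn}(\omega)
#' \max(|\omega| - \lambda, 0)}. Continuous but biased; used here as a
#' baseline denoiser.
#'
#' @inheritParams aldtf_threshold
#' @return Numeric vector, same length as `w`.
#' @export
soft_threshold <- function(w, threshold) {
  w <- as.numeric(w)
  if (!all(is.finite(w))) stop("coefficients must all be finite", call. = FALSE)
  if (!is.finite(threshold) || threshold < 0) {
    stop("threshold must be a finite non-negative number", call. = FALSE)
  }
  sign(w) * pmax(abs(w) - threshold, 0)
}

#' Hard thresholding
#'
#' Classical hard rule: coefficients with \eqn{|\omega| > \lambda} are kept
#' unchanged, the rest are zeroed (the boundary \eqn{|\omega| = \lambda} is
#' zeroed). Unbiased for survivors but discontinuous, which can cause
#' pseudo-Gibbs oscillations in the reconstruction.
#'
#' @inheritParams aldtf_threshold
#' @return Numeric vector, same length as `w`.
#' @export
hard_threshold <- function(w, threshold) {
  w <- as.numeric(w)
  if (!all(is.finite(w))) stop("coefficients must all be finite", call. = FALSE)
  if (!is.finite(threshold) || threshold < 0) {
    stop("threshold must be a finite non-negative number", call. = FALSE)
  }
  w * (abs(w) > threshold)
}
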