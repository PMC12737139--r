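#' Uniformly sampled single-channel signal
#'
#' Light-weight container for a real-valued, uniformly sampled signal: the
#' sample vector, the sampling rate in Hz, and a free-text label. All
#' denoising, metric and generator functions in the package consume and
#' produce this class (plain numeric vectors are accepted where a sampling
#' rate is not needed and are coerced internally).
#'
#' @param samples Numeric vector of at least 2 finite samples.
#' @param fs Sampling rate in Hz (> 0).
#' @param label Optional free-text description.
#'
#' @return An object of class `sampled_signal`: a list with elements
#'   `samples`, `fs`, `label`.
#' @examples
#' s <- sampled_signal(sin(2 * pi * 2 * (0:999) / 250), fs = 250)
#' s
#' @export
sampled_signal <- function(samples, fs, label = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    stop("a sampled_signal needs at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    bad <- which(!is.finite(samples))[1L]
    stop(sprintf("non-finite sample at position %d", bad), call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number (Hz)", call. = FALSE)
  }
  structure(
    list(samples = samples, fs = as.numeric(fs), label = as.character(label)[1L]),
    class = "sampled_signal"
  )
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf(
    "<sampled_signal> %d samples @ %g Hz (%.3f s)%s\n",
    length(x$samples), x$fs, length(x$samples) / x$fs,
    if (nzchar(x$label)) paste0(" - ", x$label) else ""
  ))
  invisible(x)
}

#' @export
length.sampled_signal <- function(x) length(x$samples)

# Accept either a sampled_signal or a bare numeric vector (with fs supplied
# by the caller when required); returns a sampled_signal.
as_sampled_signal <- function(x, fs = NULL, label = "") {
  if (inherits(x, "sampled_signal")) return(x)
  if (is.numeric(x)) {
    if (is.null(fs)) {
      stop("a plain numeric vector needs an explicit sampling rate", call. = FALSE)
    }
    return(sampled_signal(x, fs = fs, label = label))
  }
  stop("expected a sampled_signal or numeric vector", call. = FALSE)
}

# numeric payload of either representation
signal_samples <- function(x) {
  if (inherits(x, "sampled_signal")) x$samples else as.numeric(x)
}
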