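#' Binary-interpolation search for a tuning factor
#'
#' Derivative-free maximization of a (typically unimodal) objective on a
#' closed interval. Each iteration evaluates the objective at five points —
#' the interval ends, the midpoint, and the two quarter points — and
#' contracts the interval around the best point's bracket:
#'
#' * best at `start` or `left` (maximizer in the left half): keep
#'   `[start, mid]`
#' * best at `right` or `end` (maximizer in the right half): keep
#'   `[mid, end]`
#' * best at `mid` (maximizer in the central bracket): keep `[left, right]`
#'
#' For a unimodal objective the maximizer always lies between the
#' neighbours of the best evaluated point, so every contraction keeps it
#' inside the interval; each branch halves the width, and the loop
#' terminates in at most `ceil(log2((upper - lower)/tol))` iterations. Ties
#' go to the earliest listed branch. Objective values are cached by
#' abscissa, so repeated endpoints cost nothing across iterations.
#'
#' @param objective Function of one numeric argument returning a finite
#'   scalar.
#' @param lower,upper Search interval, `lower < upper`.
#' @param tol Termination width (default `1e-6`).
#' @return List with `alpha_opt` (= final interval midpoint),
#'   `objective_opt` (objective at `alpha_opt`), `trace` (a `search_trace`:
#'   data frame of per-iteration abscissae and objective values, plus
#'   attributes `final_alpha`, `final_objective`, `n_evaluations`), and
#'   `best_observed` (max objective over every point evaluated).
#' @examples
#' r <- optimize_tuning_factor(function(a) -(a - 0.3)^2, 0, 1)
#' r$alpha_opt
#' @export
optimize_tuning_factor <- function(objective, lower, upper, tol = 1e-6) {
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper) {
    stop("need finite lower < upper", call. = FALSE)
  }
  if (!is.finite(tol) || tol <= 0) stop("tol must be positive", call. = FALSE)

  cache <- new.env(parent = emptyenv())
  n_evals <- 0L
  f <- function(a) {
    key <- sprintf("%.17g", a)
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- objective(a)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("objective returned a non-finite value at alpha = %.10g", a),
           call. = FALSE)
    }
    n_evals <<- n_evals + 1L
    cache[[key]] <- v
    v
  }

  a_start <- lower
  a_end <- upper
  rows <- list()
  while (a_end - a_start > tol) {
    a_mid <- (a_start + a_end) / 2
    a_left <- (a_start + a_mid) / 2
    a_right <- (a_mid + a_end) / 2
    vals <- c(
      start = f(a_start), left = f(a_left), mid = f(a_mid),
      right = f(a_right), end = f(a_end)
    )
    best <- names(vals)[which.max(vals)] # first max on ties
    rows[[length(rows) + 1L]] <- data.frame(
      alpha_start = a_start, alpha_left = a_left, alpha_mid = a_mid,
      alpha_right = a_right, alpha_end = a_end,
      n_start = vals[["start"]], n_left = vals[["left"]], n_mid = vals[["mid"]],
      n_right = vals[["right"]], n_end = vals[["end"]],
      best_point = best
    )
    if (best %in% c("start", "left")) {
      a_end <- a_mid
    } else if (best %in% c("right", "end")) {
      a_start <- a_mid
    } else { # best == "mid"
      a_start <- a_left
      a_end <- a_right
    }
  }
  alpha_opt <- (a_start + a_end) / 2
  obj_opt <- f(alpha_opt)
  trace <- if (length(rows)) do.call(rbind, rows) else data.frame()
  best_observed <- max(vapply(ls(cache), function(k) cache[[k]], numeric(1)))
  attr(trace, "final_alpha") <- alpha_opt
  attr(trace, "final_objective") <- best_observed
  attr(trace, "n_evaluations") <- n_evals
  class(trace) <- c("search_trace", class(trace))
  list(
    alpha_opt = alpha_opt,
    objective_opt = obj_opt,
    trace = trace,
    best_observed = best_observed
  )
}

#' @export
print.search_trace <- function(x, ...) {
  cat(sprintf(
    "<search_trace> %d iteration(s), %d objective evaluation(s), final alpha = %.8g, best objective = %.8g\n",
    nrow(x), attr(x, "n_evaluations"), attr(x, "final_alpha"),
    attr(x, "final_objective")
  ))
  invisible(x)
}
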