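# CSV / JSON input-output. CSV is the interchange format: either a single
# numeric column of samples (sampling rate supplied by the caller) or two
# columns (time, value) from which the rate is inferred.

#' Read a sampled signal from CSV
#'
#' Accepts a one-column CSV (samples; `fs_override` required) or a
#' two-column CSV (time in seconds, value; the sampling rate is inferred
#' from the median time step and the steps must be uniform to within 0.1%).
#' A header row is detected automatically. Non-numeric or non-finite rows
#' are rejected with their line number.
#'
#' @param path CSV file path.
#' @param fs_override Sampling rate in Hz; required for one-column files,
#'   overrides the inferred rate for two-column files.
#' @return A [sampled_signal()].
#' @export
read_signal <- function(path, fs_override = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  has_header <- !all(grepl("^[-+0-9.eE, \t]*$", first))
  df <- utils::read.csv(path, header = has_header,
                        colClasses = NA, stringsAsFactors = FALSE)
  offset <- if (has_header) 1L else 0L
  if (ncol(df) < 1L || ncol(df) > 2L) {
    stop(sprintf("expected 1 or 2 columns, found %d", ncol(df)), call. = FALSE)
  }
  for (cn in seq_len(ncol(df))) {
    col <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(!is.finite(col))
    if (length(bad)) {
      stop(sprintf("non-numeric or non-finite value at line %d, column %d",
                   bad[1L] + offset, cn), call. = FALSE)
    }
    df[[cn]] <- col
  }
  if (ncol(df) == 1L) {
    if (is.null(fs_override)) {
      stop("one-column CSV: a sampling rate (fs_override) is required",
           call. = FALSE)
    }
    return(sampled_signal(df[[1L]], fs_override, label = basename(path)))
  }
  tm <- df[[1L]]
  steps <- diff(tm)
  if (any(steps <= 0)) {
    stop(sprintf("non-increasing time at line %d",
                 which(steps <= 0)[1L] + 1L + offset), call. = FALSE)
  }
  med <- stats::median(steps)
  if (max(abs(steps - med)) > 0.001 * med) {
    stop(sprintf("non-uniform sampling (>0.1%% jitter) near line %d",
                 which.max(abs(steps - med)) + 1L + offset), call. = FALSE)
  }
  fs <- if (!is.null(fs_override)) fs_override else 1 / med
  sampled_signal(df[[2L]], fs, label = basename(path))
}

#' Write a sampled signal to CSV
#'
#' Two columns (`time`, `value`), so the sampling rate survives a
#' round-trip through [read_signal()].
#'
#' @param signal A [sampled_signal()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_signal <- function(signal, path) {
  stopifnot(inherits(signal, "sampled_signal"))
  n <- length(signal$samples)
  df <- data.frame(
    time = (seq_len(n) - 1L) / signal$fs,
    value = signal$samples
  )
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

report_version <- function() {
  as.character(utils::packageVersion("aldtf"))
}

trace_to_list <- function(tr) {
  if (is.null(tr)) return(NULL)
  list(
    iterations = as.data.frame(tr)[
      , c("alpha_start", "alpha_left", "alpha_mid", "alpha_right", "alpha_end",
          "n_start", "n_left", "n_mid", "n_right", "n_end", "best_point")
    ],
    final_alpha = attr(tr, "final_alpha"),
    final_objective = attr(tr, "final_objective"),
    n_evaluations = attr(tr, "n_evaluations")
  )
}

#' Write a denoising result to disk
#'
#' Produces `<prefix>.csv` (the denoised waveform, time/value columns) and
#' `<prefix>.report.json` (schema-versioned report: per-layer thresholds and
#' tuning factors, periodicity objective before/after, search traces,
#' configuration echo, tool version).
#'
#' @param result A `denoise_result` from [aldtf_denoise()] or
#'   [baseline_denoise()].
#' @param out_prefix Output path prefix.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_result <- function(result, out_prefix) {
  stopifnot(inherits(result, "denoise_result"))
  csv_path <- paste0(out_prefix, ".csv")
  json_path <- paste0(out_prefix, ".report.json")
  write_signal(result$output, csv_path)
  cfg <- result$config_echo
  report <- list(
    schema_version = 1L,
    tool = "aldtf",
    tool_version = report_version(),
    method = result$method,
    config = list(
      wavelet = cfg$wavelet, levels = cfg$levels,
      threshold_method = cfg$threshold_method,
      min_period_s = cfg$min_period_s, tolerance = cfg$tolerance,
      passes = cfg$passes, seed = cfg$seed
    ),
    fs = result$output$fs,
    n_samples = length(result$output$samples),
    rules = lapply(result$rules, function(r) {
      list(level = r$level, threshold = r$threshold, tuning = r$tuning)
    }),
    nzopp_in = result$nzopp_in,
    nzopp_out = result$nzopp_out,
    n_objective_evals = result$n_objective_evals,
    alpha_increases_with_depth = result$alpha_increases_with_depth,
    traces = lapply(result$traces, trace_to_list),
    threshold_traces = lapply(result$threshold_traces, trace_to_list)
  )
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(csv_path, json_path))
}
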