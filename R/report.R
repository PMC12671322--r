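#' Run detection on a recording and produce the app-style report
#'
#' Mirrors the monitoring-app output for one EEG file: file metadata
#' (channel count, sampling frequency, duration), elapsed processing time,
#' the number of seizure events detected per channel, the total number of
#' seizure epochs, the event list and a parameter echo.
#'
#' @param input a [recording()] or a path to an EDF file.
#' @param model a `seizure_model` or a path to a saved model artifact.
#' @param epoch_len_s epoch length in seconds (default 10).
#' @param window_epochs AMFBC window in epochs (default 60); `NA` disables
#'   baseline correction.
#' @param taps,theta postprocessing parameters (defaults 10 and 0.5).
#' @return An object of class `detection_report` (a list; see
#'   [write_report()] for serialization).
#' @export
detect_report <- function(input, model, epoch_len_s = 10, window_epochs = 60L,
                          taps = 10L, theta = 0.5) {
  rec <- if (inherits(input, "recording")) input else read_edf(input)
  if (is.character(model)) model <- load_model(model)
  det <- run_pipeline(rec, model, epoch_len_s, window_epochs, taps, theta)
  rep <- det$report
  rep$model <- list(version = model$version,
                    databases = model$metadata$databases)
  structure(rep, class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.detection_report <- function(x, ...) {
  lines <- c(
    "==== Seizure detection report ====",
    sprintf("Channels            : %d", x$n_channels),
    sprintf("Sampling frequency  : %g Hz", x$fs),
    sprintf("Duration            : %.1f s (%s)", x$duration_s, x$duration_hms),
    sprintf("Epoch length        : %g s (%d epochs)", x$epoch_len_s, x$n_epochs),
    sprintf("Elapsed time        : %.3f s", x$elapsed_s),
    sprintf("Total seizure epochs: %d", x$total_seizure_epochs),
    "Seizure events per channel:")
  for (ch in names(x$events_per_channel))
    lines <- c(lines, sprintf("  %-10s %d", ch, x$events_per_channel[[ch]]))
  if (nrow(x$events)) {
    lines <- c(lines, "Events:")
    for (i in seq_len(nrow(x$events)))
      lines <- c(lines, sprintf("  %-10s %8.1f - %8.1f s",
                                x$events$channel[i], x$events$start_s[i],
                                x$events$end_s[i]))
  }
  c(lines, sprintf("Parameters: taps=%d threshold=%g baseline_window=%s",
                   x$parameters$taps, x$parameters$threshold,
                   as.character(x$parameters$baseline_window)))
}

#' Serialize a detection report to JSON
#'
#' @param report a `detection_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "detection_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
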