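#' Epoch-level sensitivity and specificity
#'
#' Standard confusion-matrix rates over (epoch, channel) cells:
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`. When a
#' class is absent from the truth (e.g. a seizure-free file), the
#' corresponding rate is undefined and reported as `NA` — never silently
#' 0 or 1.
#'
#' @param pred,truth 0/1 matrices (or vectors) of equal shape.
#' @return List with `sensitivity`, `specificity` and `counts`
#'   (`tp`, `fn`, `tn`, `fp`).
#' @export
epoch_metrics <- function(pred, truth) {
  if (!all(dim(as.matrix(pred)) == dim(as.matrix(truth))))
    stop("prediction and truth shapes differ")
  p <- as.vector(pred); t <- as.vector(truth)
  if (!all(p %in% c(0, 1)) || !all(t %in% c(0, 1)))
    stop("labels must be binary (0/1)")
  tp <- sum(p == 1 & t == 1); fn <- sum(p == 0 & t == 1)
  tn <- sum(p == 0 & t == 0); fp <- sum(p == 1 & t == 0)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       counts = list(tp = tp, fn = fn, tn = tn, fp = fp))
}

#' Event-level false detection rate per hour
#'
#' A predicted event is TRUE when it overlaps any ground-truth interval by
#' at least `min_overlap_s` seconds on the same channel (channel-less
#' truth matches every channel). Several predicted events overlapping the
#' same truth interval each count as TRUE (no one-to-one matching).
#' `fdr_per_hour = false events / duration_h`.
#'
#' @param pred_events event data frame (`start_s`, `end_s`, `channel`).
#' @param truth_intervals a [seizure_intervals()] data frame.
#' @param duration_h recording duration in hours (> 0).
#' @param min_overlap_s minimum overlap in seconds (default 1).
#' @return List with `fdr_per_hour`, `true_events`, `false_events`.
#' @export
event_fdr <- function(pred_events, truth_intervals, duration_h,
                      min_overlap_s = 1) {
  if (!is.numeric(duration_h) || length(duration_h) != 1L || duration_h <= 0)
    stop("`duration_h` must be positive")
  if (is.null(pred_events) || nrow(pred_events) == 0L)
    return(list(fdr_per_hour = 0, true_events = 0L, false_events = 0L))
  n_true <- 0L
  for (i in seq_len(nrow(pred_events))) {
    hit <- FALSE
    if (!is.null(truth_intervals) && nrow(truth_intervals) > 0L) {
      for (j in seq_len(nrow(truth_intervals))) {
        same_channel <- is.na(truth_intervals$channel[j]) ||
          is.na(pred_events$channel[i]) ||
          truth_intervals$channel[j] == pred_events$channel[i]
        if (!same_channel) next
        ov <- min(pred_events$end_s[i], truth_intervals$end_s[j]) -
              max(pred_events$start_s[i], truth_intervals$start_s[j])
        if (ov >= min_overlap_s) { hit <- TRUE; break }
      }
    }
    n_true <- n_true + hit
  }
  n_false <- nrow(pred_events) - n_true
  list(fdr_per_hour = n_false / duration_h,
       true_events = as.integer(n_true), false_events = as.integer(n_false))
}

#' Run the full detection pipeline on a recording and score it
#'
#' Chains epoching, feature extraction, adaptive median baseline
#' correction, per-epoch classification, moving-average postprocessing and
#' event formation, then scores the result against the recording's
#' ground-truth annotations. Epoch-level sensitivity/specificity use the
#' raw per-epoch predictions; the event FDR uses the post-threshold
#' events.
#'
#' @param rec a [recording()] with ground-truth annotations.
#' @param model a `seizure_model`.
#' @param epoch_len_s epoch length in seconds (default 10).
#' @param window_epochs AMFBC window in epochs (default 60); `NA` disables.
#' @param taps,theta postprocessing parameters.
#' @return List with `metrics` (sensitivity, specificity, fdr_per_hour,
#'   counts, duration_h), `events` and `report` (a detection report, see
#'   [detect_report()]).
#' @export
evaluate_recording <- function(rec, model, epoch_len_s = 10,
                               window_epochs = 60L, taps = 10L, theta = 0.5) {
  stopifnot(inherits(rec, "recording"))
  det <- run_pipeline(rec, model, epoch_len_s, window_epochs, taps, theta)
  truth <- label_epochs(det$features, rec$annotations, fs = rec$fs)
  em <- epoch_metrics(det$pred, truth)
  fdr <- event_fdr(det$events, rec$annotations, rec$duration_s / 3600)
  list(metrics = list(sensitivity = em$sensitivity,
                      specificity = em$specificity,
                      fdr_per_hour = fdr$fdr_per_hour,
                      counts = c(em$counts, fdr[c("true_events", "false_events")]),
                      duration_h = rec$duration_s / 3600),
       events = det$events,
       report = det$report)
}

# shared pipeline core: recording -> features -> AMFBC -> predict ->
# postprocess -> events + report fields
run_pipeline <- function(rec, model, epoch_len_s, window_epochs, taps, theta) {
  t0 <- proc.time()[["elapsed"]]
  es <- segment_epochs(rec, epoch_len_s)
  fm <- extract_features(es)
  fmc <- if (!is.na(window_epochs)) baseline_correct(fm, window_epochs) else fm
  pred <- predict_epochs(model, fmc)
  events <- list(); pos <- matrix(0L, nrow(pred), ncol(pred))
  for (c in seq_along(fm$channel_labels)) {
    y <- moving_average(pred[, c], taps)
    pos[, c] <- as.integer(y >= theta)
    events[[c]] <- threshold_events(y, theta, epoch_len_s, fm$epoch_start_s,
                                    fm$channel_labels[c])
  }
  events <- do.call(rbind, events)
  summ <- detection_summary(events, pos, fm$channel_labels)
  elapsed <- proc.time()[["elapsed"]] - t0
  report <- list(
    n_channels = nrow(rec$data),
    fs = rec$fs,
    duration_s = rec$duration_s,
    duration_hms = format_hms(rec$duration_s),
    elapsed_s = round(elapsed, 3),
    epoch_len_s = epoch_len_s,
    n_epochs = length(fm$epoch_start_s),
    events_per_channel = as.list(summ$events_per_channel),
    total_seizure_epochs = summ$total_seizure_epochs,
    events = events,
    parameters = list(taps = taps, threshold = theta,
                      baseline_window = window_epochs))
  list(features = fmc, pred = pred, events = events, report = report)
}
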