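#' Causal moving-average smoothing of classifier output
#'
#' `y(t) = mean(labels[(t - taps + 1):t])` with the pre-recording history
#' taken as zero — a streaming-friendly causal filter with no look-ahead,
#' matching sequential processing of a recording. With the default 10
#' taps, an isolated positive epoch reaches at most `y = 0.1`, so the
#' subsequent 0.5 threshold discards it: this is the mechanism that
#' suppresses isolated false detections.
#'
#' @param labels numeric/integer vector of 0/1 per-epoch labels.
#' @param taps filter length in epochs (>= 1, default 10).
#' @return Numeric vector in `[0, 1]`, same length as `labels`.
#' @export
moving_average <- function(labels, taps = 10L) {
  taps <- as.integer(taps)
  if (is.na(taps) || taps < 1L) stop("`taps` must be >= 1")
  if (length(labels) == 0L) return(numeric(0))
  if (!all(labels %in% c(0, 1))) stop("labels must be binary (0/1)")
  cs <- cumsum(c(rep(0, taps), labels))
  n <- length(labels)
  (cs[(taps + 1L):(taps + n)] - cs[1L:n]) / taps
}

#' Form seizure events from smoothed classifier output
#'
#' Epochs with smoothed value `>= theta` are positive; each maximal run of
#' positive epochs becomes one event spanning
#' `[first_epoch_start, last_epoch_start + epoch_len_s)`. Runs separated
#' by up to `merge_gap_epochs` negative epochs can optionally be merged
#' (default 0: any gap ends an event).
#'
#' @param smoothed numeric vector in `[0, 1]` (from [moving_average()]).
#' @param theta detection threshold in `(0, 1]` (default 0.5: a majority
#'   of the last `taps` epochs must be positive).
#' @param epoch_len_s epoch length in seconds.
#' @param epoch_start_s per-epoch start times (default regular grid).
#' @param channel channel label attached to the events.
#' @param merge_gap_epochs merge events separated by gaps of at most this
#'   many epochs (default 0).
#' @return A [seizure_intervals()]-shaped data frame of events.
#' @export
threshold_events <- function(smoothed, theta = 0.5, epoch_len_s = 10,
                             epoch_start_s = NULL, channel = NA_character_,
                             merge_gap_epochs = 0L) {
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta > 1)
    stop("`theta` must lie in (0, 1]")
  if (length(smoothed) == 0L) return(seizure_intervals())
  if (any(smoothed < -1e-12) || any(smoothed > 1 + 1e-12))
    stop("smoothed values must lie in [0, 1]")
  if (is.null(epoch_start_s))
    epoch_start_s <- (seq_along(smoothed) - 1L) * epoch_len_s
  pos <- smoothed >= theta
  if (merge_gap_epochs > 0L) {
    r <- rle(pos)
    ends <- cumsum(r$lengths)
    fill <- which(!r$values & r$lengths <= merge_gap_epochs)
    fill <- fill[fill > 1L & fill < length(r$values)]  # interior gaps only
    for (g in fill)
      pos[(ends[g] - r$lengths[g] + 1L):ends[g]] <- TRUE
  }
  r <- rle(pos)
  ends <- cumsum(r$lengths); begins <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep)) return(seizure_intervals())
  seizure_intervals(epoch_start_s[begins[keep]],
                    epoch_start_s[ends[keep]] + epoch_len_s,
                    channel)
}

#' Summarize detections into report counts
#'
#' @param events event data frame (rows from [threshold_events()], possibly
#'   several channels).
#' @param positive_epochs epoch x channel 0/1 matrix of post-threshold
#'   positives (or a per-channel list of binary vectors).
#' @param channel_labels channel labels for the per-channel counts.
#' @return List with `events_per_channel` (named integer vector) and
#'   `total_seizure_epochs` (post-threshold positives summed over
#'   channels).
#' @export
detection_summary <- function(events, positive_epochs, channel_labels) {
  if (is.list(positive_epochs) && !is.matrix(positive_epochs))
    positive_epochs <- do.call(cbind, positive_epochs)
  per_channel <- vapply(channel_labels, function(ch)
    sum(!is.na(events$channel) & events$channel == ch), integer(1))
  list(events_per_channel = per_channel,
       total_seizure_epochs = as.integer(sum(positive_epochs)))
}
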