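#' Adaptive median feature baseline correction (AMFBC)
#'
#' EEG feature distributions shift between recording databases (different
#' hardware gains, references and montages add per-database offsets in
#' feature space). AMFBC removes these by subtracting, per channel and per
#' feature, the exact median of a rolling window of the last `W` raw epoch
#' features. The median's 50% breakdown point keeps rare seizure epochs
#' from dragging the baseline, so no seizure/non-seizure gating is needed.
#'
#' `baseline_init()` seeds the rolling buffers with up to the first `W`
#' epochs of a feature matrix; `baseline_step()` corrects one epoch against
#' the current median and then pushes its raw values into the buffer
#' (correction always uses the median from *before* the push);
#' `baseline_correct()` applies the whole causal scheme over a feature
#' matrix. Epochs inside the seed window are corrected against the seeded
#' median (cold start: the first epochs are both seed and corrected data).
#' The even-count median is the mean of the two middle values.
#'
#' @param fm a `feature_matrix` from [extract_features()].
#' @param window_epochs rolling window length `W` in epochs (>= 1).
#'   Default 60 (10 minutes of 10 s epochs): long enough that a typical
#'   seizure never fills half the window, short enough to adapt within a
#'   recording.
#' @return `baseline_init()`: a `baseline_state`. `baseline_correct()`: a
#'   `feature_matrix` of corrected values with the same shape.
#' @name amfbc
NULL

#' @rdname amfbc
#' @export
baseline_init <- function(fm, window_epochs = 60L) {
  stopifnot(inherits(fm, "feature_matrix"))
  W <- as.integer(window_epochs)
  if (is.na(W) || W < 1L) stop("`window_epochs` must be >= 1")
  d <- dim(fm$values)
  if (d[1L] < 1L) stop("feature matrix has no epochs")
  state <- structure(
    list(window_epochs = W,
         buffer = array(NA_real_, dim = c(W, d[2L], d[3L])),
         n = 0L, pos = 0L,
         current_median = matrix(NA_real_, d[2L], d[3L])),
    class = "baseline_state")
  for (e in seq_len(min(W, d[1L])))
    state <- baseline_push(state, fm$values[e, , , drop = FALSE])
  state
}

baseline_push <- function(state, raw) {
  W <- state$window_epochs
  state$pos <- (state$pos %% W) + 1L
  state$buffer[state$pos, , ] <- raw
  state$n <- min(state$n + 1L, W)
  nc <- dim(state$buffer)[2L]; nf <- dim(state$buffer)[3L]
  for (c in seq_len(nc))
    for (f in seq_len(nf))
      state$current_median[c, f] <-
        stats::median(state$buffer[seq_len(state$n), c, f])
  state
}

#' @rdname amfbc
#' @param raw channel x feature matrix of one epoch's raw feature values.
#' @param state a `baseline_state`.
#' @return `baseline_step()`: list with `corrected` (channel x feature
#'   matrix) and `state` (updated).
#' @export
baseline_step <- function(raw, state) {
  stopifnot(inherits(state, "baseline_state"))
  raw <- as.matrix(raw)
  if (!all(dim(raw) == dim(state$current_median)))
    stop("channel/feature dimensions do not match the baseline state")
  if (any(!is.finite(raw))) stop("raw feature values must be finite")
  corrected <- raw - state$current_median
  state <- baseline_push(state, raw)
  list(corrected = corrected, state = state)
}

#' @rdname amfbc
#' @details
#' `baseline_correct()` block-seeds the buffer with the first
#' `min(W, n_epochs)` epochs and corrects those warm-up epochs against
#' the seeded median (so a single-epoch input corrects to exactly zero);
#' from epoch `W + 1` on it streams causally, correcting each epoch with
#' the pre-push median exactly as `baseline_step()` does. Block seeding
#' matters for robustness: correcting warm-up epochs against a median of
#' only the epochs seen so far would let a seizure that starts early in
#' the recording dominate the young buffer and cancel itself out. The
#' price is that warm-up corrections are not causal; from epoch `W + 1`
#' onward the corrected value never depends on later epochs. Correction
#' is invariant at every epoch to a constant offset added to all epochs.
#' @export
baseline_correct <- function(fm, window_epochs = 60L) {
  stopifnot(inherits(fm, "feature_matrix"))
  state <- baseline_init(fm, window_epochs)
  d <- dim(fm$values)
  seed_n <- min(state$window_epochs, d[1L])
  out <- fm$values
  for (e in seq_len(seed_n))
    out[e, , ] <- fm$values[e, , ] - state$current_median
  if (d[1L] > seed_n) {
    for (e in (seed_n + 1L):d[1L]) {
      step <- baseline_step(matrix(fm$values[e, , ], d[2L], d[3L]), state)
      out[e, , ] <- step$corrected
      state <- step$state
    }
  }
  res <- fm
  res$values <- out
  res
}
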