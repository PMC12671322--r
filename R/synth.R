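#' Configuration for the multi-database synthetic EEG generator
#'
#' The generator emulates the setting a cross-database seizure detector
#' must survive: several "databases" (recording sites) that differ in
#' sampling rate, channel count and global affine amplitude idiosyncrasies
#' (per-database gain and DC offset), each containing long background EEG
#' with planted high-amplitude rhythmic seizure discharges and exact
#' ground-truth intervals.
#'
#' Background is 1/f-shaped Gaussian noise plus intermittent alpha (10 Hz)
#' bursts. A seizure is a 3-5 Hz rhythmic discharge with a second harmonic
#' at half amplitude and linear 2 s onset/offset ramps, superimposed on
#' the affected channels. Database variation is purely affine — the
#' minimal structure the adaptive median baseline correction claims to
#' fix. Defaults reflect a desk-scale cross-database experiment: 3
#' databases of 30 minutes each with seizure amplitude 3x the background
#' RMS and inter-database gains/offsets large enough to dominate the
#' feature-space class gap.
#'
#' @param n_databases number of simulated databases.
#' @param fs per-database sampling rates in Hz (>= 64; recycled).
#' @param n_channels per-database channel counts (recycled).
#' @param gain per-database multiplicative gains (recycled). Gains are
#'   kept >= 1 by default: both features log-compress amplitude, so a
#'   gain >> 1 shifts them nearly additively, whereas a gain << 1 crushes
#'   the class gap itself instead of shifting it.
#' @param offset_uv per-database additive DC offsets in microvolts.
#' @param duration_s recording duration in seconds (>= 10).
#' @param n_recordings recordings per database.
#' @param n_seizures seizures planted per recording.
#' @param seizure_duration_range_s min/max seizure duration in seconds.
#' @param affected_fraction fraction of channels a seizure affects
#'   (at least one channel; 1 = generalized seizures).
#' @param min_gap_s minimum gap between consecutive seizures in seconds.
#'   The default (360 s) emulates the sparsity of seizures in long-term
#'   EEG and keeps any adaptive-baseline window under 50% seizure, the
#'   rolling median's breakdown point.
#' @param background_rms_uv background RMS amplitude in microvolts.
#' @param one_over_f_exponent spectral exponent of the 1/f background.
#' @param alpha_burst_rate_per_min rate of 1-3 s alpha (10 Hz) bursts.
#' @param seizure_freq_range_hz dominant seizure frequency range in Hz.
#' @param amplitude_ratio RMS of the seizure discharge as a multiple of
#'   the channel's background RMS (> 1). RMS-based scaling (rather than
#'   peak amplitude) makes the in-seizure/out-of-seizure RMS contrast
#'   `sqrt(1 + amplitude_ratio^2)` by construction, independent of the
#'   harmonic content of the discharge.
#' @param seed mandatory integer RNG seed (< 2^31).
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_databases = 3L,
                         fs = c(256, 128, 64),
                         n_channels = 8L,
                         gain = c(1, 12, 90),
                         offset_uv = c(0, 200, -300),
                         duration_s = 1800,
                         n_recordings = 1L,
                         n_seizures = 4L,
                         seizure_duration_range_s = c(120, 180),
                         min_gap_s = 360,
                         affected_fraction = 1,
                         background_rms_uv = 30,
                         one_over_f_exponent = 1,
                         alpha_burst_rate_per_min = 2,
                         seizure_freq_range_hz = c(3, 5),
                         amplitude_ratio = 3,
                         seed = NULL) {
  if (is.null(seed)) stop("`seed` is mandatory for reproducible generation")
  seed <- as.integer(seed)
  n_databases <- as.integer(n_databases)
  if (n_databases < 1L) stop("need at least one database")
  fs <- rep_len(fs, n_databases)
  n_channels <- rep_len(as.integer(n_channels), n_databases)
  gain <- rep_len(gain, n_databases)
  offset_uv <- rep_len(offset_uv, n_databases)
  if (any(fs < 64)) stop("sampling rates must be >= 64 Hz")
  if (any(fs != round(fs))) stop("sampling rates must be integer Hz")
  if (any(n_channels < 1L)) stop("need at least one channel")
  if (duration_s < 10) stop("duration must cover at least one epoch (10 s)")
  if (duration_s != round(duration_s)) stop("duration must be whole seconds")
  if (amplitude_ratio <= 1) stop("`amplitude_ratio` must exceed 1")
  if (affected_fraction <= 0 || affected_fraction > 1)
    stop("`affected_fraction` must lie in (0, 1]")
  if (length(seizure_duration_range_s) != 2L ||
      seizure_duration_range_s[1] > seizure_duration_range_s[2] ||
      seizure_duration_range_s[1] <= 0)
    stop("invalid `seizure_duration_range_s`")
  if (min_gap_s < 0) stop("`min_gap_s` must be non-negative")
  if (length(seizure_freq_range_hz) != 2L ||
      any(seizure_freq_range_hz < 0.5))
    stop("invalid `seizure_freq_range_hz`")
  structure(as.list(environment()), class = "synth_config")
}

# deterministic per-recording seed below 2^31
recording_seed <- function(seed, database_index, record_index) {
  (as.double(seed) * 48271 + database_index * 100003 + record_index * 101) %%
    2147483647
}

one_over_f_noise <- function(n, exponent, fs) {
  w <- stats::rnorm(n)
  spec <- stats::fft(w)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f)            # two-sided frequency index
  shape <- c(0, (f[-1] * fs / n)^(-exponent / 2))
  x <- Re(stats::fft(spec * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate one synthetic EEG recording with planted seizures
#'
#' @param config a [synth_config()].
#' @param database_index which database's sampling rate / channel count /
#'   gain / offset to use (1-based).
#' @param record_index recording number within the database (enters the
#'   per-recording RNG seed, so every recording is distinct yet exactly
#'   reproducible).
#' @return A [recording()] whose annotations exactly match the planted
#'   seizure intervals (channel-specific when a seizure affects a strict
#'   subset of channels).
#' @export
generate_recording <- function(config, database_index = 1L, record_index = 1L) {
  stopifnot(inherits(config, "synth_config"))
  i <- as.integer(database_index)
  if (i < 1L || i > config$n_databases) stop("database_index out of range")
  fs <- config$fs[i]; nc <- config$n_channels[i]
  dur <- config$duration_s
  n <- as.integer(dur * fs)
  set.seed(recording_seed(config$seed, i, as.integer(record_index)))

  b <- config$background_rms_uv
  data <- matrix(0, nc, n)
  tt <- seq_len(n) / fs
  for (c in seq_len(nc)) {
    x <- one_over_f_noise(n, config$one_over_f_exponent, fs) * b
    n_bursts <- round(dur / 60 * config$alpha_burst_rate_per_min)
    for (k in seq_len(n_bursts)) {
      bd <- stats::runif(1, 1, 3)
      bs <- stats::runif(1, 0, dur - bd)
      idx <- which(tt >= bs & tt < bs + bd)
      env <- 0.5 * (1 - cos(2 * pi * seq_along(idx) / length(idx)))
      x[idx] <- x[idx] + b * env * sin(2 * pi * 10 * tt[idx] +
                                       stats::runif(1, 0, 2 * pi))
    }
    data[c, ] <- x
  }

  intervals <- place_seizures(config, dur)
  starts <- intervals$start_s; durs <- intervals$end_s - intervals$start_s
  ann_start <- numeric(0); ann_end <- numeric(0); ann_chan <- character(0)
  labels <- paste0("CH", seq_len(nc))
  # scale the discharge so its RMS is amplitude_ratio times the channel's
  # background RMS; sqrt(0.625) is the RMS of sin + harmonic at half
  # amplitude relative to the fundamental's peak
  bg_rms <- apply(data, 1L, stats::sd)
  A_ch <- config$amplitude_ratio * bg_rms / sqrt(0.625)
  for (k in seq_along(starts)) {
    n_aff <- max(1L, ceiling(config$affected_fraction * nc))
    aff <- sort(sample.int(nc, n_aff))
    f0 <- stats::runif(1, config$seizure_freq_range_hz[1],
                       config$seizure_freq_range_hz[2])
    idx <- which(tt >= starts[k] & tt < starts[k] + durs[k])
    tl <- tt[idx] - starts[k]
    ramp_s <- min(2, durs[k] / 4)
    env <- pmin(1, pmin(tl, durs[k] - tl) / ramp_s)
    for (c in aff) {
      phi <- stats::runif(1, 0, 2 * pi)
      data[c, idx] <- data[c, idx] +
        A_ch[c] * env * (sin(2 * pi * f0 * tl + phi) +
                         0.5 * sin(4 * pi * f0 * tl + 2 * phi))
    }
    if (n_aff == nc) {
      ann_start <- c(ann_start, starts[k]); ann_end <- c(ann_end, starts[k] + durs[k])
      ann_chan <- c(ann_chan, NA_character_)
    } else {
      ann_start <- c(ann_start, rep(starts[k], n_aff))
      ann_end <- c(ann_end, rep(starts[k] + durs[k], n_aff))
      ann_chan <- c(ann_chan, labels[aff])
    }
  }

  data <- config$gain[i] * data + config$offset_uv[i]
  recording(data, fs, labels,
            annotations = seizure_intervals(ann_start, ann_end, ann_chan))
}

# uniform non-overlapping placement with a guard gap between events, via
# the spacings construction: the slack left after durations and guard gaps
# is split uniformly into k+1 inter-event spacings (differences of sorted
# uniforms), giving an exactly uniform feasible layout with no rejection
place_seizures <- function(config, dur) {
  gap_s <- config$min_gap_s
  k <- config$n_seizures
  if (k == 0L) return(seizure_intervals())
  durs <- stats::runif(k, config$seizure_duration_range_s[1],
                       config$seizure_duration_range_s[2])
  slack <- dur - sum(durs) - (k - 1L) * gap_s
  if (slack < 0)
    stop("infeasible seizure packing: ", k, " seizures of up to ",
         config$seizure_duration_range_s[2], " s with ", gap_s,
         " s gaps do not fit in ", dur, " s")
  g <- diff(c(0, sort(stats::runif(k, 0, slack)), slack))[seq_len(k)]
  starts <- numeric(k)
  starts[1L] <- g[1L]
  if (k > 1L)
    for (j in 2L:k)
      starts[j] <- starts[j - 1L] + durs[j - 1L] + gap_s + g[j]
  seizure_intervals(starts, starts + durs)
}

#' Generate a multi-database corpus of synthetic recordings
#'
#' One group of recordings per database, each with that database's
#' sampling rate, channel count, gain and offset. When `out_dir` is given,
#' every recording is written as an EDF file plus a ground-truth sidecar
#' CSV, and a manifest JSON records the file list, database tags, seed and
#' configuration.
#'
#' @param config a [synth_config()].
#' @param out_dir optional output directory (created if missing).
#' @return A list of entries `list(recording, database_id, record_index,
#'   edf = path-or-NULL, truth = path-or-NULL)`.
#' @export
generate_corpus <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  out <- list()
  manifest <- list()
  for (i in seq_len(config$n_databases)) {
    db <- paste0("db", i)
    for (r in seq_len(config$n_recordings)) {
      rec <- generate_recording(config, i, r)
      entry <- list(recording = rec, database_id = db, record_index = r,
                    edf = NULL, truth = NULL)
      if (!is.null(out_dir)) {
        stem <- file.path(out_dir, sprintf("%s_rec%02d", db, r))
        entry$edf <- write_edf(rec, paste0(stem, ".edf"))
        entry$truth <- write_truth_csv(rec$annotations, paste0(stem, "_truth.csv"))
        manifest[[length(manifest) + 1L]] <- list(
          database_id = db, record_index = r,
          edf = basename(entry$edf), truth = basename(entry$truth),
          fs = config$fs[i], n_channels = config$n_channels[i],
          duration_s = config$duration_s)
      }
      out[[length(out) + 1L]] <- entry
    }
  }
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(seed = config$seed, recordings = manifest,
           config = unclass(config)[setdiff(names(config), "seed")]),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Featurize and label a synthetic corpus per database
#'
#' Convenience bridge from [generate_corpus()] to the training /
#' cross-validation layer: extracts features for every recording, labels
#' epochs from the planted ground truth, and concatenates recordings of
#' the same database along the epoch axis (epoch start times continue
#' across recordings).
#'
#' @param corpus output of [generate_corpus()].
#' @param epoch_len_s epoch length in seconds (default 10).
#' @return A list of [labeled_features()], one per database, tagged with
#'   its `database_id`.
#' @export
corpus_features <- function(corpus, epoch_len_s = 10) {
  ids <- vapply(corpus, function(e) e$database_id, character(1))
  lapply(unique(ids), function(db) {
    parts <- corpus[ids == db]
    fms <- list(); labs <- list(); t_off <- 0
    for (e in parts) {
      es <- segment_epochs(e$recording, epoch_len_s)
      fm <- extract_features(es, database_id = db)
      labs[[length(labs) + 1L]] <-
        label_epochs(fm, e$recording$annotations, fs = e$recording$fs)
      fm$epoch_start_s <- fm$epoch_start_s + t_off
      t_off <- t_off + e$recording$duration_s
      fms[[length(fms) + 1L]] <- fm
    }
    merged <- fms[[1L]]
    if (length(fms) > 1L) {
      merged$values <- do.call(abind_epochs, lapply(fms, `[[`, "values"))
      merged$epoch_start_s <- unlist(lapply(fms, `[[`, "epoch_start_s"))
    }
    labeled_features(merged, do.call(rbind, labs))
  })
}

abind_epochs <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1L]])
  total <- sum(vapply(arrs, function(a) dim(a)[1L], numeric(1)))
  out <- array(NA_real_, c(total, d[2L], d[3L]), dimnames = dimnames(arrs[[1L]]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1L]), , ] <- a
    at <- at + dim(a)[1L]
  }
  out
}
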