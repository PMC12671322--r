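#' Construct a multi-channel EEG recording
#'
#' A `recording` bundles a channels-by-samples matrix of microvolt samples
#' with its sampling rate, channel labels and (optionally) ground-truth
#' seizure intervals. It is the in-memory counterpart of one EDF file.
#'
#' @param data numeric matrix, channels x samples, in microvolts. All
#'   channels share the sample count and the sampling rate.
#' @param fs sampling rate in Hz (positive scalar, uniform across channels).
#' @param channel_labels character vector of channel names, one per row of
#'   `data`. Defaults to `"CH1"`, `"CH2"`, ...
#' @param annotations seizure ground truth as returned by
#'   [seizure_intervals()], or `NULL` for none.
#' @return An object of class `recording` with fields `data`, `fs`,
#'   `channel_labels`, `duration_s` and `annotations`.
#' @seealso [read_edf()], [write_edf()], [segment_epochs()]
#' @export
recording <- function(data, fs, channel_labels = NULL, annotations = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric channels x samples matrix")
  if (nrow(data) < 1L || ncol(data) < 1L)
    stop("recording must have at least one channel and one sample")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  if (is.null(channel_labels))
    channel_labels <- paste0("CH", seq_len(nrow(data)))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data))
    stop("one channel label per data row is required")
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique")
  duration_s <- ncol(data) / fs
  annotations <- validate_intervals(annotations, duration_s, channel_labels)
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         duration_s = duration_s, annotations = annotations),
    class = "recording")
}

#' Ground-truth seizure intervals
#'
#' Intervals are half-open `[start_s, end_s)` in seconds from recording
#' start. A missing channel (`NA`) means the seizure applies to all
#' channels (e.g. a generalized seizure).
#'
#' @param start_s,end_s numeric vectors of onset/offset times in seconds,
#'   `0 <= start_s < end_s`.
#' @param channel optional character vector of channel labels (`NA` =
#'   all channels). Recycled to the interval count.
#' @return A data frame with columns `start_s`, `end_s`, `channel`.
#' @export
seizure_intervals <- function(start_s = numeric(), end_s = numeric(),
                              channel = NA_character_) {
  start_s <- as.numeric(start_s); end_s <- as.numeric(end_s)
  if (length(start_s) != length(end_s))
    stop("`start_s` and `end_s` must have equal length")
  if (length(start_s) == 0L)
    return(data.frame(start_s = numeric(), end_s = numeric(),
                      channel = character(), stringsAsFactors = FALSE))
  channel <- rep_len(as.character(channel), length(start_s))
  if (any(!is.finite(start_s)) || any(!is.finite(end_s)))
    stop("interval times must be finite")
  if (any(start_s < 0) || any(start_s >= end_s))
    stop("intervals require 0 <= start_s < end_s")
  df <- data.frame(start_s = start_s, end_s = end_s, channel = channel,
                   stringsAsFactors = FALSE)
  df[order(df$start_s), , drop = FALSE]
}

validate_intervals <- function(ann, duration_s, channel_labels) {
  if (is.null(ann))
    return(seizure_intervals())
  if (!is.data.frame(ann) || !all(c("start_s", "end_s") %in% names(ann)))
    stop("annotations must be a data frame with start_s, end_s[, channel]")
  if (is.null(ann$channel)) ann$channel <- NA_character_
  ann <- seizure_intervals(ann$start_s, ann$end_s, ann$channel)
  if (nrow(ann) && any(ann$end_s > duration_s + 1e-9))
    stop("annotations must lie within [0, duration_s]")
  known <- is.na(ann$channel) | ann$channel %in% channel_labels
  if (!all(known))
    stop("annotation channel not present in recording: ",
         paste(unique(ann$channel[!known]), collapse = ", "))
  ann
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s), %g Hz, %.1f s (%s), %d annotation(s)\n",
              nrow(x$data), x$fs, x$duration_s, format_hms(x$duration_s),
              nrow(x$annotations)))
  invisible(x)
}

format_hms <- function(s) {
  s <- round(s)
  sprintf("%02d:%02d:%02d", s %/% 3600L, (s %% 3600L) %/% 60L, s %% 60L)
}

# ---- EDF / EDF+ codec -------------------------------------------------------
#
# 16-bit EDF with an optional "EDF Annotations" signal carrying TAL
# (time-stamped annotation list) records. Data records are 1 s long, so
# writing requires an integer sampling rate and a whole number of seconds.
# Physical ranges are symmetric per channel, auto-computed from the data
# extrema rounded up to the next integer microvolt.

EDF_ANN_LABEL <- "EDF Annotations"

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too wide: '", x, "'")
  formatC(x, width = width, flag = "-")
}

edf_num_field <- function(x, width) {
  # fit a number into `width` ASCII chars without losing header precision
  for (digits in seq(width, 1L)) {
    s <- formatC(x, digits = digits, width = 1L, format = "g", flag = "-")
    if (nchar(s) <= width) return(pad_field(s, width))
  }
  stop("cannot format ", x, " in ", width, " chars")
}

#' Write a recording to an EDF/EDF+ file
#'
#' Samples are quantized to 16 bits over a symmetric physical range chosen
#' per channel from the data extrema (rounded up to an integer microvolt),
#' so the round-trip error is at most one quantization step. Annotations
#' are serialized as EDF+ TAL annotations; channel-specific seizures use
#' the `"<text>@<channel>"` convention in the annotation text.
#'
#' @param rec a [recording()].
#' @param path output file path.
#' @param annotation_text text used for seizure annotations (default
#'   `"seizure"`; [read_edf()]'s default pattern matches it).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, annotation_text = "seizure") {
  stopifnot(inherits(rec, "recording"))
  if (any(!is.finite(rec$data)))
    stop("cannot write non-finite samples to EDF")
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writing requires an integer sampling rate (1 s data records)")
  fs <- as.integer(round(fs))
  n_samp <- ncol(rec$data)
  if (n_samp %% fs != 0L)
    stop("EDF writing requires a whole number of seconds of data")
  n_rec <- n_samp %/% fs
  nc <- nrow(rec$data)
  has_ann <- TRUE  # always write an annotation signal (EDF+C needs the clock TALs)

  phys_max <- vapply(seq_len(nc), function(i) {
    m <- max(abs(rec$data[i, ]))
    max(1, ceiling(m))
  }, numeric(1))

  # digital conversion over the full declared range [-32768, 32767], the
  # exact inverse of the reader's rescaling
  dig <- matrix(0L, nc, n_samp)
  for (i in seq_len(nc)) {
    d <- round((rec$data[i, ] + phys_max[i]) / (2 * phys_max[i]) * 65535 - 32768)
    dig[i, ] <- as.integer(pmin(pmax(d, -32768), 32767))
  }

  # TALs per record: clock TAL, plus each annotation in the record holding
  # its onset
  tals <- lapply(seq_len(n_rec), function(r) sprintf("+%d\x14\x14", r - 1L))
  ann <- rec$annotations
  if (nrow(ann)) {
    for (k in seq_len(nrow(ann))) {
      txt <- annotation_text
      if (!is.na(ann$channel[k])) txt <- paste0(txt, "@", ann$channel[k])
      r <- min(n_rec, floor(ann$start_s[k]) + 1L)
      tals[[r]] <- c(tals[[r]],
        sprintf("+%s\x15%s\x14%s\x14",
                format(ann$start_s[k], trim = TRUE, scientific = FALSE),
                format(ann$end_s[k] - ann$start_s[k], trim = TRUE,
                       scientific = FALSE),
                txt))
    }
  }
  # each TAL is terminated by a NUL byte
  tal_bytes <- lapply(tals, function(x)
    unlist(lapply(x, function(s) c(charToRaw(s), as.raw(0L)))))
  ann_spr <- max(8L, ceiling(max(vapply(tal_bytes, length, integer(1))) / 2) + 1L)

  ns <- nc + 1L
  header_bytes <- 256L * (ns + 1L)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeBin(charToRaw(pad_field(x, width)), con)
  wr("0", 8L)                          # version
  wr("X X X X", 80L)                   # local patient id (anonymous)
  wr("Startdate X X X X", 80L)         # local recording id
  wr("01.01.00", 8L); wr("00.00.00", 8L)
  wr(header_bytes, 8L)
  wr("EDF+C", 44L)
  wr(n_rec, 8L)
  wr("1", 8L)                          # record duration, seconds
  wr(ns, 4L)

  labels <- c(rec$channel_labels, EDF_ANN_LABEL)
  for (l in labels) wr(l, 16L)
  for (i in seq_len(ns)) wr("", 80L)                   # transducer
  for (i in seq_len(ns)) wr(if (i <= nc) "uV" else "", 8L)
  for (i in seq_len(ns))
    writeBin(charToRaw(if (i <= nc) edf_num_field(-phys_max[i], 8L)
                       else pad_field("-32768", 8L)), con)
  for (i in seq_len(ns))
    writeBin(charToRaw(if (i <= nc) edf_num_field(phys_max[i], 8L)
                       else pad_field("32767", 8L)), con)
  for (i in seq_len(ns)) wr("-32768", 8L)              # digital min
  for (i in seq_len(ns)) wr("32767", 8L)               # digital max
  for (i in seq_len(ns)) wr("", 80L)                   # prefilter
  for (i in seq_len(ns)) wr(if (i <= nc) fs else ann_spr, 8L)
  for (i in seq_len(ns)) wr("", 32L)                   # reserved

  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(nc))
      writeBin(dig[i, idx], con, size = 2L, endian = "little")
    raw_tal <- tal_bytes[[r]]
    buf <- raw(2L * ann_spr)
    buf[seq_along(raw_tal)] <- raw_tal
    writeBin(buf, con)
  }
  invisible(path)
}

read_header_field <- function(con, width) {
  trimws(rawToChar(readBin(con, "raw", width)))
}

#' Read an EDF/EDF+ recording
#'
#' Reads 16-bit EDF signals, rescales them to physical units, and maps
#' EDF+ TAL annotations whose text matches `annotation_pattern`
#' (case-insensitive) to ground-truth seizure intervals. Annotation text
#' of the form `"<text>@<channel>"` yields a channel-specific interval.
#'
#' @param path path to an EDF/EDF+ file.
#' @param annotation_pattern regular expression selecting seizure
#'   annotations (default `"seiz"`, case-insensitive).
#' @return A [recording()].
#' @export
read_edf <- function(path, annotation_pattern = "seiz") {
  if (!file.exists(path)) stop("no such file: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop("not a valid EDF file (truncated header): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_header_field(con, 8L)
  if (version != "0") stop("not a valid EDF file (bad version field): ", path)
  readBin(con, "raw", 160L)            # patient + recording id
  readBin(con, "raw", 16L)             # date + time
  header_bytes <- as.integer(read_header_field(con, 8L))
  readBin(con, "raw", 44L)             # reserved (EDF+C/EDF+D marker)
  n_rec <- as.integer(read_header_field(con, 8L))
  rec_dur <- as.numeric(read_header_field(con, 8L))
  ns <- as.integer(read_header_field(con, 4L))
  if (is.na(ns) || ns < 1L) stop("EDF file declares no signals: ", path)
  if (is.na(n_rec) || n_rec < 1L) stop("EDF file declares no data records: ", path)

  rd <- function(width) vapply(seq_len(ns), function(i)
    read_header_field(con, width), character(1))
  labels   <- rd(16L); rd(80L); rd(8L)
  phys_min <- as.numeric(rd(8L)); phys_max <- as.numeric(rd(8L))
  dig_min  <- as.numeric(rd(8L)); dig_max  <- as.numeric(rd(8L))
  rd(80L)
  spr <- suppressWarnings(as.integer(rd(8L))); rd(32L)
  if (is.na(header_bytes) || header_bytes != 256L * (ns + 1L))
    stop("corrupt EDF header (size field mismatch): ", path)
  if (any(is.na(spr)) || any(spr < 1L) ||
      any(is.na(phys_min)) || any(is.na(phys_max)) ||
      any(is.na(dig_min)) || any(is.na(dig_max)))
    stop("corrupt EDF signal header: ", path)
  if (sz < header_bytes + 2 * sum(spr) * n_rec)
    stop("truncated EDF data section: ", path)

  is_ann <- labels == EDF_ANN_LABEL
  sig_idx <- which(!is_ann)
  if (length(sig_idx) == 0L) stop("EDF file has no data channels: ", path)
  if (length(unique(spr[sig_idx])) != 1L)
    stop("unsupported EDF layout: channels with differing sampling rates")
  fs <- spr[sig_idx[1L]] / rec_dur

  total <- sum(spr)
  raw_all <- readBin(con, "integer", n = total * n_rec, size = 2L,
                     endian = "little", signed = TRUE)
  if (length(raw_all) < total * n_rec)
    stop("truncated EDF data section: ", path)

  nc <- length(sig_idx)
  n_samp <- spr[sig_idx[1L]] * n_rec
  data <- matrix(0, nc, n_samp)
  tal_text <- character(0)
  offs <- c(0L, cumsum(spr))
  for (r in seq_len(n_rec)) {
    base <- (r - 1L) * total
    for (j in seq_len(nc)) {
      i <- sig_idx[j]
      v <- raw_all[(base + offs[i] + 1L):(base + offs[i] + spr[i])]
      gain <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
      data[j, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
        (v - dig_min[i]) * gain + phys_min[i]
    }
    for (i in which(is_ann)) {
      v <- raw_all[(base + offs[i] + 1L):(base + offs[i] + spr[i])]
      b <- writeBin(v, raw(), size = 2L, endian = "little")
      tal_text <- c(tal_text, split_raw_on_nul(b))
    }
  }

  ann <- parse_tal_annotations(tal_text, annotation_pattern)
  recording(data, fs, labels[sig_idx], annotations = ann)
}

# NUL bytes separate TALs inside an annotation signal's record
split_raw_on_nul <- function(b) {
  if (!length(b)) return(character(0))
  r <- rle(b == as.raw(0L))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(!r$values)
  vapply(keep, function(k) rawToChar(b[starts[k]:ends[k]]), character(1))
}

parse_tal_annotations <- function(tals, pattern) {
  if (!length(tals)) return(seizure_intervals())
  # TAL: [+-]onset(\x15 duration)? \x14 text \x14 ...
  starts <- numeric(0); ends <- numeric(0); chans <- character(0)
  for (p in tals) {
    f <- strsplit(p, "\x14", fixed = TRUE)[[1L]]
    if (length(f) < 2L) next
    od <- strsplit(f[1L], "\x15", fixed = TRUE)[[1L]]
    onset <- suppressWarnings(as.numeric(od[1L]))
    dur <- if (length(od) > 1L) suppressWarnings(as.numeric(od[2L])) else NA_real_
    for (txt in f[-1L]) {
      if (!nzchar(txt) || !grepl(pattern, txt, ignore.case = TRUE)) next
      if (is.na(onset) || is.na(dur) || dur <= 0) next
      ch <- NA_character_
      if (grepl("@", txt, fixed = TRUE))
        ch <- sub("^.*@", "", txt)
      starts <- c(starts, onset); ends <- c(ends, onset + dur)
      chans <- c(chans, ch)
    }
  }
  seizure_intervals(starts, ends, chans)
}

#' Write a seizure ground-truth sidecar CSV
#'
#' Columns `start_s,end_s,channel` (empty channel = all channels).
#'
#' @param intervals a [seizure_intervals()] data frame.
#' @param path output CSV path.
#' @export
write_truth_csv <- function(intervals, path) {
  utils::write.csv(intervals, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a seizure ground-truth sidecar CSV
#' @param path CSV with columns `start_s,end_s[,channel]`.
#' @return a [seizure_intervals()] data frame.
#' @export
read_truth_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ch <- if ("channel" %in% names(df)) df$channel else NA_character_
  if (is.character(ch)) ch[!nzchar(ch)] <- NA_character_
  seizure_intervals(df$start_s, df$end_s, ch)
}

# ---- epoching ---------------------------------------------------------------

#' Segment a recording into fixed-length epochs
#'
#' Splits every channel into consecutive non-overlapping windows of
#' `epoch_len_s` seconds (default 10 s, the unit of feature extraction and
#' classification). A trailing remainder shorter than one epoch is dropped
#' with a warning.
#'
#' @param rec a [recording()].
#' @param epoch_len_s epoch length in seconds (> 0).
#' @return An object of class `epoch_set`: list with `epochs` (array,
#'   epoch x channel x sample), `epoch_start_s`, `epoch_len_s`, `fs`,
#'   `channel_labels`.
#' @export
segment_epochs <- function(rec, epoch_len_s = 10) {
  stopifnot(inherits(rec, "recording"))
  if (!is.numeric(epoch_len_s) || length(epoch_len_s) != 1L || epoch_len_s <= 0)
    stop("`epoch_len_s` must be a positive scalar")
  spe <- round(epoch_len_s * rec$fs)
  if (spe < 4)
    stop("epochs of ", epoch_len_s, " s at ", rec$fs,
         " Hz have < 4 samples; features are undefined")
  n_samp <- ncol(rec$data)
  n_epoch <- n_samp %/% spe
  if (n_samp %% spe != 0L)
    warning(sprintf("dropping trailing %.3f s (< one epoch)",
                    (n_samp %% spe) / rec$fs))
  nc <- nrow(rec$data)
  epochs <- array(0, dim = c(n_epoch, nc, spe))
  if (n_epoch > 0L)
    for (e in seq_len(n_epoch))
      epochs[e, , ] <- rec$data[, ((e - 1L) * spe + 1L):(e * spe), drop = FALSE]
  structure(
    list(epochs = epochs,
         epoch_start_s = (seq_len(n_epoch) - 1L) * epoch_len_s,
         epoch_len_s = epoch_len_s, fs = rec$fs,
         channel_labels = rec$channel_labels),
    class = "epoch_set")
}
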