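test_that("recording validates its invariants", {
  d <- matrix(rnorm(512), 2, 256)
  r <- recording(d, 256)
  expect_equal(r$duration_s, 1)
  expect_equal(r$channel_labels, c("CH1", "CH2"))

  expect_error(recording(d, -1), "positive")
  expect_error(recording(d, 256, channel_labels = "only-one"), "label")
  expect_error(recording(d, 256, channel_labels = c("A", "A")), "unique")
  expect_error(
    recording(d, 256, annotations = seizure_intervals(0.5, 2)),
    "within")
  expect_error(
    recording(d, 256, annotations = seizure_intervals(0, 0.5, "CHX")),
    "CHX")
  expect_error(seizure_intervals(3, 2), "start_s < end_s")
})

test_that("epoch segmentation follows the floor rule and drops remainders", {
  r <- tiny_recording(2, 256, 60)
  es <- segment_epochs(r, 10)
  expect_equal(dim(es$epochs), c(6, 2, 2560))
  expect_equal(es$epoch_start_s, seq(0, 50, 10))

  r25 <- tiny_recording(1, 256, 25)
  expect_warning(es25 <- segment_epochs(r25, 10), "dropping")
  expect_equal(dim(es25$epochs)[1], 2)

  r9 <- tiny_recording(1, 256, 9)
  expect_warning(es9 <- segment_epochs(r9, 10), "dropping")
  expect_equal(dim(es9$epochs)[1], 0)

  expect_error(segment_epochs(r, 0.01), "4 samples")
})

test_that("remainder-free epochs concatenate back to the sample matrix", {
  r <- tiny_recording(3, 128, 40)
  es <- segment_epochs(r, 10)
  rebuilt <- do.call(cbind, lapply(seq_len(dim(es$epochs)[1]),
                                   function(e) es$epochs[e, , ]))
  expect_identical(rebuilt, r$data)
})

test_that("EDF round trip preserves structure and stays within quantization", {
  ann <- seizure_intervals(c(5.5, 20), c(9.5, 31), c(NA, "CH2"))
  r <- tiny_recording(2, 128, 60, annotations = ann)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(r, path)
  r2 <- read_edf(path)

  expect_identical(r2$channel_labels, r$channel_labels)
  expect_equal(r2$fs, r$fs)
  expect_equal(r2$duration_s, r$duration_s)
  step <- vapply(seq_len(nrow(r$data)), function(i)
    2 * max(1, ceiling(max(abs(r$data[i, ])))) / 65535, numeric(1))
  for (i in seq_len(nrow(r$data)))
    expect_lte(max(abs(r2$data[i, ] - r$data[i, ])), step[i])
  expect_equal(r2$annotations$start_s, ann$start_s, tolerance = 1e-9)
  expect_equal(r2$annotations$end_s, ann$end_s, tolerance = 1e-9)
  expect_identical(r2$annotations$channel, ann$channel)

  # empty annotations round-trip to empty
  r0 <- tiny_recording(1, 128, 20)
  p0 <- withr::local_tempfile(fileext = ".edf")
  write_edf(r0, p0)
  expect_identical(nrow(read_edf(p0)$annotations), 0L)
})

test_that("EDF reader rejects malformed files", {
  expect_error(read_edf(tempfile()), "no such file")
  bad <- withr::local_tempfile(fileext = ".edf")
  writeBin(charToRaw("not an EDF header"), bad)
  expect_error(read_edf(bad), "EDF")
  r <- tiny_recording(1, 128, 20)
  p <- withr::local_tempfile(fileext = ".edf")
  write_edf(r, p)
  full <- readBin(p, "raw", file.info(p)$size)
  writeBin(full[1:600], bad)
  expect_error(read_edf(bad), "truncated|corrupt")
  expect_error(write_edf(recording(matrix(c(1, NaN), 1, 2), 2), p), "finite")
})

test_that("files written here are read identically by an independent EDF reader", {
  ann <- seizure_intervals(3, 8)
  r <- tiny_recording(2, 128, 30, annotations = ann)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(r, path)
  script <- paste(
    "import sys, json, mne",
    "raw = mne.io.read_raw_edf(sys.argv[1], verbose='ERROR')",
    "a = raw.annotations",
    "print(json.dumps({'sfreq': raw.info['sfreq'], 'ch': raw.ch_names,",
    "  'n': int(raw.n_times),",
    "  'onset': float(a.onset[0]), 'dur': float(a.duration[0]),",
    "  'desc': str(a.description[0]),",
    "  'x0': (raw.get_data()[0, :5] * 1e6).tolist()}))",
    sep = "\n")
  sf <- withr::local_tempfile(fileext = ".py")
  writeLines(script, sf)
  out <- system2("python", c(sf, path), stdout = TRUE, stderr = FALSE)
  info <- jsonlite::fromJSON(out[length(out)])
  expect_equal(info$sfreq, 128)
  expect_equal(info$ch, c("CH1", "CH2"))
  expect_equal(info$n, 30 * 128)
  expect_equal(info$onset, 3)
  expect_equal(info$dur, 5)
  expect_equal(info$desc, "seizure")
  expect_equal(as.numeric(info$x0), r$data[1, 1:5], tolerance = 0.01)
})

test_that("ground-truth sidecar CSV round-trips", {
  ann <- seizure_intervals(c(1, 50), c(20, 61.5), c("CH1", NA))
  p <- withr::local_tempfile(fileext = ".csv")
  write_truth_csv(ann, p)
  back <- read_truth_csv(p)
  expect_equal(back$start_s, ann$start_s)
  expect_equal(back$end_s, ann$end_s)
  expect_identical(back$channel, ann$channel)
})
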