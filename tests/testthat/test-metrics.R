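test_that("epoch metrics match hand counts and conventions", {
  p <- c(0, 0, 0, 1, 1, 1, 1, 1, 0, 0)
  t <- c(0, 0, 0, 0, 1, 1, 1, 1, 1, 1)
  m <- epoch_metrics(p, t)
  expect_equal(m$counts, list(tp = 4L, fn = 2L, tn = 3L, fp = 1L))
  expect_equal(m$sensitivity, 4 / 6)
  expect_equal(m$specificity, 3 / 4)

  eq <- epoch_metrics(t, t)
  expect_equal(eq$sensitivity, 1); expect_equal(eq$specificity, 1)

  nf <- epoch_metrics(rep(0, 5), rep(0, 5))
  expect_true(is.na(nf$sensitivity))
  expect_equal(nf$specificity, 1)
  expect_error(epoch_metrics(1:4 %% 2, 1:6 %% 2), "shape")
})

test_that("epoch metrics agree with a confusion-matrix oracle on random tensors", {
  set.seed(30)
  for (i in 1:20) {
    n <- 500
    p <- matrix(sample(0:1, n, replace = TRUE), ncol = 5)
    t <- matrix(sample(0:1, n, replace = TRUE, prob = c(.9, .1)), ncol = 5)
    m <- epoch_metrics(p, t)
    cm <- table(factor(p, 0:1), factor(t, 0:1))
    expect_equal(m$counts$tp, cm["1", "1"], ignore_attr = TRUE)
    expect_equal(m$counts$tn, cm["0", "0"], ignore_attr = TRUE)
    # permutation invariance over channels
    perm <- sample(5)
    expect_identical(epoch_metrics(p[, perm], t[, perm]), m)
  }
})

test_that("event FDR applies the any-overlap same-channel rule", {
  truth <- seizure_intervals(c(100, 500), c(160, 590), c(NA, "CH2"))
  pred <- seizure_intervals(
    c(110, 400, 510, 3000), c(130, 420, 550, 3010),
    c("CH1", "CH1", "CH1", "CH2"))
  r <- event_fdr(pred, truth, duration_h = 1)
  # 110-130 overlaps global truth; 510-550 overlaps CH2-only truth on CH1 -> no
  expect_equal(r$true_events, 1L)
  expect_equal(r$false_events, 3L)
  expect_equal(r$fdr_per_hour, 3)

  # 3 false events in a 2 h seizure-free recording = 1.5 per hour
  free <- event_fdr(pred[1:3, ], seizure_intervals(), 2)
  expect_equal(free$fdr_per_hour, 1.5)
  expect_equal(event_fdr(seizure_intervals(), truth, 2)$fdr_per_hour, 0)
  expect_error(event_fdr(pred, truth, 0), "positive")
})

test_that("event counts equal a brute-force all-pairs overlap check", {
  set.seed(31)
  for (i in 1:100) {
    np <- sample(0:8, 1); nt <- sample(0:5, 1)
    mk <- function(n) {
      s <- runif(n, 0, 3500)
      seizure_intervals(s, s + runif(n, 5, 200),
                        sample(c(NA, "CH1", "CH2"), n, replace = TRUE))
    }
    pred <- mk(np); truth <- mk(nt)
    r <- event_fdr(pred, truth, duration_h = 1)
    brute <- 0L
    if (np > 0) for (a in seq_len(np)) {
      hit <- FALSE
      if (nt > 0) for (b in seq_len(nt)) {
        chan_ok <- is.na(truth$channel[b]) || is.na(pred$channel[a]) ||
          truth$channel[b] == pred$channel[a]
        ov <- min(pred$end_s[a], truth$end_s[b]) -
              max(pred$start_s[a], truth$start_s[b])
        if (chan_ok && ov >= 1) hit <- TRUE
      }
      brute <- brute + hit
    }
    expect_equal(r$true_events, brute)
    expect_equal(r$false_events, nrow(pred) - brute)
  }
})

test_that("fdr scales inversely with duration for fixed events", {
  pred <- seizure_intervals(c(10, 700), c(40, 760), c("CH1", "CH1"))
  for (h in c(0.5, 2, 8))
    expect_equal(event_fdr(pred, seizure_intervals(), h)$fdr_per_hour, 2 / h)
})

test_that("evaluate_recording equals a manual chain of the stage operations", {
  cfg <- synth_config(duration_s = 600, n_seizures = 1, n_channels = 2,
                      seizure_duration_range_s = c(60, 90), min_gap_s = 10,
                      seed = 17)
  rec <- generate_recording(cfg, 1, 1)
  train_rec <- generate_recording(cfg, 1, 2)
  fm_t <- extract_features(segment_epochs(train_rec), "train")
  lf <- labeled_features(baseline_correct(fm_t, 20),
                         label_epochs(fm_t, train_rec$annotations, fs = 256))
  model <- train_detector(lf)

  res <- evaluate_recording(rec, model, window_epochs = 20)

  fm <- baseline_correct(extract_features(segment_epochs(rec)), 20)
  pred <- predict_epochs(model, fm)
  em <- epoch_metrics(pred, label_epochs(fm, rec$annotations, fs = 256))
  expect_equal(res$metrics$sensitivity, em$sensitivity)
  expect_equal(res$metrics$specificity, em$specificity)
  events <- do.call(rbind, lapply(1:2, function(c)
    threshold_events(moving_average(pred[, c], 10), 0.5, 10,
                     fm$epoch_start_s, fm$channel_labels[c])))
  fdr <- event_fdr(events, rec$annotations, rec$duration_s / 3600)
  expect_equal(res$metrics$fdr_per_hour, fdr$fdr_per_hour)

  # re-running the pipeline is bit-reproducible
  res2 <- evaluate_recording(rec, model, window_epochs = 20)
  expect_identical(res$metrics, res2$metrics)
  expect_identical(res$events, res2$events)
})
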