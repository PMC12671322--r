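make_cluster_data <- function(n_per, centers, sd = 1, seed = 5, labels = NULL) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k)
    cbind(rnorm(n_per, centers[k, 1], sd), rnorm(n_per, centers[k, 2], sd))))
  if (is.null(labels)) labels <- rep(c(0L, 1L), each = nrow(centers) / 2 * n_per)
  v <- array(NA_real_, c(nrow(rows), 1, 2))
  v[, 1, 1] <- rows[, 1]; v[, 1, 2] <- rows[, 2]
  labeled_features(make_fm(v, database_id = "sim"),
                   matrix(labels, ncol = 1))
}

test_that("epoch labeling follows the any-overlap rule per channel", {
  fm <- make_fm(array(0, c(6, 2, 2)))  # epochs [0,10) ... [50,60)
  ann <- seizure_intervals(c(15, 39.99), c(24, 41), c(NA, "CH2"))
  lab <- label_epochs(fm, ann, fs = 256)
  expect_equal(lab[, 1], c(0L, 1L, 1L, 0L, 0L, 0L))       # global seizure
  expect_equal(lab[, 2], c(0L, 1L, 1L, 1L, 1L, 0L))       # + CH2-only event
  # minimum-overlap fraction is configurable
  lab50 <- label_epochs(fm, ann, min_overlap_s = 5)
  expect_equal(lab50[, 1], c(0L, 1L, 0L, 0L, 0L, 0L))
  expect_identical(label_epochs(fm, seizure_intervals()), matrix(0L, 6, 2,
    dimnames = list(NULL, c("CH1", "CH2"))))
})

test_that("well-separated clusters are learned perfectly; XOR needs the RBF", {
  sep <- make_cluster_data(100, rbind(c(0, 0), c(10, 10)))
  m <- train_detector(sep)
  expect_identical(predict_epochs(m, sep$features),
                   matrix(sep$labels, ncol = 1, dimnames = list(NULL, "CH1")))

  xor <- make_cluster_data(100, rbind(c(0, 0), c(8, 8), c(0, 8), c(8, 0)),
                           seed = 6)
  mx <- train_detector(xor)
  acc <- mean(predict_epochs(mx, xor$features) == xor$labels)
  expect_gt(acc, 0.9)
  # a linear rule cannot beat chance on XOR geometry
  x <- cbind(xor$features$values[, 1, 1], xor$features$values[, 1, 2])
  lin <- stats::glm(xor$labels ~ x, family = stats::binomial())
  lin_acc <- mean((stats::fitted(lin) > 0.5) == (xor$labels == 1))
  expect_lt(lin_acc, 0.6)
})

test_that("training rejects degenerate inputs", {
  one_class <- make_cluster_data(100, rbind(c(0, 0), c(10, 10)),
                                 labels = rep(0L, 200))
  expect_error(train_detector(one_class), "both")
  flat <- make_cluster_data(100, rbind(c(0, 0), c(10, 10)))
  flat$features$values[, , 2] <- 3
  expect_error(train_detector(flat), "md")
})

test_that("standardization statistics reproduce unit-scale training features", {
  d <- make_cluster_data(200, rbind(c(1, -4), c(6, 3)), sd = 2)
  m <- train_detector(d)
  x <- cbind(as.vector(d$features$values[, , 1]),
             as.vector(d$features$values[, , 2]))
  xs <- sweep(sweep(x, 2, m$center), 2, m$scale, "/")
  expect_lt(max(abs(colMeans(xs))), 1e-9)
  expect_lt(max(abs(apply(xs, 2, sd) - 1)), 1e-9)
})

test_that("predictions are deterministic and shape-preserving", {
  d <- make_cluster_data(100, rbind(c(0, 0), c(10, 10)))
  m <- train_detector(d)
  v <- array(rnorm(5 * 3 * 2, 5, 4), c(5, 3, 2))
  fm <- make_fm(v)
  p1 <- predict_epochs(m, fm)
  expect_equal(dim(p1), c(5, 3))
  expect_identical(p1, predict_epochs(m, fm))
  dup <- make_fm(v[c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5), , , drop = FALSE])
  expect_identical(predict_epochs(m, dup)[c(1, 3, 5, 7, 9), ], p1)
})

test_that("model save/load round-trips to bit-identical predictions", {
  d <- make_cluster_data(100, rbind(c(0, 0), c(6, 6)))
  m <- train_detector(d)
  path <- withr::local_tempfile(fileext = ".szm")
  save_model(m, path)
  m2 <- load_model(path)
  set.seed(11)
  fm <- make_fm(array(rnorm(1000 * 1 * 2, 3, 5), c(1000, 1, 2)))
  expect_identical(predict_epochs(m2, fm), predict_epochs(m, fm))

  # corrupted / version-mismatched artifacts are rejected
  truncated <- withr::local_tempfile()
  writeLines(substr(paste(readLines(path), collapse = ""), 1, 80), truncated)
  expect_error(load_model(truncated), "corrupt")
  obj <- jsonlite::fromJSON(readLines(path))
  obj$version <- "0.0"
  bad <- withr::local_tempfile()
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17)), bad)
  expect_error(load_model(bad), "version")
  obj$version <- "1.0"; obj$feature_order <- c("md", "sdi")
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17)), bad)
  expect_error(load_model(bad), "feature order")
})

test_that("LODO harness holds each database out exactly once without leakage", {
  set.seed(12)
  mk <- function(id, mu) {
    v <- array(NA_real_, c(120, 1, 2))
    lab <- rep(c(0L, 1L), 60)
    v[, 1, 1] <- rnorm(120, mu + 3 * lab); v[, 1, 2] <- rnorm(120, mu + 3 * lab)
    labeled_features(make_fm(v, database_id = id), matrix(lab, ncol = 1))
  }
  ds <- list(mk("a", 0), mk("b", 50), mk("c", -30))
  res <- lodo_cv(ds, window_epochs = 20)
  expect_identical(res$folds$database_id, c("a", "b", "c"))
  expect_equal(nrow(res$folds), 3)
  expect_error(lodo_cv(list(mk("a", 0), mk("a", 1))), "duplicate")
  expect_error(lodo_cv(ds[1]), "2 databases")
})
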