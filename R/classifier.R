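MODEL_FORMAT_VERSION <- "1.0"
FEATURE_ORDER <- c("sdi", "md")

#' Label epochs from ground-truth seizure intervals
#'
#' An (epoch, channel) cell is positive when the epoch window
#' `[start, start + epoch_len)` overlaps a seizure interval on the same
#' channel (or a channel-less interval, which applies to all channels) by
#' at least `min_overlap_s` seconds. The default, one sample, makes any
#' overlap positive.
#'
#' @param fm a `feature_matrix` (or `epoch_set`) carrying epoch start
#'   times, epoch length and channel labels.
#' @param intervals a [seizure_intervals()] data frame.
#' @param fs sampling rate, used only to express the default minimum
#'   overlap of one sample; ignored when `min_overlap_s` is given.
#' @param min_overlap_s minimum overlap in seconds for an epoch to count
#'   as seizure (default `1/fs`, i.e. any overlap).
#' @return Integer epoch x channel matrix of 0/1 labels.
#' @export
label_epochs <- function(fm, intervals, fs = 256, min_overlap_s = NULL) {
  starts <- fm$epoch_start_s
  len <- fm$epoch_len_s
  chans <- fm$channel_labels
  if (is.null(min_overlap_s)) min_overlap_s <- 1 / fs
  labels <- matrix(0L, length(starts), length(chans),
                   dimnames = list(NULL, chans))
  if (is.null(intervals) || nrow(intervals) == 0L) return(labels)
  for (k in seq_len(nrow(intervals))) {
    ov <- pmin(starts + len, intervals$end_s[k]) -
          pmax(starts, intervals$start_s[k])
    hit <- ov >= min_overlap_s - 1e-12
    if (!any(hit)) next
    cols <- if (is.na(intervals$channel[k])) seq_along(chans)
            else which(chans == intervals$channel[k])
    labels[hit, cols] <- 1L
  }
  labels
}

#' Bundle features with per-epoch, per-channel labels
#'
#' @param fm a `feature_matrix`.
#' @param labels epoch x channel matrix of 0/1 labels (e.g. from
#'   [label_epochs()]).
#' @return An object of class `labeled_features`.
#' @export
labeled_features <- function(fm, labels) {
  stopifnot(inherits(fm, "feature_matrix"))
  labels <- as.matrix(labels)
  d <- dim(fm$values)
  if (!all(dim(labels) == d[1:2]))
    stop("label matrix must be epoch x channel, matching the features")
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be 0/1")
  structure(list(features = fm, labels = matrix(as.integer(labels), d[1L], d[2L])),
            class = "labeled_features")
}

# flatten epoch x channel x feature into rows (one row per channel epoch)
flatten_features <- function(fm) {
  d <- dim(fm$values)
  matrix(fm$values, d[1L] * d[2L], d[3L],
         dimnames = list(NULL, FEATURE_ORDER))
}

#' Train the per-epoch seizure classifier
#'
#' Fits a radial-basis support vector machine on standardized features,
#' with inverse-class-frequency weights (long-term EEG is overwhelmingly
#' non-seizure; without weighting the all-negative classifier dominates).
#' Every (epoch, channel) cell is one training example. The kernel width
#' defaults to the median heuristic: `gamma = 1 / (2 * s^2)` where `s` is
#' the median pairwise Euclidean distance between standardized training
#' rows (subsampled deterministically to at most `max_pairs_rows` rows).
#'
#' The returned artifact is self-contained: it stores the standardization
#' statistics, support vectors, dual coefficients, intercept and label
#' orientation, so predictions are reproducible without the fitting
#' library, and [save_model()] can serialize it to portable JSON.
#'
#' @param data a [labeled_features()] object, or a list of them (pooled).
#' @param cost soft-margin cost `C` (default 1).
#' @param gamma RBF kernel width; `NULL` (default) = median heuristic.
#' @param max_pairs_rows subsample cap for the median heuristic.
#' @return An object of class `seizure_model`.
#' @export
train_detector <- function(data, cost = 1, gamma = NULL,
                           max_pairs_rows = 1000L) {
  if (inherits(data, "labeled_features")) data <- list(data)
  x <- do.call(rbind, lapply(data, function(d) flatten_features(d$features)))
  y <- unlist(lapply(data, function(d) as.vector(d$labels)))
  db_ids <- unique(unlist(lapply(data, function(d) d$features$database_id)))
  epoch_len <- data[[1L]]$features$epoch_len_s
  if (length(unique(y)) < 2L)
    stop("training data must contain both seizure and non-seizure epochs")
  if (min(table(y)) < 10L)
    stop("need at least 10 examples per class")

  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  if (any(scale == 0))
    stop("degenerate (zero-variance) feature: ",
         paste(FEATURE_ORDER[scale == 0], collapse = ", "))
  xs <- sweep(sweep(x, 2L, center), 2L, scale, "/")

  if (is.null(gamma)) {
    idx <- unique(round(seq(1L, nrow(xs), length.out = min(nrow(xs), max_pairs_rows))))
    s <- stats::median(stats::dist(xs[idx, , drop = FALSE]))
    gamma <- if (s > 0) 1 / (2 * s^2) else 1
  }

  n <- length(y)
  w <- c("0" = n / (2 * sum(y == 0L)), "1" = n / (2 * sum(y == 1L)))
  fit <- e1071::svm(xs, factor(y, levels = c("0", "1")),
                    scale = FALSE, kernel = "radial",
                    cost = cost, gamma = gamma, class.weights = w)

  model <- structure(
    list(version = MODEL_FORMAT_VERSION,
         feature_order = FEATURE_ORDER,
         kernel = "radial", cost = cost, gamma = gamma,
         class_weights = unname(w),
         center = unname(center), scale = unname(scale),
         sv = unname(as.matrix(fit$SV)),
         sv_coef = unname(as.vector(fit$coefs)),
         rho = as.numeric(fit$rho),
         decision_sign = 1,
         metadata = list(databases = db_ids, epoch_len_s = epoch_len,
                         n_train = n, n_positive = sum(y == 1L))),
    class = "seizure_model")

  # orient the decision function: libsvm's sign convention depends on the
  # order classes are first seen, so calibrate against the fit's own
  # training predictions
  mine <- decision_values(model, xs, standardized = TRUE)
  theirs <- as.integer(as.character(stats::predict(fit, xs)))
  agree <- mean((mine > 0) == (theirs == 1L))
  if (agree < 0.5) model$decision_sign <- -1
  model
}

decision_values <- function(model, x, standardized = FALSE) {
  if (!standardized)
    x <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  sv <- model$sv
  d2 <- outer(rowSums(x^2), rowSums(sv^2), "+") - 2 * tcrossprod(x, sv)
  d2[d2 < 0] <- 0
  k <- exp(-model$gamma * d2)
  model$decision_sign * (as.vector(k %*% model$sv_coef) - model$rho)
}

#' Predict per-epoch, per-channel seizure labels
#'
#' Applies the stored standardization and RBF decision function; output is
#' a deterministic 0/1 matrix of the input's epoch x channel shape.
#'
#' @param model a `seizure_model`.
#' @param fm a `feature_matrix` (feature order must match the model tag).
#' @return Integer epoch x channel matrix of 0/1 predictions.
#' @export
predict_epochs <- function(model, fm) {
  stopifnot(inherits(model, "seizure_model"), inherits(fm, "feature_matrix"))
  d <- dim(fm$values)
  if (d[3L] != length(model$feature_order))
    stop("feature dimension mismatch with model")
  if (!identical(unname(dimnames(fm$values)[[3L]]), model$feature_order))
    stop("feature order mismatch: model expects [",
         paste(model$feature_order, collapse = ", "), "]")
  dec <- decision_values(model, flatten_features(fm))
  matrix(as.integer(dec > 0), d[1L], d[2L],
         dimnames = list(NULL, fm$channel_labels))
}

#' Save / load a trained model artifact
#'
#' The artifact is versioned JSON with doubles serialized at 17
#' significant digits, which round-trips IEEE doubles exactly: a loaded
#' model's predictions are bit-identical to the saved model's. Loading
#' rejects artifacts with a missing or unknown format version or a
#' feature-order tag that does not match the current code.
#'
#' @param model a `seizure_model`.
#' @param path file path (conventional extension `.szm`).
#' @return `load_model()` returns the `seizure_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "seizure_model"))
  json <- jsonlite::toJSON(unclass(model), digits = I(17), auto_unbox = TRUE,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("no such model file: ", path)
  obj <- tryCatch(jsonlite::fromJSON(readLines(path, warn = FALSE)),
                  error = function(e) stop("corrupted model file: ", path,
                                           " (", conditionMessage(e), ")"))
  if (is.null(obj$version))
    stop("model file has no format version: ", path)
  if (!identical(obj$version, MODEL_FORMAT_VERSION))
    stop("unsupported model format version '", obj$version, "'")
  if (!identical(as.character(obj$feature_order), FEATURE_ORDER))
    stop("model feature order [", paste(obj$feature_order, collapse = ", "),
         "] does not match this package's [",
         paste(FEATURE_ORDER, collapse = ", "), "]")
  obj$sv <- matrix(as.numeric(obj$sv), nrow = nrow(obj$sv))
  obj$sv_coef <- as.numeric(obj$sv_coef)
  structure(obj, class = "seizure_model")
}

#' @export
print.seizure_model <- function(x, ...) {
  cat(sprintf(
    "<seizure_model v%s> RBF SVM: C=%g, gamma=%.4g, %d support vectors\n",
    x$version, x$cost, x$gamma, nrow(x$sv)))
  cat(sprintf("  trained on %d epochs (%d seizure) from: %s\n",
              x$metadata$n_train, x$metadata$n_positive,
              paste(x$metadata$databases, collapse = ", ")))
  invisible(x)
}

#' Leave-one-database-out cross-validation
#'
#' The cross-site generalization harness: for each database `D`, features
#' are baseline-corrected *within* each database (the adaptive median
#' correction is a per-recording/per-database causal filter), a model is
#' trained on all databases except `D`, and evaluated on `D`. Held-out
#' data never influences training. Per-fold epoch sensitivity/specificity
#' are computed on the raw per-epoch predictions; the moving-average +
#' threshold postprocessing then forms events, scored as the event
#' false-detection rate per hour.
#'
#' @param datasets list of [labeled_features()] with distinct
#'   `database_id`s (>= 2).
#' @param window_epochs AMFBC window (epochs); `NA` disables correction.
#' @param taps,theta postprocessing parameters (see [moving_average()] and
#'   [threshold_events()]).
#' @param cost,gamma SVM hyperparameters (see [train_detector()]).
#' @return List with `folds` (data frame: one row per held-out database,
#'   with sensitivity, specificity, balanced accuracy, FDR/h and counts)
#'   and `pooled` (metrics over all folds' predictions combined).
#' @export
lodo_cv <- function(datasets, window_epochs = 60L, taps = 10L, theta = 0.5,
                    cost = 1, gamma = NULL) {
  if (length(datasets) < 2L) stop("LODO needs at least 2 databases")
  ids <- vapply(datasets, function(d) {
    id <- d$features$database_id
    if (is.null(id)) stop("every dataset needs a database_id")
    id
  }, character(1))
  if (anyDuplicated(ids)) stop("duplicate database_id in LODO datasets")

  use_amfbc <- !is.na(window_epochs)
  corrected <- lapply(datasets, function(d) {
    fm <- if (use_amfbc) baseline_correct(d$features, window_epochs)
          else d$features
    labeled_features(fm, d$labels)
  })

  fold_rows <- list()
  pool_pred <- integer(0); pool_truth <- integer(0)
  pool_false_events <- 0; pool_hours <- 0
  for (k in seq_along(ids)) {
    model <- train_detector(corrected[-k], cost = cost, gamma = gamma)
    held <- corrected[[k]]
    pred <- predict_epochs(model, held$features)
    em <- epoch_metrics(pred, held$labels)
    ev <- score_fold_events(pred, held, taps, theta)
    fold_rows[[k]] <- data.frame(
      database_id = ids[k],
      sensitivity = em$sensitivity, specificity = em$specificity,
      balanced_accuracy = mean(c(em$sensitivity, em$specificity)),
      fdr_per_hour = ev$fdr_per_hour,
      tp = em$counts$tp, fn = em$counts$fn,
      tn = em$counts$tn, fp = em$counts$fp,
      false_events = ev$false_events, true_events = ev$true_events,
      duration_h = ev$duration_h,
      stringsAsFactors = FALSE)
    pool_pred <- c(pool_pred, as.vector(pred))
    pool_truth <- c(pool_truth, as.vector(held$labels))
    pool_false_events <- pool_false_events + ev$false_events
    pool_hours <- pool_hours + ev$duration_h
  }
  pooled_em <- epoch_metrics(matrix(pool_pred, ncol = 1L),
                             matrix(pool_truth, ncol = 1L))
  list(folds = do.call(rbind, fold_rows),
       pooled = list(sensitivity = pooled_em$sensitivity,
                     specificity = pooled_em$specificity,
                     fdr_per_hour = pool_false_events / pool_hours,
                     counts = pooled_em$counts))
}

# postprocess one fold's predictions channel-by-channel and score events
# against truth intervals reconstructed from the label runs
score_fold_events <- function(pred, held, taps, theta) {
  fm <- held$features
  len <- fm$epoch_len_s
  n_epochs <- length(fm$epoch_start_s)
  duration_h <- n_epochs * len / 3600
  events <- list(); truths <- list()
  for (c in seq_along(fm$channel_labels)) {
    y <- moving_average(pred[, c], taps)
    events[[c]] <- threshold_events(y, theta, len, fm$epoch_start_s,
                                    fm$channel_labels[c])
    truths[[c]] <- runs_to_intervals(held$labels[, c], fm$epoch_start_s, len,
                                     fm$channel_labels[c])
  }
  ev <- do.call(rbind, events)
  tr <- do.call(rbind, truths)
  fdr <- event_fdr(ev, tr, duration_h)
  c(fdr, list(duration_h = duration_h))
}

runs_to_intervals <- function(labels, starts, len, channel) {
  r <- rle(as.integer(labels))
  ends <- cumsum(r$lengths); begins <- ends - r$lengths + 1L
  keep <- which(r$values == 1L)
  if (!length(keep))
    return(seizure_intervals())
  seizure_intervals(starts[begins[keep]], starts[ends[keep]] + len,
                    channel)
}
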