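# shared fixtures, all built in code

# feature matrix straight from a values array (epoch x channel x 2)
make_fm <- function(values, epoch_len_s = 10, database_id = NULL) {
  d <- dim(values)
  dimnames(values) <- list(NULL, paste0("CH", seq_len(d[2])), c("sdi", "md"))
  structure(
    list(values = values,
         epoch_start_s = (seq_len(d[1]) - 1) * epoch_len_s,
         epoch_len_s = epoch_len_s,
         channel_labels = paste0("CH", seq_len(d[2])),
         database_id = database_id),
    class = "feature_matrix")
}

# constant-feature stream with one channel
const_fm <- function(n_epochs, sdi = 1, md = 2) {
  v <- array(0, c(n_epochs, 1, 2))
  v[, 1, 1] <- sdi; v[, 1, 2] <- md
  make_fm(v)
}

# small deterministic recording: 1/f-free white noise, optional planted tone
tiny_recording <- function(n_channels = 2, fs = 256, duration_s = 60,
                           annotations = NULL, seed = 99) {
  set.seed(seed)
  data <- matrix(rnorm(n_channels * fs * duration_s, sd = 20),
                 n_channels, fs * duration_s)
  recording(data, fs, annotations = annotations)
}

# brute-force cofactor-expansion determinant (oracle for md_feature)
cofactor_det <- function(m) {
  n <- nrow(m)
  if (n == 1) return(m[1, 1])
  s <- 0
  for (j in seq_len(n))
    s <- s + (-1)^(1 + j) * m[1, j] * cofactor_det(m[-1, -j, drop = FALSE])
  s
}

# independent re-implementation of the successive decomposition cascade
sdi_oracle <- function(x) {
  L <- floor(log2(length(x)))
  s <- x[1:(2^L)]
  tot <- 0
  for (k in 1:L) {
    ns <- numeric(length(s) / 2)
    dsum <- 0
    for (i in seq_along(ns)) {
      a <- s[2 * i - 1]; b <- s[2 * i]
      ns[i] <- (a + b) / 2
      dsum <- dsum + abs(a - b) / 2
    }
    tot <- tot + dsum / length(ns)
    s <- ns
  }
  log2(1 + tot / L)
}

# brute-force causal windowed mean
ma_oracle <- function(labels, taps) {
  vapply(seq_along(labels), function(t)
    sum(labels[max(1, t - taps + 1):t]) / taps, numeric(1))
}

# default-scale corpus used by end-to-end tests (seed fixed once)
acceptance_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(seed = 1)
      cache <<- corpus_features(generate_corpus(cfg))
    }
    cache
  }
})
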