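# Shared fixtures and independent oracles for the test suite.

# A tiny labeled matrix with hand-controllable values.
tiny_matrix <- function(values, labels, K = ncol(values)) {
  spike_matrix(values, labels = labels)
}

# Two well-separated classes in K dimensions around distinct centers.
two_blob_matrix <- function(n_per = 20, K = 8, gap = 100, sd = 2,
                            seed = 1) {
  set.seed(seed)
  a <- matrix(round(rnorm(n_per * K, 0, sd)), n_per, K)
  b <- matrix(round(rnorm(n_per * K, gap, sd)), n_per, K)
  spike_matrix(rbind(a, b), labels = rep(c("u1", "u2"), each = n_per))
}

# Random labeled matrix for property-style loops (small K, 2-4 classes).
random_small_matrix <- function(seed, K = 10, n_classes = NULL,
                                n_per_range = c(5, 12)) {
  set.seed(seed)
  if (is.null(n_classes)) n_classes <- sample(2:4, 1)
  rows <- lapply(seq_len(n_classes), function(ci) {
    n_i <- sample(n_per_range[1]:n_per_range[2], 1)
    center <- round(rnorm(K, 0, 20))
    matrix(round(rnorm(n_i * K, rep(center, each = n_i), 5)),
           n_i, K)
  })
  spike_matrix(do.call(rbind, rows),
               labels = rep(sprintf("u%d", seq_len(n_classes)),
                            vapply(rows, nrow, integer(1))))
}

# Oracle: literal evaluation of the greedy step criterion for class
# `cl` given already-selected 0-based indices; returns the best next
# 0-based index by exhaustive scan (ties -> smallest index).
oracle_next_feature <- function(matrix, cl, selected,
                                renormalize = TRUE) {
  prof <- build_profiles(matrix, renormalize = renormalize)
  sal <- prof$saliency[prof$class == cl][order(
    prof$feature[prof$class == cl])]
  K <- ncol(matrix$waveforms)
  best <- -Inf; best_k <- NA_integer_
  for (k in setdiff(0:(K - 1), selected)) {
    pen <- 1
    for (h in selected) {
      pen <- pen * (1 - feature_correlation(matrix, cl, k, h))
    }
    score <- sal[k + 1] * pen
    if (score > best + 1e-12) { best <- score; best_k <- k }
  }
  best_k
}

# Oracle: direct per-border window membership check for one spike.
oracle_matches <- function(waveform, config) {
  out <- character(0)
  for (w in config$windows) {
    ok <- TRUE
    for (l in seq_along(w$feature_indices)) {
      v <- waveform[w$feature_indices[l] + 1]
      if (v < w$lower[l] || v > w$upper[l]) { ok <- FALSE; break }
    }
    if (ok) out <- c(out, w$class)
  }
  out
}

# Build a sorter_config directly from bounds (bypassing fitting).
manual_config <- function(windows, K) {
  wl <- lapply(windows, function(w) {
    list(class = w$class, feature_indices = w$feature_indices,
         lower = w$lower, upper = w$upper, train_j = NA_real_)
  })
  names(wl) <- vapply(windows, `[[`, character(1), "class")
  structure(list(channel_id = "manual", K = K,
                 L = length(windows[[1]]$feature_indices),
                 windows = wl), class = "sorter_config")
}
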