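#' Construct a spike matrix
#'
#' A `spike_matrix` holds aligned extracellular spike waveforms, one spike
#' per row and one sample (feature) per column, together with optional
#' per-spike class labels and channel metadata. Waveform values are stored
#' as integers on the signed scale of the recording's quantisation (for
#' 8-bit data, -128..127).
#'
#' @param waveforms Numeric matrix, `n_spikes x K`. Coerced to integer
#'   storage; values must already be whole numbers.
#' @param labels Optional character vector of class labels, one per row,
#'   or `NULL` for unlabeled data.
#' @param channel_id Character scalar identifying the channel.
#' @param sample_rate_hz Sampling rate in Hz (default 30000).
#'
#' @return An object of class `spike_matrix`.
#' @export
spike_matrix <- function(waveforms, labels = NULL, channel_id = "ch0",
                         sample_rate_hz = 30000) {
  if (!is.matrix(waveforms)) {
    waveforms <- matrix(waveforms, nrow = NROW(waveforms))
  }
  storage <- waveforms
  if (!is.integer(storage)) {
    if (any(abs(storage - round(storage)) > 1e-8)) {
      stop("waveform values must be whole numbers (quantized amplitudes)",
           call. = FALSE)
    }
    storage <- matrix(as.integer(round(storage)), nrow = nrow(waveforms))
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(storage)) {
      stop("labels must have one entry per spike (row)", call. = FALSE)
    }
  }
  structure(
    list(waveforms = storage, labels = labels,
         channel_id = as.character(channel_id),
         sample_rate_hz = as.numeric(sample_rate_hz)),
    class = "spike_matrix"
  )
}

#' @export
print.spike_matrix <- function(x, ...) {
  cat(sprintf("<spike_matrix> %d spikes x %d samples, channel '%s', %g Hz\n",
              nrow(x$waveforms), ncol(x$waveforms), x$channel_id,
              x$sample_rate_hz))
  if (is.null(x$labels)) {
    cat("  unlabeled\n")
  } else {
    tab <- table(x$labels)
    cat("  classes:", paste(sprintf("%s(%d)", names(tab), tab),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.spike_matrix <- function(x) dim(x$waveforms)

n_spikes <- function(x) nrow(x$waveforms)
n_features <- function(x) ncol(x$waveforms)

#' Tidy a spike matrix into long format
#'
#' @param x A `spike_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `spike`, `sample`, `amplitude` and
#'   (when labels are present) `label`. Sample indices are 0-based to
#'   match feature indexing elsewhere in the package.
#' @export
tidy.spike_matrix <- function(x, ...) {
  n <- nrow(x$waveforms); k <- ncol(x$waveforms)
  out <- tibble::tibble(
    spike = rep(seq_len(n), each = k),
    sample = rep(0:(k - 1), times = n),
    amplitude = as.vector(t(x$waveforms))
  )
  if (!is.null(x$labels)) out$label <- rep(x$labels, each = k)
  out
}

#' @export
glance.spike_matrix <- function(x, ...) {
  tibble::tibble(
    n_spikes = nrow(x$waveforms),
    n_samples = ncol(x$waveforms),
    n_classes = if (is.null(x$labels)) NA_integer_ else
      length(unique(x$labels)),
    channel_id = x$channel_id,
    sample_rate_hz = x$sample_rate_hz
  )
}

#' Plot spike waveforms
#'
#' Overlays all waveforms, colored by class label when available.
#'
#' @param object A `spike_matrix`.
#' @param max_spikes Cap on the number of spikes drawn (default 200).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spike_matrix <- function(object, max_spikes = 200, ...) {
  df <- tidy(object)
  keep <- unique(df$spike)
  if (length(keep) > max_spikes) {
    keep <- keep[seq(1, length(keep), length.out = max_spikes)]
    df <- dplyr::filter(df, .data$spike %in% keep)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$sample,
                                        y = .data$amplitude,
                                        group = .data$spike)) +
    ggplot2::labs(x = "sample", y = "amplitude (quantized)",
                  title = sprintf("channel %s", object$channel_id))
  if ("label" %in% names(df)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$label),
                                alpha = 0.4)
  } else {
    p <- p + ggplot2::geom_line(alpha = 0.4)
  }
  p
}

#' Split a labeled spike matrix into stratified halves
#'
#' Splits per class so both halves preserve the class proportions
#' (the even train/test breakdown used throughout the package).
#'
#' @param matrix A labeled `spike_matrix`.
#' @param train_frac Fraction assigned to the training half (default 0.5).
#' @param seed Integer seed controlling the within-class shuffle.
#' @return A list with `train` and `test` spike matrices.
#' @export
split_spike_matrix <- function(matrix, train_frac = 0.5, seed = 1) {
  stopifnot(inherits(matrix, "spike_matrix"))
  if (is.null(matrix$labels)) stop("split requires labels", call. = FALSE)
  rng <- local_rng(seed)
  idx_train <- integer(0)
  for (cl in sort(unique(matrix$labels))) {
    rows <- which(matrix$labels == cl)
    rows <- rows[sample.int(length(rows))]
    n_tr <- max(1L, floor(length(rows) * train_frac))
    idx_train <- c(idx_train, rows[seq_len(n_tr)])
  }
  idx_train <- sort(idx_train)
  idx_test <- setdiff(seq_len(nrow(matrix$waveforms)), idx_train)
  list(
    train = subset_spikes(matrix, idx_train),
    test = subset_spikes(matrix, idx_test)
  )
}

subset_spikes <- function(matrix, rows) {
  spike_matrix(matrix$waveforms[rows, , drop = FALSE],
               labels = if (is.null(matrix$labels)) NULL else
                 matrix$labels[rows],
               channel_id = matrix$channel_id,
               sample_rate_hz = matrix$sample_rate_hz)
}

# Run code under a private RNG state seeded with `seed`, restoring the
# caller's state on exit of the calling function.
local_rng <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  withr::defer({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, envir = envir)
  invisible(NULL)
}
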