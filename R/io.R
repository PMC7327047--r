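#' Write a spike matrix to disk
#'
#' Two formats are supported: delimited text (`"csv"`) with one spike per
#' row and an optional trailing `label` column, and flat little-endian
#' binary (`"bin"`) with a JSON sidecar (`<path>.json`) recording dtype,
#' shape, labels, and sampling rate.
#'
#' @param matrix A `spike_matrix`.
#' @param path Output file path.
#' @param format `"csv"` or `"bin"`.
#' @return `path`, invisibly.
#' @export
write_spike_matrix <- function(matrix, path, format = c("csv", "bin")) {
  stopifnot(inherits(matrix, "spike_matrix"))
  format <- match.arg(format)
  w <- matrix$waveforms
  if (format == "csv") {
    df <- as.data.frame(w)
    names(df) <- sprintf("s%d", seq_len(ncol(w)) - 1L)
    if (!is.null(matrix$labels)) df$label <- matrix$labels
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    # row-major so each spike is a contiguous record
    writeBin(as.integer(t(w)), con, size = 2L, endian = "little")
    sidecar <- list(
      dtype = "int16", n_spikes = nrow(w), n_samples = ncol(w),
      labels = matrix$labels, channel_id = matrix$channel_id,
      sample_rate_hz = matrix$sample_rate_hz
    )
    jsonlite::write_json(sidecar, paste0(path, ".json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  invisible(path)
}

#' Read a spike matrix from disk
#'
#' @param path File path written by [write_spike_matrix()].
#' @param format `"csv"` or `"bin"`.
#' @param sample_rate_hz Sampling rate for csv input (binary input takes
#'   it from the sidecar).
#' @return A `spike_matrix`.
#' @export
read_spike_matrix <- function(path, format = c("csv", "bin"),
                              sample_rate_hz = 30000) {
  format <- match.arg(format)
  if (format == "csv") {
    lines <- readLines(path)
    if (length(lines) == 0) stop("empty file: ", path, call. = FALSE)
    fields <- strsplit(lines, ",", fixed = TRUE)
    header <- fields[[1]]
    has_header <- any(is.na(suppressWarnings(as.numeric(header))))
    has_label <- if (has_header) tolower(header[length(header)]) == "label"
      else FALSE
    body <- if (has_header) fields[-1] else fields
    if (length(body) == 0) {
      if (!has_header) stop("no data rows in ", path, call. = FALSE)
      k <- length(header) - as.integer(has_label)
      return(spike_matrix(matrix(integer(0), 0, k),
                          sample_rate_hz = sample_rate_hz))
    }
    widths <- lengths(body)
    if (length(unique(widths)) != 1) {
      bad <- which(widths != widths[1])[1]
      stop(sprintf(
        "ragged delimited file %s: row %d has %d fields, expected %d",
        path, bad + has_header, widths[bad], widths[1]), call. = FALSE)
    }
    ncol_total <- widths[1]
    if (!has_header) {
      # no header: a non-numeric final field marks a label column
      has_label <- is.na(suppressWarnings(
        as.numeric(body[[1]][ncol_total])))
    }
    k <- ncol_total - as.integer(has_label)
    labels <- if (has_label)
      vapply(body, function(r) r[ncol_total], character(1)) else NULL
    vals <- vapply(body, function(r) {
      v <- suppressWarnings(as.numeric(r[seq_len(k)]))
      v
    }, numeric(k))
    vals <- if (k == 1) matrix(vals, ncol = 1) else t(vals)
    if (anyNA(vals)) {
      bad <- which(apply(vals, 1, anyNA))[1]
      stop(sprintf("non-numeric waveform value in %s at data row %d",
                   path, bad), call. = FALSE)
    }
    spike_matrix(vals, labels = labels, sample_rate_hz = sample_rate_hz)
  } else {
    sc_path <- paste0(path, ".json")
    if (!file.exists(sc_path)) {
      stop("missing JSON sidecar: ", sc_path, call. = FALSE)
    }
    sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
    if (!identical(sc$dtype, "int16")) {
      stop("unsupported dtype in sidecar: ", sc$dtype, call. = FALSE)
    }
    n <- as.integer(sc$n_spikes); k <- as.integer(sc$n_samples)
    expected_bytes <- n * k * 2L
    actual_bytes <- file.size(path)
    if (actual_bytes != expected_bytes) {
      stop(sprintf(
        "sidecar shape %d x %d implies %d bytes but %s has %d bytes",
        n, k, expected_bytes, path, actual_bytes), call. = FALSE)
    }
    con <- file(path, "rb")
    on.exit(close(con))
    raw_vals <- readBin(con, "integer", n = n * k, size = 2L,
                        signed = TRUE, endian = "little")
    labels <- sc$labels
    if (!is.null(labels) && length(labels) == 0) labels <- NULL
    spike_matrix(matrix(raw_vals, nrow = n, byrow = TRUE),
                 labels = labels,
                 channel_id = sc$channel_id %||% "ch0",
                 sample_rate_hz = sc$sample_rate_hz %||% sample_rate_hz)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
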