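#' Bit widths of the on-implant sorter
#'
#' Register and comparator widths of the online spike sorter: a 5-bit
#' index comparator selects the stored salient-feature position and two
#' 7-bit comparators test the window bounds; samples arrive at 8 bits.
#' The 5-bit index register constrains salient features to a 32-sample
#' sub-window of the spike, which is why the feature-selection step has
#' an emulator-compatible restricted search mode.
#'
#' @param index_bits Feature-index register width (default 5).
#' @param bound_bits Window-bound register width (default 7).
#' @param classid_bits Class-identifier register width (default 3).
#' @param sample_bits Sample resolution (default 8).
#' @return A `bit_widths` list.
#' @export
bit_widths <- function(index_bits = 5, bound_bits = 7, classid_bits = 3,
                       sample_bits = 8) {
  w <- list(index_bits = as.integer(index_bits),
            bound_bits = as.integer(bound_bits),
            classid_bits = as.integer(classid_bits),
            sample_bits = as.integer(sample_bits))
  if (any(unlist(w) < 1)) stop("all widths must be >= 1", call. = FALSE)
  structure(w, class = "bit_widths")
}

#' Register banks shared across channels
#'
#' @param n_classes Total stored classes across all channels
#'   (default 512).
#' @param features_per_class Salient features per class (default 2).
#' @param widths A [bit_widths()].
#' @return A `register_banks` list with the derived per-bank bit counts:
#'   `index_bank_bits = n_classes * features_per_class * index_bits`,
#'   `bound_bank_bits = n_classes * features_per_class * 2 * bound_bits`
#'   (upper and lower per feature), and
#'   `classid_bank_bits = n_classes * features_per_class * classid_bits`.
#' @export
register_banks <- function(n_classes = 512, features_per_class = 2,
                           widths = bit_widths()) {
  n_classes <- as.integer(n_classes)
  features_per_class <- as.integer(features_per_class)
  structure(list(
    n_classes = n_classes,
    features_per_class = features_per_class,
    index_bank_bits = n_classes * features_per_class *
      widths$index_bits,
    bound_bank_bits = n_classes * features_per_class * 2L *
      widths$bound_bits,
    classid_bank_bits = n_classes * features_per_class *
      widths$classid_bits
  ), class = "register_banks")
}

#' Memory budget of the on-implant register banks
#'
#' @param banks A [register_banks()].
#' @param widths A [bit_widths()] (recorded in the report).
#' @return A tibble: per-bank bits, `total_bits`, and each bank in
#'   kibibits (bits / 1024).
#' @export
memory_report <- function(banks = register_banks(),
                          widths = bit_widths()) {
  tibble::tibble(
    index_bank_bits = banks$index_bank_bits,
    bound_bank_bits = banks$bound_bank_bits,
    classid_bank_bits = banks$classid_bank_bits,
    total_bits = banks$index_bank_bits + banks$bound_bank_bits +
      banks$classid_bank_bits,
    index_bank_kibit = banks$index_bank_bits / 1024,
    bound_bank_kibit = banks$bound_bank_bits / 1024,
    classid_bank_kibit = banks$classid_bank_bits / 1024
  )
}

#' Quantize a sorter configuration for the implant
#'
#' Maps window bounds onto the `bound_bits`-wide signed grid over
#' `[-full_scale, +full_scale)`: the grid step is
#' `full_scale / 2^(bound_bits - 1)`, lower bounds round down and upper
#' bounds round up, so the quantized window always contains the trained
#' one (classification can gain spurious matches under quantization but
#' never lose a true one). Feature indices are stored verbatim and must
#' fit `index_bits`; class identifiers are assigned in label order and
#' must fit `classid_bits`.
#'
#' @param config A `sorter_config`.
#' @param widths A [bit_widths()].
#' @param full_scale Amplitude full scale; defaults to
#'   `2^(sample_bits - 1)` so the bound grid aligns with the sample
#'   grid (step 2 for 8-bit samples against 7-bit bounds — the sample
#'   LSB is effectively ignored at the comparator).
#' @return A `quantized_config`: list with `channel_id`, `K`, `L`,
#'   `step` (grid step in sample units), `widths`, and `windows`
#'   (per class: `class`, `class_id`, `feature_indices`, `lower_q`,
#'   `upper_q` — register values on the bound grid).
#' @export
quantize_config <- function(config, widths = bit_widths(),
                            full_scale = 2^(widths$sample_bits - 1)) {
  stopifnot(inherits(config, "sorter_config"))
  idx_max <- 2^widths$index_bits
  b_top <- 2^(widths$bound_bits - 1) - 1
  b_bot <- -2^(widths$bound_bits - 1)
  step <- full_scale / 2^(widths$bound_bits - 1)
  classes <- vapply(config$windows, `[[`, character(1), "class")
  if (length(classes) > 2^widths$classid_bits) {
    stop("too many classes for classid_bits", call. = FALSE)
  }
  windows <- lapply(seq_along(config$windows), function(i) {
    w <- config$windows[[i]]
    if (any(w$feature_indices >= idx_max)) {
      bad <- w$feature_indices[w$feature_indices >= idx_max][1]
      stop(sprintf(paste0(
        "feature index %d does not fit %d-bit index registers ",
        "(max %d); rerun salient feature selection with ",
        "max_feature = %d"), bad, widths$index_bits, idx_max - 1,
        idx_max), call. = FALSE)
    }
    lo_q <- pmax(b_bot, pmin(b_top, floor(w$lower / step)))
    hi_q <- pmax(b_bot, pmin(b_top, ceiling(w$upper / step)))
    list(class = w$class, class_id = i - 1L,
         feature_indices = as.integer(w$feature_indices),
         lower_q = as.integer(lo_q), upper_q = as.integer(hi_q))
  })
  names(windows) <- classes
  structure(list(channel_id = config$channel_id, K = config$K,
                 L = config$L, step = step, widths = widths,
                 windows = windows),
            class = "quantized_config")
}

#' Dequantize a configuration back to amplitude units
#'
#' @param qconfig A `quantized_config`.
#' @return A `sorter_config` whose bounds sit on the quantized grid.
#' @export
dequantize_config <- function(qconfig) {
  windows <- lapply(qconfig$windows, function(w) list(
    class = w$class, feature_indices = w$feature_indices,
    lower = w$lower_q * qconfig$step,
    upper = w$upper_q * qconfig$step, train_j = NA_real_))
  structure(list(channel_id = qconfig$channel_id, K = qconfig$K,
                 L = qconfig$L, windows = windows),
            class = "sorter_config")
}

#' Emulate the on-implant sorter on a spike matrix
#'
#' Behavioral model of the online spike sorter's comparator datapath:
#' per spike and per configured feature, the stored index selects a
#' sample and two bound comparators test
#' `lower_q * step <= sample <= upper_q * step` on the quantized grid.
#' All arithmetic is integer-only (the grid `step` must be a positive
#' integer, as it is for 8-bit samples against 7-bit bounds); conflict
#' resolution uses the same normalized-depth rule as the floating-point
#' path, evaluated in exact rational (integer numerator/denominator)
#' arithmetic.
#'
#' @param matrix A `spike_matrix` whose samples fit `sample_bits`.
#' @param qconfig A `quantized_config`.
#' @param widths A [bit_widths()] (defaults to the config's).
#' @return Character vector of resolved labels.
#' @export
emulate_sort <- function(matrix, qconfig, widths = qconfig$widths) {
  stopifnot(inherits(matrix, "spike_matrix"),
            inherits(qconfig, "quantized_config"))
  if (ncol(matrix$waveforms) != qconfig$K) {
    stop("matrix K does not match config", call. = FALSE)
  }
  s_top <- 2^(widths$sample_bits - 1) - 1
  s_bot <- -2^(widths$sample_bits - 1)
  w <- matrix$waveforms
  if (any(w > s_top | w < s_bot)) {
    stop("sample values exceed sample_bits signed range", call. = FALSE)
  }
  step <- qconfig$step
  if (step != as.integer(step) || step < 1) {
    stop("integer-only emulation requires an integer grid step",
         call. = FALSE)
  }
  step <- as.integer(step)
  vapply(seq_len(nrow(w)), function(r) {
    emulate_one(w[r, ], qconfig, step)
  }, character(1))
}

emulate_one <- function(spike, qconfig, step) {
  best_label <- NULL
  best_num <- 0L; best_den <- 1L
  n_match <- 0L
  for (wd in qconfig$windows) {
    x <- spike[wd$feature_indices + 1L]
    lo <- wd$lower_q * step
    hi <- wd$upper_q * step
    if (any(x < lo | x > hi)) next
    n_match <- n_match + 1L
    # depth_l = 1 - |x - c|/hw = (width - |2x - (lo+hi)|) / width with
    # width = hi - lo; kept as an exact integer fraction num/den
    num <- 1L; den <- 1L
    for (l in seq_along(x)) {
      width <- hi[l] - lo[l]
      if (width == 0L) next                # zero-width dim: depth 1
      a <- width - abs(2L * x[l] - (lo[l] + hi[l]))
      b <- width
      # keep the smaller fraction a/b vs num/den
      if (a * den < num * b) { num <- a; den <- b }
    }
    if (is.null(best_label) ||
        num * best_den > best_num * den ||
        (num * best_den == best_num * den && wd$class < best_label)) {
      best_label <- wd$class
      best_num <- num; best_den <- den
    }
  }
  if (n_match == 0L) "UNCLASSIFIED" else best_label
}

#' Serialize a quantized configuration as a register image
#'
#' Writes the register contents as flat hexadecimal words (one line per
#' register, two's-complement within each declared width) plus a JSON
#' memory map describing the layout.
#'
#' @param qconfig A `quantized_config`.
#' @param path Output path for the hex image; the memory map goes to
#'   `<path>.map.json`.
#' @return `path`, invisibly.
#' @export
write_register_image <- function(qconfig, path) {
  wdt <- qconfig$widths
  to_hex <- function(value, bits) {
    v <- as.integer(value)
    if (v < 0) v <- v + 2^bits           # two's complement
    sprintf(paste0("%0", ceiling(bits / 4), "X"), v)
  }
  lines <- character(0)
  layout <- list()
  for (wd in qconfig$windows) {
    for (l in seq_along(wd$feature_indices)) {
      lines <- c(lines,
                 to_hex(wd$feature_indices[l], wdt$index_bits),
                 to_hex(wd$lower_q[l], wdt$bound_bits),
                 to_hex(wd$upper_q[l], wdt$bound_bits),
                 to_hex(wd$class_id, wdt$classid_bits))
      layout[[length(layout) + 1]] <- list(
        class = wd$class, dim = l - 1,
        registers = c("index", "lower", "upper", "class_id"))
    }
  }
  writeLines(lines, path)
  jsonlite::write_json(
    list(channel_id = qconfig$channel_id, step = qconfig$step,
         widths = unclass(wdt), record_order = layout),
    paste0(path, ".map.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.quantized_config <- function(x, ...) {
  cat(sprintf(
    "<quantized_config> channel '%s', %d classes, L = %d, step = %g\n",
    x$channel_id, length(x$windows), x$L, x$step))
  invisible(x)
}

#' @export
tidy.quantized_config <- function(x, ...) {
  purrr::map_dfr(x$windows, function(w) tibble::tibble(
    class = w$class, class_id = w$class_id,
    dim = seq_along(w$feature_indices),
    feature = w$feature_indices,
    lower_q = w$lower_q, upper_q = w$upper_q,
    lower = w$lower_q * x$step, upper = w$upper_q * x$step))
}
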