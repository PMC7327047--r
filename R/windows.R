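#' Fit per-class discrimination windows
#'
#' Each class gets one axis-aligned window in its own salient feature
#' space: per salient feature, a closed interval `[lower, upper]`. A
#' spike matches the class iff every salient-feature value falls inside
#' its interval. Bounds are initialized at the class's (`p_lo`, `p_hi`)
#' percentiles and, when `refine = TRUE`, improved by a coordinate-wise
#' grid search over the class's order statistics that maximizes the
#' one-vs-rest balanced accuracy
#' `J = (in-window rate of the class + out-of-window rate of the rest)/2`,
#' breaking ties toward the wider window, iterated to convergence or at
#' most `max_sweeps` sweeps. Because J is flat while a bound moves
#' through empty amplitude space, refinement finishes with a margin
#' step that pushes each bound halfway toward the nearest competing
#' spike beyond it (or to the pooled data range when none exists),
#' which changes nothing on the training set but keeps held-out spikes
#' from dropping off the window edge.
#'
#' @param matrix Labeled training `spike_matrix`.
#' @param feature_sets Named list of `salient_feature_set`, one per
#'   class (e.g. from [select_all_features()]).
#' @param p_lo,p_hi Percentile bounds for initialization (defaults 1
#'   and 99).
#' @param refine Run the balanced-accuracy refinement (default `TRUE`).
#' @param max_sweeps Maximum refinement sweeps (default 10).
#' @return A `sorter_config`: list with `channel_id`, `K`, `L`, and
#'   `windows` — a list per class of `class`, `feature_indices`
#'   (0-based), `lower`, `upper`, `train_j`.
#' @export
fit_windows <- function(matrix, feature_sets, p_lo = 1, p_hi = 99,
                        refine = TRUE, max_sweeps = 10) {
  stopifnot(inherits(matrix, "spike_matrix"))
  if (is.null(matrix$labels)) stop("training matrix must be labeled",
                                   call. = FALSE)
  if (!(p_lo >= 0 && p_lo < p_hi && p_hi <= 100)) {
    stop("need 0 <= p_lo < p_hi <= 100", call. = FALSE)
  }
  classes <- sort(unique(matrix$labels))
  missing_sets <- setdiff(classes, names(feature_sets))
  if (length(missing_sets) > 0) {
    stop("no feature set for class(es): ",
         paste(missing_sets, collapse = ", "), call. = FALSE)
  }
  windows <- lapply(classes, function(cl) {
    fs <- feature_sets[[cl]]
    own <- matrix$waveforms[matrix$labels == cl, fs$indices + 1,
                            drop = FALSE]
    if (nrow(own) < 2) {
      stop(sprintf("class '%s' has < 2 training spikes", cl),
           call. = FALSE)
    }
    rest <- matrix$waveforms[matrix$labels != cl, fs$indices + 1,
                             drop = FALSE]
    lower <- apply(own, 2, stats::quantile, probs = p_lo / 100,
                   type = 1, names = FALSE)
    upper <- apply(own, 2, stats::quantile, probs = p_hi / 100,
                   type = 1, names = FALSE)
    if (refine) {
      ref <- refine_window(own, rest, lower, upper, max_sweeps)
      lower <- ref$lower; upper <- ref$upper
    }
    list(class = cl, feature_indices = fs$indices,
         lower = as.numeric(lower), upper = as.numeric(upper),
         train_j = window_j(own, rest, lower, upper))
  })
  names(windows) <- classes
  structure(list(channel_id = matrix$channel_id,
                 K = ncol(matrix$waveforms),
                 L = windows[[1]]$feature_indices |> length(),
                 windows = windows),
            class = "sorter_config")
}

# balanced accuracy of the rectangle [lower, upper] on own vs rest rows
window_j <- function(own, rest, lower, upper) {
  inside <- function(m) {
    if (nrow(m) == 0) return(logical(0))
    ok <- rep(TRUE, nrow(m))
    for (l in seq_along(lower)) {
      ok <- ok & m[, l] >= lower[l] & m[, l] <= upper[l]
    }
    ok
  }
  tpr <- if (nrow(own) > 0) mean(inside(own)) else 0
  tnr <- if (nrow(rest) > 0) mean(!inside(rest)) else 1
  (tpr + tnr) / 2
}

# Coordinate-wise search: per dimension, scan all (lo, hi) pairs of the
# class's order statistics with the other dimensions' bounds fixed.
# Counting is done on sorted projections so each pair costs O(log n).
refine_window <- function(own, rest, lower, upper, max_sweeps) {
  L <- length(lower)
  n_own <- nrow(own); n_rest <- nrow(rest)
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (l in seq_len(L)) {
      other <- setdiff(seq_len(L), l)
      mask_own <- rep(TRUE, n_own)
      mask_rest <- rep(TRUE, n_rest)
      for (m in other) {
        mask_own <- mask_own & own[, m] >= lower[m] & own[, m] <= upper[m]
        if (n_rest > 0) {
          mask_rest <- mask_rest & rest[, m] >= lower[m] &
            rest[, m] <= upper[m]
        }
      }
      x_own <- sort(own[mask_own, l])
      x_rest <- sort(rest[mask_rest, l])
      cand <- sort(unique(own[, l]))
      nc <- length(cand)
      pairs_lo <- rep(cand, times = nc:1)
      pairs_hi <- unlist(lapply(seq_len(nc), function(i) cand[i:nc]))
      count_in <- function(xs, lo, hi) {
        if (length(xs) == 0) return(rep(0L, length(lo)))
        findInterval(hi, xs) - findInterval(lo - 0.5, xs)
      }
      tp <- count_in(x_own, pairs_lo, pairs_hi)
      fp <- count_in(x_rest, pairs_lo, pairs_hi)
      j_vals <- (tp / n_own + (n_rest - fp) / max(n_rest, 1)) / 2
      width <- pairs_hi - pairs_lo
      best <- order(-j_vals, -width)[1]   # ties -> wider window
      if (pairs_lo[best] != lower[l] || pairs_hi[best] != upper[l]) {
        cur_j <- window_j(own, rest, lower, upper)
        if (j_vals[best] > cur_j ||
            (j_vals[best] == cur_j &&
             width[best] > (upper[l] - lower[l]))) {
          lower[l] <- pairs_lo[best]
          upper[l] <- pairs_hi[best]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  # Margin step: the training objective is flat while a bound moves
  # through empty amplitude space, so push each bound halfway toward
  # the nearest competing spike beyond it (or to the pooled data range
  # when none is in the way). Training J is unchanged; held-out spikes
  # in the class's tails stop falling off the window edge.
  all_vals <- rbind(own, rest)
  for (l in seq_len(L)) {
    other <- setdiff(seq_len(L), l)
    mask_rest <- rep(TRUE, n_rest)
    for (m in other) {
      if (n_rest > 0) {
        mask_rest <- mask_rest & rest[, m] >= lower[m] &
          rest[, m] <= upper[m]
      }
    }
    xr <- rest[mask_rest, l]
    below <- xr[xr < lower[l]]
    above <- xr[xr > upper[l]]
    lower[l] <- if (length(below) > 0)
      (lower[l] + max(below)) / 2 else min(all_vals[, l])
    upper[l] <- if (length(above) > 0)
      (upper[l] + min(above)) / 2 else max(all_vals[, l])
  }
  list(lower = lower, upper = upper)
}

#' Classify one spike against a sorter configuration
#'
#' A class matches iff, for every salient feature l of that class,
#' `lower[l] <= waveform[index[l]] <= upper[l]` (closed intervals).
#' Conflicts among multiple matches are resolved by [resolve_label()].
#'
#' @param waveform Numeric vector of length K.
#' @param config A `sorter_config`.
#' @return A list: `matched_labels` (character), `resolved_label`
#'   (single label or `"UNCLASSIFIED"`), `depth_scores` (named, one per
#'   match, in `[0, 1]`).
#' @export
classify_spike <- function(waveform, config) {
  if (length(waveform) != config$K) {
    stop("waveform length does not match config K", call. = FALSE)
  }
  matches <- character(0)
  depths <- numeric(0)
  for (w in config$windows) {
    vals <- waveform[w$feature_indices + 1]
    if (all(vals >= w$lower & vals <= w$upper)) {
      matches <- c(matches, w$class)
      depths <- c(depths, window_depth(vals, w$lower, w$upper))
    }
  }
  names(depths) <- matches
  list(matched_labels = matches,
       resolved_label = resolve_label(matches, depths),
       depth_scores = depths)
}

# normalized depth: min over dims of 1 - |x - center| / half_width;
# zero-width dims count as depth 1 (x necessarily equals the bound).
window_depth <- function(vals, lower, upper) {
  hw <- (upper - lower) / 2
  ctr <- (upper + lower) / 2
  per_dim <- ifelse(hw > 0, 1 - abs(vals - ctr) / hw, 1)
  min(per_dim)
}

#' Resolve multiple window matches to one label
#'
#' No match yields `"UNCLASSIFIED"`; a single match is returned as-is;
#' among several matches the label with maximal normalized depth wins,
#' ties going to the smallest class label.
#'
#' @param matches Character vector of matched class labels.
#' @param depths Named numeric depth per match.
#' @return A single label or `"UNCLASSIFIED"`.
#' @export
resolve_label <- function(matches, depths) {
  if (length(matches) == 0) return("UNCLASSIFIED")
  if (length(matches) == 1) return(matches)
  ord <- order(-depths, matches)
  matches[ord[1]]
}

#' Sort a stream of spikes
#'
#' Row-wise, stateless classification of every spike in a matrix.
#'
#' @param matrix A `spike_matrix` (labels ignored if present).
#' @param config A `sorter_config`.
#' @return Character vector of resolved labels, one per spike.
#' @export
sort_stream <- function(matrix, config) {
  stopifnot(inherits(matrix, "spike_matrix"))
  if (ncol(matrix$waveforms) != config$K) {
    stop("matrix has K = ", ncol(matrix$waveforms),
         " but config expects K = ", config$K, call. = FALSE)
  }
  vapply(seq_len(nrow(matrix$waveforms)), function(i)
    classify_spike(matrix$waveforms[i, ], config)$resolved_label,
    character(1))
}

#' @export
print.sorter_config <- function(x, ...) {
  cat(sprintf("<sorter_config> channel '%s', %d classes, L = %d, K = %d\n",
              x$channel_id, length(x$windows), x$L, x$K))
  for (w in x$windows) {
    cat(sprintf("  %s: features [%s], J = %.3f\n", w$class,
                paste(w$feature_indices, collapse = ", "), w$train_j))
  }
  invisible(x)
}

#' @export
tidy.sorter_config <- function(x, ...) {
  purrr::map_dfr(x$windows, function(w) tibble::tibble(
    class = w$class, dim = seq_along(w$feature_indices),
    feature = w$feature_indices, lower = w$lower, upper = w$upper,
    train_j = w$train_j))
}

#' @export
glance.sorter_config <- function(x, ...) {
  tibble::tibble(channel_id = x$channel_id,
                 n_classes = length(x$windows), L = x$L, K = x$K,
                 mean_train_j = mean(vapply(x$windows, `[[`, numeric(1),
                                            "train_j")))
}

#' Plot discrimination windows over training data
#'
#' For `L = 2` configurations, scatter each class's training spikes in
#' every class's salient feature plane with its window rectangle.
#'
#' @param object A `sorter_config`.
#' @param matrix The labeled training `spike_matrix` to scatter.
#' @param ... Unused.
#' @return A ggplot object faceted by window class.
#' @export
autoplot.sorter_config <- function(object, matrix, ...) {
  stopifnot(object$L == 2)
  pts <- purrr::map_dfr(object$windows, function(w) tibble::tibble(
    window_class = w$class,
    x = matrix$waveforms[, w$feature_indices[1] + 1],
    y = matrix$waveforms[, w$feature_indices[2] + 1],
    label = matrix$labels))
  rects <- tidy(object) |>
    tidyr::pivot_wider(id_cols = "class",
                       names_from = "dim",
                       values_from = c("lower", "upper"))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label),
                        alpha = 0.5, size = 0.8) +
    ggplot2::geom_rect(data = rects,
                       ggplot2::aes(xmin = .data$lower_1,
                                    xmax = .data$upper_1,
                                    ymin = .data$lower_2,
                                    ymax = .data$upper_2),
                       inherit.aes = FALSE, fill = NA,
                       colour = "black", linetype = "dashed") +
    ggplot2::facet_wrap(~window_class, scales = "free") +
    ggplot2::labs(x = "salient feature 1", y = "salient feature 2")
}

#' Write / read a sorter configuration as JSON
#'
#' @param config A `sorter_config`.
#' @param path File path.
#' @return `path` invisibly (write); a `sorter_config` (read).
#' @export
write_sorter_config <- function(config, path) {
  payload <- list(
    channel_id = config$channel_id, L = config$L, K = config$K,
    windows = lapply(unname(config$windows), function(w) list(
      class = w$class, indices = w$feature_indices,
      lower = w$lower, upper = w$upper)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sorter_config
#' @export
read_sorter_config <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  wlist <- lapply(seq_len(nrow(p$windows)), function(i) list(
    class = p$windows$class[i],
    feature_indices = as.integer(p$windows$indices[[i]]),
    lower = as.numeric(p$windows$lower[[i]]),
    upper = as.numeric(p$windows$upper[[i]]),
    train_j = NA_real_))
  names(wlist) <- p$windows$class
  structure(list(channel_id = p$channel_id, K = p$K, L = p$L,
                 windows = wlist), class = "sorter_config")
}
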