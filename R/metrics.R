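#' Per-class classification accuracy
#'
#' Per-class CA is the recall of the class: the fraction of its test
#' spikes given the correct label (an `"UNCLASSIFIED"` output counts as
#' wrong). The chance level of a class is its empirical relative
#' frequency in the test set — the expected recall of proportional
#' random guessing — and the chance-level-independent accuracy rescales
#' CA so that chance maps to 0 and perfection to 1.
#'
#' @param true_labels,predicted_labels Equal-length character vectors.
#' @return An `eval_report` tibble with one row per class: `class`,
#'   `n_test`, `ca`, `chance`, `ca_cli`; attributes `overall_ca`
#'   (spike-weighted), `overall_ca_macro` (class-weighted), and
#'   `overall_ca_cli` (mean per-class ca_cli).
#' @export
classification_accuracy <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  classes <- sort(unique(true_labels))
  chance <- chance_level(true_labels)
  per <- purrr::map_dfr(classes, function(cl) {
    idx <- true_labels == cl
    tibble::tibble(
      class = cl, n_test = sum(idx),
      ca = mean(predicted_labels[idx] == cl),
      chance = chance[[cl]]
    )
  })
  per$ca_cli <- (per$ca - per$chance) / (1 - per$chance)
  out <- per
  attr(out, "overall_ca") <- sum(per$ca * per$n_test) / sum(per$n_test)
  attr(out, "overall_ca_macro") <- mean(per$ca)
  attr(out, "overall_ca_cli") <- mean(per$ca_cli)
  class(out) <- c("eval_report", class(out))
  out
}

#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    overall_ca = attr(x, "overall_ca"),
    overall_ca_macro = attr(x, "overall_ca_macro"),
    overall_ca_cli = attr(x, "overall_ca_cli"),
    n_classes = nrow(x),
    n_test = sum(x$n_test)
  )
}

#' Chance level per class
#'
#' @param test_labels Character vector of test-set labels.
#' @return Named numeric vector of empirical class frequencies.
#' @export
chance_level <- function(test_labels) {
  if (length(test_labels) == 0) stop("empty label vector", call. = FALSE)
  tab <- table(test_labels)
  stats::setNames(as.numeric(tab) / length(test_labels), names(tab))
}

#' Chance-level-independent classification accuracy
#'
#' `ca_cli = (ca - chance) / (1 - chance)`: 0 at chance performance,
#' 1 at perfection, negative below chance.
#'
#' @param ca Classification accuracy in `[0, 1]`.
#' @param chance Chance level in `[0, 1)`.
#' @return Numeric (vectorized).
#' @export
ca_cli <- function(ca, chance) {
  if (any(chance >= 1)) stop("chance must be < 1", call. = FALSE)
  (ca - chance) / (1 - chance)
}

#' Gaussian naive Bayes classification
#'
#' Reference classifier for validating feature sets: per class and per
#' feature a Gaussian likelihood (sample mean, variance floored at
#' `1e-9` times the mean feature variance to survive quantized data),
#' class priors from training frequencies, prediction by maximum
#' posterior over the chosen features. Ties break toward the smallest
#' label.
#'
#' @param train Labeled `spike_matrix` (>= 2 spikes per class).
#' @param test `spike_matrix` to classify.
#' @param feature_indices Optional 0-based feature subset (all K when
#'   `NULL`).
#' @return Character vector of predicted labels.
#' @export
bayes_classify <- function(train, test, feature_indices = NULL) {
  feats <- if (is.null(feature_indices)) seq_len(ncol(train$waveforms))
    else as.integer(feature_indices) + 1L
  nb_train_predict(train$waveforms[, feats, drop = FALSE],
                   train$labels,
                   test$waveforms[, feats, drop = FALSE])
}

# Gaussian naive Bayes on plain numeric feature matrices (also drives
# the static-feature baselines).
nb_train_predict <- function(xtr, ytr, xte) {
  storage.mode(xtr) <- "double"
  storage.mode(xte) <- "double"
  classes <- sort(unique(ytr))
  floor_var <- 1e-9 * mean(apply(xtr, 2, stats::var))
  if (!is.finite(floor_var) || floor_var <= 0) floor_var <- 1e-12
  scores <- vapply(classes, function(cl) {
    rows <- xtr[ytr == cl, , drop = FALSE]
    if (nrow(rows) < 2) {
      stop(sprintf("class '%s' needs >= 2 training spikes", cl),
           call. = FALSE)
    }
    mu <- colMeans(rows)
    v <- pmax(apply(rows, 2, stats::var), floor_var)
    lp <- log(nrow(rows) / nrow(xtr))
    ll <- -0.5 * colSums((t(xte) - mu)^2 / v) -
      0.5 * sum(log(2 * pi * v))
    lp + ll
  }, numeric(nrow(xte)))
  scores <- matrix(scores, nrow = nrow(xte),
                   dimnames = list(NULL, classes))
  classes[apply(scores, 1, which.max)]   # ties -> smallest label
}

#' Static waveform features
#'
#' Simplified reconstructions of common hardware-friendly static
#' feature extractors, used as baselines:
#' \itemize{
#'   \item `SDE` — spike and derivative extrema: peak-to-peak amplitude,
#'     max and min of the first difference.
#'   \item `FSDE` — first and second derivative extrema: max/min of the
#'     first and of the second difference.
#'   \item `DDsE` — discrete-derivative extrema at lags 1, 3, 7 (max and
#'     min of each lagged difference).
#'   \item `ZCF` — zero-crossing features: 0-based indices of the first
#'     two zero crossings after the trough, plus the trough amplitude.
#' }
#' These follow the one-line definitions used when comparing selection
#' strategies, not the full pipelines of the methods they echo.
#'
#' @param matrix A `spike_matrix` with K >= 4.
#' @param method One of `"SDE"`, `"FSDE"`, `"DDsE"`, `"ZCF"`.
#' @return Numeric feature matrix, one row per spike.
#' @export
static_features <- function(matrix, method = c("SDE", "FSDE", "DDsE",
                                               "ZCF")) {
  method <- match.arg(method)
  x <- matrix$waveforms
  storage.mode(x) <- "double"
  if (ncol(x) < 4) stop("need K >= 4", call. = FALSE)
  one <- function(v) {
    switch(method,
      SDE = {
        d1 <- diff(v)
        c(max(v) - min(v), max(d1), min(d1))
      },
      FSDE = {
        d1 <- diff(v); d2 <- diff(d1)
        c(max(d1), min(d1), max(d2), min(d2))
      },
      DDsE = {
        unlist(lapply(c(1, 3, 7), function(lag) {
          d <- v[-seq_len(lag)] - v[seq_len(length(v) - lag)]
          c(max(d), min(d))
        }))
      },
      ZCF = {
        trough <- which.min(v)
        after <- v[trough:length(v)]
        sign_after <- sign(after)
        zc <- which(sign_after[-1] * sign_after[-length(sign_after)] <= 0 &
                      sign_after[-1] != sign_after[-length(sign_after)])
        zc_abs <- trough - 2L + zc  # 0-based last sample before change
        c(if (length(zc_abs) >= 1) zc_abs[1] else length(v) - 1,
          if (length(zc_abs) >= 2) zc_abs[2] else length(v) - 1,
          v[trough])
      })
  }
  t(apply(x, 1, one))
}

#' CA-versus-CA regression
#'
#' Ordinary least squares of one method's accuracies on a reference
#' method's accuracies across channels, plus the Pearson correlation —
#' the standard diagnostic for how much a feature-selection front-end
#' buffers the classifier against signal variability (slope < 1 means
#' the method's accuracy degrades more slowly than the reference's).
#'
#' @param ca_reference,ca_method Equal-length numeric vectors (n >= 2).
#' @return A tibble: `slope`, `intercept`, `r`, `n`.
#' @export
ca_ca_regression <- function(ca_reference, ca_method) {
  if (length(ca_reference) != length(ca_method) ||
      length(ca_reference) < 2) {
    stop("need two equal-length vectors with n >= 2", call. = FALSE)
  }
  if (stats::sd(ca_reference) == 0) {
    stop("reference accuracies are constant; slope undefined",
         call. = FALSE)
  }
  fit <- stats::lm(ca_method ~ ca_reference)
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    # Pearson r is undefined for a constant response
    r = if (stats::sd(ca_method) == 0) NA_real_ else
      stats::cor(ca_reference, ca_method),
    n = length(ca_reference)
  )
}

#' Correlation between log-saliency and chance-corrected accuracy
#'
#' @param log_saliencies,ca_cli_values Equal-length numeric vectors
#'   (n >= 3).
#' @return Pearson correlation coefficient.
#' @export
saliency_ca_correlation <- function(log_saliencies, ca_cli_values) {
  if (length(log_saliencies) != length(ca_cli_values) ||
      length(log_saliencies) < 3) {
    stop("need two equal-length vectors with n >= 3", call. = FALSE)
  }
  if (stats::sd(log_saliencies) == 0 || stats::sd(ca_cli_values) == 0) {
    stop("zero variance input", call. = FALSE)
  }
  stats::cor(log_saliencies, ca_cli_values)
}

#' Write an evaluation report to JSON or delimited text
#'
#' @param report An `eval_report`.
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  } else {
    payload <- list(
      per_class = lapply(seq_len(nrow(report)), function(i)
        as.list(report[i, ])),
      overall_ca = attr(report, "overall_ca"),
      overall_ca_macro = attr(report, "overall_ca_macro"),
      overall_ca_cli = attr(report, "overall_ca_cli"))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
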