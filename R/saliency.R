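#' Per-class feature statistics
#'
#' Computes, for every class in a labeled spike matrix, the per-feature
#' sample mean and sample standard deviation (n - 1 denominator) plus the
#' class prior (relative frequency in the data). These moments feed the
#' exponential class-discrimination index.
#'
#' @param matrix A labeled `spike_matrix` with at least two classes and
#'   at least two spikes per class.
#' @return A tibble with one row per (class, feature): columns `class`,
#'   `feature` (0-based), `mean`, `sd`, `prior`, `n`.
#' @export
estimate_class_stats <- function(matrix) {
  stopifnot(inherits(matrix, "spike_matrix"))
  if (is.null(matrix$labels)) stop("matrix must be labeled", call. = FALSE)
  classes <- sort(unique(matrix$labels))
  if (length(classes) < 2) stop("need >= 2 classes", call. = FALSE)
  n_total <- nrow(matrix$waveforms)
  purrr::map_dfr(classes, function(cl) {
    rows <- matrix$waveforms[matrix$labels == cl, , drop = FALSE]
    if (nrow(rows) < 2) {
      stop(sprintf("class '%s' has %d spike(s); need >= 2 to estimate",
                   cl, nrow(rows)), call. = FALSE)
    }
    tibble::tibble(
      class = cl,
      feature = 0:(ncol(rows) - 1),
      mean = colMeans(rows),
      sd = apply(rows, 2, stats::sd),
      prior = nrow(rows) / n_total,
      n = nrow(rows)
    )
  })
}

#' Exponential class-discrimination index
#'
#' For one feature, the separation of classes i and j is
#' `d_ij = exp(|mu_i - mu_j| / sqrt(P_i sigma_i^2 + P_j sigma_j^2))`,
#' the exponential of the prior-weighted standardized mean difference.
#' By construction `d_ij >= 1` and `d_ij = d_ji`. When both classes have
#' zero variance on the feature the exponent is 0/0 if the means also
#' coincide (returns 1) and is clipped at `e_max` otherwise, with a
#' `degenerate` flag.
#'
#' @param mean_i,mean_j Class means on the feature.
#' @param sd_i,sd_j Class standard deviations.
#' @param prior_i,prior_j Class priors.
#' @param e_max Exponent clip for degenerate (zero-variance) separations
#'   (default 30).
#' @return A numeric scalar with attribute `degenerate` (logical).
#' @export
discrimination_index <- function(mean_i, mean_j, sd_i, sd_j,
                                 prior_i, prior_j, e_max = 30) {
  num <- abs(mean_i - mean_j)
  den <- sqrt(prior_i * sd_i^2 + prior_j * sd_j^2)
  degenerate <- FALSE
  if (den == 0) {
    expo <- if (num == 0) 0 else { degenerate <- TRUE; e_max }
  } else {
    expo <- min(num / den, e_max)
  }
  structure(exp(expo), degenerate = degenerate)
}

# Vectorized d_ij over all K features for two stats blocks.
dij_vector <- function(mu_i, mu_j, sd_i, sd_j, p_i, p_j, e_max = 30) {
  num <- abs(mu_i - mu_j)
  den <- sqrt(p_i * sd_i^2 + p_j * sd_j^2)
  expo <- ifelse(den == 0, ifelse(num == 0, 0, e_max),
                 pmin(num / den, e_max))
  exp(expo)
}

#' Class saliency of a feature
#'
#' The saliency of class i on feature k combines how far the class sits
#' from every other class (weighted geometric mean of the discrimination
#' indices `d_ij[k]`) with how evenly it is separated from them (the
#' homogeneity, a geometric-to-arithmetic mean ratio):
#' \deqn{\varsigma_i[k] = \frac{\left(\prod_{j \ne i} d_{ij}[k]^{P_j}\right)^2}
#'   {\sum_{j \ne i} P_j \, d_{ij}[k]}}
#' The decomposition reported alongside uses the prior mass
#' `S = sum_{j != i} P_j`: `G = (prod d^(P_j))^(1/S)` and
#' `H = G / (sum P_j d / S)`, with `H = 1` exactly when all `d_ij[k]`
#' are equal (AM-GM equality).
#'
#' @param d Vector of discrimination indices `d_ij[k]`, one per other
#'   class j.
#' @param priors_other Priors `P_j` of the other classes, aligned with
#'   `d`.
#' @param renormalize If `TRUE`, rescale `priors_other` to sum to 1
#'   before evaluation (makes saliency equal `G * H` exactly); default
#'   `FALSE` uses the raw priors.
#' @return A list: `saliency`, `geo_mean` (G), `homogeneity` (H).
#' @export
class_saliency <- function(d, priors_other, renormalize = FALSE) {
  if (length(d) < 1) stop("need at least one other class", call. = FALSE)
  p <- priors_other
  if (renormalize) p <- p / sum(p)
  s_mass <- sum(p)
  log_wgm <- sum(p * log(d))             # log prod d^Pj
  geo <- exp(log_wgm / s_mass)
  arith <- sum(p * d) / s_mass
  list(
    saliency = exp(2 * log_wgm) / sum(p * d),
    geo_mean = geo,
    homogeneity = geo / arith
  )
}

#' Saliency profiles for every class
#'
#' Computes, per class, the full K-length discrimination, geometric-mean,
#' homogeneity, and saliency vectors over all features.
#'
#' @param matrix A labeled `spike_matrix`.
#' @param e_max Degenerate-variance exponent clip (default 30).
#' @param renormalize Weighting of the other classes (default `TRUE`:
#'   priors renormalized over the competing classes so their mass is 1,
#'   which makes the saliency equal the geometric-mean x homogeneity
#'   product exactly and keeps it increasing in every discrimination
#'   index regardless of the number of classes; `FALSE` evaluates the
#'   raw-prior form, which for two near-balanced classes is flat or
#'   even decreasing in separation).
#' @return A tibble of class `saliency_profile` with one row per
#'   (class, feature): `class`, `feature` (0-based), `geo_mean`,
#'   `homogeneity`, `saliency`, plus a `d` list-column holding the named
#'   vector of per-other-class discrimination indices.
#' @export
build_profiles <- function(matrix, e_max = 30, renormalize = TRUE) {
  stats_tbl <- estimate_class_stats(matrix)
  profiles_from_stats(stats_tbl, e_max = e_max,
                      renormalize = renormalize)
}

#' Saliency profiles from precomputed class statistics
#'
#' @param stats_tbl Output of [estimate_class_stats()].
#' @inheritParams build_profiles
#' @return As [build_profiles()].
#' @export
profiles_from_stats <- function(stats_tbl, e_max = 30,
                                renormalize = TRUE) {
  classes <- sort(unique(stats_tbl$class))
  if (length(classes) < 2) stop("need >= 2 classes", call. = FALSE)
  by_class <- split(stats_tbl, stats_tbl$class)
  by_class <- lapply(by_class, function(df) df[order(df$feature), ])
  K <- nrow(by_class[[1]])
  out <- purrr::map_dfr(classes, function(ci) {
    si <- by_class[[ci]]
    others <- setdiff(classes, ci)
    dmat <- vapply(others, function(cj) {
      sj <- by_class[[cj]]
      dij_vector(si$mean, sj$mean, si$sd, sj$sd,
                 si$prior[1], sj$prior[1], e_max)
    }, numeric(K))
    dmat <- matrix(dmat, nrow = K,
                   dimnames = list(NULL, others))
    p_other <- vapply(others, function(cj) by_class[[cj]]$prior[1],
                      numeric(1))
    comp <- lapply(seq_len(K), function(k)
      class_saliency(dmat[k, ], p_other, renormalize = renormalize))
    tibble::tibble(
      class = ci,
      feature = si$feature,
      geo_mean = vapply(comp, `[[`, numeric(1), "geo_mean"),
      homogeneity = vapply(comp, `[[`, numeric(1), "homogeneity"),
      saliency = vapply(comp, `[[`, numeric(1), "saliency"),
      d = lapply(seq_len(K), function(k) dmat[k, ])
    )
  })
  class(out) <- c("saliency_profile", class(out))
  out
}

#' Plot saliency profiles
#'
#' @param object A `saliency_profile` tibble from [build_profiles()].
#' @param what One of `"saliency"`, `"geo_mean"`, `"homogeneity"`.
#' @param ... Unused.
#' @return A ggplot object (log y scale for saliency).
#' @export
autoplot.saliency_profile <- function(object,
                                      what = c("saliency", "geo_mean",
                                               "homogeneity"), ...) {
  what <- match.arg(what)
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$feature,
                                    y = .data[[what]],
                                    colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "feature (sample index)", y = what)
  if (what == "saliency") p <- p + ggplot2::scale_y_log10()
  p
}

#' Within-class feature correlation
#'
#' Absolute Pearson correlation between two feature columns, computed
#' over the spikes of one class only (class-conditional by default).
#' Anti-correlated features are as redundant as correlated ones, hence
#' the absolute value. Returns 0 when either column is constant within
#' the class.
#'
#' @param matrix A labeled `spike_matrix`.
#' @param class_label The class whose spikes define the population.
#' @param kappa,h_feature 0-based feature indices.
#' @param pooled If `TRUE`, compute over all spikes instead of the
#'   class's spikes.
#' @return Absolute correlation in `[0, 1]`.
#' @export
feature_correlation <- function(matrix, class_label, kappa, h_feature,
                                pooled = FALSE) {
  w <- if (pooled) matrix$waveforms else
    matrix$waveforms[matrix$labels == class_label, , drop = FALSE]
  if (nrow(w) < 3) stop("need >= 3 spikes for correlation", call. = FALSE)
  x <- w[, kappa + 1]; y <- w[, h_feature + 1]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  abs(stats::cor(x, y))
}

#' Greedy salient feature selection
#'
#' Selects, for one class, the L features that maximize class saliency
#' while avoiding redundancy. The first feature is the most salient
#' feature (MSF), the plain saliency argmax. Each later step l maximizes
#' `saliency[kappa] * prod_{h<l} (1 - rho(kappa, k_h))` over the
#' remaining features, where rho is the class-conditional absolute
#' Pearson correlation with each already-selected feature. Ties break
#' toward the smallest feature index.
#'
#' @param matrix A labeled `spike_matrix`.
#' @param class_label Class to select features for.
#' @param L Number of features to select (1..K).
#' @param profile Optional precomputed [build_profiles()] tibble.
#' @param e_max Degenerate-variance exponent clip.
#' @param max_feature If not `NULL`, restrict the search to 0-based
#'   feature indices `< max_feature` (the emulator-compatible mode that
#'   keeps indices within a narrow hardware index register).
#' @param pooled_correlation Use pooled instead of class-conditional
#'   correlations.
#' @return A `salient_feature_set`: list with `class`, `indices`
#'   (0-based, length L), `criterion` (criterion value at each step),
#'   `saliencies` (saliency of each selected feature), `correlations`
#'   (L x L absolute correlation matrix among selected features), `K`,
#'   `L`.
#' @export
select_salient_features <- function(matrix, class_label, L = 2,
                                    profile = NULL, e_max = 30,
                                    max_feature = NULL,
                                    pooled_correlation = FALSE) {
  K <- ncol(matrix$waveforms)
  if (L < 1 || L > K) stop("L must be in 1..K", call. = FALSE)
  if (is.null(profile)) profile <- build_profiles(matrix, e_max = e_max)
  prof_i <- profile[profile$class == class_label, ]
  prof_i <- prof_i[order(prof_i$feature), ]
  if (nrow(prof_i) == 0) {
    stop("class not present in profile: ", class_label, call. = FALSE)
  }
  sal <- prof_i$saliency
  allowed <- rep(TRUE, K)
  if (!is.null(max_feature) && max_feature < K) {
    if (L > max_feature) stop("L exceeds the restricted search range",
                              call. = FALSE)
    allowed[(max_feature + 1):K] <- FALSE
  }
  w_class <- matrix$waveforms[matrix$labels == class_label, ,
                              drop = FALSE]
  if (pooled_correlation) w_class <- matrix$waveforms
  sds <- apply(w_class, 2, stats::sd)
  cor_with <- function(sel0) {
    # abs Pearson of every feature against selected feature (0-based)
    j <- sel0 + 1
    if (sds[j] == 0) return(rep(0, K))
    r <- suppressWarnings(
      as.vector(stats::cor(w_class, w_class[, j])))
    r[is.na(r)] <- 0
    abs(r)
  }
  chosen <- integer(0)
  crit_values <- numeric(0)
  penalty <- rep(1, K)
  for (step in seq_len(L)) {
    score <- sal * penalty
    score[!allowed] <- -Inf
    if (length(chosen) > 0) score[chosen + 1] <- -Inf
    best <- which.max(score)           # ties -> smallest index
    chosen <- c(chosen, best - 1L)
    crit_values <- c(crit_values, score[best])
    if (step < L) penalty <- penalty * (1 - cor_with(best - 1L))
  }
  cors <- diag(1, L)
  if (L > 1 && nrow(w_class) >= 3) {
    sub <- w_class[, chosen + 1, drop = FALSE]
    cm <- suppressWarnings(abs(stats::cor(sub)))
    cm[is.na(cm)] <- 0
    diag(cm) <- 1
    cors <- cm
  }
  structure(list(class = class_label, indices = chosen,
                 criterion = crit_values,
                 saliencies = sal[chosen + 1],
                 correlations = cors, K = K, L = L),
            class = "salient_feature_set")
}

#' @export
print.salient_feature_set <- function(x, ...) {
  cat(sprintf("<salient_feature_set> class %s: features [%s]\n",
              x$class, paste(x$indices, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.salient_feature_set <- function(x, ...) {
  tibble::tibble(class = x$class, step = seq_len(x$L),
                 feature = x$indices, criterion = x$criterion,
                 saliency = x$saliencies)
}

#' Salient feature sets for every class
#'
#' @param matrix A labeled `spike_matrix`.
#' @param L Features per class.
#' @param ... Passed to [select_salient_features()].
#' @return Named list of `salient_feature_set`, one per class.
#' @export
select_all_features <- function(matrix, L = 2, ...) {
  profile <- build_profiles(matrix)
  classes <- sort(unique(matrix$labels))
  sets <- lapply(classes, function(cl)
    select_salient_features(matrix, cl, L = L, profile = profile, ...))
  names(sets) <- classes
  sets
}

#' Serialize salient feature sets to JSON
#'
#' @param sets List of `salient_feature_set` (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_sets <- function(sets, path) {
  if (inherits(sets, "salient_feature_set")) sets <- list(sets)
  payload <- lapply(sets, function(s) list(
    class = s$class, indices = s$indices, saliencies = s$saliencies,
    correlations = apply(s$correlations, 1, as.numeric,
                         simplify = FALSE),
    K = s$K, L = s$L))
  jsonlite::write_json(unname(payload), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
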