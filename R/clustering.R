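#' K-means clustering of spike waveforms
#'
#' Euclidean k-means on the raw K-dimensional waveforms with k-means++
#' seeding; the best of `n_restarts` runs by within-cluster sum of
#' squares (inertia) is kept. Lloyd iterations are delegated to
#' [stats::kmeans()].
#'
#' @param matrix A `spike_matrix`.
#' @param k Number of clusters (>= 1, <= n_spikes).
#' @param n_restarts Independent seeded restarts (default 10).
#' @param seed Integer seed.
#' @param iter_max Lloyd iteration cap (default 300).
#' @return A list: `labels` (integer 1..k per spike), `centroids`
#'   (k x K), `inertia`.
#' @export
kmeans_cluster <- function(matrix, k, n_restarts = 10, seed = 1,
                           iter_max = 300) {
  stopifnot(inherits(matrix, "spike_matrix"))
  x <- matrix$waveforms
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (n < k) stop(sprintf("n_spikes (%d) < k (%d)", n, k),
                  call. = FALSE)
  local_rng(seed)
  if (k == 1) {
    ctr <- matrix(colMeans(x), 1)
    return(list(labels = rep(1L, n), centroids = ctr,
                inertia = sum(sweep(x, 2, ctr)^2)))
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- kmeanspp_centers(x, k)
    fit <- suppressWarnings(
      stats::kmeans(x, centers = centers, iter.max = iter_max,
                    algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) {
      best <- fit
    }
  }
  list(labels = as.integer(best$cluster),
       centroids = unname(best$centers),
       inertia = best$tot.withinss)
}

# k-means++ seeding: first center uniform, later centers with
# probability proportional to squared distance to the nearest center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(x, 2, x[idx[1], ])^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      idx[j + 1] <- sample.int(n, 1)
    } else {
      idx[j + 1] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[idx[j + 1], ])^2))
  }
  x[idx, , drop = FALSE]
}

#' Silhouette statistic
#'
#' Standard silhouette per point: `s = (b - a) / max(a, b)` with `a` the
#' mean distance to the point's own cluster (excluding itself) and `b`
#' the smallest mean distance to any other cluster. Degenerate cases use
#' the conventions `0/0 -> 0` and `s = 0` for points in singleton
#' clusters.
#'
#' @param matrix A `spike_matrix`.
#' @param labels Integer or character cluster labels, one per spike.
#' @return A list: `silhouettes` (per point) and `mean`.
#' @export
silhouette_score <- function(matrix, labels) {
  x <- matrix$waveforms
  storage.mode(x) <- "double"
  labels <- as.integer(factor(labels))
  n <- nrow(x)
  if (length(labels) != n) stop("one label per spike required",
                                call. = FALSE)
  ks <- sort(unique(labels))
  if (length(ks) < 2) stop("silhouette needs >= 2 clusters",
                           call. = FALSE)
  dm <- as.matrix(stats::dist(x))
  s <- numeric(n)
  sizes <- table(labels)
  for (i in seq_len(n)) {
    own <- labels[i]
    if (sizes[[as.character(own)]] == 1) { s[i] <- 0; next }
    a <- mean(dm[i, labels == own & seq_len(n) != i])
    b <- min(vapply(setdiff(ks, own), function(kk)
      mean(dm[i, labels == kk]), numeric(1)))
    denom <- max(a, b)
    s[i] <- if (denom == 0) 0 else (b - a) / denom
  }
  list(silhouettes = s, mean = mean(s))
}

#' Cluster a channel with silhouette-based model selection
#'
#' Runs [kmeans_cluster()] for each k in `k_min..k_max` (defaults 2..4,
#' the plausible per-channel unit counts) and keeps the k with the
#' highest mean silhouette, ties going to the smaller k.
#'
#' @param matrix A `spike_matrix`.
#' @param k_min,k_max Candidate range (defaults 2 and 4).
#' @param seed Integer seed.
#' @param n_restarts Restarts per k.
#' @return A `clustering_result`: list with `labels`, `k`,
#'   `silhouette_by_k` (named numeric), `centroids`, `inertia`.
#' @export
cluster_channel <- function(matrix, k_min = 2, k_max = 4, seed = 1,
                            n_restarts = 10) {
  n <- nrow(matrix$waveforms)
  if (!(2 <= k_min && k_min <= k_max && k_max <= n - 1)) {
    stop("need 2 <= k_min <= k_max <= n_spikes - 1", call. = FALSE)
  }
  fits <- list()
  sil <- numeric(0)
  for (k in k_min:k_max) {
    fit <- kmeans_cluster(matrix, k, n_restarts = n_restarts,
                          seed = seed + k)
    fits[[as.character(k)]] <- fit
    sil[as.character(k)] <- silhouette_score(matrix, fit$labels)$mean
  }
  best_k <- as.integer(names(sil)[which.max(sil)])  # ties -> smaller k
  best <- fits[[as.character(best_k)]]
  structure(list(labels = best$labels, k = best_k,
                 silhouette_by_k = sil, centroids = best$centroids,
                 inertia = best$inertia),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> k = %d (mean silhouette %.3f)\n",
              x$k, x$silhouette_by_k[as.character(x$k)]))
  invisible(x)
}

#' @export
tidy.clustering_result <- function(x, ...) {
  tibble::tibble(k = as.integer(names(x$silhouette_by_k)),
                 mean_silhouette = as.numeric(x$silhouette_by_k),
                 chosen = as.integer(names(x$silhouette_by_k)) == x$k)
}

#' @export
glance.clustering_result <- function(x, ...) {
  tibble::tibble(k = x$k,
                 mean_silhouette =
                   as.numeric(x$silhouette_by_k[as.character(x$k)]),
                 inertia = x$inertia)
}

#' Serialize a clustering result to JSON
#'
#' @param result A `clustering_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clustering_result <- function(result, path) {
  jsonlite::write_json(list(
    k = result$k,
    labels = result$labels,
    silhouette_by_k = as.list(result$silhouette_by_k),
    centroids = apply(result$centroids, 1, as.numeric,
                      simplify = FALSE),
    inertia = result$inertia
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write cluster labels back into a spike matrix
#'
#' @param matrix A `spike_matrix`.
#' @param result A `clustering_result`.
#' @return The matrix with labels `"c1"`, `"c2"`, ... installed.
#' @export
apply_cluster_labels <- function(matrix, result) {
  matrix$labels <- sprintf("c%d", result$labels)
  matrix
}
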