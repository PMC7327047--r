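#' Train a channel end to end
#'
#' The full offline training loop of the external (shadow-sorter)
#' module: label the spikes if necessary (k-means + silhouette), split
#' the labeled spikes into even stratified train/test halves, run
#' salient feature selection per class, fit discrimination windows on
#' the training half, quantize the configuration for the implant, and
#' evaluate both the floating-point and the emulated fixed-point sorter
#' on the held-out half.
#'
#' @param matrix A `spike_matrix` (labeled or not).
#' @param L Salient features per class (default 2).
#' @param k_min,k_max Cluster-count range when the input is unlabeled.
#' @param p_lo,p_hi,refine Window-fitting parameters, see
#'   [fit_windows()].
#' @param widths [bit_widths()] for the quantized configuration.
#' @param emulator_compatible Restrict feature selection to indices that
#'   fit the index registers (default `TRUE`; with 5-bit indices this
#'   is the first 32 samples).
#' @param seed Integer seed (split and, if needed, clustering).
#' @return A `channel_fit`: list with `config`, `qconfig`,
#'   `feature_sets`, `profile`, `report` (float-path `eval_report` on
#'   the held-out half), `report_emulated`, `agreement` (fraction of
#'   held-out spikes on which the two paths give the same label),
#'   `clustering` (or `NULL`), `split`, `seed`.
#' @export
train_channel <- function(matrix, L = 2, k_min = 2, k_max = 4,
                          p_lo = 1, p_hi = 99, refine = TRUE,
                          widths = bit_widths(),
                          emulator_compatible = TRUE, seed = 1) {
  stopifnot(inherits(matrix, "spike_matrix"))
  clustering <- NULL
  if (is.null(matrix$labels)) {
    clustering <- cluster_channel(matrix, k_min = k_min, k_max = k_max,
                                  seed = seed)
    matrix <- apply_cluster_labels(matrix, clustering)
  }
  halves <- split_spike_matrix(matrix, 0.5, seed = seed)
  train <- halves$train; test <- halves$test
  max_feature <- if (emulator_compatible) 2^widths$index_bits else NULL
  profile <- build_profiles(train)
  classes <- sort(unique(train$labels))
  feature_sets <- lapply(classes, function(cl)
    select_salient_features(train, cl, L = L, profile = profile,
                            max_feature = max_feature))
  names(feature_sets) <- classes
  config <- fit_windows(train, feature_sets, p_lo = p_lo, p_hi = p_hi,
                        refine = refine)
  qconfig <- quantize_config(config, widths)
  pred_float <- sort_stream(test, config)
  pred_q <- emulate_sort(test, qconfig)
  structure(list(
    config = config, qconfig = qconfig, feature_sets = feature_sets,
    profile = profile,
    report = classification_accuracy(test$labels, pred_float),
    report_emulated = classification_accuracy(test$labels, pred_q),
    agreement = mean(pred_float == pred_q),
    clustering = clustering,
    split = c(train = nrow(train$waveforms),
              test = nrow(test$waveforms)),
    seed = seed), class = "channel_fit")
}

#' @export
print.channel_fit <- function(x, ...) {
  cat(sprintf(
    "<channel_fit> %d classes, L = %d | held-out CA %.1f%%, CA_CLI %.1f%%, float/quantized agreement %.1f%%\n",
    length(x$config$windows), x$config$L,
    100 * attr(x$report, "overall_ca"),
    100 * attr(x$report, "overall_ca_cli"),
    100 * x$agreement))
  invisible(x)
}

#' @export
tidy.channel_fit <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x$report), path = "float") |>
    dplyr::bind_rows(
      dplyr::mutate(tibble::as_tibble(x$report_emulated),
                    path = "emulated"))
}

#' @export
glance.channel_fit <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$config$windows), L = x$config$L,
    n_train = x$split[["train"]], n_test = x$split[["test"]],
    overall_ca = attr(x$report, "overall_ca"),
    overall_ca_cli = attr(x$report, "overall_ca_cli"),
    overall_ca_emulated = attr(x$report_emulated, "overall_ca"),
    agreement = x$agreement,
    clustered_k = if (is.null(x$clustering)) NA_integer_ else
      x$clustering$k
  )
}

#' End-to-end sorting study on synthetic channels
#'
#' Runs the full offline training loop ([train_channel()]) on a set of
#' seeded synthetic channels with 2-4 well-isolated units each and
#' returns the per-channel summary: held-out accuracy of the
#' floating-point sorter, of the fixed-point emulated sorter, and the
#' agreement between the two datapaths.
#'
#' @param n_channels Number of channels (default 50).
#' @param n_spikes Spikes per channel (default 400, i.e. a couple of
#'   hundred per unit half of which trains and half tests).
#' @param snr_range Channel SNR scale drawn uniformly from this range
#'   (default `c(8, 16)`, the well-isolated regime); all units share
#'   one noise floor set so the weakest unit sits at the drawn scale.
#' @param L Salient features per class (default 2).
#' @param seed Integer seed.
#' @return A tibble, one row per channel: the [glance()] columns of
#'   each `channel_fit` plus `channel` and `n_units`.
#' @export
sorting_study <- function(n_channels = 50, n_spikes = 400,
                          snr_range = c(8, 16), L = 2, seed = 1) {
  local_rng(seed)
  channel_seeds <- sample.int(2^30, n_channels)
  purrr::map_dfr(seq_len(n_channels), function(ch) {
    cs <- channel_seeds[ch]
    local_rng(cs)
    n_units <- sample(2:4, 1)
    templates <- generate_templates(n_units, seed = cs)
    pp <- vapply(templates, `[[`, numeric(1), "peak_to_peak")
    snr_floor <- stats::runif(1, snr_range[1], snr_range[2])
    spec <- channel_spec(
      templates = templates,
      snr_per_unit = snr_floor * pp / min(pp),
      n_spikes = n_spikes, seed = cs)
    fit <- train_channel(synthesize_channel(spec), L = L, seed = cs)
    dplyr::bind_cols(tibble::tibble(channel = ch, n_units = n_units),
                     glance(fit))
  })
}

#' Planted-feature recovery study
#'
#' Repeatedly builds [planted_channel()] data and checks whether the
#' first two selected salient features of each class fall inside the
#' planted subset.
#'
#' @param n_runs Number of seeded runs (default 100).
#' @param snr Channel SNR (default 4).
#' @param n_spikes Spikes per run (default 200).
#' @param seed Integer seed.
#' @return A tibble, one row per run: `run`, `hit` (`TRUE` when the
#'   first two features of every class are planted), and the selected
#'   indices per class.
#' @export
planted_recovery_study <- function(n_runs = 100, snr = 4,
                                   n_spikes = 200, seed = 1) {
  local_rng(seed)
  run_seeds <- sample.int(2^30, n_runs)
  purrr::map_dfr(seq_len(n_runs), function(r) {
    pc <- planted_channel(snr = snr, n_spikes = n_spikes,
                          seed = run_seeds[r])
    profile <- build_profiles(pc$matrix)
    sel <- lapply(sort(unique(pc$matrix$labels)), function(cl)
      select_salient_features(pc$matrix, cl, L = 2,
                              profile = profile)$indices)
    tibble::tibble(
      run = r,
      hit = all(unlist(sel) %in% pc$planted),
      indices = list(sel))
  })
}

# Draw a realistic synthetic channel: one shared background-noise
# floor (extracellular noise is common to every unit an electrode
# sees), so per-unit SNR varies through spike amplitude. The channel
# SNR scale follows a lognormal spanning roughly 0.3..22 with a mean
# near 4.5, emulating the spread reported for cortical array data.
draw_study_channel <- function(n_spikes, cs) {
  n_units <- sample(2:4, 1)
  templates <- generate_templates(n_units, seed = cs)
  pp <- vapply(templates, `[[`, numeric(1), "peak_to_peak")
  snr_channel <- min(max(stats::rlnorm(1, log(3.5), 0.8), 0.5), 15)
  snr_per_unit <- snr_channel * pp / mean(pp)
  spec <- channel_spec(templates = templates,
                       snr_per_unit = snr_per_unit,
                       n_spikes = n_spikes, seed = cs)
  list(matrix = synthesize_channel(spec), snr = snr_per_unit,
       n_units = n_units)
}

#' Saliency-versus-accuracy study on synthetic channels
#'
#' Reproduces, on synthetic data, the diagnostic relating a feature's
#' (log) class saliency to the chance-corrected accuracy that feature
#' achieves on its own. For each simulated channel (2-4 units over a
#' shared noise floor, channel SNR drawn from a broad lognormal
#' emulating the spread of real extracellular recordings), every
#' sampled (class, feature) pair contributes one point pairing the
#' feature's log saliency with the class's CA_CLI under a
#' one-dimensional Gaussian naive Bayes classifier restricted to that
#' feature, evaluated on a held-out half. Uninformative baseline
#' samples anchor the low-saliency, near-chance end of the scatter;
#' trough and rebound samples of well-isolated units populate the high
#' end.
#'
#' @param n_channels Number of channels to simulate (default 200).
#' @param features_per_class Features sampled per class (evenly spread
#'   over the spike; default 12).
#' @param n_spikes Spikes per channel (default 300).
#' @param seed Integer seed.
#' @return A tibble: `channel`, `class`, `feature`, `log_saliency`,
#'   `ca`, `chance`, `ca_cli`.
#' @export
saliency_ca_study <- function(n_channels = 200,
                              features_per_class = 12,
                              n_spikes = 300, seed = 1) {
  local_rng(seed)
  channel_seeds <- sample.int(2^30, n_channels)
  purrr::map_dfr(seq_len(n_channels), function(ch) {
    cs <- channel_seeds[ch]
    local_rng(cs)
    drawn <- draw_study_channel(n_spikes, cs)
    m <- drawn$matrix
    if (length(unique(m$labels)) < 2 ||
        min(table(m$labels)) < 8) return(NULL)
    halves <- split_spike_matrix(m, 0.5, seed = cs)
    profile <- build_profiles(halves$train)
    classes <- sort(unique(halves$train$labels))
    K <- ncol(m$waveforms)
    feats <- as.integer(round(seq(0, K - 1,
                                  length.out = features_per_class)))
    chance <- chance_level(halves$test$labels)
    purrr::map_dfr(classes, function(cl) {
      prof_cl <- profile[profile$class == cl, ]
      purrr::map_dfr(feats, function(k) {
        pred <- bayes_classify(halves$train, halves$test,
                               feature_indices = k)
        idx <- halves$test$labels == cl
        ca_k <- mean(pred[idx] == cl)
        chance_cl <- chance[[cl]]
        tibble::tibble(
          channel = ch, class = cl, feature = k,
          log_saliency =
            log(prof_cl$saliency[prof_cl$feature == k]),
          ca = ca_k, chance = chance_cl,
          ca_cli = ca_cli(ca_k, chance_cl))
      })
    })
  })
}

#' Benchmark feature strategies across synthetic channels
#'
#' Compares salient feature selection against the static-feature
#' baselines and against Gaussian naive Bayes on the full waveform, all
#' followed by the same naive Bayes classifier, across seeded synthetic
#' channels. Returns per-channel, per-method accuracies suitable for
#' CA-CA regression diagnostics.
#'
#' @param n_channels Number of channels (default 50).
#' @param L Salient features per class for the SFS method.
#' @param n_spikes Spikes per channel.
#' @param methods Methods to run; subset of
#'   `c("SFS", "FULL", "SDE", "FSDE", "DDsE", "ZCF")`.
#' @param seed Integer seed.
#' @return A tibble: `channel`, `method`, `n_features`, `overall_ca`,
#'   `overall_ca_cli`.
#' @export
benchmark_methods <- function(n_channels = 50, L = 2, n_spikes = 300,
                              methods = c("SFS", "FULL", "SDE", "FSDE",
                                          "DDsE", "ZCF"),
                              seed = 1) {
  local_rng(seed)
  channel_seeds <- sample.int(2^30, n_channels)
  purrr::map_dfr(seq_len(n_channels), function(ch) {
    cs <- channel_seeds[ch]
    local_rng(cs)
    drawn <- draw_study_channel(n_spikes, cs)
    m <- drawn$matrix
    if (length(unique(m$labels)) < 2 ||
        min(table(m$labels)) < 8) return(NULL)
    halves <- split_spike_matrix(m, 0.5, seed = cs)
    train <- halves$train; test <- halves$test
    purrr::map_dfr(methods, function(meth) {
      if (meth == "SFS") {
        # per-class salient features + per-class Bayes, as in the
        # saliency validation: each class judged in its own subspace
        profile <- build_profiles(train)
        classes <- sort(unique(train$labels))
        per <- purrr::map_dfr(classes, function(cl) {
          fs <- select_salient_features(train, cl, L = L,
                                        profile = profile)
          pred <- bayes_classify(train, test,
                                 feature_indices = fs$indices)
          rp <- classification_accuracy(test$labels, pred)
          rp[rp$class == cl, ]
        })
        tibble::tibble(channel = ch, method = meth, n_features = L,
                       overall_ca = sum(per$ca * per$n_test) /
                         sum(per$n_test),
                       overall_ca_cli = mean(per$ca_cli))
      } else {
        pred <- if (meth == "FULL") bayes_classify(train, test)
          else nb_train_predict(static_features(train, meth),
                                train$labels,
                                static_features(test, meth))
        rp <- classification_accuracy(test$labels, pred)
        nf <- if (meth == "FULL") ncol(train$waveforms) else
          ncol(static_features(subset_spikes(train, 1:2), meth))
        tibble::tibble(channel = ch, method = meth, n_features = nf,
                       overall_ca = attr(rp, "overall_ca"),
                       overall_ca_cli = attr(rp, "overall_ca_cli"))
      }
    })
  })
}
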