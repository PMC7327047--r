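#' Generate biphasic extracellular spike templates
#'
#' Each template emulates the canonical extracellular action-potential
#' shape: a sharp negative trough followed by a slower positive rebound
#' that decays back to baseline. Units on one channel are kept
#' morphologically distinct by drawing trough latencies without
#' replacement from a coarse grid before jittering the remaining shape
#' parameters, mirroring the fact that different neurons seen by one
#' electrode produce different wave-shapes.
#'
#' @param n_units Number of templates (units) to generate, >= 1.
#' @param K Samples per template (default 48, i.e. 1.6 ms at 30 kHz).
#' @param morphology_params Optional named list overriding the parameter
#'   ranges: `trough_depth` (c(lo, hi), amplitude units),
#'   `trough_width` (samples), `rebound_frac` (fraction of trough depth),
#'   `rebound_lag` (samples after trough), `rebound_width` (samples),
#'   `trough_latency_grid` (candidate trough positions, 0-based).
#' @param seed Integer seed.
#' @return A list of `n_units` templates; each has `samples` (length-K
#'   numeric), `peak_to_peak`, and `label` (`"u1"`, `"u2"`, ...).
#' @export
generate_templates <- function(n_units, K = 48, morphology_params = list(),
                               seed = 1) {
  if (!is.numeric(n_units) || n_units < 1) {
    stop("n_units must be >= 1", call. = FALSE)
  }
  if (!is.numeric(K) || K < 8) stop("K must be >= 8", call. = FALSE)
  n_units <- as.integer(n_units); K <- as.integer(K)
  p <- utils::modifyList(list(
    trough_depth = c(60, 110),
    trough_width = c(1.2, 2.4),
    rebound_frac = c(0.3, 0.6),
    rebound_lag = c(6, 12),
    rebound_width = c(3, 6),
    trough_latency_grid = seq(9, min(K - 10, 23), by = 2)
  ), morphology_params)
  local_rng(seed)
  grid <- p$trough_latency_grid
  lat <- if (n_units <= length(grid)) sample(grid, n_units) else
    sample(grid, n_units, replace = TRUE) +
      stats::runif(n_units, -0.5, 0.5)
  t_axis <- seq_len(K) - 1
  lapply(seq_len(n_units), function(u) {
    depth <- stats::runif(1, p$trough_depth[1], p$trough_depth[2])
    tw <- stats::runif(1, p$trough_width[1], p$trough_width[2])
    rfrac <- stats::runif(1, p$rebound_frac[1], p$rebound_frac[2])
    rlag <- stats::runif(1, p$rebound_lag[1], p$rebound_lag[2])
    rw <- stats::runif(1, p$rebound_width[1], p$rebound_width[2])
    s <- -depth * exp(-0.5 * ((t_axis - lat[u]) / tw)^2) +
      depth * rfrac * exp(-0.5 * ((t_axis - lat[u] - rlag) / rw)^2)
    list(samples = s, peak_to_peak = max(s) - min(s),
         label = sprintf("u%d", u))
  })
}

#' Specify a synthetic channel
#'
#' Bundles everything needed to synthesize one channel's worth of
#' labeled spikes: the unit templates, their relative firing
#' probabilities, per-unit signal-to-noise ratios, and the quantisation
#' of the simulated front-end. SNR follows the convention
#' SNR = peak-to-peak amplitude / (2 x noise standard deviation).
#'
#' @param n_units Number of units, 2..4 for typical channels.
#' @param templates List of templates from [generate_templates()];
#'   generated automatically when `NULL`.
#' @param priors Relative class probabilities (summing to 1); uniform
#'   when `NULL`.
#' @param snr_per_unit Positive SNR per unit (recycled if scalar).
#' @param n_spikes Number of spikes to draw.
#' @param jitter_samples Max absolute integer alignment jitter.
#' @param quantization_bits Signed quantisation depth (default 8).
#' @param sample_rate_hz Sampling rate (default 30000).
#' @param K Samples per spike (default 48).
#' @param seed Integer seed.
#' @return A `channel_spec` list.
#' @export
channel_spec <- function(n_units = 3, templates = NULL, priors = NULL,
                         snr_per_unit = 4.5, n_spikes = 500,
                         jitter_samples = 0, quantization_bits = 8,
                         sample_rate_hz = 30000, K = 48, seed = 1) {
  if (is.null(templates)) {
    templates <- generate_templates(n_units, K = K, seed = seed)
  }
  n_units <- length(templates)
  if (is.null(priors)) priors <- rep(1 / n_units, n_units)
  snr_per_unit <- rep_len(snr_per_unit, n_units)
  if (abs(sum(priors) - 1) > 1e-9) {
    stop("priors must sum to 1", call. = FALSE)
  }
  if (length(priors) != n_units) {
    stop("priors must match the number of templates", call. = FALSE)
  }
  if (any(snr_per_unit <= 0)) stop("all SNR values must be > 0",
                                   call. = FALSE)
  if (n_spikes <= 0) stop("n_spikes must be > 0", call. = FALSE)
  structure(list(
    n_units = n_units, templates = templates, priors = priors,
    snr_per_unit = snr_per_unit, n_spikes = as.integer(n_spikes),
    jitter_samples = as.integer(jitter_samples),
    quantization_bits = as.integer(quantization_bits),
    sample_rate_hz = sample_rate_hz, K = length(templates[[1]]$samples),
    seed = as.integer(seed)
  ), class = "channel_spec")
}

# Channel full scale: headroom above the largest template excursion so
# typical noise does not saturate the quantizer.
channel_full_scale <- function(spec) {
  1.2 * max(vapply(spec$templates,
                   function(tp) max(abs(tp$samples)), numeric(1)))
}

quantize_samples <- function(x, bits, full_scale) {
  top <- 2^(bits - 1) - 1
  bot <- -2^(bits - 1)
  step <- full_scale / 2^(bits - 1)
  q <- round(x / step)
  pmin(pmax(q, bot), top)
}

#' Synthesize a labeled spike matrix for one channel
#'
#' Draws each spike's class from the channel priors, superposes
#' independent Gaussian noise with standard deviation
#' `peak_to_peak / (2 * SNR)`, applies optional uniform integer
#' alignment jitter, and quantizes to signed integers with saturation.
#'
#' @param spec A [channel_spec()].
#' @return A labeled `spike_matrix`.
#' @export
synthesize_channel <- function(spec) {
  stopifnot(inherits(spec, "channel_spec"))
  local_rng(spec$seed)
  K <- spec$K
  fs_amp <- channel_full_scale(spec)
  cls <- sample.int(spec$n_units, spec$n_spikes, replace = TRUE,
                    prob = spec$priors)
  w <- matrix(0, spec$n_spikes, K)
  for (u in seq_len(spec$n_units)) {
    rows <- which(cls == u)
    if (length(rows) == 0) next
    tp <- spec$templates[[u]]
    noise_sd <- tp$peak_to_peak / (2 * spec$snr_per_unit[u])
    base <- tp$samples
    if (spec$jitter_samples > 0) {
      shifts <- sample(-spec$jitter_samples:spec$jitter_samples,
                       length(rows), replace = TRUE)
    } else shifts <- rep(0L, length(rows))
    for (idx in seq_along(rows)) {
      shifted <- shift_vector(base, shifts[idx])
      w[rows[idx], ] <- shifted +
        if (noise_sd > 0) stats::rnorm(K, 0, noise_sd) else 0
    }
  }
  wq <- quantize_samples(w, spec$quantization_bits, fs_amp)
  spike_matrix(matrix(as.integer(wq), nrow = spec$n_spikes),
               labels = vapply(cls, function(u) spec$templates[[u]]$label,
                               character(1)),
               channel_id = sprintf("syn-%d", spec$seed),
               sample_rate_hz = spec$sample_rate_hz)
}

shift_vector <- function(x, by) {
  n <- length(x)
  if (by == 0) return(x)
  out <- numeric(n)
  if (by > 0) out[(by + 1):n] <- x[1:(n - by)]
  else out[1:(n + by)] <- x[(1 - by):n]
  out
}

#' Synthesize a continuous trace with known spike times
#'
#' Places template instances at Poisson-distributed times on a Gaussian
#' noise background, with a refractory guard of one spike length so
#' insertions never overlap. Useful for exercising threshold detection
#' and alignment.
#'
#' @param spec A [channel_spec()] (noise level taken from the first
#'   unit's SNR).
#' @param duration_s Trace duration in seconds.
#' @param rate_hz_per_unit Firing rate per unit in Hz (recycled).
#' @return A list: `trace` (numeric vector), `times` (0-based sample
#'   index of each insertion start), `labels`, `noise_sd`.
#' @export
synthesize_continuous <- function(spec, duration_s,
                                  rate_hz_per_unit = 5) {
  stopifnot(inherits(spec, "channel_spec"))
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  rates <- rep_len(rate_hz_per_unit, spec$n_units)
  if (any(rates < 0)) stop("rates must be >= 0", call. = FALSE)
  K <- spec$K
  fs <- spec$sample_rate_hz
  if (sum(rates) * K / fs > 0.5) {
    stop("firing rates too high for non-overlapping insertions",
         call. = FALSE)
  }
  local_rng(spec$seed)
  n_samp <- as.integer(round(duration_s * fs))
  pp1 <- spec$templates[[1]]$peak_to_peak
  noise_sd <- pp1 / (2 * spec$snr_per_unit[1])
  trace <- if (noise_sd > 0) stats::rnorm(n_samp, 0, noise_sd) else
    numeric(n_samp)
  events <- list()
  for (u in seq_len(spec$n_units)) {
    if (rates[u] == 0) next
    n_ev <- stats::rpois(1, rates[u] * duration_s)
    if (n_ev == 0) next
    t_ev <- sort(as.integer(floor(stats::runif(n_ev, 0,
                                               n_samp - K))))
    events[[length(events) + 1]] <-
      data.frame(time = t_ev, unit = u)
  }
  if (length(events) == 0) {
    return(list(trace = trace, times = integer(0),
                labels = character(0), noise_sd = noise_sd))
  }
  ev <- do.call(rbind, events)
  ev <- ev[order(ev$time), , drop = FALSE]
  keep <- logical(nrow(ev))
  last_end <- -1L
  for (i in seq_len(nrow(ev))) {
    if (ev$time[i] > last_end) {
      keep[i] <- TRUE
      last_end <- ev$time[i] + K - 1L
    }
  }
  ev <- ev[keep, , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    rng_idx <- ev$time[i] + seq_len(K)
    trace[rng_idx] <- trace[rng_idx] +
      spec$templates[[ev$unit[i]]]$samples
  }
  list(trace = trace, times = ev$time,
       labels = vapply(ev$unit, function(u) spec$templates[[u]]$label,
                       character(1)),
       noise_sd = noise_sd)
}

#' Synthesize a channel whose classes differ only at planted samples
#'
#' Builds a two-class channel from one biphasic template where the
#' second class deviates only at a small set of planted sample indices
#' (alternating positive/negative offsets of a fixed fraction of the
#' template's peak-to-peak amplitude). Every other sample carries no
#' between-class mean difference, so feature selection should recover
#' the planted subset.
#'
#' @param n_planted Number of informative samples (default 4).
#' @param planted_at 0-based planted indices; evenly spread by default.
#' @param offset_frac Planted offset as a fraction of peak-to-peak
#'   amplitude (default 0.25).
#' @param snr Channel SNR for both classes (default 4).
#' @param n_spikes Total spikes (default 200, balanced priors).
#' @param K Samples per spike.
#' @param seed Integer seed.
#' @return A list: `matrix` (labeled `spike_matrix`) and `planted`
#'   (0-based indices).
#' @export
planted_channel <- function(n_planted = 4, planted_at = NULL,
                            offset_frac = 0.25, snr = 4,
                            n_spikes = 200, K = 48, seed = 1) {
  base <- generate_templates(1, K = K, seed = seed)[[1]]
  if (is.null(planted_at)) {
    planted_at <- as.integer(round(seq(4, K - 5,
                                       length.out = n_planted)))
  }
  alt <- base$samples
  offs <- base$peak_to_peak * offset_frac *
    rep_len(c(1, -1), length(planted_at))
  alt[planted_at + 1] <- alt[planted_at + 1] + offs
  tpl <- list(
    list(samples = base$samples, peak_to_peak = base$peak_to_peak,
         label = "u1"),
    list(samples = alt, peak_to_peak = max(alt) - min(alt),
         label = "u2"))
  spec <- channel_spec(templates = tpl, snr_per_unit = snr,
                       n_spikes = n_spikes, seed = seed)
  list(matrix = synthesize_channel(spec), planted = planted_at)
}

#' Detect and align spikes from a continuous trace
#'
#' Scans for first threshold crossings (negative-going by default:
#' sample <= threshold while the previous sample was above it), extracts
#' a K-sample window starting `pre_samples` before the crossing, and
#' enforces a dead time of K samples after each detection. Windows that
#' would be truncated by the trace boundaries are discarded.
#'
#' @param trace Numeric vector.
#' @param threshold Detection threshold (same units as `trace`).
#' @param pre_samples Samples kept before the crossing (default 8); the
#'   crossing sample sits at 0-based index `pre_samples` in each window.
#' @param K Window length in samples (default 48).
#' @param polarity `"negative"` (default) or `"positive"` going.
#' @param sample_rate_hz Stored in the returned matrix.
#' @return A list: `matrix` (unlabeled `spike_matrix`; waveforms rounded
#'   to integers) and `times` (0-based crossing sample indices).
#' @export
detect_and_align <- function(trace, threshold, pre_samples = 8, K = 48,
                             polarity = c("negative", "positive"),
                             sample_rate_hz = 30000) {
  polarity <- match.arg(polarity)
  if (pre_samples < 0 || K <= pre_samples) {
    stop("need K > pre_samples >= 0", call. = FALSE)
  }
  n <- length(trace)
  if (n == 0) {
    return(list(matrix = spike_matrix(matrix(integer(0), 0, K),
                                      sample_rate_hz = sample_rate_hz),
                times = integer(0)))
  }
  below <- if (polarity == "negative") trace <= threshold else
    trace >= threshold
  crossings <- which(below[-1] & !below[-n]) + 1L  # 1-based index
  hits <- integer(0)
  last_end <- -Inf
  for (cx in crossings) {
    if (cx <= last_end) next
    start <- cx - pre_samples          # 1-based window start
    if (start < 1 || start + K - 1 > n) next
    hits <- c(hits, cx)
    last_end <- cx + K - 1L
  }
  w <- matrix(0L, length(hits), K)
  for (i in seq_along(hits)) {
    w[i, ] <- as.integer(round(
      trace[(hits[i] - pre_samples):(hits[i] - pre_samples + K - 1)]))
  }
  list(matrix = spike_matrix(w, sample_rate_hz = sample_rate_hz),
       times = hits - 1L)
}
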