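test_that("templates are biphasic, seeded, and pairwise distinct", {
  tpl <- generate_templates(1, K = 48, seed = 7)
  expect_length(tpl, 1)
  expect_length(tpl[[1]]$samples, 48)
  expect_lt(min(tpl[[1]]$samples), 0)
  expect_gt(max(tpl[[1]]$samples), 0)
  expect_equal(tpl[[1]]$peak_to_peak,
               max(tpl[[1]]$samples) - min(tpl[[1]]$samples))

  expect_identical(generate_templates(3, K = 48, seed = 11),
                   generate_templates(3, K = 48, seed = 11))

  for (s in 1:100) {
    tp <- generate_templates(4, K = 48, seed = s)
    for (i in 1:3) for (j in (i + 1):4) {
      expect_gt(sqrt(sum((tp[[i]]$samples - tp[[j]]$samples)^2)), 0)
    }
  }

  expect_error(generate_templates(0, K = 48), "n_units")
  expect_error(generate_templates(2, K = 4), "K")
})

test_that("zero-noise synthesis reproduces the quantized templates", {
  tpl <- generate_templates(2, K = 48, seed = 3)
  spec <- channel_spec(templates = tpl, snr_per_unit = Inf,
                       n_spikes = 20, seed = 3)
  m <- synthesize_channel(spec)
  fs <- 1.2 * max(vapply(tpl, function(t) max(abs(t$samples)),
                         numeric(1)))
  for (u in 1:2) {
    rows <- which(m$labels == tpl[[u]]$label)
    qt <- pmin(pmax(round(tpl[[u]]$samples / (fs / 128)), -128), 127)
    for (r in rows) expect_equal(unname(m$waveforms[r, ]), qt)
  }
})

test_that("class draws follow the priors within binomial bounds", {
  spec <- channel_spec(n_units = 2, priors = c(0.5, 0.5),
                       snr_per_unit = 6, n_spikes = 10000, seed = 5)
  m <- synthesize_channel(spec)
  counts <- table(m$labels)
  expect_true(all(abs(counts - 5000) < 4 * sqrt(10000 * 0.25)))
})

test_that("empirical SNR of generated spikes matches the request", {
  tpl <- generate_templates(1, K = 48, seed = 9)
  spec <- channel_spec(templates = tpl, priors = 1, snr_per_unit = 4.5,
                       n_spikes = 5000, seed = 9)
  # one unit only: force a second dummy? synthesize handles n_units = 1
  m <- synthesize_channel(spec)
  w <- m$waveforms
  resid_sd <- mean(apply(w, 2, sd))
  mean_wave <- colMeans(w)
  pp <- max(mean_wave) - min(mean_wave)
  snr_hat <- pp / (2 * resid_sd)
  expect_lt(abs(snr_hat - 4.5) / 4.5, 0.05)
})

test_that("quantization saturates instead of wrapping", {
  # SNR far below 1 drives samples beyond full scale
  spec <- channel_spec(n_units = 2, snr_per_unit = 0.3,
                       n_spikes = 500, seed = 13)
  m <- synthesize_channel(spec)
  expect_true(all(m$waveforms >= -128 & m$waveforms <= 127))
  expect_true(any(m$waveforms == 127 | m$waveforms == -128))
  expect_error(channel_spec(n_units = 2, snr_per_unit = c(4, -1)),
               "SNR")
})

test_that("continuous synthesis places non-overlapping labeled spikes", {
  spec <- channel_spec(n_units = 1, snr_per_unit = 10, n_spikes = 10,
                       seed = 21)
  quiet <- synthesize_continuous(spec, duration_s = 0.5,
                                 rate_hz_per_unit = 0)
  expect_length(quiet$times, 0)
  expect_length(quiet$trace, 15000)

  res <- synthesize_continuous(spec, duration_s = 10,
                               rate_hz_per_unit = 5)
  expect_lt(abs(length(res$times) - 50), 4 * sqrt(50))
  gaps <- diff(res$times)
  expect_true(all(gaps >= 48))

  spec0 <- channel_spec(n_units = 1, snr_per_unit = Inf, n_spikes = 10,
                        seed = 22)
  res0 <- synthesize_continuous(spec0, duration_s = 5,
                                rate_hz_per_unit = 4)
  tpl <- spec0$templates[[1]]$samples
  for (t0 in res0$times) {
    expect_equal(res0$trace[t0 + seq_len(48)], tpl)
  }

  expect_error(synthesize_continuous(spec, duration_s = 1,
                                     rate_hz_per_unit = 1000),
               "too high")
})

test_that("detection recovers threshold crossings and honors dead time", {
  # hand-built trace: baseline 0 with one negative excursion
  trace <- rep(0, 200)
  trace[101:104] <- c(-30, -60, -40, -10)
  det <- detect_and_align(trace, threshold = -20, pre_samples = 8,
                          K = 48)
  expect_equal(nrow(det$matrix$waveforms), 1)
  expect_equal(det$times, 100)                  # 0-based crossing
  expect_equal(det$matrix$waveforms[1, 9], -30) # crossing at index 8

  expect_equal(nrow(detect_and_align(trace, threshold = -100,
                                     K = 48)$matrix$waveforms), 0)
  expect_equal(nrow(detect_and_align(numeric(0), -20,
                                     K = 48)$matrix$waveforms), 0)
})

test_that("detection finds nearly all ground-truth spikes at high SNR", {
  spec <- channel_spec(n_units = 2, snr_per_unit = 12, n_spikes = 10,
                       seed = 31)
  res <- synthesize_continuous(spec, duration_s = 8,
                               rate_hz_per_unit = 4)
  thr <- -4 * res$noise_sd
  det <- detect_and_align(res$trace, threshold = thr, pre_samples = 8,
                          K = 48)
  # an insertion at t crosses threshold a few samples after onset
  hits <- vapply(res$times, function(t)
    any(det$times >= t & det$times <= t + 47), logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("spike matrices round-trip through csv and binary formats", {
  set.seed(41)
  m <- spike_matrix(matrix(sample(-128:127, 10 * 48, TRUE), 10, 48),
                    labels = sample(c("u1", "u2"), 10, TRUE),
                    channel_id = "rt", sample_rate_hz = 30000)
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_spike_matrix(m, p1, "csv")
  m1 <- read_spike_matrix(p1, "csv")
  expect_equal(m1$waveforms, m$waveforms)
  expect_equal(m1$labels, m$labels)

  p2 <- withr::local_tempfile(fileext = ".bin")
  write_spike_matrix(m, p2, "bin")
  m2 <- read_spike_matrix(p2, "bin")
  expect_equal(m2$waveforms, m$waveforms)
  expect_equal(m2$labels, m$labels)
  expect_equal(m2$sample_rate_hz, 30000)

  # unlabeled round trip
  mu <- spike_matrix(m$waveforms)
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_spike_matrix(mu, p3, "csv")
  expect_null(read_spike_matrix(p3, "csv")$labels)
})

test_that("malformed files produce diagnostic errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,2,3", "4,5", "6,7,8"), p)
  expect_error(read_spike_matrix(p, "csv"), "row 2")

  m <- spike_matrix(matrix(1:96, 2, 48))
  pb <- withr::local_tempfile(fileext = ".bin")
  write_spike_matrix(m, pb, "bin")
  sc <- jsonlite::read_json(paste0(pb, ".json"), simplifyVector = TRUE)
  sc$n_spikes <- 5
  jsonlite::write_json(sc, paste0(pb, ".json"), auto_unbox = TRUE)
  expect_error(read_spike_matrix(pb, "bin"), "bytes")
})

test_that("stratified splitting preserves classes and is seeded", {
  m <- two_blob_matrix(n_per = 21, seed = 2)
  sp <- split_spike_matrix(m, 0.5, seed = 4)
  expect_equal(sort(unique(sp$train$labels)), c("u1", "u2"))
  expect_equal(sort(unique(sp$test$labels)), c("u1", "u2"))
  expect_equal(nrow(sp$train$waveforms) + nrow(sp$test$waveforms), 42)
  sp2 <- split_spike_matrix(m, 0.5, seed = 4)
  expect_identical(sp$train$waveforms, sp2$train$waveforms)
})
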