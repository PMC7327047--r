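test_that("register-bank accounting reproduces the shared-memory budget", {
  rep_default <- memory_report()
  expect_identical(rep_default$index_bank_bits, 512L * 2L * 5L)
  expect_identical(rep_default$bound_bank_bits, 512L * 2L * 2L * 7L)
  expect_identical(rep_default$classid_bank_bits, 512L * 2L * 3L)
  expect_equal(rep_default$index_bank_kibit, 5)
  expect_equal(rep_default$bound_bank_kibit, 14)
  expect_equal(rep_default$classid_bank_kibit, 3)
  expect_equal(rep_default$total_bits,
               rep_default$index_bank_bits +
                 rep_default$bound_bank_bits +
                 rep_default$classid_bank_bits)
  small <- memory_report(register_banks(1, 1, bit_widths(1, 1, 1, 8)),
                         bit_widths(1, 1, 1, 8))
  expect_equal(c(small$index_bank_bits, small$bound_bank_bits,
                 small$classid_bank_bits), c(1, 2, 1))
  expect_error(bit_widths(0), "widths")
})

test_that("bound quantization is outward and contains the window", {
  # step = 2 for 8-bit samples against 7-bit bounds
  cfg <- manual_config(list(list(class = "a",
                                 feature_indices = c(0, 1),
                                 lower = c(-28, -4), upper = c(70, 104))),
                       K = 4)
  q <- quantize_config(cfg)
  expect_equal(q$step, 2)
  expect_equal(q$windows$a$lower_q, c(-14L, -2L))
  expect_equal(q$windows$a$upper_q, c(35L, 52L))
  # grid-aligned bounds are stored exactly
  dq <- dequantize_config(q)
  expect_equal(dq$windows$a$lower, c(-28, -4))
  expect_equal(dq$windows$a$upper, c(70, 104))
  # random configs: dequantized window contains the original
  set.seed(5)
  for (i in 1:50) {
    lo <- runif(2, -120, 100); hi <- lo + runif(2, 0, 25)
    c2 <- manual_config(list(list(class = "a",
                                  feature_indices = c(2, 3),
                                  lower = lo, upper = hi)), K = 6)
    d2 <- dequantize_config(quantize_config(c2))
    expect_true(all(d2$windows$a$lower <= lo + 1e-9))
    expect_true(all(d2$windows$a$upper >= hi - 1e-9))
  }
})

test_that("feature indices and class ids must fit their registers", {
  cfg <- manual_config(list(list(class = "a", feature_indices = c(40, 1),
                                 lower = c(0, 0), upper = c(1, 1))),
                       K = 48)
  expect_error(quantize_config(cfg), "40")
  many <- manual_config(lapply(1:9, function(i)
    list(class = sprintf("c%d", i), feature_indices = 0,
         lower = 0, upper = 1)), K = 4)
  expect_error(quantize_config(many), "classid")
})

test_that("the fixed-point path equals the float path on grid bounds", {
  set.seed(6)
  for (rep in 1:10) {
    # bounds already on the step-2 grid
    windows <- lapply(1:3, function(ci) {
      lo <- 2 * round(runif(2, -60, 40))
      list(class = sprintf("u%d", ci),
           feature_indices = sample(0:15, 2),
           lower = lo, upper = lo + 2 * round(runif(2, 0, 40)))
    })
    cfg <- manual_config(windows, K = 16)
    q <- quantize_config(cfg)
    m <- spike_matrix(matrix(sample(-128:127, 40 * 16, TRUE), 40, 16))
    expect_equal(emulate_sort(m, q), sort_stream(m, cfg))
  }
})

test_that("full-range windows match every spike and bounds are closed", {
  full <- manual_config(list(
    list(class = "a", feature_indices = c(0, 1),
         lower = c(-128, -128), upper = c(126, 126)),
    list(class = "b", feature_indices = c(0, 1),
         lower = c(-128, -128), upper = c(126, 126))), K = 4)
  q <- quantize_config(full)
  m <- spike_matrix(matrix(sample(-128:126, 20 * 4, TRUE), 20, 4))
  labs <- emulate_sort(m, q)
  expect_true(all(labs == "a"))  # identical windows tie -> smallest
  # spike exactly at a quantized bound is inside
  edge <- manual_config(list(list(class = "a", feature_indices = 0,
                                  lower = -14, upper = 22)), K = 2)
  qe <- quantize_config(edge)
  expect_equal(emulate_sort(spike_matrix(matrix(c(-14L, 0L), 1, 2)),
                            qe), "a")
  expect_equal(emulate_sort(spike_matrix(matrix(c(22L, 0L), 1, 2)),
                            qe), "a")
  expect_equal(emulate_sort(spike_matrix(matrix(c(23L, 0L), 1, 2)),
                            qe), "UNCLASSIFIED")
})

test_that("emulation rejects out-of-range samples and fractional steps", {
  cfg <- manual_config(list(list(class = "a", feature_indices = 0,
                                 lower = 0, upper = 10)), K = 2)
  q <- quantize_config(cfg, bit_widths(sample_bits = 4))
  m <- spike_matrix(matrix(c(100L, 0L), 1, 2))
  expect_error(emulate_sort(m, q), "range")
  q2 <- quantize_config(cfg, full_scale = 100)  # step 100/64, not integer
  expect_error(emulate_sort(spike_matrix(matrix(0L, 1, 2)), q2),
               "integer")
})

test_that("quantization only widens windows: float matches are kept", {
  for (s in 1:5) {
    tpl <- generate_templates(3, K = 48, seed = 300 + s)
    spec <- channel_spec(templates = tpl, snr_per_unit = 10,
                         n_spikes = 120, seed = 300 + s)
    m <- synthesize_channel(spec)
    sets <- select_all_features(m, L = 2, max_feature = 32)
    cfg <- fit_windows(m, sets)
    dq <- dequantize_config(quantize_config(cfg))
    for (r in seq_len(nrow(m$waveforms))) {
      fm <- classify_spike(m$waveforms[r, ], cfg)$matched_labels
      qm <- classify_spike(m$waveforms[r, ], dq)$matched_labels
      expect_true(all(fm %in% qm))
    }
  }
})

test_that("register images serialize with a memory map", {
  cfg <- manual_config(list(
    list(class = "a", feature_indices = c(3, 9), lower = c(-20, 0),
         upper = c(10, 40)),
    list(class = "b", feature_indices = c(1, 2), lower = c(-6, -8),
         upper = c(6, 8))), K = 16)
  q <- quantize_config(cfg)
  p <- withr::local_tempfile(fileext = ".hex")
  write_register_image(q, p)
  lines <- readLines(p)
  expect_length(lines, 2 * 2 * 4)  # classes x dims x registers
  expect_true(all(grepl("^[0-9A-F]+$", lines)))
  map <- jsonlite::read_json(paste0(p, ".map.json"),
                             simplifyVector = TRUE)
  expect_equal(map$step, 2)
  expect_equal(map$widths$index_bits, 5)
})
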