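test_that("class statistics match hand arithmetic", {
  m <- tiny_matrix(rbind(c(0, 2), c(2, 2), c(5, 5), c(5, 5), c(5, 5)),
                   labels = c("a", "a", "b", "b", "b"))
  st <- estimate_class_stats(m)
  a <- st[st$class == "a", ]
  expect_equal(a$mean, c(1, 2))
  expect_equal(a$sd, c(sqrt(2), 0))
  expect_equal(unique(a$prior), 2 / 5)
  b <- st[st$class == "b", ]
  expect_equal(b$sd, c(0, 0))
  # priors sum to 1 over classes
  expect_equal(sum(tapply(st$prior, st$class, unique)), 1)

  m1 <- tiny_matrix(rbind(c(0, 0), c(1, 1), c(2, 2)),
                    labels = c("a", "a", "b"))
  expect_error(estimate_class_stats(m1), "class 'b'")
})

test_that("discrimination index matches its closed forms", {
  expect_equal(as.numeric(discrimination_index(3, 3, 1, 5, 0.2, 0.8)),
               1)
  d <- discrimination_index(0, 3, 2, 2, 0.5, 0.5)
  expect_equal(as.numeric(d), exp(1.5), tolerance = 1e-12)
  expect_false(attr(d, "degenerate"))
  dg <- discrimination_index(0, 1, 0, 0, 0.5, 0.5)
  expect_equal(as.numeric(dg), exp(30))
  expect_true(attr(dg, "degenerate"))
  # 0/0 convention
  d0 <- discrimination_index(2, 2, 0, 0, 0.5, 0.5)
  expect_equal(as.numeric(d0), 1)
  # symmetry and d >= 1 on random inputs
  set.seed(1)
  for (i in 1:50) {
    mu <- rnorm(2); sdv <- runif(2, 0.1, 3); p <- runif(1, 0.05, 0.95)
    dij <- as.numeric(discrimination_index(mu[1], mu[2], sdv[1],
                                           sdv[2], p, 1 - p))
    dji <- as.numeric(discrimination_index(mu[2], mu[1], sdv[2],
                                           sdv[1], 1 - p, p))
    expect_equal(dij, dji, tolerance = 1e-12)
    expect_gte(dij, 1)
  }
})

test_that("class saliency matches closed forms and AM-GM structure", {
  # two classes, literal weighting
  s2 <- class_saliency(exp(1), 0.5)
  expect_equal(s2$saliency, 2, tolerance = 1e-12)
  # three equal classes
  s3 <- class_saliency(c(exp(1), exp(1)), c(1 / 3, 1 / 3))
  expect_equal(s3$saliency, 1.5 * exp(1 / 3), tolerance = 1e-12)
  expect_equal(s3$homogeneity, 1, tolerance = 1e-12)
  # equal d across j gives H = 1 under any priors
  s_eq <- class_saliency(rep(2.5, 3), c(0.1, 0.3, 0.4))
  expect_equal(s_eq$homogeneity, 1, tolerance = 1e-12)
  # H in (0, 1] and saliency > 0 on random instances; renormalized
  # saliency equals G x H exactly
  set.seed(2)
  for (i in 1:100) {
    n_other <- sample(1:3, 1)
    d <- exp(runif(n_other, 0, 4))
    p <- runif(n_other, 0.05, 0.5)
    lit <- class_saliency(d, p)
    expect_gt(lit$homogeneity, 0)
    expect_lte(lit$homogeneity, 1 + 1e-12)
    expect_gt(lit$saliency, 0)
    ren <- class_saliency(d, p, renormalize = TRUE)
    expect_equal(ren$saliency, ren$geo_mean * ren$homogeneity,
                 tolerance = 1e-12)
  }
})

test_that("profiles agree with elementwise saliency calls", {
  m <- random_small_matrix(5, K = 8, n_classes = 3)
  st <- estimate_class_stats(m)
  prof <- build_profiles(m)
  cl <- "u2"
  others <- c("u1", "u3")
  p_other <- vapply(others, function(cj)
    unique(st$prior[st$class == cj]), numeric(1))
  for (k in 0:7) {
    d <- vapply(others, function(cj) {
      si <- st[st$class == cl & st$feature == k, ]
      sj <- st[st$class == cj & st$feature == k, ]
      as.numeric(discrimination_index(si$mean, sj$mean, si$sd, sj$sd,
                                      si$prior, sj$prior))
    }, numeric(1))
    expect_equal(
      prof$saliency[prof$class == cl & prof$feature == k],
      class_saliency(d, p_other, renormalize = TRUE)$saliency,
      tolerance = 1e-9)
  }
})

test_that("a class duplicated under two labels has d = 1 throughout", {
  set.seed(7)
  block <- matrix(round(rnorm(40 * 6, 0, 10)), 40, 6)
  m <- spike_matrix(rbind(block, block),
                    labels = rep(c("a", "b"), each = 40))
  prof <- build_profiles(m)
  expect_true(all(vapply(prof$d, function(v) all(v == 1),
                         logical(1))))
  expect_true(all(abs(prof$saliency - 1) < 1e-12))
})

test_that("feature correlation is absolute, class-conditional Pearson", {
  set.seed(8)
  x <- round(rnorm(50, 0, 20))
  w <- cbind(x, -2 * x, round(rnorm(50, 0, 20)), 7)
  m <- spike_matrix(w, labels = rep(c("a", "b"), 25))
  expect_equal(feature_correlation(m, "a", 0, 0), 1)
  expect_equal(feature_correlation(m, "a", 0, 1), 1)
  expect_equal(feature_correlation(m, "a", 0, 3), 0)  # zero variance
  set.seed(9)
  big <- spike_matrix(matrix(round(rnorm(20000, 0, 50)), 10000, 2),
                      labels = rep("a", 10000))
  big$labels[1] <- "b"  # keep >= 2 classes irrelevant here
  expect_lt(feature_correlation(big, "a", 0, 1), 0.05)
})

test_that("greedy selection finds a planted feature and exhausts K", {
  set.seed(10)
  base <- matrix(round(rnorm(120 * 20, 0, 4)), 120, 20)
  base[61:120, 14] <- base[61:120, 14] + 40  # 0-based feature 13
  m <- spike_matrix(base, labels = rep(c("a", "b"), each = 60))
  for (cl in c("a", "b")) {
    fs <- select_salient_features(m, cl, L = 1)
    expect_equal(fs$indices[1], 13)
  }
  fs_all <- select_salient_features(m, "a", L = 20)
  expect_setequal(fs_all$indices, 0:19)
  expect_error(select_salient_features(m, "a", L = 21), "L")
})

test_that("each greedy step matches the exhaustive oracle", {
  for (s in 1:20) {
    m <- random_small_matrix(s, K = sample(6:12, 1))
    cl <- sample(unique(m$labels), 1)
    L <- 3
    fs <- select_salient_features(m, cl, L = L)
    sel <- integer(0)
    for (l in seq_len(L)) {
      expect_equal(fs$indices[l], oracle_next_feature(m, cl, sel),
                   info = sprintf("seed %d step %d", s, l))
      sel <- c(sel, fs$indices[l])
    }
  }
})

test_that("saliency and selection are invariant to amplitude scaling", {
  m <- random_small_matrix(11, K = 8, n_classes = 3)
  m3 <- spike_matrix(m$waveforms * 3L, labels = m$labels)
  p1 <- build_profiles(m); p3 <- build_profiles(m3)
  expect_equal(p1$saliency, p3$saliency, tolerance = 1e-9)
  expect_equal(p1$homogeneity, p3$homogeneity, tolerance = 1e-9)
  f1 <- select_salient_features(m, "u1", L = 4)
  f3 <- select_salient_features(m3, "u1", L = 4)
  expect_identical(f1$indices, f3$indices)
})

test_that("profile argmax equals the first selected feature", {
  for (s in c(3, 14, 25)) {
    m <- random_small_matrix(s, K = 9)
    prof <- build_profiles(m)
    for (cl in unique(m$labels)) {
      sal <- prof$saliency[prof$class == cl]
      feat <- prof$feature[prof$class == cl]
      expect_equal(
        select_salient_features(m, cl, L = 1,
                                profile = prof)$indices[1],
        feat[which.max(sal)])
    }
  }
})

test_that("feature sets serialize to JSON", {
  m <- random_small_matrix(1, K = 8)
  sets <- select_all_features(m, L = 2)
  p <- withr::local_tempfile(fileext = ".json")
  write_feature_sets(sets, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(nrow(back), length(sets))
  expect_equal(back$indices[[1]], sets[[1]]$indices)
})
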