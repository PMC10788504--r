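test_that("no sources and no propagation yields an all-zero raster", {
  w <- matrix(0, 4, 4)
  gt <- ground_truth(w, w, cbind(1, 2), effect_size = 1,
                     miss_attenuation = 1, spontaneous_rate = 0,
                     sigma_target = 0)
  r <- simulate_cascades(gt, "rest", n_bins = 50, seed = 1)
  expect_equal(sum(r), 0)
})

test_that("a probability-1 edge always fires", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- 1
  gt <- ground_truth(w, w, cbind(1, 2), effect_size = 1,
                     miss_attenuation = 1, spontaneous_rate = 0,
                     sigma_target = 1)
  fired <- vapply(1:200, function(s) {
    r <- simulate_cascades(gt, "rest", n_bins = 3, seed = s, init = 1)
    r[2, 2]
  }, logical(1))
  expect_true(all(fired))
})

test_that("condition and outcome labels are validated", {
  gt <- make_ground_truth(n_regions = 10)
  expect_error(simulate_cascades(gt, "sleep", n_bins = 5),
               class = "avalanchr_label_error")
  expect_error(simulate_cascades(gt, "mi", outcome = "draw", n_bins = 5),
               class = "avalanchr_label_error")
})

test_that("miss trials interpolate between conditions", {
  gt <- make_ground_truth(n_regions = 12, effect_size = 2,
                          miss_attenuation = 0.5)
  w_hit <- avalanchr:::trial_weights(gt, "mi", "hit")
  w_miss <- avalanchr:::trial_weights(gt, "mi", "miss")
  w_rest <- avalanchr:::trial_weights(gt, "rest")
  expect_equal(w_hit, gt$weights_mi)
  expect_equal(w_rest, gt$weights_rest)
  expect_equal(w_miss, w_rest + 0.5 * (w_hit - w_rest))
  # attenuation 1 makes hit and miss identical
  gt1 <- make_ground_truth(n_regions = 12, effect_size = 2,
                           miss_attenuation = 1)
  expect_equal(avalanchr:::trial_weights(gt1, "mi", "miss"),
               avalanchr:::trial_weights(gt1, "mi", "hit"))
})

test_that("resting rows realize the target branching ratio exactly", {
  for (st in c(0.8, 1)) {
    gt <- make_ground_truth(n_regions = 30, sigma_target = st)
    expect_equal(rowSums(gt$weights_rest), rep(st, 30), tolerance = 1e-12)
  }
  gt <- make_ground_truth(n_regions = 30, effect_size = 2)
  diff_idx <- which(gt$weights_mi != gt$weights_rest)
  planted_idx <- (gt$planted_edges[, 2] - 1) * 30 + gt$planted_edges[, 1]
  expect_setequal(diff_idx, planted_idx)
})

test_that("embedding empty rasters crosses threshold at the analytic rate", {
  raster <- matrix(FALSE, 4, 5000)
  sig <- embed_signals(raster, threshold_z = 3, seed = 21)
  data <- epoched_data(list(sig), 250, condition = "mi")
  frac <- mean(binarize(data, 3)$active[[1]])
  p <- 2 * (1 - pnorm(3))
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / length(raster)))
})

test_that("embed -> binarize round-trips planted cells bit-exactly", {
  set.seed(22)
  for (threshold in c(2, 3)) {
    for (len in 1:3) {
      raster <- random_raster(6, 200, density = 0.02)
      sig <- embed_signals(raster, bin_length_samples = len,
                           threshold_z = threshold, seed = 100 + len)
      expect_equal(ncol(sig), 200 * len)
      data <- epoched_data(list(sig), 250, condition = "mi")
      rebin <- binarize(data, threshold, len)$active[[1]]
      expect_true(all(rebin[raster]))
    }
  }
})

test_that("embedding is deterministic given the seed and checks geometry", {
  set.seed(99)
  raster <- random_raster(3, 200, 0.02)
  expect_identical(embed_signals(raster, seed = 5), embed_signals(raster, seed = 5))
  expect_error(embed_signals(raster, bin_length_samples = 2, n_samples = 20),
               class = "avalanchr_geometry_error")
  expect_error(embed_signals(matrix(TRUE, 2, 50), threshold_z = 3),
               class = "avalanchr_embed_error")
})

test_that("cohorts are byte-reproducible and respect degenerate jitter", {
  spec <- cohort_spec("small", n_subjects = 3, n_trials_per_condition = 4,
                      subject_variability = 0, seed = 9)
  gt <- make_ground_truth(n_regions = 19)
  ch1 <- make_cohort(spec, gt, signal = "raster")
  ch2 <- make_cohort(spec, gt, signal = "raster")
  expect_identical(ch1$subjects[[2]]$active, ch2$subjects[[2]]$active)
  expect_identical(ch1$scores, ch2$scores)
  # zero jitter: all subjects share the ground-truth weights exactly
  expect_equal(unique(ch1$scores$realized_effect),
               ch1$scores$realized_effect[1])
})

test_that("null cohorts show no MI-vs-Rest difference in avalanche counts", {
  rejections <- 0
  for (s in 1:8) {
    spec <- cohort_spec("small", n_subjects = 1,
                        n_trials_per_condition = 20, seed = 200 + s)
    gt <- make_ground_truth(n_regions = 19, effect_size = 1)
    ch <- make_cohort(spec, gt, signal = "raster")
    subj <- ch$subjects[[1]]
    counts <- vapply(subj$active, function(m) {
      nrow(segment_avalanches(m))
    }, numeric(1))
    p <- wilcox.test(counts[subj$trials$condition == "mi"],
                     counts[subj$trials$condition == "rest"],
                     exact = FALSE)$p.value
    rejections <- rejections + (p < 0.01)
  }
  expect_lte(rejections, 1)
})

test_that("BCI scores increase with the realized planted effect", {
  spec <- cohort_spec("paper", n_subjects = 12, n_trials_per_condition = 2,
                      seed = 31)
  gt <- make_ground_truth(n_regions = 68, effect_size = 2)
  ch <- make_cohort(spec, gt, signal = "raster")
  expect_true(all(ch$scores$bci_score >= 0 & ch$scores$bci_score <= 1))
  expect_gt(cor(ch$scores$bci_score, ch$scores$realized_effect,
                method = "spearman"), 0.3)
})

test_that("collect_avalanches returns at least the requested multi-bin runs", {
  gt <- make_ground_truth(n_regions = 19)
  catalog <- collect_avalanches(gt, n_avalanches = 50, n_bins = 500, seed = 3)
  expect_gte(sum(catalog$duration_bins >= 2), 50)
  expect_identical(
    catalog,
    collect_avalanches(gt, n_avalanches = 50, n_bins = 500, seed = 3)
  )
})
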