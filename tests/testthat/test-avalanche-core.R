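test_that("binarize rejects zero-variance regions with an informative error", {
  sig <- list(rbind(rep(1, 50), rnorm(50)))
  data <- epoched_data(sig, 250, condition = "mi")
  err <- expect_error(binarize(data), class = "avalanchr_zero_variance_error")
  expect_match(conditionMessage(err), "Region 1")
  expect_match(conditionMessage(err), "trial 1")
})

test_that("binarize crossing rate on white noise matches the normal tail", {
  set.seed(41)
  n <- 10000
  data <- epoched_data(list(matrix(rnorm(2 * n), 2, n)), 250,
                       condition = "mi")
  raster <- binarize(data, threshold_z = 3, bin_length_samples = 1)
  p <- 2 * (1 - pnorm(3))
  frac <- mean(raster$active[[1]])
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / (2 * n)))
})

test_that("a single large deflection is detected and OR-binning keeps it", {
  set.seed(7)
  m <- matrix(rnorm(2 * 300), 2, 300)
  m[1, 101] <- 10 * sd(m[1, ])
  data <- epoched_data(list(m), 250, condition = "rest")
  for (len in 1:3) {
    raster <- binarize(data, threshold_z = 3, bin_length_samples = len)
    expect_true(raster$active[[1]][1, ceiling(101 / len)])
  }
})

test_that("avalanche segmentation finds maximal runs and flags truncation", {
  m <- matrix(FALSE, 3, 12)
  m[1, 2:4] <- TRUE
  m[c(2, 3), 7:8] <- TRUE
  cat1 <- segment_avalanches(m)
  expect_equal(nrow(cat1), 2)
  expect_equal(cat1$duration_bins, c(3L, 2L))
  expect_equal(cat1$start_bin, c(2L, 7L))
  expect_false(any(cat1$truncated_start | cat1$truncated_end))
  expect_equal(cat1$size, c(3, 4))

  expect_equal(nrow(segment_avalanches(matrix(FALSE, 3, 5))), 0)

  full <- segment_avalanches(matrix(TRUE, 2, 6))
  expect_equal(nrow(full), 1)
  expect_equal(full$duration_bins, 6L)
  expect_true(full$truncated_start && full$truncated_end)
})

test_that("transition matrix matches the hand-enumerated example", {
  # bins: {A}, {B}, {B, C}
  av <- raster_from_bins(3, list(1, 2, c(2, 3)))
  atm <- transition_matrix(av)
  expect_equal(unclass(atm)[1, ], c(0, 1, 0), ignore_attr = TRUE)
  expect_equal(unclass(atm)[2, ], c(0, 1, 1), ignore_attr = TRUE)
  expect_equal(unclass(atm)[3, ], c(0, 0, 0), ignore_attr = TRUE)
})

test_that("self-persistence and zero-successor conventions hold", {
  alone <- raster_from_bins(2, list(1, 1))
  expect_equal(unclass(transition_matrix(alone))[1, 1], 1)
  # region 2 active only in the final bin: all-zero row, not NaN
  last_only <- raster_from_bins(2, list(1, c(1, 2)))
  expect_equal(unclass(transition_matrix(last_only))[2, ], c(0, 0),
               ignore_attr = TRUE)
  # single-bin avalanche has no transitions
  expect_null(transition_matrix(raster_from_bins(2, list(1))))
})

test_that("average_atm is the edge-wise arithmetic mean", {
  m0 <- avalanchr:::new_transition_matrix(matrix(0, 2, 2), "avalanche", 1L)
  m1 <- avalanchr:::new_transition_matrix(matrix(1, 2, 2), "avalanche", 1L)
  expect_equal(unclass(average_atm(list(m1))), matrix(1, 2, 2),
               ignore_attr = TRUE)
  avg <- average_atm(list(m0, m1, NULL))
  expect_equal(unclass(avg), matrix(0.5, 2, 2), ignore_attr = TRUE)
  expect_equal(attr(avg, "n_avalanches_averaged"), 2L)
  expect_error(average_atm(list(NULL)), class = "avalanchr_empty_error")
})

test_that("transition matrices agree exactly with the brute-force oracle", {
  set.seed(11)
  for (rep in 1:20) {
    r <- sample(2:5, 1)
    av <- random_raster(r, sample(2:8, 1), density = 0.5)
    av[sample(r, 1), ] <- TRUE # keep every bin active so it is one avalanche
    expect_equal(unclass(transition_matrix(av)), brute_force_atm(av),
                 ignore_attr = TRUE)
  }
})

test_that("fast trial ATMs equal averaged per-avalanche matrices", {
  set.seed(12)
  raster <- binary_raster(
    active = lapply(1:4, function(i) random_raster(5, 40, 0.12)),
    threshold_z = 3, bin_length_samples = 1,
    condition = c("mi", "mi", "rest", "rest")
  )
  ta <- suppressMessages(extract_trial_atms(raster))
  seg <- segment_avalanches(raster)
  for (tr in 1:4) {
    slices <- seg$active[seg$trial == tr & seg$duration_bins >= 2]
    if (length(slices) == 0) {
      expect_equal(ta$n_avalanches[tr], 0L)
    } else {
      ref <- Reduce(`+`, lapply(slices, brute_force_atm)) / length(slices)
      expect_equal(unclass(ta$atm[[tr]]), ref, tolerance = 1e-12,
                   ignore_attr = TRUE)
      expect_equal(ta$n_avalanches[tr], length(slices))
    }
  }
})

test_that("ATM entries stay in [0,1] and inactive sources give zero rows", {
  set.seed(13)
  av <- random_raster(6, 20, 0.2)
  av[6, ] <- FALSE            # region never active
  av[, colSums(av) == 0] <- NA # avoid empty bins inside the run
  av[is.na(av)] <- FALSE
  av[1, ] <- TRUE             # force a single maximal run
  atm <- transition_matrix(av)
  expect_true(all(atm >= 0 & atm <= 1))
  expect_equal(unclass(atm)[6, ], rep(0, 6), ignore_attr = TRUE)
})

test_that("avalanche count is non-increasing with coarser bins", {
  set.seed(14)
  for (rep in 1:10) {
    raster <- binary_raster(list(random_raster(6, 60, 0.08)),
                            threshold_z = 3, bin_length_samples = 1,
                            condition = "mi")
    counts <- sapply(1:3, function(len) {
      r2 <- raster
      r2$active <- lapply(r2$active, avalanchr:::or_bin, len)
      nrow(segment_avalanches(r2))
    })
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("the pipeline is invariant to region ordering", {
  set.seed(15)
  av <- random_raster(5, 12, 0.4)
  av[2, ] <- TRUE
  perm <- sample(5)
  atm <- unclass(transition_matrix(av))
  atm_perm <- unclass(transition_matrix(av[perm, ]))
  expect_equal(atm_perm, atm[perm, perm], ignore_attr = TRUE)
})

test_that("branching ratio follows the per-avalanche geometric-mean formula", {
  one <- tibble::tibble(duration_bins = 3L, n_events = list(c(1, 2, 4)))
  expect_equal(branching_ratio(one)$sigma, 2)

  two <- tibble::tibble(
    duration_bins = c(2L, 2L),
    n_events = list(c(1, 2), c(2, 1))
  )
  est <- branching_ratio(two)
  expect_equal(est$per_avalanche_sigmas, c(2, 0.5))
  expect_equal(est$sigma, 1)

  doubling <- tibble::tibble(duration_bins = 5L,
                             n_events = list(c(1, 2, 4, 8, 16)))
  expect_equal(branching_ratio(doubling)$sigma, 2)

  # single-bin avalanches are excluded and counted
  mixed <- tibble::tibble(duration_bins = c(1L, 3L),
                          n_events = list(3, c(1, 2, 4)))
  est2 <- branching_ratio(mixed)
  expect_equal(est2$sigma, 2)
  expect_equal(est2$n_single_bin_excluded, 1L)

  only_single <- tibble::tibble(duration_bins = 1L, n_events = list(2))
  expect_error(branching_ratio(only_single), class = "avalanchr_empty_error")
})

test_that("condition averages weight trials equally and skip empty trials", {
  m1 <- matrix(0.2, 2, 2)
  m2 <- matrix(0.6, 2, 2)
  ta <- fake_trial_atms(list(m1, m2, m2), c("mi", "mi", "rest"))
  ta$n_avalanches[2] <- 5L # trial averaging must ignore avalanche counts
  ca <- condition_atms(ta)
  expect_equal(unclass(ca$atm[[which(ca$condition == "mi")]]),
               matrix(0.4, 2, 2), ignore_attr = TRUE)
  expect_equal(ca$n_trials_used, c(2L, 1L))
})
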