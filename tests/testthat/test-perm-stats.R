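test_that("BH step-up matches the hand-worked example", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06)
  out <- bh_correct(p, alpha = 0.05)
  expect_equal(out$reject, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(out$threshold, 0.008)
  expect_equal(bh_correct(rep(1, 5))$reject, rep(FALSE, 5))
  expect_equal(bh_correct(rep(0, 5))$reject, rep(TRUE, 5))
  expect_equal(bh_correct(numeric(0))$reject, logical(0))
})

test_that("identical condition ensembles produce a flat edge test", {
  m <- matrix(runif(9), 3, 3)
  ta <- fake_trial_atms(rep(list(m), 8), rep(c("mi", "rest"), each = 4))
  et <- subject_edge_test(ta, n_permutations = 200, seed = 1)
  expect_equal(et$observed_diff, matrix(0, 3, 3))
  expect_false(any(et$significant))
  expect_true(all(et$p_values > 0.99))
})

test_that("exhaustive mode reproduces full enumeration at 3v3", {
  set.seed(2)
  mats <- replicate(6, matrix(runif(4), 2, 2), simplify = FALSE)
  cond <- c("mi", "rest", "mi", "rest", "mi", "rest")
  ta <- fake_trial_atms(mats, cond)
  et <- subject_edge_test(ta, n_permutations = 10000, seed = 1)
  expect_equal(et$method, "exhaustive")
  expect_equal(et$n_permutations, choose(6, 3))
  oracle <- matrix(exhaustive_edge_p(mats, cond), 2, 2, byrow = TRUE)
  expect_equal(et$p_values, oracle, tolerance = 1e-12)
})

test_that("Monte-Carlo p-values converge to the exhaustive oracle", {
  set.seed(3)
  mats <- replicate(8, matrix(runif(4), 2, 2), simplify = FALSE)
  cond <- rep(c("mi", "rest"), each = 4)
  ta <- fake_trial_atms(mats, cond)
  n_perm <- 4000
  mc <- subject_edge_test(ta, n_permutations = n_perm, seed = 4,
                          exhaustive = FALSE)
  oracle <- matrix(exhaustive_edge_p(mats, cond), 2, 2, byrow = TRUE)
  expect_equal(mc$method, "montecarlo")
  expect_true(all(abs(mc$p_values - oracle) <= 2 / sqrt(n_perm)))
  expect_true(all(mc$p_values >= 1 / (n_perm + 1)))
})

test_that("degenerate labels are rejected", {
  m <- matrix(runif(4), 2, 2)
  ta <- fake_trial_atms(rep(list(m), 4), c("mi", "mi", "mi", "rest"))
  expect_error(subject_edge_test(ta, 100),
               class = "avalanchr_degenerate_labels")
})

test_that("group reliability finds a universally significant edge", {
  set.seed(6)
  r <- 10
  tests <- lapply(1:15, function(s) {
    sig <- matrix(FALSE, r, r)
    sig[sample(r * r, 2)] <- TRUE # ~2% density noise edges
    sig[3, 7] <- TRUE             # planted concordant edge
    fake_edge_test(sig, sprintf("S%02d", s))
  })
  rel <- group_reliability(tests, n_permutations = 4000, alpha = 0.05,
                           seed = 7)
  expect_equal(rel$concordance_counts[3, 7], 15)
  expect_true(rel$reliable[3, 7])
  # binomial oracle: 15 hits at per-subject density ~5/400 is astronomically
  # unlikely, so the permutation p must sit at its floor
  expect_equal(rel$p_values[3, 7], 1 / 4001)
  expect_error(group_reliability(tests[1], 100))
})

test_that("no significant edges anywhere means nothing is reliable", {
  tests <- lapply(1:5, function(s) fake_edge_test(matrix(FALSE, 6, 6)))
  rel <- group_reliability(tests, n_permutations = 200, seed = 1)
  expect_false(any(rel$reliable))
  expect_true(all(rel$p_values == 1))
})

test_that("random significance placement stays below the FDR level", {
  set.seed(8)
  fracs <- vapply(1:10, function(rep) {
    tests <- lapply(1:12, function(s) {
      sig <- matrix(FALSE, 15, 15)
      sig[sample(225, 8)] <- TRUE
      fake_edge_test(sig)
    })
    mean(group_reliability(tests, n_permutations = 500, seed = rep)$reliable)
  }, numeric(1))
  expect_lte(mean(fracs), 0.05)
})

test_that("node concordance flags a hub and controls false positives", {
  r <- 68
  hub <- matrix(FALSE, r, r)
  hub[1, 2:6] <- TRUE
  hub[7:10, 1] <- TRUE
  nodes <- node_concordance(hub, n_permutations = 4000, seed = 9)
  expect_true(nodes$significant[1])
  expect_equal(nodes$degree[1], 9)

  empty <- node_concordance(matrix(FALSE, 10, 10), 100)
  expect_false(any(empty$significant))
  expect_true(all(empty$p_values == 1))

  set.seed(10)
  rate <- vapply(1:10, function(rep) {
    rnd <- matrix(FALSE, 30, 30)
    rnd[sample(900, 20)] <- TRUE
    mean(node_concordance(rnd, n_permutations = 300, seed = rep)$significant)
  }, numeric(1))
  expect_lte(mean(rate), 0.05)
})

test_that("hit/miss contrast is antisymmetric under outcome swap", {
  set.seed(11)
  mats <- replicate(16, matrix(runif(9), 3, 3), simplify = FALSE)
  cond <- rep(c("mi", "rest"), each = 8)
  out <- rep(c("hit", "hit", "miss", "miss"), 4)
  ta <- fake_trial_atms(mats, cond, out)
  swapped <- ifelse(out == "hit", "miss", "hit")
  ta_sw <- fake_trial_atms(mats, cond, swapped)
  hm <- hit_miss_contrast(ta, n_permutations = 50, seed = 1)
  hm_sw <- hit_miss_contrast(ta_sw, n_permutations = 50, seed = 1)
  expect_equal(hm_sw$statistic, -hm$statistic)
  expect_equal(hm_sw$summary_stat, -hm$summary_stat)
})

test_that("hit/miss contrast needs all four cells and honors the mask", {
  mats <- replicate(8, matrix(runif(4), 2, 2), simplify = FALSE)
  ta_bad <- fake_trial_atms(mats, rep(c("mi", "rest"), each = 4),
                            rep("hit", 8))
  expect_error(hit_miss_contrast(ta_bad, n_permutations = 10),
               class = "avalanchr_cell_error")

  ta <- fake_trial_atms(mats, rep(c("mi", "rest"), each = 4),
                        rep(c("hit", "miss"), 4))
  mask <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  hm <- hit_miss_contrast(ta, edge_mask = mask, n_permutations = 20, seed = 2)
  expect_equal(is.na(hm$statistic), !mask)
  expect_equal(sum(!is.na(hm$p_values)), 1)
})

test_that("area correlation recovers a planted premotor-parietal block", {
  set.seed(12)
  n_sub <- 10
  am <- synthetic_area_map(19)
  blk <- avalanchr:::planted_block(19)
  scores <- seq(0.3, 0.9, length.out = n_sub)
  diffs <- lapply(scores, function(sc) {
    d <- matrix(rnorm(19 * 19, 0, 0.02), 19, 19)
    d[blk$from, blk$to] <- d[blk$from, blk$to] + 0.3 * sc
    d
  })
  res <- bci_correlation(diffs, scores, am, n_permutations = 2000, seed = 13)
  expect_equal(dim(res$block_means), c(5, 5))
  expect_equal(sum(!is.na(res$block_p)), 25)
  expect_true(res$significant["pre/motor", "parietal"])
  expect_gt(res$block_means["pre/motor", "parietal"], 0)
})

test_that("area correlation rejects constant scores and mismatched maps", {
  diffs <- replicate(5, matrix(rnorm(16), 4, 4), simplify = FALSE)
  am <- tibble::tibble(region = sprintf("R%02d", 1:4),
                       area = c("a", "a", "b", "b"))
  expect_error(bci_correlation(diffs, rep(0.5, 5), am, 100),
               class = "avalanchr_constant_scores")
  am_bad <- am[1:3, ]
  expect_error(bci_correlation(diffs, seq(0.1, 0.5, 0.1), am_bad, 100),
               "3 regions")
})

test_that("pure-noise scores yield no significant blocks in most runs", {
  set.seed(14)
  n_sig <- vapply(1:8, function(rep) {
    diffs <- replicate(8, matrix(rnorm(19 * 19), 19, 19), simplify = FALSE)
    scores <- runif(8)
    res <- bci_correlation(diffs, scores, synthetic_area_map(19),
                           n_permutations = 500, seed = rep)
    sum(res$significant, na.rm = TRUE)
  }, numeric(1))
  expect_gte(mean(n_sig == 0), 0.75)
})

test_that("tidiers expose edge tables with matching dimensions", {
  m <- matrix(runif(9), 3, 3)
  ta <- fake_trial_atms(rep(list(m), 6), rep(c("mi", "rest"), 3))
  et <- subject_edge_test(ta, n_permutations = 100, seed = 1)
  td <- tidy(et)
  expect_equal(nrow(td), 9)
  expect_named(td, c("from", "to", "observed_diff", "p_value", "significant"))
  expect_equal(glance(et)$n_edges, 9)
})
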