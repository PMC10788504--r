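# orthonormal zero-mean rows: sample covariance of t(x) is exactly identity
unit_design <- function() {
  rbind(c(1, 1, -1, -1), c(1, -1, 1, -1)) * sqrt(3) / 2
}

test_that("CSP solves the diagonal-covariance problem in closed form", {
  z <- unit_design()
  t1 <- diag(c(sqrt(2), 1)) %*% z # class 1 covariance diag(2, 1)
  t2 <- diag(c(1, sqrt(2))) %*% z # class 2 covariance diag(1, 2)
  fit <- csp_fit(list(t1, t1, t2, t2), c("a", "a", "b", "b"),
                 n_modes = 2, shrinkage = "none")
  expect_equal(fit$eigenvalues, c(2 / 3, 1 / 3), tolerance = 1e-10)
  # filters align with the coordinate axes; variance ratio 2 on the first
  expect_lt(abs(fit$filters[1, 2]), 1e-10)
  expect_lt(abs(fit$filters[2, 1]), 1e-10)
  v1 <- var(as.vector(fit$filters[1, , drop = FALSE] %*% t1))
  v2 <- var(as.vector(fit$filters[1, , drop = FALSE] %*% t2))
  expect_equal(v1 / v2, 2, tolerance = 1e-10)
})

test_that("identical class covariances carry no discriminative modes", {
  z <- unit_design()
  fit <- csp_fit(list(z, z, z, z), c("a", "a", "b", "b"),
                 n_modes = 2, shrinkage = "none")
  expect_equal(fit$all_eigenvalues, c(0.5, 0.5), tolerance = 1e-10)
})

test_that("CSP matches a dense generalized-eigendecomposition oracle", {
  set.seed(21)
  trials <- replicate(12, matrix(rnorm(4 * 60), 4, 60), simplify = FALSE)
  labels <- rep(c("a", "b"), each = 6)
  fit <- csp_fit(trials, labels, n_modes = 8, shrinkage = "none")

  cov_of <- function(idx) {
    x <- t(do.call(cbind, lapply(trials[idx], function(m) m - rowMeans(m))))
    crossprod(x) / nrow(x)
  }
  c1 <- cov_of(1:6)
  c2 <- cov_of(7:12)
  oracle <- eigen(solve(c1 + c2) %*% c1)
  ord <- order(Re(oracle$values), decreasing = TRUE)
  expect_equal(sort(fit$all_eigenvalues, decreasing = TRUE),
               Re(oracle$values)[ord], tolerance = 1e-8)
  # with 4 regions all 4 modes are retained, in eigenvalue-descending order
  for (i in seq_len(4)) {
    w <- fit$filters[i, ] / sqrt(sum(fit$filters[i, ]^2))
    v <- Re(oracle$vectors[, ord][, i])
    v <- v / sqrt(sum(v^2))
    if (sign(v[which.max(abs(v))]) < 0) v <- -v
    expect_equal(w, v, tolerance = 1e-8)
  }
})

test_that("CSP errors on singular covariances unless shrinkage is on", {
  # 3 regions but rank-2 trials
  z <- unit_design()
  t1 <- rbind(z, z[1, ] + z[2, ])
  expect_error(csp_fit(list(t1, t1, t1, t1), c("a", "a", "b", "b"),
                       shrinkage = "none"),
               class = "avalanchr_singular_covariance")
  fit <- csp_fit(list(t1, t1, t1, t1), c("a", "a", "b", "b"),
                 shrinkage = "ledoit-wolf")
  expect_s3_class(fit, "csp_filters")
  expect_true(all(fit$shrinkage_intensity > 0))
})

test_that("CSP features are log-variances of the filtered time courses", {
  set.seed(22)
  trials <- replicate(6, matrix(rnorm(3 * 80), 3, 80), simplify = FALSE)
  fit <- csp_fit(trials, rep(c("a", "b"), 3), n_modes = 2)
  feats <- csp_features(trials, fit)
  brute <- t(sapply(trials, function(m) {
    y <- fit$filters %*% m
    log(apply(y, 1, var))
  }))
  expect_equal(feats, brute, tolerance = 1e-12)
  # doubling the amplitude shifts every feature by log 4
  feats2 <- csp_features(lapply(trials, function(m) 2 * m), fit)
  expect_equal(feats2, feats + log(4), tolerance = 1e-10)
  # degenerate zero trial is floored, not -Inf
  f0 <- csp_features(list(matrix(0, 3, 80)), fit)
  expect_true(all(is.finite(f0)))
})

test_that("ATM features flatten the directed matrix row-major", {
  m <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) m[i, j] <- (10 * i + j) / 100
  ta <- fake_trial_atms(list(m, m), c("mi", "rest"))
  feats <- atm_features(ta)
  expect_equal(dim(feats), c(2, 9))
  expect_equal(feats[1, ], c(m[1, ], m[2, ], m[3, ]) , tolerance = 1e-12)
  expect_equal(feats[1, ], feats[2, ])
  # trials without avalanches become zero vectors and are flagged
  ta$n_avalanches[2] <- 0L
  ta$atm[2] <- list(NULL)
  feats2 <- atm_features(ta)
  expect_equal(feats2[2, ], rep(0, 9))
  expect_equal(attr(feats2, "imputed"), 2L)
})

test_that("threshold selection is nested, seeded, and skips bad candidates", {
  set.seed(23)
  ch <- decoding_cohort(n_subjects = 1, n_trials_per_condition = 12, seed = 8)
  subj <- ch$subjects[[1]]
  one <- suppressWarnings(
    select_atm_threshold(subj, grid = 3, inner_splits = 3, seed = 1)
  )
  expect_equal(one$threshold_z, 3)
  # a hopeless threshold is skipped with a warning
  expect_warning(
    sel <- select_atm_threshold(subj, grid = c(3, 50), inner_splits = 3,
                                seed = 1),
    "no avalanches"
  )
  expect_equal(sel$threshold_z, 3)
  expect_true(is.na(sel$inner_accuracy[2]))
  # deterministic under a fixed seed
  s1 <- suppressWarnings(select_atm_threshold(subj, seed = 4))
  s2 <- suppressWarnings(select_atm_threshold(subj, seed = 4))
  expect_identical(s1, s2)
  expect_error(
    suppressWarnings(select_atm_threshold(subj, grid = c(40, 50), seed = 1)),
    class = "avalanchr_empty_error"
  )
})

test_that("pipeline evaluation shares splits, is seeded, and does not leak", {
  ch <- decoding_cohort(n_subjects = 1, n_trials_per_condition = 12, seed = 6)
  subj <- ch$subjects[[1]]
  r1 <- suppressWarnings(evaluate_pipelines(subj, n_splits = 3, seed = 42))
  r2 <- suppressWarnings(evaluate_pipelines(subj, n_splits = 3, seed = 42))
  expect_identical(r1$accuracies, r2$accuracies)
  expect_identical(r1$splits, r2$splits)
  expect_equal(nrow(r1$accuracies), 6)
  # both classes appear in every (stratified) test split
  for (ts in r1$splits) {
    expect_setequal(unique(subj$trials$condition[ts]), c("mi", "rest"))
  }
  # leakage canary: corrupting a pure test trial must not move the fitted
  # threshold choice of the split that holds it out
  test1 <- r1$splits[[1]]
  victim <- setdiff(test1, unlist(r1$splits[-1]))[1]
  expect_false(is.na(victim))
  subj2 <- subj
  subj2$signals[[victim]] <- subj2$signals[[victim]] * 3 +
    matrix(rnorm(length(subj2$signals[[victim]]), 0, 0.5),
           nrow(subj2$signals[[victim]]))
  r3 <- suppressWarnings(evaluate_pipelines(subj2, n_splits = 1, seed = 42))
  expect_identical(r3$splits[[1]], test1)
  expect_equal(
    r3$accuracies$threshold_z[r3$accuracies$pipeline == "atm"],
    r1$accuracies$threshold_z[r1$accuracies$pipeline == "atm"][1]
  )
})

test_that("pipeline comparison handles forced and degenerate cases", {
  acc <- tidyr::expand_grid(subject = c("S1", "S2"), split = 1:20,
                            pipeline = c("atm", "csp"))
  acc$accuracy <- 0.7
  same <- compare_pipelines(acc)
  expect_true(all(same$decision == "no_difference"))
  expect_true(all(same$degenerate))

  set.seed(24)
  acc2 <- acc
  acc2$accuracy <- ifelse(acc2$pipeline == "atm", 0.8, 0.7) +
    rnorm(nrow(acc2), 0, 0.01)
  shifted <- compare_pipelines(acc2)
  expect_true(all(shifted$decision == "atm_better"))
  expect_false(any(shifted$degenerate))
  expect_true(all(shifted$mean_diff > 0.08))
  expect_true(all(shifted$wilcoxon_p_adj < 0.05))
})
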