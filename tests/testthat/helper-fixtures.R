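# Shared fixture builders: everything is generated in code, seeded.

# regions x bins logical raster from a list of per-bin active region sets
raster_from_bins <- function(n_regions, active_sets) {
  m <- matrix(FALSE, n_regions, length(active_sets))
  for (t in seq_along(active_sets)) m[active_sets[[t]], t] <- TRUE
  m
}

# sparse random raster with roughly the requested density
random_raster <- function(n_regions, n_bins, density = 0.15) {
  matrix(runif(n_regions * n_bins) < density, n_regions, n_bins)
}

# hand-built trial_atms container from plain matrices + labels
fake_trial_atms <- function(mats, condition, outcome = NULL,
                            subject_id = "T01") {
  n <- length(mats)
  r <- nrow(mats[[1]])
  atms <- lapply(mats, function(m) {
    avalanchr:::new_transition_matrix(m, scope = "trial", n_avalanches = 1L)
  })
  out <- tibble::tibble(
    trial = seq_len(n),
    condition = tolower(condition),
    outcome = if (is.null(outcome)) rep(NA_character_, n) else tolower(outcome),
    n_avalanches = rep(1L, n),
    atm = atms
  )
  structure(
    out, class = c("trial_atms", class(out)),
    n_regions = r, region_names = sprintf("R%02d", seq_len(r)),
    threshold_z = 3, bin_length_samples = 1L, mode = "per_avalanche",
    subject_id = subject_id
  )
}

# edge_test stub carrying a given significance mask
fake_edge_test <- function(sig, subject_id = "S01") {
  structure(
    list(
      subject_id = subject_id,
      observed_diff = sig * 0.01,
      p_values = ifelse(sig, 1e-4, 0.5),
      significant = sig,
      bh_threshold = 1e-4, alpha = 0.05, n_permutations = 10000,
      method = "montecarlo", n_trials = c(mi = 10, rest = 10),
      region_names = sprintf("R%02d", seq_len(nrow(sig)))
    ),
    class = "edge_test"
  )
}

# frame-count oracle for the transition matrix of one avalanche slice
brute_force_atm <- function(active) {
  r <- nrow(active)
  dur <- ncol(active)
  num <- matrix(0, r, r)
  den <- numeric(r)
  for (t in seq_len(dur - 1)) {
    for (i in seq_len(r)) {
      if (!active[i, t]) next
      den[i] <- den[i] + 1
      for (j in seq_len(r)) {
        if (active[j, t + 1]) num[i, j] <- num[i, j] + 1
      }
    }
  }
  out <- matrix(0, r, r)
  for (i in seq_len(r)) if (den[i] > 0) out[i, ] <- num[i, ] / den[i]
  out
}

# exhaustive label-permutation oracle for the edge test
exhaustive_edge_p <- function(mats, condition) {
  a <- t(sapply(mats, function(m) as.vector(t(m))))
  n <- length(condition)
  n_mi <- sum(condition == "mi")
  obs <- colMeans(a[condition == "mi", , drop = FALSE]) -
    colMeans(a[condition == "rest", , drop = FALSE])
  sets <- utils::combn(n, n_mi)
  geq <- numeric(ncol(a))
  for (s in seq_len(ncol(sets))) {
    idx <- sets[, s]
    d <- colMeans(a[idx, , drop = FALSE]) -
      colMeans(a[-idx, , drop = FALSE])
    geq <- geq + (abs(d) >= abs(obs) - 1e-12)
  }
  geq / ncol(sets)
}

# small epoched dataset with a planted condition effect, for decoding tests
decoding_cohort <- function(n_subjects = 2, n_trials_per_condition = 32,
                            effect_size = 3, seed = 5) {
  spec <- cohort_spec("small", n_subjects = n_subjects,
                      n_trials_per_condition = n_trials_per_condition,
                      trial_duration_s = 5, seed = seed)
  gt <- make_ground_truth(n_regions = 19, effect_size = effect_size,
                          sigma_target = 0.8, spontaneous_rate = 4e-3)
  make_cohort(spec, gt, signal = "continuous")
}
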