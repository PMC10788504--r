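# MI-vs-Rest trial decoding: ATM features against a common spatial
# patterns (CSP) baseline, shared stratified shuffle splits, linear-kernel
# maximum-margin classifier, and per-subject statistical comparison.

# Ledoit-Wolf shrinkage of a sample covariance toward a scaled identity.
# X: samples x variables, already centered. Returns the shrunk covariance
# and the shrinkage intensity.
lw_shrink <- function(x) {
  n <- nrow(x)
  p <- ncol(x)
  s <- crossprod(x) / n
  mu <- mean(diag(s))
  d2 <- sum((s - diag(mu, p))^2) / p
  q <- rowSums(x^2)
  b2bar <- (sum(q^2) - 2 * sum((x %*% s) * x) + n * sum(s^2)) / n^2 / p
  b2 <- min(b2bar, d2)
  lambda <- if (d2 > 0) b2 / d2 else 0
  list(sigma = (1 - lambda) * s + lambda * diag(mu, p), lambda = lambda)
}

as_trial_list <- function(trials) {
  if (is.array(trials) && length(dim(trials)) == 3) {
    trials <- lapply(seq_len(dim(trials)[1]), function(i) trials[i, , ])
  }
  stopifnot(is.list(trials), length(trials) > 0)
  trials
}

# Class-average covariance from a set of trials (each regions x samples),
# per-trial centered, with optional Ledoit-Wolf shrinkage.
class_covariance <- function(trials, shrinkage) {
  centered <- lapply(trials, function(m) m - rowMeans(m))
  x <- t(do.call(cbind, centered)) # samples x regions
  if (shrinkage == "ledoit-wolf") {
    lw <- lw_shrink(x)
    list(sigma = lw$sigma, lambda = lw$lambda)
  } else {
    list(sigma = crossprod(x) / nrow(x), lambda = 0)
  }
}

#' Fit common spatial patterns
#'
#' Computes CSP spatial filters for two-class epoched data: the generalized
#' eigenvectors of the two class-average covariance matrices, obtained by
#' whitening their sum and eigendecomposing the first class in the whitened
#' space. The `n_modes` retained filters are the eigenvalue extremes (the
#' `n_modes / 2` most discriminative modes for each class). Filters are
#' deterministic up to sign; the sign is fixed so each filter's
#' largest-magnitude coefficient is positive.
#'
#' @param trials List of regions x samples matrices (or a trials x regions
#'   x samples array).
#' @param labels Two-class label vector (one per trial).
#' @param n_modes Number of spatial modes to retain (default 8: the 4 top
#'   and 4 bottom eigenvalue extremes).
#' @param shrinkage `"ledoit-wolf"` (default) shrinks each class covariance
#'   toward a scaled identity with automatically chosen intensity;
#'   `"none"` uses the raw covariances and fails with a hint if they are
#'   singular.
#' @return An object of class `csp_filters`: `filters` (n_modes x regions),
#'   the associated `eigenvalues` (variance ratios in the whitened space),
#'   and fit metadata.
#' @export
csp_fit <- function(trials, labels, n_modes = 8,
                    shrinkage = c("ledoit-wolf", "none")) {
  shrinkage <- match.arg(shrinkage)
  trials <- as_trial_list(trials)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) abort("CSP requires exactly two classes.")
  if (any(table(labels) < 2)) abort("Need at least 2 trials per class.")
  cls <- levels(labels)
  c1 <- class_covariance(trials[labels == cls[1]], shrinkage)
  c2 <- class_covariance(trials[labels == cls[2]], shrinkage)
  cc <- c1$sigma + c2$sigma
  ec <- eigen(cc, symmetric = TRUE)
  tol <- max(ec$values) * 1e-10
  if (any(ec$values < tol)) {
    abort(
      "Composite covariance is singular; use shrinkage = 'ledoit-wolf' or supply longer trials.",
      class = "avalanchr_singular_covariance"
    )
  }
  wh <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)
  e1 <- eigen(wh %*% c1$sigma %*% t(wh), symmetric = TRUE)
  filters_all <- t(e1$vectors) %*% wh
  p <- nrow(filters_all)
  n_modes <- min(n_modes, p)
  n_top <- ceiling(n_modes / 2)
  n_bot <- n_modes - n_top
  pick <- c(seq_len(n_top), if (n_bot > 0) (p - n_bot + 1):p)
  filters <- filters_all[pick, , drop = FALSE]
  for (i in seq_len(nrow(filters))) {
    j <- which.max(abs(filters[i, ]))
    if (filters[i, j] < 0) filters[i, ] <- -filters[i, ]
  }
  structure(
    list(
      filters = filters,
      eigenvalues = e1$values[pick],
      all_eigenvalues = e1$values,
      n_modes = n_modes,
      classes = cls,
      shrinkage = shrinkage,
      shrinkage_intensity = c(c1$lambda, c2$lambda),
      n_regions = ncol(filters)
    ),
    class = "csp_filters"
  )
}

#' @export
print.csp_filters <- function(x, ...) {
  cat(sprintf(
    "<csp_filters> %d modes x %d regions (%s shrinkage); eigenvalues %s\n",
    x$n_modes, x$n_regions, x$shrinkage,
    paste(sprintf("%.3f", x$eigenvalues), collapse = ", ")
  ))
  invisible(x)
}

#' CSP log-variance features
#'
#' Projects each trial through the fitted spatial filters and returns, per
#' mode, the log of the variance of the filtered time course (the log of
#' the average power; the log is a standard conditioning transform and is
#' monotone). Degenerate variances are floored at machine epsilon.
#'
#' @param trials List of regions x samples matrices (or 3-D array).
#' @param filters A `csp_filters` object.
#' @return A trials x modes numeric feature matrix.
#' @export
csp_features <- function(trials, filters) {
  stopifnot(inherits(filters, "csp_filters"))
  trials <- as_trial_list(trials)
  if (nrow(trials[[1]]) != filters$n_regions) {
    abort("Region count of the data does not match the fitted filters.")
  }
  feats <- t(vapply(trials, function(m) {
    y <- filters$filters %*% m
    v <- apply(y, 1, var)
    log(pmax(v, .Machine$double.eps))
  }, numeric(filters$n_modes)))
  feats
}

#' ATM feature vectors
#'
#' Flattens each trial's transition matrix into a feature vector in
#' row-major order (`regions^2` values, diagonal included; ATMs are
#' directed, so the full matrix is used). Trials without avalanches are
#' imputed as all-zero vectors and flagged in the `imputed` attribute.
#'
#' @param trial_atms A `trial_atms` tibble from [extract_trial_atms()].
#' @return A trials x regions^2 numeric matrix with attribute `imputed`.
#' @export
atm_features <- function(trial_atms) {
  stopifnot(inherits(trial_atms, "trial_atms"))
  r2 <- attr(trial_atms, "n_regions")^2
  feats <- t(vapply(seq_len(nrow(trial_atms)), function(i) {
    m <- trial_atms$atm[[i]]
    if (is.null(m)) numeric(r2) else flatten_rowmajor(unclass(m))
  }, numeric(r2)))
  attr(feats, "imputed") <- which(trial_atms$n_avalanches == 0)
  feats
}

# Linear-kernel maximum-margin classifier (C = 1) with train-set
# standardization; zero-variance features pass through unscaled.
fit_linear_svm <- function(x, y) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, s, "/")
  model <- e1071::svm(xs, as.factor(y), kernel = "linear", cost = 1,
                      scale = FALSE)
  list(model = model, mu = mu, s = s)
}

predict_linear_svm <- function(fit, x) {
  xs <- sweep(sweep(x, 2, fit$mu), 2, fit$s, "/")
  as.character(predict(fit$model, xs))
}

stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# Inner-CV threshold selection on precomputed per-threshold feature
# matrices, using only the rows in `train_idx`.
select_threshold_inner <- function(features_by_threshold, labels, train_idx,
                                   inner_splits) {
  grid <- as.numeric(names(features_by_threshold))
  y <- labels[train_idx]
  fold <- stratified_folds(y, inner_splits)
  acc <- vapply(seq_along(grid), function(g) {
    f <- features_by_threshold[[g]]
    if (is.null(f)) return(NA_real_)
    x <- f[train_idx, , drop = FALSE]
    mean(vapply(seq_len(inner_splits), function(kf) {
      tr <- fold != kf
      fit <- fit_linear_svm(x[tr, , drop = FALSE], y[tr])
      mean(predict_linear_svm(fit, x[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1)))
  }, numeric(1))
  if (all(is.na(acc))) {
    abort("No threshold in the grid yielded avalanches.",
          class = "avalanchr_empty_error")
  }
  best <- which(acc == max(acc, na.rm = TRUE))[1] # ties: smallest threshold
  list(threshold_z = grid[best], inner_accuracy = acc)
}

#' Select the ATM binarization threshold on training data
#'
#' Chooses, from a grid of z-thresholds, the one whose ATM features give
#' the best inner cross-validated accuracy on the supplied (training)
#' trials. Selection is nested: call this on the training split only, so no
#' test information leaks into the choice. Ties go to the smallest
#' threshold; grid values that produce no avalanches are skipped with a
#' warning.
#'
#' @param data An [epoched_data()] object (the training trials).
#' @param grid Candidate z-thresholds (default `c(2.5, 3, 3.5, 4)`).
#' @param bin_length_samples Bin length used for the ATMs.
#' @param inner_splits Number of stratified inner CV folds.
#' @param seed Optional integer seed for the fold assignment.
#' @return A list with `threshold_z` (the selected value) and
#'   `inner_accuracy` (per-grid-point accuracies, `NA` where skipped).
#' @export
select_atm_threshold <- function(data, grid = c(2.5, 3, 3.5, 4),
                                 bin_length_samples = 1, inner_splits = 5,
                                 seed = NULL) {
  stopifnot(inherits(data, "epoched_data"), length(grid) > 0)
  feats <- features_over_grid(data, grid, bin_length_samples)
  with_seed(seed, {
    select_threshold_inner(feats, data$trials$condition,
                           seq_len(nrow(data$trials)), inner_splits)
  })
}

# Per-threshold ATM feature matrices for all trials (label-free transform,
# so it is safe to compute once before splitting).
features_over_grid <- function(data, grid, bin_length_samples) {
  feats <- lapply(grid, function(th) {
    tryCatch(
      {
        ta <- suppressMessages(
          extract_trial_atms(data, threshold_z = th,
                             bin_length_samples = bin_length_samples)
        )
        if (all(ta$n_avalanches == 0)) {
          warn(sprintf("Threshold %.2g produced no avalanches; skipped.", th))
          NULL
        } else {
          atm_features(ta)
        }
      },
      avalanchr_zero_variance_error = function(e) {
        warn(sprintf("Threshold %.2g skipped: %s", th, conditionMessage(e)))
        NULL
      }
    )
  })
  names(feats) <- as.character(grid)
  feats
}

#' Evaluate the ATM and CSP decoding pipelines
#'
#' Benchmarks ATM features against the CSP baseline for MI-vs-Rest trial
#' classification on one subject: `n_splits` seeded stratified random
#' splits put 80% of the trials (by default) in the train split and 20% in
#' the test split; on each split both pipelines are fit on the identical
#' train trials (CSP filters + log-variance features; ATM features at a
#' z-threshold selected by nested inner CV on the train split) and scored
#' by accuracy on the identical test trials, using a linear-kernel
#' maximum-margin classifier.
#'
#' @param data An [epoched_data()] object with both conditions present.
#' @param n_splits Number of shuffle splits (default 50).
#' @param test_fraction Fraction of each class held out per split.
#' @param threshold_grid Candidate z-thresholds for the ATM pipeline.
#' @param bin_length_samples Bin length for the ATM pipeline.
#' @param n_modes Number of CSP modes (default 8).
#' @param inner_splits Inner CV folds for threshold selection.
#' @param seed Optional integer seed; fixes the split definitions and fold
#'   assignments.
#' @return An object of class `decoding_result`: an `accuracies` tibble
#'   (`split`, `pipeline`, `accuracy`, `threshold_z`), the split
#'   definitions, and parameters.
#' @export
evaluate_pipelines <- function(data, n_splits = 50, test_fraction = 0.2,
                               threshold_grid = c(2.5, 3, 3.5, 4),
                               bin_length_samples = 1, n_modes = 8,
                               inner_splits = 5, seed = NULL) {
  stopifnot(inherits(data, "epoched_data"))
  labels <- data$trials$condition
  if (any(table(labels) < 10)) {
    abort("Need at least 10 trials per class for split evaluation.")
  }
  feats <- features_over_grid(data, threshold_grid, bin_length_samples)
  n <- length(labels)
  idx_by_class <- split(seq_len(n), labels)
  rows <- vector("list", n_splits)
  splits <- vector("list", n_splits)
  with_seed(seed, {
    for (sp in seq_len(n_splits)) {
      test_idx <- sort(unlist(lapply(idx_by_class, function(ix) {
        sample(ix, max(1, round(test_fraction * length(ix))))
      }), use.names = FALSE))
      train_idx <- setdiff(seq_len(n), test_idx)
      splits[[sp]] <- test_idx
      # ATM pipeline: nested threshold selection on the train split only
      sel <- select_threshold_inner(feats, labels, train_idx, inner_splits)
      fa <- feats[[as.character(sel$threshold_z)]]
      fit_a <- fit_linear_svm(fa[train_idx, , drop = FALSE], labels[train_idx])
      acc_a <- mean(predict_linear_svm(fit_a, fa[test_idx, , drop = FALSE]) ==
                      labels[test_idx])
      # CSP pipeline on the identical split
      filt <- csp_fit(data$signals[train_idx], labels[train_idx],
                      n_modes = n_modes)
      fc_train <- csp_features(data$signals[train_idx], filt)
      fc_test <- csp_features(data$signals[test_idx], filt)
      fit_c <- fit_linear_svm(fc_train, labels[train_idx])
      acc_c <- mean(predict_linear_svm(fit_c, fc_test) == labels[test_idx])
      rows[[sp]] <- tibble(
        split = sp,
        pipeline = c("atm", "csp"),
        accuracy = c(acc_a, acc_c),
        threshold_z = c(sel$threshold_z, NA_real_)
      )
    }
  })
  structure(
    list(
      subject_id = data$subject_id,
      accuracies = dplyr::bind_rows(rows),
      splits = splits,
      params = list(
        n_splits = n_splits, test_fraction = test_fraction,
        threshold_grid = threshold_grid, n_modes = n_modes,
        bin_length_samples = bin_length_samples, inner_splits = inner_splits,
        seed = seed
      )
    ),
    class = "decoding_result"
  )
}

#' @export
print.decoding_result <- function(x, ...) {
  s <- glance(x)
  cat(sprintf("<decoding_result %s> %d splits\n", x$subject_id,
              x$params$n_splits))
  print(s)
  invisible(x)
}

#' @export
tidy.decoding_result <- function(x, ...) {
  dplyr::mutate(x$accuracies, subject = x$subject_id, .before = 1)
}

#' @export
glance.decoding_result <- function(x, ...) {
  x$accuracies %>%
    dplyr::group_by(.data$pipeline) %>%
    dplyr::summarise(
      mean_accuracy = mean(.data$accuracy),
      sd_accuracy = sd(.data$accuracy),
      n_splits = dplyr::n(),
      .groups = "drop"
    ) %>%
    dplyr::mutate(subject = x$subject_id, .before = 1)
}

#' Decode every subject of a cohort
#'
#' Runs [evaluate_pipelines()] for each subject of a synthetic cohort (which
#' must carry continuous signals, since CSP operates on them).
#'
#' @param cohort A [make_cohort()] result with `signal = "continuous"`.
#' @inheritParams evaluate_pipelines
#' @return A list of `decoding_result`, one per subject.
#' @export
evaluate_cohort <- function(cohort, n_splits = 50, test_fraction = 0.2,
                            threshold_grid = c(2.5, 3, 3.5, 4),
                            bin_length_samples = 1, n_modes = 8,
                            inner_splits = 5, seed = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (cohort$signal != "continuous") {
    abort("Decoding needs continuous signals; regenerate the cohort with signal = 'continuous'.")
  }
  with_seed(seed, {
    lapply(cohort$subjects, function(subj) {
      evaluate_pipelines(
        subj, n_splits = n_splits, test_fraction = test_fraction,
        threshold_grid = threshold_grid,
        bin_length_samples = bin_length_samples, n_modes = n_modes,
        inner_splits = inner_splits, seed = NULL
      )
    })
  })
}

#' Compare the two decoding pipelines per subject
#'
#' For each subject, runs a paired t-test (confirmed by a paired Wilcoxon
#' signed-rank test) on the per-split accuracies of the ATM and CSP
#' pipelines, corrects the t-test p-values across subjects with BH/FDR, and
#' reports a three-way decision: `"atm_better"`, `"csp_better"`, or
#' `"no_difference"`. Zero-variance accuracy differences make the tests
#' degenerate; the decision then follows the sign of the mean difference
#' and is flagged.
#'
#' @param results A `decoding_result`, a list of them, or a tidy accuracy
#'   tibble with columns `subject`, `split`, `pipeline`, `accuracy`.
#' @param alpha FDR level across subjects.
#' @return A tibble of class `pipeline_comparison`, one row per subject.
#' @export
compare_pipelines <- function(results, alpha = 0.05) {
  if (inherits(results, "decoding_result")) results <- list(results)
  acc <- if (is.data.frame(results)) results else
    purrr::map_dfr(results, tidy)
  stopifnot(all(c("subject", "split", "pipeline", "accuracy") %in% names(acc)))
  wide <- acc %>%
    dplyr::select("subject", "split", "pipeline", "accuracy") %>%
    tidyr::pivot_wider(names_from = "pipeline", values_from = "accuracy")
  per_subject <- wide %>%
    dplyr::group_by(.data$subject) %>%
    dplyr::group_modify(function(df, key) {
      d <- df$atm - df$csp
      degenerate <- sd(d) == 0
      if (degenerate) {
        t_stat <- NA_real_
        t_p <- if (all(d == 0)) 1 else 0
        w_p <- t_p
      } else {
        tt <- t.test(df$atm, df$csp, paired = TRUE)
        wt <- suppressWarnings(wilcox.test(df$atm, df$csp, paired = TRUE,
                                           exact = FALSE))
        t_stat <- unname(tt$statistic)
        t_p <- tt$p.value
        w_p <- wt$p.value
      }
      tibble(
        mean_atm = mean(df$atm), sd_atm = sd(df$atm),
        mean_csp = mean(df$csp), sd_csp = sd(df$csp),
        mean_diff = mean(d), t_statistic = t_stat, t_p = t_p,
        wilcoxon_p = w_p, degenerate = degenerate
      )
    }) %>%
    dplyr::ungroup()
  per_subject <- per_subject %>%
    dplyr::mutate(
      t_p_adj = p.adjust(.data$t_p, method = "BH"),
      wilcoxon_p_adj = p.adjust(.data$wilcoxon_p, method = "BH"),
      decision = dplyr::case_when(
        .data$t_p_adj <= alpha & .data$mean_diff > 0 ~ "atm_better",
        .data$t_p_adj <= alpha & .data$mean_diff < 0 ~ "csp_better",
        TRUE ~ "no_difference"
      )
    )
  structure(per_subject, class = c("pipeline_comparison", class(per_subject)),
            alpha = alpha)
}
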