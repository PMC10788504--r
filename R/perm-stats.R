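# Multi-level permutation statistics on avalanche transition matrices:
# subject-level edge test, group-level reliability, node-level clustering,
# hit/miss contrast, and the BCI-score correlation over functional areas.

.p_tol <- 1e-12 # tie tolerance when comparing permuted to observed statistics

#' Benjamini-Hochberg step-up correction
#'
#' Controls the false discovery rate across a family of p-values: the k
#' smallest are rejected, where k is the largest index with
#' `p_(k) <= k * alpha / m`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (`NA`s allowed;
#'   they are never rejected).
#' @param alpha FDR level.
#' @return A list with `reject` (logical vector), `threshold` (the largest
#'   rejected p-value, 0 if none), and `alpha`.
#' @export
bh_correct <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) {
    return(list(reject = logical(0), threshold = 0, alpha = alpha))
  }
  check_prob(p_values[!is.na(p_values)], "p_values")
  adj <- p.adjust(p_values, method = "BH")
  reject <- !is.na(adj) & adj <= alpha
  threshold <- if (any(reject)) max(p_values[reject]) else 0
  list(reject = reject, threshold = threshold, alpha = alpha)
}

# trials x edges feature matrix from a trial_atms object (row-major edge
# order), restricted to trials that carry an ATM.
atm_matrix <- function(trial_atms) {
  used <- trial_atms[trial_atms$n_avalanches > 0, ]
  n_dropped <- sum(trial_atms$n_avalanches == 0)
  if (n_dropped > 0) {
    warn(sprintf("Dropping %d trial(s) without avalanches from the test.",
                 n_dropped))
  }
  r2 <- attr(trial_atms, "n_regions")^2
  a <- t(vapply(used$atm, function(m) flatten_rowmajor(unclass(m)),
                numeric(r2)))
  list(a = a, trials = used)
}

#' Subject-level permutation test on ATM edges
#'
#' Tests, edge by edge (diagonal included), whether the mean MI transition
#' probability differs from the mean Rest probability, by randomly
#' reallocating the trial-specific transition matrices to the two conditions.
#' The two-sided p-value of an edge is the rank of the observed absolute
#' difference within the null distribution of absolute permuted differences,
#' with the observed allocation included (so `p >= 1 / (n_permutations + 1)`).
#' P-values are Benjamini-Hochberg corrected across all edges.
#'
#' When the number of distinct label assignments is at most
#' `n_permutations`, the full enumeration is used instead of Monte-Carlo
#' sampling (override with `exhaustive`).
#'
#' @param trial_atms A `trial_atms` tibble from [extract_trial_atms()].
#' @param n_permutations Number of label permutations (default 10000).
#' @param alpha FDR level for the BH correction across edges.
#' @param seed Optional integer seed.
#' @param exhaustive Force (`TRUE`) or forbid (`FALSE`) exhaustive
#'   enumeration; `NULL` picks it automatically.
#' @return An object of class `edge_test` with the observed difference
#'   matrix (mean MI minus mean Rest), p-value matrix, BH-significant
#'   logical matrix, and test metadata.
#' @export
subject_edge_test <- function(trial_atms, n_permutations = 10000,
                              alpha = 0.05, seed = NULL, exhaustive = NULL) {
  stopifnot(inherits(trial_atms, "trial_atms"))
  am <- atm_matrix(trial_atms)
  cond <- am$trials$condition
  n_mi <- sum(cond == "mi")
  n_rest <- sum(cond == "rest")
  if (n_mi < 2 || n_rest < 2) {
    abort("Need at least 2 usable trials per condition.",
          class = "avalanchr_degenerate_labels")
  }
  n <- n_mi + n_rest
  w_obs <- ifelse(cond == "mi", 1 / n_mi, -1 / n_rest)
  observed <- drop(w_obs %*% am$a)
  abs_obs <- abs(observed)
  n_comb <- choose(n, n_mi)
  use_exhaustive <- exhaustive %||% (n_comb <= n_permutations)
  geq <- numeric(length(observed))
  if (use_exhaustive) {
    sets <- combn(n, n_mi)
    n_used <- ncol(sets)
    for (start in seq(1, n_used, by = 1000)) {
      idx <- start:min(start + 999, n_used)
      wc <- matrix(-1 / n_rest, length(idx), n)
      for (r in seq_along(idx)) wc[r, sets[, idx[r]]] <- 1 / n_mi
      d <- abs(wc %*% am$a)
      geq <- geq + colSums(t(t(d) >= (abs_obs - .p_tol)))
    }
    p <- geq / n_used
    method <- "exhaustive"
    n_perm_used <- n_used
  } else {
    with_seed(seed, {
      done <- 0
      while (done < n_permutations) {
        nr <- min(1000, n_permutations - done)
        wc <- t(replicate(nr, w_obs[sample.int(n)]))
        d <- abs(wc %*% am$a)
        geq <- geq + colSums(t(t(d) >= (abs_obs - .p_tol)))
        done <- done + nr
      }
    })
    p <- (1 + geq) / (n_permutations + 1)
    method <- "montecarlo"
    n_perm_used <- n_permutations
  }
  bh <- bh_correct(p, alpha)
  r <- attr(trial_atms, "n_regions")
  structure(
    list(
      subject_id = attr(trial_atms, "subject_id"),
      observed_diff = matrix(observed, r, r, byrow = TRUE),
      p_values = matrix(p, r, r, byrow = TRUE),
      significant = matrix(bh$reject, r, r, byrow = TRUE),
      bh_threshold = bh$threshold,
      alpha = alpha,
      n_permutations = n_perm_used,
      method = method,
      n_trials = c(mi = n_mi, rest = n_rest),
      region_names = attr(trial_atms, "region_names")
    ),
    class = "edge_test"
  )
}

#' @export
print.edge_test <- function(x, ...) {
  cat(sprintf(
    "<edge_test %s> %d x %d edges, %d/%d MI/Rest trials, %s (%d perms): %d significant at FDR %.3g\n",
    x$subject_id %||% "?", nrow(x$p_values), ncol(x$p_values),
    x$n_trials["mi"], x$n_trials["rest"], x$method, x$n_permutations,
    sum(x$significant), x$alpha
  ))
  invisible(x)
}

#' @export
tidy.edge_test <- function(x, ...) {
  rn <- x$region_names %||% default_region_names(nrow(x$p_values))
  tibble(
    from = rep(rn, each = length(rn)),
    to = rep(rn, times = length(rn)),
    observed_diff = flatten_rowmajor(x$observed_diff),
    p_value = flatten_rowmajor(x$p_values),
    significant = as.logical(flatten_rowmajor(x$significant))
  )
}

#' @export
glance.edge_test <- function(x, ...) {
  tibble(
    subject = x$subject_id %||% NA_character_,
    n_edges = length(x$p_values),
    n_significant = sum(x$significant),
    bh_threshold = x$bh_threshold,
    n_permutations = x$n_permutations,
    method = x$method
  )
}

#' Group-level reliability of significant edges
#'
#' Counts, for each edge, in how many subjects the edge test declared it
#' significant, and compares that concordance against a null in which each
#' subject's significant edges are relocated uniformly at random over all
#' edges (diagonal included), preserving their number per subject. The
#' per-edge p-value is the probability of a null concordance at least as
#' large as observed (observed included); BH correction is applied across
#' edges. Edges passing it are the "reliable" edges.
#'
#' @param edge_results List of [subject_edge_test()] results (>= 2).
#' @inheritParams subject_edge_test
#' @return An object of class `reliability_map` with `concordance_counts`,
#'   `p_values`, and `reliable` matrices.
#' @export
group_reliability <- function(edge_results, n_permutations = 10000,
                              alpha = 0.05, seed = NULL) {
  stopifnot(is.list(edge_results), length(edge_results) >= 2)
  sig <- lapply(edge_results, function(e) {
    stopifnot(inherits(e, "edge_test"))
    e$significant
  })
  dims <- vapply(sig, dim, integer(2))
  if (any(dims != dims[, 1])) abort("Subjects have differing edge counts.")
  obs <- Reduce(`+`, lapply(sig, function(m) m * 1L))
  k <- vapply(sig, sum, integer(1))
  m_cells <- length(obs)
  obs_vec <- as.vector(obs)
  geq <- numeric(m_cells)
  with_seed(seed, {
    for (perm in seq_len(n_permutations)) {
      cells <- unlist(lapply(k[k > 0], function(ks) sample.int(m_cells, ks)),
                      use.names = FALSE)
      counts <- tabulate(as.integer(cells %||% integer(0)), nbins = m_cells)
      geq <- geq + (counts >= obs_vec)
    }
  })
  p_vec <- (1 + geq) / (n_permutations + 1)
  bh <- bh_correct(p_vec, alpha)
  r <- nrow(obs)
  structure(
    list(
      concordance_counts = obs,
      p_values = matrix(p_vec, r, r),
      reliable = matrix(bh$reject, r, r),
      alpha = alpha,
      n_permutations = n_permutations,
      n_subjects = length(sig),
      subject_edge_counts = k,
      region_names = edge_results[[1]]$region_names
    ),
    class = "reliability_map"
  )
}

#' @export
print.reliability_map <- function(x, ...) {
  cat(sprintf(
    "<reliability_map> %d subjects, %d edges: %d reliable at FDR %.3g (%d perms)\n",
    x$n_subjects, length(x$p_values), sum(x$reliable), x$alpha,
    x$n_permutations
  ))
  invisible(x)
}

#' @export
tidy.reliability_map <- function(x, ...) {
  rn <- x$region_names %||% default_region_names(nrow(x$p_values))
  tibble(
    from = rep(rn, each = length(rn)),
    to = rep(rn, times = length(rn)),
    n_subjects_significant = flatten_rowmajor(x$concordance_counts),
    p_value = flatten_rowmajor(x$p_values),
    reliable = as.logical(flatten_rowmajor(x$reliable))
  )
}

#' @export
glance.reliability_map <- function(x, ...) {
  tibble(
    n_subjects = x$n_subjects,
    n_edges = length(x$p_values),
    n_reliable = sum(x$reliable),
    reliable_fraction = mean(x$reliable),
    n_permutations = x$n_permutations
  )
}

#' Node-level clustering of reliable edges
#'
#' Tests whether reliable (or otherwise selected) edges cluster on specific
#' regions: the observed nodal degree (incoming plus outgoing incident
#' edges, diagonal counted once) is compared against degrees obtained by
#' placing the same number of edges uniformly at random over the full
#' matrix. One-sided p-values per region, BH corrected across regions.
#'
#' @param reliable A square logical edge matrix, or a `reliability_map`
#'   (its `reliable` matrix is used).
#' @inheritParams subject_edge_test
#' @return An object of class `node_result` with per-region `degree`,
#'   `p_values`, and `significant`.
#' @export
node_concordance <- function(reliable, n_permutations = 10000,
                             alpha = 0.05, seed = NULL) {
  region_names <- NULL
  if (inherits(reliable, "reliability_map")) {
    region_names <- reliable$region_names
    reliable <- reliable$reliable
  }
  stopifnot(is.matrix(reliable), nrow(reliable) == ncol(reliable))
  r <- nrow(reliable)
  reliable <- reliable & TRUE
  deg <- rowSums(reliable) + colSums(reliable) - diag(reliable)
  n_edges <- sum(reliable)
  if (n_edges == 0) {
    p <- rep(1, r)
    significant <- rep(FALSE, r)
  } else {
    geq <- numeric(r)
    with_seed(seed, {
      for (perm in seq_len(n_permutations)) {
        cells <- sample.int(r * r, n_edges)
        i <- ((cells - 1L) %% r) + 1L
        j <- ((cells - 1L) %/% r) + 1L
        dnull <- tabulate(i, r) + tabulate(j, r) - tabulate(i[i == j], r)
        geq <- geq + (dnull >= deg)
      }
    })
    p <- (1 + geq) / (n_permutations + 1)
    significant <- bh_correct(p, alpha)$reject
  }
  structure(
    list(
      degree = deg, p_values = p, significant = significant,
      n_edges = n_edges, alpha = alpha, n_permutations = n_permutations,
      region_names = region_names %||% default_region_names(r)
    ),
    class = "node_result"
  )
}

#' @export
print.node_result <- function(x, ...) {
  cat(sprintf(
    "<node_result> %d regions, %d placed edges: %d significant at FDR %.3g\n",
    length(x$degree), x$n_edges, sum(x$significant), x$alpha
  ))
  invisible(x)
}

#' @export
tidy.node_result <- function(x, ...) {
  tibble(
    region = x$region_names,
    degree = as.numeric(x$degree),
    p_value = x$p_values,
    significant = x$significant
  )
}

#' Hit/miss contrast of condition differences
#'
#' Tests, within one subject, whether the MI-vs-Rest transition difference
#' is larger on successful (hit) than unsuccessful (miss) trials. The
#' statistic per edge is
#' `|mean(MI, hit) - mean(Rest, hit)| - |mean(MI, miss) - mean(Rest, miss)|`;
#' the null reallocates hit/miss labels at random within each condition, and
#' the p-value is one-sided (greater). Evaluated on an optional edge mask
#' (typically the reliable edges); a scalar summary (the mean statistic over
#' the masked edges, with its own permutation p-value) supports aggregation
#' across subjects.
#'
#' @param trial_atms A `trial_atms` tibble with outcome labels.
#' @param edge_mask Optional square logical matrix restricting the edges
#'   tested; `NULL` tests all edges.
#' @inheritParams subject_edge_test
#' @return An object of class `hit_miss_test`.
#' @export
hit_miss_contrast <- function(trial_atms, edge_mask = NULL,
                              n_permutations = 10000, seed = NULL) {
  stopifnot(inherits(trial_atms, "trial_atms"))
  am <- atm_matrix(trial_atms)
  cond <- am$trials$condition
  out <- am$trials$outcome
  if (anyNA(out)) abort("Outcome labels are required for the hit/miss contrast.")
  cells <- table(cond, out)
  if (!all(dim(cells) == c(2, 2)) || any(cells == 0)) {
    abort("All four condition x outcome cells must be non-empty.",
          class = "avalanchr_cell_error")
  }
  r <- attr(trial_atms, "n_regions")
  if (is.null(edge_mask)) edge_mask <- matrix(TRUE, r, r)
  stopifnot(is.matrix(edge_mask), all(dim(edge_mask) == r))
  mask_vec <- as.logical(flatten_rowmajor(edge_mask))
  a <- am$a[, mask_vec, drop = FALSE]
  n <- nrow(a)

  weight_pair <- function(outc) {
    w_hit <- numeric(n)
    w_miss <- numeric(n)
    for (cc in c("mi", "rest")) {
      sgn <- if (cc == "mi") 1 else -1
      ih <- cond == cc & outc == "hit"
      im <- cond == cc & outc == "miss"
      w_hit[ih] <- sgn / sum(ih)
      w_miss[im] <- sgn / sum(im)
    }
    list(hit = w_hit, miss = w_miss)
  }
  stat_for <- function(w) abs(drop(w$hit %*% a)) - abs(drop(w$miss %*% a))
  obs <- stat_for(weight_pair(out))
  obs_summary <- mean(obs)
  geq <- numeric(length(obs))
  geq_summary <- 0
  mi_idx <- which(cond == "mi")
  rest_idx <- which(cond == "rest")
  with_seed(seed, {
    for (perm in seq_len(n_permutations)) {
      op <- out
      op[mi_idx] <- out[mi_idx][sample.int(length(mi_idx))]
      op[rest_idx] <- out[rest_idx][sample.int(length(rest_idx))]
      null_stat <- stat_for(weight_pair(op))
      geq <- geq + (null_stat >= (obs - .p_tol))
      geq_summary <- geq_summary + (mean(null_stat) >= (obs_summary - .p_tol))
    }
  })
  p <- (1 + geq) / (n_permutations + 1)
  stat_mat <- matrix(NA_real_, r, r)
  p_mat <- matrix(NA_real_, r, r)
  stat_mat[t(edge_mask)] <- obs # row-major fill via transposed index
  p_mat[t(edge_mask)] <- p
  stat_mat <- t(stat_mat)
  p_mat <- t(p_mat)
  structure(
    list(
      subject_id = attr(trial_atms, "subject_id"),
      statistic = stat_mat,
      p_values = p_mat,
      edge_mask = edge_mask,
      summary_stat = obs_summary,
      summary_p = (1 + geq_summary) / (n_permutations + 1),
      n_permutations = n_permutations,
      cell_counts = cells,
      region_names = attr(trial_atms, "region_names")
    ),
    class = "hit_miss_test"
  )
}

#' @export
print.hit_miss_test <- function(x, ...) {
  cat(sprintf(
    "<hit_miss_test %s> %d masked edges: mean contrast %.4f (p = %.4g, %d perms)\n",
    x$subject_id %||% "?", sum(x$edge_mask), x$summary_stat, x$summary_p,
    x$n_permutations
  ))
  invisible(x)
}

#' @export
tidy.hit_miss_test <- function(x, ...) {
  rn <- x$region_names %||% default_region_names(nrow(x$p_values))
  keep <- as.logical(flatten_rowmajor(x$edge_mask))
  tibble(
    from = rep(rn, each = length(rn))[keep],
    to = rep(rn, times = length(rn))[keep],
    statistic = flatten_rowmajor(x$statistic)[keep],
    p_value = flatten_rowmajor(x$p_values)[keep]
  )
}

#' Summarize hit/miss contrasts across subjects
#'
#' Runs [hit_miss_contrast()] for each subject of a list of `trial_atms`
#' and reports the per-subject summary statistic and p-value plus a
#' sign-consistency count. Subjects with an empty condition x outcome cell
#' are skipped with a warning.
#'
#' @param atms_list List of `trial_atms` (one per subject).
#' @inheritParams hit_miss_contrast
#' @return A list with `per_subject` (tibble) and `tests` (the individual
#'   `hit_miss_test` objects).
#' @export
hit_miss_summary <- function(atms_list, edge_mask = NULL,
                             n_permutations = 10000, seed = NULL) {
  with_seed(seed, {
    tests <- lapply(atms_list, function(ta) {
      tryCatch(
        hit_miss_contrast(ta, edge_mask, n_permutations, seed = NULL),
        avalanchr_cell_error = function(e) {
          warn(sprintf("Subject %s skipped: %s",
                       attr(ta, "subject_id") %||% "?", conditionMessage(e)))
          NULL
        }
      )
    })
  })
  keep <- !vapply(tests, is.null, logical(1))
  per_subject <- purrr::map_dfr(tests[keep], function(t) {
    tibble(subject = t$subject_id %||% NA_character_,
           summary_stat = t$summary_stat, summary_p = t$summary_p)
  })
  list(per_subject = per_subject, tests = tests[keep],
       n_positive = sum(per_subject$summary_stat > 0),
       n_subjects = nrow(per_subject))
}

#' Correlation between edge differences and BCI performance over areas
#'
#' Computes, for every edge, the Spearman correlation across subjects
#' between the MI-minus-Rest transition difference and the subject's BCI
#' score, averages the coefficients within every directed pair of
#' functional areas (self-connections included; with 5 areas this yields
#' 5 x 5 = 25 block means), and validates each block mean against a null in
#' which the edge-to-block assignment of the coefficients is randomly
#' reallocated. Two-sided p-values per block, BH corrected across the
#' blocks.
#'
#' Edges whose difference is constant across subjects have no defined
#' correlation; they are excluded from block averages and from the
#' reallocation pool.
#'
#' @param edge_diffs List (one element per subject) of `edge_test` objects
#'   or of observed-difference matrices.
#' @param bci_scores Numeric vector of per-subject BCI scores in `[0, 1]`.
#' @param area_map Data frame with columns `region` and `area` mapping each
#'   region to a functional area (see [default_area_map()],
#'   [synthetic_area_map()]).
#' @inheritParams subject_edge_test
#' @return An object of class `area_correlation` with `edge_correlations`
#'   (regions x regions), `block_means`, `block_p`, and `significant`
#'   (areas x areas, rows = source area).
#' @export
bci_correlation <- function(edge_diffs, bci_scores, area_map,
                            n_permutations = 10000, alpha = 0.05,
                            seed = NULL) {
  diffs <- lapply(edge_diffs, function(e) {
    if (inherits(e, "edge_test")) e$observed_diff else e
  })
  s <- length(diffs)
  if (s < 4) abort("Need at least 4 subjects for the correlation analysis.")
  stopifnot(length(bci_scores) == s)
  if (sd(bci_scores) == 0) {
    abort("BCI scores are constant; the correlation is undefined.",
          class = "avalanchr_constant_scores")
  }
  r <- nrow(diffs[[1]])
  stopifnot(all(vapply(diffs, function(m) all(dim(m) == r), logical(1))))
  stopifnot(is.data.frame(area_map), all(c("region", "area") %in% names(area_map)))
  if (nrow(area_map) != r) {
    abort(sprintf("`area_map` has %d regions but the data has %d.",
                  nrow(area_map), r))
  }
  d <- t(vapply(diffs, flatten_rowmajor, numeric(r * r))) # subjects x edges
  rank_scores <- rank(bci_scores)
  rank_d <- apply(d, 2, rank)
  rho <- suppressWarnings(as.vector(cor(rank_d, rank_scores)))
  rho[apply(d, 2, function(col) all(col == col[1]))] <- NA_real_

  areas <- factor(area_map$area, levels = unique(area_map$area))
  k <- nlevels(areas)
  from_area <- as.integer(areas)[rep(seq_len(r), each = r)]
  to_area <- as.integer(areas)[rep(seq_len(r), times = r)]
  block <- (from_area - 1L) * k + to_area
  valid <- !is.na(rho)
  counts <- tabulate(block[valid], nbins = k * k)
  obs_means <- as.vector(rowsum(rho[valid], block[valid],
                                reorder = TRUE)) / counts[counts > 0]
  # rowsum drops empty groups; rebuild a full-length vector
  means_full <- rep(NA_real_, k * k)
  means_full[sort(unique(block[valid]))] <- obs_means
  pool <- rho[valid]
  bv <- block[valid]
  ge <- numeric(k * k)
  le <- numeric(k * k)
  with_seed(seed, {
    for (perm in seq_len(n_permutations)) {
      pm <- rowsum(pool[sample.int(length(pool))], bv, reorder = TRUE)
      full <- rep(NA_real_, k * k)
      full[sort(unique(bv))] <- as.vector(pm) / counts[counts > 0]
      ge <- ge + (full >= (means_full - .p_tol))
      le <- le + (full <= (means_full + .p_tol))
    }
  })
  p <- pmin(1, 2 * pmin(1 + ge, 1 + le) / (n_permutations + 1))
  p[is.na(means_full)] <- NA_real_
  bh <- bh_correct(p, alpha)
  area_names <- levels(areas)
  structure(
    list(
      edge_correlations = matrix(rho, r, r, byrow = TRUE),
      block_means = matrix(means_full, k, k, byrow = TRUE,
                           dimnames = list(area_names, area_names)),
      block_p = matrix(p, k, k, byrow = TRUE,
                       dimnames = list(area_names, area_names)),
      significant = matrix(bh$reject, k, k, byrow = TRUE,
                           dimnames = list(area_names, area_names)),
      areas = area_names,
      alpha = alpha,
      n_permutations = n_permutations,
      n_subjects = s,
      region_names = area_map$region
    ),
    class = "area_correlation"
  )
}

#' @export
print.area_correlation <- function(x, ...) {
  cat(sprintf(
    "<area_correlation> %d subjects, %d x %d area blocks: %d significant at FDR %.3g\n",
    x$n_subjects, nrow(x$block_means), ncol(x$block_means),
    sum(x$significant, na.rm = TRUE), x$alpha
  ))
  invisible(x)
}

#' @export
tidy.area_correlation <- function(x, ...) {
  k <- length(x$areas)
  tibble(
    from_area = rep(x$areas, each = k),
    to_area = rep(x$areas, times = k),
    mean_correlation = flatten_rowmajor(x$block_means),
    p_value = flatten_rowmajor(x$block_p),
    significant = as.logical(flatten_rowmajor(x$significant))
  )
}

#' Functional-area maps
#'
#' `default_area_map()` returns the shipped assignment of the 68
#' Desikan-Killiany cortical regions to five coarse functional areas
#' (executive, pre/motor, parietal, temporal, occipital). The grouping is
#' an approximate lobe-level assignment and is meant to be edited for real
#' studies (the CSV lives in `inst/extdata/desikan_5area_map.csv`).
#'
#' `synthetic_area_map()` splits an arbitrary synthetic parcellation into
#' five contiguous groups carrying the same area labels, aligned with the
#' planted-hub layout of [make_ground_truth()]: the group holding the
#' default planted sources is `"pre/motor"`, the group holding the default
#' planted targets is `"parietal"`, and the remaining regions are split
#' into `"executive"`, `"temporal"`, and `"occipital"`.
#'
#' @param region_names Character vector of region names (or a count).
#' @return A tibble with columns `region` and `area`.
#' @export
default_area_map <- function() {
  path <- system.file("extdata", "desikan_5area_map.csv",
                      package = "avalanchr", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname default_area_map
#' @export
synthetic_area_map <- function(region_names) {
  if (is.numeric(region_names) && length(region_names) == 1) {
    region_names <- default_region_names(region_names)
  }
  n <- length(region_names)
  if (n < 14) abort("Need at least 14 regions for the 5-area map.")
  blk <- planted_block(n)
  area <- rep(NA_character_, n)
  area[blk$from] <- "pre/motor"
  area[blk$to] <- "parietal"
  gap <- setdiff((max(blk$from) + 1):(min(blk$to) - 1), c(blk$from, blk$to))
  area[gap] <- "executive"
  tail_idx <- which(is.na(area))
  half <- ceiling(length(tail_idx) / 2)
  area[tail_idx[seq_len(half)]] <- "temporal"
  area[tail_idx[-seq_len(half)]] <- "occipital"
  tibble(region = region_names,
         area = factor(area, levels = c("executive", "pre/motor", "parietal",
                                        "temporal", "occipital")) |>
           as.character())
}
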