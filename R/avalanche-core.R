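#' Epoched source-level data
#'
#' Container for one subject's epoched, source-reconstructed recording:
#' a list of regions x samples signal matrices (one per trial), the
#' sampling rate, per-trial condition (`"mi"` / `"rest"`) and optional
#' outcome (`"hit"` / `"miss"`) labels, and region names.
#'
#' @param signals List of regions x samples numeric matrices, or a 3-D
#'   array with dimensions trials x regions x samples.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param condition Per-trial condition labels, `"mi"` or `"rest"`
#'   (case-insensitive).
#' @param outcome Optional per-trial outcome labels, `"hit"` or `"miss"`.
#' @param region_names Optional character vector of region names.
#' @param subject_id Subject identifier.
#' @return An object of class `epoched_data`.
#' @export
epoched_data <- function(signals, sampling_rate_hz, condition,
                         outcome = NULL, region_names = NULL,
                         subject_id = "S01") {
  if (is.array(signals) && length(dim(signals)) == 3) {
    signals <- lapply(seq_len(dim(signals)[1]), function(tr) signals[tr, , ])
  }
  if (!is.list(signals) || length(signals) == 0) {
    abort("`signals` must be a non-empty list of regions x samples matrices.")
  }
  dims <- vapply(signals, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]
    abort(sprintf("Trial %d has dimensions %d x %d; expected %d x %d.",
                  bad, dims[1, bad], dims[2, bad], dims[1, 1], dims[2, 1]),
          class = "avalanchr_shape_error")
  }
  if (any(vapply(signals, anyNA, logical(1)))) {
    abort("Signals contain missing samples.")
  }
  n_trials <- length(signals)
  condition <- norm_labels(condition, .conditions, "condition")
  if (length(condition) != n_trials) {
    abort("`condition` length must equal the number of trials.",
          class = "avalanchr_shape_error")
  }
  if (!is.null(outcome)) {
    outcome <- norm_labels(outcome, .outcomes, "outcome")
    if (length(outcome) != n_trials) {
      abort("`outcome` length must equal the number of trials.",
            class = "avalanchr_shape_error")
    }
  } else {
    outcome <- rep(NA_character_, n_trials)
  }
  region_names <- region_names %||% rownames(signals[[1]]) %||%
    default_region_names(dims[1, 1])
  structure(
    list(
      subject_id = subject_id,
      signals = lapply(signals, unname),
      sampling_rate_hz = sampling_rate_hz,
      trials = tibble(
        trial = seq_len(n_trials),
        condition = condition,
        outcome = outcome
      ),
      region_names = region_names
    ),
    class = "epoched_data"
  )
}

#' @export
print.epoched_data <- function(x, ...) {
  cat(sprintf(
    "<epoched_data %s> %d trials x %d regions x %d samples @ %g Hz (%d MI / %d Rest)\n",
    x$subject_id, nrow(x$trials), length(x$region_names),
    ncol(x$signals[[1]]), x$sampling_rate_hz,
    sum(x$trials$condition == "mi"), sum(x$trials$condition == "rest")
  ))
  invisible(x)
}

#' Binary activation raster
#'
#' Thresholded, binned activation raster for one subject: a list of
#' regions x bins logical matrices plus the threshold and bin length that
#' produced them. Usually built by [binarize()]; the constructor is exported
#' for cohorts simulated directly at the binary level.
#'
#' @param active List of regions x bins logical matrices (one per trial).
#' @param threshold_z Threshold, in z-units, used (or assumed) to binarize.
#' @param bin_length_samples Samples per bin, an integer in `{1, 2, 3}`.
#' @inheritParams epoched_data
#' @param sampling_rate_hz Sampling rate of the underlying signal.
#' @return An object of class `binary_raster`.
#' @export
binary_raster <- function(active, threshold_z, bin_length_samples,
                          condition, outcome = NULL, region_names = NULL,
                          subject_id = "S01", sampling_rate_hz = NA_real_) {
  stopifnot(is.list(active), length(active) > 0)
  active <- lapply(active, function(m) {
    storage.mode(m) <- "logical"
    unname(m)
  })
  n_trials <- length(active)
  condition <- norm_labels(condition, .conditions, "condition")
  outcome <- if (is.null(outcome)) rep(NA_character_, n_trials) else
    norm_labels(outcome, .outcomes, "outcome")
  structure(
    list(
      subject_id = subject_id,
      active = active,
      threshold_z = threshold_z,
      bin_length_samples = as.integer(bin_length_samples),
      sampling_rate_hz = sampling_rate_hz,
      trials = tibble(trial = seq_len(n_trials), condition = condition,
                      outcome = outcome),
      region_names = region_names %||% default_region_names(nrow(active[[1]]))
    ),
    class = "binary_raster"
  )
}

#' @export
print.binary_raster <- function(x, ...) {
  frac <- mean(vapply(x$active, mean, numeric(1)))
  cat(sprintf(
    "<binary_raster %s> %d trials x %d regions x %d bins (|z| > %g, bin %d); %.2f%% active\n",
    x$subject_id, nrow(x$trials), length(x$region_names),
    ncol(x$active[[1]]), x$threshold_z, x$bin_length_samples, 100 * frac
  ))
  invisible(x)
}

# OR-bin a logical matrix over consecutive groups of `len` columns;
# trailing samples that do not fill a bin are dropped.
or_bin <- function(active, len) {
  if (len == 1) return(active)
  n_bins <- floor(ncol(active) / len)
  out <- active[, seq(1, by = len, length.out = n_bins), drop = FALSE]
  for (l in seq_len(len - 1)) {
    out <- out | active[, seq(1 + l, by = len, length.out = n_bins), drop = FALSE]
  }
  out
}

#' Binarize epoched signals
#'
#' Z-scores each region independently over time within each trial, marks a
#' sample active when `|z| > threshold_z`, and ORs samples into bins of
#' `bin_length_samples` (1-3) samples: a bin is active when any of its
#' samples crosses threshold. Trailing samples that do not fill a complete
#' bin are dropped.
#'
#' @param data An [epoched_data()] object.
#' @param threshold_z Positive threshold in z-units; activity is defined by
#'   the absolute z-value crossing it (default 3).
#' @param bin_length_samples Integer bin length in samples, 1 to 3.
#' @return A [binary_raster()].
#' @export
binarize <- function(data, threshold_z = 3, bin_length_samples = 1) {
  stopifnot(inherits(data, "epoched_data"))
  if (!is.numeric(threshold_z) || threshold_z <= 0) {
    abort("`threshold_z` must be > 0.")
  }
  bin_length_samples <- check_count(bin_length_samples, "bin_length_samples")
  if (!bin_length_samples %in% 1:3) {
    abort("`bin_length_samples` must be 1, 2, or 3.")
  }
  active <- vector("list", nrow(data$trials))
  for (tr in seq_along(active)) {
    m <- data$signals[[tr]]
    mu <- rowMeans(m)
    s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
    if (any(s == 0)) {
      r <- which(s == 0)[1]
      abort(
        sprintf(
          "Region %d (%s) has zero variance in trial %d; z-scoring is undefined.",
          r, data$region_names[r], tr
        ),
        class = "avalanchr_zero_variance_error"
      )
    }
    z <- abs((m - mu) / s)
    active[[tr]] <- or_bin(z > threshold_z, bin_length_samples)
  }
  binary_raster(
    active = active, threshold_z = threshold_z,
    bin_length_samples = bin_length_samples,
    condition = data$trials$condition, outcome = data$trials$outcome,
    region_names = data$region_names, subject_id = data$subject_id,
    sampling_rate_hz = data$sampling_rate_hz
  )
}

# Maximal runs of bins with >= 1 active region; 1-column matrix of
# start/end/truncation flags. `m` is a regions x bins logical matrix.
find_runs <- function(m) {
  any_active <- colSums(m) > 0
  if (!any(any_active)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  r <- rle(any_active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Segment neuronal avalanches
#'
#' An avalanche starts when at least one region is above threshold and
#' finishes when no region is active: within each trial, avalanches are the
#' maximal runs of consecutive bins with at least one active region. Runs
#' touching the first or last bin of a trial are kept and flagged truncated.
#'
#' @param raster A [binary_raster()], or a single regions x bins logical
#'   matrix (treated as one trial).
#' @return A tibble (one row per avalanche) with columns `trial`,
#'   `avalanche`, `start_bin`, `end_bin`, `duration_bins`, `size` (total
#'   activations), `truncated_start`, `truncated_end`, plus list-columns
#'   `n_events` (per-bin activation counts) and `active` (the regions x
#'   duration logical slice). Attributes record the region count and bin
#'   length.
#' @export
segment_avalanches <- function(raster) {
  if (is.matrix(raster)) {
    mats <- list(raster)
    bin_length <- 1L
    n_regions <- nrow(raster)
  } else {
    stopifnot(inherits(raster, "binary_raster"))
    mats <- raster$active
    bin_length <- raster$bin_length_samples
    n_regions <- length(raster$region_names)
  }
  per_trial <- lapply(seq_along(mats), function(tr) {
    m <- mats[[tr]]
    runs <- find_runs(m)
    if (nrow(runs) == 0) return(NULL)
    slices <- lapply(seq_len(nrow(runs)), function(a) {
      m[, runs$start[a]:runs$end[a], drop = FALSE]
    })
    tibble(
      trial = tr,
      avalanche = seq_len(nrow(runs)),
      start_bin = runs$start,
      end_bin = runs$end,
      duration_bins = runs$end - runs$start + 1L,
      size = vapply(slices, sum, numeric(1)),
      truncated_start = runs$start == 1L,
      truncated_end = runs$end == ncol(m),
      n_events = lapply(slices, colSums),
      active = slices
    )
  })
  out <- dplyr::bind_rows(per_trial)
  if (nrow(out) == 0) {
    out <- tibble(
      trial = integer(0), avalanche = integer(0), start_bin = integer(0),
      end_bin = integer(0), duration_bins = integer(0), size = numeric(0),
      truncated_start = logical(0), truncated_end = logical(0),
      n_events = list(), active = list()
    )
  }
  attr(out, "n_regions") <- n_regions
  attr(out, "bin_length_samples") <- bin_length
  out
}

#' Avalanche transition matrix of a single avalanche
#'
#' Entry `(i, j)` is the conditional probability that region `j` is active
#' at bin `t + 1` given region `i` was active at bin `t`, estimated over the
#' frames of one avalanche: the number of frames with `i` active at `t` and
#' `j` active at `t + 1`, divided by the number of frames (before the last
#' bin) with `i` active. The diagonal is computed identically and encodes
#' self-persistence. Rows whose source region never has a successor frame
#' are set to zero so that averaging stays well defined.
#'
#' @param avalanche A regions x duration logical matrix (one avalanche
#'   slice, e.g. from the `active` list-column of [segment_avalanches()]),
#'   or a one-row slice of that catalog.
#' @param n_regions Region count; defaults to `nrow(avalanche)`.
#' @return A `transition_matrix` (regions x regions numeric matrix with
#'   attributes `scope = "avalanche"` and `n_avalanches_averaged = 1`), or
#'   `NULL` for single-bin avalanches, which admit no transition.
#' @export
transition_matrix <- function(avalanche, n_regions = NULL) {
  if (is.data.frame(avalanche)) {
    stopifnot(nrow(avalanche) == 1, "active" %in% names(avalanche))
    avalanche <- avalanche$active[[1]]
  }
  stopifnot(is.matrix(avalanche))
  n_regions <- n_regions %||% nrow(avalanche)
  stopifnot(n_regions == nrow(avalanche))
  dur <- ncol(avalanche)
  if (dur < 2) return(NULL)
  x <- t(avalanche) * 1 # frames x regions
  num <- crossprod(x[-dur, , drop = FALSE], x[-1, , drop = FALSE])
  den <- colSums(x[-dur, , drop = FALSE])
  atm <- num / ifelse(den > 0, den, 1)
  atm[den == 0, ] <- 0
  new_transition_matrix(atm, scope = "avalanche", n_avalanches = 1L)
}

new_transition_matrix <- function(m, scope, n_avalanches) {
  structure(
    m,
    scope = scope,
    n_avalanches_averaged = as.integer(n_avalanches),
    class = c("transition_matrix", class(m))
  )
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf(
    "<transition_matrix> %d x %d, scope '%s', averaged over %d avalanche(s)\n",
    nrow(x), ncol(x), attr(x, "scope"), attr(x, "n_avalanches_averaged")
  ))
  print(unclass(x)[seq_len(min(5, nrow(x))), seq_len(min(5, ncol(x)))])
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

#' Average transition matrices edge-wise
#'
#' Arithmetic mean, entry by entry, of per-avalanche (or per-trial)
#' transition matrices. `NULL` elements (single-bin avalanches) are dropped
#' first.
#'
#' @param atms List of `transition_matrix` objects (possibly with `NULL`s).
#' @param scope Scope recorded on the result, `"trial"` or `"condition"`.
#' @return A `transition_matrix` with `n_avalanches_averaged` equal to the
#'   total number of avalanches behind the inputs.
#' @export
average_atm <- function(atms, scope = "trial") {
  atms <- atms[!vapply(atms, is.null, logical(1))]
  if (length(atms) == 0) {
    abort("No defined transition matrices to average (no multi-bin avalanches).",
          class = "avalanchr_empty_error")
  }
  total <- sum(vapply(atms, function(a) {
    attr(a, "n_avalanches_averaged") %||% 1L
  }, integer(1)))
  m <- Reduce(`+`, lapply(atms, unclass)) / length(atms)
  new_transition_matrix(m, scope = scope, n_avalanches = total)
}

#' Branching ratio of a set of avalanches
#'
#' For each avalanche spanning `Nbin >= 2` bins, the per-avalanche branching
#' parameter is the geometric mean over consecutive bins of the ratio of
#' activations in the next bin (descendants) to activations in the current
#' bin (ancestors). The overall branching ratio is the geometric mean of the
#' per-avalanche parameters. A value of 1 marks critical dynamics, below 1
#' subcritical, above 1 supercritical. Single-bin avalanches admit no ratio
#' and are excluded (their count is recorded).
#'
#' @param avalanches An avalanche catalog from [segment_avalanches()] (or
#'   [collect_avalanches()]).
#' @return An object of class `branching_estimate` with elements `sigma`,
#'   `per_avalanche_sigmas`, `n_avalanches_used`, `n_single_bin_excluded`,
#'   and `bin_length_samples`.
#' @export
branching_ratio <- function(avalanches) {
  stopifnot(is.data.frame(avalanches), "n_events" %in% names(avalanches))
  multi <- avalanches$duration_bins >= 2
  if (!any(multi)) {
    abort("No avalanche with >= 2 bins; the branching ratio is undefined.",
          class = "avalanchr_empty_error")
  }
  sigmas <- vapply(avalanches$n_events[multi], function(n) {
    exp(mean(diff(log(n))))
  }, numeric(1))
  structure(
    list(
      sigma = exp(mean(log(sigmas))),
      per_avalanche_sigmas = sigmas,
      n_avalanches_used = sum(multi),
      n_single_bin_excluded = sum(!multi),
      bin_length_samples = attr(avalanches, "bin_length_samples") %||% NA_integer_
    ),
    class = "branching_estimate"
  )
}

#' @export
print.branching_estimate <- function(x, ...) {
  cat(sprintf(
    "<branching_estimate> sigma = %.4f over %d avalanches (%d single-bin excluded), bin length %s\n",
    x$sigma, x$n_avalanches_used, x$n_single_bin_excluded,
    as.character(x$bin_length_samples)
  ))
  invisible(x)
}

#' @export
glance.branching_estimate <- function(x, ...) {
  tibble(
    sigma = x$sigma,
    n_avalanches_used = x$n_avalanches_used,
    n_single_bin_excluded = x$n_single_bin_excluded,
    bin_length_samples = x$bin_length_samples
  )
}

#' Per-trial avalanche transition matrices
#'
#' Pipeline composition binarize -> segment -> per-avalanche transition
#' matrices -> average within trial. Returns one (possibly undefined) ATM
#' per trial plus the condition labels, ready for the permutation statistics
#' and for classification. Condition-level averages are available through
#' [condition_atms()].
#'
#' @param data An [epoched_data()] (binarized internally) or a
#'   [binary_raster()] (used as is; if its bin length is 1 and a larger
#'   `bin_length_samples` is requested, bins are OR-merged).
#' @inheritParams binarize
#' @param mode `"per_avalanche"` (default) averages the per-avalanche
#'   conditional probabilities edge-wise; `"pooled"` pools transition counts
#'   across a trial's avalanches before normalizing.
#' @return A tibble of class `trial_atms` with columns `trial`, `condition`,
#'   `outcome`, `n_avalanches` and the list-column `atm` (`NULL` for trials
#'   without multi-bin avalanches, which are flagged in a message).
#' @export
extract_trial_atms <- function(data, threshold_z = 3, bin_length_samples = 1,
                               mode = c("per_avalanche", "pooled")) {
  mode <- match.arg(mode)
  if (inherits(data, "epoched_data")) {
    raster <- binarize(data, threshold_z, bin_length_samples)
  } else if (inherits(data, "binary_raster")) {
    raster <- data
    if (raster$bin_length_samples != bin_length_samples) {
      if (raster$bin_length_samples == 1L) {
        raster$active <- lapply(raster$active, or_bin, bin_length_samples)
        raster$bin_length_samples <- as.integer(bin_length_samples)
      } else {
        abort("Raster is already binned; cannot re-bin to a different length.")
      }
    }
  } else {
    abort("`data` must be an epoched_data or binary_raster object.")
  }
  n_regions <- length(raster$region_names)
  res <- lapply(raster$active, function(m) {
    runs <- find_runs(m)
    multi <- runs$end - runs$start >= 1
    if (!any(multi)) return(list(atm = NULL, n = 0L))
    out <- trial_atm_cpp(m, as.integer(runs$start[multi] - 1L),
                         as.integer(runs$end[multi] - 1L),
                         pooled = (mode == "pooled"))
    list(atm = out$atm, n = out$n_avalanches)
  })
  n_aval <- vapply(res, function(x) as.integer(x$n), integer(1))
  atms <- lapply(res, function(x) {
    if (is.null(x$atm)) NULL else
      new_transition_matrix(x$atm, scope = "trial", n_avalanches = x$n)
  })
  if (any(n_aval == 0)) {
    inform(sprintf(
      "%d of %d trials contained no multi-bin avalanche and carry no ATM.",
      sum(n_aval == 0), length(n_aval)
    ))
  }
  out <- tibble(
    trial = raster$trials$trial,
    condition = raster$trials$condition,
    outcome = raster$trials$outcome,
    n_avalanches = n_aval,
    atm = atms
  )
  structure(
    out,
    class = c("trial_atms", class(out)),
    n_regions = n_regions,
    region_names = raster$region_names,
    threshold_z = raster$threshold_z,
    bin_length_samples = raster$bin_length_samples,
    mode = mode,
    subject_id = raster$subject_id
  )
}

#' Condition-average transition matrices
#'
#' Averages the per-trial ATMs within each condition (trials without
#' avalanches are excluded).
#'
#' @param trial_atms A `trial_atms` tibble from [extract_trial_atms()].
#' @return A tibble with one row per condition: `condition`,
#'   `n_trials_used`, `n_avalanches`, and the list-column `atm`.
#' @export
condition_atms <- function(trial_atms) {
  stopifnot(inherits(trial_atms, "trial_atms"))
  used <- trial_atms[trial_atms$n_avalanches > 0, ]
  conds <- unique(used$condition)
  rows <- lapply(conds, function(cc) {
    sub <- used[used$condition == cc, ]
    tibble(
      condition = cc,
      n_trials_used = nrow(sub),
      n_avalanches = sum(sub$n_avalanches),
      atm = list(average_atm(sub$atm, scope = "condition"))
    )
  })
  dplyr::bind_rows(rows)
}

#' @export
tidy.trial_atms <- function(x, ...) {
  region_names <- attr(x, "region_names")
  used <- x[x$n_avalanches > 0, ]
  purrr::map_dfr(seq_len(nrow(used)), function(i) {
    m <- used$atm[[i]]
    tibble(
      trial = used$trial[i],
      condition = used$condition[i],
      from = rep(region_names, each = ncol(m)),
      to = rep(region_names, times = nrow(m)),
      probability = flatten_rowmajor(unclass(m))
    )
  })
}
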