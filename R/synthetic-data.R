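#' Ground truth for the synthetic cascade generator
#'
#' Bundles the generative parameters of the branching cascade model: a
#' regions-by-regions matrix of transmission probabilities for the resting
#' state, a second matrix for motor imagery (MI) differing only on a set of
#' planted edges, and the scalars governing outcome attenuation, spontaneous
#' initiations, and the intended branching ratio.
#'
#' The cascade model is an independent-Bernoulli branching process on a
#' directed graph: a region active at bin `t` triggers each of its outgoing
#' edges (the self-persistence diagonal included) independently at `t + 1`.
#' The expected number of offspring of one active region is therefore its
#' row sum, so a matrix whose rows sum to `sigma_target` realizes a cascade
#' process with that branching ratio (up to saturation, since a region
#' cannot be activated twice within one bin).
#'
#' @param weights_rest,weights_mi Square numeric matrices of transmission
#'   probabilities in `[0, 1]`. They must differ exactly on `planted_edges`.
#' @param planted_edges Two-column integer matrix of `(from, to)` indices
#'   where the two conditions differ.
#' @param effect_size Multiplicative factor (>= 0) applied to the planted
#'   transmission probabilities under MI.
#' @param miss_attenuation Factor in `[0, 1]` scaling the MI-minus-Rest
#'   weight difference on miss trials, so that misses interpolate between
#'   the two conditions (1 makes hit and miss trials identically
#'   distributed, 0 makes MI misses look like rest).
#' @param spontaneous_rate Per-region, per-bin probability of a spontaneous
#'   initiation.
#' @param sigma_target Intended mean offspring count (branching ratio) of
#'   the resting cascade process.
#'
#' @return An object of class `ground_truth`.
#' @seealso [make_ground_truth()] for the standard constructor.
#' @export
ground_truth <- function(weights_rest, weights_mi, planted_edges,
                         effect_size, miss_attenuation,
                         spontaneous_rate, sigma_target) {
  stopifnot(is.matrix(weights_rest), nrow(weights_rest) == ncol(weights_rest))
  stopifnot(identical(dim(weights_rest), dim(weights_mi)))
  check_prob(weights_rest, "weights_rest")
  check_prob(weights_mi, "weights_mi")
  check_prob(miss_attenuation, "miss_attenuation")
  check_prob(spontaneous_rate, "spontaneous_rate")
  if (!is.numeric(effect_size) || effect_size < 0) {
    abort("`effect_size` must be a non-negative number.")
  }
  planted_edges <- matrix(as.integer(planted_edges), ncol = 2)
  diff_idx <- which(weights_rest != weights_mi, arr.ind = TRUE)
  planted_lin <- sort((planted_edges[, 2] - 1L) * nrow(weights_rest) + planted_edges[, 1])
  diff_lin <- sort((diff_idx[, 2] - 1L) * nrow(weights_rest) + diff_idx[, 1])
  if (effect_size != 1 && !all(diff_lin %in% planted_lin)) {
    abort("`weights_rest` and `weights_mi` may differ only on `planted_edges`.")
  }
  structure(
    list(
      weights_rest = weights_rest, weights_mi = weights_mi,
      planted_edges = planted_edges, effect_size = effect_size,
      miss_attenuation = miss_attenuation,
      spontaneous_rate = spontaneous_rate, sigma_target = sigma_target
    ),
    class = "ground_truth"
  )
}

#' Build a standard planted-edge ground truth
#'
#' Constructs a resting connectivity where every region carries a
#' self-persistence loop plus `out_degree` ring neighbours, with all rows
#' renormalized to sum to `sigma_target` (so the resting cascade has the
#' requested branching ratio). A block of planted edges from the
#' `planted_from` regions to the `planted_to` regions (all pairs) receives
#' baseline weight before renormalization; under MI those entries are
#' multiplied by `effect_size` (capped at 0.95).
#'
#' The planted blocks default to a "premotor-like" source group at the start
#' of the region list and a "parietal-like" target group at its middle, so
#' the condition effect is spatially clustered the way a motor-imagery
#' contrast is expected to be.
#'
#' @param n_regions Number of regions (default 68).
#' @param sigma_target Branching ratio of the resting process (default 1,
#'   i.e. critical dynamics).
#' @param effect_size,miss_attenuation,spontaneous_rate See [ground_truth()].
#' @param out_degree Ring out-degree excluding the self-loop.
#' @param planted_from,planted_to Region index vectors delimiting the
#'   planted block; defaults are `1:4` and the three regions after the
#'   midpoint.
#' @return A `ground_truth` object.
#' @export
make_ground_truth <- function(n_regions = 68, sigma_target = 1,
                              effect_size = 2, miss_attenuation = 0.5,
                              spontaneous_rate = 1e-3, out_degree = 4,
                              planted_from = NULL, planted_to = NULL) {
  n_regions <- check_count(n_regions, "n_regions", min = 3)
  blk <- planted_block(n_regions)
  planted_from <- planted_from %||% blk$from
  planted_to <- planted_to %||% blk$to
  stopifnot(all(planted_from >= 1), all(planted_from <= n_regions),
            all(planted_to >= 1), all(planted_to <= n_regions))
  w <- matrix(0, n_regions, n_regions)
  base <- 1 / (out_degree + 1)
  for (i in seq_len(n_regions)) {
    targets <- unique(c(i, (i + seq_len(out_degree) - 1L) %% n_regions + 1L))
    w[i, targets] <- base
  }
  # planted edges model strong anatomical pathways (twice the baseline ring
  # weight) laid out as a 2-regular bipartite wiring between the source and
  # target hub groups: each source projects to two targets and each target
  # receives from two sources, so the condition effect is clustered on the
  # hubs while no single source row gains excessive outflow under MI
  nf <- length(planted_from)
  nt <- length(planted_to)
  planted <- unique(rbind(
    cbind(planted_from, planted_to[(2 * seq_len(nf) - 2) %% nt + 1]),
    cbind(planted_from, planted_to[(2 * seq_len(nf) - 1) %% nt + 1])
  ))
  colnames(planted) <- c("from", "to")
  w[planted] <- pmax(w[planted], 2 * base)
  # renormalize rows so the resting branching ratio equals sigma_target
  w <- w * (sigma_target / rowSums(w))
  if (any(w > 1)) abort("`sigma_target` too large for this graph density.")
  w_mi <- w
  w_mi[planted] <- pmin(w[planted] * effect_size, 0.95)
  ground_truth(
    weights_rest = w, weights_mi = w_mi, planted_edges = planted,
    effect_size = effect_size, miss_attenuation = miss_attenuation,
    spontaneous_rate = spontaneous_rate, sigma_target = sigma_target
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d regions, %d planted edges, effect %.2gx, sigma_target %.3g\n",
    nrow(x$weights_rest), nrow(x$planted_edges), x$effect_size, x$sigma_target
  ))
  invisible(x)
}

# Effective transmission matrix for a trial of the given condition/outcome.
trial_weights <- function(gt, condition, outcome = NA_character_) {
  condition <- norm_labels(condition, .conditions, "condition")
  if (!is.na(outcome)) outcome <- norm_labels(outcome, .outcomes, "outcome")
  if (condition == "rest") return(gt$weights_rest)
  if (!is.na(outcome) && outcome == "miss") {
    gt$weights_rest + gt$miss_attenuation * (gt$weights_mi - gt$weights_rest)
  } else {
    gt$weights_mi
  }
}

# Adjacency-list form consumed by the compiled simulator (0-based targets).
edge_lists <- function(w) {
  idx <- apply(w, 1, function(row) which(row > 0), simplify = FALSE)
  list(
    idx = lapply(idx, function(j) as.integer(j - 1L)),
    w = lapply(seq_len(nrow(w)), function(i) unname(w[i, idx[[i]]]))
  )
}

# Default planted hub layout: a source group at the start of the region
# list ("premotor-like") and a target group just past the midpoint
# ("parietal-like"); 8 regions each for large parcellations, 4 for small.
planted_block <- function(n_regions) {
  k <- if (n_regions >= 40) 8L else max(2L, min(4L, n_regions - 5L))
  list(from = seq_len(k), to = floor(n_regions / 2) + seq_len(k))
}

# Mean extra regions per spontaneous seed event (cluster size is
# 1 + Poisson(.cluster_lambda)). Clustered initiations give avalanches
# multi-event first bins; the value is calibrated once, at the default
# 68-region critical geometry, so the within-avalanche geometric branching
# estimator is centered on sigma_target.
.cluster_lambda <- 0.25

#' Simulate a binary cascade raster
#'
#' Runs the branching cascade of a [ground_truth()] for one trial: seed
#' events arrive at a per-bin rate matching an average per-region
#' initiation probability of `gt$spontaneous_rate`, each activating a
#' small cluster of `1 + Poisson(0.25)` regions at once (co-activation at
#' onset mirrors real recordings, where avalanches often start with several
#' regions crossing threshold in the same bin), and each active region then
#' triggers each of its outgoing edges independently in the next bin, with
#' the transmission probabilities appropriate to the requested condition
#' and outcome.
#'
#' @param gt A `ground_truth` object.
#' @param condition `"mi"` or `"rest"` (case-insensitive).
#' @param outcome `"hit"`, `"miss"`, or `NA`; on MI trials `"miss"`
#'   attenuates the planted effect by `gt$miss_attenuation`.
#' @param n_bins Number of time bins to simulate.
#' @param seed Optional integer seed; `NULL` continues the current RNG
#'   stream.
#' @param init Optional integer vector of regions forced active at bin 1.
#' @return A regions x bins logical matrix.
#' @export
simulate_cascades <- function(gt, condition = "rest", outcome = NA,
                              n_bins, seed = NULL, init = integer(0)) {
  stopifnot(inherits(gt, "ground_truth"))
  n_bins <- check_count(n_bins, "n_bins")
  w <- trial_weights(gt, condition, if (length(outcome)) outcome[1] else NA)
  el <- edge_lists(w)
  seed_rate <- min(1, nrow(w) * gt$spontaneous_rate / (1 + .cluster_lambda))
  with_seed(seed, {
    raster <- simulate_raster_cpp(
      el$idx, el$w, nrow(w), seed_rate, .cluster_lambda, n_bins,
      as.integer(init - 1L)
    )
  })
  rownames(raster) <- default_region_names(nrow(w))
  raster
}

#' Collect simulated avalanches
#'
#' Repeatedly simulates trials from a ground truth and segments them until at
#' least `n_avalanches` multi-bin avalanches have been collected. Convenience
#' wrapper used to study estimator behaviour (e.g. branching-ratio recovery
#' at criticality).
#'
#' @inheritParams simulate_cascades
#' @param n_avalanches Minimum number of multi-bin avalanches to collect.
#' @param n_bins Bins per simulated trial.
#' @return An avalanche catalog tibble (see [segment_avalanches()]).
#' @export
collect_avalanches <- function(gt, n_avalanches = 1000, n_bins = 2000,
                               condition = "rest", outcome = NA, seed = NULL) {
  with_seed(seed, {
    pieces <- list()
    got <- 0L
    trial_offset <- 0L
    while (got < n_avalanches) {
      raster <- simulate_cascades(gt, condition, outcome, n_bins)
      cat_i <- segment_avalanches(raster)
      if (nrow(cat_i) > 0) {
        cat_i$trial <- cat_i$trial + trial_offset
        pieces[[length(pieces) + 1L]] <- cat_i
        got <- got + sum(cat_i$duration_bins >= 2)
      }
      trial_offset <- trial_offset + 1L
    }
  })
  out <- dplyr::bind_rows(pieces)
  attr(out, "n_regions") <- nrow(gt$weights_rest)
  attr(out, "bin_length_samples") <- 1L
  out
}

#' Embed a binary raster into continuous signals
#'
#' Inverse of the binarization step: generates seeded Gaussian background
#' noise and plants, in the first sample of every active bin, a deflection
#' large enough that per-region z-scoring over time leaves it above
#' `threshold_z` in absolute value. Re-binarizing the output with the same
#' threshold and bin length therefore recovers the input raster exactly on
#' the planted cells (background samples may still cross threshold at the
#' chance rate `2 * (1 - pnorm(threshold_z))`).
#'
#' Deflection signs alternate within each region so the planted activity
#' leaves the series mean near zero. The deflection amplitude is chosen
#' per region from the fraction `f` of planted samples: with margin `m = 1.3`
#' the amplitude `k` solves `k / sqrt(1 + f k^2) = m * threshold_z`, which
#' is only possible while `(m * threshold_z)^2 * f < 1` -- denser rasters
#' raise an error asking for a larger bin length or a lower threshold.
#'
#' @param raster Regions x bins logical matrix.
#' @param bin_length_samples Samples per bin in the output signal.
#' @param noise_sd Standard deviation of the Gaussian background.
#' @param threshold_z Binarization threshold the embedding must survive.
#' @param seed Optional integer seed.
#' @param n_samples Expected sample count; must equal
#'   `ncol(raster) * bin_length_samples` when given.
#' @return A regions x samples numeric matrix.
#' @export
embed_signals <- function(raster, bin_length_samples = 1, noise_sd = 1,
                          threshold_z = 3, seed = NULL, n_samples = NULL) {
  stopifnot(is.matrix(raster))
  if (threshold_z <= 0) abort("`threshold_z` must be > 0.")
  bin_length_samples <- check_count(bin_length_samples, "bin_length_samples")
  n_regions <- nrow(raster)
  n_bins <- ncol(raster)
  samples <- n_bins * bin_length_samples
  if (!is.null(n_samples) && n_samples != samples) {
    abort(
      sprintf(
        "Bin/sample geometry mismatch: %d bins x %d samples/bin != %d samples.",
        n_bins, bin_length_samples, n_samples
      ),
      class = "avalanchr_geometry_error"
    )
  }
  with_seed(seed, {
    sig <- matrix(rnorm(n_regions * samples, 0, noise_sd), n_regions, samples)
  })
  for (r in seq_len(n_regions)) {
    bins <- which(raster[r, ])
    if (length(bins) == 0) next
    f <- length(bins) / samples
    # after z-scoring, a planted amplitude k*noise_sd lands near
    # z = k / sqrt(1 + f k^2), which saturates at 1/sqrt(f): denser rasters
    # cap the achievable z. Aim 30% above threshold, or as close to the
    # saturation limit as the density allows.
    z_target <- min(1.3 * threshold_z, 0.97 / sqrt(f))
    if (z_target <= 1.02 * threshold_z) {
      abort(
        sprintf(
          "Region %d raster too dense (%.1f%% of samples active) to embed at threshold %.2g; increase bin_length_samples or lower the threshold.",
          r, 100 * f, threshold_z
        ),
        class = "avalanchr_embed_error"
      )
    }
    k <- z_target / sqrt(1 - z_target^2 * f)
    signs <- rep_len(c(1, -1), length(bins))
    planted_at <- (bins - 1L) * bin_length_samples + 1L
    for (attempt in 1:6) {
      sig[r, planted_at] <- signs * k * noise_sd
      z <- abs(sig[r, ] - mean(sig[r, ])) / sd(sig[r, ])
      if (all(z[planted_at] > threshold_z)) break
      if (attempt == 6) {
        abort(
          sprintf("Could not embed region %d above threshold %.2g (density %.1f%%).",
                  r, threshold_z, 100 * f),
          class = "avalanchr_embed_error"
        )
      }
      k <- k * 1.05
    }
  }
  rownames(sig) <- rownames(raster)
  sig
}

#' Cohort design for the synthetic generator
#'
#' Describes the study geometry: cohort size, trial counts, parcellation
#' size, epoch length and sampling rate, the hit rate of the simulated BCI
#' task, and the between-subject variability of the planted connectivity.
#' The `"paper"` profile mirrors a 20-subject, 68-region, 7-s epoch,
#' 48-trials-per-condition design; the `"small"` profile (19 regions, 2-s
#' epochs) is a fast geometry for tests and examples.
#'
#' @param n_subjects,n_trials_per_condition,n_regions Counts.
#' @param trial_duration_s Epoch length in seconds.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param hit_rate Fraction of trials labelled `hit`.
#' @param subject_variability Standard deviation (log scale) of the
#'   per-subject multiplicative jitter applied to the ground-truth weights,
#'   and of the per-subject gain on the planted effect.
#' @param seed Integer seed from which the whole cohort is reproducible.
#' @param profile `"paper"` or `"small"`; sets the defaults above.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(profile = c("paper", "small"),
                        n_subjects = NULL, n_trials_per_condition = NULL,
                        n_regions = NULL, trial_duration_s = NULL,
                        sampling_rate_hz = 250, hit_rate = 0.7,
                        subject_variability = 0.15, seed = 1) {
  profile <- match.arg(profile)
  defaults <- switch(profile,
    paper = list(n_subjects = 20, n_trials_per_condition = 48,
                 n_regions = 68, trial_duration_s = 7),
    small = list(n_subjects = 6, n_trials_per_condition = 20,
                 n_regions = 19, trial_duration_s = 2)
  )
  spec <- list(
    profile = profile,
    n_subjects = check_count(n_subjects %||% defaults$n_subjects, "n_subjects"),
    n_trials_per_condition = check_count(
      n_trials_per_condition %||% defaults$n_trials_per_condition,
      "n_trials_per_condition"
    ),
    n_regions = check_count(n_regions %||% defaults$n_regions, "n_regions", min = 3),
    trial_duration_s = trial_duration_s %||% defaults$trial_duration_s,
    sampling_rate_hz = sampling_rate_hz,
    hit_rate = check_prob(hit_rate, "hit_rate"),
    subject_variability = subject_variability,
    seed = as.integer(seed)
  )
  if (spec$trial_duration_s <= 0 || spec$sampling_rate_hz <= 0) {
    abort("`trial_duration_s` and `sampling_rate_hz` must be positive.")
  }
  structure(spec, class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec '%s'> %d subjects, 2 x %d trials, %d regions, %.3gs @ %gHz, seed %d\n",
    x$profile, x$n_subjects, x$n_trials_per_condition, x$n_regions,
    x$trial_duration_s, x$sampling_rate_hz, x$seed
  ))
  invisible(x)
}

# Slope of the logistic link from realized planted effect to BCI score, and
# the sd of the seeded score noise. The slope is set so that the typical
# between-subject spread of the realized effect (subject_variability times
# the planted weight mass) moves the score by an amount comparable to, but
# larger than, the noise floor.
.bci_score_slope <- 10
.bci_score_noise_sd <- 0.05

#' Generate a synthetic multi-subject cohort
#'
#' Draws a cohort from a [cohort_spec()] and a [ground_truth()]: per-subject
#' connectivity is a jittered copy of the ground truth (multiplicative
#' log-normal jitter on the non-zero weights plus a subject-level gain on
#' the planted MI-minus-Rest difference), condition labels are balanced and
#' shuffled, outcomes are drawn at `hit_rate`, miss trials attenuate the
#' planted effect, and each subject receives a BCI score that is a logistic
#' function of their realized planted effect plus seeded Gaussian noise
#' (sd 0.05), clipped to `[0, 1]`.
#'
#' @param spec A `cohort_spec`.
#' @param gt A `ground_truth` whose region count matches `spec$n_regions`.
#' @param signal `"continuous"` embeds every trial raster into Gaussian
#'   noise (the full pipeline input, required for CSP decoding);
#'   `"raster"` keeps the binary cascade rasters, which is lighter and
#'   sufficient for everything downstream of binarization.
#' @param noise_sd,threshold_z Embedding parameters for
#'   `signal = "continuous"` (see [embed_signals()]).
#' @return An object of class `synthetic_cohort`: per-subject data
#'   ([epoched_data()] or [binary_raster()]), a `scores` tibble with the
#'   per-subject BCI scores and realized effects, and the generating
#'   `ground_truth` and `cohort_spec`.
#' @export
make_cohort <- function(spec, gt, signal = c("continuous", "raster"),
                        noise_sd = 1, threshold_z = 3) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(gt, "ground_truth"))
  signal <- match.arg(signal)
  if (nrow(gt$weights_rest) != spec$n_regions) {
    abort("`gt` region count does not match `spec$n_regions`.")
  }
  n_bins <- as.integer(round(spec$trial_duration_s * spec$sampling_rate_hz))
  n_trials <- 2L * spec$n_trials_per_condition
  region_names <- default_region_names(spec$n_regions)
  set.seed(spec$seed)
  subjects <- vector("list", spec$n_subjects)
  scores <- numeric(spec$n_subjects)
  effects <- numeric(spec$n_subjects)
  sv <- spec$subject_variability
  for (s in seq_len(spec$n_subjects)) {
    jitter <- matrix(exp(rnorm(spec$n_regions^2, 0, sv)),
                     spec$n_regions, spec$n_regions)
    gain <- exp(rnorm(1, 0, sv))
    w_rest <- pmin(gt$weights_rest * jitter, 1)
    delta <- (gt$weights_mi - gt$weights_rest) * jitter * gain
    w_mi <- pmin(w_rest + delta, 1)
    gt_s <- ground_truth(
      w_rest, w_mi, gt$planted_edges, gt$effect_size,
      gt$miss_attenuation, gt$spontaneous_rate, gt$sigma_target
    )
    effects[s] <- mean(delta[gt$planted_edges])
    # logistic link centered at the nominal (gain = 1) planted effect, so
    # scores average hit_rate and vary monotonically with the realized effect
    nominal <- mean((gt$weights_mi - gt$weights_rest)[gt$planted_edges])
    scores[s] <- min(1, max(0,
      plogis(qlogis(spec$hit_rate) +
               .bci_score_slope * (effects[s] - nominal)) +
        rnorm(1, 0, .bci_score_noise_sd)
    ))
    condition <- sample(rep(.conditions, each = spec$n_trials_per_condition))
    outcome <- ifelse(rbinom(n_trials, 1, spec$hit_rate) == 1, "hit", "miss")
    rasters <- vector("list", n_trials)
    for (tr in seq_len(n_trials)) {
      rasters[[tr]] <- simulate_cascades(
        gt_s, condition = condition[tr], outcome = outcome[tr], n_bins = n_bins
      )
    }
    sid <- sprintf("S%02d", s)
    if (signal == "raster") {
      subjects[[s]] <- binary_raster(
        active = rasters, threshold_z = threshold_z, bin_length_samples = 1L,
        condition = condition, outcome = outcome,
        region_names = region_names, subject_id = sid,
        sampling_rate_hz = spec$sampling_rate_hz
      )
    } else {
      sigs <- lapply(rasters, embed_signals,
                     bin_length_samples = 1, noise_sd = noise_sd,
                     threshold_z = threshold_z)
      subjects[[s]] <- epoched_data(
        signals = sigs, sampling_rate_hz = spec$sampling_rate_hz,
        condition = condition, outcome = outcome,
        region_names = region_names, subject_id = sid
      )
    }
  }
  names(subjects) <- sprintf("S%02d", seq_len(spec$n_subjects))
  structure(
    list(
      subjects = subjects,
      scores = tibble(
        subject = names(subjects),
        bci_score = scores,
        realized_effect = effects
      ),
      ground_truth = gt,
      spec = spec,
      signal = signal
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d subjects (%s signals), %d regions, %d trials each\n",
    length(x$subjects), x$signal, x$spec$n_regions,
    2L * x$spec$n_trials_per_condition
  ))
  print(head(x$scores, 5))
  invisible(x)
}

#' @rdname make_cohort
#' @param x A `synthetic_cohort`.
#' @export
cohort_scores <- function(x) {
  stopifnot(inherits(x, "synthetic_cohort"))
  x$scores
}
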