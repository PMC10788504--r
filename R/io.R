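# Plain-text containers and pipeline orchestration. Cohorts and epochs are
# stored as directories of JSON metadata + CSV tables/signal matrices, so
# every artifact is inspectable and diffable.

write_matrix_csv <- function(m, path) {
  readr::write_csv(as.data.frame(m), path, col_names = FALSE)
}

read_matrix_csv <- function(path) {
  unname(as.matrix(readr::read_csv(path, col_names = FALSE,
                                   show_col_types = FALSE, progress = FALSE)))
}

#' Export and import epoched data
#'
#' `export_epochs()` writes an [epoched_data()] object to a directory:
#' `meta.json` (subject, sampling rate, region names), `trials.csv`
#' (per-trial condition/outcome labels), and one `trial_###.csv`
#' regions x samples matrix per trial. `import_epochs()` reads such a
#' directory back, validating shapes and labels.
#'
#' @param data An `epoched_data` object.
#' @param dir Directory to write to / read from.
#' @return `export_epochs()` returns `dir` invisibly; `import_epochs()`
#'   returns an `epoched_data`.
#' @export
export_epochs <- function(data, dir) {
  stopifnot(inherits(data, "epoched_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    subject_id = data$subject_id,
    sampling_rate_hz = data$sampling_rate_hz,
    region_names = data$region_names,
    n_trials = nrow(data$trials)
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  readr::write_csv(data$trials, file.path(dir, "trials.csv"))
  for (tr in seq_len(nrow(data$trials))) {
    write_matrix_csv(data$signals[[tr]],
                     file.path(dir, sprintf("trial_%03d.csv", tr)))
  }
  invisible(dir)
}

#' @rdname export_epochs
#' @export
import_epochs <- function(dir) {
  if (!file.exists(file.path(dir, "meta.json"))) {
    abort(sprintf("No epoch container at '%s' (meta.json missing).", dir))
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  trials <- readr::read_csv(file.path(dir, "trials.csv"),
                            show_col_types = FALSE, progress = FALSE)
  signals <- lapply(seq_len(meta$n_trials), function(tr) {
    m <- read_matrix_csv(file.path(dir, sprintf("trial_%03d.csv", tr)))
    if (nrow(m) != length(meta$region_names)) {
      abort(
        sprintf("Trial %d has %d regions; expected %d.", tr, nrow(m),
                length(meta$region_names)),
        class = "avalanchr_shape_error"
      )
    }
    m
  })
  epoched_data(
    signals = signals, sampling_rate_hz = meta$sampling_rate_hz,
    condition = trials$condition,
    outcome = if ("outcome" %in% names(trials)) trials$outcome else NULL,
    region_names = meta$region_names, subject_id = meta$subject_id
  )
}

#' Write / read a synthetic cohort container
#'
#' Serializes a [make_cohort()] result to a directory of JSON + CSV files:
#' cohort metadata and generator parameters, per-subject BCI scores,
#' ground-truth weight matrices and planted edges, and per-subject signal
#' (or raster) matrices. Continuous paper-scale cohorts are large on disk;
#' prefer the `"raster"` signal type or the small profile when archiving.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Target directory.
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` the
#'   reconstructed `synthetic_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gt <- cohort$ground_truth
  meta <- list(
    signal = cohort$signal,
    spec = unclass(cohort$spec),
    ground_truth = list(
      effect_size = gt$effect_size,
      miss_attenuation = gt$miss_attenuation,
      spontaneous_rate = gt$spontaneous_rate,
      sigma_target = gt$sigma_target
    )
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  readr::write_csv(cohort$scores, file.path(dir, "scores.csv"))
  write_matrix_csv(gt$weights_rest, file.path(dir, "weights_rest.csv"))
  write_matrix_csv(gt$weights_mi, file.path(dir, "weights_mi.csv"))
  readr::write_csv(
    tibble(from = gt$planted_edges[, 1], to = gt$planted_edges[, 2]),
    file.path(dir, "planted_edges.csv")
  )
  for (sid in names(cohort$subjects)) {
    subj <- cohort$subjects[[sid]]
    sdir <- file.path(dir, sid)
    if (cohort$signal == "continuous") {
      export_epochs(subj, sdir)
    } else {
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      readr::write_csv(subj$trials, file.path(sdir, "trials.csv"))
      jsonlite::write_json(
        list(subject_id = subj$subject_id, threshold_z = subj$threshold_z,
             bin_length_samples = subj$bin_length_samples,
             sampling_rate_hz = subj$sampling_rate_hz,
             region_names = subj$region_names,
             n_trials = nrow(subj$trials)),
        file.path(sdir, "meta.json"), auto_unbox = TRUE
      )
      for (tr in seq_len(nrow(subj$trials))) {
        write_matrix_csv(subj$active[[tr]] * 1L,
                         file.path(sdir, sprintf("trial_%03d.csv", tr)))
      }
    }
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  scores <- readr::read_csv(file.path(dir, "scores.csv"),
                            show_col_types = FALSE, progress = FALSE)
  planted <- as.matrix(readr::read_csv(file.path(dir, "planted_edges.csv"),
                                       show_col_types = FALSE, progress = FALSE))
  gt <- ground_truth(
    weights_rest = read_matrix_csv(file.path(dir, "weights_rest.csv")),
    weights_mi = read_matrix_csv(file.path(dir, "weights_mi.csv")),
    planted_edges = planted,
    effect_size = meta$ground_truth$effect_size,
    miss_attenuation = meta$ground_truth$miss_attenuation,
    spontaneous_rate = meta$ground_truth$spontaneous_rate,
    sigma_target = meta$ground_truth$sigma_target
  )
  spec <- do.call(cohort_spec, meta$spec[setdiff(names(meta$spec), "profile")] |>
                    c(list(profile = meta$spec$profile)))
  sids <- scores$subject
  subjects <- lapply(sids, function(sid) {
    sdir <- file.path(dir, sid)
    if (meta$signal == "continuous") {
      import_epochs(sdir)
    } else {
      smeta <- jsonlite::read_json(file.path(sdir, "meta.json"),
                                   simplifyVector = TRUE)
      trials <- readr::read_csv(file.path(sdir, "trials.csv"),
                                show_col_types = FALSE, progress = FALSE)
      active <- lapply(seq_len(smeta$n_trials), function(tr) {
        read_matrix_csv(file.path(sdir, sprintf("trial_%03d.csv", tr))) == 1
      })
      binary_raster(
        active = active, threshold_z = smeta$threshold_z,
        bin_length_samples = smeta$bin_length_samples,
        condition = trials$condition, outcome = trials$outcome,
        region_names = smeta$region_names, subject_id = smeta$subject_id,
        sampling_rate_hz = smeta$sampling_rate_hz
      )
    }
  })
  names(subjects) <- sids
  structure(
    list(subjects = subjects, scores = scores, ground_truth = gt,
         spec = spec, signal = meta$signal),
    class = "synthetic_cohort"
  )
}

pipeline_defaults <- function() {
  list(
    profile = "small",
    out_dir = "avalanchr-run",
    seed = 1,
    effect_size = 2,
    miss_attenuation = 0.5,
    spontaneous_rate = 1e-3,
    sigma_target = 1,
    threshold_z = 3,
    bin_length_samples = 1,
    n_permutations = 1000,
    alpha = 0.05,
    decode = TRUE,
    n_splits = 50,
    test_fraction = 0.2,
    area_map = NULL,
    save_cohort = FALSE,
    n_subjects = NULL,
    n_trials_per_condition = NULL,
    n_regions = NULL
  )
}

#' Validate a pipeline configuration
#'
#' Fills in defaults and validates the configuration consumed by
#' [run_pipeline()]. Accepts a named list or the path of a YAML file.
#'
#' @param config Named list or YAML file path; unknown fields are rejected.
#' @return The resolved configuration list (class `pipeline_config`).
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("Config file '%s' not found.", config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config field(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (!cfg$profile %in% c("small", "paper")) {
    abort("`profile` must be 'small' or 'paper'.")
  }
  check_prob(cfg$alpha, "alpha")
  check_prob(cfg$test_fraction, "test_fraction")
  cfg$n_permutations <- check_count(cfg$n_permutations, "n_permutations")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[stage %s] %s", stage, conditionMessage(e)), parent = e)
  })
}

#' Run the full avalanche analysis pipeline
#'
#' End-to-end orchestration: simulate (or reload) a synthetic cohort,
#' extract per-trial avalanche transition matrices, run the multi-level
#' permutation statistics (subject edge tests, group reliability, node
#' clustering, hit/miss contrast, BCI-score area correlation), optionally
#' benchmark ATM-vs-CSP decoding, and write the report tables. Every output
#' lands in `config$out_dir` alongside the resolved configuration and a
#' run manifest (seed, package version, file hashes) sufficient to
#' reproduce the run.
#'
#' @param config A named list, YAML file path, or [pipeline_config()].
#' @return Invisibly, a list with the cohort, per-subject ATMs and edge
#'   tests, the reliability/node/hit-miss/correlation results, and (when
#'   enabled) the decoding comparison.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    pipeline_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(out, "config_resolved.yaml"))

  cohort <- run_stage("simulate", {
    cohort_dir <- file.path(out, "cohort")
    if (cfg$save_cohort && file.exists(file.path(cohort_dir, "meta.json"))) {
      read_cohort(cohort_dir)
    } else {
      spec <- cohort_spec(
        profile = cfg$profile, seed = cfg$seed,
        n_subjects = cfg$n_subjects,
        n_trials_per_condition = cfg$n_trials_per_condition,
        n_regions = cfg$n_regions
      )
      gt <- make_ground_truth(
        n_regions = spec$n_regions, sigma_target = cfg$sigma_target,
        effect_size = cfg$effect_size,
        miss_attenuation = cfg$miss_attenuation,
        spontaneous_rate = cfg$spontaneous_rate
      )
      ch <- make_cohort(spec, gt,
                        signal = if (cfg$decode) "continuous" else "raster",
                        threshold_z = cfg$threshold_z)
      if (cfg$save_cohort) write_cohort(ch, cohort_dir)
      ch
    }
  })
  readr::write_csv(cohort$scores, file.path(out, "scores.csv"))

  atms <- run_stage("avalanches", {
    res <- lapply(cohort$subjects, function(subj) {
      suppressMessages(extract_trial_atms(
        subj, threshold_z = cfg$threshold_z,
        bin_length_samples = cfg$bin_length_samples
      ))
    })
    catalog <- purrr::map_dfr(names(cohort$subjects), function(sid) {
      subj <- cohort$subjects[[sid]]
      raster <- if (inherits(subj, "binary_raster")) subj else
        binarize(subj, cfg$threshold_z, cfg$bin_length_samples)
      seg <- segment_avalanches(raster)
      dplyr::mutate(
        dplyr::select(seg, "trial", "avalanche", "start_bin", "end_bin",
                      "duration_bins", "size"),
        subject = sid, .before = 1
      )
    })
    readr::write_csv(catalog, file.path(out, "avalanche_catalog.csv"))
    res
  })

  stats <- run_stage("stats", {
    area_map <- if (is.null(cfg$area_map)) {
      if (cohort$spec$n_regions == 68) default_area_map() else
        synthetic_area_map(cohort$spec$n_regions)
    } else {
      if (!file.exists(cfg$area_map)) {
        abort(sprintf(
          "Area map '%s' not found; supply a CSV with columns region,area or unset `area_map` to use the built-in mapping.",
          cfg$area_map
        ))
      }
      readr::read_csv(cfg$area_map, show_col_types = FALSE, progress = FALSE)
    }
    edge_tests <- lapply(atms, subject_edge_test,
                         n_permutations = cfg$n_permutations,
                         alpha = cfg$alpha, seed = NULL)
    rel <- group_reliability(edge_tests, n_permutations = cfg$n_permutations,
                             alpha = cfg$alpha)
    nodes <- node_concordance(rel, n_permutations = cfg$n_permutations,
                              alpha = cfg$alpha)
    mask <- if (any(rel$reliable)) rel$reliable else NULL
    hm <- hit_miss_summary(atms, edge_mask = mask,
                           n_permutations = cfg$n_permutations)
    corr <- bci_correlation(edge_tests, cohort$scores$bci_score, area_map,
                            n_permutations = cfg$n_permutations,
                            alpha = cfg$alpha)
    readr::write_csv(dplyr::filter(tidy(rel), .data$reliable),
                     file.path(out, "reliable_edges.csv"))
    readr::write_csv(tidy(nodes), file.path(out, "node_significance.csv"))
    readr::write_csv(hm$per_subject, file.path(out, "hit_miss.csv"))
    readr::write_csv(tidy(corr), file.path(out, "area_correlation.csv"))
    list(edge_tests = edge_tests, reliability = rel, nodes = nodes,
         hit_miss = hm, correlation = corr)
  })

  decoding <- NULL
  if (cfg$decode) {
    decoding <- run_stage("decode", {
      results <- evaluate_cohort(
        cohort, n_splits = cfg$n_splits, test_fraction = cfg$test_fraction,
        seed = cfg$seed
      )
      comparison <- compare_pipelines(results, alpha = cfg$alpha)
      readr::write_csv(purrr::map_dfr(results, tidy),
                       file.path(out, "decoding_accuracies.csv"))
      readr::write_csv(comparison, file.path(out, "decoding_comparison.csv"))
      list(results = results, comparison = comparison)
    })
  }

  run_stage("report", {
    report <- list(
      n_subjects = length(cohort$subjects),
      n_reliable_edges = sum(stats$reliability$reliable),
      significant_regions =
        stats$nodes$region_names[stats$nodes$significant],
      hit_miss_positive_subjects = stats$hit_miss$n_positive,
      significant_area_blocks = sum(stats$correlation$significant,
                                    na.rm = TRUE),
      decoding = if (!is.null(decoding)) {
        as.list(table(decoding$comparison$decision))
      }
    )
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    files <- setdiff(list.files(out, recursive = TRUE), "manifest.json")
    manifest <- list(
      package_version = as.character(utils::packageVersion("avalanchr")),
      seed = cfg$seed,
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
      files = lapply(setNames(files, files), function(f) {
        unname(tools::md5sum(file.path(out, f)))
      })
    )
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })

  invisible(list(cohort = cohort, atms = atms, stats = stats,
                 decoding = decoding, config = cfg))
}
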