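# ggplot2 views of the main result types.

atm_tile_data <- function(m, region_names = NULL) {
  rn <- region_names %||% default_region_names(nrow(m))
  tibble(
    from = factor(rep(rn, each = ncol(m)), levels = rn),
    to = factor(rep(rn, times = nrow(m)), levels = rn),
    value = flatten_rowmajor(unclass(m))
  )
}

#' @export
autoplot.transition_matrix <- function(object, ...) {
  df <- atm_tile_data(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "P(j active | i active)",
                                  limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(
      x = "target region j", y = "source region i",
      title = sprintf("Avalanche transition matrix (%s, %d avalanches)",
                      attr(object, "scope"),
                      attr(object, "n_avalanches_averaged"))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @export
autoplot.edge_test <- function(object, ...) {
  df <- tidy(object)
  rn <- object$region_names %||% default_region_names(nrow(object$p_values))
  df$from <- factor(df$from, levels = rn)
  df$to <- factor(df$to, levels = rn)
  lim <- max(abs(df$observed_diff))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$observed_diff)) +
    ggplot2::geom_tile(
      data = df[df$significant, , drop = FALSE],
      fill = NA, colour = "black", linewidth = 0.3
    ) +
    ggplot2::scale_fill_gradient2(name = "MI - Rest", limits = c(-lim, lim)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "target region", y = "source region",
                  title = sprintf("Edge-wise condition differences (%s)",
                                  object$subject_id %||% "")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @export
autoplot.reliability_map <- function(object, ...) {
  df <- tidy(object)
  rn <- object$region_names %||% default_region_names(nrow(object$p_values))
  df$from <- factor(df$from, levels = rn)
  df$to <- factor(df$to, levels = rn)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$n_subjects_significant)) +
    ggplot2::geom_tile(
      data = df[df$reliable, , drop = FALSE],
      fill = NA, colour = "red", linewidth = 0.3
    ) +
    ggplot2::scale_fill_viridis_c(name = "# subjects") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "target region", y = "source region",
                  title = "Cross-subject concordance of significant edges") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @export
autoplot.branching_estimate <- function(object, ...) {
  df <- tibble(sigma_i = object$per_avalanche_sigmas)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sigma_i)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$sigma, colour = "red") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "per-avalanche branching parameter",
      y = "avalanches",
      title = sprintf("Branching ratio = %.3f (n = %d)", object$sigma,
                      object$n_avalanches_used)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.area_correlation <- function(object, ...) {
  df <- tidy(object)
  df$from_area <- factor(df$from_area, levels = object$areas)
  df$to_area <- factor(df$to_area, levels = object$areas)
  lim <- max(abs(df$mean_correlation), na.rm = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to_area, y = .data$from_area)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$mean_correlation)) +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$significant & !is.na(.data$significant), "*", "")
    ), size = 6) +
    ggplot2::scale_fill_gradient2(name = "mean Spearman",
                                  limits = c(-lim, lim)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "target area", y = "source area",
                  title = "Edge-difference vs BCI-score correlation by area") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.decoding_result <- function(object, ...) {
  ggplot2::ggplot(object$accuracies,
                  ggplot2::aes(x = .data$pipeline, y = .data$accuracy)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "accuracy",
                  title = sprintf("Per-split decoding accuracy (%s)",
                                  object$subject_id)) +
    ggplot2::theme_minimal()
}

#' Scatter of per-subject decoding performance
#'
#' One dot per subject: mean ATM accuracy against mean CSP accuracy over
#' the shared splits, coloured by the FDR-corrected comparison decision;
#' the dashed diagonal marks equal accuracy (dots below it favour ATM).
#'
#' @param comparison A [compare_pipelines()] result.
#' @return A ggplot object.
#' @export
plot_comparison <- function(comparison) {
  stopifnot(inherits(comparison, "pipeline_comparison"))
  ggplot2::ggplot(comparison,
                  ggplot2::aes(x = .data$mean_atm, y = .data$mean_csp,
                               colour = .data$decision)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(
      atm_better = "salmon", csp_better = "mediumpurple",
      no_difference = "grey50"
    )) +
    ggplot2::coord_equal(xlim = c(0.3, 1), ylim = c(0.3, 1)) +
    ggplot2::labs(x = "ATM + SVM accuracy", y = "CSP + SVM accuracy",
                  colour = NULL,
                  title = "Individual-level classification performance") +
    ggplot2::theme_minimal()
}
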