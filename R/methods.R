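#' @export
print.cohort_scan <- function(x, ...) {
  cat("<cohort_scan>\n")
  cat(sprintf("  samples: %d   loci: %d   pairs compared: %d\n",
              length(x$sample_ids), nrow(x$loci), nrow(x$comparisons)))
  cat(sprintf("  flagged pairs: %d (MATCH %d, BORDERLINE_MATCH %d)\n",
              nrow(x$matches),
              sum(x$matches$status == "MATCH"),
              sum(x$matches$status == "BORDERLINE_MATCH")))
  if (!is.null(x$expected)) {
    cat(sprintf("  expected pairs: %d (CONCORDANT %d, REVIEW %d, DISCORDANT %d)\n",
                nrow(x$expected),
                sum(x$expected$verdict == "CONCORDANT"),
                sum(x$expected$verdict == "REVIEW"),
                sum(x$expected$verdict == "DISCORDANT")))
    cat(sprintf("  unexpected matches: %d\n", nrow(x$unexpected_matches)))
  }
  invisible(x)
}

#' Tidy a cohort scan into its pairwise comparison table
#'
#' @param x A [scan_cohort()] result.
#' @param ... Unused.
#' @return The `comparisons` tibble (one row per unordered sample pair).
#' @method tidy cohort_scan
#' @export
tidy.cohort_scan <- function(x, ...) {
  x$comparisons
}

#' One-row summary of a cohort scan
#'
#' @param x A [scan_cohort()] result.
#' @param ... Unused.
#' @return A one-row tibble with sample/pair/match counts.
#' @method glance cohort_scan
#' @export
glance.cohort_scan <- function(x, ...) {
  tibble(
    n_samples = length(x$sample_ids),
    n_loci = nrow(x$loci),
    n_pairs = nrow(x$comparisons),
    n_match = sum(x$comparisons$status == "MATCH"),
    n_borderline = sum(x$comparisons$status == "BORDERLINE_MATCH"),
    n_unevaluable = sum(x$comparisons$status == "UNEVALUABLE"),
    n_expected = if (is.null(x$expected)) NA_integer_ else nrow(x$expected),
    n_expected_discordant = if (is.null(x$expected)) NA_integer_ else
      sum(x$expected$verdict == "DISCORDANT"),
    n_unexpected_matches = if (is.null(x$unexpected_matches)) NA_integer_ else
      nrow(x$unexpected_matches)
  )
}

#' Correlation heatmap of a cohort scan
#'
#' @param object A [scan_cohort()] result.
#' @param ... Unused.
#' @return A ggplot: the symmetric pairwise VAF-correlation matrix on a
#'   fixed `[-1, 1]` fill scale, unit diagonal.
#' @method autoplot cohort_scan
#' @export
autoplot.cohort_scan <- function(object, ...) {
  mat <- correlation_matrix(object)
  df <- tidyr::expand_grid(x = rownames(mat), y = colnames(mat)) %>%
    mutate(correlation = as.vector(t(mat)),
           x = factor(.data$x, levels = rownames(mat)),
           y = factor(.data$y, levels = rev(colnames(mat))))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166AC",
                                  mid = "#F7F7F7", high = "#B2182B",
                                  midpoint = 0, na.value = "grey80") +
    ggplot2::labs(x = NULL, y = NULL, fill = "VAF\ncorrelation") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1, vjust = 0.5),
                   panel.grid = ggplot2::element_blank())
}

#' Per-size summary of a subset-power experiment
#'
#' @param x A [subset_sensitivity()] result.
#' @param ... Unused.
#' @return A tibble with one row per subset size: mean detections and mean
#'   false positives over iterations, plus detection rates relative to the
#'   planted totals.
#' @method glance subset_power
#' @export
glance.subset_power <- function(x, ...) {
  planted_u <- attr(x, "planted_unexpected")
  planted_d <- attr(x, "planted_discordant")
  as_tibble(x) %>%
    group_by(.data$subset_size) %>%
    summarise(
      iterations = n(),
      mean_detected_unexpected = mean(.data$detected_unexpected),
      mean_detected_discordant = mean(.data$detected_discordant),
      mean_false_positives = mean(.data$false_positives),
      .groups = "drop"
    ) %>%
    mutate(
      unexpected_detection_rate = .data$mean_detected_unexpected /
        max(planted_u, 1L),
      discordant_detection_rate = .data$mean_detected_discordant /
        max(planted_d, 1L)
    ) %>%
    arrange(desc(.data$subset_size))
}

#' Plot detection and false positives against subset size
#'
#' @param object A [subset_sensitivity()] result.
#' @param ... Unused.
#' @return A ggplot: per-iteration points and per-size means for detected
#'   planted pairs and false positives as the panel shrinks.
#' @method autoplot subset_power
#' @export
autoplot.subset_power <- function(object, ...) {
  long <- as_tibble(object) %>%
    tidyr::pivot_longer(c("detected_unexpected", "detected_discordant",
                          "false_positives"),
                        names_to = "metric", values_to = "count")
  means <- long %>%
    group_by(.data$subset_size, .data$metric) %>%
    summarise(count = mean(.data$count), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(.data$subset_size, .data$count,
                                     colour = .data$metric)) +
    ggplot2::geom_jitter(width = 0.25, height = 0, alpha = 0.4, size = 1) +
    ggplot2::geom_line(data = means) +
    ggplot2::geom_point(data = means, size = 2) +
    ggplot2::scale_x_reverse(breaks = sort(unique(long$subset_size))) +
    ggplot2::labs(x = "SNPs in subset", y = "pairs per iteration",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
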