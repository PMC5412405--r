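#' Histogram plot of a whole-lesion voxel sample
#'
#' @param sample A [extract_voi_values()] result or numeric vector.
#' @param bin_count Number of equal-width bins (same convention as
#'   [compute_features()]).
#' @return A ggplot object.
#' @export
plot_adc_histogram <- function(sample, bin_count = 64) {
  values <- if (inherits(sample, "voxel_sample")) sample$values else as.numeric(sample)
  h <- voi_histogram(values, bin_count)
  df <- tibble(adc = h$centers, count = h$counts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$adc, y = .data$count)) +
    ggplot2::geom_col(width = if (h$degenerate) NULL else diff(h$edges[1:2]),
                      fill = "grey35") +
    ggplot2::labs(x = "ADC (1e-5 mm²/s)", y = "voxel count") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.adc_correlations <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$marker, y = .data$feature,
                                       fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$significant, sprintf("%.2f*", .data$rho),
                     sprintf("%.2f", .data$rho))), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", high = "#b2182b",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho",
                  caption = "* p <= 0.05") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @export
autoplot.adc_group_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("feature", "group1", "group2", "mean1", "mean2",
                        "sd1", "sd2", "significant")],
    cols = c("mean1", "mean2"), names_to = "which", values_to = "mean"
  )
  long$group <- ifelse(long$which == "mean1", long$group1, long$group2)
  long$sd <- ifelse(long$which == "mean1", long$sd1, long$sd2)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$mean,
                                     fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.25) +
    ggplot2::facet_wrap(~ .data$feature, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c("FALSE" = "grey65", "TRUE" = "#b2182b")) +
    ggplot2::labs(x = NULL, y = "group mean ± SD",
                  fill = "p ≤ 0.05") +
    ggplot2::theme_minimal()
}
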