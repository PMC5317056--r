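#' Plot the sweep-scan ratio track
#'
#' Per-window race/cultivar diversity ratio along each chromosome with
#' the sweep threshold as a horizontal line; masked windows are dropped
#' and infinite ratios drawn at the panel ceiling.
#'
#' @param ratio_track Output of [sweep_ratio_profile()].
#' @param threshold Threshold line (default 25).
#' @return A ggplot object.
#' @export
plot_sweep_scan <- function(ratio_track, threshold = 25) {
  d <- dplyr::filter(ratio_track, !.data$masked, !is.na(.data$ratio))
  cap <- max(c(threshold * 2, d$ratio[is.finite(d$ratio)]), na.rm = TRUE)
  d <- dplyr::mutate(d, ratio_plot = pmin(.data$ratio, cap),
                     mid = (.data$start + .data$end) / 2e6)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mid, y = .data$ratio_plot)) +
    ggplot2::geom_point(size = 0.6, colour = "grey30") +
    ggplot2::geom_hline(yintercept = threshold, colour = "firebrick",
                        linetype = 2) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)",
                  y = expression(pi[race] / pi[cultivar])) +
    ggplot2::theme_minimal()
}

#' Plot windowed diversity tracks
#'
#' @param stats Tibble from [window_pi()] (optionally row-bound for
#'   several populations with a `population` column).
#' @return A ggplot object.
#' @export
plot_diversity <- function(stats) {
  aes <- if ("population" %in% names(stats)) {
    ggplot2::aes(x = (.data$start + .data$end) / 2e6, y = .data$pi,
                 colour = .data$population)
  } else {
    ggplot2::aes(x = (.data$start + .data$end) / 2e6, y = .data$pi)
  }
  ggplot2::ggplot(stats, aes) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = expression(pi ~ "(per bp)")) +
    ggplot2::theme_minimal()
}

#' Plot the first two genotype principal components
#'
#' @param x A `cotton_pca`.
#' @return A ggplot object, points coloured by species/group.
#' @export
plot_pca <- function(x) {
  d <- dplyr::mutate(x$scores,
                     pop = paste(.data$species, .data$group))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                  colour = .data$pop)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * x$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * x$var_explained[2]),
      colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an LD decay profile
#'
#' @param profile Tibble from [ld_decay()].
#' @return A ggplot object (mean r-squared versus bin midpoint, log-x).
#' @export
plot_ld_decay <- function(profile) {
  d <- dplyr::filter(profile, .data$n_pairs > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                  y = .data$mean_r2)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Distance (bp)", y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
}
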