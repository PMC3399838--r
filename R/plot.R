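#' Plot an MSE-vs-bin-size profile
#'
#' MSE (with between-fold standard-error bars) against bin size on a log
#' axis, one line per covariate mode; the dashed horizontal line marks
#' the phenotypic variance, above which a model has no predictability.
#'
#' @param object A `bin_size_profile` from [scan_bin_sizes()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.bin_size_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_size, y = .data$mse,
                                   colour = .data$mode)) +
    ggplot2::geom_hline(yintercept = attr(object, "var_y"),
                        linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mse - .data$mse_se,
                                          ymax = .data$mse + .data$mse_se)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = sprintf("bin size (%s)", df$unit[1]),
                  y = "cross-validated MSE", colour = NULL)
}

#' Plot per-bin LOD scores
#'
#' LOD score of every tested (nonzero-effect) bin along the genome, with
#' the significance threshold as a horizontal line.
#'
#' @param object A `bin_tests` tibble from [wald_lod()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.bin_tests <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$bin, y = .data$lod)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$bin, yend = 0)) +
    ggplot2::geom_hline(yintercept = attr(object, "lod_threshold"),
                        linetype = "dashed") +
    ggplot2::labs(x = "bin", y = "LOD")
}

#' Plot a single-marker scan
#'
#' @param object A `marker_scan` from [single_marker_scan()].
#' @param ... Unused.
#' @return A ggplot of per-marker LOD scores in map order.
#' @exportS3Method ggplot2::autoplot
autoplot.marker_scan <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      index = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$lod)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::labs(x = "marker index", y = "LOD")
}
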