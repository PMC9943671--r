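#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Ratiometric plane of decoded spots
#'
#' Scatter of per-spot detection/reference ratios (first channel vs second
#' for multi-channel designs; strip plot for one channel), colored by decoded
#' transcript - the separation of code clusters is the visual core of the
#' decoding.
#'
#' @param decoded `nl_decoded` object.
#' @param max_points subsample cap for plotting.
#' @return a ggplot.
#' @export
plot_ratio_plane <- function(decoded, max_points = 20000L) {
  stopifnot(inherits(decoded, "nl_decoded"))
  cfg <- codebook_config(decoded$codebook)
  df <- tibble::as_tibble(decoded$spots)
  if (nrow(df) > max_points) df <- dplyr::slice_sample(df, n = max_points)
  df$decoded <- dplyr::coalesce(df$gene_id, "REJECT")
  r1 <- paste0("r_", cfg$channel_names[1])
  if (cfg$channels >= 2L) {
    r2 <- paste0("r_", cfg$channel_names[2])
    p <- ggplot2::ggplot(df, ggplot2::aes(.data[[r1]], .data[[r2]],
                                          color = .data$decoded)) +
      ggplot2::geom_point(alpha = 0.4, size = 0.8) +
      ggplot2::labs(x = paste0(cfg$channel_names[1], "/",
                               cfg$reference_channel, " ratio"),
                    y = paste0(cfg$channel_names[2], "/",
                               cfg$reference_channel, " ratio"),
                    color = "transcript")
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$decoded, .data[[r1]],
                                          color = .data$decoded)) +
      ggplot2::geom_jitter(width = 0.2, alpha = 0.4, size = 0.8) +
      ggplot2::labs(x = NULL, y = paste0(cfg$channel_names[1], "/",
                                         cfg$reference_channel, " ratio")) +
      ggplot2::guides(color = "none")
  }
  p + ggplot2::theme_minimal()
}

#' @method autoplot nl_decoded
#' @export
autoplot.nl_decoded <- function(object, ...) plot_ratio_plane(object, ...)

#' Intensity ladder of a single-channel barcode series
#'
#' Boxplots of raw detection intensity and of the detection/reference ratio
#' against the repeat level: the raw signal spreads with amplicon length
#' while the ratio collapses onto the level.
#'
#' @param photometry tibble from [simulate_spot_intensities()].
#' @param codebook the codebook.
#' @return a ggplot.
#' @export
plot_intensity_ladder <- function(photometry, codebook) {
  cfg <- codebook_config(codebook)
  ch <- cfg$channel_names[1]
  df <- photometry |>
    dplyr::filter(.data[[paste0("level_", ch)]] >= 1L) |>
    dplyr::mutate(level = factor(.data[[paste0("level_", ch)]]),
                  ratio = .data[[paste0("I_", ch)]] / .data$I_Re)
  long <- dplyr::bind_rows(
    dplyr::transmute(df, level = .data$level,
                     value = .data[[paste0("I_", ch)]],
                     what = "raw De intensity"),
    dplyr::transmute(df, level = .data$level, value = .data$ratio,
                     what = "De/Re ratio")
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$level, .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~what, scales = "free_y") +
    ggplot2::labs(x = "repeat level (DFP count)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Per-gene copy-number histograms
#'
#' @param expr `nl_expression` tibble.
#' @return a ggplot faceted by gene.
#' @export
plot_expression_histograms <- function(expr) {
  long <- expr |>
    tibble::as_tibble() |>
    tidyr::pivot_longer(-"gene_id", names_to = "cell", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(.data$count)) +
    ggplot2::geom_histogram(binwidth = 1) +
    ggplot2::facet_wrap(~gene_id, scales = "free") +
    ggplot2::labs(x = "decoded copies per cell", y = "cells") +
    ggplot2::theme_minimal()
}

#' @method autoplot nl_centroid_fit
#' @export
autoplot.nl_centroid_fit <- function(object, ...) {
  df <- tibble::as_tibble(as.table(object$confusion))
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), color = "white") +
    ggplot2::labs(x = "predicted", y = "true cell type") +
    ggplot2::theme_minimal()
}
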