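# ggplot2 views of the main result types.

#' Plot an MS2 spectrum with optional fragment annotations
#'
#' Stick spectrum; matched peaks (from [match_spectrum()]) are coloured by
#' fragment kind and labelled with their annotation.
#'
#' @param spectrum Tibble with `mz`, `intensity`.
#' @param matches Optional output of [match_spectrum()].
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum, matches = NULL) {
  p <- ggplot2::ggplot(spectrum, ggplot2::aes(x = .data$mz)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, y = 0,
                                       yend = .data$intensity),
                          colour = "grey40") +
    ggplot2::labs(x = "m/z", y = "intensity (arb. u.)") +
    ggplot2::theme_minimal()
  if (!is.null(matches) && nrow(matches) > 0) {
    p <- p +
      ggplot2::geom_segment(
        data = matches,
        ggplot2::aes(x = .data$peak_mz, xend = .data$peak_mz, y = 0,
                     yend = .data$peak_intensity, colour = .data$kind)
      ) +
      ggplot2::geom_text(
        data = matches,
        ggplot2::aes(x = .data$peak_mz, y = .data$peak_intensity,
                     label = .data$annotation, colour = .data$kind),
        angle = 90, hjust = -0.05, size = 2.5, show.legend = FALSE
      ) +
      ggplot2::labs(colour = "fragment kind")
  }
  p
}

#' Plot detected homolog series over the feature map
#'
#' Features in the m/z vs retention-time plane; members of each detected
#' series are connected, visualising the repeat-unit ladders.
#'
#' @param features Feature tibble (`feature_id`, `mz`, `rt_min`).
#' @param series Output of [detect_series()].
#' @return A ggplot object.
#' @export
plot_series <- function(features, series) {
  p <- ggplot2::ggplot(features, ggplot2::aes(x = .data$rt_min, y = .data$mz)) +
    ggplot2::geom_point(colour = "grey60") +
    ggplot2::labs(x = "retention time (min)", y = "m/z") +
    ggplot2::theme_minimal()
  if (nrow(series) > 0) {
    paths <- purrr::imap_dfr(series$members, function(ids, i) {
      dplyr::mutate(
        features[match(ids, features$feature_id), c("mz", "rt_min")],
        series_id = factor(series$series_id[i])
      )
    })
    p <- p +
      ggplot2::geom_path(data = paths,
                         ggplot2::aes(colour = .data$series_id)) +
      ggplot2::geom_point(data = paths,
                          ggplot2::aes(colour = .data$series_id)) +
      ggplot2::labs(colour = "series")
  }
  p
}

#' Plot a relative-abundance report
#'
#' Horizontal bar chart of within-group percentages, largest first.
#'
#' @param report Output of [abundance_report()].
#' @return A ggplot object.
#' @export
plot_abundance <- function(report) {
  ggplot2::ggplot(
    report,
    ggplot2::aes(x = .data$pct, y = stats::reorder(.data$name, .data$pct))
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "relative abundance (%)", y = NULL) +
    ggplot2::theme_minimal()
}
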