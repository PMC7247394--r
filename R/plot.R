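#' Whole-genome alignment dot plot
#'
#' Draws the chained alignments of [dotplot_data()] as diagonal segments in
#' cumulative coordinates, with chromosome/scaffold boundaries as grid lines;
#' forward matches ascend, reverse matches descend.
#'
#' @param segments Tibble from [dotplot_data()].
#' @param ref_lengths,query_lengths Named length vectors (for boundary
#'   lines); optional.
#' @return A ggplot object.
#' @export
plot_dotplot <- function(segments, ref_lengths = NULL, query_lengths = NULL) {
  p <- ggplot2::ggplot(segments) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$ref_x0, xend = .data$ref_x1,
      y = .data$query_y0, yend = .data$query_y1,
      colour = .data$strand), linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = c(`+` = "#1f77b4", `-` = "#d62728")) +
    ggplot2::labs(x = "reference (cumulative bp)",
                  y = "assembly (cumulative bp)") +
    ggplot2::theme_minimal()
  if (!is.null(ref_lengths)) {
    p <- p + ggplot2::geom_vline(
      xintercept = cumsum(as.numeric(ref_lengths[sort(names(ref_lengths))])),
      colour = "grey80", linewidth = 0.3)
  }
  if (!is.null(query_lengths)) {
    p <- p + ggplot2::geom_hline(
      yintercept = cumsum(as.numeric(query_lengths[sort(names(query_lengths))])),
      colour = "grey80", linewidth = 0.3)
  }
  p
}

#' @export
autoplot.sv_calls <- function(object, ...) {
  ev <- tidy(object)
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$kind, y = .data$size / 1e6)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "event size (Mb)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.scaffold_plan <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$scaffold_start / 1e6, xmax = .data$scaffold_end / 1e6,
      ymin = 0, ymax = 1, fill = .data$type), colour = "grey30",
      linewidth = 0.1) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$scaffold_id),
                        switch = "y") +
    ggplot2::scale_fill_manual(values = c(W = "#9ecae1", N = "grey50"),
                               labels = c(W = "contig", N = "gap")) +
    ggplot2::labs(x = "scaffold position (Mb)", y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank(),
                   strip.text.y.left = ggplot2::element_text(angle = 0))
}

#' Coverage profile plot
#'
#' Step plot of per-base depth runs for one or more contigs, with
#' zero-coverage runs highlighted.
#'
#' @param profiles Coverage-run tibble from [coverage_from_alignments()].
#' @return A ggplot object.
#' @export
plot_coverage <- function(profiles) {
  ggplot2::ggplot(profiles) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start / 1e3, xmax = .data$end / 1e3,
      ymin = 0, ymax = .data$depth),
      fill = "#74a9cf") +
    ggplot2::geom_rect(
      data = filter(profiles, .data$depth == 0),
      ggplot2::aes(xmin = .data$start / 1e3, xmax = .data$end / 1e3,
                   ymin = -0.5, ymax = 0), fill = "#d62728") +
    ggplot2::facet_wrap(~contig_id, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (kb)", y = "depth") +
    ggplot2::theme_minimal()
}
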