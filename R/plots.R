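#' Plot a conservation profile
#'
#' Majority fraction per alignment column, with conserved columns
#' highlighted and the threshold drawn as a horizontal line.
#'
#' @param object A [conservation_profile()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot conservation_profile
#' @export
autoplot.conservation_profile <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$column, y = .data$majority_fraction,
                               colour = .data$is_conserved)) +
    ggplot2::geom_point(size = 0.8, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2c7fb8",
                                            `FALSE` = "grey70"),
                                 name = "conserved") +
    ggplot2::labs(x = "alignment column", y = "majority fraction") +
    ggplot2::theme_minimal()
}

#' Plot a CSI catalogue along the reference protein
#'
#' One horizontal segment per CSI spanning its reported region, the indel
#' itself overdrawn, faceted/coloured by indel type.
#'
#' @param object A [detect_csis()] / [run_csi()] result (`csi_tbl`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot csi_tbl
#' @export
autoplot.csi_tbl <- function(object, ...) {
  d <- as_tibble(object)
  d$label <- sprintf("%s %d-%d", d$protein, d$region_start, d$region_end)
  ggplot2::ggplot(d, ggplot2::aes(y = .data$label)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$region_start,
                                       xend = .data$region_end,
                                       yend = .data$label),
                          colour = "grey70", linewidth = 1) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$indel_start,
                                       xend = .data$indel_end,
                                       yend = .data$label,
                                       colour = .data$indel_type),
                          linewidth = 3) +
    ggplot2::labs(x = "reference position (aa)", y = NULL,
                  colour = "indel") +
    ggplot2::theme_minimal()
}

#' Plot per-protein CXXC motif counts
#' @param object A [count_motifs()] result (`motif_counts`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot motif_counts
#' @export
autoplot.motif_counts <- function(object, ...) {
  d <- as_tibble(object)
  d$sequence_id <- factor(d$sequence_id, levels = rev(d$sequence_id))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_motifs, y = .data$sequence_id)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = "CXXC motifs", y = NULL) +
    ggplot2::theme_minimal()
}

#' Gene-arrangement diagram around an anchor
#'
#' Draws each genome's neighborhood as arrows along a genomic axis
#' (offsets from the anchor), coloured by gene family — a text-free
#' rendition of the classical gene-neighborhood figure.
#'
#' @param neighborhoods An [extract_neighborhood()] result.
#' @return A ggplot object.
#' @export
plot_neighborhoods <- function(neighborhoods) {
  d <- neighborhoods
  d$x <- d$offset
  ggplot2::ggplot(d, ggplot2::aes(y = .data$genome_id)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = ifelse(.data$strand == "+", .data$x - 0.4,
                              .data$x + 0.4),
                   xend = ifelse(.data$strand == "+", .data$x + 0.4,
                                 .data$x - 0.4),
                   yend = .data$genome_id, colour = .data$family),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "cm")),
      linewidth = 2) +
    ggplot2::labs(x = "gene offset from anchor", y = NULL,
                  colour = "family") +
    ggplot2::theme_minimal()
}
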