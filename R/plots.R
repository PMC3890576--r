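#' Plot a genome-scan LOD profile
#'
#' LOD score along the genome, faceted by chromosome, with the genome-wide
#' significance threshold (if attached) as a dashed line and cofactor
#' positions marked with rug ticks.
#'
#' @param object An `iril_scan` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.iril_scan <- function(object, ...) {
  thr <- attr(object, "threshold")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$pos_cm, y = .data$lod)) +
    ggplot2::geom_line(colour = "#2c6e91") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (cM)", y = "LOD") +
    ggplot2::theme_minimal()
  if (!is.null(thr)) {
    p <- p + ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                                 colour = "grey40")
  }
  cof <- attr(object, "cofactors")
  if (length(cof)) {
    at <- object[!is.na(object$marker) & object$marker %in% cof, ]
    p <- p + ggplot2::geom_rug(data = at, sides = "b", colour = "grey30")
  }
  p
}

#' Plot a partial-correlation trait network
#'
#' Nodes on a circle, edges drawn with width proportional to the partial
#' correlation magnitude and colour by sign (blue positive, red negative).
#'
#' @param object An `iril_trait_network`.
#' @param label_size Node label size.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.iril_trait_network <- function(object, label_size = 3, ...) {
  nodes <- object$nodes
  theta <- seq(0, 2 * pi, length.out = length(nodes) + 1)[seq_along(nodes)]
  layout <- tibble::tibble(trait = nodes, x = cos(theta), y = sin(theta))
  edges <- object$edges |>
    dplyr::left_join(dplyr::rename(layout, xa = "x", ya = "y"),
                     by = c(trait_a = "trait")) |>
    dplyr::left_join(dplyr::rename(layout, xb = "x", yb = "y"),
                     by = c(trait_b = "trait"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, linewidth = abs(.data$partial_r),
                   colour = .data$partial_r > 0),
      alpha = 0.7, show.legend = c(linewidth = FALSE, colour = TRUE)
    ) +
    ggplot2::geom_point(data = layout, ggplot2::aes(.data$x, .data$y),
                        size = 8, colour = "grey85") +
    ggplot2::geom_text(data = layout,
                       ggplot2::aes(.data$x, .data$y, label = .data$trait),
                       size = label_size) +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2c6e91",
                                            `FALSE` = "#c0392b"),
                                 labels = c(`TRUE` = "positive",
                                            `FALSE` = "negative"),
                                 name = "partial r") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Plot entry-mean heritabilities by trait and regime
#'
#' @param h2 Wide heritability tibble (e.g. `run_pipeline()$h2` or
#'   [read_heritability_table()] output) with `trait` and `H2_<regime>`
#'   columns.
#' @return A ggplot object.
#' @export
plot_heritability <- function(h2) {
  long <- tidyr::pivot_longer(h2, dplyr::starts_with("H2_"),
                              names_to = "regime", values_to = "H2",
                              names_prefix = "H2_")
  trait_col <- if ("abbreviation" %in% names(long)) "abbreviation" else "trait"
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[trait_col]], y = .data$H2,
                                     fill = .data$regime)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = expression(H^2)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
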