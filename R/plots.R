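#' Plot an inferred network as an activation cascade
#'
#' Genes are laid out left to right by activation zone (so the cascade
#' reads in time order) and stacked within a zone; edges are drawn as
#' arrows, dashed for inhibitory regulation.
#'
#' @param object a [grn_network()] (with activation zones assigned).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot grn_network
#' @export
autoplot.grn_network <- function(object, ...) {
  act <- object$activation
  if (is.null(act))
    act <- tibble::tibble(gene = object$genes, activation_time = NA_real_,
                          zone = 1L)
  nodes <- dplyr::mutate(
    dplyr::group_by(act, .data$zone),
    y = seq_along(.data$gene) - (dplyr::n() + 1) / 2)
  nodes <- dplyr::ungroup(nodes)
  p <- ggplot2::ggplot(nodes, ggplot2::aes(.data$zone, .data$y))
  if (nrow(object$edges)) {
    e <- dplyr::left_join(object$edges,
                          dplyr::select(nodes, regulator = "gene",
                                        x0 = "zone", y0 = "y"),
                          by = "regulator")
    e <- dplyr::left_join(e,
                          dplyr::select(nodes, target = "gene",
                                        x1 = "zone", y1 = "y"),
                          by = "target")
    p <- p + ggplot2::geom_segment(
      data = e,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, linetype = .data$sign),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "in")),
      colour = "grey40")
  }
  p +
    ggplot2::geom_label(ggplot2::aes(label = .data$gene)) +
    ggplot2::scale_linetype_manual(values = c("+" = "solid",
                                              "-" = "dashed"),
                                   name = "regulation") +
    ggplot2::scale_x_continuous(breaks = sort(unique(nodes$zone))) +
    ggplot2::labs(x = "activation zone", y = NULL)
}
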