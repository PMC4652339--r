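#' Plot an orthophylogram as a ggplot dendrogram
#'
#' Draws the ultrametric tree with the height axis equal to the
#' symmetrized orthology distance at each merge (node height times two).
#'
#' @param object An `orthophylogram` from [upgma()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot orthophylogram
#' @export
autoplot.orthophylogram <- function(object, ...) {
  phy <- object$phylo
  n_tip <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  total <- max(depth[seq_len(n_tip)])
  height <- total - depth                    # node height above the leaves
  # leaf y positions in plotting order
  y <- rep(NA_real_, n_tip + phy$Nnode)
  y[seq_len(n_tip)] <- seq_len(n_tip)
  for (node in rev(unique(phy$edge[, 1]))) {
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    y[node] <- mean(y[kids])
  }
  seg <- list()
  for (r in seq_len(nrow(phy$edge))) {
    par <- phy$edge[r, 1]; child <- phy$edge[r, 2]
    seg[[length(seg) + 1L]] <- tibble(
      x = height[par], xend = height[child],
      y = y[child], yend = y[child])
    seg[[length(seg) + 1L]] <- tibble(
      x = height[par], xend = height[par],
      y = y[par], yend = y[child])
  }
  seg <- bind_rows(seg)
  tips <- tibble(label = phy$tip.label, x = height[seq_len(n_tip)],
                 y = y[seq_len(n_tip)])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
      ggplot2::aes(x = .data$x, xend = .data$xend,
                   y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = tips,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      hjust = -0.05) +
    ggplot2::scale_x_reverse(expand = ggplot2::expansion(mult = c(.05, .35))) +
    ggplot2::labs(x = "orthology distance from leaves (node height)",
                  y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank(),
                   panel.grid.minor.y = ggplot2::element_blank())
}

#' Volcano-style plot of a differential-expression result
#'
#' @param object A `de_result` from [de_filter()].
#' @param ... Unused.
#' @return A ggplot object (log2 mean difference vs -log10 raw p, genes
#'   passing the conjunction rule highlighted).
#' @method autoplot de_result
#' @export
autoplot.de_result <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_diff,
                                   y = -log10(pmax(.data$p_value, 1e-300)),
                                   colour = .data$passes)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "log2 mean difference", y = "-log10 p",
                  colour = "passes") +
    ggplot2::theme_minimal()
}

#' Time-course plot of relative expression
#'
#' @param object A `relative_expression` from [delta_delta_ct()].
#' @param ... Unused.
#' @return A ggplot object (fold change per condition, one line per
#'   gene, log2 y scale).
#' @method autoplot relative_expression
#' @export
autoplot.relative_expression <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$fold,
                                   group = .data$gene,
                                   colour = .data$gene)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::labs(y = "relative expression (fold of calibrator)") +
    ggplot2::theme_minimal()
}
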