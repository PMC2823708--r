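#' Plot an unmixing fit in the leading reduced dimensions
#'
#' Scatter of the samples' first two PCA scores with the fitted simplex
#' vertices (and its edges projected onto those dimensions) overlaid --
#' the standard diagnostic view: the point cloud should fill the simplex
#' and the vertices should sit just outside its extremes.
#'
#' @param object A `"mix_fit"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mix_fit <- function(object, ...) {
  P <- object$reduced$scores
  if (ncol(P) == 1) P <- cbind(P, 0)
  V <- object$simplex$vertices
  if (ncol(V) == 1) V <- cbind(V, 0)
  pts <- tibble::tibble(x = P[, 1], y = P[, 2])
  verts <- tibble::tibble(x = V[, 1], y = V[, 2],
                          component = component_ids(nrow(V)))
  pairs <- utils::combn(nrow(V), 2)
  segs <- tibble::tibble(x = V[pairs[1, ], 1], y = V[pairs[1, ], 2],
                         xend = V[pairs[2, ], 1], yend = V[pairs[2, ], 2])
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5, size = 1, colour = "firebrick") +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(xend = .data$xend, yend = .data$yend),
                          linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(data = verts, shape = 4, size = 4, stroke = 1.5,
                        colour = "navy") +
    ggplot2::geom_text(data = verts, ggplot2::aes(label = .data$component),
                       nudge_y = diff(range(pts$y)) * 0.04, colour = "navy") +
    ggplot2::labs(x = "dimension 1", y = "dimension 2",
                  title = sprintf("%d-component unmixing (volume %.3g)",
                                  object$k, object$volume)) +
    ggplot2::theme_minimal()
}

#' Stacked-bar view of mixture fractions
#'
#' One bar per sample, filled by component fraction; optionally faceted by
#' a sample-type labelling.
#'
#' @param fit A `"mix_fit"` (or bare fraction matrix with rownames).
#' @param labels Optional labelling as in [summarize_fractions_by_type()].
#' @return A ggplot object.
#' @export
plot_fractions <- function(fit, labels = NULL) {
  f <- if (inherits(fit, "mix_fit")) fit$fractions else fit
  long <- tibble::as_tibble(pmax(f, 0), rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "component",
                        values_to = "fraction")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id,
                                          y = .data$fraction,
                                          fill = .data$component)) +
    ggplot2::geom_col(position = "stack", width = 1) +
    ggplot2::labs(x = NULL, y = "mixture fraction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  if (!is.null(labels)) {
    if (!is.data.frame(labels))
      labels <- tibble::tibble(sample_id = names(labels),
                               type = unname(labels))
    long2 <- dplyr::inner_join(long, labels, by = "sample_id")
    p <- p %+% long2 + ggplot2::facet_grid(~type, scales = "free_x",
                                           space = "free_x")
  }
  p
}

# Simple layered tree layout: BFS depths from the root, leaves spread
# evenly, internal nodes centred over their children.
tree_layout <- function(phy, root = 1) {
  k <- length(phy$component_ids)
  adj <- lapply(seq_len(k), function(i) integer(0))
  for (i in seq_len(nrow(phy$edges))) {
    e <- phy$edges[i, ]
    adj[[e[1]]] <- c(adj[[e[1]]], e[2])
    adj[[e[2]]] <- c(adj[[e[2]]], e[1])
  }
  x <- numeric(k); depth <- numeric(k)
  leaf_counter <- 0
  assign_x <- function(node, from, d) {
    depth[node] <<- d
    kids <- setdiff(adj[[node]], from)
    if (length(kids) == 0) {
      leaf_counter <<- leaf_counter + 1
      x[node] <<- leaf_counter
    } else {
      for (kid in kids) assign_x(kid, node, d + 1)
      x[node] <<- mean(x[kids])
    }
  }
  assign_x(root, 0L, 0)
  tibble::tibble(node = seq_len(k), id = phy$component_ids,
                 x = x, y = -depth)
}

#' Plot a component phylogeny
#'
#' Draws the (rooted-for-display) spanning tree with nodes labelled by
#' component and, when bootstrap confidences are available, edges labelled
#' by confidence and drawn solid above `0.5`, dashed below.
#'
#' @param object A `"mix_phylogeny"`.
#' @param root Component id or index used to orient the drawing (display
#'   only; the tree itself is unrooted).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mix_phylogeny <- function(object, root = 1, ...) {
  if (is.character(root)) root <- match(root, object$component_ids)
  lay <- tree_layout(object, root)
  e <- object$edges
  segs <- tibble::tibble(
    x = lay$x[e[, 1]], y = lay$y[e[, 1]],
    xend = lay$x[e[, 2]], yend = lay$y[e[, 2]],
    confidence = if (is.null(object$edge_confidence)) NA_real_
                 else object$edge_confidence)
  segs$strong <- is.na(segs$confidence) | segs$confidence > 0.5
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linetype = .data$strong),
                          colour = "grey30", show.legend = FALSE) +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid",
                                              `FALSE` = "dashed")) +
    ggplot2::geom_label(data = lay, ggplot2::aes(x = .data$x, y = .data$y,
                                                 label = .data$id)) +
    ggplot2::theme_void()
  if (!all(is.na(segs$confidence))) {
    segs$mx <- (segs$x + segs$xend) / 2
    segs$my <- (segs$y + segs$yend) / 2
    p <- p + ggplot2::geom_text(
      data = segs,
      ggplot2::aes(x = .data$mx, y = .data$my,
                   label = sprintf("%.0f%%", 100 * .data$confidence)),
      size = 3, colour = "grey20", nudge_x = 0.08)
  }
  p
}

#' @importFrom ggplot2 autoplot %+%
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
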