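# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_segment geom_point
#'   geom_text labs coord_flip theme_minimal scale_color_manual
NULL

#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance

#' Plot the top enriched GO terms
#'
#' Horizontal bars of -log10(p) for the `n_terms` most enriched terms.
#'
#' @param object A `go_enrichment`.
#' @param n_terms Number of terms to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.go_enrichment <- function(object, n_terms = 15L, ...) {
  df <- head(as_tibble(object), n_terms)
  df$label <- ifelse(nzchar(df$name), df$name, df$term_id)
  df$label <- factor(df$label, levels = rev(df$label))
  ggplot(df, aes(x = .data$label, y = -log10(.data$p_value))) +
    geom_col(fill = "#3b6ea5") +
    coord_flip() +
    labs(x = NULL, y = expression(-log[10](p)),
         title = "Parent-child-union GO enrichment") +
    theme_minimal()
}

#' Plot an interaction network
#'
#' Force-directed layout (Fruchterman-Reingold, fixed seed) with seed
#' proteins distinguished from added neighbors.
#'
#' @param object An `interaction_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.interaction_network <- function(object, seed = 1L, ...) {
  nodes <- object$nodes
  if (nrow(nodes) == 0L) {
    return(ggplot() + labs(title = "Empty interaction network") + theme_minimal())
  }
  g <- igraph::graph_from_data_frame(object$edges[, c("protein_a", "protein_b")],
                                     directed = FALSE, vertices = nodes$protein_id)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  lay <- tibble(protein_id = igraph::V(g)$name, x = xy[, 1L], y = xy[, 2L])
  lay <- left_join(lay, nodes, by = "protein_id")
  ed <- object$edges
  ed$x <- lay$x[match(ed$protein_a, lay$protein_id)]
  ed$y <- lay$y[match(ed$protein_a, lay$protein_id)]
  ed$xend <- lay$x[match(ed$protein_b, lay$protein_id)]
  ed$yend <- lay$y[match(ed$protein_b, lay$protein_id)]
  ggplot() +
    geom_segment(data = ed, aes(x = .data$x, y = .data$y,
                                xend = .data$xend, yend = .data$yend),
                 color = "grey60") +
    geom_point(data = lay, aes(x = .data$x, y = .data$y, color = .data$role),
               size = 3) +
    geom_text(data = lay, aes(x = .data$x, y = .data$y, label = .data$protein_id),
              vjust = -1, size = 3) +
    scale_color_manual(values = c(seed = "#c23b22", added = "#3b6ea5")) +
    labs(title = sprintf("Interaction neighborhood (%d hop%s, mode %s)",
                         object$hops, if (object$hops > 1L) "s" else "",
                         object$mode),
         x = NULL, y = NULL, color = NULL) +
    theme_minimal()
}

#' Plot the three-way EC classification of a pathway
#'
#' @param object A `pathway_highlight`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pathway_highlight <- function(object, ...) {
  df <- as_tibble(object)
  df$ec_number <- factor(df$ec_number, levels = rev(sort(df$ec_number)))
  ggplot(df, aes(x = .data$ec_number, y = 1, fill = .data$status)) +
    geom_col() +
    coord_flip() +
    ggplot2::scale_fill_manual(values = c(IN_SET = "#40b0a6",
                                          IN_GENOME_ONLY = "grey65",
                                          ABSENT = "grey90")) +
    labs(x = "EC number", y = NULL, fill = NULL,
         title = sprintf("Pathway %s", attr(object, "pathway"))) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
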