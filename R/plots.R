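#' Bar chart of Venn region counts
#'
#' Region counts of a phylum-level Venn partition, ordered by the number of
#' groups in each region — the tabular equivalent of a multi-set Venn
#' diagram.
#'
#' @param vp Venn partition tibble from [venn_partition()].
#' @param drop_empty Drop regions with zero features (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_venn_regions <- function(vp, drop_empty = TRUE) {
  if (drop_empty) vp <- filter(vp, .data$count > 0)
  vp |>
    mutate(region = factor(.data$region, levels = .data$region[order(.data$n_groups, -.data$count)])) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$region, y = .data$count,
                                 fill = factor(.data$n_groups))) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "features", fill = "groups in region") +
    ggplot2::theme_minimal()
}

#' Per-extract total and strain-specific feature counts
#'
#' Mirrors the standard cohort overview: one bar panel with total features
#' per extract, one with strain-specific features, coloured by phylum, with
#' a dashed line at the specificity threshold used for prioritization.
#'
#' @param reports Report tibble from [build_strain_reports()].
#' @param specific_threshold Threshold line for the specific-feature panel.
#' @return A ggplot object.
#' @export
plot_strain_specificity <- function(reports, specific_threshold = 80) {
  long <- reports |>
    select("extract_id", "phylum", total = "total_features",
           specific = "specific_features") |>
    tidyr::pivot_longer(c("total", "specific"), names_to = "panel",
                        values_to = "n") |>
    mutate(panel = factor(.data$panel, levels = c("total", "specific")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$extract_id, y = .data$n,
                                     fill = .data$phylum)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(
      data = tibble(panel = factor("specific", levels = c("total", "specific")),
                    y = specific_threshold),
      ggplot2::aes(yintercept = .data$y), linetype = "dashed") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "features") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 6))
}

#' Annotation level shares
#'
#' @param annotations Annotation tibble from [annotate_cascade()].
#' @return A ggplot object (bar chart of level percentages).
#' @export
plot_annotation_levels <- function(annotations) {
  annotation_summary(annotations) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$level, y = .data$pct, fill = .data$level)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "annotation level", y = "% of features") +
    ggplot2::theme_minimal()
}

#' Plot a molecular network
#'
#' Fruchterman-Reingold layout of the molecular network; singletons are
#' omitted (as in the usual network figures) unless requested. Nodes can be
#' coloured by any node column, e.g. `family`.
#'
#' @param object A `molecular_network`.
#' @param colour_by Node column to colour by (default `"family"`).
#' @param show_singletons Include degree-zero nodes.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot molecular_network
#' @export
autoplot.molecular_network <- function(object, colour_by = "family",
                                       show_singletons = FALSE, ...) {
  nodes <- object$nodes
  if (!show_singletons) nodes <- filter(nodes, !.data$is_singleton)
  if (nrow(nodes) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "empty network"))
  }
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(object$edges$node_a),
                   to = as.character(object$edges$node_b)),
    directed = FALSE, vertices = data.frame(name = as.character(nodes$feature_id)))
  set.seed(1L)
  xy <- igraph::layout_with_fr(g)
  nodes$x <- xy[, 1]
  nodes$y <- xy[, 2]
  seg <- object$edges |>
    left_join(nodes |> select(node_a = "feature_id", xa = "x", ya = "y"), by = "node_a") |>
    left_join(nodes |> select(node_b = "feature_id", xb = "x", yb = "y"), by = "node_b") |>
    filter(!is.na(.data$xa), !is.na(.data$xb))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$xa, y = .data$ya,
                                       xend = .data$xb, yend = .data$yb),
                          colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = factor(.data[[colour_by]])),
                        size = 2) +
    ggplot2::labs(colour = colour_by) +
    ggplot2::theme_void()
}
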