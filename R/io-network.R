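#' Write a molecular network to GraphML or a TSV edge list
#'
#' GraphML output is Cytoscape-compatible: nodes carry `mz`, `rt`, `family`,
#' and — when annotation and exclusivity tables are supplied — `level`,
#' `name`, `class_label` and `dominant_extract`; edges carry `score` and
#' `n_matched`. The edge-list format writes one TSV row per edge with the
#' same edge attributes (an empty network yields a header-only file).
#'
#' @param network A `molecular_network`.
#' @param path Output path.
#' @param format `"graphml"` or `"edgelist"`.
#' @param annotations Optional annotation tibble from [annotate_cascade()].
#' @param exclusivity Optional tibble from [family_exclusivity()].
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("graphml", "edgelist"),
                          annotations = NULL, exclusivity = NULL) {
  format <- match.arg(format)
  nodes <- network$nodes
  if (!is.null(annotations)) {
    nodes <- left_join(nodes,
                       annotations |> select("feature_id", "level", "name", "class_label"),
                       by = "feature_id")
  }
  if (!is.null(exclusivity)) {
    nodes <- left_join(nodes,
                       exclusivity |> select("family", "dominant_extract"),
                       by = "family")
  }
  if (format == "edgelist") {
    readr::write_tsv(network$edges, path, progress = FALSE)
    return(invisible(path))
  }
  vert <- as.data.frame(nodes)
  vert$name <- as.character(vert$feature_id)
  vert <- vert[c("name", setdiff(names(vert), "name"))]
  vert$family <- ifelse(is.na(vert$family), -1L, vert$family)
  vert$rt <- ifelse(is.na(vert$rt), -1, vert$rt)
  for (col in names(vert)) {
    if (is.character(vert[[col]])) vert[[col]][is.na(vert[[col]])] <- ""
  }
  ed <- data.frame(from = as.character(network$edges$node_a),
                   to = as.character(network$edges$node_b),
                   score = network$edges$score,
                   n_matched = network$edges$n_matched)
  g <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = vert)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a molecular network written by [write_network()]
#'
#' @param path Path to the file.
#' @param format `"graphml"` or `"edgelist"`.
#' @return A list with `nodes` (`NULL` for edge lists) and `edges` tibbles.
#' @export
read_network <- function(path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("network file not found: ", path))
  if (format == "edgelist") {
    edges <- readr::read_tsv(path, col_types = readr::cols(
      node_a = readr::col_integer(), node_b = readr::col_integer(),
      score = readr::col_double(), n_matched = readr::col_integer()
    ), progress = FALSE)
    return(list(nodes = NULL, edges = as_tibble(edges)))
  }
  g <- igraph::read_graph(path, format = "graphml")
  vat <- igraph::as_data_frame(g, what = "vertices")
  eat <- igraph::as_data_frame(g, what = "edges")
  nodes <- as_tibble(vat) |> mutate(feature_id = as.integer(.data$name)) |>
    select(-"name", -any_of("id"))
  edges <- as_tibble(eat) |>
    mutate(node_a = pmin(as.integer(.data$from), as.integer(.data$to)),
           node_b = pmax(as.integer(.data$from), as.integer(.data$to))) |>
    select("node_a", "node_b", any_of(c("score", "n_matched"))) |>
    arrange(.data$node_a, .data$node_b)
  list(nodes = nodes, edges = edges)
}
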