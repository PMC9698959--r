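#' Molecular network construction parameters
#'
#' Edge and family thresholds for feature-based molecular networking:
#' minimum cosine score 0.5, minimum matched peaks 4, mutual top-10 edge
#' retention, and a molecular-family size cap of 100 nodes.
#'
#' @param min_cosine Minimum modified-cosine score for an edge.
#' @param min_matched_peaks Minimum matched peak pairs for an edge.
#' @param top_k Edges survive only if each endpoint ranks in the other's
#'   `top_k` most similar nodes.
#' @param max_family_size Maximum connected-component size; larger components
#'   lose their lowest-scoring edges until they comply.
#' @param inclusive If `TRUE` (default) the score and matched-peak cutoffs
#'   are inclusive (`>=`); if `FALSE`, strict (`>`).
#' @return A list of class `network_params`.
#' @export
network_params <- function(min_cosine = 0.5, min_matched_peaks = 4,
                           top_k = 10, max_family_size = 100,
                           inclusive = TRUE) {
  stopifnot(min_cosine >= 0, min_cosine <= 1, min_matched_peaks >= 1,
            top_k >= 1, max_family_size >= 2)
  structure(list(min_cosine = min_cosine, min_matched_peaks = min_matched_peaks,
                 top_k = top_k, max_family_size = max_family_size,
                 inclusive = inclusive),
            class = "network_params")
}

#' Build a feature-based molecular network
#'
#' Computes the modified cosine for every pair of spectra that survive the
#' precursor exclusion window, keeps edges passing the score and
#' matched-peak thresholds, applies the mutual top-k rule, and splits
#' oversized connected components by removing their lowest-scoring edges
#' ([cap_families()]). Connected components with at least two nodes are the
#' molecular families; degree-zero nodes are singletons.
#'
#' @param spectra Spectra tibble (see [read_mgf()]).
#' @param sim [similarity_params()].
#' @param net [network_params()].
#' @param quant Optional quantification tibble; when given, node m/z and
#'   retention times are taken from it (otherwise from the spectra).
#' @return An object of class `molecular_network`: a list with tibbles
#'   `nodes` (`feature_id`, `mz`, `rt`, `family`, `is_singleton`) and
#'   `edges` (`node_a`, `node_b`, `score`, `n_matched`; `node_a < node_b`),
#'   plus the parameter sets. Features whose spectra are emptied by the
#'   precursor window filter are excluded.
#' @seealso [network_summary()], [family_exclusivity()], [write_network()]
#' @export
build_network <- function(spectra, sim = similarity_params(),
                          net = network_params(), quant = NULL) {
  spectra <- filter_precursor_window(spectra, sim$precursor_window)
  spectra <- spectra[spectra$n_peaks > 0, , drop = FALSE]
  spectra <- spectra[order(spectra$feature_id), , drop = FALSE]
  if (nrow(spectra) == 0) abort("no spectrum survives the precursor window filter")

  norm <- map(spectra$peaks, normalize_peaks, intensity_power = sim$intensity_power)
  ids <- spectra$feature_id
  prec <- spectra$precursor_mz
  n <- length(ids)

  edges <- vector("list", n)
  # 1e-9 guard so accumulated floating error cannot flip a boundary score
  score_ok <- if (net$inclusive) {
    function(s) s >= net$min_cosine - 1e-9
  } else {
    function(s) s > net$min_cosine + 1e-9
  }
  ge <- if (net$inclusive) `>=` else `>`
  for (i in seq_len(max(n - 1, 0))) {
    rows <- vector("list", n - i)
    for (j in seq.int(i + 1, n)) {
      r <- cosine_core(norm[[i]]$mz, norm[[i]]$weight,
                       norm[[j]]$mz, norm[[j]]$weight,
                       prec[i] - prec[j], sim$fragment_tol)
      if (score_ok(r$score) && ge(r$n_matched, net$min_matched_peaks)) {
        rows[[j - i]] <- c(ids[i], ids[j], r$score, r$n_matched)
      }
    }
    edges[[i]] <- rows
  }
  em <- do.call(rbind, unlist(edges, recursive = FALSE))
  edge_tbl <- if (is.null(em)) empty_edges() else {
    tibble(node_a = as.integer(pmin(em[, 1], em[, 2])),
           node_b = as.integer(pmax(em[, 1], em[, 2])),
           score = em[, 3], n_matched = as.integer(em[, 4]))
  }
  edge_tbl <- topk_prune(edge_tbl, net$top_k)

  nodes <- tibble(feature_id = ids,
                  mz = prec,
                  rt = if ("rt" %in% names(spectra)) spectra$rt else NA_real_)
  if (!is.null(quant)) {
    nodes$mz <- quant$mz[match(ids, quant$feature_id)]
    nodes$rt <- quant$rt[match(ids, quant$feature_id)]
  }
  network <- structure(list(nodes = nodes, edges = edge_tbl,
                            sim_params = sim, net_params = net),
                       class = "molecular_network")
  network <- cap_families(network, net$max_family_size)
  network
}

empty_edges <- function() {
  tibble(node_a = integer(), node_b = integer(),
         score = double(), n_matched = integer())
}

#' Mutual top-k edge pruning
#'
#' An edge survives only if each endpoint appears among the other's `top_k`
#' most similar partners. Partners are ranked by descending score with ties
#' broken by ascending partner id, so pruning is deterministic.
#'
#' @param edges Edge tibble (`node_a`, `node_b`, `score`, `n_matched`).
#' @param top_k Rank cutoff.
#' @return The pruned edge tibble.
#' @export
topk_prune <- function(edges, top_k) {
  if (nrow(edges) == 0) return(edges)
  inc <- bind_rows(
    tibble(node = edges$node_a, partner = edges$node_b, score = edges$score,
           edge = seq_len(nrow(edges))),
    tibble(node = edges$node_b, partner = edges$node_a, score = edges$score,
           edge = seq_len(nrow(edges)))
  ) |>
    group_by(.data$node) |>
    arrange(desc(.data$score), .data$partner, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup()
  ok <- inc |>
    group_by(.data$edge) |>
    summarise(keep = all(.data$rank <= top_k), .groups = "drop")
  edges[sort(ok$edge[ok$keep]), , drop = FALSE]
}

components_of <- function(nodes, edges) {
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges$node_a), to = as.character(edges$node_b)),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$feature_id))
  )
  comp <- igraph::components(g)
  setNames(comp$membership[as.character(nodes$feature_id)], nodes$feature_id)
}

#' Cap molecular family sizes
#'
#' While any connected component exceeds `max_family_size`, the globally
#' lowest-scoring edge inside an oversized component is removed (ties broken
#' by canonical `(node_a, node_b)` order) and components are recomputed.
#' Edge removal only ever splits components, so capping is idempotent.
#'
#' @param network A `molecular_network`.
#' @param max_family_size Size cap.
#' @return The network with compliant components and refreshed `family` /
#'   `is_singleton` node columns.
#' @export
cap_families <- function(network, max_family_size = network$net_params$max_family_size) {
  edges <- network$edges
  nodes <- network$nodes
  repeat {
    memb <- components_of(nodes, edges)
    sizes <- table(memb)
    big <- as.integer(names(sizes)[sizes > max_family_size])
    if (length(big) == 0) break
    in_big <- memb[as.character(edges$node_a)] %in% big
    cand <- which(in_big)
    pick <- cand[order(edges$score[cand], edges$node_a[cand], edges$node_b[cand])][1]
    edges <- edges[-pick, , drop = FALSE]
  }
  network$edges <- edges
  network$nodes <- annotate_families(nodes, edges)
  network
}

# assign family ids (component of size >= 2, numbered by smallest member id)
annotate_families <- function(nodes, edges) {
  memb <- components_of(nodes, edges)
  sizes <- table(memb)
  fam_comps <- as.integer(names(sizes)[sizes >= 2])
  first_member <- vapply(fam_comps, function(cid) min(nodes$feature_id[memb == cid]), double(1))
  fam_id <- setNames(rank(first_member), fam_comps)
  nodes$family <- ifelse(memb %in% fam_comps,
                         as.integer(fam_id[as.character(memb)]), NA_integer_)
  nodes$is_singleton <- is.na(nodes$family)
  nodes
}

#' Family membership table of a molecular network
#'
#' @param network A `molecular_network`.
#' @return A tibble with `family`, `size` and a `members` list-column of
#'   feature ids.
#' @export
network_families <- function(network) {
  network$nodes |>
    filter(!is.na(.data$family)) |>
    group_by(.data$family) |>
    summarise(size = n(), members = list(sort(.data$feature_id)), .groups = "drop") |>
    arrange(.data$family)
}

#' Strain exclusivity of molecular families
#'
#' For each family, finds the extract with the most family nodes that are
#' strain-specific to it (present in that extract only) and reports the
#' fraction of family nodes exclusive to that extract. Families with
#' fraction 1 are strain-exclusive — a whole family of candidate compounds
#' seen in a single strain.
#'
#' @param network A `molecular_network`.
#' @param pm Presence tibble covering all network nodes.
#' @return A tibble with `family`, `size`, `dominant_extract`,
#'   `n_exclusive`, `fraction_exclusive`, `is_exclusive`.
#' @export
family_exclusivity <- function(network, pm) {
  fams <- network_families(network)
  if (nrow(fams) == 0) {
    return(tibble(family = integer(), size = integer(),
                  dominant_extract = character(), n_exclusive = integer(),
                  fraction_exclusive = double(), is_exclusive = logical()))
  }
  missing <- setdiff(unlist(fams$members), pm$feature_id)
  if (length(missing) > 0) {
    abort(paste0("presence matrix does not cover node(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  m <- presence_as_matrix(pm)
  tot <- rowSums(m)
  solo_sample <- ifelse(tot == 1L, colnames(m)[max.col(m, ties.method = "first")], NA)
  names(solo_sample) <- rownames(m)

  fams |>
    mutate(ex = map(.data$members, function(ids) {
      s <- solo_sample[as.character(ids)]
      s <- s[!is.na(s)]
      if (length(s) == 0) return(list(extract = NA_character_, n = 0L))
      tab <- sort(table(s), decreasing = TRUE)
      top <- tab[tab == tab[1]]
      list(extract = sort(names(top))[1], n = as.integer(tab[1]))
    })) |>
    mutate(dominant_extract = map_chr(.data$ex, "extract"),
           n_exclusive = map_int(.data$ex, "n"),
           fraction_exclusive = .data$n_exclusive / .data$size,
           is_exclusive = .data$fraction_exclusive == 1) |>
    select("family", "size", "dominant_extract", "n_exclusive",
           "fraction_exclusive", "is_exclusive")
}

#' Summary counts of a molecular network
#'
#' @param network A `molecular_network`.
#' @return One-row tibble: `n_nodes`, `n_edges`, `n_families`,
#'   `n_singletons`, `singleton_fraction`.
#' @export
network_summary <- function(network) {
  n_nodes <- nrow(network$nodes)
  n_singletons <- sum(network$nodes$is_singleton)
  tibble(
    n_nodes = n_nodes,
    n_edges = nrow(network$edges),
    n_families = length(unique(stats::na.omit(network$nodes$family))),
    n_singletons = n_singletons,
    singleton_fraction = if (n_nodes == 0) 0 else n_singletons / n_nodes
  )
}

#' @export
print.molecular_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf(paste0("<molecular_network> %d nodes, %d edges, %d families, ",
                     "%d singletons (%.1f%%)\n"),
              s$n_nodes, s$n_edges, s$n_families, s$n_singletons,
              100 * s$singleton_fraction))
  invisible(x)
}

#' Tidy the edge table of a molecular network
#'
#' @param x A `molecular_network`.
#' @param ... Unused.
#' @return The edge tibble with the family id of each edge attached.
#' @method tidy molecular_network
#' @export
tidy.molecular_network <- function(x, ...) {
  x$edges |>
    left_join(x$nodes |> select(node_a = "feature_id", family_a = "family"),
              by = "node_a") |>
    select("node_a", "node_b", "score", "n_matched", family = "family_a")
}

#' One-row summary of a molecular network
#'
#' @param x A `molecular_network`.
#' @param ... Unused.
#' @return See [network_summary()].
#' @method glance molecular_network
#' @export
glance.molecular_network <- function(x, ...) network_summary(x)
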