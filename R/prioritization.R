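#' Strain prioritization parameters
#'
#' Flag thresholds for the per-strain reports: the strain-specific feature
#' count threshold of 80 (the working cutoff separating "talented"
#' producers), the 80% unknown-fraction threshold, and the 16S similarity
#' cutoffs of 98.7% (species boundary) and 95% (genus boundary) used to
#' call taxonomic novelty.
#'
#' @param specific_threshold Strain-specific feature count flag cutoff.
#' @param unknown_threshold_pct Percent-unknown flag cutoff.
#' @param species_similarity_cutoff 16S identity below which a strain is a
#'   potential new species.
#' @param genus_similarity_cutoff 16S identity below which a strain is a
#'   potential new genus.
#' @return A list of class `priority_params`.
#' @export
priority_params <- function(specific_threshold = 80, unknown_threshold_pct = 80,
                            species_similarity_cutoff = 98.7,
                            genus_similarity_cutoff = 95) {
  stopifnot(specific_threshold >= 0, unknown_threshold_pct >= 0,
            species_similarity_cutoff >= 0, genus_similarity_cutoff >= 0)
  structure(list(specific_threshold = specific_threshold,
                 unknown_threshold_pct = unknown_threshold_pct,
                 species_similarity_cutoff = species_similarity_cutoff,
                 genus_similarity_cutoff = genus_similarity_cutoff),
            class = "priority_params")
}

#' Per-strain talent reports
#'
#' Combines occurrence, annotation and network evidence into one row per
#' non-blank extract: total detected features, strain-specific features,
#' percent unannotated features, strain-exclusive molecular families, 16S
#' similarity, and flags for high specificity, high unknown share, and
#' taxonomic novelty.
#'
#' @param pm Presence tibble from [presence_matrix()].
#' @param annotations Annotation tibble from [annotate_cascade()], or `NULL`
#'   (percent unknown then reported as `NA`).
#' @param network A `molecular_network`, or `NULL` (no family columns).
#' @param meta Metadata tibble.
#' @param params [priority_params()].
#' @return A tibble with one row per extract: `extract_id`, `strain_id`,
#'   `phylum`, `total_features`, `specific_features`, `pct_unknown`,
#'   `n_exclusive_families`, `exclusive_families` (list-column of family
#'   ids), `taxonomy_similarity`, and logical flags `flag_specific`,
#'   `flag_unknown`, `novel_species`, `novel_genus`.
#' @seealso [rank_strains()]
#' @export
build_strain_reports <- function(pm, annotations = NULL, network = NULL, meta,
                                 params = priority_params()) {
  samples <- presence_samples(pm)
  missing <- setdiff(samples, meta$extract_id)
  if (length(missing) > 0) {
    abort(paste0("missing metadata for extract(s): ", paste(missing, collapse = ", ")))
  }
  m <- presence_as_matrix(pm)
  spec <- strain_specific_counts(pm)

  unknown_pct <- function(s) {
    if (is.null(annotations)) return(NA_real_)
    ids <- pm$feature_id[m[, s]]
    if (length(ids) == 0) return(0)
    lv <- annotations$level[match(ids, annotations$feature_id)]
    100 * mean(lv == "unknown")
  }
  excl <- if (!is.null(network)) family_exclusivity(network, pm) else NULL
  excl_fams <- function(s) {
    if (is.null(excl)) return(integer())
    sort(excl$family[excl$is_exclusive & excl$dominant_extract == s])
  }

  out <- tibble(
    extract_id = samples,
    total_features = as.integer(colSums(m)),
    specific_features = spec$n_specific[match(samples, spec$sample_id)],
    pct_unknown = map_dbl(samples, unknown_pct),
    exclusive_families = map(samples, excl_fams)
  ) |>
    mutate(n_exclusive_families = map_int(.data$exclusive_families, length)) |>
    left_join(meta |> select("extract_id", "strain_id", "phylum",
                             taxonomy_similarity = "similarity_pct"),
              by = "extract_id") |>
    mutate(
      flag_specific = .data$specific_features >= params$specific_threshold,
      flag_unknown = !is.na(.data$pct_unknown) &
        .data$pct_unknown >= params$unknown_threshold_pct,
      novel_species = .data$taxonomy_similarity < params$species_similarity_cutoff,
      novel_genus = .data$taxonomy_similarity < params$genus_similarity_cutoff
    ) |>
    select("extract_id", "strain_id", "phylum", "total_features",
           "specific_features", "pct_unknown", "n_exclusive_families",
           "exclusive_families", "taxonomy_similarity", "flag_specific",
           "flag_unknown", "novel_species", "novel_genus")
  out
}

#' Rank strains by metabolite talent
#'
#' Default ranking is lexicographic: strain-specific feature count
#' (descending), then percent unknown (descending), then number of
#' strain-exclusive families (descending), with ties broken by extract ID so
#' the order is total and deterministic. Alternatively, supply `weights` for
#' a weighted sum of the three min-max-scaled criteria.
#'
#' @param reports Report tibble from [build_strain_reports()].
#' @param weights Optional named numeric vector with entries `specific`,
#'   `unknown`, `families`.
#' @return The reports, ordered, with a leading `rank` column (and
#'   `priority_score` when weights are used).
#' @export
rank_strains <- function(reports, weights = NULL) {
  if (nrow(reports) == 0) abort("no reports to rank")
  pu <- dplyr::coalesce(reports$pct_unknown, 0)
  if (is.null(weights)) {
    ord <- order(-reports$specific_features, -pu,
                 -reports$n_exclusive_families, reports$extract_id)
    out <- reports[ord, , drop = FALSE]
  } else {
    stopifnot(all(c("specific", "unknown", "families") %in% names(weights)))
    scale01 <- function(x) {
      r <- range(x)
      if (r[1] == r[2]) rep(0, length(x)) else (x - r[1]) / (r[2] - r[1])
    }
    score <- weights[["specific"]] * scale01(reports$specific_features) +
      weights[["unknown"]] * scale01(pu) +
      weights[["families"]] * scale01(reports$n_exclusive_families)
    out <- reports |> mutate(priority_score = score)
    out <- out[order(-score, reports$extract_id), , drop = FALSE]
  }
  out |> mutate(rank = row_number()) |> select("rank", dplyr::everything())
}
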