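#' Presence/absence calls from a quantification table
#'
#' A feature is called present in a sample when its peak area exceeds
#' `threshold` (strictly). Blank/QC samples flagged in the metadata are
#' dropped before calling, so all downstream occurrence analytics operate on
#' biological extracts only. The default threshold of 0 matches gap-filled
#' MZmine exports, where 0 encodes absence.
#'
#' @param quant Quantification tibble (see [read_quant_table()]).
#' @param meta Sample metadata tibble covering every sample column of `quant`.
#' @param threshold Area cutoff; presence is `area > threshold`.
#' @return A presence tibble: `feature_id` plus one logical column per
#'   retained (non-blank) sample, with the cutoff stored in the `threshold`
#'   attribute.
#' @seealso [venn_partition()], [strain_specific_counts()]
#' @export
presence_matrix <- function(quant, meta, threshold = 0) {
  samples <- quant_samples(quant)
  unknown <- setdiff(samples, meta$extract_id)
  if (length(unknown) > 0) {
    abort(paste0("sample(s) without metadata: ", paste(unknown, collapse = ", ")))
  }
  blanks <- meta$extract_id[meta$is_blank]
  keep <- setdiff(samples, blanks)
  out <- tibble(feature_id = quant$feature_id)
  for (s in keep) out[[s]] <- quant[[s]] > threshold
  attr(out, "threshold") <- threshold
  class(out) <- c("presence_tbl", class(out))
  out
}

presence_samples <- function(pm) setdiff(names(pm), "feature_id")

presence_as_matrix <- function(pm) {
  s <- presence_samples(pm)
  m <- as.matrix(as.data.frame(pm[s]))
  rownames(m) <- pm$feature_id
  colnames(m) <- s
  m
}

#' Venn partition of features over sample groups
#'
#' Assigns every feature detected in at least one retained sample to exactly
#' one Venn region: the set of groups (e.g. phyla) in which it is present in
#' at least one member sample. Features absent everywhere are excluded, so
#' region counts are disjoint and sum to the number of detected features.
#'
#' @param pm Presence tibble from [presence_matrix()].
#' @param meta Metadata tibble with `extract_id` and the grouping column.
#' @param group Name of the metadata column to group by (default `"phylum"`).
#' @return A tibble with one row per non-empty group subset: `region`
#'   (group names joined by `&`, sorted), `groups` (list-column of group
#'   names), `n_groups`, and `count`. All subsets are enumerated, including
#'   those with zero features.
#' @export
venn_partition <- function(pm, meta, group = "phylum") {
  samples <- presence_samples(pm)
  if (!group %in% names(meta)) abort(paste0("no metadata column '", group, "'"))
  labels <- setNames(as.character(meta[[group]]), meta$extract_id)[samples]
  if (length(labels) == 0 || all(is.na(labels))) abort("empty grouping")
  if (anyNA(labels)) abort("every retained sample needs a group label")
  groups <- sort(unique(labels))
  if (length(groups) > 12) abort("more than 12 groups: Venn partition not enumerable")

  m <- presence_as_matrix(pm)
  # per-feature set of groups with >= 1 presence, encoded as a bitmask
  group_hit <- vapply(groups, function(g) {
    rowSums(m[, labels == g, drop = FALSE]) > 0
  }, logical(nrow(m)))
  group_hit <- matrix(group_hit, nrow = nrow(m))
  mask <- as.integer(group_hit %*% 2^(seq_along(groups) - 1))

  all_masks <- seq_len(2^length(groups) - 1)
  counts <- tabulate(mask[mask > 0], nbins = max(all_masks))
  subset_of <- function(b) groups[bitwAnd(b, 2^(seq_along(groups) - 1)) > 0]
  tibble(
    region = map_chr(all_masks, function(b) paste(subset_of(b), collapse = "&")),
    groups = map(all_masks, subset_of),
    n_groups = map_int(all_masks, function(b) length(subset_of(b))),
    count = counts[all_masks]
  ) |>
    arrange(.data$n_groups, .data$region)
}

#' Per-group counts of group-specific features
#'
#' Extracts the singleton regions of a Venn partition: features detected in
#' exactly one group. Their sum is the "specific to any one group" total.
#'
#' @param vp Venn partition tibble from [venn_partition()].
#' @return A tibble with `group` and `count`.
#' @export
group_specific_counts <- function(vp) {
  vp |>
    filter(.data$n_groups == 1L) |>
    mutate(group = map_chr(.data$groups, 1)) |>
    select("group", "count")
}

#' Strain-specific feature counts
#'
#' Counts, per sample, the features whose presence set is exactly that one
#' sample — i.e. detected in this extract and in no other.
#'
#' @param pm Presence tibble from [presence_matrix()].
#' @return A tibble with `sample_id` and `n_specific`.
#' @export
strain_specific_counts <- function(pm) {
  m <- presence_as_matrix(pm)
  tot <- rowSums(m)
  solo <- m[tot == 1L, , drop = FALSE]
  tibble(sample_id = colnames(m), n_specific = as.integer(colSums(solo)))
}

#' Correlation between group uniqueness and group size
#'
#' Pearson product-moment correlation between the number of group-specific
#' features and the number of isolates per group, the summary used to ask
#' whether more sampled strains yield proportionally more unique chemistry.
#'
#' @param specific_counts Named numeric vector of group-specific feature
#'   counts, or a tibble from [group_specific_counts()].
#' @param isolate_counts Named numeric vector of isolates per group (same
#'   names).
#' @return The correlation coefficient (double). Summaries print it rounded
#'   to 2 decimals.
#' @export
uniqueness_isolate_correlation <- function(specific_counts, isolate_counts) {
  if (is.data.frame(specific_counts)) {
    specific_counts <- setNames(specific_counts$count, specific_counts$group)
  }
  if (!setequal(names(specific_counts), names(isolate_counts))) {
    abort("specific_counts and isolate_counts must cover the same groups")
  }
  if (length(specific_counts) < 3) abort("need at least 3 groups for a correlation")
  x <- as.numeric(specific_counts)
  y <- as.numeric(isolate_counts[names(specific_counts)])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("undefined correlation: zero variance in counts")
  }
  cor(x, y)
}

#' Count features below a precursor mass cutoff
#'
#' Counts, within a given feature set, the features whose tabulated precursor
#' m/z is strictly below `max_mz`. For the singly charged ions dominating
#' positive-mode data the feature m/z is used directly as the mass.
#'
#' @param quant Quantification tibble.
#' @param feature_ids Integer vector of feature ids (must exist in `quant`).
#' @param max_mz Cutoff in Da (strict `<`).
#' @return Integer count.
#' @export
mass_filter_count <- function(quant, feature_ids, max_mz) {
  unknown <- setdiff(feature_ids, quant$feature_id)
  if (length(unknown) > 0) {
    abort(paste0("unknown feature id(s): ", paste(head(unknown, 5), collapse = ", ")))
  }
  mz <- quant$mz[match(feature_ids, quant$feature_id)]
  sum(mz < max_mz)
}
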