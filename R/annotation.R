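#' Dereplication (annotation) parameters
#'
#' Thresholds for the three-level annotation cascade. Library hits (levels 1
#' and 2) require a cosine score of at least `lib_min_score` with at least
#' `lib_min_peaks` matched peaks; level 1 additionally requires precursor
#' m/z and retention-time agreement with an in-house standard. In-silico
#' candidates (level 3) are accepted when the structure score is below
#' `csi_max_score` and the best molecular-formula confidence exceeds
#' `zodiac_min` (strictly).
#'
#' @param lib_min_score Minimum library-match cosine score.
#' @param lib_min_peaks Minimum matched peaks for a library hit.
#' @param csi_max_score Acceptance cutoff for the in-silico structure score
#'   (accept when `csi_score < csi_max_score`).
#' @param zodiac_min Formula-confidence cutoff in \[0, 1\] (accept when
#'   `zodiac_score > zodiac_min`).
#' @param rt_tol Retention-time tolerance for level-1 matches (minutes).
#' @param precursor_tol Precursor m/z tolerance (Da).
#' @return A list of class `annotation_params`.
#' @export
annotation_params <- function(lib_min_score = 0.6, lib_min_peaks = 3,
                              csi_max_score = -150, zodiac_min = 0.6,
                              rt_tol = 0.2, precursor_tol = 0.02) {
  stopifnot(lib_min_score >= 0, lib_min_score <= 1, lib_min_peaks >= 1,
            zodiac_min > 0, zodiac_min <= 1, rt_tol > 0, precursor_tol > 0)
  structure(list(lib_min_score = lib_min_score, lib_min_peaks = lib_min_peaks,
                 csi_max_score = csi_max_score, zodiac_min = zodiac_min,
                 rt_tol = rt_tol, precursor_tol = precursor_tol),
            class = "annotation_params")
}

#' Level-1 annotation against in-house reference standards
#'
#' The strictest identification: a hit requires agreement of precursor m/z
#' (within `precursor_tol`), retention time (within `rt_tol`) and MS/MS
#' spectrum (library-match thresholds) with a pure standard measured under
#' identical conditions. The best hit per feature (highest score) wins.
#'
#' @param quant Quantification tibble supplying feature m/z and RT.
#' @param spectra Spectra tibble for the features.
#' @param inhouse In-house library: spectra tibble with `library_id`,
#'   `name`, `precursor_mz`, `rt`, `peaks`, and optionally `class_label`.
#' @param params [annotation_params()].
#' @return Annotation tibble (`feature_id`, `level = "1"`, `name`,
#'   `source = "inhouse"`, `class_label`, `score`, `n_matched`) with one row
#'   per matched feature.
#' @export
level1_match <- function(quant, spectra, inhouse, params = annotation_params()) {
  if (is.null(inhouse) || nrow(inhouse) == 0) return(empty_annotations())
  sim <- similarity_params(precursor_tol = params$precursor_tol)
  hits <- library_match(spectra, inhouse, sim,
                        min_score = params$lib_min_score,
                        min_peaks = params$lib_min_peaks)
  if (nrow(hits) == 0) return(empty_annotations())
  feat_rt <- setNames(quant$rt, quant$feature_id)
  lib_rt <- setNames(inhouse$rt, inhouse$library_id)
  hits <- hits |>
    filter(abs(feat_rt[as.character(.data$feature_id)] -
               lib_rt[.data$library_id]) <= params$rt_tol)
  best_hits(hits, level = "1", source = "inhouse")
}

#' Level-2 annotation against an external spectral library
#'
#' Putative identification by precursor mass and MS/MS agreement with
#' externally acquired library spectra (no retention-time information).
#'
#' @param spectra Spectra tibble for the features.
#' @param external External library: spectra tibble with `library_id`,
#'   `name`, `precursor_mz`, `peaks`, optionally `class_label`.
#' @param params [annotation_params()].
#' @return Annotation tibble with `level = "2"`, `source =
#'   "spectral_library"`.
#' @export
level2_match <- function(spectra, external, params = annotation_params()) {
  if (is.null(external) || nrow(external) == 0) return(empty_annotations())
  sim <- similarity_params(precursor_tol = params$precursor_tol)
  hits <- library_match(spectra, external, sim,
                        min_score = params$lib_min_score,
                        min_peaks = params$lib_min_peaks)
  if (nrow(hits) == 0) return(empty_annotations())
  best_hits(hits, level = "2", source = "spectral_library")
}

best_hits <- function(hits, level, source) {
  hits |>
    group_by(.data$feature_id) |>
    arrange(desc(.data$score), .data$library_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    mutate(level = level, source = source) |>
    select("feature_id", "level", "name", "source", "class_label",
           "score", "n_matched")
}

empty_annotations <- function() {
  tibble(feature_id = integer(), level = character(), name = character(),
         source = character(), class_label = character(),
         score = double(), n_matched = integer())
}

#' Level-3 annotation from in-silico structure candidates
#'
#' Filters an in-silico candidate table (structure score plus formula
#' confidence per feature). Per feature the best candidate — highest
#' formula confidence, then lowest structure score — is accepted only when
#' `csi_score < csi_max_score` and `zodiac_score > zodiac_min` (strict).
#'
#' @param candidates Tibble with `feature_id`, `formula`, `structure`,
#'   `csi_score`, `zodiac_score`, `class_label`.
#' @param params [annotation_params()].
#' @return Annotation tibble with `level = "3"`, `source = "insilico"`.
#' @export
level3_filter <- function(candidates, params = annotation_params()) {
  if (nrow(candidates) == 0) return(empty_annotations())
  num_ok <- is.numeric(candidates$csi_score) && is.numeric(candidates$zodiac_score)
  if (!num_ok || anyNA(candidates$csi_score) || anyNA(candidates$zodiac_score)) {
    abort("malformed in-silico candidate scores")
  }
  candidates |>
    group_by(.data$feature_id) |>
    arrange(desc(.data$zodiac_score), .data$csi_score, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    filter(.data$csi_score < params$csi_max_score,
           .data$zodiac_score > params$zodiac_min) |>
    mutate(level = "3", source = "insilico",
           name = dplyr::coalesce(as.character(.data$structure), .data$formula),
           score = .data$zodiac_score, n_matched = NA_integer_) |>
    select("feature_id", "level", "name", "source", "class_label",
           "score", "n_matched")
}

#' Three-level dereplication cascade
#'
#' Annotates features consecutively: in-house standards first (level 1),
#' then external spectral libraries (level 2), then filtered in-silico
#' candidates (level 3). A feature annotated at one level is never
#' re-annotated at a lower-confidence level; features missed by all three
#' are `"unknown"`. The result covers every feature of `quant` exactly once.
#'
#' @param quant Quantification tibble.
#' @param spectra Spectra tibble (features without a spectrum can still be
#'   annotated at level 3).
#' @param inhouse,external,insilico Optional annotation inputs (see
#'   [level1_match()], [level2_match()], [level3_filter()]); `NULL` skips a
#'   level.
#' @param params [annotation_params()].
#' @return Annotation tibble with one row per feature: `feature_id`,
#'   `level` (`"1"`, `"2"`, `"3"`, `"unknown"`), `name`, `source`,
#'   `class_label`, `score`, `n_matched`.
#' @seealso [annotation_summary()], [propagate_classes()]
#' @export
annotate_cascade <- function(quant, spectra, inhouse = NULL, external = NULL,
                             insilico = NULL, params = annotation_params()) {
  ann <- empty_annotations()
  remaining <- quant$feature_id
  take <- function(new) {
    new <- new[new$feature_id %in% remaining, , drop = FALSE]
    remaining <<- setdiff(remaining, new$feature_id)
    bind_rows(ann, new)
  }
  if (!is.null(inhouse) && nrow(inhouse) > 0 && nrow(spectra) > 0) {
    ann <- take(level1_match(quant, spectra, inhouse, params))
  }
  if (!is.null(external) && nrow(external) > 0 && nrow(spectra) > 0) {
    ann <- take(level2_match(spectra, external, params))
  }
  if (!is.null(insilico) && nrow(insilico) > 0) {
    ann <- take(level3_filter(insilico, params))
  }
  unknown <- tibble(feature_id = remaining, level = "unknown", name = "",
                    source = "none", class_label = "",
                    score = NA_real_, n_matched = NA_integer_)
  bind_rows(ann, unknown) |> arrange(.data$feature_id)
}

#' Annotation level counts and shares
#'
#' @param annotations Annotation tibble from [annotate_cascade()].
#' @return A tibble with `level`, `n` and `pct` (percent of all features);
#'   the four levels partition the feature set.
#' @export
annotation_summary <- function(annotations) {
  total <- nrow(annotations)
  tibble(level = c("1", "2", "3", "unknown")) |>
    left_join(count(annotations, .data$level), by = "level") |>
    mutate(n = dplyr::coalesce(.data$n, 0L),
           pct = if (total == 0) 0 else 100 * .data$n / total)
}

#' Propagate chemical classes to molecular families
#'
#' Assigns each molecular family the most frequent chemical class among its
#' annotated members (majority rule). Families with no annotated member, or
#' with a tie between classes, are `"unclassified"` rather than resolved
#' arbitrarily.
#'
#' @param network A `molecular_network`.
#' @param annotations Annotation tibble from [annotate_cascade()].
#' @return A tibble with `family` and `class_label`.
#' @export
propagate_classes <- function(network, annotations) {
  fams <- network_families(network)
  cls <- setNames(annotations$class_label, annotations$feature_id)
  fams |>
    mutate(class_label = map_chr(.data$members, function(ids) {
      v <- cls[as.character(ids)]
      v <- v[!is.na(v) & nzchar(v)]
      if (length(v) == 0) return("unclassified")
      tab <- sort(table(v), decreasing = TRUE)
      if (length(tab) > 1 && tab[2] == tab[1]) return("unclassified")
      names(tab)[1]
    })) |>
    select("family", "class_label")
}
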