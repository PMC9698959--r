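#' Load the packaged 60-isolate study metadata
#'
#' Returns the cohort metadata for the 60 difficult-to-grow marine and soil
#' bacterial isolates distributed with the package: extract ID, strain ID,
#' phylum (Proteobacteria, Bacteroidetes, Actinobacteria or Firmicutes),
#' genus, 16S rRNA percent identity to the closest described relative, and a
#' flag marking potential new species (< 98.7% identity) or genera (< 95%).
#'
#' @return A tibble with one row per extract: `extract_id`, `strain_id`,
#'   `accession`, `source`, `origin`, `cultivation_strategy`,
#'   `isolation_medium`, `phylum`, `genus`, `closest_relative`,
#'   `similarity_pct`, `taxon_flag` (`""`, `"species"` or `"genus"`),
#'   `is_blank`.
#' @seealso [read_sample_metadata()], [build_strain_reports()]
#' @export
load_study_metadata <- function() {
  path <- system.file("extdata", "study_isolates.tsv", package = "metabotalent",
                      mustWork = TRUE)
  read_sample_metadata(path)
}

#' Read a sample metadata table
#'
#' A TSV mapping extract IDs to strain, phylum, genus and 16S similarity.
#' Required columns: `extract_id`, `strain_id`, `phylum`, `genus`,
#' `similarity_pct`; optional `is_blank` (defaults to `FALSE`) marks blank/QC
#' injections, which every occurrence analytic excludes.
#'
#' @param path Path to the TSV file.
#' @return A metadata tibble (see [load_study_metadata()]).
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) abort(paste0("metadata table not found: ", path))
  meta <- readr::read_tsv(path, col_types = readr::cols(
    extract_id = readr::col_character(),
    strain_id = readr::col_character(),
    phylum = readr::col_character(),
    genus = readr::col_character(),
    similarity_pct = readr::col_double(),
    .default = readr::col_character()
  ), progress = FALSE)
  need <- c("extract_id", "strain_id", "phylum", "genus", "similarity_pct")
  missing <- setdiff(need, names(meta))
  if (length(missing) > 0) {
    abort(paste0("metadata table missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(meta$extract_id)) abort("duplicate extract_id in metadata")
  if (!"is_blank" %in% names(meta)) meta$is_blank <- FALSE
  meta$is_blank <- as.logical(meta$is_blank)
  bad <- !meta$is_blank & (is.na(meta$similarity_pct) |
                           meta$similarity_pct <= 0 | meta$similarity_pct > 100)
  if (any(bad)) abort("similarity_pct must lie in (0, 100] for non-blank samples")
  as_tibble(meta)
}
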