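#' Read an MZmine-style feature quantification table
#'
#' Parses the CSV dialect produced by MZmine's "Export to CSV" step: one row
#' per feature with `row ID`, `row m/z`, `row retention time` columns and one
#' `<sample> Peak area` column per sample. m/z values are in Da and retention
#' times in minutes throughout the package. Empty or missing area cells are
#' read as 0 (the gap-filled-export convention; downstream absence semantics
#' rely on it). Extra non-area columns (e.g. `row number of detected peaks`)
#' are tolerated and dropped.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `feature_id` (integer), `mz`, `rt`, and one
#'   numeric peak-area column per sample (the sample's extract ID).
#' @seealso [write_quant_table()], [read_mgf()], [presence_matrix()]
#' @export
read_quant_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("quantification table not found: ", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, name_repair = "minimal")
  nms <- names(raw)
  id_col <- which(nms == "row ID")
  mz_col <- which(nms == "row m/z")
  rt_col <- which(nms == "row retention time")
  for (need in c("row ID", "row m/z", "row retention time")) {
    if (!need %in% nms) {
      abort(paste0("malformed quantification table header: missing column '", need, "'"))
    }
  }
  area_cols <- grep(" Peak area$", nms)
  if (length(area_cols) == 0) {
    abort("malformed quantification table header: no '<sample> Peak area' column")
  }
  sample_ids <- sub(" Peak area$", "", nms[area_cols])
  sample_ids <- sub("\\.(mzX?ML|mzml|cdf)$", "", sample_ids)
  if (anyDuplicated(sample_ids)) {
    abort("duplicate sample columns in quantification table")
  }

  feature_id <- as.integer(raw[[id_col]])
  if (anyDuplicated(feature_id)) {
    abort("duplicate feature ids in quantification table")
  }
  areas <- lapply(raw[area_cols], function(x) {
    x <- suppressWarnings(as.numeric(x))
    x[is.na(x)] <- 0
    x
  })
  names(areas) <- sample_ids
  out <- tibble(
    feature_id = feature_id,
    mz = as.numeric(raw[[mz_col]]),
    rt = as.numeric(raw[[rt_col]])
  )
  bind_cols(out, as_tibble(areas))
}

#' Write a feature quantification table in the MZmine CSV dialect
#'
#' Inverse of [read_quant_table()]; round-trips feature ids, m/z, retention
#' times and peak areas.
#'
#' @param quant Quantification tibble (`feature_id`, `mz`, `rt`, sample columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(quant, path) {
  samples <- quant_samples(quant)
  out <- tibble(
    `row ID` = quant$feature_id,
    `row m/z` = quant$mz,
    `row retention time` = quant$rt
  )
  for (s in samples) out[[paste0(s, " Peak area")]] <- quant[[s]]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Sample (extract) columns of a quantification tibble
#'
#' @param quant Quantification tibble as returned by [read_quant_table()].
#' @return Character vector of sample IDs.
#' @export
quant_samples <- function(quant) {
  setdiff(names(quant), c("feature_id", "mz", "rt"))
}
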