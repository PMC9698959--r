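#' Read MS/MS spectra from a Mascot generic format (MGF) file
#'
#' Each `BEGIN IONS`/`END IONS` block becomes one spectrum. The feature key is
#' taken from the `FEATURE_ID` field, falling back to `SCANS` (both dialects
#' occur in MZmine/GNPS exports); the precursor m/z from the first token of
#' `PEPMASS`. Peak lines are `m/z intensity` pairs; peaks are returned sorted
#' by m/z ascending. Blocks without a precursor are skipped with a warning;
#' duplicate feature keys are an error.
#'
#' @param path Path to the MGF file.
#' @return A spectra tibble with columns `feature_id` (integer),
#'   `precursor_mz` (Da), `rt` (minutes; `NA` when the block carries no
#'   `RTINSECONDS`), `n_peaks`, and a list-column `peaks` of data frames with
#'   columns `mz` and `intensity`.
#' @seealso [write_mgf()], [modified_cosine()], [build_network()]
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) abort(paste0("MGF file not found: ", path))
  lines <- readr::read_lines(path, progress = FALSE)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends)) abort("malformed MGF: unbalanced BEGIN IONS/END IONS")
  recs <- map2(starts, ends, function(s, e) parse_mgf_block(lines[(s + 1):(e - 1)]))
  recs <- recs[!map_lgl(recs, is.null)]
  if (length(recs) == 0) {
    return(tibble(feature_id = integer(), precursor_mz = double(), rt = double(),
                  n_peaks = integer(), peaks = list()))
  }
  out <- tibble(
    feature_id = map_int(recs, "feature_id"),
    precursor_mz = map_dbl(recs, "precursor_mz"),
    rt = map_dbl(recs, "rt"),
    n_peaks = map_int(recs, function(r) nrow(r$peaks)),
    peaks = map(recs, "peaks")
  )
  if (anyDuplicated(out$feature_id)) abort("duplicate feature ids in MGF")
  out
}

parse_mgf_block <- function(block) {
  block <- block[nzchar(trimws(block))]
  is_field <- grepl("=", block, fixed = TRUE)
  fields <- block[is_field]
  keys <- toupper(sub("=.*$", "", fields))
  vals <- sub("^[^=]*=", "", fields)
  getf <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_

  pep <- getf("PEPMASS")
  if (is.na(pep)) {
    warn("MGF block without PEPMASS skipped")
    return(NULL)
  }
  key <- getf("FEATURE_ID")
  if (is.na(key)) key <- getf("SCANS")
  if (is.na(key)) {
    warn("MGF block without FEATURE_ID or SCANS skipped")
    return(NULL)
  }
  rt_s <- getf("RTINSECONDS")
  peak_lines <- block[!is_field]
  mat <- do.call(rbind, lapply(strsplit(trimws(peak_lines), "[ \t]+"), function(x) {
    as.numeric(x[1:2])
  }))
  if (is.null(mat) || nrow(mat) == 0) {
    warn("MGF block without peaks skipped")
    return(NULL)
  }
  ord <- order(mat[, 1])
  list(
    feature_id = as.integer(key),
    precursor_mz = as.numeric(strsplit(pep, "[ \t]+")[[1]][1]),
    rt = if (is.na(rt_s)) NA_real_ else as.numeric(rt_s) / 60,
    peaks = data.frame(mz = mat[ord, 1], intensity = mat[ord, 2])
  )
}

#' Write spectra to a Mascot generic format (MGF) file
#'
#' Writes one `BEGIN IONS` block per spectrum with `FEATURE_ID`, `PEPMASS`,
#' `SCANS` (mirroring the feature id) and, when available, `RTINSECONDS`
#' fields. Inverse of [read_mgf()] up to printed precision.
#'
#' @param spectra Spectra tibble (see [read_mgf()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  blocks <- pmap(list(spectra$feature_id, spectra$precursor_mz,
                      spectra$rt %||% rep(NA_real_, nrow(spectra)), spectra$peaks),
                 function(id, pmz, rt, pk) {
    hdr <- c("BEGIN IONS",
             paste0("FEATURE_ID=", id),
             paste0("PEPMASS=", sprintf("%.5f", pmz)),
             paste0("SCANS=", id))
    if (!is.na(rt)) hdr <- c(hdr, paste0("RTINSECONDS=", sprintf("%.3f", rt * 60)))
    c(hdr, sprintf("%.5f %.8g", pk$mz, pk$intensity), "END IONS", "")
  })
  readr::write_lines(unlist(blocks), path)
  invisible(path)
}
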