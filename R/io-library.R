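#' Read an annotated spectral library from MGF
#'
#' Library blocks carry `LIBRARY_ID` (or `FEATURE_ID`/`SCANS`), `NAME`,
#' optionally `CLASS` and `RTINSECONDS`, a `PEPMASS` precursor and a peak
#' list. Suitable for both in-house standard libraries (with retention
#' times) and external spectral libraries (without).
#'
#' @param path Path to the MGF file.
#' @return A library tibble: `library_id`, `name`, `class_label`,
#'   `precursor_mz`, `rt` (minutes or `NA`), `n_peaks`, `peaks`.
#' @seealso [write_library_mgf()], [library_match()]
#' @export
read_library_mgf <- function(path) {
  if (!file.exists(path)) abort(paste0("library MGF not found: ", path))
  lines <- readr::read_lines(path, progress = FALSE)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends)) abort("malformed MGF: unbalanced BEGIN IONS/END IONS")
  recs <- map2(starts, ends, function(s, e) {
    block <- lines[(s + 1):(e - 1)]
    block <- block[nzchar(trimws(block))]
    is_field <- grepl("=", block, fixed = TRUE)
    keys <- toupper(sub("=.*$", "", block[is_field]))
    vals <- sub("^[^=]*=", "", block[is_field])
    getf <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    pep <- getf("PEPMASS")
    id <- getf("LIBRARY_ID")
    if (is.na(id)) id <- getf("FEATURE_ID")
    if (is.na(id)) id <- getf("SCANS")
    if (is.na(pep) || is.na(id)) {
      warn("library MGF block without id or PEPMASS skipped")
      return(NULL)
    }
    mat <- do.call(rbind, lapply(strsplit(trimws(block[!is_field]), "[ \t]+"),
                                 function(x) as.numeric(x[1:2])))
    if (is.null(mat) || nrow(mat) == 0) return(NULL)
    ord <- order(mat[, 1])
    rt_s <- getf("RTINSECONDS")
    list(library_id = id,
         name = getf("NAME") %|NA|% id,
         class_label = getf("CLASS") %|NA|% "",
         precursor_mz = as.numeric(strsplit(pep, "[ \t]+")[[1]][1]),
         rt = if (is.na(rt_s)) NA_real_ else as.numeric(rt_s) / 60,
         peaks = data.frame(mz = mat[ord, 1], intensity = mat[ord, 2]))
  })
  recs <- recs[!map_lgl(recs, is.null)]
  tibble(
    library_id = map_chr(recs, "library_id"),
    name = map_chr(recs, "name"),
    class_label = map_chr(recs, "class_label"),
    precursor_mz = map_dbl(recs, "precursor_mz"),
    rt = map_dbl(recs, "rt"),
    n_peaks = map_int(recs, function(r) nrow(r$peaks)),
    peaks = map(recs, "peaks")
  )
}

`%|NA|%` <- function(x, y) if (is.na(x)) y else x

#' Write an annotated spectral library to MGF
#'
#' @param library Library tibble (see [read_library_mgf()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_library_mgf <- function(library, path) {
  blocks <- pmap(list(library$library_id, library$name, library$class_label,
                      library$precursor_mz,
                      library$rt %||% rep(NA_real_, nrow(library)), library$peaks),
                 function(id, name, cls, pmz, rt, pk) {
    hdr <- c("BEGIN IONS",
             paste0("LIBRARY_ID=", id),
             paste0("NAME=", name),
             paste0("CLASS=", cls),
             paste0("PEPMASS=", sprintf("%.5f", pmz)))
    if (!is.na(rt)) hdr <- c(hdr, paste0("RTINSECONDS=", sprintf("%.3f", rt * 60)))
    c(hdr, sprintf("%.5f %.8g", pk$mz, pk$intensity), "END IONS", "")
  })
  readr::write_lines(unlist(blocks), path)
  invisible(path)
}

#' Read an in-silico candidate table
#'
#' TSV with columns `feature_id`, `formula`, `structure`, `csi_score`,
#' `zodiac_score`, `class_label` (one row per candidate; multiple
#' candidates per feature allowed). Non-numeric score fields are an error.
#'
#' @param path Path to the TSV file.
#' @return The candidate tibble.
#' @export
read_insilico_table <- function(path) {
  if (!file.exists(path)) abort(paste0("in-silico candidate table not found: ", path))
  x <- readr::read_tsv(path, col_types = readr::cols(
    feature_id = readr::col_integer(),
    csi_score = readr::col_double(),
    zodiac_score = readr::col_double(),
    .default = readr::col_character()
  ), progress = FALSE)
  need <- c("feature_id", "csi_score", "zodiac_score")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(paste0("candidate table missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyNA(x$csi_score) || anyNA(x$zodiac_score)) {
    abort("malformed in-silico candidate scores")
  }
  if (!"formula" %in% names(x)) x$formula <- NA_character_
  if (!"structure" %in% names(x)) x$structure <- NA_character_
  if (!"class_label" %in% names(x)) x$class_label <- ""
  as_tibble(x)
}
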