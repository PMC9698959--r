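#' Spectral similarity parameters
#'
#' Tolerances and weighting used by the modified cosine and library matching.
#' Defaults follow common feature-based molecular networking practice:
#' fragment and precursor tolerances of 0.02 Da, removal of fragments within
#' +/- 17 Da of the precursor, and square-root intensity weighting.
#'
#' @param fragment_tol Fragment m/z match tolerance (Da).
#' @param precursor_tol Precursor m/z tolerance for library matching (Da).
#' @param precursor_window Half-width (Da) of the precursor exclusion window
#'   applied by [filter_precursor_window()].
#' @param intensity_power Exponent applied to raw intensities before
#'   L2 normalization (0.5 = square-root weighting).
#' @return A list of class `similarity_params`.
#' @export
similarity_params <- function(fragment_tol = 0.02, precursor_tol = 0.02,
                              precursor_window = 17, intensity_power = 0.5) {
  stopifnot(fragment_tol > 0, precursor_tol > 0, precursor_window >= 0,
            intensity_power >= 0)
  structure(list(fragment_tol = fragment_tol, precursor_tol = precursor_tol,
                 precursor_window = precursor_window,
                 intensity_power = intensity_power),
            class = "similarity_params")
}

#' Remove fragment ions near the precursor
#'
#' Drops every peak whose m/z lies within `window` Da of the spectrum's
#' precursor (inclusive). Residual precursor signal and its isotopes
#' otherwise dominate cosine scores between unrelated spectra. Spectra left
#' with zero peaks are flagged (`n_peaks == 0`) and excluded from networking.
#'
#' @param spectra Spectra tibble (see [read_mgf()]).
#' @param window Half-width of the exclusion window in Da.
#' @return The spectra tibble with filtered `peaks` and updated `n_peaks`.
#' @export
filter_precursor_window <- function(spectra, window = 17) {
  stopifnot(window >= 0)
  spectra$peaks <- map2(spectra$peaks, spectra$precursor_mz, function(pk, pmz) {
    pk[abs(pk$mz - pmz) > window, , drop = FALSE]
  })
  spectra$n_peaks <- map_int(spectra$peaks, nrow)
  spectra
}

#' Intensity-weighted, unit-norm peak vector
#'
#' Raises intensities to `intensity_power` and scales the resulting weights
#' to unit Euclidean norm, so that the cosine of two identical spectra is 1.
#'
#' @param peaks Data frame with `mz` and `intensity` (at least one peak).
#' @param intensity_power Exponent for intensity weighting.
#' @return Data frame with `mz` and unit-norm `weight`.
#' @export
normalize_peaks <- function(peaks, intensity_power = 0.5) {
  if (nrow(peaks) == 0) abort("cannot normalize an empty spectrum")
  w <- peaks$intensity^intensity_power
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) abort("cannot normalize a spectrum with all-zero intensities")
  data.frame(mz = peaks$mz, weight = w / nrm)
}

# Greedy one-to-one assignment over candidate peak pairs.
# Candidates match directly (|mza - mzb| <= tol) or shifted by the signed
# precursor difference (|mza - mzb - dprec| <= tol); each peak is consumed
# once. Ties in the weight product break on smaller mz_a, then mz_b.
cosine_core <- function(mza, wa, mzb, wb, dprec, tol) {
  diffs <- outer(mza, mzb, "-")
  cand <- abs(diffs) <= tol | abs(diffs - dprec) <= tol
  idx <- which(cand, arr.ind = TRUE, useNames = FALSE)
  if (nrow(idx) == 0) return(list(score = 0, n_matched = 0L))
  prod <- wa[idx[, 1]] * wb[idx[, 2]]
  ord <- order(-prod, mza[idx[, 1]], mzb[idx[, 2]])
  used_a <- logical(length(mza))
  used_b <- logical(length(mzb))
  score <- 0
  n <- 0L
  for (k in ord) {
    i <- idx[k, 1]
    j <- idx[k, 2]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE
      used_b[j] <- TRUE
      score <- score + prod[k]
      n <- n + 1L
    }
  }
  list(score = score, n_matched = n)
}

spectrum_parts <- function(s) {
  if (is.data.frame(s) && "peaks" %in% names(s)) {
    if (nrow(s) != 1) abort("expected a single spectrum (one-row tibble)")
    list(precursor_mz = s$precursor_mz[[1]], peaks = s$peaks[[1]])
  } else if (is.list(s) && all(c("precursor_mz", "peaks") %in% names(s))) {
    s
  } else {
    abort("a spectrum is a one-row spectra tibble or a list(precursor_mz, peaks)")
  }
}

#' Modified cosine similarity between two MS/MS spectra
#'
#' Computes the modified cosine score: fragment peaks may match either
#' directly (within `fragment_tol`) or offset by the signed precursor mass
#' difference, which links spectra of structurally related compounds that
#' differ by a single modification. Peaks are intensity-weighted
#' (`intensity_power`, then L2-normalized) and a one-to-one peak assignment
#' is chosen greedily by descending weight product with a deterministic
#' tie-break; the score is the sum of matched weight products and lies in
#' \[0, 1\].
#'
#' @param a,b Spectra: one-row spectra tibbles or lists with `precursor_mz`
#'   and `peaks`. Both must be non-empty.
#' @param params [similarity_params()].
#' @return A one-row tibble with `score` and `n_matched` (matched peak
#'   pairs).
#' @export
modified_cosine <- function(a, b, params = similarity_params()) {
  a <- spectrum_parts(a)
  b <- spectrum_parts(b)
  if (nrow(a$peaks) == 0 || nrow(b$peaks) == 0) {
    abort("modified_cosine requires non-empty spectra")
  }
  na <- normalize_peaks(a$peaks, params$intensity_power)
  nb <- normalize_peaks(b$peaks, params$intensity_power)
  res <- cosine_core(na$mz, na$weight, nb$mz, nb$weight,
                     a$precursor_mz - b$precursor_mz, params$fragment_tol)
  tibble(score = res$score, n_matched = res$n_matched)
}

#' Match query spectra against an annotated spectral library
#'
#' Candidate library entries are restricted to those whose precursor m/z
#' lies within `precursor_tol` of the query; the modified cosine is computed
#' against each candidate, and hits are kept when `score >= min_score` and
#' `n_matched >= min_peaks`, sorted by descending score per query. An empty
#' hit table is a valid result.
#'
#' @param query Spectra tibble of query spectra.
#' @param library Spectra tibble of library entries, with a `library_id`
#'   column and optionally `name` and `class_label`.
#' @param params [similarity_params()].
#' @param min_score Minimum cosine score for a hit.
#' @param min_peaks Minimum number of matched peaks for a hit.
#' @return A tibble of hits: `feature_id`, `library_id`, `name`,
#'   `class_label`, `score`, `n_matched`.
#' @export
library_match <- function(query, library, params = similarity_params(),
                          min_score = 0.6, min_peaks = 3) {
  if (nrow(library) == 0) abort("library is empty")
  if (!"library_id" %in% names(library)) {
    library$library_id <- paste0("LIB", seq_len(nrow(library)))
  }
  if (!"name" %in% names(library)) library$name <- library$library_id
  if (!"class_label" %in% names(library)) library$class_label <- ""

  lib_norm <- map(library$peaks, normalize_peaks, intensity_power = params$intensity_power)
  hits <- map(seq_len(nrow(query)), function(qi) {
    qpk <- query$peaks[[qi]]
    if (nrow(qpk) == 0) return(NULL)
    qn <- normalize_peaks(qpk, params$intensity_power)
    cand <- which(abs(library$precursor_mz - query$precursor_mz[qi]) <= params$precursor_tol)
    if (length(cand) == 0) return(NULL)
    rows <- map(cand, function(li) {
      r <- cosine_core(qn$mz, qn$weight, lib_norm[[li]]$mz, lib_norm[[li]]$weight,
                       query$precursor_mz[qi] - library$precursor_mz[li],
                       params$fragment_tol)
      tibble(feature_id = query$feature_id[qi],
             library_id = library$library_id[li],
             name = library$name[li],
             class_label = library$class_label[li],
             score = r$score, n_matched = r$n_matched)
    })
    bind_rows(rows)
  })
  out <- bind_rows(hits)
  if (nrow(out) == 0) {
    return(tibble(feature_id = integer(), library_id = character(),
                  name = character(), class_label = character(),
                  score = double(), n_matched = integer()))
  }
  out |>
    filter(.data$score >= min_score, .data$n_matched >= min_peaks) |>
    arrange(.data$feature_id, desc(.data$score), .data$library_id)
}
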