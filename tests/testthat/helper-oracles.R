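# Independent oracles and small fixture builders used across the suite.

# Brute-force Venn partition: per feature, the set of groups with >= 1
# presence, counted by subset label. Independent of venn_partition().
brute_venn <- function(m, labels) {
  groups <- sort(unique(labels))
  regions <- apply(m, 1, function(row) {
    g <- sort(unique(labels[row]))
    if (length(g) == 0) NA_character_ else paste(g, collapse = "&")
  })
  table(factor(regions, levels = all_subsets(groups)))
}

all_subsets <- function(groups) {
  k <- length(groups)
  masks <- seq_len(2^k - 1)
  vapply(masks, function(b) {
    paste(groups[bitwAnd(b, 2^(seq_len(k) - 1)) > 0], collapse = "&")
  }, character(1))
}

# Brute-force strain-specific counts by per-row scan.
brute_strain_specific <- function(m) {
  vapply(seq_len(ncol(m)), function(j) {
    sum(vapply(seq_len(nrow(m)), function(i) m[i, j] && sum(m[i, ]) == 1L, logical(1)))
  }, integer(1))
}

# Exhaustive maximum-weight one-to-one matching over candidate peak pairs;
# the reference for the greedy modified cosine. Recurses over candidate
# pairs (take/skip), so only suitable for small spectra.
oracle_modified_cosine <- function(a, b, params = similarity_params()) {
  na <- normalize_peaks(a$peaks, params$intensity_power)
  nb <- normalize_peaks(b$peaks, params$intensity_power)
  d <- a$precursor_mz - b$precursor_mz
  diffs <- outer(na$mz, nb$mz, "-")
  cand <- which(abs(diffs) <= params$fragment_tol |
                  abs(diffs - d) <= params$fragment_tol, arr.ind = TRUE)
  best <- 0
  rec <- function(k, used_a, used_b, acc) {
    if (acc > best) best <<- acc
    if (k > nrow(cand)) return()
    rec(k + 1, used_a, used_b, acc)
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!(i %in% used_a) && !(j %in% used_b)) {
      rec(k + 1, c(used_a, i), c(used_b, j), acc + na$weight[i] * nb$weight[j])
    }
  }
  if (nrow(cand) > 0) rec(1, integer(), integer(), 0)
  best
}

# A spectrum literal.
spec_of <- function(precursor_mz, mz, intensity = rep(100, length(mz)), rt = NA_real_) {
  ord <- order(mz)
  list(precursor_mz = precursor_mz, rt = rt,
       peaks = data.frame(mz = mz[ord], intensity = intensity[ord]))
}

# One-row spectra tibble from spectrum literals.
spectra_tbl <- function(...) {
  specs <- list(...)
  tibble::tibble(
    feature_id = seq_along(specs),
    precursor_mz = vapply(specs, `[[`, double(1), "precursor_mz"),
    rt = vapply(specs, function(s) s$rt %||% NA_real_, double(1)),
    n_peaks = vapply(specs, function(s) nrow(s$peaks), integer(1)),
    peaks = lapply(specs, `[[`, "peaks")
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Random 4-peak spectrum on a coarse m/z grid so that candidate pair
# structure (including shifted matches) actually occurs.
random_grid_spectrum <- function(precursor_range = c(300, 320)) {
  grid <- seq(100, 200, by = 5)
  mz <- sort(sample(grid, 4)) + stats::rnorm(4, 0, 0.004)
  spec_of(stats::runif(1, precursor_range[1], precursor_range[2]),
          mz, stats::runif(4, 10, 1000))
}

# Small presence tibble straight from a logical matrix.
presence_from_matrix <- function(m, sample_ids = paste0("S", seq_len(ncol(m)))) {
  out <- tibble::tibble(feature_id = seq_len(nrow(m)))
  for (j in seq_len(ncol(m))) out[[sample_ids[j]]] <- m[, j]
  attr(out, "threshold") <- 0
  class(out) <- c("presence_tbl", class(out))
  out
}

# Desk-scale synthetic config used where full cohort size is unnecessary.
small_config <- function(seed = 1, ...) {
  synthetic_config(
    phyla = c("Proteobacteria", "Bacteroidetes", "Firmicutes"),
    strains_per_phylum = c(3, 2, 1),
    n_core = 20, n_phylum_specific = c(6, 5, 4), n_strain_specific = 4,
    n_spectral_families = 8, family_size_range = c(2, 5),
    seed = seed, ...
  )
}

noiseless_config <- function(seed = 1, ...) {
  small_config(seed = seed, mz_jitter_sd = 0, intensity_noise_cv = 0,
               dropout_prob = 0,
               level_fractions = c(l1 = 0.1, l2 = 0.15, l3 = 0.15), ...)
}
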