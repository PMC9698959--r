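#' Configuration for the synthetic cohort generator
#'
#' Describes a cohort of bacterial extracts with planted statistical
#' structure: a four-phylum design mirroring a 60-strain collection
#' (35/17/8/1 strains per phylum by default), feature strata (core features
#' detectable in every phylum, phylum-specific features, strain-specific
#' features), spectral families built from shared fragment templates, and
#' planted annotation levels whose default shares (0.6% / 6.6% / 9.2%, rest
#' unknown) follow the dereplication depth typical of such collections.
#' Fragment templates keep a minimum inter-peak spacing of 3x the fragment
#' tolerance and all precursor m/z are kept at least 0.05 Da apart, so peak
#' matchings and library hits are unambiguous at the default tolerances.
#'
#' @param phyla Phylum names.
#' @param strains_per_phylum Integer vector (same length as `phyla`).
#' @param n_core Features present in at least one strain of every phylum.
#' @param n_phylum_specific Features present only within one phylum (vector
#'   per phylum).
#' @param n_strain_specific Features present in exactly one extract, per
#'   strain.
#' @param n_blanks Blank/QC samples appended to the metadata (never contain
#'   features).
#' @param n_spectral_families Number of planted spectral families.
#' @param family_size_range,peak_count_range Integer ranges (min, max).
#' @param mz_range,rt_range Precursor m/z (Da) and retention time (min)
#'   ranges.
#' @param mz_jitter_sd Gaussian fragment m/z jitter (Da); keep at or below
#'   the fragment tolerance.
#' @param intensity_noise_cv Coefficient of variation of multiplicative
#'   intensity noise.
#' @param dropout_prob Probability that a core or phylum-specific presence
#'   is dropped (never applied to strain-specific features, and never
#'   allowed to empty a phylum for core features or reduce a
#'   phylum-specific feature below two strains).
#' @param level_fractions Named fractions for planted annotation levels
#'   (`l1`, `l2`, `l3`); the remainder is unknown.
#' @param seed Integer seed; all draws flow from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    phyla = c("Proteobacteria", "Bacteroidetes", "Actinobacteria", "Firmicutes"),
    strains_per_phylum = c(35, 17, 8, 1),
    n_core = 60,
    n_phylum_specific = c(25, 15, 8, 3),
    n_strain_specific = 5,
    n_blanks = 0,
    n_spectral_families = 15,
    family_size_range = c(3, 8),
    peak_count_range = c(6, 12),
    mz_range = c(150, 1000),
    rt_range = c(0.5, 25),
    mz_jitter_sd = 0.005,
    intensity_noise_cv = 0.1,
    dropout_prob = 0.1,
    level_fractions = c(l1 = 0.006, l2 = 0.066, l3 = 0.092),
    seed = 42) {
  cfg <- list(phyla = phyla, strains_per_phylum = as.integer(strains_per_phylum),
              n_core = n_core, n_phylum_specific = as.integer(n_phylum_specific),
              n_strain_specific = n_strain_specific, n_blanks = n_blanks,
              n_spectral_families = n_spectral_families,
              family_size_range = family_size_range,
              peak_count_range = peak_count_range,
              mz_range = mz_range, rt_range = rt_range,
              mz_jitter_sd = mz_jitter_sd,
              intensity_noise_cv = intensity_noise_cv,
              dropout_prob = dropout_prob,
              level_fractions = level_fractions, seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (length(cfg$strains_per_phylum) != length(cfg$phyla) ||
      length(cfg$n_phylum_specific) != length(cfg$phyla)) {
    abort("config error: strains_per_phylum and n_phylum_specific must match phyla")
  }
  if (any(c(cfg$n_core, cfg$n_phylum_specific, cfg$n_strain_specific,
            cfg$n_blanks) < 0) || any(cfg$strains_per_phylum < 1)) {
    abort("config error: counts must be non-negative, strains per phylum >= 1")
  }
  if (cfg$mz_jitter_sd < 0 || cfg$dropout_prob < 0 || cfg$dropout_prob >= 1) {
    abort("config error: mz_jitter_sd >= 0 and 0 <= dropout_prob < 1 required")
  }
  if (cfg$peak_count_range[1] < 4) {
    abort("config error: peak_count_range minimum must be >= 4")
  }
  if (cfg$family_size_range[1] < 2) {
    abort("config error: family_size_range minimum must be >= 2")
  }
  n_features <- cfg$n_core + sum(cfg$n_phylum_specific) +
    cfg$n_strain_specific * sum(cfg$strains_per_phylum)
  if (cfg$n_spectral_families * cfg$family_size_range[1] > n_features) {
    abort("config error: family sizes exceed total feature count")
  }
  if (sum(cfg$level_fractions) > 1) {
    abort("config error: level_fractions must sum to at most 1")
  }
  invisible(cfg)
}

# sample one element of x (never the 1:x expansion of base sample())
sample1 <- function(x) x[sample.int(length(x), 1)]

# m/z values with a minimum spacing, drawn uniformly then spread
draw_spaced <- function(n, lo, hi, spacing) {
  if (n * spacing >= hi - lo) abort("range too small for spaced draw")
  x <- sort(runif(n, lo, hi - n * spacing)) + spacing * (seq_len(n) - 1)
  x
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Produces a quantification table, MS/MS spectra, sample metadata and the
#' planted ground truth for a [synthetic_config()]. Presence follows the
#' configured strata; spectral-family members share a fragment template in
#' which each peak is either conserved (same m/z in all members) or linked
#' to a neutral loss (offset by the member's precursor shift), so that the
#' modified cosine connects all members. Peak areas are log-normal.
#' Deterministic under the config seed.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_cohort` with `quant`, `spectra`,
#'   `meta`, `truth` (tibbles `stratum`, `family`, `level`, `presence`, and
#'   `expected_specific`) and `config`.
#' @seealso [make_synthetic_libraries()], [write_cohort()]
#' @export
synthesize_cohort <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  withr::with_seed(config$seed, synthesize_cohort_impl(config))
}

synthesize_cohort_impl <- function(cfg) {
  n_strains <- sum(cfg$strains_per_phylum)
  phylum_of <- rep(cfg$phyla, cfg$strains_per_phylum)
  extract_id <- sprintf("E%03d", seq_len(n_strains))
  meta <- tibble(
    extract_id = extract_id,
    strain_id = sprintf("SYN_%s_%02d", substr(phylum_of, 1, 4),
                        unlist(lapply(cfg$strains_per_phylum, seq_len))),
    phylum = phylum_of,
    genus = sprintf("Genus_%s", substr(phylum_of, 1, 4)),
    similarity_pct = round(runif(n_strains, 92, 100), 2),
    is_blank = FALSE
  )
  if (cfg$n_blanks > 0) {
    meta <- bind_rows(meta, tibble(
      extract_id = sprintf("BLANK%02d", seq_len(cfg$n_blanks)),
      strain_id = NA_character_, phylum = NA_character_,
      genus = NA_character_, similarity_pct = NA_real_, is_blank = TRUE
    ))
  }

  # feature strata ------------------------------------------------------
  stratum <- bind_rows(
    tibble(stratum = rep("core", cfg$n_core), unit = NA_character_),
    bind_rows(map(seq_along(cfg$phyla), function(i) {
      tibble(stratum = rep("phylum", cfg$n_phylum_specific[i]),
             unit = cfg$phyla[i])
    })),
    bind_rows(map(seq_len(n_strains), function(s) {
      tibble(stratum = rep("strain", cfg$n_strain_specific),
             unit = extract_id[s])
    }))
  )
  n_features <- nrow(stratum)
  stratum <- mutate(stratum, feature_id = seq_len(n_features)) |>
    select("feature_id", "stratum", "unit")

  # spectral families ---------------------------------------------------
  bucket <- ifelse(stratum$stratum == "core", "core",
                   paste(stratum$stratum, stratum$unit, sep = ":"))
  unassigned <- split(stratum$feature_id, bucket)
  family_of <- rep(NA_integer_, n_features)
  fam <- 0L
  for (f in seq_len(cfg$n_spectral_families)) {
    avail <- names(unassigned)[map_int(unassigned, length) >= 2]
    if (length(avail) == 0) break
    wts <- map_int(unassigned[avail], length)
    b <- sample(avail, 1, prob = wts)
    size <- sample1(seq(cfg$family_size_range[1], cfg$family_size_range[2]))
    size <- min(size, length(unassigned[[b]]))
    members <- sort(sample(unassigned[[b]], size))
    fam <- fam + 1L
    family_of[members] <- fam
    unassigned[[b]] <- setdiff(unassigned[[b]], members)
  }

  # precursor m/z: family members share a base, all precursors >= 0.05 apart
  mz <- numeric(n_features)
  singles <- which(is.na(family_of))
  mz[singles] <- runif(length(singles), cfg$mz_range[1], cfg$mz_range[2])
  for (f in seq_len(fam)) {
    members <- which(family_of == f)
    base <- runif(1, max(cfg$mz_range[1], 200), cfg$mz_range[2] - 80)
    deltas <- c(0, sort(sample(seq_len(60), length(members) - 1)))
    mz[members] <- base + deltas
  }
  mz <- enforce_min_gap(mz, 0.05)
  rt <- round(runif(n_features, cfg$rt_range[1], cfg$rt_range[2]), 3)

  # spectra -------------------------------------------------------------
  peaks <- vector("list", n_features)
  for (f in seq_len(fam)) {
    members <- which(family_of == f)
    base <- min(mz[members])
    n_pk <- sample1(seq(cfg$peak_count_range[1], cfg$peak_count_range[2]))
    frag <- draw_spaced(n_pk, 50, base - 25, 0.06)
    conserved <- runif(n_pk) < 0.5
    inten <- runif(n_pk, 50, 1000)
    for (m in members) {
      delta <- mz[m] - base
      fm <- ifelse(conserved, frag, frag + delta)
      peaks[[m]] <- jitter_peaks(fm, inten, cfg)
    }
  }
  for (m in singles) {
    n_pk <- sample1(seq(cfg$peak_count_range[1], cfg$peak_count_range[2]))
    frag <- draw_spaced(n_pk, 50, max(mz[m] - 25, 80), 0.06)
    peaks[[m]] <- jitter_peaks(frag, runif(n_pk, 50, 1000), cfg)
  }
  spectra <- tibble(feature_id = seq_len(n_features), precursor_mz = mz,
                    rt = rt, n_peaks = map_int(peaks, nrow), peaks = peaks)

  # presence ------------------------------------------------------------
  pres <- matrix(FALSE, n_features, n_strains, dimnames = list(NULL, extract_id))
  strain_idx <- split(seq_len(n_strains), phylum_of)[cfg$phyla]
  for (i in seq_len(n_features)) {
    st <- stratum$stratum[i]
    if (st == "core") {
      row <- runif(n_strains) >= cfg$dropout_prob
      for (p in seq_along(cfg$phyla)) {
        idx <- strain_idx[[p]]
        if (!any(row[idx])) row[if (length(idx) == 1) idx else sample(idx, 1)] <- TRUE
      }
      pres[i, ] <- row
    } else if (st == "phylum") {
      idx <- strain_idx[[match(stratum$unit[i], cfg$phyla)]]
      if (length(idx) == 1) {
        pres[i, idx] <- TRUE
      } else {
        k <- sample1(2:length(idx))
        chosen <- sample(idx, k)
        surv <- chosen[runif(k) >= cfg$dropout_prob]
        if (length(surv) < 2) surv <- chosen[1:2]
        pres[i, surv] <- TRUE
      }
    } else {
      pres[i, stratum$unit[i]] <- TRUE
    }
  }

  areas <- matrix(0, n_features, n_strains, dimnames = list(NULL, extract_id))
  n_present <- sum(pres)
  areas[pres] <- rlnorm(n_present, meanlog = log(1e5), sdlog = 1)
  quant <- tibble(feature_id = seq_len(n_features), mz = mz, rt = rt)
  for (s in seq_len(n_strains)) quant[[extract_id[s]]] <- areas[, s]
  for (b in meta$extract_id[meta$is_blank]) quant[[b]] <- 0

  # planted annotation levels ------------------------------------------
  n_lv <- round(cfg$level_fractions * n_features)
  lvl <- rep("unknown", n_features)
  pool <- sample(seq_len(n_features))
  take <- cumsum(c(0, n_lv))
  for (k in seq_along(n_lv)) {
    if (n_lv[k] > 0) lvl[pool[(take[k] + 1):take[k + 1]]] <- sub("^l", "", names(n_lv)[k])
  }

  truth_presence <- tibble(feature_id = seq_len(n_features))
  for (s in seq_len(n_strains)) truth_presence[[extract_id[s]]] <- pres[, s]
  solo <- rowSums(pres) == 1L
  expected_specific <- tibble(
    extract_id = extract_id,
    n_specific = as.integer(colSums(pres[solo, , drop = FALSE]))
  )

  structure(list(
    quant = quant, spectra = spectra, meta = meta,
    truth = list(
      stratum = stratum,
      family = tibble(feature_id = seq_len(n_features), family = family_of),
      level = tibble(feature_id = seq_len(n_features), level = lvl),
      presence = truth_presence,
      expected_specific = expected_specific
    ),
    config = cfg
  ), class = "synthetic_cohort")
}

enforce_min_gap <- function(x, gap) {
  ord <- order(x)
  xs <- x[ord]
  for (i in seq_along(xs)[-1]) {
    if (xs[i] - xs[i - 1] < gap) xs[i] <- xs[i - 1] + gap
  }
  x[ord] <- xs
  x
}

jitter_peaks <- function(mz, intensity, cfg) {
  mzj <- mz + if (cfg$mz_jitter_sd > 0) rnorm(length(mz), 0, cfg$mz_jitter_sd) else 0
  intj <- intensity * pmax(0.05, 1 + if (cfg$intensity_noise_cv > 0)
    rnorm(length(mz), 0, cfg$intensity_noise_cv) else 0)
  ord <- order(mzj)
  data.frame(mz = mzj[ord], intensity = intj[ord])
}

#' Build annotation inputs matching a cohort's planted levels
#'
#' Features planted at level 1 get in-house library entries (precursor, RT
#' and an exact spectrum copy); level-2 features get external-library
#' entries; level-3 features get in-silico candidates drawn to pass the
#' acceptance filter (structure score below -150, formula confidence above
#' 0.6). Half of the unknown features receive deliberately failing
#' candidates, the rest nothing, so a correct cascade reproduces the
#' planted level distribution exactly on a noiseless cohort.
#'
#' @param cohort A `synthetic_cohort`.
#' @return A list with `inhouse` and `external` library tibbles and an
#'   `insilico` candidate tibble.
#' @export
make_synthetic_libraries <- function(cohort) {
  withr::with_seed(cohort$config$seed + 1L, {
    lv <- cohort$truth$level
    sp <- cohort$spectra
    classes <- c("Carboxylic acids and derivatives", "Fatty acyls",
                 "Indoles and derivatives", "Benzene and substituted derivatives",
                 "Organooxygen compounds", "Prenol lipids")
    lib_for <- function(ids, prefix) {
      rows <- sp[match(ids, sp$feature_id), , drop = FALSE]
      tibble(library_id = sprintf("%s%04d", prefix, ids),
             name = sprintf("compound_%04d", ids),
             class_label = sample(classes, length(ids), replace = TRUE),
             precursor_mz = rows$precursor_mz,
             rt = rows$rt,
             n_peaks = rows$n_peaks,
             peaks = rows$peaks)
    }
    l1 <- lv$feature_id[lv$level == "1"]
    l2 <- lv$feature_id[lv$level == "2"]
    l3 <- lv$feature_id[lv$level == "3"]
    unk <- lv$feature_id[lv$level == "unknown"]
    decoy <- sort(sample(unk, floor(length(unk) / 2)))

    passing <- tibble(
      feature_id = l3,
      formula = sprintf("C%dH%dNO%d", sample(10:40, length(l3), TRUE),
                        sample(12:60, length(l3), TRUE), sample(1:8, length(l3), TRUE)),
      structure = sprintf("struct_%04d", l3),
      csi_score = runif(length(l3), -300, -155),
      zodiac_score = runif(length(l3), 0.65, 0.99),
      class_label = sample(classes, length(l3), replace = TRUE)
    )
    fail_csi <- runif(length(decoy)) < 0.5
    failing <- tibble(
      feature_id = decoy,
      formula = sprintf("C%dH%dO%d", sample(10:40, length(decoy), TRUE),
                        sample(12:60, length(decoy), TRUE), sample(1:8, length(decoy), TRUE)),
      structure = sprintf("struct_%04d", decoy),
      csi_score = ifelse(fail_csi, runif(length(decoy), -145, -50),
                         runif(length(decoy), -300, -155)),
      zodiac_score = ifelse(fail_csi, runif(length(decoy), 0.65, 0.99),
                            runif(length(decoy), 0.05, 0.55)),
      class_label = sample(classes, length(decoy), replace = TRUE)
    )
    list(inhouse = lib_for(l1, "STD"),
         external = lib_for(l2, "SPC"),
         insilico = bind_rows(passing, failing) |> arrange(.data$feature_id))
  })
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Writes `quant.csv` (MZmine CSV dialect), `spectra.mgf`, `metadata.tsv`
#' and, when libraries are supplied, `inhouse.mgf`, `external.mgf` and
#' `insilico.tsv`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @param libraries Optional result of [make_synthetic_libraries()].
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, libraries = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(quant = file.path(dir, "quant.csv"),
             mgf = file.path(dir, "spectra.mgf"),
             meta = file.path(dir, "metadata.tsv"))
  write_quant_table(cohort$quant, paths[["quant"]])
  write_mgf(cohort$spectra, paths[["mgf"]])
  readr::write_tsv(cohort$meta, paths[["meta"]], progress = FALSE)
  if (!is.null(libraries)) {
    paths <- c(paths, inhouse = file.path(dir, "inhouse.mgf"),
               external = file.path(dir, "external.mgf"),
               insilico = file.path(dir, "insilico.tsv"))
    write_library_mgf(libraries$inhouse, paths[["inhouse"]])
    write_library_mgf(libraries$external, paths[["external"]])
    readr::write_tsv(libraries$insilico, paths[["insilico"]], progress = FALSE)
  }
  invisible(paths)
}
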