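make_inhouse <- function(s, rt, id = "STD1", name = "standard_1",
                         class_label = "Fatty acyls") {
  tibble::tibble(library_id = id, name = name, class_label = class_label,
                 precursor_mz = s$precursor_mz, rt = rt,
                 n_peaks = nrow(s$peaks), peaks = list(s$peaks))
}

test_that("level 1 requires precursor, RT and spectral agreement", {
  s <- spec_of(400, c(100, 150, 200, 250), c(10, 40, 100, 30))
  quant <- tibble::tibble(feature_id = 1L, mz = 400, rt = 5.0, S1 = 100)
  sp <- spectra_tbl(s)

  hit <- level1_match(quant, sp, make_inhouse(s, rt = 5.05))
  expect_equal(hit$level, "1")
  expect_equal(hit$source, "inhouse")
  expect_equal(hit$score, 1, tolerance = 1e-9)

  # same spectrum but RT off by 1 minute: gate closes
  expect_equal(nrow(level1_match(quant, sp, make_inhouse(s, rt = 6.0))), 0)
})

test_that("level 1 recovers jittered standards inside the tolerances", {
  co <- synthesize_cohort(small_config(
    seed = 61, level_fractions = c(l1 = 0.2, l2 = 0.1, l3 = 0.1)))
  libs <- make_synthetic_libraries(co)
  withr::with_seed(5, {
    sp <- co$spectra
    sp$peaks <- lapply(sp$peaks, function(pk) {
      pk$mz <- pk$mz + stats::runif(nrow(pk), -0.008, 0.008)
      pk[order(pk$mz), ]
    })
    sp$precursor_mz <- sp$precursor_mz + stats::runif(nrow(sp), -0.01, 0.01)
    quant <- co$quant
    quant$rt <- quant$rt + stats::runif(nrow(quant), -0.1, 0.1)
  })
  hits <- level1_match(quant, sp, libs$inhouse)
  planted <- co$truth$level$feature_id[co$truth$level$level == "1"]
  expect_setequal(hits$feature_id, planted)
})

test_that("level 2 enforces score and matched-peak thresholds", {
  s <- spec_of(400, c(100, 150, 200, 250))
  ext <- make_inhouse(s, rt = NA_real_, id = "SPC1", name = "cmpd")
  hit <- level2_match(spectra_tbl(s), ext)
  expect_equal(hit$level, "2")
  expect_equal(hit$source, "spectral_library")

  # only 2 matched peaks: rejected even at perfect score
  q2 <- spectra_tbl(spec_of(400, c(100, 150)))
  expect_equal(nrow(level2_match(q2, ext)), 0)
})

test_that("decoy libraries rarely pass the level-2 thresholds", {
  co <- synthesize_cohort(small_config(seed = 71))
  sp <- co$spectra
  withr::with_seed(9, {
    decoy <- sp
    decoy$library_id <- paste0("DEC", sp$feature_id)
    decoy$name <- decoy$library_id
    decoy$class_label <- ""
    # shuffle peak positions while keeping precursors (worst-case decoys)
    decoy$peaks <- lapply(sp$peaks, function(pk) {
      pk$mz <- sort(stats::runif(nrow(pk), 50, 300))
      pk
    })
  })
  ann <- level2_match(sp, decoy)
  expect_lte(nrow(ann) / nrow(sp), 0.05)
})

test_that("level-3 filter applies the score acceptance rule with strict bounds", {
  cand <- function(csi, zodiac) {
    tibble::tibble(feature_id = 1L, formula = "C6H12O6", structure = "s1",
                   csi_score = csi, zodiac_score = zodiac,
                   class_label = "Organooxygen compounds")
  }
  expect_equal(level3_filter(cand(-160, 0.70))$level, "3")
  expect_equal(nrow(level3_filter(cand(-140, 0.90))), 0)   # csi side fails
  expect_equal(nrow(level3_filter(cand(-160, 0.60))), 0)   # boundary: strict >
  expect_equal(nrow(level3_filter(cand(-150, 0.70))), 0)   # boundary: strict <
  expect_error(level3_filter(cand(NA_real_, 0.7)), "malformed")
})

test_that("cascade precedence keeps the highest-confidence level", {
  s <- spec_of(400, c(100, 150, 200, 250))
  quant <- tibble::tibble(feature_id = 1L, mz = 400, rt = 5, S1 = 10)
  sp <- spectra_tbl(s)
  inhouse <- make_inhouse(s, rt = 5)
  external <- make_inhouse(s, rt = NA_real_, id = "SPC1")
  ann <- annotate_cascade(quant, sp, inhouse, external)
  expect_equal(ann$level, "1")   # in-house outranks external

  # no inputs: everything unknown
  ann0 <- annotate_cascade(quant, sp)
  expect_equal(ann0$level, "unknown")
  expect_equal(ann0$name, "")
})

test_that("cascade recovers the planted level distribution exactly (noiseless)", {
  co <- synthesize_cohort(noiseless_config(seed = 81))
  libs <- make_synthetic_libraries(co)
  ann <- annotate_cascade(co$quant, co$spectra, libs$inhouse, libs$external,
                          libs$insilico)
  truth <- co$truth$level
  expect_equal(ann$level[order(ann$feature_id)],
               truth$level[order(truth$feature_id)])
  # level counts partition the features
  s <- annotation_summary(ann)
  expect_equal(sum(s$n), nrow(co$quant))
  expect_equal(sum(s$pct), 100)
})

test_that("tightening thresholds never gains annotations (monotone)", {
  co <- synthesize_cohort(small_config(seed = 91))
  libs <- make_synthetic_libraries(co)
  loose <- annotate_cascade(co$quant, co$spectra, libs$inhouse, libs$external,
                            libs$insilico, annotation_params())
  tight <- annotate_cascade(co$quant, co$spectra, libs$inhouse, libs$external,
                            libs$insilico,
                            annotation_params(lib_min_score = 0.9,
                                              csi_max_score = -250,
                                              zodiac_min = 0.9, rt_tol = 0.05))
  for (lv in c("1", "2", "3")) {
    expect_lte(sum(tight$level == lv), sum(loose$level == lv))
  }
})

test_that("class propagation uses majority with ties and gaps unclassified", {
  nodes <- tibble::tibble(feature_id = 1:9, mz = 1, rt = 1,
                          family = c(1L, 1L, 1L, 1L, 2L, 2L, 3L, 3L, NA),
                          is_singleton = is.na(c(1, 1, 1, 1, 2, 2, 3, 3, NA)))
  net <- structure(list(nodes = nodes, edges = tibble::tibble(),
                        sim_params = similarity_params(),
                        net_params = network_params()),
                   class = "molecular_network")
  ann <- tibble::tibble(
    feature_id = 1:9,
    level = c("2", "2", "2", "unknown", "2", "2", "unknown", "unknown", "2"),
    name = "x", source = "spectral_library",
    class_label = c("Indoles and derivatives", "Indoles and derivatives",
                    "Fatty acyls", "", "Fatty acyls", "Prenol lipids",
                    "", "", "Fatty acyls"),
    score = 1, n_matched = 5L)
  cls <- propagate_classes(net, ann)
  expect_equal(cls$class_label[cls$family == 1], "Indoles and derivatives")
  expect_equal(cls$class_label[cls$family == 2], "unclassified")  # 1-1 tie
  expect_equal(cls$class_label[cls$family == 3], "unclassified")  # no members annotated
})
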