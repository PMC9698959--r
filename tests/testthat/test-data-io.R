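test_that("quantification table parsing handles the MZmine dialect", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c(
    "row ID,row m/z,row retention time,S1 Peak area,S2 Peak area,row number of detected peaks",
    "1,150.05,1.2,1000,0,2",
    "2,300.10,5.5,,250.5,1",
    "3,450.20,10.0,42,17,2"
  ), csv)
  q <- read_quant_table(csv)
  expect_equal(nrow(q), 3)
  expect_equal(quant_samples(q), c("S1", "S2"))
  expect_equal(q$S1[2], 0)        # empty cell -> 0
  expect_equal(q$S2[2], 250.5)
  expect_equal(q$mz, c(150.05, 300.10, 450.20))
})

test_that("quantification table errors name the malformed part", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("row ID,row m/z,S1 Peak area", "1,150.05,10"), csv)
  expect_error(read_quant_table(csv), "row retention time")

  csv2 <- tempfile(fileext = ".csv")
  writeLines(c(
    "row ID,row m/z,row retention time,S1 Peak area",
    "1,150.05,1.2,10", "1,151.05,1.3,20"
  ), csv2)
  expect_error(read_quant_table(csv2), "duplicate feature ids")

  csv3 <- tempfile(fileext = ".csv")
  writeLines(c("row ID,row m/z,row retention time", "1,150.05,1.2"), csv3)
  expect_error(read_quant_table(csv3), "Peak area")
})

test_that("quant table parse -> serialize -> parse is idempotent", {
  co <- synthesize_cohort(small_config(seed = 11))
  p1 <- tempfile(fileext = ".csv")
  p2 <- tempfile(fileext = ".csv")
  write_quant_table(co$quant, p1)
  q1 <- read_quant_table(p1)
  write_quant_table(q1, p2)
  q2 <- read_quant_table(p2)
  expect_identical(q1, q2)
  expect_equal(q1$feature_id, co$quant$feature_id)
  expect_equal(q1$mz, co$quant$mz, tolerance = 1e-12)
})

test_that("MGF blocks parse with sorted peaks and dialect fallbacks", {
  mgf <- tempfile(fileext = ".mgf")
  writeLines(c(
    "BEGIN IONS", "FEATURE_ID=7", "PEPMASS=500.25", "RTINSECONDS=90",
    "120.1 55", "110.2 10", "130.0 99", "END IONS",
    "BEGIN IONS", "SCANS=9", "PEPMASS=400.10 12345",
    "90.5 10", "95.5 20", "END IONS"
  ), mgf)
  sp <- read_mgf(mgf)
  expect_equal(sp$feature_id, c(7L, 9L))
  expect_equal(sp$n_peaks, c(3L, 2L))
  expect_equal(sp$peaks[[1]]$mz, c(110.2, 120.1, 130.0))  # sorted ascending
  expect_equal(sp$rt[1], 1.5)
  expect_equal(sp$precursor_mz[2], 400.10)
})

test_that("MGF blocks without precursor are skipped; duplicates error", {
  mgf <- tempfile(fileext = ".mgf")
  writeLines(c(
    "BEGIN IONS", "FEATURE_ID=1", "100 10", "END IONS",
    "BEGIN IONS", "FEATURE_ID=2", "PEPMASS=200", "100 10", "END IONS"
  ), mgf)
  expect_warning(sp <- read_mgf(mgf), "PEPMASS")
  expect_equal(sp$feature_id, 2L)

  mgf2 <- tempfile(fileext = ".mgf")
  writeLines(rep(c("BEGIN IONS", "FEATURE_ID=5", "PEPMASS=200", "100 10",
                   "END IONS"), 2), mgf2)
  expect_error(read_mgf(mgf2), "duplicate")
})

test_that("a 100-block MGF round-trips unchanged", {
  co <- synthesize_cohort(synthetic_config(
    phyla = "Proteobacteria", strains_per_phylum = 20, n_core = 40,
    n_phylum_specific = 30, n_strain_specific = 2, n_spectral_families = 10,
    seed = 3))
  sp <- co$spectra[1:100, ]
  p1 <- tempfile(fileext = ".mgf")
  write_mgf(sp, p1)
  back <- read_mgf(p1)
  expect_equal(back$feature_id, sp$feature_id)
  expect_equal(back$precursor_mz, sp$precursor_mz, tolerance = 1e-5)
  expect_equal(back$n_peaks, sp$n_peaks)
  for (i in c(1, 50, 100)) {
    expect_equal(back$peaks[[i]]$mz, sp$peaks[[i]]$mz, tolerance = 1e-5)
    expect_equal(back$peaks[[i]]$intensity, sp$peaks[[i]]$intensity,
                 tolerance = 1e-6)
  }
  # second round trip is exact: printed precision is a fixed point
  p2 <- tempfile(fileext = ".mgf")
  write_mgf(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("study metadata fixture has 60 isolates with the expected rows", {
  meta <- load_study_metadata()
  expect_equal(nrow(meta), 60)
  expect_false(any(duplicated(meta$extract_id)))
  tab <- table(meta$phylum)
  expect_equal(unname(tab[["Proteobacteria"]]), 35)
  expect_equal(unname(tab[["Actinobacteria"]]), 8)
  expect_equal(unname(tab[["Firmicutes"]]), 1)
  expect_true(all(meta$similarity_pct > 0 & meta$similarity_pct <= 100))

  row322 <- meta[meta$extract_id == "322", ]
  expect_equal(row322$strain_id, "AEG42_45")
  expect_equal(row322$phylum, "Actinobacteria")
  expect_equal(row322$similarity_pct, 96.46)
})

test_that("network files round-trip through both formats", {
  co <- synthesize_cohort(small_config(seed = 5))
  net <- build_network(co$spectra, quant = co$quant)

  el <- tempfile(fileext = ".tsv")
  write_network(net, el, "edgelist")
  back <- read_network(el, "edgelist")
  expect_equal(back$edges$node_a, net$edges$node_a)
  expect_equal(back$edges$score, net$edges$score, tolerance = 1e-9)

  gml <- tempfile(fileext = ".graphml")
  write_network(net, gml, "graphml")
  back2 <- read_network(gml, "graphml")
  expect_equal(nrow(back2$nodes), nrow(net$nodes))
  expect_equal(nrow(back2$edges), nrow(net$edges))
  expect_setequal(back2$nodes$feature_id, net$nodes$feature_id)

  # empty network: valid files with zero edges
  empty <- structure(list(
    nodes = tibble::tibble(feature_id = integer(), mz = double(), rt = double(),
                           family = integer(), is_singleton = logical()),
    edges = net$edges[0, ],
    sim_params = similarity_params(), net_params = network_params()),
    class = "molecular_network")
  el0 <- tempfile(fileext = ".tsv")
  write_network(empty, el0, "edgelist")
  expect_equal(nrow(read_network(el0, "edgelist")$edges), 0)
})

test_that("library MGF and in-silico tables round-trip", {
  co <- synthesize_cohort(small_config(seed = 9))
  libs <- make_synthetic_libraries(co)
  p <- tempfile(fileext = ".mgf")
  write_library_mgf(libs$external, p)
  back <- read_library_mgf(p)
  expect_equal(back$library_id, libs$external$library_id)
  expect_equal(back$name, libs$external$name)
  expect_equal(back$class_label, libs$external$class_label)
  expect_equal(back$precursor_mz, libs$external$precursor_mz, tolerance = 1e-5)

  tsv <- tempfile(fileext = ".tsv")
  readr::write_tsv(libs$insilico, tsv)
  cand <- read_insilico_table(tsv)
  expect_equal(cand$feature_id, libs$insilico$feature_id)
  expect_equal(cand$csi_score, libs$insilico$csi_score, tolerance = 1e-9)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tcsi_score\tzodiac_score", "1\tNA\t0.7"), bad)
  expect_error(read_insilico_table(bad), "malformed")
})
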