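#' Pipeline run configuration
#'
#' Bundles input paths, parameter sets and the output directory for
#' [run_pipeline()]. Only the quantification table, MGF and metadata paths
#' are mandatory; annotation inputs are optional and skipped when `NULL`.
#'
#' @param quant,mgf,meta Paths to the quantification CSV, spectra MGF and
#'   metadata TSV.
#' @param inhouse,external Optional library MGF paths.
#' @param insilico Optional in-silico candidate TSV path.
#' @param out_dir Output directory for artifacts.
#' @param presence_threshold Area cutoff for presence calls.
#' @param sim,net,ann,prio Parameter sets (see [similarity_params()],
#'   [network_params()], [annotation_params()], [priority_params()]).
#' @param group Metadata column for the Venn partition.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(quant, mgf, meta, inhouse = NULL, external = NULL,
                            insilico = NULL, out_dir = "metabotalent_out",
                            presence_threshold = 0,
                            sim = similarity_params(), net = network_params(),
                            ann = annotation_params(), prio = priority_params(),
                            group = "phylum") {
  structure(list(quant = quant, mgf = mgf, meta = meta, inhouse = inhouse,
                 external = external, insilico = insilico, out_dir = out_dir,
                 presence_threshold = presence_threshold,
                 sim = sim, net = net, ann = ann, prio = prio, group = group),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes occurrence analytics, molecular networking, the dereplication
#' cascade and strain prioritization, writing TSV/GraphML artifacts plus a
#' JSON run manifest (parameters, package version, input MD5 hashes) into
#' the configured output directory. Identical configuration and inputs
#' yield byte-identical outputs. Stage failures raise errors naming the
#' stage; artifacts written before the failure are retained.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`presence`,
#'   `venn`, `network`, `annotations`, `reports`, `ranked`) and the paths
#'   of all written artifacts.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  inputs <- stage("input", {
    for (p in c(config$quant, config$mgf, config$meta,
                config$inhouse, config$external, config$insilico)) {
      if (!is.null(p) && !file.exists(p)) abort(paste0("input not found: ", p))
    }
    list(quant = read_quant_table(config$quant),
         spectra = read_mgf(config$mgf),
         meta = read_sample_metadata(config$meta))
  })

  occ <- stage("occurrence", {
    pm <- presence_matrix(inputs$quant, inputs$meta, config$presence_threshold)
    vp <- venn_partition(pm, inputs$meta, config$group)
    readr::write_tsv(vp |> select("region", "n_groups", "count"),
                     file.path(out, "venn_regions.tsv"), progress = FALSE)
    ssc <- strain_specific_counts(pm)
    tot <- tibble(sample_id = presence_samples(pm),
                  total_features = as.integer(colSums(presence_as_matrix(pm))))
    readr::write_tsv(left_join(tot, ssc, by = "sample_id"),
                     file.path(out, "strain_specific.tsv"), progress = FALSE)
    list(pm = pm, vp = vp)
  })

  network <- stage("network", {
    build_network(inputs$spectra, config$sim, config$net, quant = inputs$quant)
  })

  annotations <- stage("annotation", {
    inhouse <- if (!is.null(config$inhouse)) read_library_mgf(config$inhouse)
    external <- if (!is.null(config$external)) read_library_mgf(config$external)
    insilico <- if (!is.null(config$insilico)) read_insilico_table(config$insilico)
    ann <- annotate_cascade(inputs$quant, inputs$spectra, inhouse, external,
                            insilico, config$ann)
    readr::write_tsv(ann |> select(-any_of("n_matched")) |>
                       mutate(score = round(.data$score, 6)),
                     file.path(out, "annotations.tsv"), progress = FALSE)
    ann
  })

  stage("network-output", {
    excl <- family_exclusivity(network, occ$pm)
    classes <- propagate_classes(network, annotations)
    readr::write_tsv(left_join(excl, classes, by = "family") |>
                       mutate(fraction_exclusive = round(.data$fraction_exclusive, 6)),
                     file.path(out, "families.tsv"), progress = FALSE)
    write_network(network, file.path(out, "network.graphml"), "graphml",
                  annotations = annotations, exclusivity = excl)
  })

  reports <- stage("prioritization", {
    rep <- build_strain_reports(occ$pm, annotations, network, inputs$meta,
                                config$prio)
    flat <- rep |> select(-"exclusive_families") |>
      mutate(pct_unknown = round(.data$pct_unknown, 4))
    readr::write_tsv(flat, file.path(out, "reports.tsv"), progress = FALSE)
    ranked <- rank_strains(rep)
    readr::write_tsv(ranked |> select(-"exclusive_families") |>
                       mutate(pct_unknown = round(.data$pct_unknown, 4)),
                     file.path(out, "ranked.tsv"), progress = FALSE)
    list(reports = rep, ranked = ranked)
  })

  stage("manifest", {
    in_paths <- purrr::compact(config[c("quant", "mgf", "meta", "inhouse",
                                        "external", "insilico")])
    manifest <- list(
      package = "metabotalent",
      version = as.character(utils::packageVersion("metabotalent")),
      presence_threshold = config$presence_threshold,
      similarity = unclass(config$sim),
      network = unclass(config$net),
      annotation = unclass(config$ann),
      prioritization = unclass(config$prio),
      inputs = lapply(in_paths, function(p) unname(tools::md5sum(p)))
    )
    jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })

  invisible(list(presence = occ$pm, venn = occ$vp, network = network,
                 annotations = annotations, reports = reports$reports,
                 ranked = reports$ranked,
                 artifacts = file.path(out, c(
                   "venn_regions.tsv", "strain_specific.tsv", "annotations.tsv",
                   "families.tsv", "network.graphml", "reports.tsv",
                   "ranked.tsv", "run_manifest.json"))))
}
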