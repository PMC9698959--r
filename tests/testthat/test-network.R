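test_that("identical spectra form one fully connected family", {
  s <- spec_of(400, c(100, 130, 160, 190, 220), c(10, 50, 100, 40, 80))
  sp <- spectra_tbl(s, s, s)
  net <- build_network(sp)
  expect_equal(nrow(net$edges), 3)          # all pairwise
  expect_equal(network_summary(net)$n_families, 1)
  expect_equal(sum(!net$nodes$is_singleton), 3)
})

test_that("mutually dissimilar spectra stay singletons", {
  sp <- spectra_tbl(spec_of(400, c(100, 130, 160, 190)),
                    spec_of(450, c(101.5, 133, 164, 197)),
                    spec_of(500, c(103, 137, 168, 199.5)))
  net <- build_network(sp)
  expect_equal(nrow(net$edges), 0)
  s <- network_summary(net)
  expect_equal(s$n_families, 0)
  expect_equal(s$n_singletons, 3)
  expect_equal(s$singleton_fraction, 1)
})

test_that("edge thresholds honor inclusive and strict semantics", {
  # two spectra sharing exactly 4 of 8 equal-intensity peaks: score = 0.5
  common <- c(100, 120, 140, 160)
  a <- spec_of(400, c(common, 200, 220, 240, 260))
  b <- spec_of(400.5, c(common, 300, 320, 340, 360))
  r <- modified_cosine(a, b)
  expect_equal(r$score, 0.5, tolerance = 1e-9)
  expect_equal(r$n_matched, 4L)
  sp <- spectra_tbl(a, b)
  inc <- build_network(sp, net = network_params(inclusive = TRUE))
  expect_equal(nrow(inc$edges), 1)
  strict <- build_network(sp, net = network_params(inclusive = FALSE))
  expect_equal(nrow(strict$edges), 0)
})

test_that("mutual top-k pruning drops the weakest hub edge at the rank boundary", {
  # star: hub 1 with 11 leaves; leaves mutually unconnected
  edges <- tibble::tibble(node_a = 1L, node_b = 2:12,
                          score = seq(0.95, by = -0.02, length.out = 11),
                          n_matched = 5L)
  pruned <- topk_prune(edges, 10)
  expect_equal(nrow(pruned), 10)
  expect_false(12L %in% pruned$node_b)      # weakest edge dropped

  # top_k >= n - 1: vacuous
  expect_equal(nrow(topk_prune(edges, 11)), 11)
})

test_that("top-k pruning equals a brute-force rank computation on random graphs", {
  brute_topk <- function(edges, k) {
    keep <- logical(nrow(edges))
    rank_of <- function(node, partner) {
      inc <- edges[edges$node_a == node | edges$node_b == node, ]
      other <- ifelse(inc$node_a == node, inc$node_b, inc$node_a)
      ord <- order(-inc$score, other)
      which(other[ord] == partner)
    }
    for (e in seq_len(nrow(edges))) {
      keep[e] <- rank_of(edges$node_a[e], edges$node_b[e]) <= k &&
        rank_of(edges$node_b[e], edges$node_a[e]) <= k
    }
    edges[keep, ]
  }
  withr::with_seed(23, {
    for (rep in 1:10) {
      n <- sample(10:30, 1)
      pairs <- t(utils::combn(n, 2))
      take <- stats::runif(nrow(pairs)) < 0.3
      edges <- tibble::tibble(node_a = as.integer(pairs[take, 1]),
                              node_b = as.integer(pairs[take, 2]),
                              score = round(stats::runif(sum(take), 0.5, 1), 3),
                              n_matched = 5L)
      k <- sample(1:6, 1)
      expect_equal(topk_prune(edges, k), brute_topk(edges, k))
    }
  })
})

test_that("family capping removes weakest edges until components comply", {
  # path of 120 nodes with strictly increasing scores
  nodes <- tibble::tibble(feature_id = 1:120, mz = 100 + 1:120, rt = 1,
                          family = NA_integer_, is_singleton = FALSE)
  edges <- tibble::tibble(node_a = 1:119, node_b = 2:120,
                          score = 0.5 + (1:119) / 300, n_matched = 5L)
  net <- structure(list(nodes = nodes, edges = edges,
                        sim_params = similarity_params(),
                        net_params = network_params()),
                   class = "molecular_network")
  capped <- cap_families(net, 100)
  # hand-simulated removal: the 20 weakest edges go, leaving nodes 21..120
  expect_equal(capped$edges$node_a, 21:119)
  sizes <- table(capped$nodes$family)
  expect_equal(unname(as.integer(sizes)), 100)
  expect_equal(sum(capped$nodes$is_singleton), 20)

  # idempotent
  again <- cap_families(capped, 100)
  expect_equal(again$edges, capped$edges)

  # small component untouched
  net3 <- structure(list(nodes = nodes[1:3, ], edges = edges[1:2, ],
                         sim_params = similarity_params(),
                         net_params = network_params()),
                    class = "molecular_network")
  expect_equal(cap_families(net3, 100)$edges, edges[1:2, ])
})

test_that("network construction is invariant to spectra input order", {
  co <- synthesize_cohort(small_config(seed = 13))
  net1 <- build_network(co$spectra)
  withr::with_seed(1, shuffled <- co$spectra[sample(nrow(co$spectra)), ])
  net2 <- build_network(shuffled)
  expect_equal(net1$edges, net2$edges)
  expect_equal(net1$nodes, net2$nodes)
})

test_that("planted spectral families are recovered from noisy spectra", {
  aris <- vapply(1:3, function(s) {
    co <- synthesize_cohort(small_config(seed = 100 + s))
    net <- build_network(co$spectra)
    fam <- co$truth$family
    members <- fam$feature_id[!is.na(fam$family)]
    got <- net$nodes$family[match(members, net$nodes$feature_id)]
    got[is.na(got)] <- -seq_len(sum(is.na(got)))
    mclust::adjustedRandIndex(fam$family[match(members, fam$feature_id)], got)
  }, double(1))
  expect_true(all(aris >= 0.9))
})

test_that("family exclusivity flags families confined to one extract", {
  co <- synthesize_cohort(noiseless_config(seed = 41))
  net <- build_network(co$spectra)
  pm <- presence_matrix(co$quant, co$meta)
  excl <- family_exclusivity(net, pm)

  planted <- co$truth$family |>
    dplyr::inner_join(co$truth$stratum, by = "feature_id") |>
    dplyr::filter(!is.na(family))
  net_fam_of <- function(planted_fam) {
    member <- planted$feature_id[planted$family == planted_fam][1]
    net$nodes$family[net$nodes$feature_id == member]
  }

  # families planted inside one strain's specific features must be exclusive
  strain_fams <- dplyr::distinct(
    dplyr::filter(planted, stratum == "strain"), family, unit)
  expect_gt(nrow(strain_fams), 0)
  for (i in seq_len(nrow(strain_fams))) {
    row <- excl[excl$family == net_fam_of(strain_fams$family[i]), ]
    expect_equal(row$fraction_exclusive, 1.0)
    expect_true(row$is_exclusive)
    expect_equal(row$dominant_extract, strain_fams$unit[i])
  }

  # a family with members shared across extracts has fraction < 1
  core_fams <- dplyr::distinct(dplyr::filter(planted, stratum == "core"), family)
  if (nrow(core_fams) > 0) {
    fid <- net_fam_of(core_fams$family[1])
    expect_lt(excl$fraction_exclusive[excl$family == fid], 1.0)
  }
})

test_that("network summary arithmetic and invariants hold after building", {
  co <- synthesize_cohort(small_config(seed = 55))
  net <- build_network(co$spectra)
  s <- network_summary(net)
  expect_equal(s$n_singletons + sum(!net$nodes$is_singleton), s$n_nodes)
  expect_equal(s$singleton_fraction, s$n_singletons / s$n_nodes)
  # thresholds hold for every surviving edge
  expect_true(all(net$edges$score >= net$net_params$min_cosine))
  expect_true(all(net$edges$n_matched >= net$net_params$min_matched_peaks))
  expect_true(all(net$edges$node_a < net$edges$node_b))
  # no component exceeds the cap
  fams <- network_families(net)
  expect_true(all(fams$size <= net$net_params$max_family_size))
  # glance/tidy accessors
  expect_equal(glance(net), s)
  expect_equal(nrow(tidy(net)), nrow(net$edges))
})
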