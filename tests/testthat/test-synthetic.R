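small_spec <- function(seed = 7, ...) {
  synthetic_spec(seed = seed, universe_size = 400, n_drug_targets = 60,
                 frac_below_threshold = 0.5, disease_sizes = c(150, 90),
                 n_dual = 50, n_common = 8, n_drug_a_only = 6, n_drug_b_only = 4,
                 ppi_n_nodes = 40, ppi_edge_prob = 0.1,
                 planted_hub_extra_degree = 20, gmt_n_terms = 20,
                 term_size_range = c(8, 20), planted_term_overlap = 6, ...)
}

test_that("spec validation rejects infeasible requests", {
  expect_error(synthetic_spec(frac_below_threshold = 1.5), "\\[0, 1\\]")
  # overlap larger than the below-threshold drug set
  expect_error(synthetic_spec(n_drug_targets = 10, frac_below_threshold = 0.5,
                              n_common = 4, n_drug_a_only = 2, n_drug_b_only = 0),
               "infeasible")
  # requested dual overlap larger than the smaller disease set
  expect_error(synthetic_spec(disease_sizes = c(100, 50), n_dual = 60),
               "infeasible")
  expect_error(small_spec(planted_term_overlap = 30), "planted_term_overlap")
})

test_that("generators are pure functions of the spec: byte-identical reruns", {
  spec <- small_spec()
  d1 <- tempfile(); d2 <- tempfile()
  suppressMessages({
    fx1 <- gen_fixture_suite(spec, d1)
    fx2 <- gen_fixture_suite(spec, d2)
  })
  for (f in c("affinity.csv", "affinity.truth.json", "disease_a.tsv",
              "disease_b.tsv", "diseases.truth.json", "ppi_edges.tsv",
              "ppi.truth.json", "collection.gmt", "gmt.truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # different seeds give different draws
  suppressMessages(fx3 <- gen_affinity_table(small_spec(seed = 8), tempfile()))
  expect_false(identical(readLines(fx1$affinity$path), readLines(fx3$path)))
})

test_that("the potency filter recovers the affinity generator's planted labels", {
  for (frac in c(0, 0.5, 1)) {
    spec <- synthetic_spec(seed = 7, universe_size = 400, n_drug_targets = 60,
                           frac_below_threshold = frac, disease_sizes = c(150, 90),
                           n_dual = 40, n_common = 0, n_drug_a_only = 0,
                           n_drug_b_only = 0, ppi_n_nodes = 30,
                           planted_hub_extra_degree = 10, n_planted_hubs = 0,
                           term_size_range = c(8, 20), planted_term_overlap = 0,
                           gmt_n_terms = 10)
    gen <- suppressMessages(gen_affinity_table(spec, tempfile()))
    rec <- suppressMessages(read_affinity_table(gen$path))
    res <- filter_by_potency(rec, spec$threshold_nM)
    expect_equal(nrow(res$retained), round(frac * 60))
    expect_setequal(retained_symbols(res), unlist(gen$truth$retained))
  }
})

test_that("the Venn partition reproduces the disease generator's planted regions", {
  spec <- small_spec()
  d <- tempfile()
  suppressMessages({
    aff <- gen_affinity_table(spec, d)
    dis <- gen_disease_tables(spec, d)
  })
  drug <- unlist(aff$truth$retained)
  a <- association_symbols(suppressMessages(read_association_table(dis$path_a, "a")))
  b <- association_symbols(suppressMessages(read_association_table(dis$path_b, "b")))
  v <- venn_partition(drug, a, b)
  truth <- unlist(dis$truth$region_counts)
  expect_equal(v$region_counts[names(truth)], truth)
  expect_equal(v$region_members[["111"]], sort(unlist(dis$truth$common)))
})

test_that("PPI generator: planted degrees are recovered and the hub ranks first", {
  spec <- small_spec()
  d <- tempfile()
  suppressMessages({
    dis <- gen_disease_tables(spec, d)
    ppi <- gen_ppi_network(spec, d)
  })
  common <- sort(unlist(dis$truth$common))
  edges <- suppressMessages(read_edge_list(ppi$path))
  net <- build_network(edges, 400)
  deg <- drug_anchored_degrees(net, common)
  truth_deg <- unlist(ppi$truth$degrees)
  expect_equal(setNames(deg$vertex_degree, deg$symbol)[names(truth_deg)], truth_deg)
  ranked <- rank_targets(deg)
  expect_equal(ranked$symbol[1], ppi$truth$top_target)
  expect_true(ppi$truth$top_target %in% unlist(ppi$truth$hubs))
})

test_that("edge-probability-0 corner cases behave as planted", {
  base <- function(extra, hubs) {
    synthetic_spec(seed = 3, universe_size = 400, n_drug_targets = 60,
                   frac_below_threshold = 0.5, disease_sizes = c(150, 90),
                   n_dual = 50, n_common = 8, n_drug_a_only = 6,
                   n_drug_b_only = 4, ppi_n_nodes = 40, ppi_edge_prob = 0,
                   n_planted_hubs = hubs, planted_hub_extra_degree = extra,
                   gmt_n_terms = 20, term_size_range = c(8, 20),
                   planted_term_overlap = 6)
  }
  # one hub of extra degree 9, no background edges -> hub degree exactly 9
  ppi <- suppressMessages(gen_ppi_network(base(9, 1), tempfile()))
  expect_equal(max(unlist(ppi$truth$degrees)), 9L)
  expect_equal(ppi$truth$n_edges, 9L)
  # no hubs -> empty edge file
  ppi0 <- suppressMessages(gen_ppi_network(base(9, 0), tempfile()))
  expect_equal(ppi0$truth$n_edges, 0L)
  expect_equal(nrow(suppressMessages(read_edge_list(ppi0$path))), 0L)
})

test_that("GMT generator plants a recoverable top term", {
  spec <- small_spec()
  d <- tempfile()
  suppressMessages({
    dis <- gen_disease_tables(spec, d)
    gmt <- gen_gmt(spec, d)
  })
  coll <- read_gmt(gmt$path)
  expect_length(coll, spec$gmt_n_terms)
  common <- sort(unlist(dis$truth$common))
  res <- enrich(common, coll, background = spec$universe_size)
  expect_equal(res$term_id[1], gmt$truth$planted_term_id)
  expect_gte(res$k[1], gmt$truth$planted_overlap)
})

test_that("the packaged common-target ranking fixture is stable and correct", {
  t2 <- load_table2_fixture()
  expect_equal(nrow(t2), 10L)
  expect_equal(t2$symbol[which.max(t2$vertex_degree)], "PPARG")
  expect_identical(load_table2_fixture(), t2)

  t1 <- load_table1_fixture()
  expect_equal(nrow(t1), 10L)
  expect_true(all(unlist(t1$members) %in% t2$symbol))
})
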