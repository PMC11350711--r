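test_that("count matrices round-trip and are reordered to the sample sheet", {
  sheet <- toy_sheet(4)
  cts <- toy_counts(matrix(rpois(24, 50), nrow = 3), samples = sheet$sample_id)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_counts(cts, f)
  back <- read_counts(f, "mRNA", sheet)
  expect_equal(as.data.frame(back), as.data.frame(cts), ignore_attr = TRUE)
  expect_identical(attr(back, "rna_class"), "mRNA")

  # a column permutation of the file yields the identical matrix
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_counts(cts[, c("feature_id", sample(sheet$sample_id))], f2)
  expect_equal(as.data.frame(read_counts(f2, "mRNA", sheet)),
               as.data.frame(back))
})

test_that("count reading rejects broken inputs with informative errors", {
  sheet <- toy_sheet(2)
  cts <- toy_counts(matrix(1:12, nrow = 3), samples = sheet$sample_id)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_counts(cts[, -2], f)  # drop sample S01
  expect_error(read_counts(f, "mRNA", sheet), "S01")

  dup <- dplyr::bind_rows(cts, cts[1, ])
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_counts(dup, f3)
  expect_error(read_counts(f3, "mRNA", sheet), "duplicate feature")

  neg <- cts; neg$S01[1] <- -5
  f4 <- withr::local_tempfile(fileext = ".tsv")
  write_counts(neg, f4)
  expect_error(read_counts(f4, "mRNA", sheet), "non-negative")
})

test_that("sample sheets enforce the two-group design", {
  expect_error(validate_sample_sheet(tibble::tibble(sample_id = c("a", "a"),
                                                    group = c("high", "low"))),
               "duplicate sample")
  expect_error(validate_sample_sheet(tibble::tibble(sample_id = c("a", "b"),
                                                    group = c("high", "mid"))),
               "unknown group")
  expect_error(validate_sample_sheet(tibble::tibble(
    sample_id = c("a", "b", "c"), group = c("high", "high", "low"))),
    "at least 2")
  sheet <- validate_sample_sheet(toy_sheet(2))
  expect_s3_class(sheet$group, "factor")
})

test_that("run configuration defaults match the pipeline thresholds and survive YAML", {
  cfg <- run_config()
  expect_equal(cfg$lfc_min, 1)
  expect_equal(cfg$p_max, 0.05)
  expect_equal(cfg$scc_neg_max, -0.7)
  expect_equal(cfg$scc_pos_min, 0.9)
  expect_equal(cfg$cerna_p_max, 0.05)
  expect_equal(cfg$enrich_p_max, 0.05)

  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("thresholds:", "  lfc_min: 2", "  scc_neg_max: -0.8",
               "seed: 7"), f)
  cfg2 <- read_run_config(f)
  expect_equal(cfg2$lfc_min, 2)
  expect_equal(cfg2$scc_neg_max, -0.8)
  expect_equal(cfg2$seed, 7L)
  expect_equal(cfg2$p_max, 0.05)  # untouched default

  expect_error(run_config(p_max = 0), "p_max")
  expect_error(run_config(scc_neg_max = 0.2), "scc_neg_max")
  expect_error(run_config(scc_pos_min = -0.5), "scc_pos_min")
})

test_that("target maps validate, deduplicate and reject unknown classes", {
  tm <- tibble::tibble(mirna_id = c("m1", "m1", "m2"),
                       target_id = c("g1", "g1", "g2"),
                       target_class = c("mRNA", "mRNA", "lncRNA"))
  expect_equal(nrow(validate_target_map(tm)), 2)
  expect_error(validate_target_map(dplyr::mutate(tm, target_class = "rRNA")),
               "target_class")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_target_map(tm, f)
  expect_equal(nrow(read_target_map(f)), 2)
})

test_that("network exports cover the three Cytoscape dialects and round-trip", {
  d <- simulate_dataset(sim_params(n_per_group = 20, n_mrna = 30, n_mirna = 16,
                                   n_lncrna = 20, n_triples = 6,
                                   n_decoy_edges = 10, seed = 3))
  pl <- run_cerna_pipeline(d$counts, d$samples, d$target_map)
  net <- pl$network
  expect_gt(nrow(net$edges), 0)

  f_edge <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, f_edge, "edge_tsv")
  back <- read_network_edges(f_edge)
  expect_equal(as.data.frame(back), as.data.frame(net$edges))
  nodes <- readr::read_tsv(sub("\\.tsv$", "_nodes.tsv", f_edge),
                           show_col_types = FALSE)
  expect_named(nodes, c("id", "class", "direction", "degree", "is_hub"))

  f_sif <- withr::local_tempfile(fileext = ".sif")
  write_network(net, f_sif, "sif")
  expect_length(readLines(f_sif), nrow(net$edges))

  f_gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, f_gml, "graphml")
  g <- igraph::read_graph(f_gml, format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
  expect_true(all(c("class", "direction", "degree", "is_hub") %in%
                    igraph::vertex_attr_names(g)))
  expect_true(all(c("edge_type", "scc", "regulation") %in%
                    igraph::edge_attr_names(g)))
})

test_that("a one-triple network yields the expected SIF lines; empty networks export", {
  de <- list(mRNA = fake_de("m1", "up"), miRNA = fake_de("mi1", "down"),
             lncRNA = fake_de("l1", "up"))
  mirna_pairs <- tibble::tibble(
    mirna_id = "mi1", target_id = c("l1", "m1"),
    target_class = c("lncRNA", "mRNA"), pair_type = c("lncRNA-miRNA", "miRNA-mRNA"),
    scc = c(-0.9, -0.95), passes = TRUE)
  finals <- tibble::tibble(lncrna_id = "l1", mrna_id = "m1",
                           shared_mirnas = list("mi1"), k = 1L, K = 1L,
                           n = 1L, N = 5L, scc = 0.95, hyper_p = 0.01,
                           padj = 0.01, final = TRUE)
  f <- withr::local_tempfile(fileext = ".sif")

  net3 <- build_cerna_network(finals, mirna_pairs, de)
  write_network(net3, f, "sif")
  expect_length(readLines(f), 3)  # lncRNA-miRNA, miRNA-mRNA, lncRNA-mRNA

  net2 <- build_cerna_network(finals, mirna_pairs, de,
                              include_lnc_mrna_edges = FALSE)
  write_network(net2, f, "sif")
  expect_length(readLines(f), 2)

  empty <- build_cerna_network(finals[0, ], mirna_pairs, de)
  f_e <- withr::local_tempfile(fileext = ".tsv")
  write_network(empty, f_e, "edge_tsv")
  expect_equal(nrow(read_network_edges(f_e)), 0)
  write_network(empty, f_e, "graphml")
  expect_equal(igraph::gorder(igraph::read_graph(f_e, format = "graphml")), 0)
})
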