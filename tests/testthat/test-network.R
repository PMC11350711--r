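test_that("a single final pair with one witness builds the forced topology", {
  de <- list(mRNA = fake_de("m1", "up"), miRNA = fake_de("mi1", "down"),
             lncRNA = fake_de("l1", "up"))
  mirna_pairs <- tibble::tibble(
    mirna_id = "mi1", target_id = c("l1", "m1"),
    target_class = c("lncRNA", "mRNA"),
    pair_type = c("lncRNA-miRNA", "miRNA-mRNA"),
    scc = c(-0.85, -0.92), passes = TRUE)
  finals <- tibble::tibble(lncrna_id = "l1", mrna_id = "m1",
                           shared_mirnas = list("mi1"), k = 1L, K = 1L, n = 1L,
                           N = 4L, scc = 0.93, hyper_p = 0.02, padj = 0.02,
                           final = TRUE)
  net <- build_cerna_network(finals, mirna_pairs, de)
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 3)
  expect_equal(sum(net$nodes$degree), 2 * nrow(net$edges))
  # edge attributes: scc carried from the source pair tables
  e <- net$edges
  expect_equal(e$scc[e$edge_type == "miRNA-mRNA"], -0.92)
  expect_equal(e$scc[e$edge_type == "lncRNA-mRNA"], 0.93)
  # regulation = direction of the regulated (non-miRNA / mRNA) endpoint
  expect_equal(e$regulation[e$edge_type == "lncRNA-miRNA"], "up")
  expect_equal(e$regulation[e$edge_type == "miRNA-mRNA"], "up")

  net2 <- build_cerna_network(finals, mirna_pairs, de,
                              include_lnc_mrna_edges = FALSE)
  expect_equal(nrow(net2$edges), 2)

  empty <- build_cerna_network(finals[0, ], mirna_pairs, de)
  expect_equal(nrow(empty$nodes), 0)
  expect_equal(hub_nodes(empty), character())

  # an id without a DE record is a pipeline ordering bug -> hard error
  de_missing <- de; de_missing$lncRNA <- fake_de("other")
  expect_error(build_cerna_network(finals, mirna_pairs, de_missing),
               "no DE record")
})

test_that("a shared miRNA accumulates degree across the pairs it witnesses", {
  de <- list(mRNA = fake_de(c("m1", "m2")), miRNA = fake_de("mi1", "down"),
             lncRNA = fake_de(c("l1", "l2")))
  mirna_pairs <- tibble::tibble(
    mirna_id = "mi1", target_id = c("l1", "l2", "m1", "m2"),
    target_class = c("lncRNA", "lncRNA", "mRNA", "mRNA"),
    pair_type = c("lncRNA-miRNA", "lncRNA-miRNA", "miRNA-mRNA", "miRNA-mRNA"),
    scc = -0.9, passes = TRUE)
  finals <- tibble::tibble(lncrna_id = c("l1", "l2"), mrna_id = c("m1", "m2"),
                           shared_mirnas = list("mi1", "mi1"), k = 1L, K = 2L,
                           n = 1L, N = 6L, scc = 0.95, hyper_p = 0.01,
                           padj = 0.01, final = TRUE)
  net <- build_cerna_network(finals, mirna_pairs, de)
  expect_equal(net$nodes$degree[net$nodes$id == "mi1"], 4L)
  expect_equal(hub_nodes(net), "mi1")  # 4 > mean degree
})

test_that("hub calling uses a strict mean-degree rule over the whole network", {
  triangle <- make_net(tibble::tibble(
    source = c("a", "b", "c"), target = c("b", "c", "a"),
    edge_type = "lncRNA-mRNA", scc = 1, regulation = "up"))
  expect_equal(hub_nodes(triangle), character())

  star <- make_net(tibble::tibble(
    source = "hub", target = c("x1", "x2", "x3", "x4"),
    edge_type = "miRNA-mRNA", scc = -1, regulation = "up"))
  expect_equal(hub_nodes(star), "hub")  # degree 4 > mean 1.6

  single <- make_net(tibble::tibble(source = "a", target = "b",
                                    edge_type = "miRNA-mRNA", scc = -1,
                                    regulation = "up"))
  expect_equal(hub_nodes(single), character())

  # any regular graph has an empty hub set: a 6-cycle
  cyc <- make_net(tibble::tibble(
    source = letters[1:6], target = letters[c(2:6, 1)],
    edge_type = "lncRNA-miRNA", scc = -1, regulation = "up"))
  expect_equal(hub_nodes(cyc), character())

  # hub identity is invariant under relabeling
  relab <- star
  relab$edges$source <- sub("hub", "zz", relab$edges$source)
  relab <- make_net(relab$edges)
  expect_equal(hub_nodes(relab), "zz")
})

test_that("structural invariants hold on pipeline-built networks and are enforced", {
  for (seed in c(1, 5)) {
    d <- simulate_dataset(sim_params(n_per_group = 12, n_mrna = 60,
                                     n_mirna = 20, n_lncrna = 30,
                                     n_triples = 6, seed = seed))
    pl <- run_cerna_pipeline(d$counts, d$samples, d$target_map)
    net <- pl$network
    expect_silent(validate_cerna_network(net))
    expect_equal(sum(net$nodes$degree), 2 * nrow(net$edges))
  }
  # a fabricated lncRNA-mRNA edge with no witness path is rejected
  broken <- make_net(tibble::tibble(
    source = c("l1", "mi1"), target = c("m1", "l1"),
    edge_type = c("lncRNA-mRNA", "lncRNA-miRNA"),
    scc = c(0.95, -0.9), regulation = "up"))
  expect_error(validate_cerna_network(broken), "witness")
})

test_that("network summaries and igraph conversion agree with the tables", {
  d <- simulate_dataset(sim_params(n_per_group = 16, n_mrna = 40, n_mirna = 16,
                                   n_lncrna = 20, n_triples = 4, seed = 2))
  pl <- run_cerna_pipeline(d$counts, d$samples, d$target_map)
  g <- glance(pl$network)
  expect_equal(g$n_nodes, nrow(pl$network$nodes))
  expect_equal(g$n_mrna + g$n_mirna + g$n_lncrna, g$n_nodes)
  expect_equal(g$n_lncrna_mirna_edges + g$n_mirna_mrna_edges +
                 g$n_lncrna_mrna_edges, g$n_edges)
  ig <- as_igraph(pl$network)
  expect_equal(igraph::gorder(ig), g$n_nodes)
  expect_equal(unname(igraph::degree(ig)[pl$network$nodes$id]),
               pl$network$nodes$degree)
})
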