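test_that("the generator is reproducible from its seed and seeds differ", {
  p <- sim_params(n_mrna = 30, n_mirna = 12, n_lncrna = 15, n_triples = 3,
                  n_decoy_edges = 20, seed = 11)
  d1 <- simulate_dataset(p)
  d2 <- simulate_dataset(p)
  expect_identical(d1, d2)
  d3 <- simulate_dataset(sim_params(n_mrna = 30, n_mirna = 12, n_lncrna = 15,
                                    n_triples = 3, n_decoy_edges = 20,
                                    seed = 12))
  expect_false(identical(d1$counts$mRNA, d3$counts$mRNA))
})

test_that("infeasible parameters are rejected", {
  expect_error(sim_params(n_mrna = 5, n_triples = 10), "n_triples")
  expect_error(sim_params(n_mirna = 5, n_triples = 4, mirnas_per_triple = 2),
               "n_triples")
  expect_error(sim_params(frac_de = c(mRNA = 1.2, miRNA = 0, lncRNA = 0)),
               "frac_de")
  expect_error(sim_params(nb_dispersion = 0), "dispersion")
})

test_that("every planted triple's miRNAs map to both partners in the target map", {
  d <- simulate_dataset(sim_params(n_mrna = 40, n_mirna = 20, n_lncrna = 25,
                                   n_triples = 5, seed = 2))
  tm_key <- paste(d$target_map$mirna_id, d$target_map$target_id)
  tr <- d$truth$triples
  expect_true(all(paste(tr$mirna_id, tr$lncrna_id) %in% tm_key))
  expect_true(all(paste(tr$mirna_id, tr$mrna_id) %in% tm_key))
})

test_that("a null dataset calls ~5% of features and yields no ceRNA pairs", {
  d <- simulate_dataset(sim_params(
    n_mrna = 2000, n_mirna = 100, n_lncrna = 100,
    frac_de = c(mRNA = 0, miRNA = 0, lncRNA = 0),
    n_triples = 0, n_decoy_edges = 200, seed = 5))
  de <- nb_wald_test(d$counts$mRNA, d$samples)
  expect_gt(mean(de$p_value < 0.05), 0.02)
  expect_lt(mean(de$p_value < 0.05), 0.08)
  pl <- run_cerna_pipeline(d$counts, d$samples, d$target_map)
  expect_equal(sum(pl$cerna_pairs$final), 0)
})

test_that("planted differential features carry the intended effect and direction", {
  d <- simulate_dataset(sim_params(n_per_group = 20, n_mrna = 200,
                                   n_mirna = 20, n_lncrna = 20,
                                   n_triples = 0, seed = 7))
  de <- classify_de(nb_wald_test(d$counts$mRNA, d$samples))
  truth <- dplyr::filter(d$truth$de_features, rna_class == "mRNA")
  hit <- dplyr::inner_join(truth, de, by = "feature_id")
  expect_gte(mean(hit$significant & hit$direction.x == hit$direction.y), 0.9)
  # planted two-fold-squared effect: observed log2fc near +/- lfc_de
  expect_equal(mean(abs(hit$log2fc)), 2, tolerance = 0.15)
})

test_that("planted sponge triples satisfy the Spearman contract at n = 4", {
  # generator contract: averaged over 50 seeds, the planted correlations
  # clear the -0.7 / 0.9 selection thresholds at the study's sample size
  res <- vapply(1:50, function(s) {
    d <- simulate_dataset(sim_params(n_per_group = 4, n_mrna = 20,
                                     n_mirna = 12, n_lncrna = 15,
                                     n_triples = 5, n_decoy_edges = 10,
                                     seed = s))
    mats <- lapply(d$counts, function(x) {
      m <- as.matrix(x[-1]); rownames(m) <- x$feature_id; m
    })
    tr <- d$truth$triples
    mi_mr <- mapply(function(mi, mr) spearman_scc(mats$miRNA[mi, ], mats$mRNA[mr, ]),
                    tr$mirna_id, tr$mrna_id)
    ln_mr <- mapply(function(l, m) spearman_scc(mats$lncRNA[l, ], mats$mRNA[m, ]),
                    d$truth$pairs$lncrna_id, d$truth$pairs$mrna_id)
    c(mean(mi_mr), mean(ln_mr))
  }, numeric(2))
  expect_lt(mean(res[1, ]), -0.7)
  expect_gt(mean(res[2, ]), 0.9)
})

test_that("phenotype simulation reproduces group-difference behaviour", {
  traits_null <- tibble::tibble(trait = "x", group = c("high", "low"),
                                mean = 10, sd = 2)
  ps <- vapply(1:200, function(s) {
    d <- simulate_phenotypes(traits_null, n_per_group = 4, seed = s)
    compare_groups_raw(dplyr::mutate(d, animal = NULL))$p_value
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0.005)
  expect_lt(mean(ps < 0.05), 0.12)

  # a live-weight-sized effect is nearly always highly significant
  traits_lw <- tibble::tibble(trait = "lw", group = c("high", "low"),
                              mean = c(148.38, 88.75), sd = c(8.97, 9.13))
  letters <- vapply(1:20, function(s) {
    d <- simulate_phenotypes(traits_lw, n_per_group = 4, seed = s)
    compare_groups_raw(d)$letters
  }, character(1))
  expect_gte(mean(letters == "A/B"), 0.9)

  # degenerate: zero spread with different means
  d0 <- simulate_phenotypes(tibble::tibble(trait = "z", group = c("high", "low"),
                                           mean = c(1, 2), sd = 0),
                            n_per_group = 4, seed = 1)
  expect_warning(r0 <- compare_group_summaries(
    dplyr::summarise(dplyr::group_by(d0, trait, group),
                     mean = mean(value), sd = sd(value), n = dplyr::n(),
                     .groups = "drop")), "zero")
  expect_equal(r0$p_value, 0)
})

test_that("simulated qPCR tables are reproducible and recover the planted effect", {
  d <- simulate_dataset(sim_params(n_mrna = 30, n_mirna = 12, n_lncrna = 15,
                                   n_triples = 3, seed = 4))
  ct1 <- simulate_qpcr(d$truth, d$samples, seed = 9)
  ct2 <- simulate_qpcr(d$truth, d$samples, seed = 9)
  expect_identical(ct1, ct2)

  gene <- d$truth$de_features$feature_id[1]
  dirn <- d$truth$de_features$direction[1]
  r <- ddct_relative_expression(ct1, d$samples, gene)
  expected <- if (dirn == "up") 2 else -2
  expect_equal(r$test$log2_rq_ratio, expected, tolerance = 0.3 / 2)

  # reference gene is flat across groups
  ref <- dplyr::filter(ct1, gene_id == "GAPDH")
  ref_means <- tapply(ref$ct, ref$sample_id, mean)
  expect_lt(diff(range(ref_means)), 1)
})
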