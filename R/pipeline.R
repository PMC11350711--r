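#' Run the full ceRNA discovery pipeline
#'
#' Chains every stage on count matrices for the three RNA classes:
#' per-class differential expression (median-of-ratios normalization and
#' the negative-binomial Wald test for mRNA/lncRNA, per-million for miRNA),
#' threshold classification, Spearman filtering of predicted miRNA-target
#' pairs, candidate lncRNA-mRNA pairing by shared miRNAs and positive
#' correlation, the shared-miRNA hypergeometric test, and tripartite
#' network assembly with hub calling.
#'
#' @param counts Named list of wide count tibbles (`mRNA`, `miRNA`,
#'   `lncRNA`).
#' @param samples Sample sheet.
#' @param target_map Predicted miRNA-target tibble.
#' @param cfg A [run_config()].
#' @param include_lnc_mrna_edges Passed to [build_cerna_network()].
#' @return A `cerna_pipeline` list: `de` (classified per class), `expr`
#'   (normalized matrices used for correlations), `mirna_pairs`,
#'   `candidates`, `cerna_pairs`, `network`, `cfg`.
#' @export
run_cerna_pipeline <- function(counts, samples, target_map,
                               cfg = run_config(),
                               include_lnc_mrna_edges = TRUE) {
  stopifnot(all(RNA_CLASSES %in% names(counts)))
  validate_run_config(cfg)
  samples <- validate_sample_sheet(samples)

  norm_fun <- list(mRNA = normalize_by_size_factors,
                   miRNA = normalize_per_million,
                   lncRNA = normalize_by_size_factors)
  expr <- lapply(RNA_CLASSES, function(cl) norm_fun[[cl]](counts[[cl]]))
  names(expr) <- RNA_CLASSES

  de <- lapply(RNA_CLASSES, function(cl) {
    how <- if (cl == "miRNA") "per_million" else "size_factors"
    classify_de(nb_wald_test(counts[[cl]], samples, normalize = how), cfg)
  })
  names(de) <- RNA_CLASSES

  mirna_pairs <- filter_mirna_pairs(target_map, de, expr, cfg)
  candidates <- candidate_cerna_pairs(mirna_pairs, expr, cfg)
  cerna_pairs <- score_cerna_pairs(candidates, mirna_pairs, cfg)
  network <- build_cerna_network(cerna_pairs, mirna_pairs, de,
                                 include_lnc_mrna_edges = include_lnc_mrna_edges)

  out <- list(de = de, expr = expr, mirna_pairs = mirna_pairs,
              candidates = candidates, cerna_pairs = cerna_pairs,
              network = network, cfg = cfg)
  class(out) <- "cerna_pipeline"
  out
}

#' @export
print.cerna_pipeline <- function(x, ...) {
  cat("<cerna_pipeline>\n")
  for (cl in RNA_CLASSES) {
    g <- glance(x$de[[cl]])
    cat(sprintf("  %-6s DE: %d features, %d up, %d down\n", cl,
                g$n_features, g$n_up, g$n_down))
  }
  cat(sprintf("  miRNA-target pairs passing SCC < %g: %d\n",
              x$cfg$scc_neg_max, sum(x$mirna_pairs$passes)))
  cat(sprintf("  lncRNA-mRNA candidates passing SCC > %g: %d\n",
              x$cfg$scc_pos_min, sum(x$candidates$passes)))
  cat(sprintf("  final ceRNA pairs (hypergeometric p < %g): %d\n",
              x$cfg$cerna_p_max, sum(x$cerna_pairs$final)))
  network_report(x$network)
  invisible(x)
}

#' Score discovered ceRNA pairs against planted ground truth
#'
#' Compares the final lncRNA-mRNA pairs of a pipeline run with the planted
#' pairs of [simulate_dataset()]: recall is the fraction of planted pairs
#' recovered, precision the fraction of reported pairs that were planted.
#'
#' @param cerna_pairs A `cerna_pairs` tibble (only `final` rows count).
#' @param truth Truth list from [simulate_dataset()].
#' @return A one-row tibble: `n_true`, `n_found`, `n_correct`, `recall`,
#'   `precision` (`NA` precision when nothing was reported).
#' @export
evaluate_against_truth <- function(cerna_pairs, truth) {
  found <- filter(as_tibble(cerna_pairs), .data$final)
  key <- function(d) paste(d$lncrna_id, d$mrna_id)
  n_correct <- length(intersect(key(found), key(truth$pairs)))
  tibble(n_true = nrow(truth$pairs), n_found = nrow(found),
         n_correct = n_correct,
         recall = if (nrow(truth$pairs) > 0) n_correct / nrow(truth$pairs)
                  else NA_real_,
         precision = if (nrow(found) > 0) n_correct / nrow(found)
                     else NA_real_)
}
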