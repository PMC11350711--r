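#' Read a term-annotation table
#'
#' A local annotation table for over-representation analysis: one row per
#' (term, gene) assignment with columns `term_id`, `term_name`, `namespace`
#' (`BP`, `MF`, `CC` or `pathway`) and `gene_id`. Duplicate
#' (term, gene) rows are collapsed.
#'
#' @param path Path to the tab-separated annotation table.
#' @return A tibble with the four columns above.
#' @export
read_annotation <- function(path) {
  an <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_annotation(an)
}

validate_annotation <- function(annotation) {
  need <- c("term_id", "term_name", "namespace", "gene_id")
  if (!all(need %in% names(annotation))) {
    abort(sprintf("annotation needs columns: %s", paste(need, collapse = ", ")))
  }
  bad <- setdiff(unique(annotation$namespace), c("BP", "MF", "CC", "pathway"))
  if (length(bad) > 0) {
    abort(sprintf("unknown namespace value(s): %s", paste(bad, collapse = ", ")))
  }
  distinct(as_tibble(annotation)[need], .data$term_id, .data$gene_id,
           .keep_all = TRUE)
}

#' Hypergeometric over-representation of a gene set
#'
#' Tests each annotated term for over-representation in a query gene set
#' with the same exact hypergeometric upper-tail kernel as the ceRNA
#' shared-miRNA test ([hypergeom_upper_tail()]). The universe defaults to
#' every gene present in the annotation table; query genes outside the
#' universe are dropped with a warning. Terms are `significant` at
#' `p < cfg$enrich_p_max` (raw p-values, matching the pipeline's other
#' filters; a Benjamini-Hochberg column is included for inspection).
#'
#' @param query Character vector of gene ids (e.g. significant DE features).
#' @param annotation Annotation tibble (see [read_annotation()]).
#' @param universe Optional character vector overriding the default
#'   universe (e.g. all tested features).
#' @param cfg A [run_config()].
#' @return A tibble sorted by `p`: `term_id`, `term_name`, `namespace`,
#'   `k_hits`, `n_query`, `K_term`, `N_universe`, `p`, `padj`,
#'   `significant`.
#' @export
enrich <- function(query, annotation, universe = NULL, cfg = run_config()) {
  validate_run_config(cfg)
  annotation <- validate_annotation(annotation)
  if (is.null(universe)) universe <- unique(annotation$gene_id)
  universe <- unique(as.character(universe))
  if (length(universe) == 0) abort("empty universe")
  query <- unique(as.character(query))
  if (length(query) == 0) abort("empty query")
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warn(sprintf("dropping %d query gene(s) outside the universe",
                 length(outside)))
    query <- intersect(query, universe)
  }
  if (length(query) == 0) abort("no query genes left inside the universe")

  annotation <- filter(annotation, .data$gene_id %in% universe)
  N <- length(universe)
  nq <- length(query)
  res <- annotation |>
    group_by(.data$term_id, .data$term_name, .data$namespace) |>
    summarise(K_term = dplyr::n_distinct(.data$gene_id),
              k_hits = dplyr::n_distinct(intersect(.data$gene_id, query)),
              .groups = "drop") |>
    mutate(n_query = nq, N_universe = N)
  res$p <- purrr::map2_dbl(res$K_term, res$k_hits, function(K, k) {
    hypergeom_upper_tail(N, K, nq, k)
  })
  res |>
    mutate(padj = p.adjust(.data$p, method = "BH"),
           significant = .data$p < cfg$enrich_p_max) |>
    select("term_id", "term_name", "namespace", "k_hits", "n_query",
           "K_term", "N_universe", "p", "padj", "significant") |>
    arrange(.data$p, .data$term_id)
}

#' Dot plot of enrichment results
#'
#' @param result Tibble from [enrich()].
#' @param top Number of top terms to show. Default 20.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(result, top = 20) {
  d <- head(arrange(result, .data$p), top)
  d$term_name <- factor(d$term_name, levels = rev(unique(d$term_name)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k_hits / .data$n_query,
                                  y = .data$term_name,
                                  size = .data$k_hits,
                                  colour = -log10(.data$p))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "gene ratio", y = NULL, size = "hits",
                  colour = "-log10 p") +
    ggplot2::theme_minimal()
}
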