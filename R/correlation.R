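#' Spearman rank correlation
#'
#' The Pearson correlation of average ranks (ties receive the mean of the
#' ranks they span). Returns `NA` when either vector is constant, since
#' ranks are then undefined for correlation purposes; callers exclude such
#' pairs rather than treating them as zero correlation.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A number in `[-1, 1]`, or `NA` if either vector is constant.
#' @examples
#' spearman_scc(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5)) # 0.8
#' @export
spearman_scc <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) abort("missing values are not supported")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) return(NA_real_)
  cor(rank(x), rank(y))
}

# expression row lookup: named list of normalized wide tibbles -> matrices
expr_matrices <- function(expr) {
  lapply(expr, count_matrix)
}

#' Filter predicted miRNA-target pairs by expression anticorrelation
#'
#' Restricts the predicted target map to interactions whose miRNA and
#' target are both significantly differentially expressed, computes the
#' Spearman correlation of their normalized expression across all samples,
#' and keeps pairs with `scc < cfg$scc_neg_max` (strictly; the default
#' -0.7 boundary itself is excluded). Edges that reference features absent
#' from the expression matrices are skipped with a warning and counted in
#' the `n_skipped` attribute. Pairs with constant expression in either
#' member are excluded (`scc` is `NA`).
#'
#' @param target_map Tibble with `mirna_id`, `target_id`, `target_class`.
#' @param de Named list of classified `de_results` (names `mRNA`, `miRNA`,
#'   `lncRNA`; the classes referenced by the map must be present).
#' @param expr Named list of normalized expression tibbles on the same
#'   samples, same names as `de`.
#' @param cfg A [run_config()].
#' @return A tibble of scored pairs: `mirna_id`, `target_id`,
#'   `target_class`, `pair_type` (`lncRNA-miRNA` or `miRNA-mRNA`), `scc`,
#'   `passes`.
#' @export
filter_mirna_pairs <- function(target_map, de, expr, cfg = run_config()) {
  validate_run_config(cfg)
  target_map <- validate_target_map(target_map)
  sig <- lapply(de, function(d) d$feature_id[d$significant])
  mats <- expr_matrices(expr)

  tm <- filter(target_map,
               .data$mirna_id %in% sig$miRNA,
               (.data$target_class == "mRNA" & .data$target_id %in% sig$mRNA) |
                 (.data$target_class == "lncRNA" & .data$target_id %in% sig$lncRNA))

  known <- purrr::map2_lgl(tm$target_id, tm$target_class, function(id, cl) {
    id %in% rownames(mats[[cl]])
  }) & tm$mirna_id %in% rownames(mats$miRNA)
  if (any(!known)) {
    warn(sprintf("skipping %d target-map edge(s) referencing unknown features",
                 sum(!known)))
  }
  tm <- tm[known, , drop = FALSE]

  scc <- purrr::pmap_dbl(tm, function(mirna_id, target_id, target_class) {
    spearman_scc(mats$miRNA[mirna_id, ], mats[[target_class]][target_id, ])
  })
  out <- mutate(tm,
                pair_type = if_else(.data$target_class == "lncRNA",
                                    "lncRNA-miRNA", "miRNA-mRNA"),
                scc = scc,
                passes = !is.na(scc) & scc < cfg$scc_neg_max)
  attr(out, "n_skipped") <- sum(!known)
  out
}

#' Candidate lncRNA-mRNA ceRNA pairs by shared miRNAs and co-expression
#'
#' Forms every lncRNA-mRNA pair that shares at least one passing miRNA
#' partner (from [filter_mirna_pairs()]), computes the Spearman correlation
#' of the pair's normalized expression, and keeps pairs with
#' `scc > cfg$scc_pos_min` (strictly; 0.9 itself is excluded). The shared
#' miRNA requirement precedes the hypergeometric test because that test is
#' undefined at zero overlap.
#'
#' @param mirna_pairs Result of [filter_mirna_pairs()].
#' @param expr Named list of normalized expression tibbles (`mRNA`,
#'   `lncRNA` used).
#' @param cfg A [run_config()].
#' @return A tibble with `lncrna_id`, `mrna_id`, `shared_mirnas` (list
#'   column), `k` (shared count), `scc`, `passes`.
#' @export
candidate_cerna_pairs <- function(mirna_pairs, expr, cfg = run_config()) {
  validate_run_config(cfg)
  passing <- filter(mirna_pairs, .data$passes)
  empty <- tibble(lncrna_id = character(), mrna_id = character(),
                  shared_mirnas = list(), k = integer(),
                  scc = numeric(), passes = logical())
  if (nrow(passing) == 0) return(empty)

  lnc_sets <- split(passing$mirna_id[passing$target_class == "lncRNA"],
                    passing$target_id[passing$target_class == "lncRNA"])
  mrna_sets <- split(passing$mirna_id[passing$target_class == "mRNA"],
                     passing$target_id[passing$target_class == "mRNA"])
  if (length(lnc_sets) == 0 || length(mrna_sets) == 0) return(empty)

  grid <- tidyr::expand_grid(lncrna_id = names(lnc_sets),
                             mrna_id = names(mrna_sets))
  grid$shared_mirnas <- purrr::map2(grid$lncrna_id, grid$mrna_id, function(l, m) {
    sort(intersect(lnc_sets[[l]], mrna_sets[[m]]))
  })
  grid$k <- lengths(grid$shared_mirnas)
  grid <- filter(grid, .data$k >= 1L)
  if (nrow(grid) == 0) return(empty)

  mats <- expr_matrices(expr)
  grid$scc <- purrr::map2_dbl(grid$lncrna_id, grid$mrna_id, function(l, m) {
    spearman_scc(mats$lncRNA[l, ], mats$mRNA[m, ])
  })
  mutate(grid, passes = !is.na(.data$scc) & .data$scc > cfg$scc_pos_min)
}
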