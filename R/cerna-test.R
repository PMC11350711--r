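#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` where `X` is the overlap between a uniformly drawn size-`n`
#' subset and `K` marked items among `N`. Exact (no normal approximation)
#' and symmetric in `K` and `n`. `k = 0` returns exactly 1.
#'
#' This one kernel backs both the shared-miRNA ceRNA test and the
#' term over-representation test.
#'
#' @param N Universe size.
#' @param K Number of marked items.
#' @param n Draw size.
#' @param k Observed overlap.
#' @return `P(X >= k)`, in `(0, 1]`.
#' @examples
#' hypergeom_upper_tail(10, 4, 3, 2) # 1/3
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  for (v in list(N = N, K = K, n = n, k = k)) {
    if (length(v) != 1 || is.na(v) || v < 0 || v != round(v)) {
      abort("N, K, n, k must be single non-negative integers")
    }
  }
  if (k > min(K, n)) abort("k must not exceed min(K, n)")
  if (max(K, n) > N) abort("K and n must not exceed N")
  if (k == 0) return(1)
  # exact upper tail via the hypergeometric CDF complement
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Score candidate ceRNA pairs by the shared-miRNA hypergeometric test
#'
#' For each SCC-passing lncRNA-mRNA candidate, tests whether the two
#' partners share more passing miRNAs than expected by chance. With `N` the
#' miRNA universe, `K` the size of the mRNA's passing-miRNA set, `n` the
#' size of the lncRNA's set and `k` their overlap, the p-value is
#' `P(X >= k)` under the hypergeometric distribution. A pair is `final`
#' when `hyper_p < cfg$cerna_p_max`.
#'
#' By default the universe `N` is the set of distinct miRNAs appearing in
#' any passing miRNA-target pair, pooled over both target classes — the set
#' the observed overlaps are actually drawn from. Setting
#' `universe = "de_mirnas"` uses all tested miRNAs in `de_mirnas` instead.
#'
#' @param candidates Result of [candidate_cerna_pairs()] (only rows with
#'   `passes` are scored).
#' @param mirna_pairs Result of [filter_mirna_pairs()]; defines the partner
#'   sets and the default universe.
#' @param cfg A [run_config()].
#' @param universe `"passing"` (default) or `"de_mirnas"`.
#' @param de_mirnas Classified miRNA `de_results`, required when
#'   `universe = "de_mirnas"`.
#' @return A `cerna_pairs` tibble sorted by `hyper_p` (ties: `scc`
#'   descending, then lexicographic ids): `lncrna_id`, `mrna_id`,
#'   `shared_mirnas`, `k`, `K`, `n`, `N`, `scc`, `hyper_p`, `padj`, `final`.
#' @export
score_cerna_pairs <- function(candidates, mirna_pairs, cfg = run_config(),
                              universe = c("passing", "de_mirnas"),
                              de_mirnas = NULL) {
  validate_run_config(cfg)
  universe <- match.arg(universe)
  passing <- filter(mirna_pairs, .data$passes)
  cand <- filter(candidates, .data$passes)

  out_cols <- function(x) {
    x <- select(x, "lncrna_id", "mrna_id", "shared_mirnas", "k", "K", "n",
                "N", "scc", "hyper_p", "padj", "final")
    class(x) <- c("cerna_pairs", class(x))
    x
  }
  if (nrow(cand) == 0) {
    return(out_cols(tibble(lncrna_id = character(), mrna_id = character(),
                           shared_mirnas = list(), k = integer(), K = integer(),
                           n = integer(), N = integer(), scc = numeric(),
                           hyper_p = numeric(), padj = numeric(),
                           final = logical())))
  }

  N <- if (universe == "passing") {
    length(unique(passing$mirna_id))
  } else {
    if (is.null(de_mirnas)) abort("`de_mirnas` needed for universe = \"de_mirnas\"")
    nrow(de_mirnas)
  }
  if (N == 0) {
    warn("empty miRNA universe; no pairs scored")
    return(out_cols(mutate(cand[0, ], K = integer(), n = integer(),
                           N = integer(), hyper_p = numeric(),
                           padj = numeric(), final = logical())))
  }

  lnc_sets <- split(passing$mirna_id[passing$target_class == "lncRNA"],
                    passing$target_id[passing$target_class == "lncRNA"])
  mrna_sets <- split(passing$mirna_id[passing$target_class == "mRNA"],
                     passing$target_id[passing$target_class == "mRNA"])

  cand$K <- unname(lengths(mrna_sets[cand$mrna_id]))
  cand$n <- unname(lengths(lnc_sets[cand$lncrna_id]))
  cand$N <- N
  cand$hyper_p <- purrr::pmap_dbl(select(cand, "N", "K", "n", "k"),
                                  function(N, K, n, k) {
                                    hypergeom_upper_tail(N, K, n, k)
                                  })
  cand$padj <- p.adjust(cand$hyper_p, method = "BH")
  cand$final <- cand$hyper_p < cfg$cerna_p_max
  cand <- arrange(cand, .data$hyper_p, desc(.data$scc),
                  .data$lncrna_id, .data$mrna_id)
  out_cols(cand)
}

#' @method tidy cerna_pairs
#' @export
tidy.cerna_pairs <- function(x, ...) {
  mutate(as_tibble(x), shared_mirnas = purrr::map_chr(.data$shared_mirnas,
                                                      paste, collapse = ";"))
}

#' @method glance cerna_pairs
#' @export
glance.cerna_pairs <- function(x, ...) {
  tibble(n_candidates = nrow(x), n_final = sum(x$final),
         n_mirna_universe = if (nrow(x) > 0) x$N[1] else NA_integer_)
}

#' Write a ceRNA pair table
#'
#' @param pairs A `cerna_pairs` tibble.
#' @param path Output TSV path; the shared miRNA set is `;`-joined.
#' @return `path`, invisibly.
#' @export
write_cerna_pairs <- function(pairs, path) {
  readr::write_tsv(tidy.cerna_pairs(pairs), path, progress = FALSE)
  invisible(path)
}
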