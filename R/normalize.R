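#' Median-of-ratios size factors
#'
#' Library-size normalization for mRNA/lncRNA counts: each sample's factor
#' is the median of its ratios to a pseudo-reference sample built as the
#' per-feature geometric mean, computed over features with positive counts
#' in every sample; factors are then rescaled to geometric mean 1. If no
#' feature is positive in all samples the function falls back to
#' upper-quartile factors (75th percentile of positive counts), with a
#' warning.
#'
#' @param counts Wide counts tibble (integer or effectively integer counts).
#' @param samples Optional sample sheet; used only to order/validate columns.
#' @return A tibble with columns `sample_id` and `size_factor`.
#' @examples
#' cts <- tibble::tibble(feature_id = c("g1", "g2", "g3"),
#'                       A = c(10, 100, 4), B = c(20, 200, 8))
#' size_factors(cts) # B is sequenced twice as deep as A
#' @export
size_factors <- function(counts, samples = NULL) {
  if (!is.null(samples)) counts <- check_counts(counts, samples)
  m <- count_matrix(counts)
  if (ncol(m) < 1) abort("no sample columns")
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos)) {
    warn("no feature is positive in all samples; using upper-quartile size factors")
    sf <- apply(m, 2, function(x) {
      x <- x[x > 0]
      if (length(x) == 0) abort("a sample has no positive counts")
      quantile(x, 0.75, names = FALSE)
    })
  } else {
    ref <- exp(rowMeans(log(m[all_pos, , drop = FALSE])))
    sf <- apply(m[all_pos, , drop = FALSE], 2, function(x) median(x / ref))
  }
  sf <- sf / exp(mean(log(sf)))
  tibble(sample_id = colnames(m), size_factor = unname(sf))
}

#' Divide counts by their size factors
#'
#' @param counts Wide counts tibble.
#' @param factors Result of [size_factors()], or a named numeric vector.
#' @return Normalized wide tibble of the same shape.
#' @export
normalize_by_size_factors <- function(counts, factors = size_factors(counts)) {
  m <- count_matrix(counts)
  if (is.data.frame(factors)) {
    factors <- setNames(factors$size_factor, factors$sample_id)
  }
  missing <- setdiff(colnames(m), names(factors))
  if (length(missing) > 0) {
    abort(sprintf("no size factor for sample(s): %s", paste(missing, collapse = ", ")))
  }
  out <- sweep(m, 2, factors[colnames(m)], "/")
  matrix_to_counts(out, attr(counts, "rna_class"))
}

#' Per-million normalization
#'
#' Scales each sample column to sum to one million. This is the conventional
#' per-million quantification for mature miRNA counts (no length term, since
#' mature miRNAs are all ~22 nt).
#'
#' @param counts Wide counts tibble.
#' @return Wide tibble with every sample column summing to `1e6`.
#' @export
normalize_per_million <- function(counts) {
  m <- count_matrix(counts)
  tot <- colSums(m)
  zero <- colnames(m)[tot == 0]
  if (length(zero) > 0) {
    abort(sprintf("cannot per-million normalize all-zero sample(s): %s",
                  paste(zero, collapse = ", ")))
  }
  matrix_to_counts(sweep(m, 2, tot, "/") * 1e6, attr(counts, "rna_class"))
}
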