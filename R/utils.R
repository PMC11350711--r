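# internal helpers shared across modules

RNA_CLASSES <- c("mRNA", "miRNA", "lncRNA")

#' Convert a wide counts tibble to a numeric matrix
#'
#' Counts travel through the pipeline as wide tibbles: a `feature_id` column
#' followed by one numeric column per sample. Internally most arithmetic is
#' done on a plain matrix with feature ids as rownames.
#'
#' @param counts Wide counts data frame (`feature_id` + sample columns).
#' @return Numeric matrix, features x samples.
#' @keywords internal
#' @noRd
count_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), "feature_id" %in% names(counts))
  m <- as.matrix(counts[setdiff(names(counts), "feature_id")])
  storage.mode(m) <- "double"
  rownames(m) <- counts$feature_id
  m
}

#' Rebuild the wide counts tibble from a matrix
#' @keywords internal
#' @noRd
matrix_to_counts <- function(m, rna_class = NULL) {
  out <- bind_cols(tibble(feature_id = rownames(m)), as_tibble(m))
  if (!is.null(rna_class)) attr(out, "rna_class") <- rna_class
  out
}

#' Validate a counts tibble against a sample sheet
#' @keywords internal
#' @noRd
check_counts <- function(counts, samples) {
  validate_sample_sheet(samples)
  dup <- counts$feature_id[duplicated(counts$feature_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate feature id(s): %s",
                  paste(unique(dup), collapse = ", ")))
  }
  missing <- setdiff(samples$sample_id, names(counts))
  if (length(missing) > 0) {
    abort(sprintf("count matrix is missing sample column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  m <- count_matrix(counts[c("feature_id", samples$sample_id)])
  if (anyNA(m)) abort("counts contain missing values")
  if (any(m < 0)) abort("counts must be non-negative")
  invisible(counts[c("feature_id", samples$sample_id)])
}

#' Group masks for the two-group design
#' @keywords internal
#' @noRd
group_index <- function(samples) {
  list(high = samples$sample_id[samples$group == "high"],
       low  = samples$sample_id[samples$group == "low"])
}
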