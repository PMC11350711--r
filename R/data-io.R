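#' Read a sample sheet
#'
#' The sample sheet maps sequencing libraries to the two growth-rate groups.
#' It is a tab-separated file with a header and at least the columns
#' `sample_id` and `group`; any further columns are kept as covariates.
#'
#' @param path Path to a tab-separated sample sheet.
#' @return A tibble with columns `sample_id`, `group` (factor with levels
#'   `high`, `low`) and any covariate columns.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_sample_sheet(sheet)
}

#' Validate a sample sheet
#'
#' Checks the two-group design contract: unique sample ids, groups limited
#' to `high`/`low`, both groups present with at least two samples each.
#'
#' @param sheet Data frame with columns `sample_id` and `group`.
#' @return The sheet as a tibble, invisibly validated, with `group` coerced
#'   to a factor with levels `high`, `low`.
#' @export
validate_sample_sheet <- function(sheet) {
  if (!all(c("sample_id", "group") %in% names(sheet))) {
    abort("sample sheet needs `sample_id` and `group` columns")
  }
  sheet <- as_tibble(sheet)
  sheet$sample_id <- as.character(sheet$sample_id)
  dup <- sheet$sample_id[duplicated(sheet$sample_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate sample id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  bad <- setdiff(unique(as.character(sheet$group)), c("high", "low"))
  if (length(bad) > 0) {
    abort(sprintf("unknown group label(s): %s (expected high/low)",
                  paste(bad, collapse = ", ")))
  }
  sheet$group <- factor(as.character(sheet$group), levels = c("high", "low"))
  sizes <- table(sheet$group)
  if (any(sizes < 2)) {
    abort("both groups must be present with at least 2 samples each")
  }
  sheet
}

#' Read a feature-by-sample count matrix
#'
#' Reads a tab-separated count file whose header row holds sample ids and
#' whose first column holds feature ids, reorders the columns to the sample
#' sheet order, and validates the result. Column order in the file is
#' irrelevant; a sheet sample missing from the file is a hard error naming
#' that sample, as is a duplicated feature id.
#'
#' @param path Path to the TSV file.
#' @param rna_class One of `"mRNA"`, `"miRNA"`, `"lncRNA"`.
#' @param samples Sample sheet (see [read_sample_sheet()]).
#' @return A wide counts tibble: `feature_id` plus one column per sample, in
#'   sample-sheet order, with the RNA class recorded in the `rna_class`
#'   attribute.
#' @export
read_counts <- function(path, rna_class = c("mRNA", "miRNA", "lncRNA"),
                        samples = NULL) {
  rna_class <- match.arg(rna_class)
  counts <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(sprintf("failed to parse %s: %s", path,
                                      conditionMessage(e))))
  prob <- readr::problems(counts)
  if (nrow(prob) > 0) {
    abort(sprintf("parse failure in %s at line(s) %s", path,
                  paste(unique(prob$row), collapse = ", ")))
  }
  names(counts)[1] <- "feature_id"
  counts$feature_id <- as.character(counts$feature_id)
  if (is.null(samples)) {
    samples <- tibble(sample_id = setdiff(names(counts), "feature_id"),
                      group = NA)
    counts <- as_tibble(counts)
  } else {
    counts <- check_counts(counts, samples)
  }
  attr(counts, "rna_class") <- rna_class
  counts
}

#' Write a count matrix
#'
#' @param counts Wide counts tibble.
#' @param path Output path (tab-separated, UTF-8, `.` decimal).
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read a predicted miRNA-target interaction table
#'
#' The table is the output of sequence-based target prediction, consumed
#' here as given: one row per predicted interaction with columns
#' `mirna_id`, `target_id` and `target_class` (`mRNA` or `lncRNA`).
#' Duplicate rows are collapsed.
#'
#' @param path Path to the tab-separated target table.
#' @return A tibble with the three columns above, deduplicated.
#' @export
read_target_map <- function(path) {
  tm <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_target_map(tm)
}

#' Validate a target map
#' @param target_map Data frame with `mirna_id`, `target_id`, `target_class`.
#' @return Deduplicated tibble.
#' @export
validate_target_map <- function(target_map) {
  need <- c("mirna_id", "target_id", "target_class")
  if (!all(need %in% names(target_map))) {
    abort(sprintf("target map needs columns: %s", paste(need, collapse = ", ")))
  }
  tm <- as_tibble(target_map)[need]
  bad <- setdiff(unique(tm$target_class), c("mRNA", "lncRNA"))
  if (length(bad) > 0) {
    abort(sprintf("unknown target_class value(s): %s", paste(bad, collapse = ", ")))
  }
  distinct(tm)
}

#' Write a target map
#' @param target_map Target-map tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_target_map <- function(target_map, path) {
  readr::write_tsv(validate_target_map(target_map), path, progress = FALSE)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' Long-format cycle-threshold measurements: one row per well, with columns
#' `sample_id`, `gene_id`, `replicate` and `ct`.
#'
#' @param path Path to the tab-separated Ct table.
#' @return A tibble with the four columns above.
#' @export
read_ct_table <- function(path) {
  ct <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "gene_id", "replicate", "ct")
  if (!all(need %in% names(ct))) {
    abort(sprintf("Ct table needs columns: %s", paste(need, collapse = ", ")))
  }
  if (any(!is.finite(ct$ct))) abort("Ct values must be finite")
  as_tibble(ct)[need]
}
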