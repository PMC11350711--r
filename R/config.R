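#' Pipeline thresholds and run configuration
#'
#' Bundles the filtering thresholds used throughout the pipeline. The
#' defaults are the conventional ones for this kind of two-group ceRNA
#' screen: differential expression at |log2 fold-change| >= 1 and p < 0.05,
#' miRNA-target pairs kept at Spearman correlation < -0.7, lncRNA-mRNA
#' candidates at Spearman correlation > 0.9, the shared-miRNA hypergeometric
#' test and the enrichment test both at p < 0.05. All p-value cuts are on
#' raw (unadjusted) p-values; Benjamini-Hochberg columns are emitted
#' alongside for inspection but play no role in the default filtering.
#'
#' @param lfc_min Minimum absolute log2 fold-change for a feature to count
#'   as differentially expressed. Default 1 (two-fold).
#' @param p_max Differential-expression p-value cut (exclusive). Default 0.05.
#' @param scc_neg_max Upper bound (exclusive) on the Spearman correlation of
#'   a miRNA with its predicted target; pairs pass when `scc < scc_neg_max`.
#'   Must be negative. Default -0.7.
#' @param scc_pos_min Lower bound (exclusive) on the Spearman correlation of
#'   a candidate lncRNA-mRNA pair; pairs pass when `scc > scc_pos_min`.
#'   Must be positive. Default 0.9.
#' @param cerna_p_max Hypergeometric p-value cut (exclusive) for final ceRNA
#'   pairs. Default 0.05.
#' @param enrich_p_max Over-representation p-value cut (exclusive).
#'   Default 0.05.
#' @param seed Integer seed recorded with the run.
#' @param paths Optional named list of input/output paths, carried verbatim.
#'
#' @return A list of class `run_config`.
#' @examples
#' cfg <- run_config()
#' cfg$scc_neg_max
#' @export
run_config <- function(lfc_min = 1, p_max = 0.05,
                       scc_neg_max = -0.7, scc_pos_min = 0.9,
                       cerna_p_max = 0.05, enrich_p_max = 0.05,
                       seed = 1L, paths = list()) {
  cfg <- list(lfc_min = as.numeric(lfc_min), p_max = as.numeric(p_max),
              scc_neg_max = as.numeric(scc_neg_max),
              scc_pos_min = as.numeric(scc_pos_min),
              cerna_p_max = as.numeric(cerna_p_max),
              enrich_p_max = as.numeric(enrich_p_max),
              seed = as.integer(seed), paths = paths)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  for (p in c("p_max", "cerna_p_max", "enrich_p_max")) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 || v > 1) {
      abort(sprintf("`%s` must be a single number in (0, 1]", p))
    }
  }
  if (cfg$lfc_min < 0) abort("`lfc_min` must be non-negative")
  if (!(cfg$scc_neg_max < 0)) abort("`scc_neg_max` must be negative")
  if (!(cfg$scc_pos_min > 0)) abort("`scc_pos_min` must be positive")
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Recognised top-level keys are `thresholds` (with fields named as in
#' [run_config()]), `seed` and `paths`; anything missing falls back to the
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  th <- raw$thresholds %||% list()
  known <- c("lfc_min", "p_max", "scc_neg_max", "scc_pos_min",
             "cerna_p_max", "enrich_p_max")
  unknown <- setdiff(names(th), known)
  if (length(unknown) > 0) {
    warn(sprintf("ignoring unknown threshold key(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  args <- th[intersect(names(th), known)]
  args$seed <- raw$seed %||% 1L
  args$paths <- raw$paths %||% list()
  do.call(run_config, args)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(sprintf("  DE:          |log2FC| >= %g, p < %g\n", x$lfc_min, x$p_max))
  cat(sprintf("  miRNA-target SCC < %g; lncRNA-mRNA SCC > %g\n",
              x$scc_neg_max, x$scc_pos_min))
  cat(sprintf("  ceRNA hypergeometric p < %g; enrichment p < %g\n",
              x$cerna_p_max, x$enrich_p_max))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
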