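#' Relative expression by the 2^-ddCt method
#'
#' Computes per-sample relative quantities for a target gene against a
#' reference gene (GAPDH for mRNA/lncRNA assays, U6 for miRNA assays):
#' technical replicates are averaged first, then
#' `dCt_s = Ct_target,s - Ct_ref,s`,
#' `ddCt_s = dCt_s - mean(dCt over the calibrator group)`, and
#' `RQ_s = 2^-ddCt_s`. The calibrator defaults to the low group so that
#' `RQ > 1` in the high group means upregulated there, matching the sign of
#' the sequencing log2 fold-change. Groups are compared with a two-sided
#' two-sample t-test, by default on `log2(RQ)` (equivalently on ddCt;
#' variance-stabilized), optionally on raw RQ.
#'
#' @param ct Long Ct tibble (`sample_id`, `gene_id`, `replicate`, `ct`).
#' @param samples Sample sheet mapping `sample_id` to `group`.
#' @param target Target gene id.
#' @param reference Reference gene id (default `"GAPDH"`).
#' @param calibrator Calibrator group, `"low"` (default) or `"high"`.
#' @param on_log Perform the t-test on `log2(RQ)` (default `TRUE`).
#' @return A `ddct_result` list: `$samples` (per-sample `dct`, `ddct`,
#'   `rq`), `$summary` (per-group mean/SD of RQ), and `$test`
#'   (`t`, `df`, `p_value`, `log2_rq_ratio` = mean log2 RQ difference,
#'   high minus low). `tidy()` returns `$samples`, `glance()` one row.
#' @export
ddct_relative_expression <- function(ct, samples, target,
                                     reference = "GAPDH",
                                     calibrator = c("low", "high"),
                                     on_log = TRUE) {
  calibrator <- match.arg(calibrator)
  samples <- validate_sample_sheet(samples)
  ct <- as_tibble(ct)
  mean_ct <- ct |>
    filter(.data$gene_id %in% c(target, reference),
           .data$sample_id %in% samples$sample_id) |>
    group_by(.data$sample_id, .data$gene_id) |>
    summarise(ct = mean(.data$ct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "gene_id", values_from = "ct")
  if (!reference %in% names(mean_ct) ||
      anyNA(mean_ct[[reference]][match(samples$sample_id, mean_ct$sample_id)])) {
    abort(sprintf("reference gene %s missing for some sample(s)", reference))
  }
  if (!target %in% names(mean_ct) ||
      anyNA(mean_ct[[target]][match(samples$sample_id, mean_ct$sample_id)])) {
    abort(sprintf("target gene %s missing for some sample(s)", target))
  }

  d <- mean_ct |>
    mutate(dct = .data[[target]] - .data[[reference]]) |>
    left_join(select(samples, "sample_id", "group"), by = "sample_id")
  cal_mean <- mean(d$dct[d$group == calibrator])
  d <- d |>
    mutate(ddct = .data$dct - cal_mean, rq = 2^-.data$ddct) |>
    select("sample_id", "group", "dct", "ddct", "rq")

  smry <- d |>
    group_by(.data$group) |>
    summarise(mean_rq = mean(.data$rq), sd_rq = sd(.data$rq),
              n = n(), .groups = "drop")

  y <- if (on_log) log2(d$rq) else d$rq
  yh <- y[d$group == "high"]; yl <- y[d$group == "low"]
  # computed from summaries so exact noise-free fixtures (zero within-group
  # variance) degrade gracefully instead of erroring
  tt0 <- suppressWarnings(
    t_test_from_summary(mean(yh), sd(yh), length(yh),
                        mean(yl), sd(yl), length(yl), variant = "pooled"))
  tt <- list(statistic = c(t = tt0$t), parameter = c(df = tt0$df),
             p.value = tt0$p_value)
  res <- list(samples = d, summary = smry, target = target,
              reference = reference, calibrator = calibrator,
              test = tibble(t = unname(tt$statistic),
                            df = unname(tt$parameter),
                            p_value = tt$p.value,
                            log2_rq_ratio = mean(log2(d$rq[d$group == "high"])) -
                              mean(log2(d$rq[d$group == "low"]))))
  class(res) <- "ddct_result"
  res
}

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf("<ddct_result> %s vs %s (calibrator: %s group)\n",
              x$target, x$reference, x$calibrator))
  print(x$summary)
  print(x$test)
  invisible(x)
}

#' @method tidy ddct_result
#' @export
tidy.ddct_result <- function(x, ...) x$samples

#' @method glance ddct_result
#' @export
glance.ddct_result <- function(x, ...) {
  bind_cols(tibble(target = x$target),
            tidyr::pivot_wider(select(x$summary, "group", "mean_rq"),
                               names_from = "group", values_from = "mean_rq",
                               names_prefix = "mean_rq_"),
            x$test)
}
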