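#' Two-sample t-test from printed summary statistics
#'
#' Computes the independent-samples t-test directly from per-group
#' (mean, SD, n) summaries, as needed when only a published table is
#' available. `variant = "pooled"` is the classical equal-variance test with
#' `n1 + n2 - 2` degrees of freedom; `variant = "welch"` uses the
#' Satterthwaite approximation. With equal group sizes the t statistic is
#' identical under both variants; only the degrees of freedom (and hence p)
#' differ.
#'
#' Degenerate inputs: if both SDs are zero the p-value is 1 when the means
#' are equal and 0 (with a warning) when they differ.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @param variant `"pooled"` or `"welch"`.
#' @return A one-row tibble: `t`, `df`, `p_value`, and the significance
#'   `letters` pattern (see [significance_letters()]).
#' @examples
#' t_test_from_summary(148.38, 8.97, 4, 88.75, 9.13, 4)
#' @export
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) {
      t <- 0; df <- n1 + n2 - 2; p <- 1
    } else {
      warn("both SDs are zero with different means; p set to 0")
      t <- Inf * sign(mean1 - mean2); df <- n1 + n2 - 2; p <- 0
    }
  } else if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    p <- 2 * pt(-abs(t), df)
  } else {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    t <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
    p <- 2 * pt(-abs(t), df)
  }
  tibble(t = t, df = df, p_value = p, letters = significance_letters(p))
}

#' Significance letter pattern from a p-value
#'
#' The usual animal-science table annotation: different uppercase letters
#' (`"A/B"`) for p < 0.01, different lowercase letters (`"a/b"`) for
#' 0.01 <= p < 0.05, and the same letter (`"a/a"`) for p >= 0.05.
#'
#' @param p P-value(s).
#' @return Character vector of `"A/B"`, `"a/b"` or `"a/a"`.
#' @export
significance_letters <- function(p) {
  dplyr::case_when(p < 0.01 ~ "A/B", p < 0.05 ~ "a/b", .default = "a/a")
}

#' Compare groups for every trait in a summary table
#'
#' Takes a long summary table — one row per (trait, group) with columns
#' `trait`, `group`, `mean`, `sd`, `n` — and runs
#' [t_test_from_summary()] for each trait under the requested variant.
#' Rows with `|t| > 50` are flagged `suspicious`: such t values from a
#' published table usually indicate an SD column that actually holds
#' standard errors, or a typo.
#'
#' @param summaries Long summary data frame (two groups per trait).
#' @param variant `"pooled"` or `"welch"`.
#' @return A tibble with one row per trait: group means, `t`, `df`,
#'   `p_value`, `letters`, `suspicious`.
#' @export
compare_group_summaries <- function(summaries, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  need <- c("trait", "group", "mean", "sd", "n")
  if (!all(need %in% names(summaries))) {
    abort(sprintf("summary table needs columns: %s", paste(need, collapse = ", ")))
  }
  summaries |>
    group_by(.data$trait) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) != 2) abort(sprintf("trait %s must have exactly 2 groups", key$trait))
      d <- arrange(d, .data$group)  # high first, then low
      r <- t_test_from_summary(d$mean[1], d$sd[1], d$n[1],
                               d$mean[2], d$sd[2], d$n[2], variant = variant)
      bind_cols(tibble(mean_high = d$mean[1], sd_high = d$sd[1],
                       mean_low = d$mean[2], sd_low = d$sd[2],
                       n = d$n[1]), r)
    }) |>
    ungroup() |>
    mutate(suspicious = is.infinite(.data$t) | abs(.data$t) > 50)
}

#' Choose the t-test variant from a variance-homogeneity gate
#'
#' Brown-Forsythe test (Levene's test centred at the group medians) on raw
#' per-animal data: if its p-value is >= 0.05 the pooled-variance t-test is
#' used, otherwise Welch. Only applicable to raw data; summary tables carry
#' no variance-homogeneity information beyond the SDs themselves.
#'
#' @param data Long data frame with columns `group` and `value`.
#' @return `"pooled"` or `"welch"`.
#' @export
levene_gate <- function(data) {
  stopifnot(all(c("group", "value") %in% names(data)))
  g <- factor(data$group)
  if (nlevels(g) < 2) abort("need at least 2 groups")
  lt <- car::leveneTest(data$value, g, center = median)
  if (lt[1, "Pr(>F)"] >= 0.05) "pooled" else "welch"
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA on raw per-animal data. With
#' exactly two groups the F statistic equals the square of the pooled
#' two-sample t statistic.
#'
#' @param data Long data frame with columns `group` and `value`.
#' @return A one-row tibble: `F`, `df1`, `df2`, `p_value`.
#' @export
one_way_anova <- function(data) {
  stopifnot(all(c("group", "value") %in% names(data)))
  if (var(data$value) == 0) {
    g <- factor(data$group)
    return(tibble(F = 0, df1 = nlevels(g) - 1L,
                  df2 = length(data$value) - nlevels(g), p_value = 1))
  }
  a <- anova(lm(value ~ factor(group), data = data))
  tibble(F = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
         p_value = a$`Pr(>F)`[1])
}

#' Compare two groups from raw per-animal records
#'
#' For each trait in a long phenotype table (`trait`, `group`, `animal`,
#' `value`), gates the t-test variant with [levene_gate()], computes the
#' group summaries and the t-test, and annotates significance letters.
#'
#' @param data Long phenotype data frame.
#' @return A tibble with one row per trait, as in
#'   [compare_group_summaries()], plus the chosen `variant`.
#' @export
compare_groups_raw <- function(data) {
  need <- c("trait", "group", "value")
  if (!all(need %in% names(data))) {
    abort(sprintf("phenotype table needs columns: %s", paste(need, collapse = ", ")))
  }
  data |>
    group_by(.data$trait) |>
    dplyr::group_modify(function(d, key) {
      variant <- if (var(d$value) == 0) "pooled" else levene_gate(d)
      smry <- d |>
        group_by(.data$group) |>
        summarise(mean = mean(.data$value), sd = sd(.data$value), n = n(),
                  .groups = "drop") |>
        mutate(trait = key$trait)
      r <- compare_group_summaries(smry, variant = variant)
      mutate(select(r, -"trait"), variant = variant)
    }) |>
    ungroup()
}
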