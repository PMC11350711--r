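#' Published group summaries for pig meat-production traits
#'
#' The printed mean ± SD summaries (n = 4 per group) of carcass and
#' meat-quality traits, serum biochemical indices, muscle fiber diameter
#' and muscle fiber type proportions for fast- (`high`) versus
#' slow-growing (`low`) crossbred pigs, together with the significance
#' letters as printed: different lowercase letters mark p < 0.05,
#' different uppercase letters p < 0.01, and an empty letter marks a
#' non-significant comparison. These summaries are the worked-example
#' input for [compare_group_summaries()]; note that a few printed rows are
#' internally inconsistent (SD columns implausibly small for a biological
#' replicate, letters not supported by the printed mean/SD at n = 4), which
#' the `suspicious` flag of [compare_group_summaries()] helps surface.
#'
#' @param panel Optional subset: any of `"carcass_meat"`, `"serum"`,
#'   `"fiber_diameter"`, `"fiber_type"`. Default all.
#' @return A long tibble: `panel`, `trait`, `group`, `mean`, `sd`, `n`,
#'   `letter` (`NA` where no letter is printed).
#' @export
pig_trait_summaries <- function(panel = NULL) {
  path <- system.file("extdata", "pig_trait_summaries.tsv",
                      package = "spongenet", mustWork = TRUE)
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         panel = readr::col_character(),
                         trait = readr::col_character(),
                         group = readr::col_character(),
                         mean = readr::col_double(),
                         sd = readr::col_double(),
                         n = readr::col_integer(),
                         letter = readr::col_character()))
  if (!is.null(panel)) {
    panel <- match.arg(panel, unique(d$panel), several.ok = TRUE)
    d <- filter(d, .data$panel %in% !!panel)
  }
  d
}

#' Printed significance pattern of a trait row
#'
#' Converts a pair of printed letters into the same `"A/B"` / `"a/b"` /
#' `"a/a"` pattern that [significance_letters()] produces from a p-value,
#' so printed tables and recomputed tests can be compared directly.
#'
#' @param letter_high,letter_low Letters printed for the two groups
#'   (`NA` or `""` for none).
#' @return `"A/B"`, `"a/b"` or `"a/a"`.
#' @export
printed_letter_pattern <- function(letter_high, letter_low) {
  l1 <- dplyr::coalesce(letter_high, "")
  l2 <- dplyr::coalesce(letter_low, "")
  same <- l1 == l2
  upper <- l1 %in% LETTERS & l2 %in% LETTERS
  dplyr::case_when(same ~ "a/a", upper ~ "A/B", .default = "a/b")
}
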