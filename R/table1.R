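## Embedded printed surveillance table: per-stratum numerators and
## denominators for the two phenotypes, together with the published
## prevalences, differences, 90% CI bounds and equivalence decisions.

#' Printed per-stratum counts for the two computable phenotypes
#'
#' The published comparison table for prevalence year 2022: numerator `n`
#' and denominator `N` for each phenotype in each demographic stratum, plus
#' the printed prevalences (percent, one decimal), percentage-point
#' differences, 90% confidence interval bounds and the printed
#' reject-the-null (i.e. "equivalent") decision.
#'
#' @return A `data.table`, one row per stratum (three age groups, five
#'   race/ethnicity groups, two sexes, overall).
#' @export
table1_counts <- function() {
  data.table::data.table(
    dimension = c(rep("age_group", 3), rep("race_ethnicity", 5),
                  rep("sex", 2), "overall"),
    level = c("18-24", "25-34", "35-44",
              "african_american", "asian", "hispanic", "white", "other",
              "female", "male", "overall"),
    n1 = c(1506L, 4105L, 8394L, 3401L, 353L, 2063L, 7853L, 335L,
           8009L, 5996L, 14005L),
    N1 = c(88952L, 128848L, 121714L, 62064L, 8900L, 38432L, 210135L, 19983L,
           207979L, 131535L, 339514L),
    n2 = c(412L, 4568L, 13589L, 4393L, 696L, 2253L, 9706L, 1521L,
           10488L, 8081L, 18569L),
    N2 = c(196113L, 302385L, 276832L, 118634L, 28771L, 74144L, 457682L, 96099L,
           428534L, 346796L, 775330L),
    prev1_printed = c(1.7, 3.2, 6.9, 5.5, 4.0, 5.4, 3.7, 1.7, 3.9, 4.6, 4.1),
    prev2_printed = c(0.2, 1.5, 4.9, 3.7, 2.4, 3.0, 2.1, 1.6, 2.4, 2.3, 2.4),
    diff_printed = c(1.5, 1.7, 2.0, 1.8, 1.6, 2.4, 1.6, 0.1, 1.5, 2.3, 1.7),
    ci_low_printed = c(1.4, 1.6, 1.9, 1.6, 1.2, 2.2, 1.5, -0.1, 1.4, 2.2, 1.6),
    ci_high_printed = c(1.6, 1.8, 2.1, 2.0, 2.0, 2.6, 1.7, 0.3, 1.6, 2.4, 1.8),
    equivalent_printed = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE,
                           TRUE, TRUE, TRUE)
  )
}

#' Recompute the printed comparison table from its embedded counts
#'
#' Runs the prevalence and TOST stages on the embedded printed numerators
#' and denominators under the `printed_table` convention (interval centred
#' on the difference of one-decimal rounded prevalences; standard error
#' from unrounded proportions) and compares every derived cell with the
#' printed value.
#'
#' @param delta Equivalence margin in percentage points (2.5 as published).
#' @param alpha One-sided level (0.05, i.e. 90% CIs).
#' @return A `data.table` with the computed prevalences, difference, CI
#'   bounds and decision per stratum, the printed values, and logical
#'   `match_*` flags per cell.
#' @export
reproduce_table1 <- function(delta = 2.5, alpha = 0.05) {
  tab <- table1_counts()
  res <- equivalence_table(
    tab[, .(dimension, level, numerator = n1, denominator = N1)],
    tab[, .(dimension, level, numerator = n2, denominator = N2)],
    delta = delta, alpha = alpha, convention = "printed_table")
  out <- merge(tab, res[, .(dimension, level, p1_hat, p2_hat, diff, ci_low,
                            ci_high, p_tost, equivalent)],
               by = c("dimension", "level"), sort = FALSE)
  out[, `:=`(
    prev1_computed = round_half_up(p1_hat, 1),
    prev2_computed = round_half_up(p2_hat, 1),
    diff_computed = round_half_up(diff, 1),
    ci_low_computed = round_half_up(ci_low, 1),
    ci_high_computed = round_half_up(ci_high, 1)
  )]
  out[, `:=`(
    match_prev1 = prev1_computed == prev1_printed,
    match_prev2 = prev2_computed == prev2_printed,
    match_diff = diff_computed == diff_printed,
    match_ci_low = ci_low_computed == ci_low_printed,
    match_ci_high = ci_high_computed == ci_high_printed,
    match_decision = equivalent == equivalent_printed
  )]
  out[]
}
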