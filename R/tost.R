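## Two one-sided tests (TOST) of equivalence for two independent
## proportions, on the percentage-point scale, with an unpooled Wald
## standard error and normal critical values.

#' TOST equivalence test for two independent proportions
#'
#' Tests whether two prevalence estimates `n1/N1` and `n2/N2` are
#' equivalent within a margin of `delta` percentage points: both one-sided
#' hypotheses (difference at or below `-delta`; difference at or above
#' `+delta`) are tested at level `alpha`, which is the same as checking
#' that the 100(1-2*alpha)% Wald confidence interval for the difference
#' lies strictly inside `(-delta, +delta)`.
#'
#' The standard error is always computed from the unrounded sample
#' proportions.  Under `convention = "analytic"` (the default for new
#' analyses) the interval is centred on the unrounded difference; under
#' `"printed_table"` it is centred on the difference of the two
#' one-decimal, half-up rounded prevalences, which is how published
#' surveillance tables are typically laid out.
#'
#' @param n1,N1 Numerator and denominator for the first proportion.
#' @param n2,N2 Numerator and denominator for the second proportion.
#' @param delta Equivalence margin in percentage points (default 2.5).
#' @param alpha One-sided significance level (default 0.05, yielding a 90%
#'   confidence interval).
#' @param convention `"analytic"` or `"printed_table"`.
#' @return An object of class `tost_result`: a list with the sample
#'   prevalences (`p1_hat`, `p2_hat`, percent), the centred difference
#'   `diff` and `se` (percentage points), the interval `ci_low`/`ci_high`,
#'   the one-sided statistics `z_lower`/`z_upper` with p-values
#'   `p_lower`/`p_upper`, `p_tost = max(p_lower, p_upper)`, the logical
#'   `equivalent` decision, and a `warnings` field noting degenerate
#'   proportions.
#' @examples
#' tost_two_proportions(14005, 339514, 18569, 775330,
#'                      convention = "printed_table")
#' @export
tost_two_proportions <- function(n1, N1, n2, N2, delta = 2.5, alpha = 0.05,
                                 convention = c("analytic", "printed_table")) {
  convention <- match.arg(convention)
  if (any(c(N1, N2) < 1)) stop("denominators must be >= 1")
  if (n1 < 0 || n1 > N1 || n2 < 0 || n2 > N2) stop("need 0 <= n <= N")
  if (delta < 0) stop("delta must be >= 0")
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must lie in (0, 0.5)")
  p1 <- n1 / N1
  p2 <- n2 / N2
  p1_hat <- 100 * p1
  p2_hat <- 100 * p2
  warnings <- character(0)
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1)) {
    warnings <- "degenerate proportion (0 or 1): Wald standard error understates uncertainty"
    warning(warnings)
  }
  se <- 100 * sqrt(p1 * (1 - p1) / N1 + p2 * (1 - p2) / N2)
  diff <- switch(convention,
                 analytic = p1_hat - p2_hat,
                 printed_table = round_half_up(p1_hat, 1) - round_half_up(p2_hat, 1))
  z <- stats::qnorm(1 - alpha)
  ci_low <- diff - z * se
  ci_high <- diff + z * se
  z_lower <- (diff + delta) / se
  z_upper <- (diff - delta) / se
  p_lower <- stats::pnorm(z_lower, lower.tail = FALSE)
  p_upper <- stats::pnorm(z_upper)
  structure(list(
    n1 = n1, N1 = N1, n2 = n2, N2 = N2,
    p1_hat = p1_hat, p2_hat = p2_hat,
    diff = diff, se = se, ci_low = ci_low, ci_high = ci_high,
    z_lower = z_lower, z_upper = z_upper,
    p_lower = p_lower, p_upper = p_upper,
    p_tost = max(p_lower, p_upper),
    equivalent = is.finite(se) && ci_low > -delta && ci_high < delta,
    delta = delta, alpha = alpha, convention = convention,
    warnings = warnings
  ), class = "tost_result")
}

#' @export
print.tost_result <- function(x, ...) {
  cat(sprintf("TOST equivalence of two proportions (margin %.2f pp, alpha %.3f, %s)\n",
              x$delta, x$alpha, x$convention))
  cat(sprintf("  p1 = %d/%d = %.2f%%   p2 = %d/%d = %.2f%%\n",
              x$n1, x$N1, x$p1_hat, x$n2, x$N2, x$p2_hat))
  cat(sprintf("  diff = %.3f pp, %d%% CI (%.3f, %.3f), p_tost = %.4g\n",
              x$diff, round(100 * (1 - 2 * x$alpha)), x$ci_low, x$ci_high, x$p_tost))
  cat(sprintf("  equivalent: %s\n", ifelse(x$equivalent, "yes", "no")))
  invisible(x)
}

#' Per-stratum TOST table from two matched prevalence tables
#'
#' @param counts_cp1,counts_cp2 Prevalence tables from [prevalence_table()]
#'   (columns `dimension`, `level`, `numerator`, `denominator`), with
#'   strata matching one-to-one.
#' @param delta,alpha,convention Passed to [tost_two_proportions()].
#' @return A `data.table` with one row per stratum: counts, prevalences,
#'   difference, CI bounds, `p_tost` and the `equivalent` decision.
#' @export
equivalence_table <- function(counts_cp1, counts_cp2, delta = 2.5,
                              alpha = 0.05,
                              convention = c("analytic", "printed_table")) {
  convention <- match.arg(convention)
  a <- data.table::as.data.table(counts_cp1)
  b <- data.table::as.data.table(counts_cp2)
  key <- c("dimension", "level")
  only_a <- a[!b, on = key]
  only_b <- b[!a, on = key]
  if (nrow(only_a) || nrow(only_b)) {
    stop("unmatched strata: ",
         paste(unique(c(paste(only_a$dimension, only_a$level, sep = "/"),
                        paste(only_b$dimension, only_b$level, sep = "/"))),
               collapse = ", "))
  }
  m <- merge(a[, .(dimension, level, n1 = numerator, N1 = denominator)],
             b[, .(dimension, level, n2 = numerator, N2 = denominator)],
             by = key)
  res <- lapply(seq_len(nrow(m)), function(i) {
    r <- tost_two_proportions(m$n1[i], m$N1[i], m$n2[i], m$N2[i],
                              delta = delta, alpha = alpha,
                              convention = convention)
    data.table::data.table(
      dimension = m$dimension[i], level = m$level[i],
      n1 = r$n1, N1 = r$N1, n2 = r$n2, N2 = r$N2,
      p1_hat = r$p1_hat, p2_hat = r$p2_hat, diff = r$diff, se = r$se,
      ci_low = r$ci_low, ci_high = r$ci_high, p_tost = r$p_tost,
      equivalent = r$equivalent)
  })
  data.table::rbindlist(res)
}
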