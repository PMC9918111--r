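#' Analytic power for MR with a binary outcome
#'
#' Non-centrality approximation for the two-sided Wald test of an MR
#' estimate with a binary outcome: with `r2` the proportion of exposure
#' variance explained by the instrument, outcome case fraction `f` and
#' target odds ratio `OR` per unit of genetically determined exposure,
#' the test statistic is approximately normal with mean
#' \eqn{\mu = |\log OR| \sqrt{n\, r^2 f (1-f)}}, giving
#' \deqn{power = \Phi(\mu - z_{1-\alpha/2}) + \Phi(-\mu - z_{1-\alpha/2}).}
#' At `OR = 1` this returns exactly `alpha`; power is monotone in `n`,
#' `r2` and `|log OR|`.
#'
#' @param alpha Two-sided significance level.
#' @param n Outcome sample size.
#' @param r2 Variance of the exposure explained by the instrument/PRS.
#' @param or_target Odds ratio per unit genetically determined exposure.
#' @param case_fraction Outcome case fraction.
#' @return Power in `[0, 1]` (vectorized over the arguments).
#' @export
mr_power <- function(alpha = 0.05, n, r2, or_target, case_fraction) {
  stopifnot(all(alpha > 0 & alpha < 1), all(r2 > 0 & r2 < 1),
            all(case_fraction > 0 & case_fraction < 1))
  z <- stats::qnorm(1 - alpha / 2)
  mu <- abs(log(or_target)) *
    sqrt(n * r2 * case_fraction * (1 - case_fraction))
  stats::pnorm(mu - z) + stats::pnorm(-mu - z)
}

#' Power screen across a phenome
#'
#' Applies [mr_power()] to each phenotype's case fraction at one or more
#' target odds ratios and counts the phenotypes detectable at
#' `power_threshold`.
#'
#' @param case_fractions Named numeric vector of per-phenotype case
#'   fractions.
#' @param n Sample size.
#' @param r2 Instrument variance explained.
#' @param or_levels Odds ratios to screen (default 1.5 and 1.8, i.e. 50%
#'   and 80% risk increases).
#' @param alpha Two-sided level.
#' @param power_threshold Detectability threshold (default 0.8).
#' @return List with `table` (one row per phenotype, one power column per
#'   OR level) and `counts` (named count of phenotypes with power >=
#'   threshold at each OR).
#' @export
phenome_power_screen <- function(case_fractions, n, r2,
                                 or_levels = c(1.5, 1.8), alpha = 0.05,
                                 power_threshold = 0.8) {
  tab <- data.frame(phenotype = names(case_fractions),
                    case_fraction = unname(case_fractions),
                    stringsAsFactors = FALSE)
  counts <- integer(length(or_levels))
  for (k in seq_along(or_levels)) {
    pw <- mr_power(alpha, n, r2, or_levels[k], case_fractions)
    tab[[paste0("power_or_", or_levels[k])]] <- unname(pw)
    counts[k] <- sum(pw >= power_threshold)
  }
  names(counts) <- paste0("or_", or_levels)
  list(table = tab, counts = counts)
}
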