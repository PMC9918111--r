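#' Per-doubling odds-ratio scaling
#'
#' An MR log-odds coefficient expressed per unit increase in the log odds
#' of a binary exposure is rescaled to a per-doubling odds ratio by
#' multiplying by 0.693 before exponentiation. The literal constant 0.693
#' is the default (matching common reporting practice); `exact = TRUE`
#' uses `log(2)` at full precision.
#'
#' @param beta Log-odds coefficient(s).
#' @param exact Use `log(2)` instead of the literal 0.693.
#' @return Odds ratio(s) per doubling of exposure odds.
#' @export
per_doubling_or <- function(beta, exact = FALSE) {
  exp((if (exact) log(2) else 0.693) * beta)
}

doubling_const <- function(exact = FALSE) if (exact) log(2) else 0.693

new_mr_estimate <- function(method, beta, se, n_instruments,
                            p = NULL, df = NULL,
                            Q = NA_real_, Q_p = NA_real_,
                            egger_intercept = NA_real_,
                            egger_intercept_p = NA_real_,
                            exact_ln2 = FALSE) {
  if (is.null(p)) {
    p <- if (is.null(df)) 2 * stats::pnorm(-abs(beta / se)) else
      2 * stats::pt(-abs(beta / se), df)
  }
  ci <- beta + c(-1, 1) * 1.96 * se
  k <- doubling_const(exact_ln2)
  structure(list(
    method = method, beta = beta, se = se,
    ci_low = ci[1], ci_high = ci[2], p = p,
    or_per_doubling = exp(k * beta),
    or_ci_low = exp(k * ci[1]), or_ci_high = exp(k * ci[2]),
    n_instruments = n_instruments, Q = Q, Q_p = Q_p,
    egger_intercept = egger_intercept,
    egger_intercept_p = egger_intercept_p), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  inst <- if (is.na(x$n_instruments)) "" else
    sprintf(", %d instruments", x$n_instruments)
  cat(sprintf("%s: beta = %.4f (SE %.4f), p = %.3g%s\n",
              x$method, x$beta, x$se, x$p, inst))
  cat(sprintf("  OR per doubling of exposure odds: %.3f (95%% CI %.3f-%.3f)\n",
              x$or_per_doubling, x$or_ci_low, x$or_ci_high))
  if (is.finite(x$Q)) {
    cat(sprintf("  Cochran's Q = %.2f (p = %.3g)\n", x$Q, x$Q_p))
  }
  if (is.finite(x$egger_intercept)) {
    cat(sprintf("  Egger intercept = %.4f (p = %.3g)\n",
                x$egger_intercept, x$egger_intercept_p))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snp = x$n_instruments, beta = x$beta,
             se = x$se, ci_low = x$ci_low, ci_high = x$ci_high, p = x$p,
             or_per_doubling = x$or_per_doubling,
             or_ci_low = x$or_ci_low, or_ci_high = x$or_ci_high,
             Q = x$Q, Q_p = x$Q_p, egger_intercept = x$egger_intercept,
             egger_intercept_p = x$egger_intercept_p,
             stringsAsFactors = FALSE)
}

complement_allele <- function(a) chartr("ACGT", "TGCA", a)

is_palindromic_pair <- function(ea, oa) oa == complement_allele(ea)

#' Harmonize exposure and outcome summary statistics into an instrument set
#'
#' Aligns outcome effects to the exposure effect allele per variant:
#' allele swaps flip the outcome beta's sign and complement its allele
#' frequency; strand flips (allele complements) are recognized and aligned.
#' Palindromic (A/T, C/G) variants whose exposure effect-allele frequency
#' lies inside the intermediate band (inclusive) are excluded because their
#' strand cannot be resolved; palindromic variants outside the band are
#' aligned by frequency. With `strict_eaf_exclusion = TRUE` every variant
#' with exposure EAF inside the band is excluded regardless of its alleles.
#' Variants whose allele pairs are neither identical, swapped, nor
#' strand-flipped are dropped with reason `"incompatible alleles"`.
#'
#' @param exposure_stats,outcome_stats Data frames with columns `id`, `ea`,
#'   `oa`, `eaf`, `beta`, `se` and optionally `n`.
#' @param intermediate_band Length-2 inclusive EAF band (default
#'   `c(0.42, 0.58)`).
#' @param strict_eaf_exclusion Apply the band to all variants, not only
#'   palindromic ones.
#' @return An `instrument_set` data frame (one row per retained
#'   instrument) with columns `id`, `ea`, `oa`, `beta_exposure`,
#'   `se_exposure`, `eaf_exposure`, `beta_outcome`, `se_outcome`,
#'   `eaf_outcome`, `palindromic`, `f_stat`, `n_exposure`, `n_outcome`;
#'   attribute `log` records every dropped variant and its reason.
#' @export
harmonize <- function(exposure_stats, outcome_stats,
                      intermediate_band = c(0.42, 0.58),
                      strict_eaf_exclusion = FALSE) {
  ex <- exposure_stats; ou <- outcome_stats
  shared <- intersect(ex$id, ou$id)
  ex <- ex[match(shared, ex$id), , drop = FALSE]
  ou <- ou[match(shared, ou$id), , drop = FALSE]
  m <- length(shared)
  keep <- rep(TRUE, m); reason <- rep(NA_character_, m)
  flip <- rep(FALSE, m)

  pal <- is_palindromic_pair(ex$ea, ex$oa)
  in_band <- !is.na(ex$eaf) & ex$eaf >= intermediate_band[1] &
    ex$eaf <= intermediate_band[2]

  for (i in seq_len(m)) {
    ea_x <- ex$ea[i]; oa_x <- ex$oa[i]
    ea_y <- ou$ea[i]; oa_y <- ou$oa[i]
    if (pal[i]) {
      if (in_band[i]) {
        keep[i] <- FALSE; reason[i] <- "palindromic intermediate frequency"
        next
      }
      same_set <- setequal(c(ea_y, oa_y), c(ea_x, oa_x)) ||
        setequal(complement_allele(c(ea_y, oa_y)), c(ea_x, oa_x))
      if (!same_set) {
        keep[i] <- FALSE; reason[i] <- "incompatible alleles"
        next
      }
      # strand ambiguous: align by which side of 0.5 the frequencies fall
      if (!is.na(ou$eaf[i]) &&
          (ex$eaf[i] < 0.5) != (ou$eaf[i] < 0.5)) flip[i] <- TRUE
    } else if (ea_y == ea_x && oa_y == oa_x) {
      flip[i] <- FALSE
    } else if (ea_y == oa_x && oa_y == ea_x) {
      flip[i] <- TRUE
    } else if (complement_allele(ea_y) == ea_x &&
               complement_allele(oa_y) == oa_x) {
      flip[i] <- FALSE
    } else if (complement_allele(ea_y) == oa_x &&
               complement_allele(oa_y) == ea_x) {
      flip[i] <- TRUE
    } else {
      keep[i] <- FALSE; reason[i] <- "incompatible alleles"
    }
  }
  if (strict_eaf_exclusion) {
    drop_band <- keep & in_band
    keep[drop_band] <- FALSE
    reason[drop_band] <- "intermediate frequency (strict)"
  }

  log <- data.frame(id = shared[!keep], reason = reason[!keep],
                    stringsAsFactors = FALSE)
  ex <- ex[keep, , drop = FALSE]; ou <- ou[keep, , drop = FALSE]
  flip <- flip[keep]; pal <- pal[keep]
  b_out <- ifelse(flip, -ou$beta, ou$beta)
  eaf_out <- ifelse(flip, 1 - ou$eaf, ou$eaf)
  out <- data.frame(
    id = ex$id, ea = ex$ea, oa = ex$oa,
    beta_exposure = ex$beta, se_exposure = ex$se, eaf_exposure = ex$eaf,
    beta_outcome = b_out, se_outcome = ou$se, eaf_outcome = eaf_out,
    palindromic = pal,
    f_stat = (ex$beta / ex$se)^2,
    n_exposure = if ("n" %in% names(ex)) ex$n else NA_real_,
    n_outcome = if ("n" %in% names(ou)) ou$n else NA_real_,
    stringsAsFactors = FALSE)
  structure(out, log = log, class = c("instrument_set", "data.frame"))
}

#' Extract exposure- or outcome-side summary statistics from an
#' instrument set
#'
#' Returns standard summary-statistic tables aligned to the exposure
#' effect allele (useful for re-harmonization, reverse-direction analyses
#' and logging).
#'
#' @param instruments An `instrument_set`.
#' @return Data frame with `id`, `ea`, `oa`, `eaf`, `beta`, `se`, `p`, `n`.
#' @export
instruments_exposure <- function(instruments) {
  with(instruments, data.frame(
    id = id, ea = ea, oa = oa, eaf = eaf_exposure,
    beta = beta_exposure, se = se_exposure,
    p = 2 * stats::pnorm(-abs(beta_exposure / se_exposure)),
    n = n_exposure, stringsAsFactors = FALSE))
}

#' @rdname instruments_exposure
#' @export
instruments_outcome <- function(instruments) {
  with(instruments, data.frame(
    id = id, ea = ea, oa = oa, eaf = eaf_outcome,
    beta = beta_outcome, se = se_outcome,
    p = 2 * stats::pnorm(-abs(beta_outcome / se_outcome)),
    n = n_outcome, stringsAsFactors = FALSE))
}

as_instrument_set <- function(df) {
  structure(df, class = c("instrument_set", "data.frame"))
}

ratio_estimates <- function(instruments, second_order = FALSE) {
  g <- instruments$beta_exposure; sy <- instruments$se_outcome
  if (any(g == 0)) stop("Wald ratio undefined: zero exposure effect")
  b <- instruments$beta_outcome / g
  se <- if (second_order) {
    sqrt(sy^2 / g^2 +
           instruments$beta_outcome^2 * instruments$se_exposure^2 / g^4)
  } else sy / abs(g)
  list(b = b, se = se, w = 1 / se^2)
}

#' Wald ratio estimate from a single instrument
#'
#' The per-variant causal estimate: the variant-outcome effect divided by
#' the variant-exposure effect, with first-order (default) or second-order
#' delta-method standard error.
#'
#' @param beta_exposure,se_exposure Variant-exposure effect and SE.
#' @param beta_outcome,se_outcome Variant-outcome effect and SE.
#' @param second_order Include the exposure-side variance term in the SE.
#' @param exact_ln2 Use exact `log(2)` for the per-doubling OR.
#' @return An `mr_estimate`.
#' @export
wald_ratio <- function(beta_exposure, se_exposure, beta_outcome,
                       se_outcome, second_order = FALSE,
                       exact_ln2 = FALSE) {
  if (beta_exposure == 0) stop("Wald ratio undefined: zero exposure effect")
  b <- beta_outcome / beta_exposure
  se <- if (second_order) {
    sqrt(se_outcome^2 / beta_exposure^2 +
           beta_outcome^2 * se_exposure^2 / beta_exposure^4)
  } else se_outcome / abs(beta_exposure)
  new_mr_estimate("wald", b, se, 1L, exact_ln2 = exact_ln2)
}

#' Inverse-variance weighted MR estimate
#'
#' Per-instrument Wald ratios are meta-analyzed with inverse-variance
#' weights \eqn{w_j = 1/se(\hat\beta_j)^2}. Fixed-effect SE is
#' \eqn{(\sum w_j)^{-1/2}}; the multiplicative random-effects SE inflates
#' it by \eqn{\max(1, \sqrt{Q/(m-1)})}. `mode = "auto"` (default) uses
#' multiplicative random effects when heterogeneity is detected
#' (`Q_p < 0.05`, m >= 2) and fixed effects otherwise. With a single
#' instrument the estimate degenerates to the Wald ratio. Cochran's Q and
#' its p-value are attached.
#'
#' @param instruments An `instrument_set`.
#' @param mode `"auto"`, `"fixed"` or `"multiplicative_random"`.
#' @param second_order Second-order Wald-ratio SEs.
#' @param exact_ln2 Use exact `log(2)` for per-doubling ORs.
#' @return An `mr_estimate` with method `"ivw_fe"` or `"ivw_mre"`.
#' @export
ivw <- function(instruments, mode = c("auto", "fixed",
                                      "multiplicative_random"),
                second_order = FALSE, exact_ln2 = FALSE) {
  mode <- match.arg(mode)
  m <- nrow(instruments)
  stopifnot(m >= 1)
  r <- ratio_estimates(instruments, second_order)
  if (!any(is.finite(r$w))) stop("all instrument weights are non-finite")
  beta <- sum(r$w * r$b) / sum(r$w)
  se_fe <- sqrt(1 / sum(r$w))
  if (m == 1) {
    return(new_mr_estimate("ivw_fe", beta, se_fe, 1L,
                           exact_ln2 = exact_ln2))
  }
  Q <- sum(r$w * (r$b - beta)^2)
  Q_p <- stats::pchisq(Q, df = m - 1, lower.tail = FALSE)
  use_mre <- switch(mode, fixed = FALSE, multiplicative_random = TRUE,
                    auto = Q_p < 0.05)
  se <- if (use_mre) se_fe * max(1, sqrt(Q / (m - 1))) else se_fe
  new_mr_estimate(if (use_mre) "ivw_mre" else "ivw_fe", beta, se,
                  m, Q = Q, Q_p = Q_p, exact_ln2 = exact_ln2)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with a
#' free intercept, weights \eqn{1/\sigma_{Yj}^2}. Instruments are
#' re-oriented so all exposure effects are non-negative (the Egger
#' estimate is not invariant to allele orientation; this is the standard
#' convention). The slope is the causal estimate; a non-zero intercept
#' indicates directional pleiotropy. P-values use the t distribution with
#' m - 2 degrees of freedom.
#'
#' @param instruments An `instrument_set` with at least 3 rows.
#' @param exact_ln2 Use exact `log(2)` for per-doubling ORs.
#' @return An `mr_estimate` with `egger_intercept` and
#'   `egger_intercept_p` filled in.
#' @export
egger <- function(instruments, exact_ln2 = FALSE) {
  m <- nrow(instruments)
  if (m < 3) stop("insufficient instruments for Egger (need >= 3)")
  s <- sign(instruments$beta_exposure)
  s[s == 0] <- 1
  x <- instruments$beta_exposure * s
  y <- instruments$beta_outcome * s
  w <- 1 / instruments$se_outcome^2
  fit <- stats::lm(y ~ x, weights = w)
  cf <- summary(fit)$coefficients
  new_mr_estimate("egger", cf["x", 1], cf["x", 2], m,
                  p = 2 * stats::pt(-abs(cf["x", 3]), m - 2),
                  egger_intercept = cf["(Intercept)", 1],
                  egger_intercept_p =
                    2 * stats::pt(-abs(cf["(Intercept)", 3]), m - 2),
                  exact_ln2 = exact_ln2)
}

weighted_median_point <- function(b, w) {
  o <- order(b)
  b <- b[o]; w <- w[o]
  cw <- (cumsum(w) - 0.5 * w) / sum(w)
  if (cw[1] >= 0.5) return(b[1])
  below <- max(which(cw < 0.5))
  if (below == length(b)) return(b[length(b)])
  b[below] + (b[below + 1] - b[below]) *
    (0.5 - cw[below]) / (cw[below + 1] - cw[below])
}

#' Weighted median MR estimate
#'
#' The inverse-variance weighted median of the per-instrument Wald ratios
#' (cumulative-weight interpolation at 0.5), consistent when at least half
#' the weight comes from valid instruments. The SE is obtained by
#' parametric bootstrap: instrument effects are redrawn from their normal
#' sampling distributions and the weighted median recomputed.
#'
#' @param instruments An `instrument_set` with at least 3 rows.
#' @param n_boot Number of bootstrap draws (warning below 100).
#' @param seed Seed for the bootstrap.
#' @param exact_ln2 Use exact `log(2)` for per-doubling ORs.
#' @return An `mr_estimate`.
#' @export
weighted_median <- function(instruments, n_boot = 1000, seed = 1L,
                            exact_ln2 = FALSE) {
  m <- nrow(instruments)
  if (m < 3) stop("weighted median requires >= 3 instruments")
  if (n_boot < 100) warning("n_boot < 100: bootstrap SE will be unstable")
  r <- ratio_estimates(instruments)
  est <- weighted_median_point(r$b, r$w)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    g <- stats::rnorm(m, instruments$beta_exposure,
                      instruments$se_exposure)
    G <- stats::rnorm(m, instruments$beta_outcome, instruments$se_outcome)
    ok <- g != 0
    weighted_median_point(G[ok] / g[ok],
                          g[ok]^2 / instruments$se_outcome[ok]^2)
  }, 0)
  new_mr_estimate("weighted_median", est, stats::sd(boot), m,
                  exact_ln2 = exact_ln2)
}

weighted_mode_point <- function(b, w, bandwidth_factor) {
  if (bandwidth_factor <= 0) stop("zero bandwidth")
  mu <- sum(w * b) / sum(w)
  s <- sqrt(sum(w * (b - mu)^2) / sum(w))
  if (s == 0) return(b[1])
  h <- bandwidth_factor * 1.06 * s * length(b)^(-1 / 5)
  f <- function(x) {
    vapply(x, function(xx) sum(w * stats::dnorm((xx - b) / h)), 0)
  }
  grid <- seq(min(b), max(b), length.out = 512)
  fg <- f(grid)
  i <- which.max(fg)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  if (lo == hi) return(grid[i])
  stats::optimize(f, c(lo, hi), maximum = TRUE)$maximum
}

#' Weighted mode MR estimate
#'
#' The mode of the inverse-variance weighted kernel density of the Wald
#' ratios (normal kernel, bandwidth a weighted analogue of Silverman's
#' rule scaled by `bandwidth_factor`), consistent when the largest group
#' of instruments sharing a causal estimate are valid. SE by parametric
#' bootstrap.
#'
#' @inheritParams weighted_median
#' @param bandwidth_factor Multiplier on the Silverman-type bandwidth;
#'   must be positive.
#' @return An `mr_estimate`.
#' @export
weighted_mode <- function(instruments, bandwidth_factor = 1,
                          n_boot = 1000, seed = 1L, exact_ln2 = FALSE) {
  m <- nrow(instruments)
  if (m < 3) stop("weighted mode requires >= 3 instruments")
  if (bandwidth_factor <= 0) stop("zero bandwidth")
  if (n_boot < 100) warning("n_boot < 100: bootstrap SE will be unstable")
  r <- ratio_estimates(instruments)
  est <- weighted_mode_point(r$b, r$w, bandwidth_factor)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    g <- stats::rnorm(m, instruments$beta_exposure,
                      instruments$se_exposure)
    G <- stats::rnorm(m, instruments$beta_outcome, instruments$se_outcome)
    ok <- g != 0
    weighted_mode_point(G[ok] / g[ok],
                        g[ok]^2 / instruments$se_outcome[ok]^2,
                        bandwidth_factor)
  }, 0)
  new_mr_estimate("weighted_mode", est, stats::sd(boot), m,
                  exact_ln2 = exact_ln2)
}

#' Cochran's Q heterogeneity test across instruments
#'
#' \eqn{Q = \sum_j w_j (\hat\beta_j - \beta_{ref})^2} over the Wald
#' ratios with inverse-variance weights, compared to chi-square with
#' m - 1 degrees of freedom. When `beta_ref` is omitted the fixed-effect
#' IVW estimate is used.
#'
#' @param instruments An `instrument_set` with at least 2 rows.
#' @param beta_ref Reference causal estimate.
#' @return List with `Q`, `df`, `p`.
#' @export
cochran_q <- function(instruments, beta_ref = NULL) {
  m <- nrow(instruments)
  stopifnot(m >= 2)
  r <- ratio_estimates(instruments)
  if (is.null(beta_ref)) beta_ref <- sum(r$w * r$b) / sum(r$w)
  Q <- sum(r$w * (r$b - beta_ref)^2)
  list(Q = Q, df = m - 1,
       p = stats::pchisq(Q, df = m - 1, lower.tail = FALSE))
}

#' Steiger directionality test
#'
#' Compares the variance in exposure versus outcome explained by the
#' instruments. For binary traits the per-instrument variance explained is
#' approximated from the association Z statistic and sample size as
#' \eqn{r^2 = Z^2/(Z^2+n)}. The assumed causal direction is supported when
#' the instruments explain more variance in the exposure; the p-value is
#' from a Fisher z-test on the difference of the implied correlations.
#'
#' @param instruments An `instrument_set` with sample sizes `n_exposure`
#'   and `n_outcome`.
#' @return List with `direction_correct`, `p`, `r2_exposure`,
#'   `r2_outcome`.
#' @export
steiger <- function(instruments) {
  if (anyNA(instruments$n_exposure) || anyNA(instruments$n_outcome)) {
    stop("Steiger test requires sample sizes for both traits")
  }
  zx <- instruments$beta_exposure / instruments$se_exposure
  zy <- instruments$beta_outcome / instruments$se_outcome
  r2x <- zx^2 / (zx^2 + instruments$n_exposure)
  r2y <- zy^2 / (zy^2 + instruments$n_outcome)
  rx <- sqrt(sum(r2x)); ry <- sqrt(sum(r2y))
  nx <- mean(instruments$n_exposure); ny <- mean(instruments$n_outcome)
  z <- (atanh(pmin(rx, 0.999)) - atanh(pmin(ry, 0.999))) /
    sqrt(1 / (nx - 3) + 1 / (ny - 3))
  list(direction_correct = sum(r2x) > sum(r2y),
       p = 2 * stats::pnorm(-abs(z)),
       r2_exposure = sum(r2x), r2_outcome = sum(r2y))
}

#' Leave-one-out analysis
#'
#' Re-estimates the causal effect with each instrument removed in turn,
#' flagging any row whose confidence interval lies entirely on the
#' opposite sign of the full-set point estimate (i.e. the result would
#' reverse without that instrument).
#'
#' @param instruments An `instrument_set` with at least 3 rows.
#' @param estimator Estimating function taking an instrument set and
#'   returning an `mr_estimate` (default [ivw()] with fixed effects).
#' @return Data frame with one row per left-out instrument: `id_left_out`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `p`, `flagged`; attribute `full`
#'   holds the full-set estimate.
#' @export
leave_one_out <- function(instruments,
                          estimator = function(x) ivw(x, mode = "fixed")) {
  m <- nrow(instruments)
  if (m < 3) stop("leave-one-out requires >= 3 instruments")
  full <- estimator(as_instrument_set(instruments))
  rows <- lapply(seq_len(m), function(j) {
    e <- estimator(as_instrument_set(instruments[-j, , drop = FALSE]))
    data.frame(id_left_out = instruments$id[j], beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, p = e$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$flagged <- (full$beta > 0 & out$ci_high < 0) |
    (full$beta < 0 & out$ci_low > 0)
  structure(out, full = full)
}

#' Prune instruments associated with secondary (pleiotropic) traits
#'
#' Removes instruments whose association p-value with a secondary trait
#' (a risk factor of exposure and outcome) falls below `p_threshold`
#' (default the phenome-wide Bonferroni level 0.05/665 = 7.52e-5).
#'
#' @param instruments An `instrument_set`.
#' @param secondary_stats Data frame with columns `id` and `p`.
#' @param p_threshold Removal threshold.
#' @return The pruned `instrument_set`; attribute `removed` logs each
#'   removed variant and its secondary p-value.
#' @export
prune_pleiotropic <- function(instruments, secondary_stats,
                              p_threshold = 0.05 / 665) {
  sp <- secondary_stats$p[match(instruments$id, secondary_stats$id)]
  drop <- !is.na(sp) & sp < p_threshold
  removed <- data.frame(id = instruments$id[drop], secondary_p = sp[drop],
                        stringsAsFactors = FALSE)
  out <- as_instrument_set(instruments[!drop, , drop = FALSE])
  attr(out, "removed") <- removed
  attr(out, "log") <- attr(instruments, "log")
  out
}

#' Select genetic instruments from exposure summary statistics
#'
#' LD-clumps the exposure scan with the instrument-selection preset
#' (r-squared < 0.001 within 10,000 kb, p < 1e-5 by default) and reports
#' per-variant F-statistics \eqn{F_j = \hat\gamma_j^2/\sigma_{Xj}^2},
#' warning when any instrument is weak (F < 10).
#'
#' @param exposure_stats Exposure summary statistics.
#' @param ld_source Dosage matrix used as the LD reference.
#' @param p_threshold,r2_threshold,window_kb Selection parameters.
#' @return Data frame with `id` and `f_stat` for selected instruments.
#' @export
select_instruments <- function(exposure_stats, ld_source,
                               p_threshold = 1e-5, r2_threshold = 0.001,
                               window_kb = 10000) {
  ids <- clump(exposure_stats, ld_source, r2_threshold = r2_threshold,
               window_kb = window_kb, p_threshold = p_threshold)
  if (length(ids) == 0) stop("no instruments pass the selection threshold")
  ss <- exposure_stats[match(ids, exposure_stats$id), , drop = FALSE]
  f <- (ss$beta / ss$se)^2
  if (any(f < 10)) {
    warning(sum(f < 10), " instrument(s) with F < 10 (weak)")
  }
  data.frame(id = ids, f_stat = f, stringsAsFactors = FALSE)
}

#' Run the full two-sample MR estimator suite
#'
#' Convenience wrapper producing the standard per-method results table:
#' IVW (fixed and multiplicative random effects), MR-Egger, weighted
#' median and weighted mode, with Cochran's Q and the Egger intercept.
#'
#' @param instruments An `instrument_set`.
#' @param n_boot Bootstrap draws for median/mode SEs.
#' @param seed Seed for bootstraps.
#' @param exact_ln2 Use exact `log(2)` for per-doubling ORs.
#' @return Data frame with one row per method (see
#'   [as.data.frame.mr_estimate()]).
#' @export
mr_suite <- function(instruments, n_boot = 1000, seed = 1L,
                     exact_ln2 = FALSE) {
  m <- nrow(instruments)
  ests <- list(ivw(instruments, mode = "fixed", exact_ln2 = exact_ln2))
  if (m >= 2) {
    ests <- c(ests, list(ivw(instruments, mode = "multiplicative_random",
                             exact_ln2 = exact_ln2)))
  }
  if (m >= 3) {
    ests <- c(ests, list(
      egger(instruments, exact_ln2 = exact_ln2),
      weighted_median(instruments, n_boot = n_boot,
                      seed = child_seed(seed, "wm"),
                      exact_ln2 = exact_ln2),
      weighted_mode(instruments, n_boot = n_boot,
                    seed = child_seed(seed, "wmode"),
                    exact_ln2 = exact_ln2)))
  }
  do.call(rbind, lapply(ests, as.data.frame))
}
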