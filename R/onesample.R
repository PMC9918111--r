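#' One-sample Mendelian randomization by two-stage regression
#'
#' Two-stage predictor substitution for a binary exposure and binary
#' outcome: stage 1 regresses the exposure indicator on the scaled
#' polygenic score (plus covariates) by logistic regression; stage 2
#' regresses the outcome on the stage-1 fitted values taken on the linear
#' predictor (log-odds) scale, with the same covariates. The reported
#' coefficient is the stage-2 log-OR per unit of genetically predicted
#' exposure log-odds, so the per-doubling scaling (x 0.693) applies
#' directly. Standard errors are stage-2 Wald by default, with an optional
#' seeded nonparametric bootstrap that accounts for the generated
#' regressor.
#'
#' @param exposure Binary 0/1 exposure indicator.
#' @param outcome Binary 0/1 outcome indicator.
#' @param prs A `prs_profile` (or numeric vector of scaled scores) aligned
#'   with `exposure`/`outcome`.
#' @param covariates Optional covariate data frame (same alignment).
#' @param n_boot Bootstrap replicates for the SE (0 = Wald only).
#' @param seed Seed for the bootstrap.
#' @param exact_ln2 Use exact `log(2)` for the per-doubling OR.
#' @return An `mr_estimate` with method `"two_stage"`.
#' @export
two_stage_mr <- function(exposure, outcome, prs, covariates = NULL,
                         n_boot = 0, seed = 1L, exact_ln2 = FALSE) {
  s <- if (inherits(prs, "prs_profile")) prs$profiles$scaled_score else prs
  stopifnot(length(s) == length(exposure), length(s) == length(outcome))
  if (stats::sd(s) == 0) {
    stop("zero-variance polygenic score: stage-1 fitted values constant")
  }
  X0 <- if (is.null(covariates)) matrix(1, length(s), 1) else
    covariate_matrix(covariates)

  fit_stages <- function(idx) {
    X1 <- cbind(X0[idx, 1, drop = FALSE], prs = s[idx],
                X0[idx, -1, drop = FALSE])
    f1 <- logistic_fit(X1, exposure[idx])
    if (!f1$converged) stop("stage-1 logistic regression did not converge")
    lp <- as.vector(X1 %*% f1$coef)
    if (stats::sd(lp) == 0) stop("zero-variance fitted values in stage 1")
    X2 <- cbind(X0[idx, 1, drop = FALSE], fitted_exposure = lp,
                X0[idx, -1, drop = FALSE])
    f2 <- logistic_fit(X2, outcome[idx])
    c(beta = f2$coef[[2]], se = f2$se[[2]])
  }
  est <- fit_stages(seq_along(s))
  se <- est[["se"]]
  if (n_boot > 0) {
    set.seed(seed)
    bb <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(length(s), replace = TRUE)
      fit_stages(idx)[["beta"]]
    }, 0)
    se <- stats::sd(bb)
  }
  new_mr_estimate("two_stage", est[["beta"]], se, NA_integer_,
                  exact_ln2 = exact_ln2)
}
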