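# Small-scale simulation defaults used across the test files.

quick_config <- function(n = 4000, n_snps = 60, seed = 1L, ...) {
  args <- list(n_participants = n, n_snps = n_snps, ld_block_size = 5,
               ld_rho = 0, n_causal_snps = min(12, n_snps),
               h2_liability = 0.25, frac_palindromic = 0,
               frac_exclusion = 0, icd9_fraction = 0, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# Harmonized instrument set straight from the summary-level simulator.
make_instruments <- function(m = 30, beta = 0.1, seed = 1L, ...) {
  sim <- simulate_instruments(m = m, beta = beta, seed = seed, ...)
  harmonize(sim$exposure, sim$outcome)
}

# Truth-based PRS weights (no GWAS): the planted liability effects.
truth_weights <- function(dataset) {
  ids <- dataset$truth$causal_ids
  data.frame(id = ids,
             ea = dataset$variants$ea[match(ids, dataset$variants$id)],
             beta = unname(dataset$truth$b),
             stringsAsFactors = FALSE)
}

# Closed-form weighted-least-squares oracle for IVW / Egger, computed from
# first principles (normal equations), independent of the estimator code.
wls_oracle <- function(y, x, w, intercept = TRUE) {
  X <- if (intercept) cbind(1, x) else cbind(x)
  XtW <- t(X * w)
  coef <- solve(XtW %*% X, XtW %*% y)
  resid <- y - X %*% coef
  df <- length(y) - ncol(X)
  sigma2 <- sum(w * resid^2) / df
  V <- solve(XtW %*% X)
  list(coef = as.vector(coef), se = unname(sqrt(diag(V) * sigma2)),
       se_fixed = unname(sqrt(diag(V))))
}
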