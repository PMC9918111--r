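#' Per-variant logistic GWAS scan
#'
#' Fits a covariate-adjusted logistic regression of the binary trait on
#' each variant's dosage and reports Wald statistics. The cohorts produced
#' by the simulator are unrelated by construction, so plain logistic
#' regression (rather than a mixed model correcting for relatedness) is the
#' appropriate scan. Monomorphic variants and non-converged fits
#' (separation) are emitted as flagged records with `NA` statistics rather
#' than failing the scan.
#'
#' @param dataset A `cohort_dataset` (or any list with `dosage`,
#'   `variants`, `covariates`).
#' @param trait Binary 0/1 vector aligned with the dosage rows.
#' @param covariates Character vector of covariate column names (default
#'   age, sex and all principal-component columns) or a data frame.
#' @param subset Optional logical/integer row subset.
#' @param variants Optional character vector restricting the scan to these
#'   variant ids (e.g. selected instruments).
#' @return Data frame of summary statistics: `id`, `chrom`, `pos`, `ea`,
#'   `oa`, `eaf`, `beta`, `se`, `p`, `n`, `n_cases`, `flag`.
#' @export
gwas_scan <- function(dataset, trait, covariates = NULL, subset = NULL,
                      variants = NULL) {
  G <- dataset$dosage
  vmeta <- dataset$variants
  if (!is.null(variants)) {
    G <- G[, match(variants, colnames(G)), drop = FALSE]
    vmeta <- vmeta[match(variants, vmeta$id), , drop = FALSE]
  }
  cov_df <- gwas_covariates(dataset, covariates)
  if (!is.null(subset)) {
    G <- G[subset, , drop = FALSE]
    trait <- trait[subset]
    cov_df <- cov_df[subset, , drop = FALSE]
  }
  stopifnot(length(trait) == nrow(G))
  if (sum(trait == 1) < 1 || sum(trait == 0) < 1) {
    stop("trait must have at least one case and one control")
  }
  X0 <- covariate_matrix(cov_df)
  # warm start from the covariate-only null fit speeds up the per-variant
  # IRLS considerably
  null_fit <- logistic_fit(X0, trait)
  start <- c(null_fit$coef[1], 0, null_fit$coef[-1])
  X <- cbind(X0[, 1, drop = FALSE], dosage = 0, X0[, -1, drop = FALSE])

  p <- ncol(G)
  beta <- se <- pval <- rep(NA_real_, p)
  flag <- rep(NA_character_, p)
  n <- nrow(G); ncase <- sum(trait == 1)
  for (j in seq_len(p)) {
    g <- G[, j]
    if (stats::var(g) == 0) { flag[j] <- "monomorphic"; next }
    X[, 2] <- g
    f <- logistic_fit(X, trait, start = start)
    if (!f$converged || !is.finite(f$se[2])) { flag[j] <- "nonconverged"; next }
    beta[j] <- f$coef[2]; se[j] <- f$se[2]; pval[j] <- f$p[2]
  }
  data.frame(
    id = vmeta$id, chrom = vmeta$chrom,
    pos = vmeta$pos, ea = vmeta$ea,
    oa = vmeta$oa, eaf = unname(colMeans(G)) / 2,
    beta = beta, se = se, p = pval, n = n, n_cases = ncase,
    flag = flag, stringsAsFactors = FALSE)
}

gwas_covariates <- function(dataset, covariates) {
  if (is.data.frame(covariates)) return(covariates)
  cv <- dataset$covariates
  if (is.null(covariates)) {
    covariates <- intersect(c("age", "sex",
                              grep("^pc[0-9]+$", names(cv), value = TRUE)),
                            names(cv))
  }
  cv[, covariates, drop = FALSE]
}

#' Randomly split a cohort into disjoint base and target samples
#'
#' @param n Number of participants (or a `cohort_dataset`).
#' @param ratio Proportion assigned to the base sample, in `(0, 1)`.
#' @param seed Seed; the same seed gives the same partition.
#' @return List with integer index vectors `base` and `target` forming a
#'   disjoint, exhaustive partition.
#' @export
split_sample <- function(n, ratio = 0.5, seed = 1L) {
  if (inherits(n, "cohort_dataset")) n <- nrow(n$dosage)
  stopifnot(ratio > 0, ratio < 1)
  set.seed(seed)
  n_base <- round(n * ratio)
  base <- sort(sample.int(n, n_base))
  list(base = base, target = setdiff(seq_len(n), base))
}

#' Pearson chi-square test on an r x c contingency table
#'
#' Pearson's statistic without continuity correction,
#' \eqn{\sum (O - E)^2 / E} with `df = (r-1)(c-1)`, as used for descriptive
#' baseline-characteristic comparisons.
#'
#' @param table Matrix of non-negative counts with at least 2 rows and 2
#'   columns and no zero marginal.
#' @return List with `statistic`, `df`, `p`.
#' @export
contingency_chi_square <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) >= 2, ncol(table) >= 2, all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("contingency table has a zero marginal row or column")
  }
  ct <- stats::chisq.test(table, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Write / read GWAS summary statistics
#'
#' TSV with the standard column set (`id`, `chrom`, `pos`, `ea`, `oa`,
#' `eaf`, `beta`, `se`, `p`, `n`, ...); the reader tolerates extra columns
#' and requires only `id`, `ea`, `oa`, `beta`, `se`.
#'
#' @param stats Summary-statistics data frame.
#' @param path File path.
#' @export
write_sumstats <- function(stats, path) write_tsv_exact(stats, path)

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  x <- read_tsv(path)
  need <- c("id", "ea", "oa", "beta", "se")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("summary statistics file ", path, " lacks columns: ",
         paste(miss, collapse = ", "))
  }
  x
}
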