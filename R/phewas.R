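#' Phenome-wide logistic scan of a scaled polygenic score
#'
#' Each phecode indicator is regressed on the standardized PRS with
#' covariate adjustment (by default age, sex, assessment center and the
#' genetic principal components). Significance is controlled by Bonferroni
#' correction at `alpha / K`, with `K` the number of phecodes actually
#' tested. Phecodes matching the exposure's own 3-character stem are
#' excluded by default to avoid tautological hits; phecodes with zero
#' cases after alignment are skipped with a warning.
#'
#' @param prs A `prs_profile` from [score_prs()] (its participant order
#'   defines the analysis rows).
#' @param phecodes A `phecode_table` from [build_phecodes()].
#' @param covariates Covariate data frame aligned with the scored
#'   participants.
#' @param alpha Family-wise error level (default 0.05).
#' @param exclude_phecodes Phecode stems to drop (e.g. the exposure's own
#'   code).
#' @return A `phewas_result` data frame: `phecode`, `n_case`, `n_control`,
#'   `or_per_sd`, `ci_low`, `ci_high`, `p`, `significant`; attributes
#'   `alpha`, `k_tested`, `threshold`.
#' @export
run_phewas <- function(prs, phecodes, covariates = NULL, alpha = 0.05,
                       exclude_phecodes = character(0)) {
  ind <- phecodes$indicator
  pid <- prs$profiles$participant_id
  ind <- ind[match(pid, rownames(ind)), , drop = FALSE]
  keep <- !colnames(ind) %in% exclude_phecodes
  ind <- ind[, keep, drop = FALSE]
  ncase <- colSums(ind)
  zero <- ncase == 0
  if (any(zero)) {
    warning("phecodes with zero cases after alignment skipped: ",
            paste(colnames(ind)[zero], collapse = ", "))
    ind <- ind[, !zero, drop = FALSE]
  }
  K <- ncol(ind)
  threshold <- alpha / K
  s <- prs$profiles$scaled_score
  X0 <- if (is.null(covariates)) matrix(1, length(s), 1) else
    covariate_matrix(covariates)
  X <- cbind(X0[, 1, drop = FALSE], prs = s, X0[, -1, drop = FALSE])
  res <- lapply(seq_len(K), function(k) {
    f <- logistic_fit(X, ind[, k])
    b <- f$coef[2]; se <- f$se[2]
    data.frame(phecode = colnames(ind)[k],
               n_case = sum(ind[, k]), n_control = sum(ind[, k] == 0),
               or_per_sd = exp(b),
               ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
               p = f$p[2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$significant <- !is.na(out$p) & out$p < threshold
  structure(out, alpha = alpha, k_tested = K, threshold = threshold,
            class = c("phewas_result", "data.frame"))
}

#' Bonferroni threshold for a phenome-wide scan
#'
#' @param alpha Family-wise error level.
#' @param k Number of phenotypes tested.
#' @return `alpha / k`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, k) {
  stopifnot(k >= 1)
  alpha / k
}

#' Check independence of a polygenic score from putative confounders
#'
#' Regresses the scaled PRS on each candidate confounder separately
#' (linear model; categorical confounders enter as factors, tested by F
#' test) and flags any association below `0.05 / n_confounders`. A PRS
#' used as an MR instrument should show no such associations.
#'
#' @param prs A `prs_profile`.
#' @param confounders Data frame of candidate confounders aligned with the
#'   scored participants (zero columns allowed).
#' @return Data frame `confounder`, `statistic`, `p`, `flagged`. Constant
#'   confounders are skipped with a warning.
#' @export
confounder_independence <- function(prs, confounders) {
  s <- prs$profiles$scaled_score
  if (is.null(confounders) || ncol(confounders) == 0) {
    return(data.frame(confounder = character(0), statistic = numeric(0),
                      p = numeric(0), flagged = logical(0)))
  }
  rows <- lapply(names(confounders), function(nm) {
    x <- confounders[[nm]]
    if (length(unique(x[!is.na(x)])) < 2) {
      warning("constant confounder skipped: ", nm)
      return(NULL)
    }
    if (is.character(x) || is.logical(x)) x <- factor(x)
    fit <- stats::lm(s ~ x)
    a <- stats::anova(fit)
    data.frame(confounder = nm, statistic = a$`F value`[1],
               p = a$`Pr(>F)`[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    return(data.frame(confounder = character(0), statistic = numeric(0),
                      p = numeric(0), flagged = logical(0)))
  }
  out$flagged <- out$p < 0.05 / nrow(out)
  out
}
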