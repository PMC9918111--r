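#' Derive a deterministic child seed from a master seed
#'
#' All stochastic components of the package draw their randomness from child
#' seeds derived from one master seed, so that a single integer reproduces an
#' entire analysis. The derivation is a fixed integer hash; it never depends
#' on the R session state.
#'
#' @param master Master seed (single integer).
#' @param stream Stream index or label distinguishing the component.
#' @return A single integer in `[0, 2^31 - 2]` suitable for `set.seed()`.
#' @export
child_seed <- function(master, stream) {
  if (is.character(stream)) {
    stream <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  }
  stopifnot(is.numeric(master), length(master) == 1L)
  # Knuth-style multiplicative hash, kept inside 31 bits via double arithmetic
  m <- 2147483647
  h <- (abs(master) %% m)
  h <- (h * 48271 + 1) %% m
  h <- (h + (abs(stream) %% m) * 16807) %% m
  as.integer((h * 69621) %% m)
}

#' Write a data frame as a TSV with full float precision
#'
#' Numeric columns are formatted with 17 significant digits so that
#' write/read round-trips are exact for doubles.
#'
#' @param x Data frame.
#' @param path Output path.
#' @keywords internal
write_tsv_exact <- function(x, path) {
  xf <- x
  for (j in seq_along(xf)) {
    if (is.double(xf[[j]])) xf[[j]] <- sprintf("%.17g", xf[[j]])
  }
  utils::write.table(xf, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

#' Covariate-adjusted logistic regression via glm.fit
#'
#' Thin wrapper around [stats::glm.fit()] returning coefficients, standard
#' errors and Wald p-values, with warm starts to keep per-variant genome
#' scans cheap. Non-convergence and fitted probabilities at the boundary
#' (separation) are reported through the `converged` flag.
#'
#' @param X Design matrix including the intercept column.
#' @param y Binary 0/1 response.
#' @param start Optional starting coefficient vector.
#' @return List with elements `coef`, `se`, `z`, `p`, `converged`.
#' @keywords internal
logistic_fit <- function(X, y, start = NULL) {
  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = stats::binomial(), start = start,
    control = stats::glm.control(epsilon = 1e-8, maxit = 100)
  ))
  w <- fit$weights
  ok <- fit$converged && all(is.finite(fit$coefficients))
  # Fisher information from the final IRLS weights
  XtWX <- crossprod(X * sqrt(w))
  V <- tryCatch(solve(XtWX), error = function(e) NULL)
  if (is.null(V)) {
    k <- ncol(X)
    return(list(coef = rep(NA_real_, k), se = rep(NA_real_, k),
                z = rep(NA_real_, k), p = rep(NA_real_, k),
                converged = FALSE))
  }
  se <- sqrt(diag(V))
  z <- fit$coefficients / se
  list(coef = fit$coefficients, se = se, z = z,
       p = 2 * stats::pnorm(-abs(z)), converged = ok)
}

#' Build a numeric design matrix from a covariate data frame
#'
#' Factors and character columns are expanded to treatment-coded dummies;
#' numeric columns pass through. An intercept column is prepended.
#'
#' @param covariates Data frame of covariates (may have zero columns).
#' @return Numeric matrix with an `(Intercept)` first column.
#' @keywords internal
covariate_matrix <- function(covariates) {
  n <- nrow(covariates)
  if (is.null(covariates) || ncol(covariates) == 0) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  df <- as.data.frame(covariates)
  for (j in seq_along(df)) {
    if (is.character(df[[j]]) || is.logical(df[[j]])) {
      df[[j]] <- factor(df[[j]])
    }
  }
  stats::model.matrix(~ ., data = df)
}
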