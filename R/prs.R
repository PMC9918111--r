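#' Clumping parameter presets
#'
#' `iv_preset()` reproduces instrument-selection settings typical for MR
#' (r-squared < 0.001 within 10,000 kb, p < 1e-5); `prs_preset()` is a
#' conventional clumping-and-thresholding setting for polygenic scores
#' (r-squared < 0.1 within 250 kb, p < 0.05).
#'
#' @return List with `r2_threshold`, `window_kb`, `p_threshold`.
#' @export
iv_preset <- function() list(r2_threshold = 0.001, window_kb = 10000,
                             p_threshold = 1e-5)

#' @rdname iv_preset
#' @export
prs_preset <- function() list(r2_threshold = 0.1, window_kb = 250,
                              p_threshold = 0.05)

#' Greedy LD clumping of GWAS summary statistics
#'
#' Variants passing `p_threshold` are visited in order of ascending p-value
#' (ties broken by smaller standard error, then lexicographic id); each
#' retained variant removes every unvisited variant on the same chromosome
#' within `window_kb` whose squared in-sample dosage correlation with it is
#' at least `r2_threshold`. The retained set is therefore pairwise
#' r-squared below threshold within the window, and deterministic under
#' input row permutation.
#'
#' @param summary_stats Data frame with `id`, `chrom`, `pos`, `p`, `se`.
#' @param ld_source Dosage matrix with variant ids as column names (the
#'   in-sample LD reference). Variants absent from it are excluded with a
#'   warning.
#' @param r2_threshold,window_kb,p_threshold Clumping parameters; see
#'   [iv_preset()] and [prs_preset()].
#' @return Character vector of retained variant ids.
#' @export
clump <- function(summary_stats, ld_source,
                  r2_threshold = 0.001, window_kb = 10000,
                  p_threshold = 1e-5) {
  ss <- summary_stats[!is.na(summary_stats$p) &
                        summary_stats$p < p_threshold, , drop = FALSE]
  if (nrow(ss) == 0) return(character(0))
  absent <- setdiff(ss$id, colnames(ld_source))
  if (length(absent) > 0) {
    warning("variants absent from LD source excluded from clumping: ",
            paste(absent, collapse = ", "))
    ss <- ss[!ss$id %in% absent, , drop = FALSE]
  }
  if (nrow(ss) == 0) return(character(0))
  ss <- ss[order(ss$p, ss$se, ss$id), , drop = FALSE]
  Gc <- ld_source[, ss$id, drop = FALSE]
  alive <- rep(TRUE, nrow(ss))
  kept <- character(0)
  for (i in seq_len(nrow(ss))) {
    if (!alive[i]) next
    kept <- c(kept, ss$id[i])
    near <- which(alive & ss$chrom == ss$chrom[i] &
                    abs(ss$pos - ss$pos[i]) <= window_kb * 1000)
    near <- setdiff(near, i)
    if (length(near) > 0) {
      r <- suppressWarnings(stats::cor(Gc[, i], Gc[, near, drop = FALSE]))
      r2 <- as.vector(r)^2
      r2[is.na(r2)] <- 1  # zero-variance partner: drop it
      alive[near[r2 >= r2_threshold]] <- FALSE
    }
    alive[i] <- FALSE
  }
  kept
}

#' Compute polygenic risk scores from per-variant weights
#'
#' Raw score is the weighted sum of effect-allele dosages; weights whose
#' effect allele matches the variant's other allele are applied to the
#' flipped dosage. Missing dosage values are mean-imputed per variant.
#' Scores are z-standardized to mean 0, SD 1; the scaling constants are
#' returned so that a base-sample standardization can be applied to
#' held-out samples.
#'
#' @param dataset A `cohort_dataset` (or list with `dosage`, `variants`,
#'   `covariates`).
#' @param weights Data frame with columns `id`, `ea`, `beta`.
#' @param scale Optional list `list(mean=, sd=)` of scaling constants to
#'   reuse; when `NULL` the scored set's own mean/SD are used.
#' @param subset Optional row subset.
#' @return A `prs_profile` list: `profiles` (data frame `participant_id`,
#'   `raw_score`, `scaled_score`, `tertile`), `scale`, `n_used`,
#'   `skipped` ids.
#' @export
score_prs <- function(dataset, weights, scale = NULL, subset = NULL) {
  stopifnot(nrow(weights) >= 1)
  G <- dataset$dosage
  pid <- dataset$covariates$participant_id
  if (!is.null(subset)) { G <- G[subset, , drop = FALSE]; pid <- pid[subset] }
  idx <- match(weights$id, colnames(G))
  skipped <- weights$id[is.na(idx)]
  if (length(skipped) > 0) {
    message(length(skipped), " weight variant(s) absent from dosages, skipped")
  }
  use <- !is.na(idx)
  if (!any(use)) stop("no usable variants: all weight variants missing")
  w <- weights[use, , drop = FALSE]
  Gm <- G[, idx[use], drop = FALSE]
  storage.mode(Gm) <- "double"
  if (anyNA(Gm)) {
    for (j in seq_len(ncol(Gm))) {
      nas <- is.na(Gm[, j])
      if (any(nas)) Gm[nas, j] <- mean(Gm[, j], na.rm = TRUE)
    }
  }
  vea <- dataset$variants$ea[match(w$id, dataset$variants$id)]
  voa <- dataset$variants$oa[match(w$id, dataset$variants$id)]
  flip <- !is.na(voa) & w$ea == voa
  mismatch <- !(w$ea == vea | flip)
  if (any(mismatch)) {
    warning("effect allele matches neither allele for: ",
            paste(w$id[mismatch], collapse = ", "), " (skipped)")
    w <- w[!mismatch, , drop = FALSE]
    Gm <- Gm[, !mismatch, drop = FALSE]
    flip <- flip[!mismatch]
    if (ncol(Gm) == 0) stop("no usable variants after allele matching")
  }
  Gm[, flip] <- 2 - Gm[, flip, drop = FALSE]
  raw <- as.vector(Gm %*% w$beta)
  if (is.null(scale)) {
    sdr <- stats::sd(raw)
    if (!is.finite(sdr) || sdr == 0) {
      stop("polygenic score has zero variance; cannot standardize")
    }
    scale <- list(mean = mean(raw), sd = sdr)
  }
  scaled <- (raw - scale$mean) / scale$sd
  # rank-based tertiles so group sizes stay balanced even with tied scores
  rk <- rank(scaled, ties.method = "first")
  tertile <- factor(c("low", "middle", "high")[
    ceiling(3 * rk / length(rk))], levels = c("low", "middle", "high"))
  structure(list(
    profiles = data.frame(participant_id = pid, raw_score = raw,
                          scaled_score = scaled, tertile = tertile,
                          stringsAsFactors = FALSE),
    scale = scale, n_used = ncol(Gm),
    skipped = as.character(skipped)), class = "prs_profile")
}

#' @export
print.prs_profile <- function(x, ...) {
  cat("PRS profile:", nrow(x$profiles), "participants scored on",
      x$n_used, "variants\n")
  invisible(x)
}

#' Top-vs-bottom PRS tertile association with a binary outcome
#'
#' Logistic regression of the outcome on an indicator of the top PRS
#' tertile, restricted to top- and bottom-tertile participants, with
#' optional covariate adjustment.
#'
#' @param prs A `prs_profile` from [score_prs()].
#' @param outcome Binary 0/1 vector aligned with the scored participants.
#' @param covariates Optional covariate data frame (same alignment).
#' @return List with `or`, `ci_low`, `ci_high`, `p`, `n_high`, `n_low`.
#' @export
tertile_association <- function(prs, outcome, covariates = NULL) {
  t3 <- prs$profiles$tertile
  if (any(table(t3) == 0)) stop("empty PRS tertile")
  sel <- t3 %in% c("low", "high")
  hi <- as.numeric(t3[sel] == "high")
  y <- outcome[sel]
  X0 <- if (is.null(covariates)) {
    matrix(1, sum(sel), 1)
  } else covariate_matrix(covariates[sel, , drop = FALSE])
  f <- logistic_fit(cbind(X0[, 1, drop = FALSE], high = hi,
                          X0[, -1, drop = FALSE]), y)
  b <- unname(f$coef[2]); s <- unname(f$se[2])
  list(or = exp(b), ci_low = exp(b - 1.96 * s), ci_high = exp(b + 1.96 * s),
       p = unname(f$p[2]), n_high = sum(hi == 1), n_low = sum(hi == 0))
}
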