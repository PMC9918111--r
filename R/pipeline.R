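#' Subset a cohort dataset by participant rows
#'
#' @param dataset A `cohort_dataset`.
#' @param idx Integer or logical row index.
#' @return The subsetted `cohort_dataset` (diagnoses restricted to kept
#'   participants; truth vectors subsetted).
#' @export
subset_cohort <- function(dataset, idx) {
  pid <- dataset$covariates$participant_id[idx]
  tr <- dataset$truth
  tr$confounder <- tr$confounder[idx]
  tr$liability <- tr$liability[idx]
  tr$lambda <- tr$lambda[idx]
  tr$exposure <- tr$exposure[idx]
  tr$outcomes <- tr$outcomes[idx, , drop = FALSE]
  structure(list(
    dosage = dataset$dosage[idx, , drop = FALSE],
    variants = dataset$variants,
    covariates = dataset$covariates[idx, , drop = FALSE],
    flags = dataset$flags[idx, , drop = FALSE],
    diagnoses = dataset$diagnoses[
      dataset$diagnoses$participant_id %in% pid, , drop = FALSE],
    truth = tr, config = dataset$config), class = "cohort_dataset")
}

#' Run the full split-sample PheWAS-MR pipeline
#'
#' Orchestrates the complete design on a cohort: exposure ascertainment
#' with exclusions, a random base/target split, an exposure GWAS in the
#' base half, instrument selection and polygenic scoring in the target
#' half, phecode construction and a PheWAS of the scaled score in the
#' target half, and, for each Bonferroni-significant phecode, one-sample
#' (two-stage) MR plus the two-sample MR suite with sensitivity analyses
#' (Cochran's Q, MR-PRESSO, Steiger, leave-one-out). Variant-outcome
#' effects for two-sample MR are estimated in the full analysis set by
#' default (`outcome_scan = "full"`) or restricted to the target half.
#' All seeds and thresholds are recorded in the run manifest; an
#' identical manifest yields identical output.
#'
#' @param dataset A `cohort_dataset`, or `NULL` to simulate from `config`.
#' @param config A [sim_config()] used when `dataset` is `NULL`.
#' @param exposure_codes,exclusion_codes ICD-10 prefixes for exposure
#'   ascertainment and exclusion conditions.
#' @param split_ratio Base-sample proportion.
#' @param iv,prs_ct Clumping parameter lists for instrument selection and
#'   PRS construction (defaults [iv_preset()] and [prs_preset()]).
#' @param alpha Family-wise error level for the PheWAS.
#' @param min_cases Strict minimum phecode case count.
#' @param outcome_scan `"full"` or `"target"`.
#' @param n_boot Bootstrap draws for median/mode SEs.
#' @param presso_n_sim MR-PRESSO simulation count.
#' @param seed Master seed.
#' @return A `phewas_mr_report` list: `manifest`, `exposure_summary`,
#'   `exposure_stats` (base GWAS), `instruments` (selected ids and F),
#'   `phecodes`, `phewas`, `mr` (per significant phecode: one-sample and
#'   two-sample estimates, sensitivity results).
#' @export
run_pipeline <- function(dataset = NULL, config = NULL,
                         exposure_codes = "K58",
                         exclusion_codes = c("K50", "K51"),
                         split_ratio = 0.5,
                         iv = iv_preset(), prs_ct = prs_preset(),
                         alpha = 0.05, min_cases = 250,
                         outcome_scan = c("full", "target"),
                         n_boot = 500, presso_n_sim = 1000,
                         seed = 1L) {
  outcome_scan <- match.arg(outcome_scan)
  stage <- "simulate"
  out <- tryCatch({
    if (is.null(dataset)) {
      stopifnot(!is.null(config))
      dataset <- simulate_cohort(config)
    }

    stage <- "ascertain_exposure"
    asc <- ascertain_exposure(dataset$flags, dataset$diagnoses,
                              exposure_codes, exclusion_codes)
    included <- which(!asc$excluded)
    ds <- subset_cohort(dataset, included)
    y <- as.integer(asc$is_case[included])

    stage <- "split_sample"
    sp <- split_sample(length(included), ratio = split_ratio,
                       seed = child_seed(seed, "split"))

    stage <- "gwas_base"
    base_stats <- gwas_scan(ds, y, subset = sp$base)

    stage <- "select_instruments"
    ld_base <- ds$dosage[sp$base, , drop = FALSE]
    inst <- select_instruments(base_stats, ld_base,
                               p_threshold = iv$p_threshold,
                               r2_threshold = iv$r2_threshold,
                               window_kb = iv$window_kb)

    stage <- "prs"
    prs_ids <- clump(base_stats, ld_base,
                     r2_threshold = prs_ct$r2_threshold,
                     window_kb = prs_ct$window_kb,
                     p_threshold = prs_ct$p_threshold)
    if (length(prs_ids) == 0) stop("no variants pass the PRS threshold")
    wsel <- base_stats[match(prs_ids, base_stats$id), , drop = FALSE]
    weights <- data.frame(id = wsel$id, ea = wsel$ea, beta = wsel$beta,
                          stringsAsFactors = FALSE)
    prs <- score_prs(ds, weights, subset = sp$target)

    stage <- "phecodes"
    target_ids <- ds$covariates$participant_id[sp$target]
    ph <- build_phecodes(ds$diagnoses, target_ids,
                         icd9_map = if (!is.null(ds$config))
                           ds$config$icd9_map else default_icd9_map(),
                         min_cases = min_cases)

    stage <- "phewas"
    cov_target <- ds$covariates[sp$target, , drop = FALSE]
    phewas_cov <- cov_target[, intersect(
      c("age", "sex", "center", grep("^pc[0-9]+$", names(cov_target),
                                     value = TRUE)),
      names(cov_target)), drop = FALSE]
    pw <- run_phewas(prs, ph, phewas_cov, alpha = alpha,
                     exclude_phecodes = unique(substr(
                       normalize_icd(exposure_codes), 1, 3)))
    sig <- pw$phecode[pw$significant]

    stage <- "mr"
    mr_results <- list()
    exp_stats <- base_stats[match(inst$id, base_stats$id), , drop = FALSE]
    scan_subset <- if (outcome_scan == "full") NULL else sp$target
    diag_ind <- if (length(sig) > 0) {
      build_phecodes(ds$diagnoses, ds$covariates$participant_id,
                     icd9_map = if (!is.null(ds$config)) ds$config$icd9_map
                     else default_icd9_map(), min_cases = 0)
    }
    for (code in sig) {
      ind_full <- ph$indicator[, code]
      outcome_target <- ind_full[match(target_ids, rownames(ph$indicator))]
      os_cov <- cov_target[, intersect(
        c("age", "sex", grep("^pc[0-9]+$", names(cov_target),
                             value = TRUE)), names(cov_target)),
        drop = FALSE]
      one_sample <- two_stage_mr(y[sp$target], outcome_target, prs,
                                 covariates = os_cov,
                                 seed = child_seed(seed, "onesample"))

      # variant-outcome effects: diagnosis-based indicator over the scan set
      yfull <- if (code %in% colnames(diag_ind$indicator))
        diag_ind$indicator[, code] else rep(0L, nrow(ds$dosage))
      out_stats <- gwas_scan(ds, yfull, subset = scan_subset,
                             variants = inst$id)
      h <- harmonize(exp_stats, out_stats)
      suite <- mr_suite(h, n_boot = n_boot, seed = child_seed(seed, code))
      sens <- list(
        q = if (nrow(h) >= 2) cochran_q(h) else NULL,
        presso = if (nrow(h) >= 4)
          presso(h, n_sim = presso_n_sim,
                 seed = child_seed(seed, paste0(code, "p"))) else NULL,
        steiger = if (nrow(h) >= 1) steiger(h) else NULL,
        loo = if (nrow(h) >= 3) leave_one_out(h) else NULL)
      mr_results[[code]] <- list(phecode = code,
                                 one_sample = one_sample,
                                 instruments = h, suite = suite,
                                 sensitivity = sens)
    }

    manifest <- list(
      seed = seed, split_ratio = split_ratio, iv = iv, prs_ct = prs_ct,
      alpha = alpha, min_cases = min_cases, outcome_scan = outcome_scan,
      n_boot = n_boot, presso_n_sim = presso_n_sim,
      exposure_codes = exposure_codes, exclusion_codes = exclusion_codes,
      n_input = nrow(dataset$dosage), n_excluded = sum(asc$excluded),
      n_base = length(sp$base), n_target = length(sp$target),
      n_cases_base = sum(y[sp$base]), n_cases_target = sum(y[sp$target]),
      n_instruments = nrow(inst), n_prs_variants = length(prs_ids),
      k_phecodes = attr(pw, "k_tested"),
      bonferroni_threshold = attr(pw, "threshold"))

    structure(list(manifest = manifest,
                   exposure_summary = asc,
                   exposure_stats = base_stats,
                   instruments = inst,
                   phecodes = ph, phewas = pw,
                   significant_phecodes = sig,
                   mr = mr_results),
              class = "phewas_mr_report")
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  out
}

#' @export
print.phewas_mr_report <- function(x, ...) {
  m <- x$manifest
  cat("PheWAS-MR report\n")
  cat(sprintf("  base/target: %d/%d (cases %d/%d), %d excluded\n",
              m$n_base, m$n_target, m$n_cases_base, m$n_cases_target,
              m$n_excluded))
  cat(sprintf("  instruments: %d; PRS variants: %d; phecodes tested: %d\n",
              m$n_instruments, m$n_prs_variants, m$k_phecodes))
  cat("  significant phecodes:",
      if (length(x$significant_phecodes) > 0)
        paste(x$significant_phecodes, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Run the pipeline separately within strata
#'
#' Repeats the full pipeline within each level of a stratification
#' variable (by default sex), with the stratification variable removed
#' from the covariate set inside each stratum and stratum-specific
#' Bonferroni correction. Strata smaller than `min_n` are skipped with a
#' warning.
#'
#' @param dataset A `cohort_dataset`.
#' @param strata_variable Covariate column to stratify on.
#' @param min_n Minimum stratum size.
#' @param ... Passed to [run_pipeline()].
#' @return Named list of `phewas_mr_report` objects, one per stratum.
#' @export
run_stratified <- function(dataset, strata_variable = "sex", min_n = 500,
                           ...) {
  sv <- dataset$covariates[[strata_variable]]
  stopifnot(!is.null(sv))
  out <- list()
  for (lev in sort(unique(sv))) {
    idx <- which(sv == lev)
    if (length(idx) < min_n) {
      warning("stratum '", lev, "' below minimum n (", length(idx),
              " < ", min_n, "), skipped")
      next
    }
    ds <- subset_cohort(dataset, idx)
    # drop the (now constant) stratification column
    ds$covariates[[strata_variable]] <- NULL
    out[[lev]] <- run_pipeline(ds, ...)
  }
  out
}

#' Two-sample MR from summary statistics alone
#'
#' Selects instruments from the exposure scan (optionally; set
#' `select = FALSE` when the tables are already restricted to
#' instruments), harmonizes, and runs the estimator suite with Cochran's
#' Q, Steiger, leave-one-out and (when at least 4 instruments remain)
#' MR-PRESSO.
#'
#' @param exposure_stats,outcome_stats Summary-statistic tables.
#' @param ld_source Dosage matrix for clumping (required when
#'   `select = TRUE`).
#' @param select Perform instrument selection.
#' @param iv Instrument-selection parameters.
#' @param n_boot,presso_n_sim,seed Passed to the estimators.
#' @return List with `instruments`, `suite`, `q`, `steiger`, `loo`,
#'   `presso`.
#' @export
mr_two_sample <- function(exposure_stats, outcome_stats, ld_source = NULL,
                          select = FALSE, iv = iv_preset(),
                          n_boot = 1000, presso_n_sim = 1000, seed = 1L) {
  if (select) {
    stopifnot(!is.null(ld_source))
    inst <- select_instruments(exposure_stats, ld_source,
                               p_threshold = iv$p_threshold,
                               r2_threshold = iv$r2_threshold,
                               window_kb = iv$window_kb)
    exposure_stats <- exposure_stats[
      match(inst$id, exposure_stats$id), , drop = FALSE]
  }
  h <- harmonize(exposure_stats, outcome_stats)
  list(instruments = h,
       suite = mr_suite(h, n_boot = n_boot, seed = seed),
       q = if (nrow(h) >= 2) cochran_q(h) else NULL,
       steiger = if (!anyNA(h$n_exposure) && !anyNA(h$n_outcome))
         steiger(h) else NULL,
       loo = if (nrow(h) >= 3) leave_one_out(h) else NULL,
       presso = if (nrow(h) >= 4)
         presso(h, n_sim = presso_n_sim, seed = seed) else NULL)
}

#' Reverse-direction two-sample MR
#'
#' Swaps the roles of exposure and outcome and reruns [mr_two_sample()]
#' with the same instrument-selection preset, to probe reverse causation.
#' Swapping twice reproduces the forward analysis.
#'
#' @inheritParams mr_two_sample
#' @return As [mr_two_sample()].
#' @export
run_reverse_mr <- function(exposure_stats, outcome_stats,
                           ld_source = NULL, select = FALSE,
                           iv = iv_preset(), n_boot = 1000,
                           presso_n_sim = 1000, seed = 1L) {
  mr_two_sample(outcome_stats, exposure_stats, ld_source = ld_source,
                select = select, iv = iv, n_boot = n_boot,
                presso_n_sim = presso_n_sim, seed = seed)
}
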