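#' Specify a disease outcome for the cohort simulator
#'
#' Each outcome is a binary diagnosis generated from a logistic model whose
#' linear predictor combines (i) the exposure's liability expressed on an
#' approximate log-odds scale, so that `causal_beta` is a log-odds ratio per
#' unit increase in the log-odds of exposure (and `0.693 * causal_beta` the
#' log-OR per doubling of exposure odds), (ii) an unobserved standard-normal
#' confounder shared with the exposure, and (iii) optional direct
#' (horizontally pleiotropic) variant effects that bypass the exposure.
#'
#' @param name Outcome label.
#' @param icd10 ICD-10 code emitted into diagnosis records for affected
#'   participants (e.g. `"F329"`); its 3-character stem becomes the phecode.
#' @param baseline_prevalence Marginal probability of the outcome.
#' @param causal_beta Log-OR of the outcome per unit exposure log-odds.
#' @param confounder_beta Log-OR per SD of the shared confounder.
#' @param pleiotropy Named numeric vector of direct per-dosage log-odds
#'   effects, named by variant id (or integer index).
#' @return An `outcome_spec` list.
#' @export
outcome_spec <- function(name, icd10, baseline_prevalence = 0.05,
                         causal_beta = 0, confounder_beta = 0,
                         pleiotropy = numeric(0)) {
  stopifnot(baseline_prevalence > 0, baseline_prevalence < 1)
  structure(list(name = name, icd10 = toupper(gsub("\\.", "", icd10)),
                 baseline_prevalence = baseline_prevalence,
                 causal_beta = causal_beta,
                 confounder_beta = confounder_beta,
                 pleiotropy = pleiotropy),
            class = "outcome_spec")
}

#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure a split-sample
#' GWAS/PRS/PheWAS/MR analysis assumes: a binary exposure arising from a
#' liability-threshold model with a polygenic component, unobserved
#' confounding shared between exposure and outcomes, linkage-disequilibrium
#' (LD) blocks, palindromic (A/T, C/G) variants with optionally intermediate
#' allele frequency, questionnaire ascertainment flags, and dated ICD-coded
#' diagnosis records (a configurable fraction emitted in ICD-9 to exercise
#' code mapping).
#'
#' The exposure liability is \eqn{L = G + c U + \epsilon} with
#' \eqn{G = \sum_k b_k g_k} scaled so \eqn{Var(G) = h^2}, \eqn{U} a standard
#' normal confounder, and \eqn{Var(L) = 1}; exposure is \eqn{L > \tau} with
#' \eqn{\tau = \Phi^{-1}(1 - K)} for target prevalence \eqn{K}. Outcomes are
#' coupled to the continuous liability through
#' \eqn{\Lambda = 1.702 (L - \tau)}, the probit-to-logit rescaling of the
#' centred liability, which makes each outcome's `causal_beta` directly
#' interpretable on the exposure log-odds scale.
#'
#' @param n_participants Cohort size.
#' @param n_snps Number of variants.
#' @param ld_block_size Variants per LD block.
#' @param ld_rho Within-block haplotype allele correlation in `[0, 1)`;
#'   the lead variant of each block correlates `ld_rho` with each other
#'   member and members correlate `ld_rho^2` with each other.
#' @param maf_range Length-2 vector of minor/effect allele frequency bounds
#'   in `(0, 0.5]`; one frequency per block when `ld_rho > 0`.
#' @param frac_palindromic Fraction of variants given A/T or C/G alleles.
#' @param frac_palindromic_intermediate Fraction of the palindromic variants
#'   whose allele frequency is redrawn uniformly from `[0.42, 0.58]` to
#'   exercise the harmonization exclusion.
#' @param n_causal_snps Number of variants with nonzero liability effects.
#' @param h2_liability Proportion of liability variance explained by the
#'   polygenic component, in `[0, 1)`.
#' @param exposure_prevalence Target exposure prevalence (default 0.115,
#'   a realistic figure for irritable bowel syndrome in a mid-life cohort).
#' @param confounder_beta_exposure Liability-scale coefficient of the shared
#'   confounder on the exposure.
#' @param outcome_specs List of [outcome_spec()] objects (may be empty).
#' @param exposure_icd10 ICD-10 code emitted for clinically diagnosed
#'   exposure cases.
#' @param exclusion_icd10 ICD-10 code used to plant exclusion conditions.
#' @param frac_exclusion Fraction of participants planted with an exclusion
#'   diagnosis.
#' @param icd9_fraction Fraction of diagnosis records emitted as ICD-9 when
#'   the code has an entry in `icd9_map`.
#' @param icd9_map Two-column data frame (`icd9`, `icd10`) used for ICD-9
#'   emission; defaults to the small synthetic mapping shipped with the
#'   package.
#' @param age_range Integer age bounds at recruitment.
#' @param sex_ratio_female Proportion of females.
#' @param n_centers Number of assessment centers.
#' @param n_pcs Number of genetic principal-component covariates.
#' @param date_window Character length-2 ISO dates bounding diagnosis dates.
#' @param seed Master seed; fixed seed gives byte-identical datasets.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_participants = 20000,
                       n_snps = 400,
                       ld_block_size = 10,
                       ld_rho = 0,
                       maf_range = c(0.05, 0.5),
                       frac_palindromic = 0.1,
                       frac_palindromic_intermediate = 0.5,
                       n_causal_snps = 40,
                       h2_liability = 0.2,
                       exposure_prevalence = 0.115,
                       confounder_beta_exposure = 0,
                       outcome_specs = list(),
                       exposure_icd10 = "K580",
                       exclusion_icd10 = "K509",
                       frac_exclusion = 0.002,
                       icd9_fraction = 0.05,
                       icd9_map = NULL,
                       age_range = c(40, 69),
                       sex_ratio_female = 0.5334,
                       n_centers = 3,
                       n_pcs = 10,
                       date_window = c("2000-01-01", "2015-12-31"),
                       seed = 1L) {
  stopifnot(exposure_prevalence > 0, exposure_prevalence < 1,
            h2_liability >= 0, h2_liability < 1,
            ld_rho >= 0, ld_rho < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            n_causal_snps <= n_snps,
            h2_liability + confounder_beta_exposure^2 < 1)
  if (is.null(icd9_map)) icd9_map <- default_icd9_map()
  structure(as.list(environment()), class = "sim_config")
}

#' Read a simulation configuration from a YAML file
#'
#' Every [sim_config()] argument may appear as a top-level key;
#' `outcome_specs` is a list of mappings with the [outcome_spec()] fields
#' (`pleiotropy` as a code-to-effect mapping). Unknown keys are an error.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(raw$outcome_specs)) {
    raw$outcome_specs <- lapply(raw$outcome_specs, function(os) {
      if (!is.null(os$pleiotropy)) os$pleiotropy <- unlist(os$pleiotropy)
      do.call(outcome_spec, os)
    })
  }
  for (k in c("maf_range", "age_range", "date_window")) {
    if (!is.null(raw[[k]])) raw[[k]] <- unlist(raw[[k]])
  }
  do.call(sim_config, raw)
}

#' Built-in synthetic ICD-9 to ICD-10 mapping
#'
#' A small synthetic general-equivalence-style mapping used by the simulator
#' (ICD-9 emission) and by the code-mapping tests. It is not a real GEM
#' table.
#'
#' @return Data frame with columns `icd9` and `icd10`.
#' @export
default_icd9_map <- function() {
  path <- system.file("extdata", "icd9_to_icd10_synthetic.tsv",
                      package = "phewasmr")
  read_tsv(path, colClasses = "character")
}

#' Simulate a cohort dataset
#'
#' Generates genotype dosages, covariates, questionnaire flags, dated
#' diagnosis records and a planted-truth record under the model described in
#' [sim_config()]. The truth record retains the planted parameters (variant
#' effects, liability, confounder, outcome indicators) so downstream stages
#' can be tested against known ground truth.
#'
#' @param config A [sim_config()] object.
#' @return A `cohort_dataset` list with elements `dosage` (n x p integer
#'   matrix), `variants`, `covariates`, `flags`, `diagnoses`, `truth`, and
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_participants
  p <- config$n_snps

  ## --- variants and LD-block genotypes -------------------------------
  set.seed(child_seed(config$seed, "genotypes"))
  blk <- ceiling(seq_len(p) / config$ld_block_size)
  n_blk <- max(blk)
  maf <- if (config$ld_rho > 0) {
    stats::runif(n_blk, config$maf_range[1], config$maf_range[2])[blk]
  } else {
    stats::runif(p, config$maf_range[1], config$maf_range[2])
  }

  n_pal <- round(config$frac_palindromic * p)
  pal_idx <- if (n_pal > 0) sort(sample.int(p, n_pal)) else integer(0)
  palindromic <- seq_len(p) %in% pal_idx
  n_band <- round(config$frac_palindromic_intermediate * n_pal)
  if (n_band > 0) {
    band_idx <- pal_idx[sort(sample.int(n_pal, n_band))]
    maf[band_idx] <- stats::runif(n_band, 0.42, 0.58)
  }

  allele_pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                        c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pal_pairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  pick <- sample.int(nrow(allele_pairs), p, replace = TRUE)
  ea <- allele_pairs[pick, 1]; oa <- allele_pairs[pick, 2]
  if (n_pal > 0) {
    pickp <- sample.int(nrow(pal_pairs), n_pal, replace = TRUE)
    ea[pal_idx] <- pal_pairs[pickp, 1]; oa[pal_idx] <- pal_pairs[pickp, 2]
  }

  # one haplotype: lead allele per block; members copy the lead with
  # probability ld_rho, otherwise draw independently at their own frequency
  draw_hap <- function() {
    H <- matrix(stats::rbinom(n * p, 1L, rep(maf, each = n)), n, p)
    if (config$ld_rho > 0 && config$ld_block_size > 1) {
      for (b in seq_len(n_blk)) {
        cols <- which(blk == b)
        if (length(cols) < 2) next
        lead <- H[, cols[1]]
        for (j in cols[-1]) {
          copy <- stats::runif(n) < config$ld_rho
          H[copy, j] <- lead[copy]
        }
      }
    }
    H
  }
  G <- draw_hap() + draw_hap()
  storage.mode(G) <- "integer"

  ids <- sprintf("snp%04d", seq_len(p))
  colnames(G) <- ids
  variants <- data.frame(
    id = ids,
    chrom = ((blk - 1L) %% 22L) + 1L,
    pos = 1e6L + (seq_len(p) - (blk - 1L) * config$ld_block_size) * 100000L +
      ((blk - 1L) %/% 22L) * 50000000L,
    ea = ea, oa = oa,
    eaf = unname(colMeans(G)) / 2,
    palindromic = palindromic,
    stringsAsFactors = FALSE
  )

  ## --- exposure liability --------------------------------------------
  set.seed(child_seed(config$seed, "liability"))
  causal <- sort(sample.int(p, config$n_causal_snps))
  b_raw <- stats::rnorm(config$n_causal_snps)
  Graw <- as.vector(G[, causal, drop = FALSE] %*% b_raw)
  sdg <- stats::sd(Graw)
  if (config$h2_liability > 0 && sdg > 0) {
    b <- b_raw * sqrt(config$h2_liability) / sdg
  } else {
    b <- b_raw * 0
  }
  Gl <- as.vector(G[, causal, drop = FALSE] %*% b)
  Gl <- Gl - mean(Gl)
  cc <- config$confounder_beta_exposure
  U <- stats::rnorm(n)
  sd_eps <- sqrt(1 - config$h2_liability - cc^2)
  L <- Gl + cc * U + stats::rnorm(n, 0, sd_eps)
  tau <- stats::qnorm(1 - config$exposure_prevalence)
  exposure <- as.integer(L > tau)
  lambda <- 1.702 * (L - tau)   # probit-to-logit rescaled liability

  ## --- outcomes -------------------------------------------------------
  set.seed(child_seed(config$seed, "outcomes"))
  onames <- vapply(config$outcome_specs, `[[`, "", "name")
  Y <- matrix(0L, n, length(onames), dimnames = list(NULL, onames))
  intercepts <- numeric(length(onames))
  beta_marginal <- numeric(length(onames))
  for (k in seq_along(config$outcome_specs)) {
    os <- config$outcome_specs[[k]]
    eta <- os$causal_beta * lambda + os$confounder_beta * U
    if (length(os$pleiotropy) > 0) {
      pj <- names(os$pleiotropy)
      jj <- if (is.null(pj)) as.integer(seq_along(os$pleiotropy)) else
        match(pj, ids)
      if (anyNA(jj)) stop("pleiotropy refers to unknown variant in outcome '",
                          os$name, "'")
      Gp <- G[, jj, drop = FALSE]
      eta <- eta + as.vector(sweep(Gp, 2, 2 * maf[jj]) %*%
                               unname(os$pleiotropy))
    }
    f <- function(a) mean(stats::plogis(a + eta)) - os$baseline_prevalence
    if (f(-30) > 0 || f(30) < 0) {
      stop("outcome '", os$name,
           "' has saturating probabilities: prevalence ",
           os$baseline_prevalence, " unreachable with the given effects")
    }
    a <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
    intercepts[k] <- a
    prob <- stats::plogis(a + eta)
    Y[, k] <- stats::rbinom(n, 1L, prob)
    # marginal (collapsed) log-OR per unit lambda: the estimand an MR
    # analysis of this outcome targets under odds-ratio non-collapsibility
    beta_marginal[k] <- if (os$causal_beta == 0 &&
                            os$confounder_beta == 0 &&
                            length(os$pleiotropy) == 0) 0 else
      suppressWarnings(unname(stats::glm(
        prob ~ lambda, family = stats::quasibinomial())$coefficients[2]))
  }

  ## --- covariates ------------------------------------------------------
  set.seed(child_seed(config$seed, "covariates"))
  pid <- sprintf("id%06d", seq_len(n))
  covariates <- data.frame(
    participant_id = pid,
    age = sample(seq(config$age_range[1], config$age_range[2]), n,
                 replace = TRUE),
    sex = ifelse(stats::runif(n) < config$sex_ratio_female,
                 "female", "male"),
    center = paste0("center", sample.int(config$n_centers, n,
                                         replace = TRUE)),
    stringsAsFactors = FALSE
  )
  if (config$n_pcs > 0) {
    PC <- matrix(stats::rnorm(n * config$n_pcs), n, config$n_pcs)
    colnames(PC) <- paste0("pc", seq_len(config$n_pcs))
    covariates <- cbind(covariates, as.data.frame(PC))
  }

  ## --- ascertainment flags and diagnosis records ----------------------
  set.seed(child_seed(config$seed, "records"))
  is_case <- exposure == 1L
  rome3 <- is_case & stats::runif(n) < 0.3
  dhq <- is_case & stats::runif(n) < 0.5
  selfrep <- is_case & stats::runif(n) < 0.3
  icd_case <- is_case & stats::runif(n) < 0.7
  none <- is_case & !(rome3 | dhq | selfrep | icd_case)
  dhq[none] <- TRUE
  flags <- data.frame(participant_id = pid, rome3 = rome3, dhq_yes = dhq,
                      self_report = selfrep, stringsAsFactors = FALSE)

  d0 <- as.Date(config$date_window[1]); d1 <- as.Date(config$date_window[2])
  rand_date <- function(k) {
    as.character(d0 + floor(stats::runif(k) * (as.numeric(d1 - d0) + 1)))
  }
  recs <- list()
  w <- which(icd_case)
  if (length(w) > 0) {
    recs[[length(recs) + 1L]] <- data.frame(
      participant_id = pid[w], code = config$exposure_icd10,
      system = "ICD10", date = rand_date(length(w)),
      stringsAsFactors = FALSE)
  }
  for (k in seq_along(onames)) {
    w <- which(Y[, k] == 1L)
    if (length(w) > 0) {
      recs[[length(recs) + 1L]] <- data.frame(
        participant_id = pid[w], code = config$outcome_specs[[k]]$icd10,
        system = "ICD10", date = rand_date(length(w)),
        stringsAsFactors = FALSE)
    }
  }
  n_excl <- round(config$frac_exclusion * n)
  if (n_excl > 0) {
    w <- sample.int(n, n_excl)
    recs[[length(recs) + 1L]] <- data.frame(
      participant_id = pid[w], code = config$exclusion_icd10,
      system = "ICD10", date = rand_date(n_excl),
      stringsAsFactors = FALSE)
  }
  diagnoses <- if (length(recs) > 0) do.call(rbind, recs) else
    data.frame(participant_id = character(0), code = character(0),
               system = character(0), date = character(0),
               stringsAsFactors = FALSE)

  # emit a fraction of records in ICD-9 where the synthetic mapping covers
  # the code, exercising the ICD-9 -> ICD-10 conversion downstream
  if (nrow(diagnoses) > 0 && config$icd9_fraction > 0) {
    m <- config$icd9_map
    rev_map <- stats::setNames(m$icd9, m$icd10)
    mappable <- diagnoses$code %in% names(rev_map)
    to9 <- mappable & stats::runif(nrow(diagnoses)) < config$icd9_fraction
    diagnoses$code[to9] <- unname(rev_map[diagnoses$code[to9]])
    diagnoses$system[to9] <- "ICD9"
  }
  rownames(diagnoses) <- NULL

  truth <- list(
    causal_ids = ids[causal],
    b = stats::setNames(b, ids[causal]),
    tau = tau,
    h2_liability = config$h2_liability,
    confounder = U,
    liability = L,
    lambda = lambda,
    exposure = exposure,
    outcomes = Y,
    outcome_intercepts = stats::setNames(intercepts, onames),
    causal_beta = stats::setNames(
      vapply(config$outcome_specs, `[[`, 0, "causal_beta"), onames),
    beta_marginal = stats::setNames(beta_marginal, onames)
  )

  structure(list(dosage = G, variants = variants, covariates = covariates,
                 flags = flags, diagnoses = diagnoses, truth = truth,
                 config = config),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$dosage), "participants,",
      ncol(x$dosage), "variants\n")
  cat("  exposure prevalence:",
      format(mean(x$truth$exposure), digits = 3), "\n")
  cat("  outcomes:", if (ncol(x$truth$outcomes) > 0)
    paste(colnames(x$truth$outcomes), collapse = ", ") else "(none)", "\n")
  cat("  diagnosis records:", nrow(x$diagnoses), "\n")
  invisible(x)
}

#' Write a cohort dataset to a directory of TSV files
#'
#' Files written: `dosages.tsv`, `variants.tsv`, `covariates.tsv`,
#' `flags.tsv`, `diagnoses.tsv`, `truth_participants.tsv`,
#' `truth_variants.tsv`, `truth_scalars.yaml`, `outcomes.tsv`. Doubles are
#' written with 17 significant digits so [read_cohort()] reproduces the
#' dataset exactly.
#'
#' @param dataset A `cohort_dataset`.
#' @param directory Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(dataset, directory) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(directory, f)

  dos <- data.frame(participant_id = dataset$covariates$participant_id,
                    dataset$dosage, check.names = FALSE)
  write_tsv_exact(dos, fp("dosages.tsv"))
  write_tsv_exact(dataset$variants, fp("variants.tsv"))
  write_tsv_exact(dataset$covariates, fp("covariates.tsv"))
  write_tsv_exact(dataset$flags, fp("flags.tsv"))
  write_tsv_exact(dataset$diagnoses, fp("diagnoses.tsv"))

  tr <- dataset$truth
  write_tsv_exact(data.frame(participant_id =
                               dataset$covariates$participant_id,
                             confounder = tr$confounder,
                             liability = tr$liability,
                             lambda = tr$lambda,
                             exposure = tr$exposure),
                  fp("truth_participants.tsv"))
  write_tsv_exact(data.frame(id = tr$causal_ids, b = unname(tr$b)),
                  fp("truth_variants.tsv"))
  if (ncol(tr$outcomes) > 0) {
    write_tsv_exact(data.frame(participant_id =
                                 dataset$covariates$participant_id,
                               tr$outcomes, check.names = FALSE),
                    fp("outcomes.tsv"))
  } else {
    write_tsv_exact(data.frame(participant_id =
                                 dataset$covariates$participant_id),
                    fp("outcomes.tsv"))
  }
  yaml::write_yaml(list(
    tau = tr$tau, h2_liability = tr$h2_liability,
    outcome_intercepts = as.list(tr$outcome_intercepts),
    causal_beta = as.list(tr$causal_beta),
    beta_marginal = as.list(tr$beta_marginal)
  ), fp("truth_scalars.yaml"), precision = 17)
  invisible(directory)
}

#' Read a cohort dataset written by [write_cohort()]
#'
#' @param directory Directory containing the cohort file set.
#' @return A `cohort_dataset`; `read_cohort(write_cohort(x))` reproduces
#'   `x`'s data exactly (the simulation `config` is not persisted).
#' @export
read_cohort <- function(directory) {
  fp <- function(f) {
    path <- file.path(directory, f)
    if (!file.exists(path)) stop("missing cohort file: ", path)
    path
  }
  dos_path <- fp("dosages.tsv")
  nf <- utils::count.fields(dos_path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop("malformed dosage file ", dos_path, ": line ", bad, " has ",
         nf[bad], " fields, expected ", nf[1])
  }
  dos <- read_tsv(dos_path)
  G <- as.matrix(dos[, -1, drop = FALSE])
  storage.mode(G) <- "integer"
  variants <- read_tsv(fp("variants.tsv"))
  covariates <- read_tsv(fp("covariates.tsv"))
  flags <- read_tsv(fp("flags.tsv"))
  diagnoses <- read_tsv(fp("diagnoses.tsv"),
                        colClasses = c(code = "character"))
  tp <- read_tsv(fp("truth_participants.tsv"))
  tv <- read_tsv(fp("truth_variants.tsv"))
  om <- read_tsv(fp("outcomes.tsv"))
  Y <- as.matrix(om[, -1, drop = FALSE])
  if (ncol(Y) > 0) storage.mode(Y) <- "integer"
  sc <- yaml::read_yaml(fp("truth_scalars.yaml"))
  truth <- list(
    causal_ids = as.character(tv$id),
    b = stats::setNames(tv$b, tv$id),
    tau = sc$tau, h2_liability = sc$h2_liability,
    confounder = tp$confounder, liability = tp$liability,
    lambda = tp$lambda, exposure = as.integer(tp$exposure),
    outcomes = Y,
    outcome_intercepts = unlist(sc$outcome_intercepts),
    causal_beta = unlist(sc$causal_beta),
    beta_marginal = unlist(sc$beta_marginal)
  )
  for (f in c("outcome_intercepts", "causal_beta", "beta_marginal")) {
    if (length(truth[[f]]) == 0)
      truth[[f]] <- stats::setNames(numeric(0), character(0))
  }
  structure(list(dosage = G, variants = variants, covariates = covariates,
                 flags = flags, diagnoses = diagnoses, truth = truth,
                 config = NULL),
            class = "cohort_dataset")
}

#' Simulate harmonized-scale GWAS summary statistics for MR
#'
#' Generates paired exposure/outcome summary statistics for `m` instruments
#' under a chosen pleiotropy regime, for testing and calibrating the
#' summary-level MR estimators without a full cohort. Exposure effects are
#' drawn with per-instrument F-statistics uniform in `f_range` (default
#' 19-39, a realistic band for instruments selected at a relaxed p-value
#' threshold).
#'
#' @param m Number of instruments.
#' @param beta True causal effect (log-OR outcome per unit exposure
#'   log-odds).
#' @param pleiotropy One of `"none"`, `"balanced"`, `"directional"`,
#'   `"outlier"`.
#' @param pleio_sd SD of balanced/directional pleiotropic effects.
#' @param pleio_mean Mean pleiotropic effect (directional only).
#' @param outlier_scale For `"outlier"`: the single outlier's direct effect
#'   expressed in units of its outcome SE.
#' @param frac_invalid Fraction of instruments receiving pleiotropic
#'   effects under `"balanced"`/`"directional"`.
#' @param gamma_range Range of true exposure effects.
#' @param f_range Range of instrument F-statistics.
#' @param se_outcome_range Range of outcome-side standard errors.
#' @param n_exposure,n_outcome Sample sizes recorded in the tables.
#' @param seed Seed.
#' @return List with data frames `exposure` and `outcome` (columns `id`,
#'   `ea`, `oa`, `eaf`, `beta`, `se`, `p`, `n`) and a `truth` list.
#' @export
simulate_instruments <- function(m = 80, beta = 0.1,
                                 pleiotropy = c("none", "balanced",
                                                "directional", "outlier"),
                                 pleio_sd = 0.01, pleio_mean = 0.02,
                                 outlier_scale = 10, frac_invalid = 0.3,
                                 gamma_range = c(0.05, 0.15),
                                 f_range = c(19, 39),
                                 se_outcome_range = c(0.01, 0.02),
                                 n_exposure = 50000, n_outcome = 300000,
                                 seed = 1L) {
  pleiotropy <- match.arg(pleiotropy)
  set.seed(seed)
  gamma <- stats::runif(m, gamma_range[1], gamma_range[2])
  Fj <- stats::runif(m, f_range[1], f_range[2])
  se_x <- gamma / sqrt(Fj)
  se_y <- stats::runif(m, se_outcome_range[1], se_outcome_range[2])

  alpha <- rep(0, m)
  invalid <- integer(0)
  if (pleiotropy == "balanced") {
    invalid <- sample.int(m, round(frac_invalid * m))
    alpha[invalid] <- stats::rnorm(length(invalid), 0, pleio_sd)
  } else if (pleiotropy == "directional") {
    invalid <- sample.int(m, round(frac_invalid * m))
    alpha[invalid] <- stats::rnorm(length(invalid), pleio_mean, pleio_sd)
  } else if (pleiotropy == "outlier") {
    invalid <- sample.int(m, 1)
    alpha[invalid] <- outlier_scale * se_y[invalid]
  }

  gamma_hat <- gamma + stats::rnorm(m, 0, se_x)
  Gamma_hat <- beta * gamma + alpha + stats::rnorm(m, 0, se_y)
  eaf <- stats::runif(m, 0.1, 0.9)
  pairs <- rbind(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"))
  pk <- sample.int(4, m, replace = TRUE)
  ids <- sprintf("rs%05d", sample.int(99999, m))
  mk <- function(bhat, se, n) data.frame(
    id = ids, ea = pairs[pk, 1], oa = pairs[pk, 2], eaf = eaf,
    beta = bhat, se = se, p = 2 * stats::pnorm(-abs(bhat / se)), n = n,
    stringsAsFactors = FALSE)
  list(exposure = mk(gamma_hat, se_x, n_exposure),
       outcome = mk(Gamma_hat, se_y, n_outcome),
       truth = list(beta = beta, gamma = gamma, alpha = alpha,
                    invalid = ids[invalid], f = Fj))
}
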