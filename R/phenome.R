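#' Published baseline characteristics of a large mid-life cohort
#'
#' Aggregate baseline counts (n = 346,352) cross-tabulating demographic and
#' lifestyle characteristics against a questionnaire/ICD-ascertained
#' irritable bowel syndrome exposure, shipped as example input for the
#' descriptive contingency-table tests. Counts are reproduced as printed;
#' note the published sex rows are internally inconsistent (the `total`
#' column does not equal `exposure + no_exposure` for male/female,
#' suggesting a column swap at source), so cohort-level shares should be
#' computed from `total`.
#'
#' @return Data frame with columns `characteristic`, `level`, `total`,
#'   `exposure`, `no_exposure`.
#' @export
baseline_counts <- function() {
  read_tsv(system.file("extdata", "baseline_counts.tsv",
                       package = "phewasmr"))
}

normalize_icd <- function(code) toupper(gsub("\\.", "", trimws(code)))

#' Load an ICD-9 to ICD-10 mapping table
#'
#' @param path TSV file with two columns, `icd9` and `icd10`; dots are
#'   stripped and codes upper-cased on load.
#' @return Data frame with columns `icd9` and `icd10`.
#' @export
load_icd9_map <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (any(nf != 2)) {
    stop("malformed mapping file ", path, ": line ",
         which(nf != 2)[1], " does not have two columns")
  }
  m <- read_tsv(path, colClasses = "character")
  if (!all(c("icd9", "icd10") %in% names(m))) {
    stop("mapping file must have columns 'icd9' and 'icd10'")
  }
  m$icd9 <- normalize_icd(m$icd9)
  m$icd10 <- normalize_icd(m$icd10)
  m
}

#' Map ICD-9 codes to ICD-10 via a general-equivalence-style table
#'
#' ICD-10 codes (identified by their leading letter) pass through
#' unchanged. ICD-9 codes found in the mapping are converted; unmapped
#' codes are returned as `NA` and counted in the `unmapped` attribute so
#' callers can log and drop them.
#'
#' @param codes Character vector of diagnosis codes.
#' @param mapping Data frame from [load_icd9_map()] (or any two-column
#'   `icd9`/`icd10` frame).
#' @return Character vector of ICD-10 codes (`NA` where unmapped), with
#'   attribute `unmapped` giving the count of unmapped ICD-9 codes.
#' @export
map_icd9_to_icd10 <- function(codes, mapping) {
  stopifnot(length(codes) >= 0, all(nzchar(codes) | is.na(codes)))
  codes <- normalize_icd(codes)
  is_icd10 <- grepl("^[A-Z]", codes)
  out <- codes
  lut <- stats::setNames(mapping$icd10, mapping$icd9)
  out[!is_icd10] <- unname(lut[codes[!is_icd10]])
  structure(out, unmapped = sum(is.na(out) & !is.na(codes)))
}

#' Default ICD-10 chapter whitelist for phecode construction
#'
#' Letter stems of ICD-10 chapters I-XV and XVII (certain infectious
#' diseases through congenital malformations), excluding perinatal
#' conditions (P), symptoms/signs not elsewhere classified (R), injury and
#' poisoning (S-T) and external/special-purpose chapters (U-Z).
#'
#' @return Character vector of permitted leading letters.
#' @export
default_chapter_whitelist <- function() c(LETTERS[1:15], "Q")

#' Build 3-character phecodes from diagnosis records
#'
#' Diagnoses are normalized, ICD-9 records converted to ICD-10 where a
#' mapping is supplied (unmapped records dropped), truncated to their first
#' three characters, restricted to the chapter whitelist, and aggregated to
#' per-participant indicators. Phecodes with case counts not exceeding
#' `min_cases` are dropped.
#'
#' @param diagnoses Data frame with columns `participant_id`, `code`,
#'   `system` (`"ICD9"`/`"ICD10"`; optional, inferred when absent).
#' @param participants Character vector of all participant ids (defines the
#'   control denominator and indicator row order).
#' @param icd9_map Optional mapping data frame for ICD-9 conversion.
#' @param chapter_whitelist Permitted leading letters
#'   (default [default_chapter_whitelist()]).
#' @param min_cases Minimum case count; retention is strict
#'   (`case_count > min_cases`), default 250.
#' @return A `phecode_table`: list with `summary` (phecode, case_count,
#'   control_count, member_codes), `indicator` (participants x phecodes 0/1
#'   matrix) and counts of dropped records.
#' @export
build_phecodes <- function(diagnoses, participants, icd9_map = NULL,
                           chapter_whitelist = default_chapter_whitelist(),
                           min_cases = 250) {
  n <- length(participants)
  empty <- function() structure(
    list(summary = data.frame(phecode = character(0),
                              case_count = integer(0),
                              control_count = integer(0),
                              member_codes = character(0),
                              stringsAsFactors = FALSE),
         indicator = matrix(0L, n, 0, dimnames = list(participants, NULL)),
         n_unmapped = 0L, n_off_chapter = 0L),
    class = "phecode_table")
  if (nrow(diagnoses) == 0) return(empty())

  code <- normalize_icd(diagnoses$code)
  if (!is.null(icd9_map)) {
    is9 <- if ("system" %in% names(diagnoses)) {
      diagnoses$system == "ICD9"
    } else !grepl("^[A-Z]", code)
    code[is9] <- map_icd9_to_icd10(code[is9], icd9_map)
  }
  n_unmapped <- sum(is.na(code))
  keep <- !is.na(code) & grepl("^[A-Z][0-9]{2}", code) &
    diagnoses$participant_id %in% participants
  code <- code[keep]
  pidx <- match(diagnoses$participant_id[keep], participants)
  stem <- substr(code, 1, 3)
  in_chap <- substr(stem, 1, 1) %in% chapter_whitelist
  n_off <- sum(!in_chap)
  stem <- stem[in_chap]; code <- code[in_chap]; pidx <- pidx[in_chap]
  if (length(stem) == 0) {
    out <- empty(); out$n_unmapped <- n_unmapped; out$n_off_chapter <- n_off
    return(out)
  }

  pairs <- unique(data.frame(pidx = pidx, stem = stem,
                             stringsAsFactors = FALSE))
  counts <- table(pairs$stem)
  kept <- names(counts)[counts > min_cases]
  kept <- sort(kept)
  ind <- matrix(0L, n, length(kept),
                dimnames = list(participants, kept))
  sel <- pairs$stem %in% kept
  ind[cbind(pairs$pidx[sel], match(pairs$stem[sel], kept))] <- 1L
  members <- vapply(kept, function(s)
    paste(sort(unique(code[stem == s])), collapse = ","), "")
  summary <- data.frame(
    phecode = kept,
    case_count = as.integer(colSums(ind)),
    control_count = n - as.integer(colSums(ind)),
    member_codes = unname(members),
    stringsAsFactors = FALSE)
  structure(list(summary = summary, indicator = ind,
                 n_unmapped = n_unmapped, n_off_chapter = n_off),
            class = "phecode_table")
}

#' @export
print.phecode_table <- function(x, ...) {
  cat("Phecode table:", nrow(x$summary), "phecodes over",
      nrow(x$indicator), "participants\n")
  if (nrow(x$summary) > 0) print(utils::head(x$summary, 10))
  invisible(x)
}

#' Ascertain binary exposure status from flags and diagnosis records
#'
#' A participant is an exposure case when any of four alternative criteria
#' holds: (1) symptom-questionnaire criteria (`rome3`), (2) a "yes" answer
#' to the digestive-health questionnaire diagnosis question (`dhq_yes`),
#' (3) self-reported diagnosis (`self_report`), or (4) a clinical ICD-10
#' diagnosis matching `exposure_codes`. Participants carrying a confounding
#' exclusion condition (e.g. inflammatory bowel disease or prior intestinal
#' resection) dated on or before their earliest exposure diagnosis are
#' excluded from the analysis set entirely; carriers of exclusion codes
#' with no dated exposure diagnosis are excluded conservatively.
#'
#' @param flags Data frame with columns `participant_id`, `rome3`,
#'   `dhq_yes`, `self_report`.
#' @param diagnoses Diagnosis records (`participant_id`, `code`, `system`,
#'   `date`).
#' @param exposure_codes Character vector of ICD-10 code prefixes defining
#'   criterion (4); must be non-empty.
#' @param exclusion_codes Character vector of ICD-10 code prefixes defining
#'   the confounding conditions (may be empty).
#' @return Data frame with one row per participant: `participant_id`,
#'   `is_case`, `criteria` (comma-separated labels), `excluded`,
#'   `exclusion_reason`.
#' @export
ascertain_exposure <- function(flags, diagnoses,
                               exposure_codes = "K58",
                               exclusion_codes = character(0)) {
  if (length(exposure_codes) == 0) {
    stop("exposure ICD code list must not be empty")
  }
  exposure_codes <- normalize_icd(exposure_codes)
  exclusion_codes <- normalize_icd(exclusion_codes)
  pid <- flags$participant_id
  code <- normalize_icd(diagnoses$code)
  starts_with_any <- function(x, prefixes) {
    hit <- rep(FALSE, length(x))
    for (p in prefixes) hit <- hit | startsWith(x, p)
    hit
  }
  is_exp <- starts_with_any(code, exposure_codes)
  is_exc <- if (length(exclusion_codes) > 0)
    starts_with_any(code, exclusion_codes) else rep(FALSE, length(code))

  dt <- suppressWarnings(as.Date(diagnoses$date))
  first_date <- function(sel) {
    d <- stats::aggregate(dt[sel], by = list(diagnoses$participant_id[sel]),
                          FUN = function(z) if (all(is.na(z))) NA else
                            min(z, na.rm = TRUE))
    stats::setNames(as.Date(d$x, origin = "1970-01-01"), d$Group.1)
  }
  exp_date <- if (any(is_exp)) first_date(is_exp) else
    stats::setNames(as.Date(character(0)), character(0))
  exc_date <- if (any(is_exc)) first_date(is_exc) else
    stats::setNames(as.Date(character(0)), character(0))

  icd_case <- pid %in% diagnoses$participant_id[is_exp]
  crit <- cbind(rome3 = as.logical(flags$rome3),
                dhq = as.logical(flags$dhq_yes),
                self_report = as.logical(flags$self_report),
                icd10 = icd_case)
  is_case <- rowSums(crit, na.rm = TRUE) > 0

  excluded <- rep(FALSE, length(pid))
  reason <- rep(NA_character_, length(pid))
  has_exc <- pid %in% names(exc_date)
  for (i in which(has_exc)) {
    ed <- exc_date[[pid[i]]]
    xd <- if (pid[i] %in% names(exp_date)) exp_date[[pid[i]]] else
      as.Date(NA)
    if (is.na(xd)) {
      # exclusion carrier without a dated exposure diagnosis: conservative
      excluded[i] <- TRUE
      reason[i] <- "exclusion condition, no dated exposure diagnosis"
    } else if (!is.na(ed) && ed <= xd) {
      excluded[i] <- TRUE
      reason[i] <- "exclusion condition before exposure diagnosis"
    }
  }

  data.frame(
    participant_id = pid,
    is_case = is_case,
    criteria = apply(crit, 1, function(z)
      paste(colnames(crit)[which(z)], collapse = ",")),
    excluded = excluded,
    exclusion_reason = reason,
    stringsAsFactors = FALSE)
}
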