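map_tab <- data.frame(icd9 = c("5750", "311"), icd10 = c("K810", "F329"),
                      stringsAsFactors = FALSE)

test_that("ICD-9 codes map through the equivalence table", {
  out <- map_icd9_to_icd10(c("5750", "311", "9999", "K581"), map_tab)
  expect_equal(unname(out[1:2]), c("K810", "F329"))
  expect_true(is.na(out[3]))           # absent from mapping
  expect_equal(unname(out[4]), "K581") # ICD-10 passes through
  expect_equal(attr(out, "unmapped"), 1L)
  # dots stripped, case normalized
  expect_equal(unname(map_icd9_to_icd10("575.0", map_tab)[1]), "K810")
})

test_that("malformed mapping files are rejected at load", {
  path <- withr::local_tempfile(lines = c("icd9\ticd10", "5750\tK810",
                                          "bad-row-no-tab"))
  expect_error(load_icd9_map(path), "two columns")
})

test_that("phecodes truncate to 3-character stems and count members", {
  dx <- data.frame(participant_id = c("a", "a", "b"),
                   code = c("K581", "K589", "K581"),
                   system = "ICD10", date = "2010-01-01",
                   stringsAsFactors = FALSE)
  ph <- build_phecodes(dx, c("a", "b", "c"), min_cases = 0)
  expect_equal(ph$summary$phecode, "K58")
  expect_equal(ph$summary$case_count, 2L)   # a and b, once each
  expect_equal(ph$summary$control_count, 1L)
  expect_equal(ph$summary$member_codes, "K581,K589")
  expect_equal(unname(ph$indicator[, "K58"]), c(1L, 1L, 0L))
})

test_that("the chapter whitelist drops perinatal and symptom chapters", {
  dx <- data.frame(participant_id = c("a", "b", "c", "d"),
                   code = c("P071", "R529", "S720", "K581"),
                   system = "ICD10", date = NA, stringsAsFactors = FALSE)
  ph <- build_phecodes(dx, letters[1:4], min_cases = 0)
  expect_equal(ph$summary$phecode, "K58")
  expect_equal(ph$n_off_chapter, 3L)
  # whitelist is a pure filter: every output letter is whitelisted
  expect_true(all(substr(ph$summary$phecode, 1, 1) %in%
                    default_chapter_whitelist()))
})

test_that("the minimum-case filter is strictly greater-than", {
  mk <- function(k) data.frame(
    participant_id = sprintf("p%03d", seq_len(k)), code = "K581",
    system = "ICD10", date = NA, stringsAsFactors = FALSE)
  all_ids <- sprintf("p%03d", 1:300)
  expect_equal(nrow(build_phecodes(mk(250), all_ids,
                                   min_cases = 250)$summary), 0)
  expect_equal(nrow(build_phecodes(mk(251), all_ids,
                                   min_cases = 250)$summary), 1)
})

test_that("case counts are conserved against the raw pair count", {
  set.seed(42)
  dx <- data.frame(
    participant_id = sample(sprintf("p%02d", 1:40), 200, replace = TRUE),
    code = sample(c("K581", "K589", "F329", "J450", "I109"), 200,
                  replace = TRUE),
    system = "ICD10", date = NA, stringsAsFactors = FALSE)
  ph <- build_phecodes(dx, sprintf("p%02d", 1:40), min_cases = 0)
  pairs <- unique(data.frame(p = dx$participant_id,
                             s = substr(dx$code, 1, 3)))
  expect_equal(sum(ph$summary$case_count), nrow(pairs))
})

test_that("empty diagnoses give an empty phecode table, not an error", {
  ph <- build_phecodes(data.frame(participant_id = character(0),
                                  code = character(0),
                                  system = character(0),
                                  date = character(0)),
                       c("a", "b"))
  expect_equal(nrow(ph$summary), 0)
  expect_equal(dim(ph$indicator), c(2, 0))
})

test_that("exposure is the union of the four ascertainment criteria", {
  flags <- data.frame(participant_id = c("q", "r", "s", "t"),
                      rome3 = c(FALSE, FALSE, FALSE, FALSE),
                      dhq_yes = c(TRUE, FALSE, FALSE, FALSE),
                      self_report = FALSE, stringsAsFactors = FALSE)
  dx <- data.frame(participant_id = "s", code = "K580", system = "ICD10",
                   date = "2010-05-05", stringsAsFactors = FALSE)
  asc <- ascertain_exposure(flags, dx, exposure_codes = "K58")
  expect_equal(asc$is_case, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(asc$criteria[1], "dhq")
  expect_equal(asc$criteria[3], "icd10")
  expect_false(any(asc$excluded))
})

test_that("exclusion conditions dated before diagnosis remove participants", {
  flags <- data.frame(participant_id = c("a", "b", "c"),
                      rome3 = FALSE, dhq_yes = FALSE, self_report = FALSE,
                      stringsAsFactors = FALSE)
  dx <- data.frame(
    participant_id = c("a", "a", "b", "b", "c"),
    code = c("K509", "K580", "K509", "K580", "K580"),
    system = "ICD10",
    date = c("2005-01-01", "2010-01-01",   # a: IBD before IBS -> excluded
             "2012-01-01", "2010-01-01",   # b: IBD after IBS -> kept
             "2010-01-01"),
    stringsAsFactors = FALSE)
  asc <- ascertain_exposure(flags, dx, exposure_codes = "K58",
                            exclusion_codes = "K50")
  expect_true(asc$excluded[asc$participant_id == "a"])
  expect_false(asc$excluded[asc$participant_id == "b"])
  expect_false(asc$excluded[asc$participant_id == "c"])
  expect_match(asc$exclusion_reason[asc$participant_id == "a"], "before")
})

test_that("exclusion carriers without dated exposure are excluded conservatively", {
  flags <- data.frame(participant_id = "z", rome3 = FALSE, dhq_yes = TRUE,
                      self_report = FALSE, stringsAsFactors = FALSE)
  dx <- data.frame(participant_id = "z", code = "K509", system = "ICD10",
                   date = "2005-01-01", stringsAsFactors = FALSE)
  asc <- ascertain_exposure(flags, dx, exposure_codes = "K58",
                            exclusion_codes = "K50")
  expect_true(asc$excluded)
})

test_that("ascertainment is monotone in the criteria", {
  flags0 <- data.frame(participant_id = "m", rome3 = FALSE,
                       dhq_yes = FALSE, self_report = FALSE,
                       stringsAsFactors = FALSE)
  empty_dx <- data.frame(participant_id = character(0),
                         code = character(0), system = character(0),
                         date = character(0))
  base <- ascertain_exposure(flags0, empty_dx, "K58")
  expect_false(base$is_case)
  for (f in c("rome3", "dhq_yes", "self_report")) {
    fl <- flags0; fl[[f]] <- TRUE
    expect_true(ascertain_exposure(fl, empty_dx, "K58")$is_case)
  }
})

test_that("an empty exposure code list is a configuration error", {
  flags <- data.frame(participant_id = "a", rome3 = FALSE, dhq_yes = FALSE,
                      self_report = FALSE)
  expect_error(ascertain_exposure(flags, data.frame(), character(0)),
               "must not be empty")
})
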