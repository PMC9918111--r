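test_that("realized exposure prevalence tracks the configured target", {
  cfg <- quick_config(n = 20000, n_snps = 50, seed = 11)
  ds <- simulate_cohort(cfg)
  prev <- mean(ds$truth$exposure)
  expect_gt(prev, 0.105)
  expect_lt(prev, 0.125)
})

test_that("null effects give no exposure-outcome association", {
  covered <- 0L
  for (s in 1:12) {
    cfg <- quick_config(
      n = 6000, n_snps = 30, seed = 200 + s,
      outcome_specs = list(outcome_spec("null_dx", "J459", 0.1)))
    ds <- simulate_cohort(cfg)
    tab <- table(ds$truth$exposure, ds$truth$outcomes[, "null_dx"])
    lor <- log(tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1]))
    se <- sqrt(sum(1 / tab))
    if (abs(lor) < 1.96 * se) covered <- covered + 1L
  }
  expect_gte(covered, 10L)
})

test_that("realized allele frequencies concentrate at the configured MAF", {
  cfg <- quick_config(n = 20000, n_snps = 50, seed = 3,
                      maf_range = c(0.3, 0.3))
  ds <- simulate_cohort(cfg)
  expect_true(all(ds$variants$eaf >= 0.27 & ds$variants$eaf <= 0.33))
  # the stored EAF is the realized column mean / 2
  expect_equal(ds$variants$eaf, unname(colMeans(ds$dosage) / 2))
})

test_that("LD blocks induce the requested correlation structure", {
  base <- list(n_participants = 20000, n_snps = 40, ld_block_size = 8,
               n_causal_snps = 8, h2_liability = 0.2,
               frac_palindromic = 0, frac_exclusion = 0,
               icd9_fraction = 0, maf_range = c(0.2, 0.4))
  ds0 <- simulate_cohort(do.call(sim_config,
                                 c(base, list(ld_rho = 0, seed = 5))))
  r2_0 <- cor(ds0$dosage)^2
  off0 <- r2_0[upper.tri(r2_0)]
  expect_lt(mean(off0), 3 / 20000)

  ds9 <- simulate_cohort(do.call(sim_config,
                                 c(base, list(ld_rho = 0.9, seed = 5))))
  r2_9 <- cor(ds9$dosage)^2
  blk <- rep(1:5, each = 8)
  within <- outer(blk, blk, "==") & upper.tri(r2_9)
  expect_gt(mean(r2_9[within]), 0.5)
  between <- !outer(blk, blk, "==") & upper.tri(r2_9)
  expect_lt(mean(r2_9[between]), 0.01)
})

test_that("a fixed seed reproduces the dataset exactly", {
  cfg <- quick_config(n = 500, n_snps = 20, seed = 77,
                      outcome_specs = list(outcome_spec("dx", "K219", 0.1)))
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
})

test_that("palindromic variants receive ambiguous alleles and band EAFs", {
  cfg <- sim_config(n_participants = 3000, n_snps = 40, ld_rho = 0,
                    frac_palindromic = 0.5,
                    frac_palindromic_intermediate = 1,
                    n_causal_snps = 5, seed = 9)
  ds <- simulate_cohort(cfg)
  pal <- ds$variants[ds$variants$palindromic, ]
  expect_equal(nrow(pal), 20)
  expect_true(all(pal$oa == chartr("ACGT", "TGCA", pal$ea)))
  # frequencies drawn from the intermediate band, up to sampling noise
  expect_true(all(pal$eaf > 0.38 & pal$eaf < 0.62))
})

test_that("infeasible outcome prevalence is reported with the outcome name", {
  cfg <- quick_config(
    n = 1000, n_snps = 20, seed = 2,
    outcome_specs = list(outcome_spec("impossible", "A150", 1e-4,
                                      causal_beta = 40)))
  expect_error(simulate_cohort(cfg), "impossible")
})

test_that("cohort write/read round-trips exactly", {
  cfg <- quick_config(
    n = 300, n_snps = 15, seed = 13, frac_exclusion = 0.01,
    icd9_fraction = 0.3,
    outcome_specs = list(outcome_spec("dx", "K219", 0.15,
                                      causal_beta = 0.3)))
  ds <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(ds, dir)
  back <- read_cohort(dir)
  for (f in c("dosage", "variants", "covariates", "flags")) {
    expect_equal(back[[f]], ds[[f]], ignore_attr = FALSE)
  }
  expect_equal(back$diagnoses, ds$diagnoses, ignore_attr = TRUE)
  expect_equal(back$truth, ds$truth, tolerance = 1e-15)
})

test_that("a truncated dosage file fails naming the file and line", {
  ds <- simulate_cohort(quick_config(n = 50, n_snps = 5, seed = 1))
  dir <- withr::local_tempdir()
  write_cohort(ds, dir)
  path <- file.path(dir, "dosages.tsv")
  lines <- readLines(path)
  lines[10] <- sub("\t[0-2]$", "", lines[10])
  writeLines(lines, path)
  expect_error(read_cohort(dir), "dosages.tsv.*line 10")
})

test_that("an empty outcome list yields a dataset with zero outcomes", {
  ds <- simulate_cohort(quick_config(n = 200, n_snps = 10, seed = 4))
  expect_equal(ncol(ds$truth$outcomes), 0)
  dir <- withr::local_tempdir()
  write_cohort(ds, dir)
  expect_equal(ncol(read_cohort(dir)$truth$outcomes), 0)
})

test_that("null variants give uniform GWAS p-values", {
  # exposure driven by a handful of causal variants; all other variants
  # are null and their association p-values should be uniform
  cfg <- quick_config(n = 4000, n_snps = 210, seed = 21)
  ds <- simulate_cohort(cfg)
  ss <- gwas_scan(ds, ds$truth$exposure,
                  covariates = c("age", "sex"))
  nulls <- setdiff(ss$id, ds$truth$causal_ids)
  p <- ss$p[match(nulls, ss$id)]
  p <- p[!is.na(p)]
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
})

test_that("summary-level instrument simulator plants what it reports", {
  sim <- simulate_instruments(m = 50, beta = 0.2, seed = 8)
  expect_equal(nrow(sim$exposure), 50)
  expect_true(all(sim$truth$f >= 19 & sim$truth$f <= 39))
  # reported F-statistics in the instrument set reflect the planted band,
  # up to estimation noise in gamma-hat
  h <- harmonize(sim$exposure, sim$outcome)
  expect_equal(nrow(h), 50)
  expect_gt(mean(h$f_stat), 18)
  expect_lt(mean(h$f_stat), 46)
})
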