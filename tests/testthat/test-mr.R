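mk_stats <- function(id, ea, oa, eaf, beta, se, n = 1e5) {
  data.frame(id = id, ea = ea, oa = oa, eaf = eaf, beta = beta, se = se,
             p = 2 * pnorm(-abs(beta / se)), n = n,
             stringsAsFactors = FALSE)
}

test_that("harmonization aligns swapped alleles as an involution", {
  ex <- mk_stats("rs1", "A", "G", 0.3, 0.1, 0.01)
  ou_same <- mk_stats("rs1", "A", "G", 0.3, 0.05, 0.02)
  ou_swap <- mk_stats("rs1", "G", "A", 0.7, -0.05, 0.02)
  h1 <- harmonize(ex, ou_same)
  h2 <- harmonize(ex, ou_swap)
  expect_equal(h2$beta_outcome, h1$beta_outcome)
  expect_equal(h2$eaf_outcome, h1$eaf_outcome)
  # re-harmonizing the harmonized set is the identity
  h3 <- harmonize(instruments_exposure(h2), instruments_outcome(h2))
  expect_equal(as.data.frame(h3), as.data.frame(h2), ignore_attr = TRUE)
})

test_that("strand flips are recognized", {
  ex <- mk_stats("rs2", "A", "G", 0.3, 0.1, 0.01)
  ou_flip <- mk_stats("rs2", "T", "C", 0.3, 0.05, 0.02)       # complement
  ou_flipswap <- mk_stats("rs2", "C", "T", 0.7, -0.05, 0.02)  # + swap
  expect_equal(harmonize(ex, ou_flip)$beta_outcome, 0.05)
  expect_equal(harmonize(ex, ou_flipswap)$beta_outcome, 0.05)
})

test_that("palindromic variants follow the intermediate-frequency rule", {
  ex <- mk_stats(c("rs3", "rs4", "rs5"), c("A", "C", "C"),
                 c("T", "G", "G"), c(0.50, 0.30, 0.30),
                 c(0.1, 0.1, 0.1), 0.01)
  ou <- mk_stats(c("rs3", "rs4", "rs5"), c("A", "C", "C"),
                 c("T", "G", "G"), c(0.50, 0.31, 0.69),
                 c(0.05, 0.05, 0.05), 0.02)
  h <- harmonize(ex, ou)
  log <- attr(h, "log")
  expect_false("rs3" %in% h$id)  # EAF 0.50: strand unresolvable
  expect_match(log$reason[log$id == "rs3"], "palindromic")
  expect_equal(h$beta_outcome[h$id == "rs4"], 0.05)   # frequencies agree
  expect_equal(h$beta_outcome[h$id == "rs5"], -0.05)  # aligned by frequency
  expect_equal(h$eaf_outcome[h$id == "rs5"], 0.31)
  # band edges are inclusive
  ex2 <- mk_stats(c("rs6", "rs7"), "A", "T", c(0.42, 0.58), 0.1, 0.01)
  ou2 <- mk_stats(c("rs6", "rs7"), "A", "T", c(0.42, 0.58), 0.05, 0.02)
  expect_equal(nrow(harmonize(ex2, ou2)), 0)
})

test_that("strict EAF exclusion also drops non-palindromic variants", {
  ex <- mk_stats(c("rs8", "rs9"), "A", "G", c(0.50, 0.30), 0.1, 0.01)
  ou <- mk_stats(c("rs8", "rs9"), "A", "G", c(0.50, 0.30), 0.05, 0.02)
  expect_equal(nrow(harmonize(ex, ou)), 2)
  h <- harmonize(ex, ou, strict_eaf_exclusion = TRUE)
  expect_equal(h$id, "rs9")
})

test_that("incompatible allele pairs are dropped with a reason", {
  ex <- mk_stats("rs10", "A", "G", 0.3, 0.1, 0.01)
  ou <- mk_stats("rs10", "A", "C", 0.3, 0.05, 0.02)
  h <- harmonize(ex, ou)
  expect_equal(nrow(h), 0)
  expect_equal(attr(h, "log")$reason, "incompatible alleles")
})

test_that("Wald ratio arithmetic and antisymmetry", {
  e <- wald_ratio(0.25, 0.01, 0.05, 0.02)
  expect_equal(e$beta, 0.2)
  expect_equal(e$se, 0.08)
  en <- wald_ratio(-0.25, 0.01, 0.05, 0.02)
  expect_equal(en$beta, -0.2)
  expect_equal(en$se, 0.08)
  expect_error(wald_ratio(0, 0.01, 0.05, 0.02), "zero exposure effect")
})

test_that("IVW degenerates to the Wald ratio for one instrument", {
  h <- make_instruments(m = 30, seed = 4)[1, ]
  e <- ivw(as_instrument_set(h))
  w <- wald_ratio(h$beta_exposure, h$se_exposure, h$beta_outcome,
                  h$se_outcome)
  expect_equal(e$beta, w$beta)
  expect_equal(e$se, w$se)
})

test_that("IVW with equal weights is the plain mean of ratios", {
  ins <- as_instrument_set(data.frame(
    id = c("a", "b"), ea = "A", oa = "G",
    beta_exposure = 1, se_exposure = 0.1,
    beta_outcome = c(0.1, 0.3), se_outcome = 0.05,
    eaf_exposure = 0.3, eaf_outcome = 0.3, palindromic = FALSE,
    f_stat = 100, n_exposure = 1e5, n_outcome = 1e5))
  expect_equal(ivw(ins, mode = "fixed")$beta, 0.2)
})

test_that("Egger reproduces a perfect line exactly", {
  g <- c(0.1, 0.2, 0.3)
  ins <- as_instrument_set(data.frame(
    id = letters[1:3], ea = "A", oa = "G",
    beta_exposure = g, se_exposure = 0.01,
    beta_outcome = 0.01 + 0.2 * g, se_outcome = 0.02,
    eaf_exposure = 0.3, eaf_outcome = 0.3, palindromic = FALSE,
    f_stat = 100, n_exposure = 1e5, n_outcome = 1e5))
  e <- egger(ins)
  expect_equal(e$beta, 0.2, tolerance = 1e-10)
  expect_equal(e$egger_intercept, 0.01, tolerance = 1e-10)
  expect_error(egger(as_instrument_set(ins[1:2, ])), "insufficient")
})

test_that("a planted directional-pleiotropy intercept is recovered", {
  ints <- replicate(60, {
    h <- make_instruments(m = 40, beta = 0.1, seed = sample.int(1e6, 1),
                          pleiotropy = "directional", pleio_mean = 0.02,
                          pleio_sd = 0.002, frac_invalid = 1)
    egger(h)$egger_intercept
  })
  expect_lt(abs(mean(ints) - 0.02), 0.01)
  expect_gt(mean(ints), 0.01)
})

test_that("weighted median interpolates the 50% weight point", {
  ins <- as_instrument_set(data.frame(
    id = letters[1:3], ea = "A", oa = "G",
    beta_exposure = 1, se_exposure = 0.01,
    beta_outcome = c(0.1, 0.2, 0.3), se_outcome = 0.05,
    eaf_exposure = 0.3, eaf_outcome = 0.3, palindromic = FALSE,
    f_stat = 1e4, n_exposure = 1e5, n_outcome = 1e5))
  e <- weighted_median(ins, n_boot = 200, seed = 1)
  expect_equal(e$beta, 0.2)
  expect_error(weighted_median(as_instrument_set(ins[1, ])), ">= 3")
})

test_that("weighted mode finds point masses and the large-bandwidth limit", {
  ins <- as_instrument_set(data.frame(
    id = letters[1:4], ea = "A", oa = "G",
    beta_exposure = 1, se_exposure = 0.01,
    beta_outcome = 0.15, se_outcome = 0.05,
    eaf_exposure = 0.3, eaf_outcome = 0.3, palindromic = FALSE,
    f_stat = 1e4, n_exposure = 1e5, n_outcome = 1e5))
  expect_equal(weighted_mode(ins, n_boot = 100, seed = 1)$beta, 0.15)

  h <- make_instruments(m = 20, beta = 0.1, seed = 10)
  r <- with(h, beta_outcome / beta_exposure)
  w <- with(h, beta_exposure^2 / se_outcome^2)
  wmean <- sum(w * r) / sum(w)
  e_inf <- weighted_mode(h, bandwidth_factor = 1e4, n_boot = 100, seed = 1)
  expect_equal(e_inf$beta, wmean, tolerance = 1e-3)
  expect_error(weighted_mode(h, bandwidth_factor = 0), "zero bandwidth")
})

test_that("the weighted mode concentrates on the majority cluster", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    m <- 20
    r_true <- c(rep(0.1, 12), rep(0.5, 8))
    ins <- as_instrument_set(data.frame(
      id = sprintf("v%02d", 1:m), ea = "A", oa = "G",
      beta_exposure = 1, se_exposure = 0.01,
      beta_outcome = rnorm(m, r_true, 0.03), se_outcome = 0.03,
      eaf_exposure = 0.3, eaf_outcome = 0.3, palindromic = FALSE,
      f_stat = 1e4, n_exposure = 1e5, n_outcome = 1e5))
    est <- weighted_mode(ins, n_boot = 100, seed = s)$beta
    if (abs(est - 0.1) < abs(est - 0.5)) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("Cochran's Q matches brute force and its null mean", {
  h <- make_instruments(m = 25, seed = 3)
  q <- cochran_q(h)
  r <- with(h, beta_outcome / beta_exposure)
  se_r <- with(h, se_outcome / abs(beta_exposure))
  w <- 1 / se_r^2
  bref <- sum(w * r) / sum(w)
  expect_equal(q$Q, sum(w * (r - bref)^2), tolerance = 1e-10)
  expect_equal(q$df, 24)

  # degenerate: identical ratios
  ins <- as_instrument_set(data.frame(
    id = c("a", "b"), ea = "A", oa = "G", beta_exposure = c(1, 2),
    se_exposure = 0.01, beta_outcome = c(0.2, 0.4), se_outcome = 0.05,
    eaf_exposure = 0.3, eaf_outcome = 0.3, palindromic = FALSE,
    f_stat = 1e4, n_exposure = 1e5, n_outcome = 1e5))
  q0 <- cochran_q(ins)
  expect_equal(q0$Q, 0, tolerance = 1e-20)
  expect_equal(q0$p, 1)

  # homogeneous simulation: E[Q/df] ~ 1
  qs <- vapply(1:200, function(s)
    cochran_q(make_instruments(m = 20, seed = 5000 + s))$Q / 19, 0)
  expect_gt(mean(qs), 0.85)
  expect_lt(mean(qs), 1.2)
})

test_that("Steiger direction responds to where variance is explained", {
  h <- make_instruments(m = 40, beta = 0.1, seed = 6)
  st <- steiger(h)
  expect_true(st$direction_correct)
  # role swap is antisymmetric
  rev <- h
  rev[, c("beta_exposure", "se_exposure", "n_exposure")] <-
    h[, c("beta_outcome", "se_outcome", "n_outcome")]
  rev[, c("beta_outcome", "se_outcome", "n_outcome")] <-
    h[, c("beta_exposure", "se_exposure", "n_exposure")]
  st_rev <- steiger(as_instrument_set(rev))
  expect_false(st_rev$direction_correct)
  expect_equal(st_rev$r2_exposure, st$r2_outcome)
  h$n_exposure <- NA
  expect_error(steiger(h), "sample sizes")
})

test_that("leave-one-out flags the dominant planted outlier", {
  sim <- simulate_instruments(m = 20, beta = 0.1, seed = 9,
                              pleiotropy = "outlier", outlier_scale = 15)
  h <- harmonize(sim$exposure, sim$outcome)
  loo <- leave_one_out(h)
  expect_equal(nrow(loo), 20)
  full <- attr(loo, "full")
  shift <- abs(loo$beta - full$beta)
  expect_equal(loo$id_left_out[which.max(shift)], sim$truth$invalid)
  # homogeneous instruments: all rows inside the full-set CI
  h0 <- make_instruments(m = 20, beta = 0.1, seed = 11)
  loo0 <- leave_one_out(h0)
  f0 <- attr(loo0, "full")
  expect_true(all(loo0$beta > f0$ci_low & loo0$beta < f0$ci_high))
  expect_false(any(loo0$flagged))
  expect_error(leave_one_out(h0[1:2, ]), ">= 3")
})

test_that("pleiotropy pruning removes exactly the flagged variants", {
  h <- make_instruments(m = 20, seed = 12)
  sec <- data.frame(id = h$id, p = rep(0.5, 20))
  expect_equal(nrow(prune_pleiotropic(h, sec)), 20)  # identity
  sec$p[c(3, 7, 11)] <- 1e-6
  pruned <- prune_pleiotropic(h, sec)
  expect_equal(nrow(pruned), 17)
  expect_setequal(attr(pruned, "removed")$id, h$id[c(3, 7, 11)])
  # default threshold is the phenome-wide Bonferroni level
  expect_equal(eval(formals(prune_pleiotropic)$p_threshold), 0.05 / 665)
})

test_that("instrument selection reports F statistics and errors when empty", {
  set.seed(2)
  ld <- matrix(rbinom(400, 2, 0.3), 200, 2,
               dimnames = list(NULL, c("s1", "s2")))
  ss <- data.frame(id = c("s1", "s2"), chrom = 1, pos = c(1e6, 5e7),
                   ea = "A", oa = "G", eaf = 0.3,
                   beta = c(0.05, 0.2), se = c(0.01, 0.03),
                   p = c(1e-7, 1e-11))
  sel <- select_instruments(ss, ld)
  expect_equal(sel$f_stat[sel$id == "s1"], 25)
  expect_equal(sel$f_stat, (ss$beta / ss$se)[match(sel$id, ss$id)]^2,
               tolerance = 1e-12)
  ss$p <- 0.5
  expect_error(select_instruments(ss, ld), "no instruments")
})

test_that("negating outcome effects negates estimates, p unchanged", {
  h <- make_instruments(m = 25, beta = 0.1, seed = 13)
  hn <- h; hn$beta_outcome <- -h$beta_outcome
  for (fn in list(function(x) ivw(x, "fixed"),
                  function(x) ivw(x, "multiplicative_random"), egger)) {
    a <- fn(h); b <- fn(as_instrument_set(hn))
    expect_equal(b$beta, -a$beta, tolerance = 1e-12)
    expect_equal(b$p, a$p, tolerance = 1e-12)
  }
  expect_equal(weighted_median(as_instrument_set(hn), 100, 1)$beta,
               -weighted_median(h, 100, 1)$beta, tolerance = 1e-10)
})

test_that("per-doubling ORs follow exp(0.693 beta)", {
  expect_equal(signif(per_doubling_or(1), 3), 2.00)
  expect_identical(per_doubling_or(0), 1)
  expect_equal(per_doubling_or(1, exact = TRUE), 2)
  h <- make_instruments(m = 10, seed = 14)
  e <- ivw(h)
  expect_equal(e$or_per_doubling, exp(0.693 * e$beta))
  expect_equal(e$or_ci_low, exp(0.693 * e$ci_low))
})

test_that("the estimator suite table is consistent", {
  h <- make_instruments(m = 30, beta = 0.15, seed = 15)
  tab <- mr_suite(h, n_boot = 100, seed = 1)
  expect_setequal(tab$method, c("ivw_fe", "ivw_mre", "egger",
                                "weighted_median", "weighted_mode"))
  expect_true(all(tab$or_per_doubling == exp(0.693 * tab$beta)))
  expect_true(all(tab$n_snp == 30))
})
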