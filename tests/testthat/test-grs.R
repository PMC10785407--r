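test_that("risk-allele assignment follows the allele-model OR", {
  expect_equal(assignRiskAllele(2.106), "variant")
  expect_equal(assignRiskAllele(0.5), "wild")
  expect_warning(r <- assignRiskAllele(1), "convention")
  expect_equal(r, "variant")
  # from a cohort: variant-heavy cases -> variant risk allele
  co <- cohortFromCalls(cbind(c(rep("BB", 20), rep("AA", 20))),
                        rep(c("case", "control"), each = 20),
                        panel = defaultPanel(1))
  expect_equal(unname(assignRiskAlleles(co)), "variant")
})

test_that("risk codes count risk alleles in either orientation", {
  expect_equal(genotypeRiskCode(c("AA", "AB", "BB"), "variant"), 0:2)
  expect_equal(genotypeRiskCode(c("AA", "AB", "BB"), "wild"), 2:0)
  expect_error(genotypeRiskCode(c("AA", NA), "variant"), "missing")
})

test_that("GRS sums codes, is order-invariant and additive", {
  co <- grsCohort(c(12, 0, 7, 5), c("case", "control", "case", "control"))
  snps <- snpPanel(co)$snp_id
  risk <- setNames(rep("variant", 6), snps)
  g <- computeGRS(co, snps, risk)
  expect_equal(g$grs, c(12, 0, 7, 5))
  expect_equal(computeGRS(co, rev(snps), risk)$grs, g$grs)
  g13 <- computeGRS(co, snps[1:3], risk)$grs
  g46 <- computeGRS(co, snps[4:6], risk)$grs
  expect_equal(g13 + g46, g$grs)
  # flipping every risk allele maps GRS to 2K - GRS
  flipped <- setNames(rep("wild", 6), snps)
  expect_equal(computeGRS(co, snps, flipped)$grs, 12 - g$grs)
  expect_error(computeGRS(co, character(0), risk), "empty")
})

test_that("missing-genotype policy excludes or prorates", {
  co <- grsCohort(c(6, 6), c("case", "control"))
  g <- genotypes(co)
  g[1, 1] <- NA
  co2 <- SnpCohort(t(g), snpPanel(co), covariates(co))
  snps <- snpPanel(co2)$snp_id
  risk <- setNames(rep("variant", 6), snps)
  comp <- computeGRS(co2, snps, risk)
  expect_true(is.na(comp$grs[1]))
  expect_equal(comp$n_missing_snps, c(1, 0))
  pro <- computeGRS(co2, snps, risk, policy = "prorate")
  expect_equal(pro$grs[1], (6 - 2) * 6 / 5)  # subject 1 lost a BB snp
})

test_that("the replication-shaped GRS fixture reproduces published rows", {
  pub <- publishedGrsCounts()
  # reconstruct per-subject GRS values consistent with the binned counts
  # (bin medians: reference spread 3..5, open bin at 10/11)
  case_vals <- rep(c(4, 6, 7, 8, 9, 11),
                   times = pub$n_case)
  ctrl_vals <- rep(c(5, 6, 7, 8, 9, 10), times = pub$n_control)
  grs <- c(case_vals, ctrl_vals)
  status <- rep(c("case", "control"), c(sum(pub$n_case),
                                        sum(pub$n_control)))
  expect_equal(median(grs[status == "case"]), 7)
  expect_equal(median(grs[status == "control"]), 5)
  tb <- grsRiskTable(grs, status)
  expect_equal(tb$n_case, pub$n_case)
  expect_equal(tb$n_control, pub$n_control)
  expect_equal(tb$or[1], 1)
  expect_equal(tb$or[-1], c(1.833, 2.826, 2.139, 4.958, 7.583),
               tolerance = 1e-3)
  d <- grsDichotomy(grs, status, cutoff = 6)
  expect_equal(d$or, 2.734, tolerance = 1e-3)
  expect_error(grsDichotomy(grs, status, cutoff = 0), "empty")
  expect_error(grsDichotomy(grs, status, cutoff = 99), "empty")
})

test_that("trend test is null on flat risk and matches a permutation oracle", {
  flat <- grsTrendTest(cases = c(20, 20, 20), totals = c(60, 60, 60))
  expect_lt(flat$chi2, 1e-12)
  expect_equal(flat$p, 1, tolerance = 1e-9)
  expect_error(grsTrendTest(c(10, 20), c(30, 30)), "3 ordered")

  # permutation oracle on a small fixture: the Cochran-Armitage score
  # statistic under label permutation with fixed margins
  cases <- c(9, 12, 17, 22)
  totals <- c(40, 35, 35, 30)
  obs <- grsTrendTest(cases, totals)
  scores <- 0:3
  subj_scores <- rep(scores, totals)
  y <- unlist(mapply(function(k, n) c(rep(1, k), rep(0, n - k)),
                     cases, totals))
  t_obs <- sum(subj_scores * y)
  t_perm <- withr::with_seed(10, vapply(1:4000, function(i)
    sum(subj_scores * sample(y)), numeric(1)))
  p_perm <- mean(abs(t_perm - mean(t_perm)) >= abs(t_obs - mean(t_perm)))
  expect_lt(abs(p_perm - obs$p), 0.02)
})

test_that("additive risk produces an increasing dose-response", {
  panel <- defaultPanel(6, maf = 0.35)
  eff <- lapply(panel$snp_id, function(s)
    effectSpec(s, "additive", log(1.5)))
  cfg <- simulationConfig(1000, 1000, panel = panel, effects = eff,
                          intercept = -2.5, seed = 61)
  co <- simulateCaseControl(cfg)
  risk <- assignRiskAlleles(co)
  expect_true(all(risk == "variant"))
  g <- computeGRS(co, panel$snp_id, risk)
  tb <- grsRiskTable(g$grs, caseStatus(co))
  big <- tb$n_case + tb$n_control >= 20
  expect_true(all(diff(tb$or[big]) > -1e-9))
  expect_lt(attr(tb, "trend_p"), 1e-6)
})
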