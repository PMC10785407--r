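test_that("HWE chi-square matches hand computations", {
  h <- hweTest(25, 50, 25)
  expect_equal(h$chi2, 0)
  expect_equal(h$p, 1)
  h <- hweTest(30, 40, 30)
  expect_equal(h$chi2, 4, tolerance = 1e-12)
  expect_equal(h$p, 0.0455, tolerance = 1e-3)
  h <- hweTest(50, 0, 50)
  expect_equal(h$chi2, 100)
  expect_lt(h$p, 1e-20)
  h <- hweTest(80, 0, 0)
  expect_true(h$monomorphic)
  expect_equal(h$p, 1)
  expect_error(hweTest(0, 0, 0), "positive total")
})

test_that("QC excludes low call rate and control-HWE failures", {
  # 100 controls in exact HWE proportions, plus 10 cases
  calls <- c(rep("AA", 25), rep("AB", 50), rep("BB", 25))
  co <- cohortFromCalls(cbind(c(rep("AA", 10), calls)),
                        c(rep("case", 10), rep("control", 100)),
                        panel = defaultPanel(1))
  qc <- qcFilter(co)
  expect_equal(qc$kept, snpPanel(co)$snp_id)

  # mask 13/110 calls -> call rate 0.88 -> excluded
  calls2 <- cbind(c(rep("AA", 10), calls))
  calls2[withr::with_seed(1, sample.int(110, 13)), 1] <- NA
  co2 <- cohortFromCalls(calls2, c(rep("case", 10), rep("control", 100)),
                         panel = defaultPanel(1))
  qc2 <- qcFilter(co2)
  expect_length(qc2$kept, 0)
  expect_match(qc2$log$reason[1], "call_rate")

  # strong heterozygote deficit in controls (f = 0.5) -> HWE exclusion
  excl <- 0L
  for (s in 1:10) {
    g <- withr::with_seed(s, simulateGenotypes(0.3, 0.5, 500))
    co3 <- cohortFromCalls(cbind(c(rep("AA", 10), g)),
                           c(rep("case", 10), rep("control", 500)),
                           panel = defaultPanel(1))
    q <- qcFilter(co3)
    excl <- excl + (length(q$kept) == 0)
  }
  expect_gte(excl, 9)
  co4 <- cohortFromCalls(cbind(rep("AA", 5)), rep("case", 5),
                         panel = defaultPanel(1))
  expect_error(qcFilter(co4), "controls")
})

test_that("genetic-model encodings follow their dichotomies", {
  calls <- c("AA", "AB", "BB")
  expect_equal(as.character(encodeGeneticModel(calls, "recessive")),
               c("unexposed", "unexposed", "exposed"))
  expect_equal(as.character(encodeGeneticModel(calls, "dominant")),
               c("unexposed", "exposed", "exposed"))
  expect_equal(as.character(encodeGeneticModel(calls, "super_dominant")),
               c("unexposed", "exposed", "unexposed"))
  expect_equal(as.character(encodeGeneticModel(calls, "homozygote")),
               c("unexposed", "excluded", "exposed"))
  expect_equal(unname(encodeGeneticModel(calls, "additive")), 0:2)
  expect_equal(unname(encodeGeneticModel(calls, "allele")), 0:2)
  expect_error(encodeGeneticModel(c("AA", NA), "dominant"), "missing")
})

test_that("2x2 construction counts persons and alleles correctly", {
  co <- cohortFromCalls(cbind(c(rep("BB", 10), rep("AA", 10))),
                        rep(c("case", "control"), each = 10),
                        panel = defaultPanel(1))
  tb <- contingency2x2(co, snpPanel(co)$snp_id[1], "recessive")
  expect_equal(unlist(tb[c("a", "b", "c", "d")]),
               c(a = 10, b = 0, c = 0, d = 10))

  co2 <- cohortFromCalls(cbind(c("AB", "AA")), c("case", "control"),
                         panel = defaultPanel(1))
  tb2 <- contingency2x2(co2, snpPanel(co2)$snp_id[1], "allele")
  expect_equal(unlist(tb2[c("a", "b", "c", "d")]),
               c(a = 1, b = 0, c = 1, d = 2))
  expect_equal(tb2$level, "allele")

  # homozygote model drops heterozygotes; allele table doubles n_used
  cfg <- simulationConfig(80, 80, panel = defaultPanel(1), seed = 13)
  co3 <- simulateCaseControl(cfg)
  snp <- snpPanel(co3)$snp_id[1]
  n_ab <- sum(genotypes(co3)[1, ] == "AB")
  tb_h <- contingency2x2(co3, snp, "homozygote")
  expect_equal(tb_h$n_used, 160 - n_ab)
  tb_a <- contingency2x2(co3, snp, "allele")
  tb_d <- contingency2x2(co3, snp, "dominant")
  expect_equal(tb_a$a + tb_a$b + tb_a$c + tb_a$d, 2 * tb_d$n_used)
})

test_that("Woolf odds ratios reproduce published worked examples", {
  expect_equal(oddsRatioWoolf(105, 112, 48, 140)$or, 2.734,
               tolerance = 1e-3)
  expect_equal(oddsRatioWoolf(9, 3, 26, 87)$or, 10.038, tolerance = 1e-3)
  w <- oddsRatioWoolf(1, 1, 1, 1)
  expect_equal(w$or, 1)
  expect_equal(w$ci_low * w$ci_high, 1, tolerance = 1e-12)
  wz <- oddsRatioWoolf(5, 0, 5, 10)
  expect_true(wz$corrected)
  expect_error(oddsRatioWoolf(0, 5, 0, 5), "no cases")
})

test_that("odds ratios obey reciprocal symmetry under label swap", {
  withr::with_seed(5, {
    for (i in 1:25) {
      tb <- as.list(rpois(4, 20) + 1)
      names(tb) <- c("a", "b", "c", "d")
      w1 <- oddsRatioWoolf(tb$a, tb$b, tb$c, tb$d)
      w2 <- oddsRatioWoolf(tb$c, tb$d, tb$a, tb$b)  # swap exposure labels
      expect_equal(w2$or, 1 / w1$or, tolerance = 1e-12)
      expect_equal(w2$ci_low, 1 / w1$ci_high, tolerance = 1e-12)
      expect_equal(w2$p, w1$p, tolerance = 1e-12)
    }
  })
})

test_that("2x2 chi-square matches hand computation", {
  expect_equal(chiSquare2x2(10, 10, 10, 10)$chi2, 0)
  expect_equal(chiSquare2x2(10, 10, 10, 10)$p, 1)
  expect_equal(chiSquare2x2(20, 10, 10, 20)$chi2, 6.667, tolerance = 1e-3)
  expect_warning(chiSquare2x2(1, 0, 30, 40), "expected")
})

test_that("unadjusted logistic equals the cross-product OR", {
  withr::with_seed(8, {
    for (i in 1:10) {
      tb <- rpois(4, 30) + 2
      y <- rep(c(1, 0, 1, 0), tb)
      x <- rep(c(1, 1, 0, 0), tb)
      f <- fitLogistic(y, cbind(exposure = x))
      or <- (tb[1] * tb[4]) / (tb[2] * tb[3])
      expect_equal(unname(f$or["exposure"]), or, tolerance = 1e-6)
    }
  })
  expect_error(fitLogistic(rep(0:1, 10), cbind(z = rep(0, 20))),
               "rank")
})

test_that("separation is flagged, not raised", {
  y <- rep(c(1, 0), each = 20)
  x <- y  # perfect separation
  f <- fitLogistic(y, cbind(x = x))
  expect_false(f$converged)
  expect_true(f$separated)
})

test_that("adjusted fits recover a simulated covariate-free effect", {
  panel <- defaultPanel(1, maf = 0.35)
  cfg <- simulationConfig(1200, 1200, panel = panel,
                          effects = list(effectSpec("rs000001", "dominant",
                                                    0.9)),
                          seed = 55)
  co <- simulateCaseControl(cfg)
  r <- snpAssociation(co, "rs000001", "dominant",
                      adjust_for = c("age", "smoking"))
  se <- (log(r$adjusted$ci_high) - log(r$adjusted$ci_low)) / (2 * 1.96)
  expect_lt(abs(log(r$adjusted$or) - 0.9), 3 * se)
})

test_that("empty adjustment set reproduces the crude estimate", {
  cfg <- simulationConfig(150, 150, panel = defaultPanel(2), seed = 17)
  co <- simulateCaseControl(cfg)
  r <- snpAssociation(co, "rs000001", "dominant",
                      adjust_for = character(0))
  expect_equal(r$or_adjusted, r$or_crude, tolerance = 1e-6)
})

test_that("adjustment moves a confounded estimate toward the truth", {
  # smoking raises both the odds of carrying the variant (via
  # stratified MAF) and the odds of disease: crude OR is inflated
  wins <- 0L
  for (s in 1:30) {
    withr::with_seed(7000 + s, {
      n <- 1500
      smoking <- runif(n) < 0.4
      maf <- ifelse(smoking, 0.55, 0.2)
      u <- runif(n)
      calls <- ifelse(u < (1 - maf)^2, "AA",
                      ifelse(u < (1 - maf)^2 + 2 * maf * (1 - maf),
                             "AB", "BB"))
      eta <- -0.8 + 1.2 * smoking  # SNP itself is null
      status <- ifelse(runif(n) < plogis(eta), "case", "control")
      co <- cohortFromCalls(cbind(calls), status,
                            panel = defaultPanel(1),
                            covs = data.frame(smoking = smoking))
      r <- snpAssociation(co, "rs000001", "dominant",
                          adjust_for = "smoking")
      wins <- wins +
        (abs(log(r$or_adjusted)) < abs(log(r$or_crude)))
    })
  }
  expect_gte(wins, 27)  # adjusted closer to the null truth in >= 90%
})

test_that("two-stage screen selects planted SNPs and respects alpha = 1", {
  panel <- defaultPanel(8, maf = 0.3)
  eff <- list(effectSpec("rs000001", "dominant", log(2.6)))
  c1 <- simulationConfig(200, 200, panel = panel, effects = eff)
  c2 <- simulationConfig(300, 300, panel = panel, effects = eff)
  st <- generateTwoStageStudy(c1, c2, seed = 77)
  res <- twoStageScreen(st$screening, st$replication,
                        adjust_for = c("age", "smoking"))
  expect_true("rs000001" %in% res$validated$snp_id)

  res_all <- twoStageScreen(st$screening, st$replication,
                            alpha = 1, alpha_marginal = 1,
                            adjust_for = NULL, qc = FALSE)
  expect_setequal(res_all$validated$snp_id, panel$snp_id)

  # identical cohorts: stage-2 selection is idempotent under rerun
  res_same <- twoStageScreen(st$replication, st$replication,
                             adjust_for = c("age", "smoking"))
  res_same2 <- twoStageScreen(st$replication, st$replication,
                              adjust_for = c("age", "smoking"))
  expect_identical(res_same$validated, res_same2$validated)

  # null-only tiny cohorts: warn when nothing survives stage 1
  c0 <- simulationConfig(30, 30, panel = defaultPanel(1), seed = 3)
  co0 <- simulateCaseControl(c0)
  expect_warning(
    r0 <- twoStageScreen(co0, co0, alpha = 1e-6, alpha_marginal = 1e-6,
                         adjust_for = NULL, qc = FALSE),
    "stage-1")
  expect_equal(nrow(r0$validated), 0)
})

test_that("association rows reproduce their own stored tables", {
  cfg <- simulationConfig(120, 150, panel = defaultPanel(3), seed = 23)
  co <- simulateCaseControl(cfg)
  at <- associationTable(co)
  for (i in seq_len(nrow(at))) {
    w <- oddsRatioWoolf(at$a[i], at$b[i], at$c[i], at$d[i])
    expect_equal(at$or_crude[i], w$or, tolerance = 1e-9)
  }
})
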