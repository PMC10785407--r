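test_that("learning/testing partition is stratified and seeded", {
  status <- rep(c("case", "control"), c(40, 60))
  p <- partitionLearningTesting(status, 0.65, seed = 4)
  expect_equal(sum(status[p$learning] == "case"), 26)
  expect_equal(sum(status[p$learning] == "control"), 39)
  expect_equal(sort(c(p$learning, p$testing)), 1:100)
  expect_length(intersect(p$learning, p$testing), 0)
  expect_identical(p, partitionLearningTesting(status, 0.65, seed = 4))
  expect_false(identical(p, partitionLearningTesting(status, 0.65,
                                                     seed = 5)))
})

test_that("node entropy matches hand values", {
  expect_equal(nodeEntropy(10, 0), 0)
  expect_equal(nodeEntropy(25, 25), 1)
  expect_equal(nodeEntropy(30, 10), 0.8113, tolerance = 1e-4)
  expect_error(nodeEntropy(0, 0), "empty")
})

test_that("candidate splits enumerate the documented partitions", {
  g <- factor(c("AA", "AB", "BB", "AA"), levels = c("AA", "AB", "BB"))
  sp <- candidateSplits(g)
  expect_length(sp, 3)
  # the three bipartitions: {AA}|{AB,BB}, {AA,AB}|{BB}, {AA,BB}|{AB}
  expect_equal(lapply(sp, `[[`, "left"),
               list("AA", c("AA", "AB"), c("AA", "BB")))
  expect_length(candidateSplits(c(TRUE, FALSE, TRUE)), 1)
  num <- candidateSplits(c(40, 45, 50, 45))
  expect_equal(vapply(num, `[[`, numeric(1), "threshold"), c(42.5, 47.5))
  expect_length(candidateSplits(rep(3, 10)), 0)
  expect_length(candidateSplits(factor(rep("AA", 5),
                                       levels = c("AA", "AB", "BB"))), 0)
  # clinical cutpoints replace the free threshold search
  ct <- candidateSplits(c(40, 44, 46, 50), cutpoints = c(45, 95))
  expect_equal(vapply(ct, `[[`, numeric(1), "threshold"), 45)
})

test_that("bestSplit agrees with exhaustive search on small fixtures", {
  cfg <- cartConfig(min_node_size = 5)
  for (s in 1:8) {
    for (nv in c(3, 6)) {
      fx <- cartFixture(n = 50, seed = 100 + s, n_vars = nv)
      mine <- bestSplit(fx$data, fx$y, cfg)
      oracle <- bruteForceBestSplit(fx$data, fx$y, cfg)
      if (is.null(oracle)) {
        expect_null(mine)
      } else {
        expect_equal(mine$gain, oracle$gain, tolerance = 1e-10)
        expect_equal(mine$variable, oracle$variable)
      }
    }
  }
  # pure node: nothing to gain
  fx <- cartFixture(n = 40, seed = 1)
  expect_null(bestSplit(fx$data, rep(TRUE, 40), cfg))
})

test_that("grown trees conserve counts, gain and determinism", {
  fx <- cartFixture(n = 400, seed = 42, n_vars = 5)
  cfg <- cartConfig(min_node_size = 20, max_depth = 4)
  tr <- growTree(fx$data, fx$y, cfg)
  expect_s4_class(tr, "CartTree")
  expect_true(validObject(tr))
  for (nd in tr@nodes) {
    if (!nd$terminal) {
      expect_gte(nd$gain, 0)
      l <- tr@nodes[[nd$left_id]]; r <- tr@nodes[[nd$right_id]]
      expect_equal(l$n_case + r$n_case, nd$n_case)
      expect_equal(l$n_ctrl + r$n_ctrl, nd$n_ctrl)
      expect_gte(min(l$n_case + l$n_ctrl, r$n_case + r$n_ctrl), 20)
    }
  }
  tr2 <- growTree(fx$data, fx$y, cfg)
  expect_identical(tr@nodes, tr2@nodes)
  # depth 0: a single terminal root
  tr0 <- growTree(fx$data, fx$y, cartConfig(max_depth = 0))
  expect_equal(nTerminalNodes(tr0), 1)
})

test_that("routing partitions subjects over terminal nodes", {
  fx <- cartFixture(n = 300, seed = 9, n_vars = 4)
  cfg <- cartConfig(min_node_size = 25)
  tr <- growTree(fx$data, fx$y, cfg)
  leaf <- routeSubjects(tr, fx$data)
  expect_false(anyNA(leaf))
  term <- which(vapply(tr@nodes, `[[`, logical(1), "terminal"))
  expect_setequal(unique(leaf), term)
  counts <- table(leaf)
  for (id in term)
    expect_equal(unname(counts[as.character(id)]),
                 tr@nodes[[id]]$n_case + tr@nodes[[id]]$n_ctrl)
  # a missing split variable makes a subject unroutable
  d2 <- fx$data
  d2[[tr@nodes[[1]]$variable]][1] <- NA
  expect_true(is.na(routeSubjects(tr, d2)[1]))
})

test_that("first split matches rpart under the information rule", {
  skip_if_not_installed("rpart")
  fx <- cartFixture(n = 400, seed = 3, n_vars = 4)
  cfg <- cartConfig(min_node_size = 20)
  mine <- bestSplit(fx$data, fx$y, cfg)
  rp <- rpart::rpart(y ~ ., data = cbind(fx$data, y = factor(fx$y)),
                     method = "class",
                     parms = list(split = "information"),
                     control = rpart::rpart.control(minsplit = 40,
                                                    minbucket = 20,
                                                    cp = 0, xval = 0,
                                                    maxdepth = 1))
  expect_equal(mine$variable,
               as.character(rp$frame$var[1]))
})

test_that("leave-one-out pruning matches a brute-force oracle", {
  fx <- cartFixture(n = 30, seed = 12, n_vars = 3)
  cfg <- cartConfig(min_node_size = 4, cv_folds = 30, max_depth = 3,
                    one_se = FALSE, cv_metric = "misclassification")
  tr <- growTree(fx$data, fx$y, cfg)
  pr <- cvPrune(tr, fx$data, fx$y, cfg)
  alphas <- pr$cv$alpha
  # independent LOO loop: regrow on each n-1 subset, prune, predict
  oracle <- numeric(length(alphas))
  for (i in seq_len(30)) {
    ft <- growTree(fx$data[-i, , drop = FALSE], fx$y[-i], cfg)
    for (j in seq_along(alphas)) {
      pt <- pruneAtAlpha(ft, alphas[j])
      leaf <- routeSubjects(pt, fx$data[i, , drop = FALSE])
      pred <- grscart:::.nodePrediction(pt)[leaf]
      oracle[j] <- oracle[j] + (pred != fx$y[i])
    }
  }
  expect_equal(pr$cv$cv_error, oracle)
})

test_that("pruning keeps a strong split and drops pure noise", {
  withr::with_seed(31, {
    n <- 600
    d <- data.frame(g = factor(sample(c("AA", "AB", "BB"), n, TRUE,
                                      c(.4, .4, .2)),
                               levels = c("AA", "AB", "BB")),
                    age = rnorm(n, 48, 6))
    y <- runif(n) < plogis(-1 + log(8) * (d$g == "BB"))
  })
  cfg <- cartConfig(seed = 2)
  tr <- growTree(d, y, cfg)
  pr <- cvPrune(tr, d, y, cfg)
  expect_gte(nTerminalNodes(pr$tree), 2)
  expect_equal(pr$tree@nodes[[1]]$variable, "g")

  withr::with_seed(32, {
    yn <- runif(n) < 0.4
  })
  trn <- growTree(d, yn, cfg)
  prn <- cvPrune(trn, d, yn, cfg)
  expect_equal(nTerminalNodes(prn$tree), 1)
})

test_that("published terminal-node counts reproduce their odds ratios", {
  pub <- publishedCartCounts()
  rt <- nodeRiskFromCounts(pub$n_case, pub$n_control, pub$node_id)
  expect_equal(rt$node_id[rt$reference], 1)  # lowest case fraction
  expect_equal(rt$or[rt$reference], 1)
  expect_equal(rt$or[!rt$reference],
               c(1.673, 2.677, 1.168, 10.038, 3.012, 2.483, 7.585),
               tolerance = 1e-3)
})

test_that("node risk tables route, pick the reference and adjust", {
  fx <- cartFixture(n = 500, seed = 8, n_vars = 4)
  cfg <- cartConfig(min_node_size = 40)
  tr <- growTree(fx$data, fx$y, cfg)
  if (nTerminalNodes(tr) < 2) skip("degenerate fixture")
  rt <- nodeRiskTable(tr, fx$data, fx$y)
  expect_equal(sum(rt$n_case) + sum(rt$n_control), 500)
  ref <- rt[rt$reference, ]
  fracs <- rt$n_case / (rt$n_case + rt$n_control)
  expect_equal(ref$n_case / (ref$n_case + ref$n_control), min(fracs))
  # each printed OR reproduces from its own counts
  for (i in which(!rt$reference)) {
    w <- oddsRatioWoolf(rt$n_case[i], rt$n_control[i],
                        ref$n_case, ref$n_control)
    expect_equal(rt$or[i], w$or, tolerance = 1e-9)
  }
  rta <- nodeRiskTable(tr, fx$data, fx$y,
                       adjust_for = fx$data["age"])
  expect_true(all(is.finite(rta$or_adjusted[!rta$reference])))
  # single terminal node cannot be risk-estimated
  tr0 <- growTree(fx$data, fx$y, cartConfig(max_depth = 0))
  expect_error(nodeRiskTable(tr0, fx$data, fx$y), "2 terminal")
})

test_that("cartData assembles typed predictors from a cohort", {
  cfg <- simulationConfig(60, 60, panel = defaultPanel(2), seed = 19,
                          call_rate = 0.95)
  co <- simulateCaseControl(cfg)
  cd <- cartData(co, env_vars = c("age", "cne", "ppe", "smoking"))
  expect_true(is.factor(cd$data[[1]]))
  expect_true(is.numeric(cd$data$age))
  expect_true(is.logical(cd$data$ppe))
  expect_equal(nrow(cd$data) + cd$n_dropped, 120)
  expect_false(anyNA(cd$data))
})
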