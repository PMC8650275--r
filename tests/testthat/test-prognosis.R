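survFixture <- function(n = 300, coefs = c(0.8, -0.8), seed = 71,
                        nPairs = 30, censorRate = 0.3) {
  lr <- generateLRReference(2 * nPairs + 10, nPairs, seed = seed,
                            distinctGenes = TRUE)
  causal <- data.frame(pair_id = lr$pair_id[seq_along(coefs)], coef = coefs)
  b <- simulateBulkCohort(n, lr, kSubtypes = 1,
                          survivalSpec = list(baselineRate = 0.02,
                                              causal = causal,
                                              censorRate = censorRate),
                          seed = seed + 1)
  list(lr = lr, causal = causal, surv = b$survival,
       scores = bulkScores(b$se, lr, assay = "logexprs"))
}

test_that("univariate screen flags planted pairs and drops degenerate ones", {
  fx <- survFixture(n = 400, coefs = c(0.8), seed = 71)
  uni <- univariateScreen(fx$scores, fx$surv)
  hit <- uni[uni$pair_id == fx$causal$pair_id[1], ]
  expect_true(hit$candidate)
  expect_gt(hit$hr, 1)

  m <- cbind(scoreMatrix(fx$scores), CONST = 3)
  expect_warning(uni2 <- univariateScreen(m, fx$surv), "constant")
  expect_false("CONST" %in% uni2$pair_id)

  zeroEv <- fx$surv; zeroEv$event <- 0
  expect_error(univariateScreen(fx$scores, zeroEv), "no events")
})

test_that("LASSO-Cox selection recovers planted pairs and is seed-stable", {
  fx <- survFixture(n = 300, coefs = c(0.8, 0.8, -0.8, 0.8, -0.8),
                    seed = 72, nPairs = 50)
  uni <- univariateScreen(fx$scores, fx$surv)
  cand <- uni$pair_id[uni$candidate]
  expect_true(length(cand) >= 5)
  s1 <- lassoSelect(fx$scores, fx$surv, cand, seed = 3)
  s2 <- lassoSelect(fx$scores, fx$surv, cand, seed = 3)
  expect_identical(s1$selected, s2$selected)
  expect_gte(length(intersect(s1$selected, fx$causal$pair_id)), 4)
  expect_error(lassoSelect(fx$scores, fx$surv, cand[1]), ">= 2")
})

test_that("risk model recovers planted signs/magnitudes and scores deterministically", {
  fx <- survFixture(n = 500, coefs = c(0.8, -0.8), seed = 73)
  model <- fitRiskModel(fx$scores, fx$surv, fx$causal$pair_id)
  beta <- riskCoefficients(model)
  expect_equal(unname(sign(beta)), sign(fx$causal$coef))
  expect_true(all(abs(beta - fx$causal$coef) < 0.25))

  r1 <- riskScore(model, fx$scores)
  r2 <- riskScore(model, fx$scores)
  expect_identical(r1, r2)

  # single selected pair: risk is a monotone affine map of its z-score
  m1 <- fitRiskModel(fx$scores, fx$surv, fx$causal$pair_id[1])
  r <- riskScore(m1, fx$scores)
  z <- standardizeScores(
    scoreMatrix(fx$scores)[, fx$causal$pair_id[1], drop = FALSE])
  expect_equal(unname(cor(r, z[, 1])),
               unname(sign(riskCoefficients(m1))), tolerance = 1e-9)

  expect_error(riskScore(model, scoreMatrix(fx$scores)[, 3:5]), "absent")
})

test_that("median stratification uses the training cutoff with ties low", {
  expect_equal(as.character(stratifyMedian(c(1, 2, 3, 4), 2.5)),
               c("low", "low", "high", "high"))
  expect_true(all(stratifyMedian(rep(2, 5), 2) == "low"))
})

test_that("log-rank matches the hand risk-table computation exactly", {
  # 6-subject toy: group A times 1,3,5; group B times 2,4,6; all events
  surv <- data.frame(sample = paste0("p", 1:6),
                     time_months = 1:6, event = 1)
  groups <- factor(rep(c("A", "B"), 3))
  got <- kmLogrank(surv, groups)
  want <- bruteLogrank(surv$time_months, surv$event, groups)
  expect_equal(got$chisq, want$chisq, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)

  # identical patterns in both groups -> statistic 0, p = 1
  survSym <- data.frame(sample = paste0("q", 1:6),
                        time_months = rep(c(2, 5, 9), 2),
                        event = rep(c(1, 0, 1), 2))
  gotSym <- kmLogrank(survSym, factor(rep(c("A", "B"), each = 3)))
  expect_equal(gotSym$chisq, 0, tolerance = 1e-12)
  expect_equal(gotSym$p, 1, tolerance = 1e-12)

  # random <= 20-subject instances agree with the brute force
  set.seed(74)
  for (i in 1:5) {
    n <- sample(8:20, 1)
    sv <- data.frame(sample = paste0("r", seq_len(n)),
                     time_months = sample(1:15, n, TRUE) + runif(n) * 0.1,
                     event = rbinom(n, 1, 0.7))
    g <- factor(sample(c("A", "B"), n, TRUE))
    if (nlevels(droplevels(g)) < 2 || sum(sv$event) == 0) next
    got <- kmLogrank(sv, g)
    want <- bruteLogrank(sv$time_months, sv$event, g)
    expect_equal(got$chisq, want$chisq, tolerance = 1e-10)
  }

  # KM curve starts at 1 and is non-increasing per group
  fx <- survFixture(n = 100, coefs = c(0.8), seed = 75)
  model <- fitRiskModel(fx$scores, fx$surv, fx$causal$pair_id)
  grp <- stratifyMedian(riskScore(model, fx$scores), riskCutoff(model))
  km <- kmLogrank(fx$surv, grp)
  for (g in unique(km$curves$group)) {
    s <- km$curves$survival[km$curves$group == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_lte(s[1], 1)
  }
  expect_error(kmLogrank(fx$surv, factor(rep("A", 100))), "2 non-empty")
})

test_that("time-dependent AUC is 1 for perfect ranking and ~0.5 under the null", {
  # perfect ranking, no censoring
  n <- 60
  surv <- data.frame(sample = paste0("s", 1:n),
                     time_months = seq_len(n), event = 1)
  risk <- rev(seq_len(n))   # shortest survival = highest risk
  expect_equal(timeDependentAUC(risk, surv, 30), 1)

  # random scores independent of survival
  set.seed(76)
  aucs <- replicate(10, {
    fx <- survFixture(n = 250, coefs = numeric(0), seed = sample.int(1e6, 1))
    timeDependentAUC(rnorm(250), fx$surv, 36)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)

  expect_error(timeDependentAUC(risk, transform(surv, event = 0), 30),
               "no cases")
  expect_error(timeDependentAUC(risk, surv, 100), "no controls")
})

test_that("calibration is self-consistent on a large planted cohort", {
  fx <- survFixture(n = 1000, coefs = c(0.8, -0.8), seed = 77)
  model <- fitRiskModel(fx$scores, fx$surv, fx$causal$pair_id)
  cal <- calibrationTable(model, fx$scores, fx$surv, horizonMonths = 36,
                          nBins = 3)
  expect_equal(nrow(cal), 3)
  expect_true(all(abs(cal$predicted - cal$observed) < 0.05))

  # single bin equals whole-cohort KM vs mean prediction
  cal1 <- calibrationTable(model, fx$scores, fx$surv, horizonMonths = 36,
                           nBins = 1)
  expect_equal(cal1$observed,
               bruteKM(fx$surv$time_months, fx$surv$event, 36),
               tolerance = 1e-9)

  expect_error(calibrationTable(model, fx$scores, fx$surv,
                                horizonMonths = 1e6), "beyond")
})

test_that("validation metrics never use validation-derived parameters", {
  fx <- survFixture(n = 400, coefs = c(0.8), seed = 78)
  split <- trainValidationSplit(fx$surv$sample, trainFrac = 0.7, seed = 9)
  expect_equal(length(split$train), 280)
  expect_length(intersect(split$train, split$validation), 0)

  m <- scoreMatrix(fx$scores)
  model <- fitRiskModel(m[split$train, ],
                        fx$surv[fx$surv$sample %in% split$train, ],
                        fx$causal$pair_id)
  # scoring validation samples uses training center/scale: shifting the
  # validation cohort shifts its risk scores (no re-standardization)
  vm <- m[split$validation, , drop = FALSE]
  r0 <- riskScore(model, vm)
  vmShift <- vm; vmShift[, fx$causal$pair_id[1]] <-
    vmShift[, fx$causal$pair_id[1]] + 5
  r1 <- riskScore(model, vmShift)
  expect_equal(unname(r1 - r0),
               rep(unname(5 * riskCoefficients(model)[1] /
                            model@scale[fx$causal$pair_id[1]]),
                   length(r0)), tolerance = 1e-9)
  # cutoff comes from training, not validation
  expect_equal(riskCutoff(model),
               median(riskScore(model, m[split$train, ])), tolerance = 1e-12)
})
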