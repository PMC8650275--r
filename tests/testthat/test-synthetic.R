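test_that("LR reference generation is deterministic, capped, and valid", {
  expect_equal(nrow(generateLRReference(10, 0)), 0L)
  a <- generateLRReference(4, 2, seed = 7)
  b <- generateLRReference(4, 2, seed = 7)
  expect_identical(a, b)
  expect_error(generateLRReference(3, 7), "capacity")
  full <- generateLRReference(5, 20, seed = 1)
  expect_false(any(full$ligand == full$receptor))
  expect_false(anyDuplicated(full$pair_id) > 0)
  dg <- generateLRReference(20, 10, seed = 2, distinctGenes = TRUE)
  expect_false(anyDuplicated(c(dg$ligand, dg$receptor)) > 0)
  expect_error(generateLRReference(10, 6, distinctGenes = TRUE), "capacity")
})

test_that("single-cell simulator honours seeds, means and planted effects", {
  lr <- generateLRReference(30, 10, seed = 1, distinctGenes = TRUE)
  s1 <- simulateSCCounts(c(A = 50, B = 50), lr, seed = 3)
  s2 <- simulateSCCounts(c(A = 50, B = 50), lr, seed = 3)
  expect_identical(SummarizedExperiment::assay(s1$sce, "counts"),
                   SummarizedExperiment::assay(s2$sce, "counts"))
  expect_error(simulateSCCounts(c(A = 0, B = 10), lr), ">= 2 cells")
  expect_error(
    simulateSCCounts(c(A = 10, B = 10), lr,
                     planted = data.frame(pair_id = "nope", source = "A",
                                          target = "B", fold = 2)),
    "not in reference")
  expect_error(
    simulateSCCounts(c(A = 10, B = 10), lr,
                     planted = data.frame(pair_id = lr$pair_id[1],
                                          source = "A", target = "Z",
                                          fold = 2)),
    "not simulated")

  # empirical mean within 3 standard errors of the NB specification
  big <- simulateSCCounts(c(A = 600), lr, baseMean = 0.5, dispersion = 0.5,
                          seed = 9)
  cm <- rowMeans(SummarizedExperiment::assay(big$sce, "counts"))
  se3 <- 3 * sqrt(0.5 * (1 + 0.5 * 0.5) / 600)
  expect_true(all(abs(cm - 0.5) < se3 * 1.5))

  planted <- data.frame(pair_id = lr$pair_id[1], source = "A", target = "B",
                        fold = 6)
  sim <- simulateSCCounts(c(A = 500, B = 500), lr, planted, seed = 4)
  counts <- SummarizedExperiment::assay(sim$sce, "counts")
  ct <- getCellTypes(sim$sce)
  lig <- lr$ligand[1]
  expect_gt(mean(counts[lig, ct == "A"]), 2.5)
  expect_lt(mean(counts[lig, ct == "B"]), 1)
})

test_that("bulk simulator plants subtypes, survival, abundance as specified", {
  lr <- generateLRReference(100, 40, seed = 2, distinctGenes = TRUE)
  b1 <- simulateBulkCohort(60, lr, kSubtypes = 3, markersPerSubtype = 5,
                           seed = 11)
  b2 <- simulateBulkCohort(60, lr, kSubtypes = 3, markersPerSubtype = 5,
                           seed = 11)
  expect_identical(SummarizedExperiment::assay(b1$se, "exprs"),
                   SummarizedExperiment::assay(b2$se, "exprs"))
  expect_identical(b1$survival, b2$survival)
  # marker sets disjoint across subtypes
  expect_false(anyDuplicated(unlist(b1$truth$subtype_markers)) > 0)
  expect_error(
    simulateBulkCohort(60, lr, kSubtypes = 2, markersPerSubtype = 3,
                       markerAssignment = list(lr$pair_id[1:3],
                                               lr$pair_id[3:5])),
    "overlap")

  # censor rate 0 -> all events observed
  b0 <- simulateBulkCohort(50, lr, kSubtypes = 1,
                           survivalSpec = list(baselineRate = 0.02,
                                               causal = NULL,
                                               censorRate = 0), seed = 5)
  expect_true(all(b0$survival$event == 1))

  # censoring fraction close to the requested rate at n = 600
  bc <- simulateBulkCohort(600, lr, kSubtypes = 1,
                           survivalSpec = list(baselineRate = 0.02,
                                               causal = NULL,
                                               censorRate = 0.4), seed = 6)
  expect_lt(abs(mean(bc$survival$event == 0) - 0.4), 0.05)

  # log-scale marker shift recovered from the stored log assay
  b3 <- simulateBulkCohort(300, lr, kSubtypes = 2, markersPerSubtype = 4,
                           markerLogFC = 1.5, seed = 7)
  logex <- SummarizedExperiment::assay(b3$se, "logexprs")
  mk <- b3$truth$subtype_markers[["1"]]
  gene <- lr$ligand[lr$pair_id == mk[1]]
  in1 <- names(b3$truth$subtype_labels)[b3$truth$subtype_labels == 1]
  out1 <- setdiff(colnames(logex), in1)
  expect_lt(abs(mean(logex[gene, in1]) - mean(logex[gene, out1]) - 1.5), 0.2)
})

test_that("null causal coefficients yield near-zero Cox estimates", {
  lr <- generateLRReference(40, 10, seed = 3, distinctGenes = TRUE)
  set.seed(42)
  betas <- replicate(5, {
    b <- simulateBulkCohort(500, lr, kSubtypes = 1,
                            survivalSpec = list(baselineRate = 0.02,
                                                causal = data.frame(
                                                  pair_id = lr$pair_id[1],
                                                  coef = 0),
                                                censorRate = 0.3),
                            seed = sample.int(1e6, 1))
    sc <- bulkScores(b$se, lr)
    uni <- univariateScreen(sc, b$survival)
    uni$coef[uni$pair_id == lr$pair_id[1]]
  })
  expect_true(median(abs(betas)) < 0.15)
})
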