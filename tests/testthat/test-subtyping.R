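test_that("consensus clustering is deterministic and block-structured on a planted cohort", {
  bulk <- plantedBulk(n = 60, k = 3, markers = 10, nPairs = 40, seed = 41)
  cons1 <- consensusCluster(bulk$scores, kRange = 2:4, nIter = 80, seed = 1)
  cons2 <- consensusCluster(bulk$scores, kRange = 2:4, nIter = 80, seed = 1)
  expect_identical(cons1@consensus, cons2@consensus)

  M <- consensusMatrix(cons1, 3)
  expect_true(all(M >= 0 & M <= 1))
  expect_equal(max(abs(M - t(M))), 0)
  truth <- bulk$truth$subtype_labels[rownames(M)]
  sameBlock <- outer(truth, truth, "==") & upper.tri(M)
  diffBlock <- outer(truth, truth, "!=") & upper.tri(M)
  expect_gt(mean(M[sameBlock]), 0.9)
  expect_lt(mean(M[diffBlock]), 0.1)

  expect_error(consensusCluster(bulk$scores, kRange = c(2, 60), nIter = 5),
               "k must be")
  expect_error(consensusCluster(scoreMatrix(bulk$scores)[1:5, ], kRange = 2),
               ">= 10 samples")
})

test_that("duplicated samples always co-cluster in the final assignment", {
  bulk <- plantedBulk(n = 30, k = 2, markers = 8, nPairs = 30, seed = 42)
  m <- scoreMatrix(bulk$scores)
  dup <- rbind(m, `DUP1` = m[1, ])
  cons <- consensusCluster(dup, kRange = 2:3, nIter = 60, seed = 2)
  for (k in 2:3) {
    lab <- consensusAssignments(cons, k)
    expect_equal(unname(lab["DUP1"]), unname(lab[rownames(m)[1]]))
  }
})

test_that("PAC-based k selection finds the planted k and breaks ties low", {
  bulk <- plantedBulk(n = 90, k = 3, markers = 10, nPairs = 40, seed = 43)
  cons <- consensusCluster(bulk$scores, kRange = 2:5, nIter = 100, seed = 3)
  k <- selectK(cons)
  expect_equal(as.integer(k), 3L)
  expect_false(attr(k, "lowConfidence"))

  # no planted structure: low-confidence flag and smallest k on flat PAC
  null <- plantedBulk(n = 40, k = 1, markers = 0, nPairs = 30, seed = 44)
  consN <- consensusCluster(null$scores, kRange = 2:4, nIter = 60, seed = 4)
  kN <- selectK(consN)
  expect_true(attr(kN, "lowConfidence"))

  fake <- consN
  fake@pac <- c(`2` = 0.5, `3` = 0.5, `4` = 0.5)
  expect_equal(as.integer(selectK(fake)), 2L)
})

test_that("silhouette has its closed form and matches the brute oracle", {
  # two clusters of two points, within-distance 0.1, between-distance 10
  D <- matrix(10, 4, 4)
  D[1, 2] <- D[2, 1] <- D[3, 4] <- D[4, 3] <- 0.1
  diag(D) <- 0
  s <- silhouetteScore(D, c(1, 1, 2, 2))
  expect_equal(as.numeric(s), rep(1 - 0.1 / 10, 4), tolerance = 1e-12)

  # equidistant point -> silhouette 0
  D2 <- matrix(c(0, 1, 2, 2,
                 1, 0, 2, 2,
                 2, 2, 0, 2,
                 2, 2, 2, 0), 4, 4)
  s2 <- silhouetteScore(D2, c(1, 1, 2, 2))
  expect_equal(as.numeric(s2[3]), 0, tolerance = 1e-12)

  set.seed(45)
  Dr <- as.matrix(dist(matrix(rnorm(60), ncol = 3)))
  lab <- sample(1:3, 20, replace = TRUE)
  expect_equal(as.numeric(silhouetteScore(Dr, lab)),
               bruteSilhouette(Dr, lab), tolerance = 1e-12)
  expect_error(silhouetteScore(Dr, rep(1, 20)), ">= 2")
})

test_that("marker discovery recovers planted markers and is label-symmetric", {
  bulk <- plantedBulk(n = 90, k = 3, markers = 10, nPairs = 40, seed = 46)
  truth <- bulk$truth$subtype_labels
  mk <- markerPairs(bulk$scores, truth, topN = 10)
  for (k in names(bulk$truth$subtype_markers)) {
    planted <- bulk$truth$subtype_markers[[k]]
    expect_gte(length(intersect(mk[[k]]$pair_id, planted)), 9)
  }

  # a constant pair is never a marker
  m <- scoreMatrix(bulk$scores)
  m <- cbind(m, CONST = 1)
  mk2 <- markerPairs(m, truth, topN = 40)
  expect_false(any(vapply(mk2, function(t) "CONST" %in% t$pair_id,
                          logical(1))))

  # swapping labels 1 <-> 2 swaps the marker lists exactly
  swapped <- truth
  swapped[truth == 1] <- 2L; swapped[truth == 2] <- 1L
  mkS <- markerPairs(bulk$scores, swapped, topN = 10)
  expect_equal(mk[["1"]], mkS[["2"]])
  expect_equal(mk[["2"]], mkS[["1"]])

  expect_error(markerPairs(m[1:7, ], truth[1:7], topN = 5), "< 3 samples")
})

test_that("subtype assignment is centroid-faithful and flags degenerate input", {
  bulk <- plantedBulk(n = 90, k = 3, markers = 10, nPairs = 40, seed = 47)
  model <- fitSubtypeModel(bulk$scores, bulk$truth$subtype_labels, topN = 10)

  # holdout cohort from the same generator: >= 90% label agreement
  hold <- simulateBulkCohort(90, bulk$lr, kSubtypes = 3,
                             markersPerSubtype = 10, markerLogFC = 1.5,
                             noiseSd = 0.3, seed = 99)
  holdScores <- bulkScores(hold$se, bulk$lr, assay = "logexprs")
  asg <- assignSubtype(holdScores, model)
  agree <- mean(asg$subtype == hold$truth$subtype_labels[asg$sample],
                na.rm = TRUE)
  expect_gte(agree, 0.9)

  # a sample equal to a centroid correlates 1 with it
  z <- standardizeScores(scoreMatrix(bulk$scores))
  cent <- subtypeCentroids(model)
  probe <- matrix(0, nrow = 1, ncol = ncol(z),
                  dimnames = list("probe", colnames(z)))
  # embed centroid 1 into a full-width score row, rest mild noise
  set.seed(48)
  probe[1, ] <- rnorm(ncol(z), 0, 0.01)
  probe[1, colnames(cent)] <- cent["1", ]
  big <- rbind(z, probe)   # standardization within-cohort needs spread
  asg2 <- assignSubtype(big, model)
  expect_equal(asg2$subtype[asg2$sample == "probe"], 1L)

  # constant marker vector (single-sample cohort) -> unassigned
  m <- scoreMatrix(bulk$scores)
  m["S0001", ] <- 7
  asg3 <- assignSubtype(m["S0001", , drop = FALSE], model)
  expect_true(is.na(asg3$subtype))

  expect_error(
    assignSubtype(m[, seq_len(3), drop = FALSE], model), "coverage")
})

test_that("subclass concordance lights the matched diagonal only", {
  bulk <- plantedBulk(n = 90, k = 3, markers = 10, nPairs = 40, seed = 50)
  model <- fitSubtypeModel(bulk$scores, bulk$truth$subtype_labels, topN = 10)
  other <- simulateBulkCohort(90, bulk$lr, kSubtypes = 3,
                              markersPerSubtype = 10, markerLogFC = 1.5,
                              noiseSd = 0.3, seed = 77)
  oScores <- bulkScores(other$se, bulk$lr, assay = "logexprs")
  oLabels <- other$truth$subtype_labels
  cc <- subclassConcordance(model, oScores, oLabels, nPerm = 200, seed = 5)
  expect_true(all(cc$p >= 1 / 201))
  expect_true(all(diag(cc$padj) < 0.05))
  expect_true(all(cc$padj[upper.tri(cc$padj)] >= 0.05))
  expect_true(all(cc$padj[lower.tri(cc$padj)] >= 0.05))

  # shuffled labels: nothing significant
  set.seed(51)
  ccNull <- subclassConcordance(model, oScores, sample(oLabels),
                                nPerm = 200, seed = 6)
  expect_false(any(ccNull$padj < 0.05))

  expect_warning(subclassConcordance(model, oScores, oLabels, nPerm = 50,
                                     seed = 7), "coarse")
  expect_error(subclassConcordance(model, oScores, oLabels, nPerm = 0),
               ">= 1")
})
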