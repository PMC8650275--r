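# Independent brute-force oracles. These deliberately use naive loops and
# textbook formulas, never the package's vectorized code paths.

bruteStrength <- function(expr, labels, lrRef) {
  types <- sort(unique(labels))
  out <- array(NA_real_, dim = c(nrow(lrRef), length(types), length(types)),
               dimnames = list(lrRef$pair_id, types, types))
  for (p in seq_len(nrow(lrRef)))
    for (a in types)
      for (b in types) {
        mL <- mean(expr[lrRef$ligand[p], labels == a])
        mR <- mean(expr[lrRef$receptor[p], labels == b])
        out[p, a, b] <- mL * mR
      }
  out
}

bruteAffinity <- function(expr, lrRef) {
  n <- ncol(expr)
  A <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n)) {
      if (i == j) next
      for (p in seq_len(nrow(lrRef)))
        A[i, j] <- A[i, j] +
          expr[lrRef$ligand[p], i] * expr[lrRef$receptor[p], j] +
          expr[lrRef$receptor[p], i] * expr[lrRef$ligand[p], j]
    }
  A
}

brutePearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sd(x) * sd(y))
}

bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

bruteSilhouette <- function(D, labels) {
  D <- as.matrix(D)
  n <- length(labels)
  vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- if (sum(own) == 1) 0 else mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(k) mean(D[i, labels == k]), numeric(1)))
    if (sum(own) == 1) 0 else (b - a) / max(a, b)
  }, numeric(1))
}

# two-group log-rank by walking the risk table at every distinct event time
bruteLogrank <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  eventTimes <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in eventTimes) {
    atRisk <- time >= t
    n <- sum(atRisk); n1 <- sum(atRisk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O1 - E1)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

bruteKM <- function(time, event, at) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  for (t in ts[ts <= at]) {
    n <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n)
  }
  s
}

# tiny fixture builders -------------------------------------------------

toyLR <- function() {
  validateLRPairs(data.frame(ligand = c("L1", "L2"),
                             receptor = c("R1", "R2"),
                             stringsAsFactors = FALSE))
}

randomAnnotatedSCE <- function(nGenes = 20, nCells = 50, nTypes = 3,
                               seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(nGenes))
  m <- matrix(rpois(nGenes * nCells, 5), nrow = nGenes,
              dimnames = list(genes, sprintf("c%02d", seq_len(nCells))))
  types <- sample(LETTERS[seq_len(nTypes)], nCells, replace = TRUE)
  makeExpressionSE(m, valueKind = "counts", cellTypes = types)
}

randomLRFor <- function(sce, nPairs = 8, seed = 2) {
  set.seed(seed)
  genes <- rownames(sce)
  lig <- sample(genes, nPairs)
  rec <- sample(setdiff(genes, lig), nPairs)
  validateLRPairs(data.frame(ligand = lig, receptor = rec,
                             stringsAsFactors = FALSE))
}

plantedBulk <- function(n = 150, k = 3, markers = 50, logfc = 1.5,
                        noise = 0.3, seed = 1, nPairs = 200,
                        survivalSpec = list(baselineRate = 0.02,
                                            causal = NULL, censorRate = 0.3),
                        abundanceSpec = NULL) {
  lr <- generateLRReference(2 * nPairs + 20, nPairs, seed = seed,
                            distinctGenes = TRUE)
  bulk <- simulateBulkCohort(n, lr, kSubtypes = k, markersPerSubtype = markers,
                             markerLogFC = logfc, noiseSd = noise,
                             survivalSpec = survivalSpec,
                             abundanceSpec = abundanceSpec, seed = seed + 1)
  bulk$lr <- lr
  bulk$scores <- bulkScores(bulk$se, lr, assay = "logexprs")
  bulk
}
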