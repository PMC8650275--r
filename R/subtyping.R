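asScoreMatrix <- function(scores) {
  if (is(scores, "PairScoreMatrix")) scoreMatrix(scores) else scores
}

#' Consensus k-means clustering of the LR pair-score matrix
#'
#' Repeatedly subsamples the cohort (default 80% of samples, 1000
#' iterations), runs k-means for every k in `kRange` (10 seeded restarts,
#' best inertia kept), and accumulates how often each sample pair
#' co-clusters relative to how often it is co-sampled. The final assignment
#' per k is an average-linkage hierarchical cut of `1 - consensus`. Scores
#' are z-standardized per pair by default (constant pairs dropped).
#'
#' @param scores [PairScoreMatrix-class] or samples x pairs matrix.
#' @param kRange integer vector of candidate cluster numbers.
#' @param nIter subsampling iterations.
#' @param subsample fraction of samples per iteration.
#' @param seed RNG seed.
#' @param standardize z-standardize scores per pair first.
#' @param nStart k-means restarts per iteration.
#' @return [ConsensusResult-class].
#' @export
consensusCluster <- function(scores, kRange = 2:6, nIter = 1000,
                             subsample = 0.8, seed = 1, standardize = TRUE,
                             nStart = 10) {
  m <- asScoreMatrix(scores)
  n <- nrow(m)
  if (n < 10) stop("consensus clustering needs >= 10 samples", call. = FALSE)
  kRange <- sort(unique(as.integer(kRange)))
  if (any(kRange >= n)) stop("k must be < number of samples", call. = FALSE)
  if (standardize) m <- standardizeScores(m)
  nSub <- floor(subsample * n)
  S <- matrix(0, n, n)
  I <- stats::setNames(lapply(kRange, function(k) matrix(0, n, n)),
                       as.character(kRange))
  withSeed(seed, {
    for (b in seq_len(nIter)) {
      idx <- sample.int(n, nSub)
      S[idx, idx] <- S[idx, idx] + 1
      sub <- m[idx, , drop = FALSE]
      for (k in kRange) {
        cl <- kmeans(sub, centers = k, nstart = nStart, iter.max = 25)$cluster
        for (c in seq_len(k)) {
          mem <- idx[cl == c]
          I[[as.character(k)]][mem, mem] <-
            I[[as.character(k)]][mem, mem] + 1
        }
      }
    }
  })
  ids <- rownames(m)
  consensus <- lapply(I, function(Ik) {
    M <- ifelse(S > 0, Ik / pmax(S, 1), 0)
    diag(M) <- 1
    dimnames(M) <- list(ids, ids)
    M
  })
  assignments <- vapply(names(consensus), function(k) {
    hc <- hclust(as.dist(1 - consensus[[k]]), method = "average")
    cutree(hc, k = as.integer(k))
  }, integer(n))
  rownames(assignments) <- ids
  off <- upper.tri(S)
  grid <- seq(0, 1, by = 0.02)
  cdf <- do.call(rbind, lapply(names(consensus), function(k) {
    v <- consensus[[k]][off]
    data.frame(k = as.integer(k), consensus_value = grid,
               cdf = vapply(grid, function(g) mean(v <= g), numeric(1)))
  }))
  pac <- vapply(consensus, function(M) {
    v <- M[off]
    mean(v > 0.1 & v < 0.9)
  }, numeric(1))
  new("ConsensusResult", consensus = consensus, assignments = assignments,
      pac = pac, cdf = cdf,
      params = list(n_iter = nIter, subsample = subsample, seed = seed,
                    kRange = kRange, standardized = standardize))
}

#' Select the number of subtypes by PAC minimization
#'
#' Operationalizes the visual CDF criterion: returns the k whose
#' off-diagonal consensus values have the smallest proportion of ambiguous
#' clustering (PAC, fraction strictly between 0.1 and 0.9), ties broken
#' toward smaller k. When even the best PAC is high (> 0.2) there is no
#' clean block structure and the choice is flagged low-confidence.
#'
#' @param result [ConsensusResult-class] covering >= 2 values of k.
#' @return integer k with attributes `pac` (per-k table), `lowConfidence`.
#' @export
selectK <- function(result) {
  pac <- pacScores(result)
  if (length(pac) < 2) stop("selectK needs >= 2 values of k", call. = FALSE)
  ks <- as.integer(names(pac))
  best <- ks[which.min(pac)]   # which.min takes the first = smallest k on ties
  structure(best, pac = pac, lowConfidence = unname(min(pac) > 0.2))
}

#' Silhouette widths for a subtype assignment
#'
#' Standard silhouette on a distance (default: `1 - consensus`); thin
#' wrapper over [cluster::silhouette()] that also reports the per-subtype
#' mean widths.
#'
#' @param d `dist` object or square distance matrix.
#' @param labels integer cluster labels (>= 2 clusters, each non-empty).
#' @return numeric per-sample silhouette widths; per-cluster means in
#'   `attr(, "clusterMeans")`.
#' @export
silhouetteScore <- function(d, labels) {
  if (is.matrix(d)) d <- as.dist(d)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("silhouette needs >= 2 clusters", call. = FALSE)
  sil <- cluster::silhouette(labels, d)
  w <- sil[, "sil_width"]
  structure(w, clusterMeans = tapply(w, labels, mean))
}

#' Per-subtype up-regulated marker pairs
#'
#' One-vs-rest rank-sum test per pair per subtype with BH adjustment within
#' subtype; candidates need adjusted p < 0.05 and log2FC > 0 (up-regulated
#' only, log2FC on means with pseudocount 1), ranked by log2FC descending,
#' top `topN` kept.
#'
#' @param scores [PairScoreMatrix-class] or samples x pairs matrix
#'   (unstandardized; the test is rank-based, the fold change needs the
#'   original scale).
#' @param labels integer subtype labels aligned with samples.
#' @param topN markers kept per subtype (fewer if fewer qualify).
#' @return named list (by subtype) of data.frames
#'   (`pair_id`, `log2FC`, `p`, `padj`).
#' @export
markerPairs <- function(scores, labels, topN = 50) {
  m <- asScoreMatrix(scores)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(m))
  ks <- sort(unique(labels))
  small <- ks[tabulate(labels)[ks] < 3]
  if (length(small))
    stop("subtype(s) with < 3 samples: ", paste(small, collapse = ", "),
         call. = FALSE)
  out <- lapply(ks, function(k) {
    inK <- labels == k
    p <- vapply(seq_len(ncol(m)), function(j)
      suppressWarnings(wilcox.test(m[inK, j], m[!inK, j])$p.value),
      numeric(1))
    p[is.na(p)] <- 1
    l2fc <- log2((colMeans(m[inK, , drop = FALSE]) + 1) /
                   (colMeans(m[!inK, , drop = FALSE]) + 1))
    padj <- p.adjust(p, method = "BH")
    tab <- data.frame(pair_id = colnames(m), log2FC = unname(l2fc), p = p,
                      padj = padj, stringsAsFactors = FALSE)
    tab <- tab[tab$padj < 0.05 & tab$log2FC > 0, , drop = FALSE]
    tab <- tab[order(-tab$log2FC), , drop = FALSE]
    if (nrow(tab) < topN)
      message("subtype ", k, ": only ", nrow(tab), " qualifying markers")
    utils::head(tab, topN)
  })
  stats::setNames(out, as.character(ks))
}

#' Fit a subtype signature model
#'
#' Bundles a labelled training cohort into the artifact used to classify
#' new cohorts: marker tables per subtype ([markerPairs()]) and the subtype
#' centroids of standardized scores over the marker union.
#'
#' @inheritParams markerPairs
#' @return [SubtypeModel-class].
#' @export
fitSubtypeModel <- function(scores, labels, topN = 50) {
  m <- asScoreMatrix(scores)
  labels <- as.integer(labels)
  markers <- markerPairs(m, labels, topN = topN)
  union <- unique(unlist(lapply(markers, function(t) t$pair_id)))
  if (!length(union)) stop("no marker pairs found", call. = FALSE)
  z <- standardizeScores(m)
  union <- intersect(union, colnames(z))
  ks <- sort(unique(labels))
  centroids <- matrix(NA_real_, length(ks), length(union),
                      dimnames = list(as.character(ks), union))
  for (i in seq_along(ks))
    centroids[i, ] <- colMeans(z[labels == ks[i], union, drop = FALSE])
  new("SubtypeModel", k = length(ks),
      labels = stats::setNames(labels, rownames(m)),
      markers = markers, centroids = centroids,
      standardization = list(center = attr(z, "center"),
                             scale = attr(z, "scale")))
}

#' Assign subtypes to a new cohort by nearest marker centroid
#'
#' New scores are z-standardized within their own cohort, restricted to the
#' model's marker pairs (>= 50% must be present), and each sample is given
#' the subtype whose centroid its marker vector correlates with best
#' (Spearman). Confidence is the top correlation minus the runner-up;
#' undefined correlations (constant vectors) and exact ties yield NA
#' ("unassigned").
#'
#' @param newScores [PairScoreMatrix-class] or samples x pairs matrix.
#' @param model [SubtypeModel-class].
#' @return data.frame (`sample`, `subtype`, `confidence`, `correlation`).
#' @export
assignSubtype <- function(newScores, model) {
  m <- asScoreMatrix(newScores)
  centroids <- subtypeCentroids(model)
  markers <- colnames(centroids)
  present <- intersect(markers, colnames(m))
  if (length(present) < 0.5 * length(markers))
    stop("marker coverage below 50%; missing: ",
         paste(setdiff(markers, colnames(m)), collapse = ", "),
         call. = FALSE)
  # Spearman is rank-based per sample, so per-pair standardization only
  # matters for putting pairs on comparable scales; with < 3 samples it is
  # undefined and raw scores are used directly.
  z <- if (nrow(m) >= 3) suppressWarnings(standardizeScores(m)) else m
  present <- intersect(present, colnames(z))
  C <- centroids[, present, drop = FALSE]
  res <- lapply(rownames(z), function(s) {
    v <- z[s, present]
    r <- suppressWarnings(
      vapply(seq_len(nrow(C)), function(k)
        cor(v, C[k, ], method = "spearman"), numeric(1)))
    if (any(is.na(r)))
      return(data.frame(sample = s, subtype = NA_integer_,
                        confidence = NA_real_, correlation = NA_real_))
    o <- order(-r)
    tie <- length(r) > 1 && r[o[1]] == r[o[2]]
    data.frame(sample = s,
               subtype = if (tie) NA_integer_
                         else as.integer(rownames(C)[o[1]]),
               confidence = if (length(r) > 1) r[o[1]] - r[o[2]] else NA_real_,
               correlation = r[o[1]])
  })
  do.call(rbind, res)
}

concordanceStatistic <- function(zB, labelsB, markerSets, groupsB) {
  out <- vapply(groupsB, function(j) {
    inJ <- labelsB == j
    dm <- colMeans(zB[inJ, , drop = FALSE]) - colMeans(zB[!inJ, , drop = FALSE])
    vapply(markerSets, function(mk) mean(dm[mk]), numeric(1))
  }, numeric(length(markerSets)))
  matrix(out, nrow = length(markerSets))
}

#' Cross-cohort subtype concordance by label permutation
#'
#' For cohort A's subtype-i marker pairs, the statistic against cohort B's
#' subtype j is the mean (over markers) difference between the mean
#' standardized score in B's subtype-j samples and in B's other samples.
#' The null distribution permutes B's labels; one-sided add-one p-values
#' are Bonferroni-corrected by the number of (i, j) cells. Matched subtype
#' pairs across cohorts should light up on the diagonal only.
#'
#' @param modelA [SubtypeModel-class] fitted on cohort A.
#' @param scoresB [PairScoreMatrix-class] or matrix for cohort B.
#' @param labelsB integer subtype labels of cohort B samples.
#' @param nPerm label permutations (>= 1; < 100 draws a warning).
#' @param seed RNG seed.
#' @return list: `statistic`, `p`, `padj` (A-subtypes x B-subtypes
#'   matrices), `nPerm`.
#' @export
subclassConcordance <- function(modelA, scoresB, labelsB, nPerm = 1000,
                                seed = 1) {
  if (nPerm < 1) stop("nPerm must be >= 1", call. = FALSE)
  if (nPerm < 100) warning("nPerm < 100 gives coarse p-values", call. = FALSE)
  m <- asScoreMatrix(scoresB)
  labelsB <- as.integer(labelsB)
  stopifnot(length(labelsB) == nrow(m))
  markerSetsAll <- lapply(markerTables(modelA), function(t) t$pair_id)
  union <- unique(unlist(markerSetsAll))
  present <- intersect(union, colnames(m))
  if (length(present) < 0.5 * length(union))
    stop("marker coverage below 50% in cohort B", call. = FALSE)
  zB <- standardizeScores(m)
  markerSets <- lapply(markerSetsAll, function(mk)
    intersect(mk, colnames(zB)))
  if (any(!lengths(markerSets)))
    stop("a subtype's markers are entirely absent from cohort B", call. = FALSE)
  groupsB <- sort(unique(labelsB))
  obs <- concordanceStatistic(zB, labelsB, markerSets, groupsB)
  counts <- matrix(0L, nrow(obs), ncol(obs))
  withSeed(seed, {
    for (b in seq_len(nPerm)) {
      permStat <- concordanceStatistic(zB, sample(labelsB), markerSets,
                                       groupsB)
      counts <- counts + (permStat >= obs)
    }
  })
  p <- (1 + counts) / (1 + nPerm)
  dimnames(p) <- dimnames(obs) <-
    list(names(markerSets), as.character(groupsB))
  padj <- pmin(p * length(p), 1)
  list(statistic = obs, p = p, padj = padj, nPerm = nPerm)
}
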