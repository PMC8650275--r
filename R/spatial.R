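#' LR-derived cell-cell affinity
#'
#' `A[i, j] = sum over pairs of L_p(i) R_p(j) + R_p(i) L_p(j)` for `i != j`,
#' zero diagonal, symmetric by construction: two cells attract in proportion
#' to complementary ligand/receptor expression in either direction.
#'
#' @param sce expression object with a log-normalized assay.
#' @param lrRef LR reference data.frame.
#' @param pairSubset optional character vector of pair ids to restrict to.
#' @param assay assay to compute on.
#' @return symmetric non-negative cells x cells matrix.
#' @export
cellAffinity <- function(sce, lrRef, pairSubset = NULL, assay = "logcounts") {
  expr <- getAssay(sce, assay)
  if (ncol(expr) < 2L) stop("affinity needs >= 2 cells", call. = FALSE)
  lrRef <- validateLRPairs(lrRef)
  if (!is.null(pairSubset)) lrRef <- lrRef[lrRef$pair_id %in% pairSubset, ]
  mp <- matchPairs(lrRef, rownames(expr))
  if (nrow(mp$used) == 0L)
    stop("no reference pair has both genes in the matrix", call. = FALSE)
  L <- expr[mp$used$ligand, , drop = FALSE]
  R <- expr[mp$used$receptor, , drop = FALSE]
  A <- crossprod(L, R)
  A <- A + t(A)
  diag(A) <- 0
  dimnames(A) <- list(colnames(expr), colnames(expr))
  A
}

klObjective <- function(P, W, mask) {
  q <- W[mask] / sum(W[mask])
  p <- P[mask]
  pos <- p > 0
  sum(p[pos] * log(p[pos] / q[pos]))
}

#' Embed cells in 3-d from an LR affinity
#'
#' The symmetrized, row-normalized affinity becomes a target distribution P
#' over cell pairs; coordinates minimize `KL(P || Q)` where Q is the
#' Student-t (1 d.f.) kernel on 3-d Euclidean distances, by gradient descent
#' from a seeded random start. The step size starts at `learningRate` and is
#' halved whenever a step would increase the objective, so the recorded
#' objective trace is non-increasing; coordinates are re-centred to mean
#' zero every iteration.
#'
#' @param affinity symmetric non-negative matrix with zero diagonal.
#' @param nIter gradient iterations.
#' @param learningRate initial step size.
#' @param seed RNG seed for the random start.
#' @return [SpatialEmbedding-class].
#' @export
embed3D <- function(affinity, nIter = 500, learningRate = 50, seed = 1) {
  stopifnot(is.matrix(affinity), nrow(affinity) == ncol(affinity))
  if (max(abs(affinity - t(affinity))) > 1e-12)
    stop("affinity must be symmetric", call. = FALSE)
  if (any(affinity < 0)) stop("affinity must be non-negative", call. = FALSE)
  if (all(affinity == 0)) stop("all-zero affinity", call. = FALSE)
  n <- nrow(affinity)
  ids <- rownames(affinity)
  if (is.null(ids)) ids <- sprintf("cell%05d", seq_len(n))

  rs <- rowSums(affinity)
  Pr <- affinity / ifelse(rs > 0, rs, 1)
  P <- Pr + t(Pr)
  P <- P / sum(P)
  mask <- !diag(TRUE, n)

  y <- withSeed(seed, matrix(rnorm(n * 3, sd = 1e-2), ncol = 3))
  y <- scale(y, center = TRUE, scale = FALSE)

  stepSize <- learningRate
  trace <- numeric(nIter + 1)
  d2 <- as.matrix(dist(y))^2
  W <- 1 / (1 + d2); diag(W) <- 0
  trace[1] <- klObjective(P, W, mask)
  for (it in seq_len(nIter)) {
    Q <- W / sum(W[mask]); diag(Q) <- 0
    G <- (P - Q) * W
    grad <- 4 * (y * rowSums(G) - G %*% y)
    accepted <- FALSE
    while (!accepted && stepSize >= 1e-12) {
      yNew <- y - stepSize * grad
      yNew <- scale(yNew, center = TRUE, scale = FALSE)
      d2 <- as.matrix(dist(yNew))^2
      WNew <- 1 / (1 + d2); diag(WNew) <- 0
      obj <- klObjective(P, WNew, mask)
      if (obj <= trace[it]) accepted <- TRUE else stepSize <- stepSize / 2
    }
    if (accepted) { y <- yNew; W <- WNew; trace[it + 1] <- obj }
    else trace[it + 1] <- trace[it]
  }
  y <- matrix(as.numeric(y), ncol = 3,
              dimnames = list(ids, c("x", "y", "z")))
  new("SpatialEmbedding", coords = y, affinity = unname(affinity),
      stressTrace = trace)
}

#' Flag cells far from the interaction center
#'
#' Distance is Euclidean from the origin of the centred embedding.
#' `"absolute"` mode flags cells beyond a fixed distance (default 40, the
#' cut conventionally used on full tissue-reconstruction embeddings, whose
#' scale differs from this one); `"percentile"` mode
#' (default, 95th) flags cells beyond the stated percentile of all
#' distances, which is robust to the embedding's arbitrary scale.
#'
#' @param embedding [SpatialEmbedding-class].
#' @param mode `"percentile"` or `"absolute"`.
#' @param threshold percentile in (0, 100) or absolute distance; defaults
#'   95 and 40 respectively.
#' @return the embedding with `farFlag` filled; distances attached as
#'   `attr(farFlags(x), "distance")`.
#' @export
farCells <- function(embedding, mode = c("percentile", "absolute"),
                     threshold = NULL) {
  mode <- match.arg(mode)
  y <- embeddingCoords(embedding)
  d <- sqrt(rowSums(y^2))
  if (mode == "percentile") {
    if (is.null(threshold)) threshold <- 95
    if (threshold <= 0 || threshold >= 100)
      stop("percentile threshold must lie in (0, 100)", call. = FALSE)
    cut <- quantile(d, threshold / 100, names = FALSE)
  } else {
    if (is.null(threshold)) threshold <- 40
    cut <- threshold
  }
  flag <- d > cut
  attr(flag, "distance") <- d
  embedding@farFlag <- as.logical(flag)
  attr(embedding@farFlag, "distance") <- d
  names(embedding@farFlag) <- rownames(y)
  validObject(embedding)
  embedding
}

#' Differential expression between far and near cells of one cell type
#'
#' Per-gene two-sided rank-sum test (far vs near within `focusType`),
#' Benjamini-Hochberg adjustment, and a log2 fold change computed on mean
#' `expm1`-backtransformed expression with pseudocount 1. Significance
#' requires adjusted p < 0.05 and |log2FC| > 0.5.
#'
#' @param sce annotated expression object with a `logcounts` assay.
#' @param embedding [SpatialEmbedding-class] with far flags set (or a named
#'   logical vector of flags).
#' @param focusType cell type to restrict the comparison to.
#' @param assay assay to test on.
#' @return data.frame (`gene`, `log2FC`, `p`, `padj`, `direction`,
#'   `significant`), ordered by p.
#' @export
nearFarDifferential <- function(sce, embedding, focusType,
                                assay = "logcounts") {
  flags <- if (is(embedding, "SpatialEmbedding")) farFlags(embedding)
           else embedding
  if (!length(flags)) stop("far flags not set; run farCells() first",
                           call. = FALSE)
  expr <- getAssay(sce, assay)
  labels <- getCellTypes(sce)
  keep <- labels == focusType
  if (!any(keep)) stop("no cells of type ", focusType, call. = FALSE)
  expr <- expr[, keep, drop = FALSE]
  flags <- flags[colnames(expr)]
  nFar <- sum(flags); nNear <- sum(!flags)
  if (nFar < 3 || nNear < 3)
    stop("need >= 3 cells per group within ", focusType,
         " (far=", nFar, ", near=", nNear, ")", call. = FALSE)
  farM <- expr[, flags, drop = FALSE]
  nearM <- expr[, !flags, drop = FALSE]
  p <- vapply(seq_len(nrow(expr)), function(i)
    suppressWarnings(wilcox.test(farM[i, ], nearM[i, ])$p.value),
    numeric(1))
  p[is.na(p)] <- 1   # all-tied genes carry no evidence
  l2fc <- log2((rowMeans(expm1(farM)) + 1) / (rowMeans(expm1(nearM)) + 1))
  padj <- p.adjust(p, method = "BH")
  out <- data.frame(gene = rownames(expr), log2FC = l2fc, p = p, padj = padj,
                    direction = ifelse(l2fc >= 0, "up_in_far", "down_in_far"),
                    significant = padj < 0.05 & abs(l2fc) > 0.5,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p), ]
}
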