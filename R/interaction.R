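typeMeanMatrix <- function(expr, labels, types) {
  vapply(types, function(t) rowMeans(expr[, labels == t, drop = FALSE]),
         numeric(nrow(expr)))
}

#' Single-cell LR interaction strengths between cell types
#'
#' For every reference pair and every ordered (source, target) cell-type
#' combination (autocrine included), the strength is the mean ligand
#' expression over source-type cells times the mean receptor expression over
#' target-type cells. Pairs whose ligand or receptor is absent from the
#' matrix are dropped and reported.
#'
#' @param sce annotated expression object (`cell_type` in colData).
#' @param lrRef LR reference data.frame.
#' @param assay assay to score on (log-normalized by convention).
#' @return [InteractionTensor-class] without p-values.
#' @export
scStrength <- function(sce, lrRef, assay = "logcounts") {
  expr <- getAssay(sce, assay)
  labels <- getCellTypes(sce)
  if (ncol(expr) == 0L)
    stop("no annotated cells in the matrix", call. = FALSE)
  types <- sort(unique(labels))
  mp <- matchPairs(lrRef, rownames(expr))
  if (nrow(mp$used) == 0L)
    stop("no reference pair has both genes in the matrix", call. = FALSE)
  M <- typeMeanMatrix(expr, labels, types)
  ML <- M[mp$used$ligand, , drop = FALSE]
  MR <- M[mp$used$receptor, , drop = FALSE]
  P <- nrow(mp$used); Tn <- length(types)
  s <- array(ML[, rep(seq_len(Tn), times = Tn)] *
               MR[, rep(seq_len(Tn), each = Tn)],
             dim = c(P, Tn, Tn),
             dimnames = list(mp$used$pair_id, types, types))
  new("InteractionTensor", strength = s, droppedPairs = mp$dropped,
      valueKind = assay)
}

#' Permutation significance of single-cell interaction strengths
#'
#' Cell-type labels are shuffled across all cells `nPerm` times (type sizes
#' preserved), the full strength tensor recomputed under each shuffle, and
#' the one-sided add-one p-value
#' `(1 + #permuted >= observed) / (1 + nPerm)` reported per
#' (pair, source, target). The same shuffles are reused for every pair, so
#' joint calibration across pairs is valid.
#'
#' @inheritParams scStrength
#' @param nPerm number of label permutations (>= 1).
#' @param seed RNG seed for the shuffles.
#' @return [InteractionTensor-class] with p-values.
#' @export
permutationSignificance <- function(sce, lrRef, nPerm = 1000, seed = 1,
                                    assay = "logcounts") {
  stopifnot(nPerm >= 1)
  labels <- getCellTypes(sce)
  types <- sort(unique(labels))
  if (length(types) < 2L)
    stop("permutation test needs >= 2 cell types", call. = FALSE)
  obs <- scStrength(sce, lrRef, assay = assay)
  expr <- getAssay(sce, assay)
  used <- matchPairs(lrRef, rownames(expr))$used
  genesUsed <- unique(c(used$ligand, used$receptor))
  exprU <- expr[genesUsed, , drop = FALSE]
  Tn <- length(types); P <- nrow(used)
  obsMat <- matrix(strengths(obs), nrow = P)   # P x T^2, column-major slices
  colIdxL <- rep(seq_len(Tn), times = Tn)
  colIdxR <- rep(seq_len(Tn), each = Tn)
  counts <- matrix(0L, nrow = P, ncol = Tn * Tn)
  withSeed(seed, {
    for (b in seq_len(nPerm)) {
      perm <- sample(labels)
      M <- typeMeanMatrix(exprU, perm, types)
      permMat <- M[used$ligand, colIdxL, drop = FALSE] *
        M[used$receptor, colIdxR, drop = FALSE]
      counts <- counts + (permMat >= obsMat)
    }
  })
  pv <- array((1 + counts) / (1 + nPerm), dim = dim(strengths(obs)),
              dimnames = dimnames(strengths(obs)))
  new("InteractionTensor", strength = strengths(obs), pvalue = pv,
      nPerm = as.integer(nPerm), droppedPairs = droppedPairs(obs),
      valueKind = obs@valueKind)
}

#' Aggregate an interaction tensor to a type-by-type matrix
#'
#' Sums or averages strengths over pairs, the matrix behind type-level
#' interaction heatmaps and network plots.
#'
#' @param tensor [InteractionTensor-class].
#' @param aggregate `"sum"` or `"mean"`.
#' @return types x types numeric matrix.
#' @export
typeLevelStrength <- function(tensor, aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  s <- strengths(tensor)
  if (!length(s)) stop("empty tensor", call. = FALSE)
  out <- apply(s, c(2, 3), if (aggregate == "sum") sum else mean)
  out
}

#' Per-sample bulk LR pair scores
#'
#' `score[s, p]` = expression of the pair's ligand in sample `s` times the
#' expression of its receptor in the same sample, on whatever scale the
#' chosen assay carries (the scale is recorded in the result). Pairs with a
#' missing gene are reported in `droppedPairs`, never an error.
#'
#' @param se bulk expression SummarizedExperiment.
#' @param lrRef LR reference data.frame.
#' @param assay assay to score on (`"logexprs"` for log-scale products).
#' @return [PairScoreMatrix-class].
#' @export
bulkScores <- function(se, lrRef, assay = "logexprs") {
  expr <- getAssay(se, assay)
  mp <- matchPairs(lrRef, rownames(expr))
  scores <- t(expr[mp$used$ligand, , drop = FALSE] *
                expr[mp$used$receptor, , drop = FALSE])
  dimnames(scores) <- list(colnames(expr), mp$used$pair_id)
  new("PairScoreMatrix", scores = scores, droppedPairs = mp$dropped,
      valueKind = assay)
}
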