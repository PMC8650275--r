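#' @import methods
#' @importFrom stats median quantile sd cor cor.test wilcox.test p.adjust
#'   kmeans hclust cutree as.dist rnorm rnbinom rexp runif setNames
#'   pchisq uniroot complete.cases stepfun dist
#' @importFrom utils read.delim write.table packageVersion head
NULL

#' InteractionTensor: LR interaction strengths between cell types
#'
#' Holds the strength (and, after permutation testing, the p-value) of every
#' ligand-receptor pair for every ordered (source type, target type)
#' combination. `strength[p, a, b]` is the mean ligand expression of pair `p`
#' in source type `a` multiplied by the mean receptor expression in target
#' type `b`; autocrine entries (`a == b`) are included.
#'
#' @slot strength 3-d array `[pair, source type, target type]`, non-negative.
#' @slot pvalue array of the same shape with add-one permutation p-values, or
#'   a zero-length array before testing.
#' @slot nPerm integer, number of permutations behind `pvalue` (0 if none).
#' @slot droppedPairs data.frame (`pair_id`, `reason`) of reference pairs not
#'   scored, e.g. because a gene is absent from the matrix.
#' @slot valueKind character, expression scale strengths were computed on.
#' @export
setClass("InteractionTensor",
  representation(
    strength     = "array",
    pvalue       = "array",
    nPerm        = "integer",
    droppedPairs = "data.frame",
    valueKind    = "character"
  ),
  prototype(
    pvalue = array(numeric(0), dim = c(0, 0, 0)),
    nPerm = 0L,
    droppedPairs = data.frame(pair_id = character(), reason = character(),
                              stringsAsFactors = FALSE),
    valueKind = "logcounts"
  )
)

setValidity("InteractionTensor", function(object) {
  s <- object@strength
  if (length(dim(s)) != 3L)
    return("strength must be a 3-d array [pair, source, target]")
  if (dim(s)[2] != dim(s)[3])
    return("source and target dimensions must match")
  if (length(s) && any(s < 0))
    return("strengths must be non-negative")
  if (is.null(dimnames(s)) && length(s))
    return("strength array must carry dimnames (pairs, types, types)")
  if (length(object@pvalue)) {
    if (!identical(dim(object@pvalue), dim(s)))
      return("pvalue array shape must match strength array")
    if (any(object@pvalue <= 0) || any(object@pvalue > 1))
      return("p-values must lie in (0, 1]")
    if (object@nPerm >= 1L &&
        any(object@pvalue < 1 / (object@nPerm + 1) - 1e-12))
      return("p-values below the add-one bound 1/(nPerm+1)")
  }
  TRUE
})

#' PairScoreMatrix: per-sample ligand-by-receptor pair scores
#'
#' The bulk LR feature space: `scores[s, p]` is the expression of pair `p`'s
#' ligand in sample `s` multiplied by the expression of its receptor in the
#' same sample. Pairs skipped because a gene is missing are recorded in
#' `droppedPairs`.
#'
#' @slot scores numeric matrix, samples x pairs, with dimnames.
#' @slot droppedPairs data.frame (`pair_id`, `reason`).
#' @slot valueKind character, the expression scale scores were computed on.
#' @export
setClass("PairScoreMatrix",
  representation(
    scores       = "matrix",
    droppedPairs = "data.frame",
    valueKind    = "character"
  ),
  prototype(
    droppedPairs = data.frame(pair_id = character(), reason = character(),
                              stringsAsFactors = FALSE),
    valueKind = "exprs"
  )
)

setValidity("PairScoreMatrix", function(object) {
  m <- object@scores
  if (!is.numeric(m)) return("scores must be numeric")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("scores must have sample rownames and pair colnames")
  if (anyDuplicated(rownames(m))) return("duplicate sample ids")
  if (anyDuplicated(colnames(m))) return("duplicate pair ids")
  TRUE
})

#' SpatialEmbedding: 3-d LR-affinity embedding of cells
#'
#' @slot coords n x 3 coordinate matrix, re-centred to mean zero per axis.
#' @slot affinity symmetric non-negative n x n affinity with zero diagonal.
#' @slot farFlag logical per cell: beyond the far-cell distance rule
#'   (empty until [farCells()] is applied).
#' @slot stressTrace KL-divergence objective per iteration.
#' @export
setClass("SpatialEmbedding",
  representation(
    coords      = "matrix",
    affinity    = "matrix",
    farFlag     = "logical",
    stressTrace = "numeric"
  ),
  prototype(farFlag = logical(0))
)

setValidity("SpatialEmbedding", function(object) {
  y <- object@coords
  if (ncol(y) != 3L) return("coords must have 3 columns")
  if (is.null(rownames(y))) return("coords must carry cell ids as rownames")
  if (nrow(object@affinity) != nrow(y))
    return("affinity and coords disagree on cell count")
  if (any(abs(colMeans(y)) > 1e-8))
    return("coords must be centred (|mean| < 1e-8 per axis)")
  if (max(abs(object@affinity - t(object@affinity))) > 1e-12)
    return("affinity must be symmetric")
  if (any(diag(object@affinity) != 0)) return("affinity diagonal must be 0")
  if (length(object@farFlag) && length(object@farFlag) != nrow(y))
    return("farFlag length must match cell count")
  TRUE
})

#' ConsensusResult: consensus-clustering evidence over a range of k
#'
#' @slot consensus named list (by k) of samples x samples consensus matrices
#'   in `[0, 1]`: the fraction of co-samplings in which two samples
#'   co-clustered.
#' @slot assignments samples x k matrix of final labels (hierarchical cut of
#'   1 - consensus).
#' @slot pac named numeric: proportion of ambiguous clustering per k.
#' @slot cdf data.frame of the consensus-value CDF per k (for the visual
#'   criterion the PAC score operationalizes).
#' @slot params list: n_iter, subsample, seed, kRange, standardized.
#' @export
setClass("ConsensusResult",
  representation(
    consensus   = "list",
    assignments = "matrix",
    pac         = "numeric",
    cdf         = "data.frame",
    params      = "list"
  )
)

setValidity("ConsensusResult", function(object) {
  for (k in names(object@consensus)) {
    M <- object@consensus[[k]]
    if (any(M < -1e-12) || any(M > 1 + 1e-12))
      return("consensus entries must lie in [0, 1]")
    if (max(abs(M - t(M))) > 1e-12) return("consensus must be symmetric")
  }
  if (any(object@pac < 0 | object@pac > 1)) return("PAC must lie in [0, 1]")
  TRUE
})

#' SubtypeModel: fitted LR-pair subtype signature
#'
#' @slot k integer, number of subtypes.
#' @slot labels named integer vector, training sample -> subtype index.
#' @slot markers named list, per subtype a ranked data.frame
#'   (`pair_id`, `log2FC`, `p`, `padj`) of its up-regulated marker pairs
#'   (at most the requested top-n).
#' @slot centroids subtypes x marker-union matrix of mean standardized
#'   scores, used for nearest-centroid assignment of new cohorts.
#' @slot standardization list with `center`/`scale` per training pair.
#' @export
setClass("SubtypeModel",
  representation(
    k               = "integer",
    labels          = "integer",
    markers         = "list",
    centroids       = "matrix",
    standardization = "list"
  )
)

setValidity("SubtypeModel", function(object) {
  if (object@k < 1L) return("k must be >= 1")
  if (length(object@markers) != object@k)
    return("one marker table per subtype required")
  if (nrow(object@centroids) != object@k)
    return("one centroid row per subtype required")
  if (length(object@labels) && !all(object@labels %in% seq_len(object@k)))
    return("labels must be in 1..k")
  TRUE
})

#' RiskModel: LR-pair prognostic risk score
#'
#' Multivariate Cox coefficients on standardized pair scores, the training
#' standardization parameters, the training-median cutoff, and the Breslow
#' baseline cumulative hazard needed for calibrated survival predictions.
#'
#' @slot pairs character, selected pair ids.
#' @slot coefficients named numeric, log-hazard per SD of pair score.
#' @slot center,scale named numeric, training standardization per pair.
#' @slot cutoff numeric, median training risk score (validation cohorts are
#'   split at this value, never at their own median).
#' @slot baseline data.frame (`time`, `cumhaz`), Breslow baseline.
#' @export
setClass("RiskModel",
  representation(
    pairs        = "character",
    coefficients = "numeric",
    center       = "numeric",
    scale        = "numeric",
    cutoff       = "numeric",
    baseline     = "data.frame"
  )
)

setValidity("RiskModel", function(object) {
  if (length(object@coefficients) != length(object@pairs))
    return("one coefficient per selected pair required")
  if (any(!is.finite(object@coefficients)))
    return("coefficients must be finite")
  if (any(object@scale <= 0)) return("scale entries must be positive")
  TRUE
})
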