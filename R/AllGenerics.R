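#' Accessors for lriscape result objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param object an lriscape S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("strengths", function(object) standardGeneric("strengths"))
#' @rdname accessors
#' @export
setGeneric("pvalues", function(object) standardGeneric("pvalues"))
#' @rdname accessors
#' @export
setGeneric("pairIds", function(object) standardGeneric("pairIds"))
#' @rdname accessors
#' @export
setGeneric("cellTypes", function(object) standardGeneric("cellTypes"))
#' @rdname accessors
#' @export
setGeneric("droppedPairs", function(object) standardGeneric("droppedPairs"))
#' @rdname accessors
#' @export
setGeneric("scoreMatrix", function(object) standardGeneric("scoreMatrix"))
#' @rdname accessors
#' @export
setGeneric("embeddingCoords", function(object) standardGeneric("embeddingCoords"))
#' @rdname accessors
#' @export
setGeneric("cellAffinities", function(object) standardGeneric("cellAffinities"))
#' @rdname accessors
#' @export
setGeneric("farFlags", function(object) standardGeneric("farFlags"))
#' @rdname accessors
#' @export
setGeneric("stressTrace", function(object) standardGeneric("stressTrace"))
#' @rdname accessors
#' @export
setGeneric("consensusMatrix", function(object, k) standardGeneric("consensusMatrix"))
#' @rdname accessors
#' @export
setGeneric("consensusAssignments", function(object, k) standardGeneric("consensusAssignments"))
#' @rdname accessors
#' @export
setGeneric("pacScores", function(object) standardGeneric("pacScores"))
#' @rdname accessors
#' @export
setGeneric("subtypeLabels", function(object) standardGeneric("subtypeLabels"))
#' @rdname accessors
#' @export
setGeneric("markerTables", function(object) standardGeneric("markerTables"))
#' @rdname accessors
#' @export
setGeneric("subtypeCentroids", function(object) standardGeneric("subtypeCentroids"))
#' @rdname accessors
#' @export
setGeneric("riskPairs", function(object) standardGeneric("riskPairs"))
#' @rdname accessors
#' @export
setGeneric("riskCoefficients", function(object) standardGeneric("riskCoefficients"))
#' @rdname accessors
#' @export
setGeneric("riskCutoff", function(object) standardGeneric("riskCutoff"))

#' @rdname accessors
setMethod("strengths", "InteractionTensor", function(object) object@strength)
#' @rdname accessors
setMethod("pvalues", "InteractionTensor", function(object) object@pvalue)
#' @rdname accessors
setMethod("pairIds", "InteractionTensor",
          function(object) dimnames(object@strength)[[1]])
#' @rdname accessors
setMethod("cellTypes", "InteractionTensor",
          function(object) dimnames(object@strength)[[2]])
#' @rdname accessors
setMethod("droppedPairs", "InteractionTensor", function(object) object@droppedPairs)

#' @rdname accessors
setMethod("scoreMatrix", "PairScoreMatrix", function(object) object@scores)
#' @rdname accessors
setMethod("pairIds", "PairScoreMatrix", function(object) colnames(object@scores))
#' @rdname accessors
setMethod("droppedPairs", "PairScoreMatrix", function(object) object@droppedPairs)

#' @rdname accessors
setMethod("embeddingCoords", "SpatialEmbedding", function(object) object@coords)
#' @rdname accessors
setMethod("cellAffinities", "SpatialEmbedding", function(object) object@affinity)
#' @rdname accessors
setMethod("farFlags", "SpatialEmbedding", function(object) object@farFlag)
#' @rdname accessors
setMethod("stressTrace", "SpatialEmbedding", function(object) object@stressTrace)

#' @rdname accessors
setMethod("consensusMatrix", "ConsensusResult",
          function(object, k) object@consensus[[as.character(k)]])
#' @rdname accessors
setMethod("consensusAssignments", "ConsensusResult",
          function(object, k) object@assignments[, as.character(k)])
#' @rdname accessors
setMethod("pacScores", "ConsensusResult", function(object) object@pac)

#' @rdname accessors
setMethod("subtypeLabels", "SubtypeModel", function(object) object@labels)
#' @rdname accessors
setMethod("markerTables", "SubtypeModel", function(object) object@markers)
#' @rdname accessors
setMethod("subtypeCentroids", "SubtypeModel", function(object) object@centroids)

#' @rdname accessors
setMethod("riskPairs", "RiskModel", function(object) object@pairs)
#' @rdname accessors
setMethod("riskCoefficients", "RiskModel", function(object) object@coefficients)
#' @rdname accessors
setMethod("riskCutoff", "RiskModel", function(object) object@cutoff)

setMethod("show", "InteractionTensor", function(object) {
  d <- dim(object@strength)
  cat("InteractionTensor:", d[1], "pairs x", d[2], "source types x",
      d[3], "target types\n")
  cat("  expression scale:", object@valueKind, "\n")
  if (length(object@pvalue))
    cat("  permutation p-values from", object@nPerm, "shuffles (min possible",
        signif(1 / (object@nPerm + 1), 3), ")\n")
  if (nrow(object@droppedPairs))
    cat("  dropped pairs:", nrow(object@droppedPairs), "\n")
})

setMethod("show", "PairScoreMatrix", function(object) {
  cat("PairScoreMatrix:", nrow(object@scores), "samples x",
      ncol(object@scores), "pairs (scale:", object@valueKind, ")\n")
  if (nrow(object@droppedPairs))
    cat("  dropped pairs:", nrow(object@droppedPairs), "\n")
})

setMethod("show", "SpatialEmbedding", function(object) {
  cat("SpatialEmbedding:", nrow(object@coords), "cells in 3-d,",
      length(object@stressTrace), "iterations\n")
  if (length(object@farFlag))
    cat("  far cells:", sum(object@farFlag), "of", length(object@farFlag), "\n")
})

setMethod("show", "ConsensusResult", function(object) {
  cat("ConsensusResult over k =", paste(names(object@consensus), collapse = ", "),
      "\n  PAC:", paste(sprintf("%s=%.3f", names(object@pac), object@pac),
                        collapse = ", "), "\n")
})

setMethod("show", "SubtypeModel", function(object) {
  cat("SubtypeModel with", object@k, "subtypes;",
      length(unique(unlist(lapply(object@markers, function(m) m$pair_id)))),
      "marker pairs\n")
})

setMethod("show", "RiskModel", function(object) {
  cat("RiskModel:", length(object@pairs), "pairs; cutoff",
      signif(object@cutoff, 4), "\n")
  print(data.frame(pair = object@pairs,
                   coefficient = unname(object@coefficients)))
})
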