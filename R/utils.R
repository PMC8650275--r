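# internal helpers shared across modules

# run `expr` under a local RNG state seeded with `seed`
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# match LR reference genes against matrix rownames; returns usable pairs and
# a droppedPairs data.frame for the rest
matchPairs <- function(lrRef, geneIds) {
  lrRef <- validateLRPairs(lrRef)
  ok <- lrRef$ligand %in% geneIds & lrRef$receptor %in% geneIds
  dropped <- data.frame(pair_id = lrRef$pair_id[!ok],
                        reason = rep("gene absent", sum(!ok)),
                        stringsAsFactors = FALSE)
  list(used = lrRef[ok, , drop = FALSE], dropped = dropped)
}

# z-standardize a samples x pairs matrix per pair; constant pairs dropped
standardizeScores <- function(scores, center = NULL, scale = NULL) {
  stopifnot(is.matrix(scores))
  if (is.null(center)) {
    center <- colMeans(scores)
    scale <- apply(scores, 2, sd)
    keep <- scale > 0
    if (!all(keep)) {
      scores <- scores[, keep, drop = FALSE]
      center <- center[keep]
      scale <- scale[keep]
    }
  } else {
    scores <- scores[, names(center), drop = FALSE]
  }
  z <- sweep(sweep(scores, 2, center, "-"), 2, scale, "/")
  attr(z, "center") <- center
  attr(z, "scale") <- scale
  z
}

getAssay <- function(se, assay) {
  if (!assay %in% SummarizedExperiment::assayNames(se))
    stop("assay '", assay, "' not found; available: ",
         paste(SummarizedExperiment::assayNames(se), collapse = ", "),
         call. = FALSE)
  SummarizedExperiment::assay(se, assay)
}

getCellTypes <- function(se) {
  cd <- SummarizedExperiment::colData(se)
  if (!"cell_type" %in% colnames(cd))
    stop("colData must contain a 'cell_type' column", call. = FALSE)
  ct <- as.character(cd$cell_type)
  if (any(is.na(ct) | ct == ""))
    stop("cell_type labels must be non-empty", call. = FALSE)
  names(ct) <- colnames(se)
  ct
}
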