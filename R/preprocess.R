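#' Quality-control filter for single-cell count matrices
#'
#' Retains cells with more than `minUMI` total counts, more than `minGenes`
#' and fewer than `maxGenes` detected genes (count > 0), and a mitochondrial
#' count fraction below `maxMito`. Mitochondrial genes are identified by
#' `mitoPrefix` on the gene id; the fraction is computed on raw totals.
#' Inequalities are strict on both sides.
#'
#' @param sce SingleCellExperiment/SummarizedExperiment with a `counts` assay.
#' @param minUMI,minGenes,maxGenes,maxMito,mitoPrefix filter thresholds.
#' @param verbose log retained/removed tallies.
#' @return the input restricted to passing cells; the per-rule removal
#'   tallies are attached as `metadata(x)$qc_tally`.
#' @export
qcFilterCells <- function(sce, minUMI = 1000, minGenes = 200, maxGenes = 6000,
                          maxMito = 0.05, mitoPrefix = "MT-", verbose = TRUE) {
  counts <- getAssay(sce, "counts")
  if (any(counts != round(counts)))
    stop("qcFilterCells requires raw counts", call. = FALSE)
  total <- colSums(counts)
  detected <- colSums(counts > 0)
  mito <- startsWith(rownames(counts), mitoPrefix)
  mitoFrac <- if (any(mito)) colSums(counts[mito, , drop = FALSE]) / total
              else rep(0, ncol(counts))
  mitoFrac[total == 0] <- 0
  keep <- total > minUMI & detected > minGenes & detected < maxGenes &
    mitoFrac < maxMito
  tally <- c(input = ncol(counts), retained = sum(keep),
             fail_umi = sum(total <= minUMI),
             fail_min_genes = sum(detected <= minGenes),
             fail_max_genes = sum(detected >= maxGenes),
             fail_mito = sum(mitoFrac >= maxMito))
  if (verbose)
    message("qcFilterCells: retained ", tally[["retained"]], "/",
            tally[["input"]], " cells (",
            tally[["fail_umi"]], " low-UMI, ",
            tally[["fail_min_genes"]], " few-gene, ",
            tally[["fail_max_genes"]], " many-gene, ",
            tally[["fail_mito"]], " high-mito)")
  out <- sce[, keep]
  S4Vectors::metadata(out)$qc_tally <- tally
  out
}

#' Library-size log-normalization
#'
#' `log(1 + count / cell_total * scale)` per cell, the conventional
#' log-normalization; stored as a `logcounts` assay. Zero-total columns are
#' an error (they carry no usable signal and break the division).
#'
#' @param sce object with a `counts` assay.
#' @param scale library-size scale factor (default 10000).
#' @return input with an added `logcounts` assay.
#' @export
logNormalize <- function(sce, scale = 10000) {
  counts <- getAssay(sce, "counts")
  total <- colSums(counts)
  if (any(total == 0))
    stop("zero-total column(s): ",
         paste(colnames(counts)[total == 0], collapse = ", "), call. = FALSE)
  ln <- log1p(sweep(counts, 2, total, "/") * scale)
  SummarizedExperiment::assay(sce, "logcounts") <- ln
  sce
}

#' Natural-log transform for bulk linear-scale expression
#'
#' Adds a `logexprs` assay with `log(x + pseudocount)`. Bulk pair scores for
#' subtyping and prognosis are conventionally computed on the log scale.
#'
#' @param se SummarizedExperiment with an `exprs` (linear) assay.
#' @param pseudocount added before the log (default 1).
#' @return input with an added `logexprs` assay.
#' @export
bulkLogTransform <- function(se, pseudocount = 1) {
  m <- getAssay(se, "exprs")
  SummarizedExperiment::assay(se, "logexprs") <- log(m + pseudocount)
  se
}
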