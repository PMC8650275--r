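#' Validate a ligand-receptor reference table
#'
#' The LR reference is a plain data.frame with columns `pair_id`
#' (`"LIGAND:RECEPTOR"`), `ligand` and `receptor`. Every scoring function
#' validates its reference through this helper.
#'
#' @param lrRef data.frame with at least `ligand` and `receptor` columns;
#'   `pair_id` is synthesized as `"ligand:receptor"` when absent.
#' @return the validated (possibly completed) data.frame.
#' @export
validateLRPairs <- function(lrRef) {
  if (!is.data.frame(lrRef) || !all(c("ligand", "receptor") %in% names(lrRef)))
    stop("LR reference must be a data.frame with 'ligand' and 'receptor' columns",
         call. = FALSE)
  lrRef$ligand <- as.character(lrRef$ligand)
  lrRef$receptor <- as.character(lrRef$receptor)
  if (any(lrRef$ligand == "" | lrRef$receptor == "") ||
      any(is.na(lrRef$ligand) | is.na(lrRef$receptor)))
    stop("ligand and receptor ids must be non-empty", call. = FALSE)
  if (!"pair_id" %in% names(lrRef))
    lrRef$pair_id <- paste(lrRef$ligand, lrRef$receptor, sep = ":")
  if (anyDuplicated(lrRef$pair_id))
    stop("duplicate pair_id in LR reference", call. = FALSE)
  lrRef[, c("pair_id", "ligand", "receptor")]
}

#' Read a ligand-receptor pair reference from TSV
#'
#' Expects a header with `ligand` and `receptor` columns. Duplicate rows are
#' collapsed with a warning; a `pair_id` of the form `"ligand:receptor"` is
#' synthesized.
#'
#' @param path TSV file path.
#' @return data.frame (`pair_id`, `ligand`, `receptor`).
#' @export
readLRPairs <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (!all(c("ligand", "receptor") %in% names(tab)))
    stop("LR pair file must have 'ligand' and 'receptor' columns: ", path,
         call. = FALSE)
  if (nrow(tab) == 0L)
    return(data.frame(pair_id = character(), ligand = character(),
                      receptor = character(), stringsAsFactors = FALSE))
  key <- paste(tab$ligand, tab$receptor, sep = ":")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate LR pair row(s) collapsed",
            call. = FALSE)
    tab <- tab[!duplicated(key), , drop = FALSE]
  }
  validateLRPairs(tab[, c("ligand", "receptor"), drop = FALSE])
}

#' @rdname readLRPairs
#' @param lrRef validated LR reference table.
#' @export
writeLRPairs <- function(lrRef, path) {
  lrRef <- validateLRPairs(lrRef)
  write.table(lrRef, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a SummarizedExperiment / SingleCellExperiment from a value matrix
#'
#' Internal-facing constructors used by the readers and the simulators.
#' `valueKind` maps onto the assay name: counts -> `"counts"`,
#' lognorm -> `"logcounts"`, linear -> `"exprs"`, log -> `"logexprs"`.
#'
#' @param values genes x columns numeric matrix with dimnames.
#' @param valueKind one of `"counts"`, `"lognorm"`, `"linear"`, `"log"`.
#' @param cellTypes optional per-column cell-type labels (makes it an
#'   annotated SingleCellExperiment).
#' @return SummarizedExperiment (or SingleCellExperiment when annotated).
#' @export
makeExpressionSE <- function(values, valueKind = c("counts", "lognorm",
                                                   "linear", "log"),
                             cellTypes = NULL) {
  valueKind <- match.arg(valueKind)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must carry gene rownames and column ids",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate column ids", call. = FALSE)
  if (any(values < 0) && valueKind != "log")
    stop("expression values must be non-negative", call. = FALSE)
  if (valueKind == "counts" && any(values != round(values)))
    stop("counts must be integers", call. = FALSE)
  an <- c(counts = "counts", lognorm = "logcounts",
          linear = "exprs", log = "logexprs")[[valueKind]]
  assays <- stats::setNames(list(values), an)
  if (is.null(cellTypes)) {
    SummarizedExperiment::SummarizedExperiment(assays = assays)
  } else {
    if (length(cellTypes) != ncol(values))
      stop("one cell_type per column required", call. = FALSE)
    SingleCellExperiment::SingleCellExperiment(
      assays = assays,
      colData = S4Vectors::DataFrame(cell_type = as.character(cellTypes),
                                     row.names = colnames(values)))
  }
}

#' Read an expression matrix (TSV or MatrixMarket)
#'
#' TSV: genes as rows, first column gene ids, header row of column ids.
#' MatrixMarket: coordinate `.mtx` with `genes.tsv` and `barcodes.tsv`
#' sidecars in the same directory (1-based coordinates per the standard).
#'
#' @param path file path (`.mtx` for MatrixMarket).
#' @param format `"tsv"` or `"mtx"`.
#' @param valueKind scale of the stored values (caller-supplied metadata).
#' @return SummarizedExperiment with one assay named for `valueKind`.
#' @export
readExpression <- function(path, format = c("tsv", "mtx"),
                           valueKind = "counts") {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("expression TSV needs id column + data", call. = FALSE)
    genes <- as.character(tab[[1]])
    if (anyDuplicated(genes))
      stop("duplicate gene ids in ", path, ": ",
           paste(unique(genes[duplicated(genes)]), collapse = ", "),
           call. = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric entries in expression TSV", call. = FALSE)
    rownames(m) <- genes
  } else {
    mm <- Matrix::readMM(path)
    dirn <- dirname(path)
    genes <- read.delim(file.path(dirn, "genes.tsv"), header = FALSE,
                        stringsAsFactors = FALSE)[[1]]
    cells <- read.delim(file.path(dirn, "barcodes.tsv"), header = FALSE,
                        stringsAsFactors = FALSE)[[1]]
    if (nrow(mm) != length(genes) || ncol(mm) != length(cells))
      stop("mtx dimensions disagree with genes/barcodes sidecars", call. = FALSE)
    m <- as.matrix(mm)
    dimnames(m) <- list(genes, cells)
  }
  makeExpressionSE(m, valueKind = valueKind)
}

#' @rdname readExpression
#' @param se SummarizedExperiment to write.
#' @param assay assay to serialize.
#' @export
writeExpression <- function(se, path, assay = SummarizedExperiment::assayNames(se)[1]) {
  m <- getAssay(se, assay)
  out <- data.frame(gene = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-cell annotation / survival / abundance tables
#'
#' Plain TSV readers for the remaining pipeline inputs.
#' `readCellAnnotation` expects columns `cell`, `cell_type` (plus optional
#' `sample`); `readSurvival` expects `sample`, `time_months`, `event`;
#' `readAbundance` expects samples as rows (first column ids) and immune
#' cell types as remaining columns.
#'
#' @param path TSV file path.
#' @return data.frame (annotation, survival) or numeric matrix (abundance).
#' @export
readCellAnnotation <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("cell", "cell_type") %in% names(tab)))
    stop("annotation TSV must have 'cell' and 'cell_type' columns", call. = FALSE)
  if (any(tab$cell_type == "" | is.na(tab$cell_type)))
    stop("cell_type labels must be non-empty", call. = FALSE)
  tab
}

#' @rdname readCellAnnotation
#' @export
readSurvival <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("sample", "time_months", "event") %in% names(tab)))
    stop("survival TSV must have 'sample', 'time_months', 'event' columns",
         call. = FALSE)
  validateSurvival(tab)
}

#' @rdname readCellAnnotation
#' @export
readAbundance <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  if (any(is.na(m))) stop("abundance matrix has missing values", call. = FALSE)
  if (any(m < 0)) stop("abundance values must be non-negative", call. = FALSE)
  m
}

validateSurvival <- function(surv) {
  stopifnot(is.data.frame(surv),
            all(c("sample", "time_months", "event") %in% names(surv)))
  if (anyDuplicated(surv$sample)) stop("duplicate sample ids", call. = FALSE)
  if (any(!is.finite(surv$time_months)) || any(surv$time_months <= 0))
    stop("survival times must be positive and finite", call. = FALSE)
  if (!all(surv$event %in% c(0, 1)))
    stop("event must be 0/1", call. = FALSE)
  surv
}

#' Serialize an InteractionTensor to long-format TSV
#'
#' Columns: pair, source_type, target_type, strength (and pvalue when
#' permutation testing has been run).
#'
#' @param tensor InteractionTensor.
#' @param path output TSV path.
#' @export
writeInteractionTensor <- function(tensor, path) {
  s <- strengths(tensor)
  dn <- dimnames(s)
  long <- expand.grid(pair = dn[[1]], source_type = dn[[2]],
                      target_type = dn[[3]], KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  long$strength <- as.vector(s)
  if (length(pvalues(tensor))) long$pvalue <- as.vector(pvalues(tensor))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeInteractionTensor
#' @param psm PairScoreMatrix.
#' @export
writePairScores <- function(psm, path) {
  m <- scoreMatrix(psm)
  out <- data.frame(sample = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
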