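#' Correlate LR pair scores with immune-cell abundance
#'
#' Pearson correlation (with its two-sided test) between every pair's score
#' and every immune cell type's abundance over the shared samples, BH
#' adjustment within cell type. The screen behind "which interactions track
#' infiltration".
#'
#' @param scores [PairScoreMatrix-class] or samples x pairs matrix.
#' @param abundance samples x cell-types non-negative matrix.
#' @param dataset optional tag recorded in the output (for later
#'   cross-dataset intersection).
#' @return data.frame (`pair_id`, `cell_type`, `r`, `p`, `padj`, `dataset`).
#' @export
correlateScoresAbundance <- function(scores, abundance, dataset = "dataset1") {
  m <- asScoreMatrix(scores)
  shared <- intersect(rownames(m), rownames(abundance))
  if (length(shared) < 10)
    stop("need >= 10 shared samples, have ", length(shared), call. = FALSE)
  m <- m[shared, , drop = FALSE]
  ab <- abundance[shared, , drop = FALSE]
  res <- do.call(rbind, lapply(colnames(ab), function(ct) {
    stats <- lapply(seq_len(ncol(m)), function(j) {
      ct.test <- suppressWarnings(cor.test(m[, j], ab[, ct]))
      c(r = unname(ct.test$estimate), p = ct.test$p.value)
    })
    stats <- do.call(rbind, stats)
    data.frame(pair_id = colnames(m), cell_type = ct,
               r = stats[, "r"], p = stats[, "p"],
               padj = p.adjust(stats[, "p"], method = "BH"),
               dataset = dataset, stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

#' Intersect significant pair-abundance associations across datasets
#'
#' Pairs significant (adjusted p below `adjP`) for a given cell type in
#' every supplied table, optionally requiring the correlation sign to agree
#' across datasets — the rule behind shared infiltration-associated pairs.
#'
#' @param tables list (>= 2) of [correlateScoresAbundance()] outputs.
#' @param adjP adjusted-p threshold.
#' @param requireSignConsistency drop pairs whose sign flips across
#'   datasets.
#' @return data.frame (`cell_type`, `pair_id`, `sign`, `n_datasets`).
#' @export
intersectSignificant <- function(tables, adjP = 0.05,
                                 requireSignConsistency = TRUE) {
  if (!is.list(tables) || length(tables) < 2)
    stop("need >= 2 association tables", call. = FALSE)
  all <- do.call(rbind, tables)
  sig <- all[all$padj < adjP, , drop = FALSE]
  nTab <- length(tables)
  out <- do.call(rbind, lapply(split(sig, sig$cell_type), function(s) {
    byPair <- split(s, s$pair_id)
    keep <- lapply(byPair, function(b) {
      if (length(unique(b$dataset)) < nTab) return(NULL)
      signs <- sign(b$r)
      if (requireSignConsistency && length(unique(signs)) > 1) return(NULL)
      data.frame(cell_type = b$cell_type[1], pair_id = b$pair_id[1],
                 sign = if (length(unique(signs)) == 1) signs[1] else NA_real_,
                 n_datasets = length(unique(b$dataset)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, keep)
  }))
  rownames(out) <- NULL
  if (is.null(out))
    out <- data.frame(cell_type = character(), pair_id = character(),
                      sign = numeric(), n_datasets = integer(),
                      stringsAsFactors = FALSE)
  out
}

#' Per-sample cell-type infiltration proportions
#'
#' Fraction of each sample's cells carrying each annotation label; rows sum
#' to one.
#'
#' @param cellTypes named character vector, cell id -> cell type (or an
#'   annotated expression object).
#' @param sampleOfCell named character vector, cell id -> sample id; every
#'   cell must be mapped.
#' @return samples x cell-types proportion matrix.
#' @export
infiltrationProportions <- function(cellTypes, sampleOfCell) {
  if (is(cellTypes, "SummarizedExperiment")) cellTypes <- getCellTypes(cellTypes)
  unmapped <- setdiff(names(cellTypes), names(sampleOfCell))
  if (length(unmapped))
    stop("unmapped cell(s): ", paste(utils::head(unmapped, 5), collapse = ", "),
         call. = FALSE)
  samples <- sampleOfCell[names(cellTypes)]
  tab <- table(samples, cellTypes)
  prop <- sweep(unclass(tab), 1, rowSums(tab), "/")
  prop
}
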