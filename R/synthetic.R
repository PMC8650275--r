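#' Generate a synthetic ligand-receptor reference
#'
#' Draws `nPairs` distinct ordered (ligand, receptor) gene pairs from a
#' universe of `nGenes` named genes. Stands in for a curated LR database so
#' the pipeline can run with known ground truth.
#'
#' @param nGenes number of genes in the universe.
#' @param nPairs number of ordered pairs to draw (ligand != receptor).
#' @param seed RNG seed; the table is deterministic per seed.
#' @param distinctGenes if TRUE each gene appears in at most one pair
#'   (requires `nPairs <= nGenes %/% 2`), which keeps planted effects from
#'   leaking between pairs.
#' @return data.frame (`pair_id`, `ligand`, `receptor`).
#' @export
generateLRReference <- function(nGenes, nPairs, seed = 1,
                                distinctGenes = FALSE) {
  stopifnot(nGenes >= 1, nPairs >= 0)
  genes <- sprintf("G%05d", seq_len(nGenes))
  if (nPairs == 0L)
    return(data.frame(pair_id = character(), ligand = character(),
                      receptor = character(), stringsAsFactors = FALSE))
  if (distinctGenes) {
    if (nPairs > nGenes %/% 2)
      stop("capacity exceeded: ", nPairs, " disjoint pairs need ",
           2 * nPairs, " genes, have ", nGenes, call. = FALSE)
    withSeed(seed, {
      picked <- sample(genes, 2L * nPairs)
      lig <- picked[seq_len(nPairs)]
      rec <- picked[nPairs + seq_len(nPairs)]
      validateLRPairs(data.frame(ligand = lig, receptor = rec,
                                 stringsAsFactors = FALSE))
    })
  } else {
    capacity <- as.double(nGenes) * (nGenes - 1)
    if (nPairs > capacity)
      stop("capacity exceeded: only ", capacity,
           " distinct ordered pairs exist for ", nGenes, " genes",
           call. = FALSE)
    withSeed(seed, {
      idx <- sample.int(capacity, nPairs)
      i <- (idx - 1) %/% (nGenes - 1) + 1
      off <- (idx - 1) %% (nGenes - 1) + 1
      j <- off + (off >= i)   # skip the diagonal
      validateLRPairs(data.frame(ligand = genes[i], receptor = genes[j],
                                 stringsAsFactors = FALSE))
    })
  }
}

checkPlanted <- function(planted, lrRef, types) {
  if (is.null(planted) || nrow(planted) == 0L)
    return(data.frame(pair_id = character(), source = character(),
                      target = character(), fold = numeric(),
                      stringsAsFactors = FALSE))
  stopifnot(all(c("pair_id", "source", "target", "fold") %in% names(planted)))
  bad <- setdiff(planted$pair_id, lrRef$pair_id)
  if (length(bad))
    stop("planted pair id(s) not in reference: ",
         paste(bad, collapse = ", "), call. = FALSE)
  badT <- setdiff(c(planted$source, planted$target), types)
  if (length(badT))
    stop("planted cell type(s) not simulated: ",
         paste(badT, collapse = ", "), call. = FALSE)
  if (any(planted$fold < 1)) stop("fold effects must be >= 1", call. = FALSE)
  planted
}

#' Simulate annotated single-cell UMI counts with planted LR interactions
#'
#' Negative-binomial counts (mean `baseMean`, variance
#' `mu + dispersion * mu^2`) for every gene in the LR reference, over named
#' cell types. For each planted interaction `(pair, source, target, fold)`
#' the pair's ligand gene has mean `fold * baseMean` in source-type cells
#' and its receptor gene has mean `fold * baseMean` in target-type cells.
#' A configurable number of `"MT-"`-prefixed genes is appended so QC
#' filtering is exercisable.
#'
#' @param typeSizes named integer vector, cells per cell type (each >= 2).
#' @param lrRef LR reference data.frame.
#' @param planted data.frame (`pair_id`, `source`, `target`, `fold`) or NULL.
#' @param baseMean baseline NB mean per gene per cell (UMI scale).
#' @param dispersion NB dispersion (0 = Poisson limit is not allowed; use a
#'   small positive value).
#' @param nMitoGenes number of extra mitochondrial genes to append.
#' @param seed RNG seed.
#' @return list with `sce` (SingleCellExperiment: `counts` assay +
#'   `cell_type` colData) and `truth` (planted structure).
#' @export
simulateSCCounts <- function(typeSizes, lrRef, planted = NULL,
                             baseMean = 0.5, dispersion = 0.5,
                             nMitoGenes = 0, seed = 1) {
  stopifnot(length(typeSizes) >= 1, !is.null(names(typeSizes)),
            baseMean > 0, dispersion > 0)
  if (any(typeSizes < 2))
    stop("every requested cell type needs >= 2 cells; offending: ",
         paste(names(typeSizes)[typeSizes < 2], collapse = ", "),
         call. = FALSE)
  lrRef <- validateLRPairs(lrRef)
  planted <- checkPlanted(planted, lrRef, names(typeSizes))
  genes <- unique(c(lrRef$ligand, lrRef$receptor))
  if (nMitoGenes > 0) genes <- c(genes, sprintf("MT-%03d", seq_len(nMitoGenes)))
  cellType <- rep(names(typeSizes), times = typeSizes)
  nCells <- length(cellType)
  cellIds <- sprintf("cell%05d", seq_len(nCells))

  mu <- matrix(baseMean, nrow = length(genes), ncol = nCells,
               dimnames = list(genes, cellIds))
  if (nrow(planted)) {
    for (r in seq_len(nrow(planted))) {
      p <- lrRef[lrRef$pair_id == planted$pair_id[r], ]
      mu[p$ligand, cellType == planted$source[r]] <-
        planted$fold[r] * baseMean
      mu[p$receptor, cellType == planted$target[r]] <-
        planted$fold[r] * baseMean
    }
  }
  counts <- withSeed(seed, {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
           nrow = nrow(mu), dimnames = dimnames(mu))
  })
  sce <- makeExpressionSE(counts, valueKind = "counts", cellTypes = cellType)
  truth <- list(planted_interactions = planted,
                type_sizes = typeSizes,
                base_mean = baseMean,
                dispersion = dispersion)
  list(sce = sce, truth = truth)
}

# censoring rate r such that the expected censored fraction matches
# censorRate when event times are exponential with per-sample rates
calibrateCensorRate <- function(eventRates, censorRate) {
  if (censorRate <= 0) return(0)
  if (censorRate >= 1) return(Inf)
  f <- function(logr) mean(exp(logr) / (exp(logr) + eventRates)) - censorRate
  exp(uniroot(f, lower = log(1e-8), upper = log(1e8))$root)
}

#' Simulate a bulk cohort with planted subtypes, survival and abundance
#'
#' Expression is log-normal: natural-log values are
#' `baseLogMean + N(0, noiseSd)`, and for each subtype both the ligand and
#' the receptor gene of its marker pairs are shifted by `markerLogFC`
#' (natural-log scale) in that subtype's samples, so the pair product score
#' separates subtypes multiplicatively. Survival times are exponential with
#' log-hazard `sum(coef * standardized pair score)` over the causal list,
#' censored by an independent exponential calibrated to the requested
#' censoring fraction. Immune abundances are linear in standardized driver
#' pair scores plus Gaussian noise, truncated at zero.
#'
#' @param nSamples cohort size.
#' @param lrRef LR reference data.frame.
#' @param kSubtypes number of planted subtypes (1 = no marker shifts).
#' @param markersPerSubtype marker pairs planted per subtype (disjoint sets).
#' @param markerLogFC marker shift on the natural-log scale.
#' @param noiseSd per-gene log-scale noise sd.
#' @param baseLogMean baseline natural-log expression.
#' @param survivalSpec list: `baselineRate` (events/month), `causal`
#'   (data.frame `pair_id`, `coef`), `censorRate` in `[0, 1]`.
#' @param abundanceSpec data.frame (`pair_id`, `cell_type`, `rho`) of
#'   abundance drivers, or NULL for no abundance matrix.
#' @param markerAssignment optional named list subtype -> pair ids
#'   (must be disjoint); default assigns the first pairs round-robin-free.
#' @param seed RNG seed.
#' @return list: `se` (SummarizedExperiment, `exprs` + `logexprs` assays,
#'   `subtype` colData), `survival` (data.frame), `abundance` (matrix or
#'   NULL), `truth` (planted structure).
#' @export
simulateBulkCohort <- function(nSamples, lrRef, kSubtypes = 3,
                               markersPerSubtype = 50, markerLogFC = 1.5,
                               noiseSd = 0.3, baseLogMean = 2,
                               survivalSpec = list(baselineRate = 0.02,
                                                   causal = NULL,
                                                   censorRate = 0.3),
                               abundanceSpec = NULL,
                               markerAssignment = NULL, seed = 1) {
  stopifnot(nSamples >= 2, kSubtypes >= 1)
  lrRef <- validateLRPairs(lrRef)
  nPairs <- nrow(lrRef)
  if (kSubtypes > 1 && kSubtypes * markersPerSubtype > nPairs)
    stop("need kSubtypes * markersPerSubtype <= number of pairs", call. = FALSE)
  censorRate <- survivalSpec$censorRate %||% 0.3
  stopifnot(censorRate >= 0, censorRate <= 1)

  if (is.null(markerAssignment)) {
    markerAssignment <- if (kSubtypes > 1)
      split(lrRef$pair_id[seq_len(kSubtypes * markersPerSubtype)],
            rep(seq_len(kSubtypes), each = markersPerSubtype))
    else list()
  } else {
    ids <- unlist(markerAssignment)
    if (anyDuplicated(ids))
      stop("marker assignment overlaps across subtypes: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
    if (!all(ids %in% lrRef$pair_id))
      stop("marker assignment references unknown pairs", call. = FALSE)
  }
  if (length(markerAssignment))
    names(markerAssignment) <- as.character(seq_along(markerAssignment))

  genes <- unique(c(lrRef$ligand, lrRef$receptor))
  sampleIds <- sprintf("S%04d", seq_len(nSamples))

  withSeed(seed, {
    subtype <- if (kSubtypes > 1) sample(rep_len(seq_len(kSubtypes), nSamples))
               else rep(1L, nSamples)
    logex <- matrix(baseLogMean + rnorm(length(genes) * nSamples, sd = noiseSd),
                    nrow = length(genes),
                    dimnames = list(genes, sampleIds))
    for (k in names(markerAssignment)) {
      mk <- lrRef[lrRef$pair_id %in% markerAssignment[[k]], ]
      cols <- subtype == as.integer(k)
      shiftGenes <- unique(c(mk$ligand, mk$receptor))
      logex[shiftGenes, cols] <- logex[shiftGenes, cols] + markerLogFC
    }

    # standardized log-scale pair scores drive survival and abundance
    pairScore <- function(pid) {
      p <- lrRef[lrRef$pair_id == pid, ]
      s <- logex[p$ligand, ] * logex[p$receptor, ]
      as.numeric(scale(s))
    }

    causal <- survivalSpec$causal
    lp <- rep(0, nSamples)
    if (!is.null(causal) && nrow(causal)) {
      stopifnot(all(c("pair_id", "coef") %in% names(causal)))
      if (!all(causal$pair_id %in% lrRef$pair_id))
        stop("causal pair id(s) not in reference", call. = FALSE)
      if (any(!is.finite(causal$coef)))
        stop("hazard coefficients must be finite", call. = FALSE)
      for (r in seq_len(nrow(causal)))
        lp <- lp + causal$coef[r] * pairScore(causal$pair_id[r])
    }
    baselineRate <- survivalSpec$baselineRate %||% 0.02
    rates <- baselineRate * exp(lp)
    eventTime <- rexp(nSamples, rate = rates)
    if (censorRate == 0) {
      time <- eventTime; event <- rep(1L, nSamples)
    } else if (censorRate == 1) {
      time <- rexp(nSamples, rate = baselineRate); event <- rep(0L, nSamples)
    } else {
      r <- calibrateCensorRate(rates, censorRate)
      censTime <- rexp(nSamples, rate = r)
      time <- pmin(eventTime, censTime)
      event <- as.integer(eventTime <= censTime)
    }
    surv <- data.frame(sample = sampleIds, time_months = time, event = event,
                       stringsAsFactors = FALSE)

    abundance <- NULL
    if (!is.null(abundanceSpec) && nrow(abundanceSpec)) {
      stopifnot(all(c("pair_id", "cell_type", "rho") %in% names(abundanceSpec)))
      if (!all(abundanceSpec$pair_id %in% lrRef$pair_id))
        stop("abundance driver pair id(s) not in reference", call. = FALSE)
      ctypes <- unique(abundanceSpec$cell_type)
      abundance <- matrix(0, nrow = nSamples, ncol = length(ctypes),
                          dimnames = list(sampleIds, ctypes))
      for (ct in ctypes) {
        dr <- abundanceSpec[abundanceSpec$cell_type == ct, , drop = FALSE]
        sig <- rep(0, nSamples)
        for (r in seq_len(nrow(dr)))
          sig <- sig + dr$rho[r] * pairScore(dr$pair_id[r])
        resid <- sqrt(max(1 - sum(dr$rho^2), 0.05))
        abundance[, ct] <- pmax(5 + sig + rnorm(nSamples, sd = resid), 0)
      }
    }

    se <- makeExpressionSE(exp(logex), valueKind = "linear")
    SummarizedExperiment::assay(se, "logexprs") <- logex
    SummarizedExperiment::colData(se)$subtype <- subtype

    truth <- list(subtype_labels = stats::setNames(subtype, sampleIds),
                  subtype_markers = markerAssignment,
                  causal_pairs = causal,
                  abundance_drivers = abundanceSpec,
                  marker_logfc = markerLogFC,
                  censor_rate = censorRate)
    list(se = se, survival = surv, abundance = abundance, truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
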