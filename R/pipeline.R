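#' Default pipeline configuration
#'
#' Flat list of per-stage parameters; [runPipeline()] merges user overrides
#' (from a YAML file or a list) over these defaults. Every stochastic stage
#' has its own seed derived from the global `seed` entry.
#'
#' @return named list of defaults.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1,
    simulate = list(n_genes = 120, n_pairs = 40, type_sizes = c(Tcell = 60,
                    Myeloid = 60, Epithelial = 60), base_mean = 0.5,
                    dispersion = 0.5, n_mito_genes = 5,
                    bulk_n = 120, k_subtypes = 3, markers_per_subtype = 10,
                    marker_logfc = 1.5, noise_sd = 0.3, censor_rate = 0.3),
    # qcFilterCells() defaults carry the literature thresholds for real UMI
    # data; the synthetic generator's library sizes are far shallower, so the
    # pipeline's own defaults are scaled to the generator's depth.
    qc = list(min_umi = 20, min_genes = 10, max_genes = 1000,
              max_mito = 0.3, mito_prefix = "MT-"),
    interaction = list(n_perm = 1000),
    spatial = list(n_iter = 300, learning_rate = 50, far_mode = "percentile",
                   far_threshold = 95),
    subtype = list(k_range = 2:6, n_iter = 1000, subsample = 0.8, top_n = 50),
    immune = list(adj_p = 0.05),
    survival = list(n_folds = 10, horizons = c(36, 60), n_bins = 3,
                    train_frac = 0.7)
  )
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

stageLog <- function(stage, ...) {
  message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)
}

#' Run the LRI analysis pipeline end to end on synthetic data
#'
#' Orchestrates the stages — simulate, qc, score-sc, spatial, score-bulk,
#' subtype, immune, survival — writing each stage's artifacts as TSV/JSON
#' under `outdir` together with a run manifest (config snapshot, seeds,
#' package version, input checksums). With the default `stages = "all"` the
#' whole chain runs on a generated cohort; a subset runs just those stages.
#'
#' @param config NULL (defaults), a YAML file path, or a named list merged
#'   over [defaultPipelineConfig()].
#' @param outdir output directory (created if absent).
#' @param stages character vector of stage names, or `"all"`.
#' @param seed overrides the config seed when non-NULL.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(config = NULL, outdir = tempfile("lri_run_"),
                        stages = "all", seed = NULL) {
  cfg <- defaultPipelineConfig()
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    cfg <- mergeConfig(cfg, yaml::read_yaml(config))
  } else if (is.list(config)) cfg <- mergeConfig(cfg, config)
  if (!is.null(seed)) cfg$seed <- seed
  allStages <- c("simulate", "qc", "score-sc", "spatial", "score-bulk",
                 "subtype", "immune", "survival")
  if (identical(stages, "all")) stages <- allStages
  bad <- setdiff(stages, allStages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = cfg, outdir = outdir)
  baseSeed <- as.integer(cfg$seed)
  sc <- cfg$simulate

  stageLog("simulate", "generating reference and cohorts (seed ", baseSeed, ")")
  lrRef <- generateLRReference(sc$n_genes, sc$n_pairs, seed = baseSeed,
                               distinctGenes = TRUE)
  writeLRPairs(lrRef, file.path(outdir, "lr_pairs.tsv"))
  typeSizes <- unlist(sc$type_sizes)
  types <- names(typeSizes)
  planted <- data.frame(pair_id = lrRef$pair_id[1],
                        source = types[1], target = types[2], fold = 5)
  sim <- simulateSCCounts(typeSizes, lrRef, planted = planted,
                          baseMean = sc$base_mean, dispersion = sc$dispersion,
                          nMitoGenes = sc$n_mito_genes, seed = baseSeed + 1)
  causal <- data.frame(pair_id = lrRef$pair_id[c(2, 3)], coef = c(0.8, -0.8))
  drivers <- data.frame(pair_id = lrRef$pair_id[4],
                        cell_type = "Macrophage", rho = 0.6)
  bulk <- simulateBulkCohort(sc$bulk_n, lrRef, kSubtypes = sc$k_subtypes,
                             markersPerSubtype = sc$markers_per_subtype,
                             markerLogFC = sc$marker_logfc,
                             noiseSd = sc$noise_sd,
                             survivalSpec = list(baselineRate = 0.02,
                                                 causal = causal,
                                                 censorRate = sc$censor_rate),
                             abundanceSpec = drivers, seed = baseSeed + 2)
  if ("simulate" %in% stages) {
    writeExpression(sim$sce, file.path(outdir, "sc_counts.tsv"))
    write.table(data.frame(cell = colnames(sim$sce),
                           cell_type = getCellTypes(sim$sce)),
                file.path(outdir, "sc_annotation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeExpression(bulk$se, file.path(outdir, "bulk_exprs.tsv"),
                    assay = "exprs")
    write.table(bulk$survival, file.path(outdir, "survival.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(planted_interactions = planted,
           subtype_labels = as.list(bulk$truth$subtype_labels),
           subtype_markers = bulk$truth$subtype_markers,
           causal_pairs = causal, abundance_drivers = drivers),
      file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }

  sce <- sim$sce
  if ("qc" %in% stages) {
    stageLog("qc", "filtering cells")
    sce <- qcFilterCells(sce, minUMI = cfg$qc$min_umi,
                         minGenes = cfg$qc$min_genes,
                         maxGenes = cfg$qc$max_genes,
                         maxMito = cfg$qc$max_mito,
                         mitoPrefix = cfg$qc$mito_prefix)
    res$qc_tally <- S4Vectors::metadata(sce)$qc_tally
  }
  sce <- logNormalize(sce)

  if ("score-sc" %in% stages) {
    stageLog("score-sc", "interaction strengths + ", cfg$interaction$n_perm,
             " permutations")
    res$tensor <- permutationSignificance(sce, lrRef,
                                          nPerm = cfg$interaction$n_perm,
                                          seed = baseSeed + 3)
    writeInteractionTensor(res$tensor, file.path(outdir, "interaction.tsv"))
    write.table(typeLevelStrength(res$tensor, "sum"),
                file.path(outdir, "type_strength.tsv"), sep = "\t",
                quote = FALSE)
  }

  if ("spatial" %in% stages) {
    stageLog("spatial", "affinity embedding")
    A <- cellAffinity(sce, lrRef)
    emb <- embed3D(A, nIter = cfg$spatial$n_iter,
                   learningRate = cfg$spatial$learning_rate,
                   seed = baseSeed + 4)
    emb <- farCells(emb, mode = cfg$spatial$far_mode,
                    threshold = cfg$spatial$far_threshold)
    d <- attr(farFlags(emb), "distance")
    write.table(data.frame(cell = rownames(embeddingCoords(emb)),
                           embeddingCoords(emb), distance = d,
                           far = farFlags(emb)),
                file.path(outdir, "embedding.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    res$embedding <- emb
  }

  bulkSE <- bulk$se
  scores <- bulkScores(bulkSE, lrRef, assay = "logexprs")
  if ("score-bulk" %in% stages) {
    stageLog("score-bulk", ncol(scoreMatrix(scores)), " pair scores")
    writePairScores(scores, file.path(outdir, "pair_scores.tsv"))
  }

  if ("subtype" %in% stages) {
    stageLog("subtype", "consensus clustering")
    cons <- consensusCluster(scores, kRange = cfg$subtype$k_range,
                             nIter = cfg$subtype$n_iter,
                             subsample = cfg$subtype$subsample,
                             seed = baseSeed + 5)
    k <- selectK(cons)
    labels <- consensusAssignments(cons, k)
    model <- fitSubtypeModel(scores, labels, topN = cfg$subtype$top_n)
    res$subtype <- list(k = as.integer(k), pac = pacScores(cons),
                        labels = labels, model = model)
    write.table(cons@cdf, file.path(outdir, "consensus_cdf.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(k = as.integer(k), pac = as.list(pacScores(cons)),
           labels = as.list(labels),
           markers = lapply(markerTables(model), function(t) t$pair_id)),
      file.path(outdir, "subtype_model.json"), auto_unbox = TRUE, digits = NA)
  }

  if ("immune" %in% stages && !is.null(bulk$abundance)) {
    stageLog("immune", "score-abundance correlations")
    res$immune <- correlateScoresAbundance(scores, bulk$abundance,
                                           dataset = "synthetic")
    write.table(res$immune, file.path(outdir, "immune_assoc.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  if ("survival" %in% stages) {
    stageLog("survival", "risk model")
    sv <- cfg$survival
    split <- trainValidationSplit(bulk$survival$sample,
                                  trainFrac = sv$train_frac,
                                  seed = baseSeed + 6)
    m <- scoreMatrix(scores)
    trainScores <- m[split$train, , drop = FALSE]
    validScores <- m[split$validation, , drop = FALSE]
    trainSurv <- bulk$survival[bulk$survival$sample %in% split$train, ]
    validSurv <- bulk$survival[bulk$survival$sample %in% split$validation, ]
    uni <- univariateScreen(trainScores, trainSurv)
    cand <- uni$pair_id[uni$candidate]
    res$univariate <- uni
    if (length(cand) >= 2) {
      sel <- lassoSelect(trainScores, trainSurv, cand,
                         nFolds = sv$n_folds, seed = baseSeed + 7)
      if (length(sel$selected)) {
        model <- fitRiskModel(trainScores, trainSurv, sel$selected)
        res$riskModel <- model
        trainRisk <- riskScore(model, trainScores)
        validRisk <- riskScore(model, validScores)
        grp <- stratifyMedian(validRisk, riskCutoff(model))
        if (nlevels(droplevels(grp)) == 2)
          res$km <- kmLogrank(validSurv, grp)
        res$auc <- vapply(sv$horizons, function(h)
          tryCatch(timeDependentAUC(validRisk[validSurv$sample], validSurv, h),
                   error = function(e) NA_real_), numeric(1))
        jsonlite::write_json(
          list(pairs = riskPairs(model),
               coefficients = as.list(riskCoefficients(model)),
               cutoff = riskCutoff(model),
               logrank_p = if (!is.null(res$km)) res$km$p else NULL,
               auc = as.list(stats::setNames(res$auc,
                                             paste0("m", sv$horizons)))),
          file.path(outdir, "risk_model.json"), auto_unbox = TRUE,
          digits = NA)
      }
    }
  }

  manifest <- list(
    package = "lriscape",
    version = as.character(utils::packageVersion("lriscape")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = baseSeed,
    stage_seeds = stats::setNames(as.list(baseSeed + 0:7),
                                  c("reference", "sc", "bulk", "permutation",
                                    "embedding", "consensus", "split",
                                    "lasso")),
    stages = stages,
    config = cfg,
    input_checksums = as.list(tools::md5sum(
      list.files(outdir, pattern = "\\.(tsv|json)$", full.names = TRUE)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
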