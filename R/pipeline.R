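# Configuration handling and the end-to-end pipeline runner.

pipelineSchema <- function() {
  list(
    seed = NULL,
    stages = NULL,
    tissue = names(formals(TissueSimConfig)),
    nuclei = c(names(formals(NucleiSimConfig)), "n_dz", "n_lz",
               "grid_spacing"),
    expression = names(formals(ExpressionSimConfig)),
    classifier = c("k", "n_trees"),
    spatial = c("n_perm", "band_width", "bin_width", "pixel_size",
                "query_type", "reference_type"),
    signatures = c("alpha", "min_datasets", "n_cohorts", "es_n_perm"))
}

#' Default pipeline configuration
#'
#' @return Nested list with blocks \code{tissue}, \code{nuclei},
#'   \code{expression}, \code{classifier}, \code{spatial},
#'   \code{signatures}, plus the global \code{seed} and the \code{stages}
#'   to run.
#' @export
defaultPipelineConfig <- function() {
  list(seed = 1L,
       stages = c("simulate", "chrometrics", "classify", "spatial",
                  "signatures"),
       tissue = list(), nuclei = list(n_dz = 100L, n_lz = 100L),
       expression = list(),
       classifier = list(k = 10L, n_trees = 500L),
       spatial = list(n_perm = 199L, band_width = 100, bin_width = 10,
                      pixel_size = 2, query_type = "T",
                      reference_type = "B_DZ"),
       signatures = list(alpha = 0.05, min_datasets = 3L,
                         n_cohorts = 4L, es_n_perm = 499L))
}

#' Validate a pipeline configuration
#'
#' Unknown blocks or keys are rejected; missing values fall back to the
#' defaults of the corresponding generator configs.
#'
#' @param config nested list (e.g. parsed from YAML).
#' @return The merged, validated configuration.
#' @export
validatePipelineConfig <- function(config) {
  schema <- pipelineSchema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    stop("unknown config block(s): ", paste(unknown, collapse = ", "))
  base <- defaultPipelineConfig()
  for (blk in setdiff(names(schema), c("seed", "stages"))) {
    if (!is.null(config[[blk]])) {
      bad <- setdiff(names(config[[blk]]), schema[[blk]])
      if (length(bad))
        stop(sprintf("unknown key(s) in block '%s': %s", blk,
                     paste(bad, collapse = ", ")))
      base[[blk]][names(config[[blk]])] <- config[[blk]]
    }
  }
  if (!is.null(config$seed)) base$seed <- as.integer(config$seed)
  if (!is.null(config$stages)) {
    bad <- setdiff(config$stages, base$stages)
    if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
    base$stages <- config$stages
  }
  base
}

configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  unname(md5sum(tmp))
}

writeJSONResult <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  path
}

stageMessage <- function(stage, t0) {
  message(sprintf("[gcniche] stage %-12s %6.1f s", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the end-to-end analysis pipeline on synthetic data
#'
#' Chains simulation, chrometric feature extraction, DZ/LZ classification,
#' spatial statistics and signature analyses into one reproducible run.
#' Every output table is written under \code{outDir}; a run manifest
#' (config hash, seeds, file checksums, package version, timestamp) makes
#' the run verifiable. Stage subsets reuse upstream outputs already
#' present in \code{outDir}.
#'
#' @param config nested configuration list, or path to a YAML file (see
#'   \code{\link{defaultPipelineConfig}}).
#' @param outDir output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
runPipeline <- function(config = defaultPipelineConfig(),
                        outDir = "gcniche-run") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validatePipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  t0 <- as.numeric(Sys.time())
  state <- new.env(parent = emptyenv())
  paths <- list(
    cells = file.path(outDir, "cells.csv"),
    polygon = file.path(outDir, "gc_polygon.csv"),
    image = file.path(outDir, "nuclei_image.tiff"),
    mask = file.path(outDir, "nuclei_mask.tiff"),
    nucleiTruth = file.path(outDir, "nuclei_truth.tsv"),
    features = file.path(outDir, "chrometric_features.tsv"),
    cv = file.path(outDir, "cv_result.json"),
    confusion = file.path(outDir, "confusion_matrix.tsv"),
    importance = file.path(outDir, "feature_importance.tsv"),
    predictions = file.path(outDir, "predicted_labels.csv"),
    nnTest = file.path(outDir, "nn_randomization.json"),
    profile = file.path(outDir, "density_profile.tsv"),
    boundary = file.path(outDir, "interface_boundary.csv"),
    rangeDist = file.path(outDir, "range_normalized_distance.tsv"),
    de = file.path(outDir, "de_table.tsv"),
    enrichment = file.path(outDir, "enrichment.json"),
    cohort = file.path(outDir, "cohort_summary.tsv"),
    manifest = file.path(outDir, "manifest.json"))

  runStage <- function(stage, fn) {
    if (!stage %in% config$stages) return(invisible())
    tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    stageMessage(stage, t0)
  }

  runStage("simulate", function() {
    tcfg <- do.call(TissueSimConfig,
                    c(config$tissue[setdiff(names(config$tissue), "seed")],
                      list(seed = deriveSeed(seed, "tissue"))))
    sim <- simulateGCMap(tcfg)
    state$map <- sim$map
    writeCellTable(sim$map, paths$cells, paths$polygon)
    nArgs <- config$nuclei
    grid <- gridCellMap(nArgs$n_dz, nArgs$n_lz,
                        spacing = if (is.null(nArgs$grid_spacing)) 30
                        else nArgs$grid_spacing)
    ncfg <- do.call(NucleiSimConfig,
                    c(nArgs[setdiff(names(nArgs),
                                    c("n_dz", "n_lz", "grid_spacing",
                                      "seed"))],
                      list(seed = deriveSeed(seed, "nuclei"))))
    ni <- simulateNucleiImage(grid, ncfg)
    state$nucleiImage <- ni
    state$gridMap <- grid
    writeNucleiImage(ni, paths$image, paths$mask)
    write.table(ni@nuclei, paths$nucleiTruth, sep = "\t",
                row.names = FALSE, quote = FALSE)
  })

  loadNuclei <- function() {
    if (is.null(state$nucleiImage)) {
      tif <- readNucleiTiff(paths$image, paths$mask)
      truth <- read.delim(paths$nucleiTruth)
      state$nucleiImage <- new("NucleiImage", image = tif$image,
                               mask = tif$mask,
                               pixelSize = config$nuclei$pixel_size %||%
                                 formals(NucleiSimConfig)$pixel_size,
                               nuclei = truth)
    }
    state$nucleiImage
  }

  runStage("chrometrics", function() {
    ni <- loadNuclei()
    seg <- segmentNuclei(ni@image, minArea = 50,
                         pixelSize = ni@pixelSize)
    feats <- extractChrometricFeatures(ni@image, seg$mask,
                                       pixelSize = ni@pixelSize)
    # join segmented nuclei to planted cells by centroid proximity
    m <- vapply(seq_len(nrow(feats)), function(i)
      which.min((ni@nuclei$x_um - feats$x_um[i])^2 +
                (ni@nuclei$y_um - feats$y_um[i])^2), 0L)
    feats$cell_id <- ni@nuclei$cell_id[m]
    feats$label <- ni@nuclei$compartment_true[m]
    state$features <- feats
    write.table(feats, paths$features, sep = "\t", row.names = FALSE,
                quote = FALSE)
  })

  loadFeatures <- function() {
    if (is.null(state$features)) state$features <- read.delim(paths$features)
    state$features
  }

  runStage("classify", function() {
    feats <- loadFeatures()
    tab <- feats[!feats$flagged,
                 c("nucleus_id", "cell_id", "label",
                   chrometricFeatureNames())]
    tab <- tab[complete.cases(tab), ]
    cv <- runStratifiedCV(tab, k = config$classifier$k,
                          nTrees = config$classifier$n_trees,
                          seed = deriveSeed(seed, "classify"))
    writeJSONResult(list(accuracy = cv@accuracy, nir = cv@nir,
                         nir_p = cv@nirP, fold_accuracy = cv@foldAccuracy,
                         k = cv@k, seed = cv@seed), paths$cv)
    cm <- as.data.frame(cv@meanConfusion)
    cm <- cbind(true = rownames(cv@meanConfusion), cm)
    write.table(cm, paths$confusion, sep = "\t", row.names = FALSE,
                quote = FALSE)
    fit <- trainForest(tab, nTrees = config$classifier$n_trees,
                       seed = deriveSeed(seed, "classify-full"))
    write.table(featureImportanceRanking(fit), paths$importance,
                sep = "\t", row.names = FALSE, quote = FALSE)
    grid <- state$gridMap
    if (is.null(grid)) {
      ni <- loadNuclei()
      grid <- CellMap(data.frame(cell_id = ni@nuclei$cell_id,
                                 x_um = ni@nuclei$x_um,
                                 y_um = ni@nuclei$y_um,
                                 phenotype = "B",
                                 compartment_true =
                                   ni@nuclei$compartment_true))
    }
    pred <- holdoutSpatialPrediction(tab, grid, k = config$classifier$k,
                                     nTrees = config$classifier$n_trees,
                                     seed = deriveSeed(seed, "holdout"))
    write.csv(pred, paths$predictions, row.names = FALSE, quote = FALSE)
  })

  loadMap <- function() {
    if (is.null(state$map))
      state$map <- readCellTable(paths$cells, paths$polygon)
    state$map
  }

  runStage("spatial", function() {
    map <- loadMap()
    sp <- config$spatial
    tst <- nnRandomizationTest(map, sp$query_type, sp$reference_type,
                               nPerm = sp$n_perm,
                               seed = deriveSeed(seed, "nn-test"))
    writeJSONResult(list(direction = tst@direction, p_value = tst@pValue,
                         pooled_p = tst@pooledP,
                         observed_median = median(tst@observed),
                         null_median = median(tst@nullDist),
                         n_perm = tst@nPerm, seed = tst@seed), paths$nnTest)
    iface <- delineateInterface(map, bandWidth = sp$band_width,
                                pixelSize = sp$pixel_size)
    bnd <- do.call(rbind, lapply(seq_along(iface@boundary), function(i)
      data.frame(piece = i, x_um = iface@boundary[[i]][, 1],
                 y_um = iface@boundary[[i]][, 2])))
    write.csv(bnd, paths$boundary, row.names = FALSE, quote = FALSE)
    prof <- densityProfile(map, iface, binWidth = sp$bin_width)
    write.table(prof, paths$profile, sep = "\t", row.names = FALSE,
                quote = FALSE)
    rnd <- rangeNormalizedDistance(map, iface)
    write.table(rnd, paths$rangeDist, sep = "\t", row.names = FALSE,
                quote = FALSE)
  })

  runStage("signatures", function() {
    ecfg <- do.call(ExpressionSimConfig,
                    c(config$expression[setdiff(names(config$expression),
                                                "seed")],
                      list(seed = deriveSeed(seed, "expression"))))
    roi <- simulatePairedROI(ecfg)
    de <- moderatedTPairedDE(roi$se, alpha = config$signatures$alpha)
    write.table(de, paths$de, sep = "\t", row.names = FALSE, quote = FALSE)
    stats <- setNames(de$statistic, de$gene)
    es <- enrichmentScore(stats, roi$truth$de_genes,
                          nPerm = config$signatures$es_n_perm,
                          seed = deriveSeed(seed, "es"))
    writeJSONResult(list(es = es@es, p = es@permP,
                         n_leading = length(es@leadingEdge),
                         n_perm = es@nPerm), paths$enrichment)
    dzSig <- de$gene[de$significant & de$direction == "up"]
    if (length(dzSig) < 5) dzSig <- roi$truth$de_genes
    nC <- config$signatures$n_cohorts
    cohorts <- lapply(seq_len(nC), function(i) {
      ci <- ecfg
      ci$seed <- deriveSeed(seed, paste0("cohort-", i))
      simulateCohort(ci, signature = sprintf("G%04d", 1:100))$se
    })
    names(cohorts) <- sprintf("cohort%02d", seq_len(nC))
    tGenes <- rownames(cohorts[[1]])
    tGenes <- tail(tGenes, 50)
    cc <- crossCohortGeneCorrelations(cohorts, sprintf("G%04d", 1:100),
                                      tGenes,
                                      minDatasets =
                                        config$signatures$min_datasets,
                                      alpha = config$signatures$alpha)
    summary <- data.frame(gene = names(cc$counts),
                          n_significant_negative = unname(cc$counts),
                          selected = names(cc$counts) %in% cc$selected)
    write.table(summary, paths$cohort, sep = "\t", row.names = FALSE,
                quote = FALSE)
  })

  existing <- unlist(paths[vapply(paths, file.exists, TRUE)])
  manifest <- list(package = "gcniche",
                   version = as.character(utils::packageVersion("gcniche")),
                   config = config, config_hash = configHash(config),
                   seed = seed,
                   checksums = as.list(md5sum(existing)),
                   timestamp = format(Sys.time(), tz = "UTC"))
  writeJSONResult(manifest, paths$manifest)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
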