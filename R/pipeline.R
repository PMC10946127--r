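## End-to-end orchestration: simulate (optional) -> QC -> layered scans ->
## RDA association -> annotation -> summary, driven by a YAML config, with
## a manifest recording seeds, thresholds and stage timings.

#' Mark a panel as LD-pruned
#'
#' Runs [ldPrune()] and subsets the panel to the retained variants,
#' flagging the result so downstream ordination does not warn.
#'
#' @param panel a [HaplotypePanel-class].
#' @param thresholds a [qcThresholds()] list.
#' @return the pruned panel (`metadata$ldPruned = TRUE`).
#' @export
prunePanel <- function(panel, thresholds = qcThresholds()) {
  kept <- ldPrune(panel, thresholds)
  out <- panel[, kept]
  out@metadata$ldPruned <- TRUE
  out@metadata$prunedFrom <- nSites(panel)
  out
}

.stage <- function(name, manifest, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  manifest$stages[[name]] <- list(
    seconds = round(proc.time()[["elapsed"]] - t0, 2))
  assign("manifest", manifest, envir = parent.frame())
  res
}

#' Run the full analysis pipeline from a config
#'
#' Executes, in order: simulation (or loading of a fixture directory),
#' genotype QC, the layered FST + XP-EHH scans, LD pruning and the RDA
#' association analyses (environment and/or phenotype), gene annotation of
#' significant windows (skipped when no annotation file is configured),
#' and the per-contrast summary. All artifacts plus a manifest (seeds,
#' thresholds, stage timings) are written under `out`.
#'
#' @param config path to a YAML file, or an equivalent nested list, with
#'   optional blocks `simulate` (arguments of [simConfig()]), `input`
#'   (`dir` of an existing fixture), `qc`, `scan`
#'   (`layers`, `span`, `step`, `topFrac`), `rda` (`modes`,
#'   `permutations`, `sdMult`, `nAxes`), `annotation` (BED/GFF3 path) and
#'   `out` (output directory).
#' @param out output directory (overrides the config entry).
#' @param seed overrides the simulation seed.
#' @return invisibly, a list with `panel`, `frame`, `qcReport`, `scans`,
#'   `rda`, `annotation`, `summary`, and the `manifest` (also written as
#'   `manifest.json`).
#' @export
runPipeline <- function(config, out = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  outDir <- out %||% config$out %||% stop("no output directory configured")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = as.character(utils::packageVersion("selscape")),
    rversion = as.character(getRversion()),
    config = config, stages = list())

  if (!is.null(config$input$dir)) {
    fx <- .stage("load", manifest, readFixture(config$input$dir))
    panel <- fx$panel
    frame <- fx$frame
  } else {
    simArgs <- config$simulate %||% list()
    if (!is.null(seed)) simArgs$seed <- seed
    cfg <- do.call(simConfig, simArgs)
    manifest$seed <- cfg@seed
    sim <- .stage("simulate", manifest, {
      frame <- simulateMetadata(cfg)
      panel <- simulateHaplotypes(cfg, frame)
      frame <- simulateTraits(panel, frame, residualSd = 1,
                              seed = cfg@seed + 2L)
      writeFixture(panel, frame, file.path(outDir, "fixture"))
      list(panel = panel, frame = frame)
    })
    panel <- sim$panel
    frame <- sim$frame
  }

  thr <- do.call(qcThresholds, config$qc %||% list())
  qcRes <- .stage("qc", manifest, filterVariants(panel, thr))
  panel <- qcRes$panel
  manifest$qc <- qcRes$report[c("input", "removedCallRate", "removedMaf",
                                "removedHwe", "retained")]

  scanCfg <- config$scan %||% list()
  layers <- scanCfg$layers %||% c("I", "II", "III")
  scans <- .stage("scan", manifest, {
    res <- lapply(layers, function(ly)
      layeredScan(panel, frame, layer = ly,
                  span = scanCfg$span %||% 50000,
                  step = scanCfg$step %||% 25000,
                  topFrac = scanCfg$topFrac %||% 0.01))
    names(res) <- paste0("layer", layers)
    res
  })
  for (nm in names(scans)) {
    for (res in scans[[nm]]) {
      tag <- gsub("[^A-Za-z0-9]+", "_", res$contrast$name)
      utils::write.table(res$fst,
                         file.path(outDir, sprintf("%s_%s_fst.tsv", nm, tag)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(res$xpehh,
                         file.path(outDir, sprintf("%s_%s_xpehh.tsv", nm, tag)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  rdaCfg <- config$rda %||% list()
  modes <- rdaCfg$modes %||% c("environment", "phenotype")
  pruned <- .stage("prune", manifest, prunePanel(panel, thr))
  rdaRes <- .stage("rda", manifest, {
    res <- lapply(modes, function(md)
      geaPipeline(pruned, frame, mode = md,
                  sdMult = rdaCfg$sdMult %||% 3.5,
                  nAxes = rdaCfg$nAxes %||% 3L,
                  permutations = rdaCfg$permutations %||% 999L,
                  seed = rdaCfg$seed %||% 1L))
    names(res) <- modes
    res
  })
  for (md in modes) {
    utils::write.table(rdaRes[[md]]$outliers,
                       file.path(outDir, paste0("rda_", md, "_outliers.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rdaRes[[md]]$manhattan,
                       file.path(outDir, paste0("rda_", md, "_manhattan.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    r <- rdaRes[[md]]$rda
    jsonlite::write_json(
      list(eigenvalues = r@eigenvalues, proportions = r@proportions,
           r2 = r@r2, adjR2 = r@adjR2, pseudoF = r@pseudoF, permP = r@permP),
      file.path(outDir, paste0("rda_", md, ".json")),
      auto_unbox = TRUE, digits = NA)
  }

  annotation <- NULL
  if (!is.null(config$annotation)) {
    annotation <- .stage("annotate", manifest, {
      genes <- readGeneIntervals(config$annotation)
      lapply(scans, function(layerRes)
        lapply(layerRes, function(res)
          mapWindowsToGenes(res$fst, genes)))
    })
  } else manifest$stages$annotate <- list(skipped = TRUE)

  summaryTab <- .stage("summarize", manifest, {
    do.call(rbind, lapply(names(scans), function(nm)
      cbind(layer = nm, summarizeContrasts(scans[[nm]]))))
  })
  utils::write.table(summaryTab, file.path(outDir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(list(panel = panel, frame = frame, qcReport = qcRes$report,
                 scans = scans, rda = rdaRes, annotation = annotation,
                 summary = summaryTab, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
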