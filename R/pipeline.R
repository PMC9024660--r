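#' Configuration of an end-to-end pipeline run
#'
#' Either a simulator [cohortConfig()] or paths to real inputs (delimited
#' time-series or connectome matrices plus a subject table), never both.
#' Defaults follow the analysis conventions used throughout the package:
#' 10% proportional threshold density, a gamma grid from 0.3 to 5.0 in steps
#' of 0.1, 1000 consensus repetitions and an FDR level of 0.05.
#'
#' @param simConfig a [cohortConfig()], or NULL when real inputs are given.
#' @param timeseriesPaths,connectomePaths,subjectTablePath real-input paths
#'   (per-subject delimited matrices; a subject CSV with item columns).
#' @param nodeRegistry node registry data.frame (defaults to
#'   [makeNodeRegistry()] scaled to the node count).
#' @param density proportional threshold density.
#' @param gammas structural-resolution grid.
#' @param consensusReps consensus clustering restarts.
#' @param fdrQ FDR significance level used when reporting discoveries.
#' @param metrics,traits families to model.
#' @param connectomeMode simulator connectome mode
#'   ([generateConnectome()]).
#' @param outDir directory for stage outputs and the run manifest
#'   (NULL = keep everything in memory only).
#' @param seed master seed.
#' @return classed list (`RunConfig`).
#' @export
runConfig <- function(simConfig = NULL, timeseriesPaths = NULL,
                      connectomePaths = NULL, subjectTablePath = NULL,
                      nodeRegistry = NULL, density = 0.10,
                      gammas = seq(0.3, 5.0, by = 0.1),
                      consensusReps = 1000L, fdrQ = 0.05,
                      metrics = c("degree", "betweenness", "closeness",
                                  "participation", "within_module_degree"),
                      traits = c("ve_t", "iu_t"),
                      connectomeMode = c("adjacency", "timeseries"),
                      outDir = NULL, seed = 1L) {
  real <- !is.null(timeseriesPaths) || !is.null(connectomePaths)
  if (is.null(simConfig) == !real)
    stop("supply exactly one of a simulator config or real input paths",
         call. = FALSE)
  if (real && is.null(subjectTablePath))
    stop("real inputs require a subject table", call. = FALSE)
  structure(list(simConfig = simConfig, timeseriesPaths = timeseriesPaths,
                 connectomePaths = connectomePaths,
                 subjectTablePath = subjectTablePath,
                 nodeRegistry = nodeRegistry, density = density,
                 gammas = gammas, consensusReps = as.integer(consensusReps),
                 fdrQ = fdrQ, metrics = metrics, traits = traits,
                 connectomeMode = match.arg(connectomeMode),
                 outDir = outDir, seed = as.integer(seed)),
            class = "RunConfig")
}

.stage <- function(name, log, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  log(sprintf("%s done in %.1fs", name,
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation or loading; connectome construction
#' (Fisher-z + proportional threshold for time-series inputs); the per-
#' subject gamma sweep of Louvain-with-fine-tuning partitions; per-gamma
#' agreement matrices, consensus partitions and the permutation module
#' screen; the five nodal metrics per subject under the consensus modules;
#' questionnaire scoring and descriptives; modularity-trait correlations;
#' and the mixed-effects association scan with FDR correction. For
#' simulated cohorts with a non-zero planted slope the planted effect is
#' injected into the metric table before modelling. All stage outputs,
#' seeds, and a JSON manifest are written when `outDir` is set.
#'
#' @param config a [runConfig()].
#' @param verbose print stage progress.
#' @return list: `cohort`, `connectomes`, `sweeps`, `qTable`,
#'   `consensus` (per gamma), `moduleScreen` (per gamma), `metricTable`,
#'   `descriptives`, `qTraitCor` (per trait), `scan` (association results),
#'   `manifest`.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "RunConfig"))
  log <- if (verbose) function(msg) message("[connectopy] ", msg)
  else function(msg) invisible(NULL)
  simulated <- !is.null(config$simConfig)
  outDir <- config$outDir
  if (!is.null(outDir)) dir.create(outDir, recursive = TRUE,
                                   showWarnings = FALSE)

  cohort <- .stage("cohort", log, {
    if (simulated) generateCohort(config$simConfig)
    else scoreCohort(readSubjectTable(config$subjectTablePath))
  })
  sids <- cohort$subject_id

  connectomes <- .stage("connectomes", log, {
    if (simulated) {
      lapply(seq_along(sids), function(i)
        generateConnectome(config$simConfig, i,
                           mode = config$connectomeMode,
                           density = config$density))
    } else if (!is.null(config$timeseriesPaths)) {
      lapply(config$timeseriesPaths, function(p)
        proportionalThreshold(fisherZConnectome(readTimeSeries(p)),
                              density = config$density))
    } else {
      lapply(config$connectomePaths, function(p)
        proportionalThreshold(readConnectome(p), density = config$density))
    }
  })
  names(connectomes) <- sids

  sweepSeeds <- spawnSeeds(config$seed, length(sids))
  sweeps <- .stage("gamma sweep", log, {
    out <- Map(function(conn, s)
      gammaSweep(connValues(conn), gammas = config$gammas, seed = s),
      connectomes, sweepSeeds)
    names(out) <- sids
    out
  })
  qTable <- modularityTable(sweeps)

  consSeeds <- spawnSeeds(config$seed + 1L, length(config$gammas))
  gkeys <- names(sweeps[[1]])
  consensus <- .stage("consensus", log, {
    out <- lapply(seq_along(gkeys), function(gi) {
      parts <- lapply(sweeps, `[[`, gi)
      consensusPartition(agreementMatrix(parts),
                         reps = config$consensusReps,
                         seed = consSeeds[gi],
                         gamma = config$gammas[gi])
    })
    names(out) <- gkeys
    out
  })

  screenSeeds <- spawnSeeds(config$seed + 2L, length(gkeys))
  moduleScreen <- .stage("module screen", log, {
    out <- lapply(seq_along(gkeys), function(gi)
      moduleSignificance(consensus[[gi]],
                         lapply(sweeps, `[[`, gi),
                         seed = screenSeeds[gi]))
    names(out) <- gkeys
    out
  })

  metricTable <- .stage("nodal metrics", log, {
    do.call(rbind, lapply(seq_along(gkeys), function(gi) {
      part <- consensus[[gi]]
      do.call(rbind, lapply(sids, function(sid)
        nodalMetrics(connectomes[[sid]], part, subject_id = sid,
                     gamma = config$gammas[gi])))
    }))
  })

  if (simulated && config$simConfig$planted_beta != 0) {
    metricTable <- .stage("plant effect", log,
                          plantEffect(metricTable, cohort,
                                      config$simConfig))
  }

  descriptives <- .stage("behavioral descriptives", log,
                         behavioralDescriptives(cohort))

  qTraitCor <- .stage("modularity-trait correlation", log, {
    lapply(stats::setNames(config$traits, config$traits), function(tr)
      modularityTraitCorrelation(
        qTable, stats::setNames(cohort[[tr]], cohort$subject_id)))
  })

  scan <- .stage("association scan", log, {
    modulesByGamma <- lapply(stats::setNames(gkeys, gkeys), function(g) {
      cons <- moduleAssignment(consensus[[g]])
      keep <- moduleScreen[[g]]
      mods <- keep$module[keep$keep & keep$size >= 2]
      lapply(mods, function(s) which(cons == s) - 1L)
    })
    associationScan(metricTable, cohort, modulesByGamma,
                    metrics = config$metrics, traits = config$traits)
  })

  manifest <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("connectopy")),
    seed = config$seed,
    subject_sweep_seeds = sweepSeeds,
    consensus_seeds = consSeeds,
    density = config$density, gammas = config$gammas,
    consensus_reps = config$consensusReps, fdr_q = config$fdrQ,
    simulated = simulated,
    sim_config = if (simulated) unclass(config$simConfig))

  if (!is.null(outDir)) {
    writeSubjectTable(cohort, file.path(outDir, "subjects.csv"))
    utils::write.csv(qTable, file.path(outDir, "modularity.csv"),
                     row.names = FALSE)
    writeMetricTable(metricTable, file.path(outDir, "metrics.csv"))
    for (g in gkeys)
      writePartition(consensus[[g]],
                     file.path(outDir, sprintf("consensus_gamma%s.csv", g)))
    writeAssociationTable(scan, file.path(outDir, "associations.csv"))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    log(paste("outputs written to", outDir))
  }

  list(cohort = cohort, connectomes = connectomes, sweeps = sweeps,
       qTable = qTable, consensus = consensus,
       moduleScreen = moduleScreen, metricTable = metricTable,
       descriptives = descriptives, qTraitCor = qTraitCor, scan = scan,
       manifest = manifest)
}
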