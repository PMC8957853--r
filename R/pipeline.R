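#' Default pipeline configuration
#'
#' Full set of defaults for \code{\link{runPipeline}}: the 10-subject
#' synthetic cohort, 20 um sectioning with every 15th section sampled
#' (300 um spacing), Cavalieri volumetry on normalized proportions, the
#' three permutation contrasts at 10^4 iterations (the paper-scale 10^6 is a
#' config change away), a 1 mm reference grid, and mesh extraction with 10
#' smoothing iterations at step 0.1.
#'
#' @return A nested list of class `PipelineConfig`.
#' @export
defaultPipelineConfig <- function() {
  cfg <- list(
    cohort = list(n_subjects = 10L, volume_cv = 0.25,
      position_jitter_sd = 1.0, rotation_jitter_sd = 2.0,
      scale_jitter_sd = 0.02, voxel_size = 0.5, seed = 20L),
    sectioning = list(thickness = 0.020, interval = 15L,
      offset_policy = "random", seed = 21L),
    volumetry = list(normalization = "proportion"),
    stats = list(n_iter = 10000L, seed = 22L, sided = "two"),
    probmap = list(grid_dim = c(80L, 50L, 40L),
      grid_origin = c(-40, -45, -25), voxel_size = 1, threshold = 0),
    mesh = list(smooth_iter = 10L, smooth_step = 0.1)
  )
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of
#' \code{\link{defaultPipelineConfig}}; everything else keeps its default.
#'
#' @param path YAML file path.
#' @return A `PipelineConfig` list.
#' @export
loadPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultPipelineConfig()
  for (sec in names(user)) {
    if (!sec %in% names(cfg)) stop("unknown config section: ", sec)
    for (k in names(user[[sec]])) cfg[[sec]][[k]] <- user[[sec]][[k]]
  }
  cfg
}

pipelineLog <- function(stage, msg) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> section -> volumetry -> stats -> probability
#' maps -> meshes from a single configuration and writes all artifacts plus
#' a manifest (file list with MD5 content hashes) under `outputDir`.  The
#' run is deterministic given the seeds in the configuration.  With
#' `resume = TRUE`, stages whose output files already exist are skipped.
#'
#' @param config a `PipelineConfig` (see \code{\link{defaultPipelineConfig}})
#'   or the path to a YAML file.
#' @param outputDir output directory.
#' @param resume skip stages whose outputs exist?
#' @return The manifest, invisibly: a data.frame of `file` and `md5`.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outputDir,
                        resume = FALSE) {
  if (is.character(config)) config <- loadPipelineConfig(config)
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("cohort", "volumes", "stats", "probmaps", "meshes"))
    dir.create(file.path(outputDir, d), showWarnings = FALSE)

  ## ---- stage 1: synthetic cohort -------------------------------------
  cc <- config$cohort
  spec <- cohortSpec(nSubjects = cc$n_subjects, volumeCv = cc$volume_cv,
    positionJitterSd = cc$position_jitter_sd,
    rotationJitterSd = cc$rotation_jitter_sd,
    scaleJitterSd = cc$scale_jitter_sd, voxelSize = cc$voxel_size,
    seed = cc$seed)
  pipelineLog("cohort", sprintf("generating %d subjects (seed %d)",
                                spec$nSubjects, spec$seed))
  cohort <- tryCatch(generateCohort(spec),
    error = function(e) stop("stage cohort: ", conditionMessage(e)))
  writeCohort(cohort, file.path(outputDir, "cohort"))

  ## ---- stage 2: sectioning + volumetry -------------------------------
  volFile <- file.path(outputDir, "volumes", "volumes.csv")
  if (resume && file.exists(volFile)) {
    pipelineLog("volumetry", "resuming from existing volumes.csv")
    volumes <- utils::read.csv(volFile, stringsAsFactors = FALSE)
  } else {
    sc <- config$sectioning
    pipelineLog("volumetry", sprintf(
      "Cavalieri volumetry (T = %g mm, k = %d)", sc$thickness, sc$interval))
    volumes <- tryCatch(
      cohortVolumetry(cohort, thickness = sc$thickness,
                      interval = sc$interval, seed = sc$seed),
      error = function(e) stop("stage volumetry: ", conditionMessage(e)))
    utils::write.csv(volumes, volFile, row.names = FALSE)
  }

  ## ---- stage 3: group statistics -------------------------------------
  st <- config$stats
  labMap <- structureLabels(cohort)
  subdiv <- setdiff(names(labMap), "LGB")
  ## per-nucleus tables: MGB = sum of its subdivisions
  mgb <- volumes[volumes$structure %in% subdiv, ]
  mgbAgg <- aggregateVolumes(mgb, by = c("subject_id", "sex", "hemisphere",
                                         "method"))
  mgbAgg$structure <- "MGB"
  lgb <- volumes[volumes$structure == "LGB", ]
  statsOut <- list()
  for (nm in c("MGB", "LGB")) {
    tab <- if (nm == "MGB") mgbAgg else lgb
    pipelineLog("stats", sprintf("permutation contrasts for %s (n_iter %d)",
                                 nm, st$n_iter))
    res <- volumeContrasts(tab, nm, nIter = st$n_iter, seed = st$seed,
                           sided = st$sided)
    statsOut[[nm]] <- lapply(res, function(r)
      r[c("contrastName", "C_obs", "n_iter", "exceedance_rank", "p_value",
          "sided", "seed", "significant", "degenerate")])
    jsonlite::write_json(statsOut[[nm]],
      file.path(outputDir, "stats", paste0("permutation_", nm, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  ## paired t-test: bilateral MGB vs LGB corrected volumes per subject
  mgbBil <- aggregateVolumes(mgbAgg, by = "subject_id")
  lgbBil <- aggregateVolumes(lgb, by = "subject_id")
  stopifnot(identical(mgbBil$subject_id, lgbBil$subject_id))
  tt <- pairedTTest(mgbBil$V_corr_mm3, lgbBil$V_corr_mm3)
  jsonlite::write_json(unclass(tt),
    file.path(outputDir, "stats", "ttest_MGB_vs_LGB.json"),
    auto_unbox = TRUE, digits = NA)

  ## ---- stage 4: probability maps -------------------------------------
  pm <- config$probmap
  ref <- referenceGrid(pm$grid_dim, pm$grid_origin, pm$voxel_size)
  comRows <- list()
  for (nm in c("MGB", "LGB")) {
    mapFile <- file.path(outputDir, "probmaps", paste0(nm, "_probmap.nii.gz"))
    labs <- if (nm == "MGB") unname(labMap[subdiv]) else unname(labMap["LGB"])
    pipelineLog("probmap", paste("superimposing", nm))
    masks <- lapply(seq_len(spec$nSubjects), function(i)
      toReference(cohort$volumes[[i]], cohort$transforms[[i]], ref, labs))
    map <- computeProbabilityMap(masks, structure = nm)
    writeProbabilityMap(map, mapFile)
    for (h in c("left", "right")) {
      com <- centerOfMass(map, h)
      comRows[[paste(nm, h)]] <- data.frame(structure = nm, hemisphere = h,
        x = com["x"], y = com["y"], z = com["z"], row.names = NULL)
    }
  }
  comTab <- do.call(rbind, comRows)
  utils::write.csv(comTab, file.path(outputDir, "probmaps",
                                     "centers_of_mass.csv"),
                   row.names = FALSE)

  ## ---- stage 5: surface meshes ---------------------------------------
  me <- config$mesh
  vol1 <- cohort$volumes[[1]]
  f1 <- cohort$subjects$shrinkage_factor[1]
  meshRows <- list()
  for (nm in names(labMap)) {
    for (h in c("left", "right")) {
      hv <- hemisphereVolume(vol1, h)
      pipelineLog("mesh", paste("extracting", nm, h))
      msh <- tryCatch(
        smoothMesh(extractMesh(hv, labMap[[nm]]), nIter = me$smooth_iter,
                   step = me$smooth_step),
        error = function(e) stop("stage mesh (", nm, ", ", h, ", subject ",
                                 cohort$subjects$subject_id[1], "): ",
                                 conditionMessage(e)))
      mf <- file.path(outputDir, "meshes", paste0(nm, "_", h, ".obj"))
      writeOBJ(msh, mf)
      meshRows[[paste(nm, h)]] <- data.frame(structure = nm, hemisphere = h,
        volume_mm3 = meshVolume(msh),
        volume_corr_mm3 = meshVolume(msh) * f1, row.names = NULL)
    }
  }
  utils::write.csv(do.call(rbind, meshRows),
    file.path(outputDir, "meshes", "mesh_volumes.csv"), row.names = FALSE)

  ## ---- manifest -------------------------------------------------------
  files <- sort(list.files(outputDir, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  md5 <- unname(tools::md5sum(file.path(outputDir, files)))
  manifest <- data.frame(file = files, md5 = md5, stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  pipelineLog("done", sprintf("%d artifacts written", nrow(manifest)))
  invisible(manifest)
}
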