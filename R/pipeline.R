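# End-to-end orchestration: write a simulated study to disk, run the
# pipeline from a config, and the synthetic cohort lesion study.

#' Write a complete simulated study to a directory
#'
#' Simulates and writes every acquisition the pipeline consumes, pre-aligned:
#' the CEST dynamic series and its TSV schedule, the WASSR series and
#' schedule, the AFI pair, the 5-slice inversion-recovery series with its
#' TI list, per-slice binary tissue/lesion masks, and a ground-truth bundle
#' (label map, B0/B1 fields as NIfTI, settings as JSON).
#'
#' @param phantom a [PhantomTruth-class]
#' @param outDir output directory (created if needed)
#' @param schedule CEST [OffsetSchedule-class]
#' @param wassrSched WASSR [OffsetSchedule-class]
#' @param tiList inversion times, ms
#' @param afi list with `tr1`, `tr2`, `nominalFlip`
#' @return invisibly, a named list of the written paths
#' @export
simulateStudy <- function(phantom, outDir,
                          schedule = canonicalSchedule(),
                          wassrSched = wassrSchedule(),
                          tiList = canonicalTiList(),
                          afi = list(tr1 = 35, tr2 = 160, nominalFlip = 60)) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outDir, f)
  dyn <- simulateCestDynamics(phantom, schedule, seed = phantom@seed)
  RNifti::writeNifti(dyn, p("dynamics.nii"))
  writeSchedule(schedule, p("schedule.tsv"))
  was <- simulateWassr(phantom, wassrSched, seed = phantom@seed + 1L)
  RNifti::writeNifti(was, p("wassr.nii"))
  writeSchedule(wassrSched, p("wassr_schedule.tsv"))
  afiPair <- simulateAfiPair(phantom, afi$tr1, afi$tr2, afi$nominalFlip,
                             seed = phantom@seed + 3L)
  RNifti::writeNifti(afiPair$s1, p("afi_s1.nii"))
  RNifti::writeNifti(afiPair$s2, p("afi_s2.nii"))
  ir <- simulateIrSeries(phantom, tiList, seed = phantom@seed + 2L)
  RNifti::writeNifti(ir$series, p("ir.nii"))
  jsonlite::write_json(tiList, p("ti.json"), auto_unbox = FALSE, digits = NA)
  labs <- vapply(phantom@tissues, function(t) t@label, character(1))
  for (k in seq_along(labs)) {
    m <- (ir$labelMaps == k) * 1L
    storage.mode(m) <- "integer"
    RNifti::writeNifti(m, p(sprintf("mask_%s.nii", tolower(labs[k]))))
  }
  lm <- phantom@labelMap; storage.mode(lm) <- "integer"
  RNifti::writeNifti(lm, p("truth_labels.nii"))
  RNifti::writeNifti(phantom@b0Field, p("truth_b0.nii"))
  RNifti::writeNifti(phantom@b1Field, p("truth_b1.nii"))
  truth <- list(
    seed = phantom@seed, noiseSd = phantom@noiseSd,
    noiseModel = phantom@noiseModel, drift = phantom@drift,
    tissues = lapply(phantom@tissues, function(tc) list(
      label = tc@label, zBase = tc@zBase, r1 = tc@r1,
      pools = lapply(tc@pools, function(pp) list(
        name = pp@name, amplitude = pp@amplitude, width = pp@width,
        center = pp@center)))))
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(setNames(as.list(list.files(outDir, full.names = TRUE)),
                     list.files(outDir)))
}

.PIPELINE_KEYS <- c(
  "dynamics", "schedule", "wassr", "wassrSchedule", "afiS1", "afiS2",
  "afiTr1", "afiTr2", "afiNominalFlip", "irSeries", "tiList", "masks",
  "outDir", "targetOffset", "variant", "fitZBase", "seed", "bgFraction")

#' Validate a pipeline configuration
#'
#' Checks key names against the known set, the presence of the mandatory
#' inputs, and that every referenced file exists. Returns the config with
#' defaults filled in.
#'
#' @param config named list (or path to a YAML/JSON file)
#' @return validated config list
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(config), .PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  for (key in c("dynamics", "schedule", "outDir"))
    if (is.null(config[[key]])) stop("config is missing required key: ", key)
  defaults <- list(targetOffset = 3.0, variant = "z_space_subtraction",
                   fitZBase = FALSE, seed = 1L, bgFraction = 0.05,
                   afiTr1 = 35, afiTr2 = 160, afiNominalFlip = 60)
  config <- modifyList(defaults, config)
  paths <- c(config$dynamics, config$schedule, config$wassr,
             config$wassrSchedule, config$afiS1, config$afiS2,
             config$irSeries,
             if (is.character(config$tiList)) config$tiList,
             unlist(config$masks))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  config
}

#' Run the full quantification pipeline
#'
#' Executes assemble, B0 map + recentring (when WASSR inputs are present),
#' B1 map (when AFI inputs are present), the two-pool MT fit, R1 mapping
#' with slice collapsing, contrast computation and ROI summaries, writing
#' every map as NIfTI plus a provenance JSON (parameters, stage list, input
#' MD5 hashes) into `config$outDir`. Any stage failure halts with the stage
#' name; in particular a missing inversion-recovery input stops the run
#' before the contrast stage.
#'
#' @param config named list or path, see [validateConfig()]
#' @return invisibly, the result bundle: `zstack`, `b0`, `b1`, `fits`,
#'   `r1`, `contrasts`, `roiTable`, `provenance`
#' @export
runPipeline <- function(config) {
  config <- validateConfig(config)
  out <- config$outDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message("[arexcest] stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  zstack <- stage("assemble", {
    dyn <- RNifti::readNifti(config$dynamics)
    driftCorrectNormalize(unclass(dyn)[, , , drop = FALSE],
                          readSchedule(config$schedule),
                          bgFraction = config$bgFraction)
  })

  b0 <- NULL
  if (!is.null(config$wassr)) {
    b0 <- stage("b0map", {
      was <- RNifti::readNifti(config$wassr)
      wst <- driftCorrectNormalize(unclass(was)[, , , drop = FALSE],
                                   readSchedule(config$wassrSchedule),
                                   bgFraction = config$bgFraction)
      fitWassrB0(wst)
    })
    zstack <- stage("recenter", recenterSpectra(zstack, b0))
  }

  b1 <- NULL
  if (!is.null(config$afiS1)) {
    b1 <- stage("b1map", computeAfiB1(
      drop(unclass(RNifti::readNifti(config$afiS1))),
      drop(unclass(RNifti::readNifti(config$afiS2))),
      config$afiTr1, config$afiTr2, config$afiNominalFlip))
  }

  fits <- stage("fit-mt",
    fitTwoPoolStack(zstack, defaultFitBounds(), fitZBase = config$fitZBase))

  r1 <- stage("r1map", {
    if (is.null(config$irSeries))
      stop("missing inversion-recovery input (irSeries); cannot form the ",
           "R1 map required by the AREX contrast")
    ti <- if (is.character(config$tiList))
      unlist(jsonlite::read_json(config$tiList, simplifyVector = TRUE))
      else config$tiList
    ser <- unclass(RNifti::readNifti(config$irSeries))
    nSl <- dim(ser)[3]
    slices <- array(NA_real_, dim(ser)[c(1, 2, 3)])
    for (s in seq_len(nSl)) {
      m <- fitIrR1(ser[, , s, ], ti, mask = zstack@mask)
      v <- m@r1; v[!m@mask] <- NA_real_
      slices[, , s] <- v
    }
    collapsed <- collapseSlicesMean(slices)
    ok <- is.finite(collapsed) & collapsed > 0
    new("R1Map", r1 = collapsed, m0 = collapsed * NA, invEfficiency =
          collapsed * NA, residRms = collapsed * NA, mask = ok)
  })

  contrasts <- stage("contrast",
    computeContrastMaps(zstack, fits, r1, config$targetOffset,
                        config$variant))

  roiTable <- NULL
  if (!is.null(config$masks)) {
    roiTable <- stage("roi-stats", {
      lesionNames <- intersect(names(config$masks),
                               c("wm_lesion", "cortical_lesion"))
      stacks <- lapply(config$masks, function(f)
        unclass(RNifti::readNifti(f)) != 0)
      lesionCollapsed <- Reduce(`|`, lapply(lesionNames, function(nm)
        collapseMasks(stacks[[nm]],
                      k = if (nm == "cortical_lesion") 1L else 2L)),
        accumulate = FALSE,
        init = matrix(FALSE, zstack@dims[1], zstack@dims[2]))
      rows <- lapply(names(stacks), function(nm) {
        k <- if (nm == "cortical_lesion") 1L else 2L
        excl <- if (nm %in% lesionNames) NULL else lesionCollapsed
        m <- collapseMasks(stacks[[nm]], k = k, exclude = excl)
        sm <- roiSummary(arexCorr(contrasts), m & contrasts@mask, label = nm)
        data.frame(roi = nm, n_voxels = sm$nVoxels, mean_arex = sm$mean,
                   median_arex = sm$median)
      })
      do.call(rbind, rows)
    })
    write.table(roiTable, file.path(out, "roi_summary.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }

  stage("write-maps", {
    wr <- function(m, f) RNifti::writeNifti(m, file.path(out, f))
    wr(mtrAsymCorr(contrasts), "mtr_asym_corr.nii")
    wr(mtrRexCorr(contrasts), "mtr_rex_corr.nii")
    wr(arexCorr(contrasts), "arex_corr.nii")
    wr(legacyGlucestMap(contrasts), "legacy_glucest.nii")
    wr(r1Values(r1), "r1.nii")
    if (!is.null(b0)) wr(b0Shift(b0), "b0_shift.nii")
    if (!is.null(b1)) wr(relativeFlip(b1), "b1_relative_flip.nii")
    fp <- fits@params
    for (nm in colnames(fp))
      wr(matrix(fp[, nm], zstack@dims[1], zstack@dims[2]),
         sprintf("fit_%s.nii", nm))
  })

  inputs <- c(config$dynamics, config$schedule, config$wassr,
              config$wassrSchedule, config$afiS1, config$afiS2,
              config$irSeries, unlist(config$masks))
  provenance <- list(
    package = "arexcest",
    version = as.character(utils::packageVersion("arexcest")),
    stages = c("assemble", if (!is.null(b0)) c("b0map", "recenter"),
               if (!is.null(b1)) "b1map", "fit-mt", "r1map", "contrast",
               if (!is.null(roiTable)) "roi-stats"),
    parameters = config[c("targetOffset", "variant", "fitZBase",
                          "bgFraction", "seed")],
    zspec_provenance = zstack@provenance,
    input_md5 = as.list(tools::md5sum(inputs)))
  jsonlite::write_json(provenance, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(zstack = zstack, b0 = b0, b1 = b1, fits = fits, r1 = r1,
                 contrasts = contrasts, roiTable = roiTable,
                 provenance = provenance))
}
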