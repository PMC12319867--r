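#' Process a breath-hold physiology recording end to end
#'
#' The full trace-processing chain: end-tidal peak detection and
#' interpolation, respiration extrema and RVT, per-trial CO2 changes and
#' quality grading (mean - 1 SD rule), downsampling to the 10 Hz working
#' grid, negative-cross-correlation alignment of P_ET_CO2 to RVT (with
#' trimming to common support), z-normalization, and breath-hold block
#' construction.
#'
#' @param co2 raw CO2 [PhysioTrace-class] in mmHg (use [voltsToMmHg()]
#'   first if needed).
#' @param resp respiration-effort [PhysioTrace-class].
#' @param timing [taskTiming()] table.
#' @param fsWork working sampling rate, Hz, default 10.
#' @param maxShift alignment shift bound, s, default 30.
#' @param minProminence,minSeparation end-tidal peak detection settings.
#' @param pairWindow post-hold peak search window for [trialDeltas()], s;
#'   robust to capnograph measurement delays up to about this size.
#' @param peakEdits optional peak-edit JSON path (see [applyPeakEdits()]).
#' @param sdDenominator SD convention for [qualityThreshold()].
#' @return A list with elements `peaks`, `deltas`, `threshold`, `labels`,
#'   `petco2` / `rvt` (aligned mmHg / arbitrary traces at `fsWork`),
#'   `petco2Z` / `rvtZ` (z-normalized), `blocks`, `shift`
#'   ([ShiftResult-class]) and `qc` (report data.frame).
#' @export
processPhysio <- function(co2, resp, timing, fsWork = 10, maxShift = 30,
                          minProminence = 5, minSeparation = 2,
                          pairWindow = 30, peakEdits = NULL,
                          sdDenominator = "n-1") {
  peaks <- detectEndtidalPeaks(co2, minProminence, minSeparation)
  if (!is.null(peakEdits)) peaks <- applyPeakEdits(peaks, peakEdits)
  petco2_raw <- interpolateEndtidal(co2, peaks)
  ext <- detectRespExtrema(resp, timing)
  rvt_raw <- computeRvt(resp, ext$maxima, ext$minima)

  deltas <- trialDeltas(co2, peaks, timing, window = pairWindow)
  threshold <- qualityThreshold(deltas$delta, sdDenominator)
  labels <- classifyTrials(deltas, threshold)

  petco2_10 <- resampleTrace(petco2_raw, fsWork)
  rvt_10 <- resampleTrace(rvt_raw, fsWork)
  n <- min(nSamples(petco2_10), nSamples(rvt_10))
  petco2_10@samples <- petco2_10@samples[seq_len(n)]
  rvt_10@samples <- rvt_10@samples[seq_len(n)]

  shift <- bestNegativeShift(petco2_10, rvt_10, maxShift)
  pair <- applyShift(petco2_10, rvt_10, shift)

  blocks <- buildBlocks(timing, labels, pair$a, deltas$delta)
  list(
    peaks = peaks, deltas = deltas, threshold = threshold, labels = labels,
    petco2 = pair$a, rvt = pair$b,
    petco2Z = znorm(pair$a), rvtZ = znorm(pair$b),
    blocks = blocks, shift = shift,
    qc = qcReport(deltas, threshold, labels)
  )
}

#' Generate synthetic training segments for the FCN
#'
#' Simulates `nRecordings` breath-hold sessions (with occasional
#' low-quality trials), runs the full [processPhysio()] pipeline on each,
#' and cuts the aligned, z-normalized traces into training segments of
#' consecutive high-quality breath-hold blocks.
#'
#' @param nRecordings number of simulated recordings, default 14.
#' @param nSubjects number of distinct subject IDs cycled over, default 8.
#' @param seed integer seed; each recording derives its own sub-seed.
#' @param lowQualityProb per-trial chance of an attenuated post-hold
#'   exhale, default 0.08.
#' @param ... further arguments to [synthSpec()].
#' @return A list: `segments` (list of [trainingSegment()]) and
#'   `recordings` (per-recording list with `rvtZ`, `petco2Z`,
#'   `subjectId`, and the pipeline result `proc`).
#' @export
synthTrainingSegments <- function(nRecordings = 14L, nSubjects = 8L, seed = 1L,
                                  lowQualityProb = 0.08, ...) {
  segments <- list()
  recordings <- list()
  for (i in seq_len(nRecordings)) {
    rec_seed <- seed + 7919L * i
    nt <- 8L
    low <- .withSeed(rec_seed, which(stats::runif(nt) < lowQualityProb))
    spec <- synthSpec(
      nTrials = nt, lowQualityTrials = low,
      seed = rec_seed + 1L, ...
    )
    sim <- genPhysio(spec)
    proc <- processPhysio(sim$co2, sim$resp, sim$timing)
    subj <- sprintf("S%02d", ((i - 1) %% nSubjects) + 1)
    n <- nSamples(proc$petco2Z)
    segs <- segmentForTraining(proc$blocks, seed = rec_seed + 2L)
    for (sg in segs) {
      lo <- min(sg$start_sample)
      hi <- min(max(sg$end_sample), n)
      if (hi - lo < 100) next
      segments[[length(segments) + 1]] <- trainingSegment(
        samples(proc$rvtZ)[lo:hi], samples(proc$petco2Z)[lo:hi], subj
      )
    }
    recordings[[i]] <- list(
      rvtZ = proc$rvtZ, petco2Z = proc$petco2Z,
      subjectId = subj, proc = proc, truth = sim$truth
    )
  }
  list(segments = segments, recordings = recordings)
}

#' Write a complete synthetic session to disk
#'
#' Generates a physiology session and (optionally) a BOLD phantom and
#' writes everything as BIDS-style physio TSVs with JSON sidecars, a
#' timing TSV, NIfTI volumes and ground-truth maps, so the command-line
#' workflow can run end to end from files.
#'
#' @param dir output directory.
#' @param spec a [synthSpec()].
#' @param phantom optional [phantomSpec()]; NULL skips the BOLD phantom.
#' @return Invisibly, the list of written paths.
#' @export
simulateSession <- function(dir, spec = synthSpec(), phantom = phantomSpec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- genPhysio(spec)
  paths <- list(
    co2 = file.path(dir, "co2.tsv"),
    resp = file.path(dir, "resp.tsv"),
    timing = file.path(dir, "timing.tsv"),
    petco2_ideal = file.path(dir, "petco2_ideal.tsv")
  )
  writePhysio(sim$co2, paths$co2, column = "co2")
  writePhysio(sim$resp, paths$resp, column = "respiration")
  writeTaskTiming(sim$timing, paths$timing)
  writePhysio(sim$truth$petco2Ideal, paths$petco2_ideal, column = "petco2")
  truth <- list(
    deltas = sim$truth$deltas, labels = sim$truth$labels,
    threshold = sim$truth$threshold,
    measurementDelay = sim$truth$measurementDelay
  )
  if (!is.null(phantom)) {
    ph <- genPhantom(phantom, sim$truth$petco2Ideal)
    paths$bold <- file.path(dir, "bold.nii.gz")
    paths$mask <- file.path(dir, "mask.nii.gz")
    paths$gm <- file.path(dir, "gm_mask.nii.gz")
    paths$amp_truth <- file.path(dir, "amplitude_truth.nii.gz")
    paths$delay_truth <- file.path(dir, "delay_truth.nii.gz")
    pd <- c(3, 3, 3, phantom$TR)
    writeVolume(ph$bold, paths$bold, pd)
    writeVolume(ph$mask + 0, paths$mask)
    writeVolume(ph$gmMask + 0, paths$gm)
    writeVolume(ph$truth$amplitude, paths$amp_truth)
    writeVolume(ph$truth$delay, paths$delay_truth)
    truth$TR <- phantom$TR
  }
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}

#' File-level command implementations
#'
#' Thin wrappers used by the shipped command-line script: each reads its
#' inputs from disk, calls the corresponding package functions, and writes
#' results beside a resolved-parameter JSON so every run is reproducible
#' from its outputs.
#'
#' @param co2Path,respPath,timingPath input file paths (TSV + sidecars).
#' @param outDir output directory.
#' @param ... further arguments to [processPhysio()].
#' @return The [processPhysio()] result, invisibly.
#' @export
cmdProcessPhysio <- function(co2Path, respPath, timingPath, outDir, ...) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  co2 <- readPhysio(co2Path, units = "mmHg")
  resp <- readPhysio(respPath)
  timing <- readTaskTiming(timingPath)
  proc <- processPhysio(co2, resp, timing, ...)
  writePhysio(proc$petco2, file.path(outDir, "petco2_10hz.tsv"), column = "petco2")
  writePhysio(proc$rvt, file.path(outDir, "rvt_10hz.tsv"), column = "rvt")
  writePhysio(proc$petco2Z, file.path(outDir, "petco2_z.tsv"), column = "petco2_z")
  writePhysio(proc$rvtZ, file.path(outDir, "rvt_z.tsv"), column = "rvt_z")
  utils::write.table(proc$qc, file.path(outDir, "qc_report.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  utils::write.table(proc$blocks, file.path(outDir, "blocks.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  jsonlite::write_json(
    list(
      shift_s = proc$shift@shift, shift_score = proc$shift@score,
      shift_clipped = proc$shift@clipped, threshold_mmHg = proc$threshold
    ),
    file.path(outDir, "alignment.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(proc)
}

#' @rdname cmdProcessPhysio
#' @param modelPath FCN checkpoint path (see [saveFcnModel()]).
#' @param rvtPath z-normalized RVT TSV path.
#' @param subjectId subject identifier.
#' @param outPath output TSV path for the predicted trace.
#' @export
cmdPredict <- function(modelPath, rvtPath, subjectId, outPath) {
  model <- loadFcnModel(modelPath)
  rvt <- readPhysio(rvtPath, units = "zscore")
  pred <- fcnPredict(model, rvt, subjectId)
  writePhysio(pred, outPath, column = "predicted_petco2")
  invisible(pred)
}

#' @rdname cmdProcessPhysio
#' @param boldPath,maskPath,gmPath NIfTI input paths.
#' @param regressorPath regressor TSV path (mmHg, unconvolved; the
#'   response function is chosen from the sidecar provenance: RVT gets the
#'   RRF, anything end-tidal the HRF).
#' @param TR repetition time, s.
#' @param config a [cvrConfig()].
#' @param allowArbitraryUnits forwarded to [mapCvr()].
#' @export
cmdMapCvr <- function(boldPath, maskPath, gmPath, regressorPath, outDir,
                      TR, config = cvrConfig(), allowArbitraryUnits = FALSE) {
  bold <- readVolume(boldPath)
  mask <- readVolume(maskPath) > 0
  gm <- readVolume(gmPath) > 0
  reg <- readPhysio(regressorPath, units = "mmHg")
  kernel <- if (grepl("rvt", reg@provenance, ignore.case = TRUE)) {
    rrf(reg@fs)
  } else {
    hrf(reg@fs)
  }
  reg <- convolveTrace(reg, kernel)
  maps <- mapCvr(bold, mask, gm, reg, config, TR,
    allowArbitraryUnits = allowArbitraryUnits
  )
  writeCvrMaps(maps, outDir, provenance = reg@provenance)
  invisible(maps)
}
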