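#' Configuration of the lagged-GLM CVR fit
#'
#' The lag grid runs from `-maxLag` to `+maxLag` in steps of `lagStep`
#' (default +/-9 s at 0.3 s: 61 shifted regressors). `pathology = TRUE`
#' switches to the clinical setting: +/-15 s and no boundary thresholding,
#' so regions with extremely long delays (e.g. steno-occlusive disease)
#' are retained rather than discarded at the grid edges.
#'
#' @param maxLag maximum voxelwise lag magnitude, s.
#' @param lagStep lag grid step, s.
#' @param boundaryThreshold drop voxels whose selected lag falls in the two
#'   outermost steps on either side of the grid.
#' @param polyOrder Legendre nuisance polynomial order, default 4.
#' @param bulkAlignBound bound on the global bulk shift, s, default 30.
#' @param pathology convenience switch for the clinical setting.
#' @return A classed list (`"CvrConfig"`).
#' @export
cvrConfig <- function(maxLag = 9, lagStep = 0.3, boundaryThreshold = TRUE,
                      polyOrder = 4L, bulkAlignBound = 30, pathology = FALSE) {
  if (pathology) {
    maxLag <- 15
    boundaryThreshold <- FALSE
  }
  steps <- maxLag / lagStep
  if (abs(steps - round(steps)) > 1e-9) stop("maxLag must be a multiple of lagStep")
  structure(
    list(
      maxLag = maxLag, lagStep = lagStep,
      boundaryThreshold = boundaryThreshold, polyOrder = as.integer(polyOrder),
      bulkAlignBound = bulkAlignBound
    ),
    class = "CvrConfig"
  )
}

# Legendre polynomials P_0..P_order evaluated on n points over [-1, 1].
.legendreBasis <- function(n, order) {
  x <- seq(-1, 1, length.out = n)
  P <- matrix(0, n, order + 1)
  P[, 1] <- 1
  if (order >= 1) P[, 2] <- x
  if (order >= 2) {
    for (k in 2:order) {
      P[, k + 1] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1]) / k
    }
  }
  P
}

#' Convert a BOLD series to percent signal change
#'
#' `y' = 100 * (y - mean(y)) / mean(y)` per voxel, so regression betas
#' against a mmHg regressor are in %BOLD/mmHg. Voxels with non-positive
#' temporal mean inside the mask are excluded and the mask updated.
#'
#' @param bold 4D numeric array (x, y, z, t).
#' @param mask 3D logical array of voxels to analyze.
#' @return A list: `psc` (4D array, zero outside the mask) and `mask`
#'   (possibly reduced).
#' @export
percentSignalChange <- function(bold, mask = NULL) {
  d <- dim(bold)
  stopifnot(length(d) == 4)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  nvox <- prod(d[1:3])
  Y <- matrix(bold, nvox, d[4]) # voxels x time
  mu <- rowMeans(Y)
  ok <- as.vector(mask) & mu > 0
  psc <- matrix(0, nvox, d[4])
  psc[ok, ] <- 100 * (Y[ok, , drop = FALSE] - mu[ok]) / mu[ok]
  list(
    psc = array(psc, d),
    mask = array(ok, d[1:3])
  )
}

#' Globally align a regressor to the mean gray-matter BOLD signal
#'
#' Finds the single shift (on the lag-grid step, within `+/-bound`)
#' maximizing the Pearson correlation between the shifted regressor
#' (resampled to the TR grid) and the mean gray-matter percent-signal-
#' change timeseries. Applied before voxelwise fitting so the voxel lags
#' are relative offsets around a sensible global latency.
#'
#' @param regressor [PhysioTrace-class] at 10 Hz (or finer).
#' @param gmMean numeric vector: mean GM percent-signal-change per volume.
#' @param TR repetition time, s.
#' @param bound shift bound, s, default 30.
#' @param step shift grid step, s, default 0.3.
#' @return A [ShiftResult-class].
#' @export
bulkAlign <- function(regressor, gmMean, TR, bound = 30, step = 0.3) {
  stopifnot(is(regressor, "PhysioTrace"))
  if (stats::sd(gmMean) == 0) stop("bulkAlign: constant gray-matter signal")
  if (stats::sd(regressor@samples) == 0) stop("bulkAlign: constant regressor")
  tvol <- (seq_along(gmMean) - 1) * TR
  tt <- traceTimes(regressor)
  shifts <- seq(-bound, bound, by = step)
  r <- vapply(shifts, function(s) {
    x <- stats::approx(tt, regressor@samples, xout = tvol - s, rule = 2)$y
    if (stats::sd(x) == 0) return(NA_real_)
    stats::cor(x, gmMean)
  }, numeric(1))
  best <- which.max(r)
  new("ShiftResult",
    shift = shifts[best], score = r[best],
    clipped = best %in% c(1L, length(shifts))
  )
}

#' Build the family of lag-shifted regressors
#'
#' One column per lag in `{-maxLag, ..., 0, ..., +maxLag}` (step
#' `lagStep`): the regressor delayed by `bulkShift + lag` seconds and then
#' resampled onto the TR grid. A positive lag means the column is a later
#' (delayed) copy, matching voxels that respond later. Values outside the
#' regressor support are edge-padded (with a warning).
#'
#' @param regressor [PhysioTrace-class] at 10 Hz or finer.
#' @param config a [cvrConfig()].
#' @param TR repetition time, s.
#' @param nVolumes number of volumes.
#' @param bulkShift global shift added to every lag, s.
#' @return A list: `family` (nVolumes x nLags matrix) and `lags` (s).
#' @export
lagFamily <- function(regressor, config, TR, nVolumes, bulkShift = 0) {
  stopifnot(is(regressor, "PhysioTrace"))
  lags <- seq(-config$maxLag, config$maxLag, by = config$lagStep)
  tvol <- (seq_len(nVolumes) - 1) * TR
  tt <- traceTimes(regressor)
  need <- range(c(tvol - bulkShift - max(lags), tvol - bulkShift - min(lags)))
  if (need[1] < tt[1] - 1e-9 || need[2] > tt[length(tt)] + 1e-9) {
    warning("lagFamily: regressor shorter than scan span + max lag; edge-padding")
  }
  fam <- vapply(lags, function(l) {
    stats::approx(tt, regressor@samples, xout = tvol - bulkShift - l, rule = 2)$y
  }, numeric(nVolumes))
  list(family = fam, lags = lags)
}

# Core lagged-GLM engine. Y: (n x V) percent-signal-change; family:
# (n x L); nuisance: (n x p). Returns per-voxel beta at the R2-maximizing
# lag, the lag index, and the full-model R2. Ties in R2 go to the smallest
# |lag| (stability on flat profiles).
.lagFit <- function(Y, family, lags, nuisance) {
  qrN <- qr(nuisance)
  Qn <- qr.Q(qrN)
  Yr <- Y - Qn %*% crossprod(Qn, Y)
  Xr <- family - Qn %*% crossprod(Qn, family)
  xn2 <- colSums(Xr^2)
  C <- crossprod(Xr, Yr) # L x V
  bad <- xn2 < 1e-12
  score <- C^2 / pmax(xn2, 1e-12)
  score[bad, ] <- -Inf
  # tie-break: evaluate lags in order of increasing |lag|
  ord <- order(abs(lags), lags)
  sel_ord <- max.col(t(score[ord, , drop = FALSE]), ties.method = "first")
  sel <- ord[sel_ord]
  V <- ncol(Y)
  pick <- cbind(sel, seq_len(V))
  beta <- (C / pmax(xn2, 1e-12))[pick]
  sse <- colSums(Yr^2) - score[pick]
  tss <- colSums(sweep(Y, 2, colMeans(Y))^2)
  r2 <- ifelse(tss > 0, 1 - sse / tss, NA_real_)
  list(beta = beta, lagIndex = sel, r2 = r2)
}

#' Fit the lagged GLM in one voxel
#'
#' Ordinary least squares of the voxel timeseries on each lag-shifted
#' regressor plus the nuisance polynomials; the lag maximizing the
#' full-model R2 is selected (ties to the smallest |lag|). The regressor
#' beta at the winning lag is the CVR amplitude (%BOLD/mmHg when the
#' series is percent signal change and the regressor mmHg); the winning
#' lag plus the bulk shift is the hemodynamic delay.
#'
#' @param y voxel timeseries (percent signal change), length n.
#' @param family matrix of lag-shifted regressors from [lagFamily()] (or
#'   the list it returns).
#' @param nuisance nuisance design matrix (default: Legendre order 4).
#' @param lags lag values (s) of the family columns (taken from `family`
#'   when it is a [lagFamily()] result).
#' @param bulkShift global shift added to the selected lag, s.
#' @return A list: `amplitude`, `delay`, `r2`, `atBoundary`, `lag`.
#' @export
fitVoxel <- function(y, family, nuisance = NULL, lags = NULL, bulkShift = 0) {
  if (is.list(family)) {
    lags <- family$lags
    family <- family$family
  }
  if (is.null(lags)) stop("fitVoxel: lag values required")
  n <- length(y)
  if (is.null(nuisance)) nuisance <- .legendreBasis(n, 4)
  if (qr(cbind(family[, 1], nuisance))$rank < ncol(nuisance) + 1) {
    return(list(
      amplitude = NA_real_, delay = NA_real_, r2 = NA_real_,
      atBoundary = NA, lag = NA_real_
    ))
  }
  f <- .lagFit(matrix(y, ncol = 1), family, lags, nuisance)
  L <- length(lags)
  list(
    amplitude = f$beta[1], delay = bulkShift + lags[f$lagIndex[1]],
    r2 = f$r2[1],
    atBoundary = f$lagIndex[1] %in% c(1L, 2L, L - 1L, L),
    lag = lags[f$lagIndex[1]]
  )
}

#' Map CVR amplitude and delay voxelwise
#'
#' The full lagged-GLM pipeline: percent signal change, bulk alignment of
#' the regressor to the mean gray-matter signal, per-voxel lag selection by
#' maximum full-model R2, and gray-matter-median delay normalization.
#' Voxels whose winning lag falls in the two outermost grid steps on
#' either side are flagged (`boundaryMask`) and, when
#' `config$boundaryThreshold` is TRUE, removed from the delay maps.
#'
#' @param bold 4D BOLD array.
#' @param mask 3D logical analysis mask.
#' @param gmMask 3D logical gray-matter mask.
#' @param regressor [PhysioTrace-class] in mmHg, already convolved with the
#'   appropriate response function (HRF for end-tidal CO2 variants, RRF for
#'   RVT).
#' @param config a [cvrConfig()].
#' @param TR repetition time, s.
#' @param allowArbitraryUnits permit a non-mmHg regressor (amplitude units
#'   are then not %BOLD/mmHg), default FALSE.
#' @return A [CvrMaps-class].
#' @export
mapCvr <- function(bold, mask, gmMask, regressor, config = cvrConfig(), TR,
                   allowArbitraryUnits = FALSE) {
  stopifnot(is(regressor, "PhysioTrace"))
  if (regressor@units != "mmHg" && !allowArbitraryUnits) {
    stop("mapCvr: regressor is not in mmHg (set allowArbitraryUnits to override)")
  }
  if (regressor@convolvedWith == "none") {
    stop("mapCvr: regressor must be convolved with a response function first")
  }
  if (!any(gmMask)) stop("mapCvr: empty gray-matter mask")
  d <- dim(bold)
  nv <- d[4]

  ps <- percentSignalChange(bold, mask)
  mask <- ps$mask
  nvox <- prod(d[1:3])
  P <- matrix(ps$psc, nvox, nv)
  gsel <- as.vector(gmMask) & as.vector(mask)
  gmMean <- colMeans(P[gsel, , drop = FALSE])

  bulk <- bulkAlign(regressor, gmMean, TR,
    bound = config$bulkAlignBound,
    step = config$lagStep
  )
  lf <- lagFamily(regressor, config, TR, nv, bulkShift = bulk@shift)
  nuis <- .legendreBasis(nv, config$polyOrder)

  vsel <- which(as.vector(mask))
  fit <- .lagFit(t(P[vsel, , drop = FALSE]), lf$family, lf$lags, nuis)

  amp <- del <- r2 <- array(NA_real_, d[1:3])
  boundary <- array(FALSE, d[1:3])
  amp[vsel] <- fit$beta
  del[vsel] <- bulk@shift + lf$lags[fit$lagIndex]
  r2[vsel] <- fit$r2
  L <- length(lf$lags)
  boundary[vsel] <- fit$lagIndex %in% c(1L, 2L, L - 1L, L)

  if (config$boundaryThreshold) del[boundary] <- NA_real_
  gm_del <- del[gmMask & mask]
  gm_median <- stats::median(gm_del, na.rm = TRUE)
  new("CvrMaps",
    amplitude = amp, delay = del, delayNormalized = del - gm_median,
    r2 = r2, boundaryMask = boundary, mask = mask,
    gmMedianDelay = gm_median, bulkShift = bulk@shift,
    config = unclass(config)
  )
}

#' Mask of extreme-delay clusters
#'
#' Binarizes voxels with (un-normalized) delay at or above `threshold`
#' seconds, labels connected components (6-neighborhood face connectivity
#' by default) and removes clusters smaller than `minCluster` voxels.
#' Used to localize pathologically delayed vascular territories.
#'
#' @param delay 3D delay map, s (NAs treated as below threshold).
#' @param threshold delay cutoff, s, default 10.
#' @param minCluster minimum cluster size in voxels, default 15.
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (all neighbors).
#' @return A 3D logical array.
#' @export
extremeDelayMask <- function(delay, threshold = 10, minCluster = 15,
                             connectivity = 6) {
  stopifnot(length(dim(delay)) == 3, connectivity %in% c(6, 18, 26))
  bin <- !is.na(delay) & delay >= threshold
  d <- dim(bin)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  nd <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- offs[nd > 0 & switch(as.character(connectivity),
    "6" = nd == 1, "18" = nd <= 2, "26" = nd <= 3
  ), ]
  lab <- array(0L, d)
  cur <- 0L
  keep <- array(FALSE, d)
  idx_all <- which(bin)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    comp <- start
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      z <- (v - 1) %/% (d[1] * d[2])
      rem <- (v - 1) %% (d[1] * d[2])
      y <- rem %/% d[1]
      x <- rem %% d[1]
      nx <- x + offs$dx
      ny <- y + offs$dy
      nz <- z + offs$dz
      okn <- nx >= 0 & nx < d[1] & ny >= 0 & ny < d[2] & nz >= 0 & nz < d[3]
      nb <- 1 + nx[okn] + ny[okn] * d[1] + nz[okn] * d[1] * d[2]
      nb <- nb[bin[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- cur
        queue <- c(queue, nb)
        comp <- c(comp, nb)
      }
    }
    if (length(comp) >= minCluster) keep[comp] <- TRUE
  }
  keep
}

#' Write CVR maps to NIfTI with a JSON sidecar
#'
#' @param maps a [CvrMaps-class].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix, default `"cvr"`.
#' @param pixdim voxel dimensions passed to [writeVolume()].
#' @param provenance regressor provenance recorded in the sidecar.
#' @return The sidecar path, invisibly.
#' @export
writeCvrMaps <- function(maps, dir, prefix = "cvr", pixdim = NULL,
                         provenance = "unknown") {
  stopifnot(is(maps, "CvrMaps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(x) file.path(dir, paste0(prefix, "_", x, ".nii.gz"))
  writeVolume(maps@amplitude, p("amplitude"), pixdim)
  writeVolume(maps@delay, p("delay"), pixdim)
  writeVolume(maps@delayNormalized, p("delay_normalized"), pixdim)
  writeVolume(maps@r2, p("r2"), pixdim)
  writeVolume(maps@boundaryMask + 0, p("boundary_mask"), pixdim)
  sidecar <- file.path(dir, paste0(prefix, "_maps.json"))
  jsonlite::write_json(
    list(
      config = maps@config, bulkShift = maps@bulkShift,
      gmMedianDelay = maps@gmMedianDelay, regressorProvenance = provenance
    ),
    sidecar,
    auto_unbox = TRUE, digits = NA
  )
  invisible(sidecar)
}
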