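# Local maxima: rise followed by fall; plateaus inherit the rising edge, so a
# flat-topped peak is reported at the last sample of its plateau.
.localMaxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  s <- sign(diff(x))
  nz <- which(s != 0)
  if (length(nz) < 2) return(integer())
  zpos <- which(s == 0)
  if (length(zpos)) {
    prev <- findInterval(zpos, nz)
    keepz <- prev > 0
    s[zpos[keepz]] <- s[nz[prev[keepz]]]
  }
  which(s[-length(s)] > 0 & s[-1] < 0) + 1L
}

# Topographic prominence of peaks at `idx` in signal x.
.prominence <- function(x, idx) {
  vapply(idx, function(i) {
    h <- x[i]
    # walk left until a strictly higher sample (or the edge)
    left <- x[seq_len(i - 1)]
    higher_l <- which(left > h)
    lmin <- if (length(higher_l)) min(x[(max(higher_l) + 1):(i - 1)]) else min(left, h)
    right <- x[seq(i + 1, length(x))]
    higher_r <- which(right > h)
    rmin <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1)]) else min(right, h)
    h - max(lmin, rmin)
  }, numeric(1))
}

# Shared peak finder: local maxima filtered by prominence, then greedy
# min-separation keeping the taller peak of any conflicting pair.
.findPeaks <- function(x, fs, minProminence = 0, minSeparation = 0) {
  idx <- .localMaxima(x)
  if (!length(idx)) return(integer())
  if (minProminence > 0) {
    prom <- .prominence(x, idx)
    idx <- idx[prom >= minProminence]
  }
  if (!length(idx) || minSeparation <= 0) return(idx)
  min_gap <- minSeparation * fs
  ord <- idx[order(-x[idx], idx)]
  kept <- integer()
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Detect end-tidal peaks in a raw CO2 trace
#'
#' Finds the local maxima of the respiratory CO2 waveform (one per
#' exhalation in compliant breathing) that meet a topographic-prominence
#' and minimum-separation requirement. Deterministic parameters replace
#' the manual verification step of interactive processing; a peak-edit
#' sidecar can be applied afterwards via [applyPeakEdits()].
#'
#' @param co2 a [PhysioTrace-class] in mmHg (volts accepted with a warning).
#' @param minProminence minimum peak prominence in trace units, default 5.
#' @param minSeparation minimum time between retained peaks in seconds
#'   (the taller of two conflicting peaks is kept), default 2.
#' @return A [PeakSet-class] of kind `"endtidal_max"`. Empty (with a
#'   warning) if no peak qualifies on a nonconstant trace.
#' @export
detectEndtidalPeaks <- function(co2, minProminence = 5, minSeparation = 2) {
  stopifnot(is(co2, "PhysioTrace"))
  if (co2@units == "volts") {
    warning("detecting end-tidal peaks on a trace still in volts; calibrate with voltsToMmHg() for mmHg thresholds")
  }
  if (minSeparation < 0) stop("minSeparation must be >= 0")
  idx <- .findPeaks(co2@samples, co2@fs, minProminence, minSeparation)
  if (!length(idx) && stats::sd(co2@samples) > 0) {
    warning("no end-tidal peaks detected on a nonconstant trace")
  }
  peakSet(idx, kind = "endtidal_max")
}

#' Apply a peak-edit sidecar
#'
#' Human QC hook: a JSON file with `add` and `remove` sample-index lists is
#' merged into a detected [PeakSet-class], which is then marked verified.
#'
#' @param peaks a [PeakSet-class].
#' @param edits path to a JSON file (keys `add`, `remove`) or an equivalent
#'   list.
#' @return The edited, verified [PeakSet-class].
#' @export
applyPeakEdits <- function(peaks, edits) {
  stopifnot(is(peaks, "PeakSet"))
  if (is.character(edits)) edits <- jsonlite::read_json(edits, simplifyVector = TRUE)
  idx <- peaks@indices
  if (!is.null(edits$remove)) idx <- setdiff(idx, as.integer(edits$remove))
  if (!is.null(edits$add)) idx <- union(idx, as.integer(edits$add))
  peakSet(idx, kind = peaks@kind, verified = TRUE)
}

#' Linearly interpolate end-tidal peaks into a P_ET_CO2 trace
#'
#' Builds the end-tidal envelope: a piecewise-linear trace through
#' (peak time, peak value) pairs, sampled at the CO2 trace's own rate and
#' constant-extrapolated before the first and after the last peak.
#'
#' @param co2 the raw CO2 [PhysioTrace-class].
#' @param peaks a [PeakSet-class] with at least 2 peaks.
#' @return A [PhysioTrace-class] (same fs and units, provenance
#'   `"measured_petco2"`).
#' @export
interpolateEndtidal <- function(co2, peaks) {
  stopifnot(is(co2, "PhysioTrace"), is(peaks, "PeakSet"))
  idx <- peaks@indices
  if (length(idx) < 2) stop("interpolateEndtidal requires at least 2 peaks")
  y <- stats::approx(idx, co2@samples[idx],
    xout = seq_along(co2@samples), rule = 2
  )$y
  physioTrace(y,
    fs = co2@fs, units = co2@units, t0 = co2@t0,
    provenance = "measured_petco2"
  )
}

#' Detect alternating respiration-belt extrema
#'
#' Finds breath maxima and minima of a respiration-effort trace and
#' enforces alternation. Breath holds are preceded and followed by an
#' exhalation, producing two consecutive belt minima with no intervening
#' breath maximum; only the pre-hold minimum is retained. For consecutive
#' same-kind extrema not straddling a hold, the more extreme one is kept.
#'
#' Maxima below `minProminence` are rejected as non-breath bumps (e.g. the
#' slight belt drift during a hold), while minima are kept down to a small
#' noise floor (`minProminenceMin`): an exhale trough that "shoulders" a
#' deeper one across a hold has low topographic prominence but is a real
#' breath event, and is exactly the trough the pre-hold rule must see.
#'
#' @param resp a [PhysioTrace-class] (any units).
#' @param timing optional [taskTiming()] data.frame; used to recognise
#'   minima pairs that straddle a breath hold.
#' @param minProminence minimum breath-maximum prominence; default 10% of
#'   the trace range.
#' @param minProminenceMin minimum minima prominence (noise floor);
#'   default 1% of the trace range.
#' @return A list with [PeakSet-class] elements `maxima` and `minima`.
#' @export
detectRespExtrema <- function(resp, timing = NULL, minProminence = NULL,
                              minProminenceMin = NULL) {
  stopifnot(is(resp, "PhysioTrace"))
  x <- resp@samples
  rng <- diff(range(x))
  if (rng == 0) {
    return(list(
      maxima = peakSet(integer(), "resp_max"),
      minima = peakSet(integer(), "resp_min")
    ))
  }
  if (is.null(minProminence)) minProminence <- 0.1 * rng
  if (is.null(minProminenceMin)) minProminenceMin <- 0.01 * rng
  imax <- .findPeaks(x, resp@fs, minProminence, 0)
  imin <- .findPeaks(-x, resp@fs, minProminenceMin, 0)
  if (!length(imax) || !length(imin)) {
    return(list(
      maxima = peakSet(imax, "resp_max"),
      minima = peakSet(imin, "resp_min")
    ))
  }
  ext <- rbind(
    data.frame(i = imax, kind = "max"),
    data.frame(i = imin, kind = "min")
  )
  ext <- ext[order(ext$i), ]
  tms <- resp@t0 + (ext$i - 1) / resp@fs

  straddlesHold <- function(t1, t2) {
    if (is.null(timing)) return(FALSE)
    any(!timing$skipped & timing$hold_start >= t1 & timing$hold_end <= t2)
  }

  keep <- rep(TRUE, nrow(ext))
  j <- 1L
  while (j < nrow(ext)) {
    nxt <- which(keep & seq_len(nrow(ext)) > j)
    if (!length(nxt)) break
    k <- nxt[1]
    if (ext$kind[j] == ext$kind[k]) {
      if (ext$kind[j] == "min" && straddlesHold(tms[j], tms[k])) {
        keep[k] <- FALSE # drop the post-hold exhale trough
      } else if (ext$kind[j] == "min") {
        if (x[ext$i[j]] <= x[ext$i[k]]) keep[k] <- FALSE else { keep[j] <- FALSE; j <- k }
      } else {
        if (x[ext$i[j]] >= x[ext$i[k]]) keep[k] <- FALSE else { keep[j] <- FALSE; j <- k }
      }
    } else {
      j <- k
    }
  }
  ext <- ext[keep, ]
  list(
    maxima = peakSet(ext$i[ext$kind == "max"], "resp_max"),
    minima = peakSet(ext$i[ext$kind == "min"], "resp_min")
  )
}

#' Compute respiration volume per time (RVT)
#'
#' Per-breath RVT is the breath depth (belt value at a breath maximum minus
#' the value at the preceding minimum) divided by the breath period (time
#' from that maximum to the next maximum). Values are anchored at the
#' breath maxima and linearly interpolated to the belt's sampling rate;
#' the final breath reuses the preceding period.
#'
#' @param resp the respiration-effort [PhysioTrace-class].
#' @param maxima,minima [PeakSet-class] pairs from [detectRespExtrema()].
#' @return A [PhysioTrace-class] in arbitrary units, provenance `"rvt"`.
#' @export
computeRvt <- function(resp, maxima, minima) {
  stopifnot(is(resp, "PhysioTrace"), is(maxima, "PeakSet"), is(minima, "PeakSet"))
  imax <- maxima@indices
  imin <- minima@indices
  if (length(imax) < 2) stop("computeRvt requires at least 2 breath maxima")
  x <- resp@samples
  depth <- rep(NA_real_, length(imax))
  for (j in seq_along(imax)) {
    prev_min <- imin[imin < imax[j]]
    if (length(prev_min)) depth[j] <- x[imax[j]] - x[max(prev_min)]
  }
  ok <- !is.na(depth)
  imax <- imax[ok]
  depth <- depth[ok]
  if (length(imax) < 2) stop("computeRvt: fewer than 2 breaths with a preceding minimum")
  period <- diff(imax) / resp@fs
  period <- c(period, period[length(period)]) # last breath reuses prior period
  rvt_at_max <- depth / period
  y <- stats::approx(imax, rvt_at_max, xout = seq_along(x), rule = 2)$y
  physioTrace(y,
    fs = resp@fs, units = "arbitrary", t0 = resp@t0,
    provenance = "rvt"
  )
}
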