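# Exhaustive bounded shift search shared by both directions.
# Shifting `a` by s seconds means comparing a(t - s) with b(t): for s < 0 the
# content of `a` moves earlier; overlap is trimmed accordingly.
.shiftSearch <- function(a, b, shifts_samples, fs) {
  n <- min(length(a), length(b))
  a <- a[seq_len(n)]
  b <- b[seq_len(n)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("shift search on a constant trace")
  }
  r <- vapply(shifts_samples, function(s) {
    if (s <= 0) {
      k <- -s
      aa <- a[seq(1 + k, n)]
      bb <- b[seq(1, n - k)]
    } else {
      aa <- a[seq(1, n - s)]
      bb <- b[seq(1 + s, n)]
    }
    if (stats::sd(aa) == 0 || stats::sd(bb) == 0) return(NA_real_)
    stats::cor(aa, bb)
  }, numeric(1))
  r
}

#' Align P_ET_CO2 to RVT by bounded negative shift
#'
#' Finds the shift (in integer samples, at most `maxShift` seconds, never
#' positive) that makes the end-tidal CO2 trace maximally *anti*-correlated
#' with RVT: a breath hold lowers respiratory volume while raising arterial
#' CO2, and the CO2 measurement lags the belt (sampling-line transit plus
#' physiological delay), so P_ET_CO2 may only be moved earlier in time.
#' The search is exhaustive over integer sample lags, hence exactly optimal
#' within the bound.
#'
#' @param petco2 end-tidal CO2 [PhysioTrace-class].
#' @param rvt RVT [PhysioTrace-class] at the same sampling rate.
#' @param maxShift bound on |shift| in seconds, default 30.
#' @return A [ShiftResult-class]; `shift` is <= 0, `score` the (negative)
#'   Pearson correlation at the optimum, `clipped` TRUE if the optimum sat
#'   at `-maxShift`.
#' @export
bestNegativeShift <- function(petco2, rvt, maxShift = 30) {
  stopifnot(is(petco2, "PhysioTrace"), is(rvt, "PhysioTrace"))
  if (!isTRUE(all.equal(petco2@fs, rvt@fs))) stop("traces must share a sampling rate")
  S <- round(maxShift * petco2@fs)
  shifts <- seq(-S, 0L)
  r <- .shiftSearch(petco2@samples, rvt@samples, shifts, petco2@fs)
  best <- which.min(r) # most negative correlation
  new("ShiftResult",
    shift = shifts[best] / petco2@fs, score = r[best],
    clipped = best == 1L
  )
}

#' Align an RRF-convolved RVT regressor to measured P_ET_CO2
#'
#' Mirror of [bestNegativeShift()]: only non-negative shifts (moving the
#' first trace later in time) are allowed, and the positive correlation is
#' maximized. Used when comparing RRF-convolved RVT against HRF-convolved
#' measured end-tidal CO2, whose response functions have different
#' latencies.
#'
#' @param a the trace to be shifted later (e.g. RRF-convolved RVT).
#' @param b the reference trace (e.g. HRF-convolved measured P_ET_CO2).
#' @param maxShift bound on the shift in seconds, default 30.
#' @return A [ShiftResult-class] with `shift` in `[0, maxShift]`.
#' @export
bestPositiveShift <- function(a, b, maxShift = 30) {
  stopifnot(is(a, "PhysioTrace"), is(b, "PhysioTrace"))
  if (!isTRUE(all.equal(a@fs, b@fs))) stop("traces must share a sampling rate")
  S <- round(maxShift * a@fs)
  shifts <- seq(0L, S)
  r <- .shiftSearch(a@samples, b@samples, shifts, a@fs)
  best <- which.max(r)
  new("ShiftResult",
    shift = shifts[best] / a@fs, score = r[best],
    clipped = best == length(shifts)
  )
}

#' Apply a shift and trim both traces to common support
#'
#' Applies a [ShiftResult-class] (or plain shift in seconds) to `a` and
#' trims `b` so both traces cover the same span: for a negative shift the
#' start of `a` and the end of `b` are dropped, mirroring the convention of
#' trimming the RVT tail after moving P_ET_CO2 earlier.
#'
#' @param a,b [PhysioTrace-class] traces at a common rate.
#' @param shift a [ShiftResult-class] or numeric shift in seconds.
#' @return A list with trimmed traces `a` and `b` of equal length.
#' @export
applyShift <- function(a, b, shift) {
  if (is(shift, "ShiftResult")) shift <- shift@shift
  s <- round(shift * a@fs)
  n <- min(length(a@samples), length(b@samples))
  if (s <= 0) {
    k <- -s
    ya <- a@samples[seq(1 + k, n)]
    yb <- b@samples[seq(1, n - k)]
  } else {
    ya <- a@samples[seq(1, n - s)]
    yb <- b@samples[seq(1 + s, n)]
  }
  a@samples <- ya
  b@samples <- yb
  list(a = a, b = b)
}

#' Z-normalize a trace
#'
#' Zero mean, unit standard deviation (population, i.e. n denominator).
#'
#' @param trace a nonconstant [PhysioTrace-class].
#' @return The z-normalized trace with units `"zscore"`.
#' @export
znorm <- function(trace) {
  stopifnot(is(trace, "PhysioTrace"))
  x <- trace@samples
  n <- length(x)
  s <- sqrt(sum((x - mean(x))^2) / n)
  if (s == 0) stop("znorm: constant trace")
  out <- trace
  out@samples <- (x - mean(x)) / s
  out@units <- "zscore"
  out
}

# Earliest run of k consecutive high-quality blocks (skipped blocks break
# sequences). Returns row indices into `blocks`, or NULL.
.firstHighRun <- function(blocks, k) {
  high <- blocks$quality == "high"
  r <- rle(high)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    if (r$values[j] && r$lengths[j] >= k) {
      return(starts[j]:(starts[j] + k - 1L))
    }
  }
  NULL
}

#' Rescale a surrogate regressor to mmHg via breath-hold block extrema
#'
#' Linearly maps the target trace so its global minimum and maximum equal
#' the minimum and maximum of the *measured* end-tidal CO2 over the first
#' run of `k` sequential high-quality breath-hold blocks. This converts a
#' unit-free surrogate (predicted P_ET_CO2 or RVT) into mmHg using only the
#' portion of the measured recording known to be reliable.
#'
#' @param target nonconstant [PhysioTrace-class] to rescale.
#' @param measured measured end-tidal CO2 [PhysioTrace-class] in mmHg, on
#'   the same grid the blocks index into.
#' @param blocks `data.frame` from [buildBlocks()].
#' @param k number of sequential high-quality blocks to use (1, 2 or 3).
#' @param extrema `"global"` (default): the target's global extrema are
#'   mapped onto the measured block extrema; `"block"`: the target's
#'   extrema within the same block span are mapped instead.
#' @return The rescaled trace in mmHg (provenance preserved).
#' @export
rescaleMinmax <- function(target, measured, blocks, k = 1L,
                          extrema = c("global", "block")) {
  stopifnot(is(target, "PhysioTrace"), is(measured, "PhysioTrace"))
  extrema <- match.arg(extrema)
  if (!(k %in% 1:3)) stop("k must be 1, 2 or 3")
  run <- .firstHighRun(blocks, k)
  if (is.null(run)) {
    stop(sprintf("rescaleMinmax: no run of %d sequential high-quality blocks", k))
  }
  sel <- unlist(lapply(run, function(i) {
    seq(blocks$start_sample[i], blocks$end_sample[i])
  }))
  sel <- sel[sel >= 1 & sel <= length(measured@samples)]
  lo <- min(measured@samples[sel])
  hi <- max(measured@samples[sel])
  if (hi == lo) stop("rescaleMinmax: measured block range is degenerate")
  x <- target@samples
  if (extrema == "global") {
    xmin <- min(x)
    xmax <- max(x)
  } else {
    sel_t <- sel[sel <= length(x)]
    xmin <- min(x[sel_t])
    xmax <- max(x[sel_t])
  }
  if (xmax == xmin) stop("rescaleMinmax: target is constant")
  out <- target
  out@samples <- lo + (x - xmin) * (hi - lo) / (xmax - xmin)
  out@units <- "mmHg"
  out
}
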