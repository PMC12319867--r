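#' Accessors for PhysioTrace and related classes
#'
#' `samples()` returns the sample vector, `samplingRate()` the rate in Hz,
#' `traceUnits()` the declared units, `startTime()` the start time,
#' `traceTimes()` the per-sample time vector, `traceDuration()` the span in
#' seconds and `nSamples()` the length.
#'
#' @param x a [PhysioTrace-class] (or, for `nSamples`, anything with a length).
#' @return The corresponding slot or derived quantity.
#' @name trace-accessors
NULL

#' @rdname trace-accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname trace-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname trace-accessors
#' @export
setGeneric("traceUnits", function(x) standardGeneric("traceUnits"))
#' @rdname trace-accessors
#' @export
setGeneric("startTime", function(x) standardGeneric("startTime"))
#' @rdname trace-accessors
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))
#' @rdname trace-accessors
#' @export
setGeneric("traceDuration", function(x) standardGeneric("traceDuration"))
#' @rdname trace-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname trace-accessors
#' @export
setMethod("samples", "PhysioTrace", function(x) x@samples)
#' @rdname trace-accessors
#' @export
setMethod("samplingRate", "PhysioTrace", function(x) x@fs)
#' @rdname trace-accessors
#' @export
setMethod("traceUnits", "PhysioTrace", function(x) x@units)
#' @rdname trace-accessors
#' @export
setMethod("startTime", "PhysioTrace", function(x) x@t0)
#' @rdname trace-accessors
#' @export
setMethod("traceTimes", "PhysioTrace", function(x) {
  x@t0 + (seq_along(x@samples) - 1) / x@fs
})
#' @rdname trace-accessors
#' @export
setMethod("traceDuration", "PhysioTrace", function(x) {
  (length(x@samples) - 1) / x@fs
})
#' @rdname trace-accessors
#' @export
setMethod("nSamples", "PhysioTrace", function(x) length(x@samples))

#' Peak accessors
#' @param x a [PeakSet-class].
#' @return `peakIndices()` returns the integer sample indices; `peakKind()`
#'   the extremum kind.
#' @name peak-accessors
NULL

#' @rdname peak-accessors
#' @export
setGeneric("peakIndices", function(x) standardGeneric("peakIndices"))
#' @rdname peak-accessors
#' @export
setGeneric("peakKind", function(x) standardGeneric("peakKind"))
#' @rdname peak-accessors
#' @export
setMethod("peakIndices", "PeakSet", function(x) x@indices)
#' @rdname peak-accessors
#' @export
setMethod("peakKind", "PeakSet", function(x) x@kind)

setMethod("show", "PhysioTrace", function(object) {
  cat(sprintf(
    "PhysioTrace: %d samples @ %g Hz (%.1f s), units=%s, t0=%g\n  provenance=%s, convolvedWith=%s\n  range [%.4g, %.4g]\n",
    length(object@samples), object@fs,
    (length(object@samples) - 1) / object@fs,
    object@units, object@t0, object@provenance, object@convolvedWith,
    min(object@samples), max(object@samples)
  ))
})

setMethod("show", "PeakSet", function(object) {
  cat(sprintf(
    "PeakSet: %d %s peaks%s\n", length(object@indices), object@kind,
    if (object@verified) " (verified)" else ""
  ))
})

setMethod("show", "ShiftResult", function(object) {
  cat(sprintf(
    "ShiftResult: shift = %+.2f s, r = %.4f%s\n",
    object@shift, object@score, if (object@clipped) " (clipped at bound)" else ""
  ))
})

setMethod("show", "FcnConfig", function(object) {
  cat(sprintf(
    "FcnConfig: %d layers (%d conv + %d transposed), %d epochs, peakWeight=%g\n  lr0=%g, plateau factor=%g patience=%d, kernel=%d, maxChannels=%d, seed=%d\n",
    object@nLayers, object@nLayers / 2, object@nLayers / 2, object@epochs,
    object@peakWeight, object@lr0, object@plateauFactor, object@plateauPatience,
    object@kernelSize, object@maxChannels, object@seed
  ))
})

setMethod("show", "FcnModel", function(object) {
  np <- sum(vapply(object@layers, function(l) length(l$W) + length(l$b), numeric(1)))
  cat(sprintf(
    "FcnModel: %d layers, %d parameters, %d known subjects\n",
    length(object@layers), np, length(object@subjects)
  ))
  show(object@config)
})

setMethod("show", "CvrMaps", function(object) {
  d <- dim(object@amplitude)
  amp <- object@amplitude[object@mask]
  cat(sprintf(
    "CvrMaps: %s grid, %d voxels in mask\n  amplitude (%%BOLD/mmHg): median %.4f\n  delay (s): GM median %.2f, bulk shift %+.2f\n",
    paste(d, collapse = "x"), sum(object@mask),
    stats::median(amp, na.rm = TRUE), object@gmMedianDelay, object@bulkShift
  ))
})
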