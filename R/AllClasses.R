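#' @import methods
NULL

.TRACE_UNITS <- c("volts", "mmHg", "arbitrary", "zscore")
.PEAK_KINDS <- c("endtidal_max", "resp_max", "resp_min")

#' PhysioTrace: a uniformly sampled physiological signal
#'
#' Container for a 1D physiological recording (exhaled CO2, respiration
#' effort, end-tidal CO2, RVT, or a derived regressor). The time of sample
#' `i` is `t0 + (i - 1) / fs`.
#'
#' @slot samples numeric vector of signal values.
#' @slot fs sampling rate in Hz.
#' @slot units one of `"volts"`, `"mmHg"`, `"arbitrary"`, `"zscore"`.
#' @slot t0 start time in seconds.
#' @slot provenance free-form tag recording how the trace was derived
#'   (e.g. `"measured_petco2"`, `"predicted_petco2"`, `"rvt"`).
#' @slot convolvedWith `"none"`, `"hrf"` or `"rrf"`: the response function
#'   this trace has been convolved with.
#'
#' @seealso [physioTrace()], [readPhysio()], [resampleTrace()]
#' @exportClass PhysioTrace
setClass("PhysioTrace",
  representation(
    samples = "numeric",
    fs = "numeric",
    units = "character",
    t0 = "numeric",
    provenance = "character",
    convolvedWith = "character"
  ),
  prototype(provenance = "unknown", convolvedWith = "none", t0 = 0)
)

setValidity("PhysioTrace", function(object) {
  msg <- character()
  if (length(object@fs) != 1 || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@samples) < 2)
    msg <- c(msg, "trace must have at least 2 samples")
  if (!all(is.finite(object@samples)))
    msg <- c(msg, "all samples must be finite")
  if (!(object@units %in% .TRACE_UNITS))
    msg <- c(msg, sprintf("units must be one of: %s", paste(.TRACE_UNITS, collapse = ", ")))
  if (length(object@t0) != 1 || !is.finite(object@t0))
    msg <- c(msg, "t0 must be a single finite number")
  if (!(object@convolvedWith %in% c("none", "hrf", "rrf")))
    msg <- c(msg, "convolvedWith must be 'none', 'hrf' or 'rrf'")
  if (length(msg)) msg else TRUE
})

#' Construct a PhysioTrace
#'
#' @param samples numeric vector of signal values.
#' @param fs sampling rate, Hz.
#' @param units signal units (`"volts"`, `"mmHg"`, `"arbitrary"`, `"zscore"`).
#' @param t0 start time in seconds.
#' @param provenance free-form provenance tag.
#' @param convolvedWith `"none"`, `"hrf"` or `"rrf"`.
#' @return A [PhysioTrace-class] object.
#' @examples
#' tr <- physioTrace(sin(seq(0, 10, by = 0.1)), fs = 10, units = "arbitrary")
#' traceDuration(tr)
#' @export
physioTrace <- function(samples, fs, units = "arbitrary", t0 = 0,
                        provenance = "unknown", convolvedWith = "none") {
  new("PhysioTrace",
    samples = as.numeric(samples), fs = as.numeric(fs),
    units = units, t0 = as.numeric(t0),
    provenance = provenance, convolvedWith = convolvedWith
  )
}

#' PeakSet: detected extrema of a physiological trace
#'
#' Sorted sample indices of detected peaks (or troughs), tagged with the
#' kind of extremum they represent.
#'
#' @slot indices strictly increasing integer sample indices (1-based).
#' @slot kind `"endtidal_max"`, `"resp_max"` or `"resp_min"`.
#' @slot verified whether the set has been human-verified / edited.
#' @exportClass PeakSet
setClass("PeakSet",
  representation(indices = "integer", kind = "character", verified = "logical"),
  prototype(verified = FALSE)
)

setValidity("PeakSet", function(object) {
  msg <- character()
  if (!(object@kind %in% .PEAK_KINDS))
    msg <- c(msg, sprintf("kind must be one of: %s", paste(.PEAK_KINDS, collapse = ", ")))
  if (length(object@indices) && any(diff(object@indices) <= 0))
    msg <- c(msg, "indices must be strictly increasing")
  if (length(object@indices) && any(object@indices < 1))
    msg <- c(msg, "indices must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a PeakSet
#' @param indices integer sample indices (1-based), any order; sorted internally.
#' @param kind extremum kind (`"endtidal_max"`, `"resp_max"`, `"resp_min"`).
#' @param verified logical; has the set been manually verified/edited?
#' @return A [PeakSet-class] object.
#' @export
peakSet <- function(indices, kind = "endtidal_max", verified = FALSE) {
  new("PeakSet",
    indices = as.integer(sort(unique(indices))),
    kind = kind, verified = verified
  )
}

#' ShiftResult: the optimum of a bounded cross-correlation search
#'
#' @slot shift optimal shift in seconds (an integer number of samples at
#'   the working rate; negative means the first trace was moved earlier).
#' @slot score Pearson correlation at the optimum.
#' @slot clipped TRUE if the optimum sat on the search boundary.
#' @exportClass ShiftResult
setClass("ShiftResult",
  representation(shift = "numeric", score = "numeric", clipped = "logical")
)

#' CvrMaps: voxelwise cerebrovascular reactivity results
#'
#' @slot amplitude 3D array, CVR amplitude in %BOLD/mmHg.
#' @slot delay 3D array, hemodynamic delay in seconds (bulk shift included);
#'   NA where masked out or (if boundary thresholding is on) at lag-grid edges.
#' @slot delayNormalized 3D array, delay minus the gray-matter median delay.
#' @slot r2 3D array, full-model R2 at the selected lag.
#' @slot boundaryMask 3D logical array; TRUE where the selected lag sat in the
#'   two outermost lag-grid steps on either side.
#' @slot mask 3D logical array of analyzed voxels.
#' @slot gmMedianDelay scalar, the gray-matter median delay subtracted to form
#'   `delayNormalized`.
#' @slot bulkShift scalar, global regressor-to-GM-mean shift in seconds.
#' @slot config list, the `cvrConfig()` used.
#' @exportClass CvrMaps
setClass("CvrMaps",
  representation(
    amplitude = "array", delay = "array", delayNormalized = "array",
    r2 = "array", boundaryMask = "array", mask = "array",
    gmMedianDelay = "numeric", bulkShift = "numeric", config = "list"
  )
)

#' FcnConfig: hyperparameters of the 1D fully-convolutional predictor
#'
#' Half of `nLayers` are strided convolutions, half transposed convolutions
#' (stride 2, kernel 16 by default). Training uses batch size 1, Adam, an
#' initial learning rate of 0.01 reduced by a factor of 0.1 after 4 epochs
#' without improvement, and per-channel instance normalization after every
#' hidden layer.
#'
#' @slot nLayers even integer, total number of layers.
#' @slot epochs number of training epochs.
#' @slot peakWeight weight lambda on the MSE-at-peaks loss term.
#' @slot lr0 initial learning rate.
#' @slot plateauFactor multiplicative learning-rate reduction factor.
#' @slot plateauPatience epochs without improvement before reduction.
#' @slot kernelSize convolution kernel width.
#' @slot maxChannels cap on per-layer channel width.
#' @slot gradClip global gradient-norm clip (numerical safeguard).
#' @slot seed integer RNG seed for weight init and segment shuffling.
#' @exportClass FcnConfig
setClass("FcnConfig",
  representation(
    nLayers = "integer", epochs = "integer", peakWeight = "numeric",
    lr0 = "numeric", plateauFactor = "numeric", plateauPatience = "integer",
    kernelSize = "integer", maxChannels = "integer", gradClip = "numeric",
    seed = "integer"
  )
)

setValidity("FcnConfig", function(object) {
  msg <- character()
  if (object@nLayers < 2 || object@nLayers %% 2 != 0)
    msg <- c(msg, "nLayers must be an even integer >= 2")
  if (object@peakWeight < 0) msg <- c(msg, "peakWeight must be >= 0")
  if (object@epochs < 1) msg <- c(msg, "epochs must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct an FcnConfig
#'
#' @param nLayers total layer count (even; half convolutional, half
#'   transposed convolutional), default 12.
#' @param epochs training epochs, default 20.
#' @param peakWeight lambda for the peak-weighted MSE loss, default 0.5.
#' @param lr0 initial Adam learning rate, default 0.01.
#' @param plateauFactor LR reduction factor on plateau, default 0.1.
#' @param plateauPatience epochs without a new loss minimum before the LR is
#'   reduced, default 4.
#' @param kernelSize convolution kernel width, default 16.
#' @param maxChannels channel-width cap, default 64.
#' @param gradClip global gradient-norm clip, default 1.
#' @param seed RNG seed, default 1.
#' @return An [FcnConfig-class] object.
#' @export
fcnConfig <- function(nLayers = 12L, epochs = 20L, peakWeight = 0.5,
                      lr0 = 0.01, plateauFactor = 0.1, plateauPatience = 4L,
                      kernelSize = 16L, maxChannels = 64L, gradClip = 1,
                      seed = 1L) {
  new("FcnConfig",
    nLayers = as.integer(nLayers), epochs = as.integer(epochs),
    peakWeight = as.numeric(peakWeight), lr0 = lr0,
    plateauFactor = plateauFactor, plateauPatience = as.integer(plateauPatience),
    kernelSize = as.integer(kernelSize), maxChannels = as.integer(maxChannels),
    gradClip = gradClip, seed = as.integer(seed)
  )
}

#' FcnModel: a trained 1D fully-convolutional predictor
#'
#' @slot layers list of per-layer parameter lists (weights, biases, type).
#' @slot config the [FcnConfig-class] used for training.
#' @slot subjects ordered character vector: the subject-ID vocabulary used
#'   for one-hot encoding.
#' @exportClass FcnModel
setClass("FcnModel",
  representation(layers = "list", config = "FcnConfig", subjects = "character")
)
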