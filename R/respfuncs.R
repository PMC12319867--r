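#' Canonical hemodynamic response function
#'
#' The standard double-gamma HRF: the difference of two gamma densities,
#' `h(t) = g(t; shape 6, rate 1) - g(t; shape 16, rate 1) / 6`, sampled at
#' `fs` over `[0, duration]` and scaled to unit peak. Peaks near 5 s with a
#' post-stimulus undershoot.
#'
#' @param fs sampling rate, Hz.
#' @param duration kernel support, s (default 32).
#' @param normalize `"peak"` (default, unit maximum) or `"area"` (unit
#'   sum; note the RRF has negative net area, so `"area"` flips its sign
#'   and is only meaningful for the HRF).
#' @return A list with elements `samples`, `fs`, `duration`, `kind`.
#' @export
hrf <- function(fs, duration = 32, normalize = c("peak", "area")) {
  normalize <- match.arg(normalize)
  if (fs <= 0) stop("fs must be > 0")
  t <- seq(0, duration, by = 1 / fs)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h <- switch(normalize, peak = h / max(h), area = h / sum(h))
  list(samples = h, fs = fs, duration = duration, kind = "hrf")
}

#' Respiration response function
#'
#' The canonical response of BOLD to a unit change in respiration volume:
#' `r(t) = 0.6 t^2.1 exp(-t/1.6) - 0.0023 t^3.54 exp(-t/4.25)`, an early
#' positive lobe followed by a long negative undershoot, sampled at `fs`
#' over `[0, duration]` and scaled to unit peak.
#'
#' @param fs sampling rate, Hz.
#' @param duration kernel support, s (default 60; the undershoot is slow).
#' @param normalize `"peak"` (default) or `"area"` (see [hrf()]).
#' @return A list with elements `samples`, `fs`, `duration`, `kind`.
#' @export
rrf <- function(fs, duration = 60, normalize = c("peak", "area")) {
  normalize <- match.arg(normalize)
  if (fs <= 0) stop("fs must be > 0")
  t <- seq(0, duration, by = 1 / fs)
  r <- 0.6 * t^2.1 * exp(-t / 1.6) - 0.0023 * t^3.54 * exp(-t / 4.25)
  r <- switch(normalize, peak = r / max(r), area = r / sum(r))
  list(samples = r, fs = fs, duration = duration, kind = "rrf")
}

#' Convolve a trace with a response-function kernel
#'
#' Causal linear convolution truncated to the input length: output sample
#' `i` depends only on input samples `<= i`. The input is convolved as-is
#' (no demeaning); units are preserved and the trace is tagged with the
#' kernel kind.
#'
#' @param trace a [PhysioTrace-class].
#' @param kernel a kernel from [hrf()] or [rrf()] at the same rate.
#' @return The convolved [PhysioTrace-class].
#' @export
convolveTrace <- function(trace, kernel) {
  stopifnot(is(trace, "PhysioTrace"))
  if (!isTRUE(all.equal(trace@fs, kernel$fs))) {
    stop("convolveTrace: trace and kernel sampling rates differ")
  }
  x <- trace@samples
  k <- kernel$samples
  n <- length(x)
  full <- stats::convolve(x, rev(k), type = "open")
  out <- trace
  out@samples <- full[seq_len(n)]
  out@convolvedWith <- kernel$kind
  out
}
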