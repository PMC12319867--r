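# Shared fixtures, all generated in code.

# smooth band-limited random trace (moving-average-filtered white noise)
smoothTrace <- function(n, fs = 10, seed = 1, width = 21) {
  set.seed(seed)
  x <- stats::filter(rnorm(n + 2 * width), rep(1 / width, width), sides = 2)
  x <- x[!is.na(x)][seq_len(n)]
  physioTrace(x, fs = fs, units = "arbitrary")
}

# tiny training segments for fast FCN mechanics tests (not learning tests)
tinySegments <- function(nseg = 4, n = 128, seed = 5) {
  set.seed(seed)
  lapply(seq_len(nseg), function(i) {
    rvt <- as.numeric(scale(cumsum(rnorm(n))))
    pet <- as.numeric(scale(-rvt + 0.2 * rnorm(n)))
    trainingSegment(rvt, pet, sprintf("S%02d", i))
  })
}

tinyFcnConfig <- function(epochs = 1L, ...) {
  fcnConfig(nLayers = 2L, epochs = epochs, kernelSize = 8L, maxChannels = 8L, ...)
}

# small noiseless phantom + matching regressor for mapping tests
smallPhantom <- function(dims = c(6L, 6L, 2L), nVolumes = 120L, noiseSd = 0,
                         seed = 11) {
  sim <- genPhysio(synthSpec(seed = seed, skipProbability = 0))
  ps <- phantomSpec(dims = dims, nVolumes = nVolumes, noiseSd = noiseSd, seed = seed)
  ph <- genPhantom(ps, sim$truth$petco2Ideal)
  reg <- convolveTrace(sim$truth$petco2Ideal, hrf(10))
  list(ph = ph, reg = reg, spec = ps)
}
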