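test_that("end-tidal peaks of a paced-breathing CO2 waveform are found at construction times", {
  fs <- 40
  t <- seq(0, 60, by = 1 / fs)
  # one exhalation hump per 6 s breath, peak 3 s into the breath
  co2 <- 2 + 36 * pmax(sin(pi * (t %% 6) / 6), 0)^4
  tr <- physioTrace(co2, fs = fs, units = "mmHg")
  pk <- detectEndtidalPeaks(tr)
  expected <- round((seq(3, 57, by = 6)) * fs) + 1
  expect_equal(length(peakIndices(pk)), length(expected))
  expect_true(all(abs(peakIndices(pk) - expected) <= 1))
})

test_that("constant traces yield no peaks; merged humps keep the taller one", {
  flat <- physioTrace(rep(5, 100), fs = 10, units = "mmHg")
  expect_length(peakIndices(detectEndtidalPeaks(flat)), 0)

  # two humps 1 s apart, second taller; minSeparation 2 s keeps the larger
  t <- seq(0, 10, by = 0.025)
  x <- 30 * exp(-((t - 4)^2) / 0.08) + 40 * exp(-((t - 5)^2) / 0.08)
  tr <- physioTrace(x + 2, fs = 40, units = "mmHg")
  pk <- detectEndtidalPeaks(tr, minProminence = 5, minSeparation = 2)
  expect_length(peakIndices(pk), 1)
  # brute-force oracle: the max over the merged window
  expect_equal(peakIndices(pk), which.max(x))
})

test_that("interpolateEndtidal is the piecewise-linear envelope through the peaks", {
  fs <- 10
  co2 <- physioTrace(rep(0, 101), fs = fs, units = "mmHg")
  co2@samples[c(11, 51)] <- c(38, 42) # peaks at t = 1 s and 5 s
  env <- interpolateEndtidal(co2, peakSet(c(11, 51)))
  expect_equal(samples(env)[31], 40) # midpoint of the line at t = 3 s
  expect_equal(samples(env)[c(11, 51)], c(38, 42)) # passes through peaks
  expect_equal(samples(env)[1], 38) # constant extrapolation before
  expect_equal(samples(env)[101], 42) # and after

  expect_error(interpolateEndtidal(co2, peakSet(11L)), "2 peaks")

  # three collinear peaks reproduce the line exactly
  line <- physioTrace(seq(30, 40, length.out = 101), fs = fs, units = "mmHg")
  env2 <- interpolateEndtidal(line, peakSet(c(1, 51, 101)))
  expect_lt(max(abs(samples(env2) - samples(line))), 1e-9)
})

test_that("respiration extrema alternate and the pre-hold-minima rule is applied", {
  # pure sinusoid: strictly alternating, counts differ by at most one
  t <- seq(0, 60, by = 1 / 40)
  sine <- physioTrace(sin(2 * pi * t / 6), fs = 40)
  ex <- detectRespExtrema(sine)
  imax <- peakIndices(ex$maxima)
  imin <- peakIndices(ex$minima)
  expect_lte(abs(length(imax) - length(imin)), 1)
  merged <- sort(c(imax, imin))
  kinds <- merged %in% imax
  expect_true(all(kinds[-1] != kinds[-length(kinds)]))

  # flat trace: both sets empty
  ex0 <- detectRespExtrema(physioTrace(rep(1, 100), fs = 10))
  expect_length(peakIndices(ex0$maxima), 0)
  expect_length(peakIndices(ex0$minima), 0)

  # generator construction: each non-skipped hold has a pre-hold exhale
  # trough and a deeper post-hold trough with no breath maximum between;
  # only the pre-hold one must be returned
  sim <- genPhysio(synthSpec(seed = 4, skipProbability = 0))
  ex2 <- detectRespExtrema(sim$resp, sim$timing)
  tmin <- (peakIndices(ex2$minima) - 1) / samplingRate(sim$resp)
  for (i in seq_len(nrow(sim$timing))) {
    hs <- sim$timing$hold_start[i]
    he <- sim$timing$hold_end[i]
    expect_true(any(tmin >= hs - 3 & tmin <= hs),
      label = sprintf("pre-hold minimum kept for trial %d", i)
    )
    expect_false(any(tmin > he & tmin < he + 3),
      label = sprintf("post-hold trough dropped for trial %d", i)
    )
  }
})

test_that("RVT matches the per-breath closed form on constructed signals", {
  fs <- 40
  t <- seq(0, 120, by = 1 / fs)
  A <- 1.3
  T_breath <- 6
  resp <- physioTrace(A * sin(2 * pi * t / T_breath), fs = fs)
  ex <- detectRespExtrema(resp)
  rvt <- computeRvt(resp, ex$maxima, ex$minima)
  # closed form: depth 2A over period T at every interior breath
  imax <- peakIndices(ex$maxima)
  interior <- imax[3:(length(imax) - 2)]
  expect_lt(max(abs(samples(rvt)[interior] - 2 * A / T_breath)) / (2 * A / T_breath), 0.01)

  # amplitude doubling doubles RVT where doubled
  resp2 <- physioTrace(c(A * sin(2 * pi * t[t <= 60] / 6), 2 * A * sin(2 * pi * t[t > 60] / 6)), fs = fs)
  ex2 <- detectRespExtrema(resp2)
  rvt2 <- computeRvt(resp2, ex2$maxima, ex2$minima)
  i1 <- peakIndices(ex2$maxima)
  early <- i1[i1 < 40 * 40 & i1 > 10 * 40]
  late <- i1[i1 > 80 * 40 & i1 < 110 * 40]
  expect_equal(
    mean(samples(rvt2)[late]) / mean(samples(rvt2)[early]), 2,
    tolerance = 0.05
  )

  # doubling the period halves RVT
  slow <- physioTrace(A * sin(2 * pi * t / 12), fs = fs)
  ex3 <- detectRespExtrema(slow)
  rvt3 <- computeRvt(slow, ex3$maxima, ex3$minima)
  i3 <- peakIndices(ex3$maxima)
  expect_equal(
    samples(rvt3)[i3[3]] / samples(rvt)[imax[3]], 0.5,
    tolerance = 0.02
  )
})

test_that("RVT is offset-invariant, gain-linear, and collapses during holds", {
  fs <- 40
  t <- seq(0, 120, by = 1 / fs)
  resp <- physioTrace(sin(2 * pi * t / 6) + 0.05 * sin(2 * pi * t / 40), fs = fs)
  ex <- detectRespExtrema(resp)
  rvt <- computeRvt(resp, ex$maxima, ex$minima)

  shifted <- resp
  shifted@samples <- resp@samples + 3.7
  exs <- detectRespExtrema(shifted)
  expect_equal(samples(computeRvt(shifted, exs$maxima, exs$minima)), samples(rvt),
    tolerance = 1e-12
  )

  scaled <- resp
  scaled@samples <- resp@samples * 2.5
  exg <- detectRespExtrema(scaled)
  expect_equal(samples(computeRvt(scaled, exg$maxima, exg$minima)), 2.5 * samples(rvt),
    tolerance = 1e-12
  )

  # apnea: within every hold, RVT dips below its 20th percentile
  sim <- genPhysio(synthSpec(seed = 6, skipProbability = 0))
  ex2 <- detectRespExtrema(sim$resp, sim$timing)
  rvt2 <- computeRvt(sim$resp, ex2$maxima, ex2$minima)
  v <- samples(rvt2)
  q20 <- quantile(v, 0.2)
  fsr <- samplingRate(sim$resp)
  for (i in seq_len(nrow(sim$timing))) {
    span <- (round(sim$timing$hold_start[i] * fsr):round(sim$timing$hold_end[i] * fsr)) + 1
    expect_lt(min(v[span]), q20)
  }
})
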