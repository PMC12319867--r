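test_that("negative shift search recovers constructed lags exactly", {
  fs <- 10
  base <- smoothTrace(2000, fs = fs, seed = 3)
  for (lag_s in c(0, 2, 11.7, 29.9)) {
    k <- round(lag_s * fs)
    p <- samples(base)
    rvt <- physioTrace(-p, fs = fs)
    pet <- physioTrace(c(rep(p[1], k), p)[seq_along(p)], fs = fs) # p delayed by lag
    res <- bestNegativeShift(pet, rvt, maxShift = 30)
    expect_equal(res@shift, -lag_s)
    expect_lt(res@score, -0.99)
    # exhaustive oracle: no allowed shift does better
    r_all <- sapply(0:300, function(kk) {
      n <- nSamples(pet)
      cor(samples(pet)[(1 + kk):n], samples(rvt)[1:(n - kk)])
    })
    expect_equal(-(which.min(r_all) - 1) / fs, res@shift)
  }
})

test_that("shift searches clip at the bound and flag it", {
  fs <- 10
  # slow oscillation: correlation improves monotonically toward the true
  # 40 s lag, so a 30 s bound must clip
  t <- (0:2999) / fs
  p <- sin(2 * pi * t / 150) + 0.02 * samples(smoothTrace(3000, fs = fs, seed = 9))
  k <- round(40 * fs) # constructed 40 s lag with a 30 s bound
  pet <- physioTrace(c(rep(p[1], k), p)[seq_along(p)], fs = fs)
  rvt <- physioTrace(-p, fs = fs)
  res <- bestNegativeShift(pet, rvt, maxShift = 30)
  expect_equal(res@shift, -30)
  expect_true(res@clipped)

  a <- physioTrace(p, fs = fs)
  lagged <- physioTrace(c(rep(p[1], k), p)[seq_along(p)], fs = fs)
  res2 <- bestPositiveShift(a, lagged, maxShift = 30)
  expect_equal(res2@shift, 30)
  expect_true(res2@clipped)
})

test_that("positive shift search mirrors the negative one", {
  fs <- 10
  p <- samples(smoothTrace(2000, fs = fs, seed = 5))
  ident <- physioTrace(p, fs = fs)
  res0 <- bestPositiveShift(ident, ident)
  expect_equal(res0@shift, 0)
  expect_gt(res0@score, 0.999999)

  # a +5 s construction: b lags a by 5 s, so a must be shifted later
  k <- 50
  b <- physioTrace(c(rep(p[1], k), p)[seq_along(p)], fs = fs)
  res <- bestPositiveShift(ident, b, maxShift = 30)
  expect_equal(res@shift, 5)

  # anti-correlated pair (slow oscillation, so no allowed shift can turn
  # the correlation positive): negative score reported, no error
  slow <- sin(2 * pi * (0:1999) / (150 * fs))
  res2 <- bestPositiveShift(
    physioTrace(slow + 0.01 * p, fs = fs),
    physioTrace(-slow, fs = fs),
    maxShift = 5
  )
  expect_lt(res2@score, 0)

  expect_error(bestNegativeShift(physioTrace(rep(1, 100), 10), ident), "constant")
})

test_that("applyShift trims both traces to common support", {
  p <- physioTrace(as.numeric(1:100), fs = 10)
  q <- physioTrace(as.numeric(101:200), fs = 10)
  out <- applyShift(p, q, -1) # 10 samples
  expect_equal(nSamples(out$a), 90)
  expect_equal(samples(out$a), as.numeric(11:100))
  expect_equal(samples(out$b), as.numeric(101:190))
})

test_that("znorm gives population mean 0 / SD 1 and is affine-invariant", {
  tr <- physioTrace(c(1, 2, 3), fs = 10)
  z <- znorm(tr)
  expect_equal(mean(samples(z)), 0)
  expect_equal(sqrt(mean(samples(z)^2)), 1)
  expect_identical(traceUnits(z), "zscore")
  expect_equal(samples(znorm(z)), samples(z), tolerance = 1e-12)

  x <- smoothTrace(500, seed = 7)
  ax <- x
  ax@samples <- 3.2 * x@samples - 17
  expect_equal(samples(znorm(ax)), samples(znorm(x)), tolerance = 1e-12)
  expect_error(znorm(physioTrace(rep(2, 10), 10)), "constant")
})

test_that("min-max rescaling maps target extrema onto the measured block range", {
  measured <- physioTrace(c(seq(30, 40, length.out = 50), seq(40, 31, length.out = 50)),
    fs = 10, units = "mmHg"
  )
  blocks <- data.frame(
    trial = 1, start_sample = 1L, end_sample = 100L,
    quality = "high", delta = 8
  )
  target <- physioTrace(c(0, 0.5, 1), fs = 10, units = "zscore")
  out <- rescaleMinmax(target, measured, blocks, k = 1)
  expect_equal(samples(out), c(30, 35, 40))
  expect_identical(traceUnits(out), "mmHg")

  # affine invariance of the target
  t2 <- target
  t2@samples <- 5 * target@samples + 2
  expect_equal(samples(rescaleMinmax(t2, measured, blocks, 1)), c(30, 35, 40))

  expect_error(
    rescaleMinmax(target, measured, transform(blocks, quality = "low"), 1),
    "high-quality"
  )
  flat <- physioTrace(rep(35, 100), fs = 10, units = "mmHg")
  expect_error(rescaleMinmax(target, flat, blocks, 1), "degenerate")
})

test_that("the rescaling interval is non-shrinking in the number of blocks", {
  # second hold reaches higher end-tidal values than the first
  m <- c(
    35 + 3 * sin(seq(0, pi, length.out = 101)), # block 1 peaks at 38
    35 + 8 * sin(seq(0, pi, length.out = 101)), # block 2 peaks at 43
    35 + 5 * sin(seq(0, pi, length.out = 101))
  )
  measured <- physioTrace(m, fs = 10, units = "mmHg")
  blocks <- data.frame(
    trial = 1:3, start_sample = c(1L, 102L, 203L),
    end_sample = c(101L, 202L, 303L), quality = "high", delta = 7
  )
  target <- smoothTrace(300, seed = 2)
  target@samples <- target@samples - min(target@samples) + 0.1
  r1 <- rescaleMinmax(target, measured, blocks, 1)
  r2 <- rescaleMinmax(target, measured, blocks, 2)
  r3 <- rescaleMinmax(target, measured, blocks, 3)
  expect_gte(max(samples(r2)), max(samples(r1)))
  expect_gte(max(samples(r3)), max(samples(r2)))
  expect_lte(min(samples(r2)), min(samples(r1)))

  # "first k sequential": a skipped block breaks the sequence, leaving no
  # run of two consecutive high-quality blocks
  blocks2 <- blocks
  blocks2$quality[2] <- "skipped"
  expect_error(rescaleMinmax(target, measured, blocks2, 2), "sequential")
})
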