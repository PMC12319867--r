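test_that("percent signal change has the right arithmetic and mask handling", {
  bold <- array(500, dim = c(2, 2, 1, 10))
  bold[2, 1, 1, ] <- c(900, 1100)[c(1, 2, 1, 2, 1, 2, 1, 2, 1, 2)]
  bold[2, 2, 1, ] <- 0 # zero-mean voxel: must be excluded
  ps <- percentSignalChange(bold)
  expect_equal(ps$psc[1, 1, 1, ], rep(0, 10))
  expect_equal(sort(unique(ps$psc[2, 1, 1, ])), c(-10, 10))
  expect_false(ps$mask[2, 2, 1])
  expect_true(ps$mask[1, 1, 1])
  expect_equal(mean(ps$psc[2, 1, 1, ]), 0)
})

test_that("bulk alignment finds constructed global shifts", {
  reg <- smoothTrace(4000, fs = 10, seed = 13)
  tt <- traceTimes(reg)
  TR <- 1.5
  tvol <- (0:179) * TR
  gm <- approx(tt, samples(reg), xout = tvol - 6, rule = 2)$y
  res <- bulkAlign(reg, gm, TR, bound = 30, step = 0.3)
  expect_equal(res@shift, 6)
  res0 <- bulkAlign(reg, approx(tt, samples(reg), xout = tvol, rule = 2)$y, TR)
  expect_equal(res0@shift, 0)
  # anti-correlated signal: negative optimum score is reported, not an error
  resn <- bulkAlign(reg, -gm, TR, bound = 3, step = 0.3)
  expect_true(is.finite(resn@score))
})

test_that("the lag family has the documented geometry", {
  reg <- smoothTrace(4000, fs = 10, seed = 17)
  lf <- lagFamily(reg, cvrConfig(), TR = 1.5, nVolumes = 150)
  expect_equal(ncol(lf$family), 61) # +/-9 s at 0.3 s
  expect_equal(
    ncol(lagFamily(reg, cvrConfig(pathology = TRUE), 1.5, 150)$family),
    101
  ) # +/-15 s
  # the zero-lag column is the plain TR resampling
  plain <- approx(traceTimes(reg), samples(reg), xout = (0:149) * 1.5)$y
  expect_equal(lf$family[, which(lf$lags == 0)], plain, tolerance = 1e-12)
  # +l then -l returns the original on interior samples
  l <- 3
  sh <- lagFamily(reg, cvrConfig(), 1.5, 150, bulkShift = l)$family[, which(lf$lags == -l)]
  expect_equal(sh[10:140], plain[10:140], tolerance = 1e-9)
})

test_that("fitVoxel recovers noiseless construction and matches a brute-force oracle", {
  set.seed(23)
  reg <- smoothTrace(4000, fs = 10, seed = 19)
  TR <- 1.5
  nv <- 150
  lf <- lagFamily(reg, cvrConfig(), TR, nv)
  tvol <- (0:(nv - 1)) * TR
  x_true <- approx(traceTimes(reg), samples(reg), xout = tvol - 2.1, rule = 2)$y
  drift <- 0.5 * (tvol / max(tvol))^2 - 0.2 * tvol / max(tvol)
  y <- 0.3 * x_true + 4 * drift
  f <- fitVoxel(y, lf)
  expect_equal(f$amplitude, 0.3, tolerance = 1e-6)
  expect_lte(abs(f$delay - 2.1), 0.15) # half a grid step
  expect_false(f$atBoundary)

  # pure drift: near-zero amplitude and R2 dominated by the nuisance
  f0 <- fitVoxel(4 * drift + rnorm(nv, 0, 1e-8), lf)
  expect_lt(abs(f0$amplitude), 1e-6)

  # brute-force oracle: per-lag lm, pick max R2
  nuis <- breathCVR:::.legendreBasis(nv, 4)
  for (rep in 1:20) {
    amp <- runif(1, -0.5, 0.5)
    dtrue <- sample(lf$lags, 1)
    yv <- amp * lf$family[, which(lf$lags == dtrue)] +
      nuis %*% rnorm(5, 0, 0.3) + rnorm(nv, 0, 0.05)
    r2 <- sapply(seq_along(lf$lags), function(j) {
      summary(lm(yv ~ lf$family[, j] + nuis - 1))$r.squared
    })
    bestr2 <- max(r2)
    fv <- fitVoxel(as.vector(yv), lf)
    j_star <- which(lf$lags == fv$lag)
    expect_equal(r2[j_star], bestr2, tolerance = 1e-10) # same optimum
    bref <- coef(lm(yv ~ lf$family[, j_star] + nuis - 1))[1]
    expect_lt(abs(fv$amplitude - bref), 1e-8)
  }
})

test_that("amplitude is equivariant to regressor scale and invariant to BOLD scale", {
  sp <- smallPhantom()
  maps <- suppressWarnings(mapCvr(sp$ph$bold, sp$ph$mask, sp$ph$gmMask, sp$reg,
    cvrConfig(),
    TR = sp$spec$TR
  ))
  reg2 <- sp$reg
  reg2@samples <- sp$reg@samples * 2
  maps2 <- suppressWarnings(mapCvr(sp$ph$bold, sp$ph$mask, sp$ph$gmMask, reg2,
    cvrConfig(),
    TR = sp$spec$TR
  ))
  expect_equal(maps2@amplitude, maps@amplitude / 2, tolerance = 1e-6)

  maps3 <- suppressWarnings(mapCvr(sp$ph$bold * 3, sp$ph$mask, sp$ph$gmMask, sp$reg,
    cvrConfig(),
    TR = sp$spec$TR
  ))
  expect_equal(maps3@amplitude, maps@amplitude, tolerance = 1e-9)
})

test_that("mapCvr recovers the phantom fields and normalizes delay to the GM median", {
  sp <- smallPhantom()
  maps <- suppressWarnings(mapCvr(sp$ph$bold, sp$ph$mask, sp$ph$gmMask, sp$reg,
    cvrConfig(),
    TR = sp$spec$TR
  ))
  expect_lt(max(abs(maps@amplitude - sp$ph$truth$amplitude), na.rm = TRUE), 0.01)
  expect_lte(max(abs(maps@delay - sp$ph$truth$delay), na.rm = TRUE), 0.3)
  # delays are exact lag-grid multiples relative to the bulk shift
  rel <- (maps@delay - maps@bulkShift) / 0.3
  expect_lt(max(abs(rel - round(rel)), na.rm = TRUE), 1e-9)
  # normalized delay has zero GM median (within a grid step)
  gm_sel <- sp$ph$gmMask & maps@mask
  expect_lte(abs(median(maps@delayNormalized[gm_sel], na.rm = TRUE)), 0.3)

  expect_error(
    mapCvr(sp$ph$bold, sp$ph$mask, sp$ph$gmMask,
      znorm(sp$reg), cvrConfig(),
      TR = sp$spec$TR
    ),
    "mmHg"
  )
  expect_error(
    mapCvr(sp$ph$bold, sp$ph$mask, array(FALSE, dim(sp$ph$gmMask)),
      sp$reg, cvrConfig(),
      TR = sp$spec$TR
    ),
    "gray-matter"
  )
})

test_that("extreme-delay clustering respects size and connectivity rules", {
  d <- array(0, dim = c(10, 10, 5))
  d[2:4, 2:4, 2:3] <- 12 # 18-voxel block: retained
  d[8, 8, 1] <- 14 # scattered singles: removed
  d[1, 8, 5] <- 14
  m <- extremeDelayMask(d, threshold = 10, minCluster = 15)
  expect_equal(sum(m), 18)
  expect_true(all(m[2:4, 2:4, 2:3]))
  expect_false(m[8, 8, 1])

  # two face-touching 8-voxel groups merge into one 16-voxel cluster
  d2 <- array(0, dim = c(10, 10, 4))
  d2[1:2, 1:2, 1:2] <- 11
  d2[3:4, 1:2, 1:2] <- 11
  expect_equal(sum(extremeDelayMask(d2)), 16)
  # corner-touching only: not connected under face connectivity
  d3 <- array(0, dim = c(10, 10, 4))
  d3[1:2, 1:2, 1:2] <- 11
  d3[3:4, 3:4, 3:4] <- 11
  expect_equal(sum(extremeDelayMask(d3)), 0)
  expect_equal(sum(extremeDelayMask(d3, minCluster = 8)), 16)
})
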