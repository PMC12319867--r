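test_that("Fisher z is atanh with its symmetry and domain contract", {
  expect_equal(fisherZ(0), 0)
  expect_equal(fisherZ(0.5), 0.5493061, tolerance = 1e-6)
  r <- runif(10, -0.99, 0.99)
  expect_equal(fisherZ(-r), -fisherZ(r))
  expect_error(fisherZ(1), "< 1")
})

test_that("trace metrics match hand-computed values", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(1.5, 1.5, 3.5, 3.5, 6)
  m <- traceMetrics(a, b, peakIndices = c(3, 5))
  # independent recomputation from the definitions
  expect_equal(m$mae, mean(abs(a - b)))
  expect_equal(m$rmse, sqrt(mean((a - b)^2)))
  expect_equal(m$rmse_at_peaks, sqrt(mean(c(0.5, 1)^2)))
  expect_equal(m$fisher_z, atanh(cor(a, b)), tolerance = 1e-12)

  ident <- traceMetrics(a, a)
  expect_equal(ident$mae, 0)
  expect_equal(ident$rmse, 0)
  expect_true(is.finite(ident$fisher_z)) # capped, not infinite
  expect_true(is.na(ident$rmse_at_peaks))

  off <- traceMetrics(a, a + 2)
  expect_equal(off$mae, 2)
  expect_equal(off$rmse, 2)
  expect_equal(off$fisher_z, ident$fisher_z) # correlation unchanged
})

test_that("map metrics exclude exactly the top 2% of truth voxels", {
  dims <- c(10, 10, 1)
  gm <- array(TRUE, dims)
  truth <- array(as.numeric(1:100), dims) # distinct values
  test <- truth + 0.5
  m <- mapMetrics(test, truth, gm)
  expect_equal(m$nVoxels, 98) # exactly 2 excluded
  expect_equal(m$mae, 0.5)
  # large outliers only above the 98th percentile leave metrics unchanged
  test2 <- test
  test2[truth > 98.5] <- 1e6
  m2 <- mapMetrics(test2, truth, gm)
  expect_equal(m2$mae, m$mae)
  expect_equal(m2$rmse, m$rmse)
  expect_equal(mapMetrics(truth, truth, gm)$mae, 0)
})

test_that("group MAE maps take absolute differences before averaging", {
  dims <- c(4, 4, 2)
  gm <- array(TRUE, dims)
  t1 <- array(0.2, dims)
  same <- maeMap(list(list(test = t1, truth = t1)), gm)
  expect_true(all(same$maeMap == 0))
  expect_equal(same$gmMedian, 0)
  p1 <- list(test = t1 + 1, truth = t1)
  p2 <- list(test = t1 - 1, truth = t1)
  both <- maeMap(list(p1, p2), gm)
  expect_true(all(both$maeMap == 1)) # |+1| and |-1| average to 1, not 0
  expect_error(
    maeMap(list(list(test = t1, truth = array(0, c(2, 2, 2)))), gm),
    "grids differ"
  )
})

test_that("Spearman rank correlation of medians behaves on the standard cases", {
  expect_equal(spearmanRankMedians(1:5, c(2, 4, 6, 8, 10))$rho, 1)
  expect_equal(spearmanRankMedians(1:5, 5:1)$rho, -1)
  expect_equal(spearmanRankMedians(c(1, 2, 3, 4), c(1, 3, 2, 4))$rho, 0.8)
  expect_error(spearmanRankMedians(rep(1, 4), 1:4), "constant")
  expect_error(spearmanRankMedians(1:2, 2:1), ">= 3")
})

test_that("Dice coefficient covers identity, disjointness and partial overlap", {
  a <- array(FALSE, c(5, 5, 2))
  b <- a
  a[1:10] <- TRUE
  b[7:16] <- TRUE # |a| = |b| = 10, overlap 4
  expect_equal(dice(a, b), 0.4)
  expect_equal(dice(a, a), 1)
  b2 <- array(FALSE, c(5, 5, 2))
  b2[20:25] <- TRUE
  expect_equal(dice(a, b2), 0)
  expect_warning(d0 <- dice(array(FALSE, c(2, 2, 1)), array(FALSE, c(2, 2, 1))), "empty")
  expect_equal(d0, 1)
})

test_that("spatial correlation in gray matter equals an independent recomputation", {
  set.seed(9)
  dims <- c(6, 6, 3)
  gm <- array(runif(prod(dims)) > 0.3, dims)
  a <- array(rnorm(prod(dims)), dims)
  b <- a + array(rnorm(prod(dims), 0, 0.5), dims)
  expect_equal(spatialCorrGm(a, b, gm), cor(a[gm], b[gm]), tolerance = 1e-12)
  expect_equal(spatialCorrGm(a, a, gm), 1)
  expect_equal(spatialCorrGm(a, -a, gm), -1)
  expect_error(spatialCorrGm(array(1, dims), a, gm), "constant")
})

test_that("paired-test helpers agree with the base implementations", {
  set.seed(4)
  x <- rnorm(12)
  y <- x + rnorm(12, 0.3)
  p <- pairedT(x, y)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(p$p, ref$p.value)
  expect_equal(p$t, unname(ref$statistic))

  set.seed(5)
  vals <- c(x, y, y + rnorm(12, 0.1, 0.2))
  cond <- rep(c("a", "b", "c"), each = 12)
  id <- rep(1:12, 3)
  tbl <- pairwiseBonferroni(vals, cond, id)
  expect_equal(nrow(tbl), 3)
  expect_true(all(tbl$p_bonferroni >= tbl$p))
  expect_true(all(tbl$p_bonferroni <= 1))
})
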