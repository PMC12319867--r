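#' Fisher z transform of a correlation
#'
#' `z = atanh(r)`; used to average and test correlations on an
#' approximately normal scale ("normalized correlation").
#'
#' @param r correlation(s) with `|r| < 1`.
#' @return `atanh(r)`.
#' @export
fisherZ <- function(r) {
  if (any(abs(r) >= 1)) stop("fisherZ: |r| must be < 1")
  atanh(r)
}

#' Compare two traces: correlation and error metrics
#'
#' Computes Fisher-z-transformed Pearson correlation, MAE, RMSE and RMSE
#' restricted to the reference trace's peaks. A correlation of exactly
#' +/-1 is capped at `+/-(1 - 1e-12)` before the z transform.
#'
#' @param a reference trace (numeric vector or [PhysioTrace-class]); peaks
#'   are defined on this trace.
#' @param b comparison trace, equal length.
#' @param peakIndices indices of the reference peaks; empty means
#'   `rmse_at_peaks` is reported as NA.
#' @return A list: `fisher_z`, `mae`, `rmse`, `rmse_at_peaks`.
#' @export
traceMetrics <- function(a, b, peakIndices = integer()) {
  if (is(a, "PhysioTrace")) a <- a@samples
  if (is(b, "PhysioTrace")) b <- b@samples
  stopifnot(length(a) == length(b))
  r <- stats::cor(a, b)
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  list(
    fisher_z = atanh(r),
    mae = mean(abs(a - b)),
    rmse = sqrt(mean((a - b)^2)),
    rmse_at_peaks = if (length(peakIndices)) {
      sqrt(mean((a[peakIndices] - b[peakIndices])^2))
    } else {
      NA_real_
    }
  )
}

#' Compare a CVR map to a ground-truth map in gray matter
#'
#' Metrics over gray-matter voxels after excluding voxels whose
#' ground-truth amplitude exceeds its 98th percentile within gray matter
#' (extreme values, typically vascular, would otherwise dominate the
#' error terms).
#'
#' @param test,truth 3D maps on a common grid.
#' @param gmMask 3D logical gray-matter mask.
#' @param excludePct percentile cutoff applied to the truth map, default 98.
#' @return A list: `fisher_z`, `mae`, `rmse`, `nVoxels`.
#' @export
mapMetrics <- function(test, truth, gmMask, excludePct = 98) {
  stopifnot(all(dim(test) == dim(truth)), all(dim(test) == dim(gmMask)))
  sel <- gmMask & !is.na(test) & !is.na(truth)
  if (!any(sel)) stop("mapMetrics: empty gray-matter selection")
  q <- stats::quantile(truth[sel], excludePct / 100, names = FALSE)
  sel <- sel & truth <= q
  a <- truth[sel]
  b <- test[sel]
  if (!length(a)) stop("mapMetrics: no voxels left after percentile exclusion")
  m <- traceMetrics(a, b)
  list(fisher_z = m$fisher_z, mae = m$mae, rmse = m$rmse, nVoxels = length(a))
}

#' Group-level MAE map and gray-matter median
#'
#' Voxelwise mean absolute error across map pairs (absolute differences
#' are taken before averaging), plus the median over gray matter.
#'
#' @param pairs list of `list(test =, truth =)` 3D map pairs on one grid.
#' @param gmMask 3D logical gray-matter mask.
#' @return A list: `maeMap` (3D array) and `gmMedian` (scalar).
#' @export
maeMap <- function(pairs, gmMask) {
  if (!length(pairs)) stop("maeMap: no map pairs")
  d <- dim(pairs[[1]]$test)
  for (p in pairs) {
    if (!all(dim(p$test) == d) || !all(dim(p$truth) == d)) {
      stop("maeMap: map grids differ")
    }
  }
  acc <- array(0, d)
  for (p in pairs) acc <- acc + abs(p$test - p$truth)
  mae <- acc / length(pairs)
  list(maeMap = mae, gmMedian = stats::median(mae[gmMask], na.rm = TRUE))
}

#' Spearman rank correlation of median CVR amplitudes
#'
#' Tests whether a surrogate regressor preserves the ranking of
#' gray-matter median CVR amplitudes across scans.
#'
#' @param truthMedians,testMedians equal-length numeric vectors (>= 3).
#' @return A list: `rho` and two-sided `p`.
#' @export
spearmanRankMedians <- function(truthMedians, testMedians) {
  stopifnot(length(truthMedians) == length(testMedians))
  if (length(truthMedians) < 3) stop("spearmanRankMedians: need >= 3 values")
  if (stats::sd(truthMedians) == 0 || stats::sd(testMedians) == 0) {
    stop("spearmanRankMedians: constant input vector")
  }
  ct <- suppressWarnings(
    stats::cor.test(truthMedians, testMedians, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Dice similarity coefficient of two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`. Two empty masks agree perfectly on
#' absence and return 1 (with a warning).
#'
#' @param a,b logical (or 0/1) arrays on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  a <- as.logical(a)
  b <- as.logical(b)
  na <- sum(a)
  nb <- sum(b)
  if (na + nb == 0) {
    warning("dice: both masks empty; returning 1")
    return(1)
  }
  2 * sum(a & b) / (na + nb)
}

#' Spatial correlation of two maps in gray matter
#'
#' @param a,b 3D maps on a common grid.
#' @param gmMask 3D logical gray-matter mask (nonempty; maps nonconstant
#'   within it).
#' @return Pearson correlation over gray-matter voxels.
#' @export
spatialCorrGm <- function(a, b, gmMask) {
  stopifnot(all(dim(a) == dim(b)), all(dim(a) == dim(gmMask)))
  sel <- gmMask & !is.na(a) & !is.na(b)
  if (!any(sel)) stop("spatialCorrGm: empty mask")
  x <- a[sel]
  y <- b[sel]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("spatialCorrGm: constant map in mask")
  stats::cor(x, y)
}

#' Thin paired-comparison helpers
#'
#' Convenience wrappers for the standard tests used when comparing
#' regressor or map metrics across methods: a two-sided paired t-test and
#' pairwise Bonferroni-corrected paired t-tests across conditions.
#'
#' @param x,y paired numeric vectors.
#' @return `pairedT()` returns a list with `t`, `df`, `p`;
#'   `pairwiseBonferroni()` a data.frame of pairwise comparisons.
#' @export
pairedT <- function(x, y) {
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' @rdname pairedT
#' @param values numeric vector of measurements.
#' @param condition factor of conditions (paired by `id`).
#' @param id factor identifying the paired unit.
#' @export
pairwiseBonferroni <- function(values, condition, id) {
  condition <- as.factor(condition)
  lev <- levels(condition)
  cmb <- utils::combn(lev, 2)
  res <- lapply(seq_len(ncol(cmb)), function(i) {
    a <- cmb[1, i]
    b <- cmb[2, i]
    ids <- intersect(id[condition == a], id[condition == b])
    xa <- values[condition == a][match(ids, id[condition == a])]
    xb <- values[condition == b][match(ids, id[condition == b])]
    ht <- stats::t.test(xa, xb, paired = TRUE)
    data.frame(a = a, b = b, t = unname(ht$statistic), p = ht$p.value)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(out$p * nrow(out), 1)
  out
}
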