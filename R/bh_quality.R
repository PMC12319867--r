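#' Breath-hold task timing
#'
#' Builds and validates the per-trial timing table: ordered trials with
#' paced-breathing start, hold start/end and recovery end (all in seconds),
#' plus a flag for intentionally skipped trials. For a skipped trial the
#' "hold" window is the rest period that replaced it (used only to place
#' block boundaries).
#'
#' @param paced_start,hold_start,hold_end,recovery_end numeric vectors, s.
#' @param skipped logical vector, default all FALSE.
#' @return A validated `data.frame` with one row per trial.
#' @export
taskTiming <- function(paced_start, hold_start, hold_end, recovery_end,
                       skipped = rep(FALSE, length(hold_start))) {
  tt <- data.frame(
    paced_start = paced_start, hold_start = hold_start,
    hold_end = hold_end, recovery_end = recovery_end, skipped = skipped
  )
  within_ok <- with(tt, paced_start <= hold_start & hold_start <= hold_end &
    hold_end <= recovery_end)
  if (!all(within_ok)) stop("taskTiming: trial times must be ordered within each trial")
  if (nrow(tt) > 1 && any(tt$recovery_end[-nrow(tt)] > tt$paced_start[-1])) {
    stop("taskTiming: trials must be strictly increasing and non-overlapping")
  }
  if (any(!tt$skipped & tt$hold_end <= tt$hold_start)) {
    stop("taskTiming: hold_end must exceed hold_start for non-skipped trials")
  }
  tt
}

#' Read / write a task-timing TSV
#' @param path TSV path with columns paced_start, hold_start, hold_end,
#'   recovery_end, skipped.
#' @return `readTaskTiming()` returns the validated timing `data.frame`.
#' @export
readTaskTiming <- function(path) {
  df <- utils::read.delim(path)
  taskTiming(df$paced_start, df$hold_start, df$hold_end, df$recovery_end,
    skipped = as.logical(df$skipped)
  )
}

#' @rdname readTaskTiming
#' @param timing a timing `data.frame` from [taskTiming()].
#' @export
writeTaskTiming <- function(timing, path) {
  utils::write.table(timing, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-trial end-tidal CO2 changes
#'
#' For each non-skipped trial, pairs the last end-tidal peak at or before
#' the hold start with the first peak at or after the hold end and reports
#' the CO2 change `delta = post - pre` (mmHg). A large delta indicates a
#' well-performed breath hold; a trial with no flanking peak on either side
#' gets a missing delta (and will be graded low).
#'
#' When the CO2 trace carries a measurement delay relative to the task
#' clock (sampling-line transit; commonly 15-25 s), pass it as `delay`:
#' both hold boundaries are shifted by `delay` before pairing. `guard`
#' loosens the post-hold boundary by a few seconds to tolerate error in an
#' estimated delay.
#'
#' @param co2 raw CO2 [PhysioTrace-class] (peak values are read from it).
#' @param peaks end-tidal [PeakSet-class].
#' @param timing [taskTiming()] table.
#' @param delay measurement delay of the CO2 trace, s (default 0).
#' @param guard tolerance subtracted from the post-hold (and added to the
#'   pre-hold) pairing boundary, s (default 0).
#' @param window optional width in seconds. When given, delay-robust
#'   pairing is used instead: within `window` seconds after the
#'   (delay-shifted) hold end, the post-hold peak is the first peak whose
#'   preceding inter-peak gap is at least 70% of the hold duration (the
#'   apnea leaves such a gap; paced breaths, only ~6 s apart, never do),
#'   falling back to the largest peak in the window. The pre-hold peak is
#'   the one immediately preceding it. This tolerates measurement delays
#'   that exceed the hold duration, where strict boundary pairing picks
#'   the wrong breath.
#' @return A `data.frame` with columns `trial`, `pre_peak`, `post_peak`,
#'   `delta` (mmHg; NA when missing) and `skipped`.
#' @export
trialDeltas <- function(co2, peaks, timing, delay = 0, guard = 0, window = NULL) {
  stopifnot(is(co2, "PhysioTrace"), is(peaks, "PeakSet"))
  if (!length(peaks@indices)) stop("trialDeltas: empty peak set")
  pk_t <- co2@t0 + (peaks@indices - 1) / co2@fs
  pk_v <- co2@samples[peaks@indices]
  n <- nrow(timing)
  pre <- post <- delta <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (timing$skipped[i]) next
    if (is.null(window)) {
      lo <- timing$hold_start[i] + delay + guard
      hi <- timing$hold_end[i] + delay - guard
      ip <- which(pk_t <= lo)
      iq <- which(pk_t >= hi)
      if (length(ip)) pre[i] <- pk_v[max(ip)]
      if (length(iq)) post[i] <- pk_v[min(iq)]
    } else {
      he <- timing$hold_end[i] + delay
      hold_dur <- timing$hold_end[i] - timing$hold_start[i]
      iw <- which(pk_t > he & pk_t <= he + window)
      # the apnea leaves an inter-peak gap of at least the hold duration;
      # the post-hold exhalation is the first breath peak after that gap
      # (paced breaths are only ~6 s apart, so they never qualify)
      ipost <- NA_integer_
      for (j in iw) {
        if (j > 1 && (pk_t[j] - pk_t[j - 1]) >= 0.7 * hold_dur) {
          ipost <- j
          break
        }
      }
      # fallback when no gap qualifies: the largest peak in the window
      if (is.na(ipost) && length(iw)) ipost <- iw[which.max(pk_v[iw])]
      if (!is.na(ipost)) {
        post[i] <- pk_v[ipost]
        if (ipost > 1) pre[i] <- pk_v[ipost - 1]
      }
    }
    if (!is.na(pre[i]) && !is.na(post[i])) delta[i] <- post[i] - pre[i]
  }
  data.frame(
    trial = seq_len(n), pre_peak = pre, post_peak = post,
    delta = delta, skipped = timing$skipped
  )
}

#' Quality threshold from positive CO2 changes
#'
#' The threshold below which a breath hold is graded low quality:
#' mean minus one standard deviation of the positive per-trial CO2 changes.
#' The sample SD (n-1 denominator) is the default; a single positive delta
#' gives SD 0.
#'
#' @param deltas numeric vector of per-trial CO2 changes, mmHg (NAs and
#'   non-positive values are excluded from the statistics).
#' @param sdDenominator `"n-1"` (sample SD, default) or `"n"`.
#' @return The threshold in mmHg.
#' @examples
#' qualityThreshold(c(6.73 - 3.13, 6.73, 6.73 + 3.13)) # 3.60
#' @export
qualityThreshold <- function(deltas, sdDenominator = c("n-1", "n")) {
  sdDenominator <- match.arg(sdDenominator)
  pos <- deltas[!is.na(deltas) & deltas > 0]
  if (!length(pos)) stop("qualityThreshold: no usable trials (no positive CO2 changes)")
  m <- mean(pos)
  s <- if (length(pos) == 1) 0 else stats::sd(pos)
  if (sdDenominator == "n") s <- s * sqrt((length(pos) - 1) / length(pos))
  m - s
}

#' Classify breath-hold trials
#'
#' A trial is high quality iff its CO2 change exceeds the threshold (with a
#' 1e-9 numeric tolerance, so degenerate all-equal deltas grade high).
#' Missing deltas grade low. Intentionally skipped trials are labeled
#' `"skipped"`; downstream training treats them as high quality, because a
#' skipped hold implies no erroneous CO2 data, merely no hypercapnic event.
#'
#' @param changes `data.frame` from [trialDeltas()].
#' @param threshold mmHg, from [qualityThreshold()].
#' @return Character vector of labels `"high"` / `"low"` / `"skipped"`.
#' @export
classifyTrials <- function(changes, threshold) {
  eps <- 1e-9
  labels <- ifelse(is.na(changes$delta) | changes$delta <= threshold - eps,
    "low", "high"
  )
  labels[changes$skipped] <- "skipped"
  labels
}

#' Partition a recording into breath-hold blocks
#'
#' Each block contains exactly one trial and runs from the halfway point
#' between the previous trial's hold end and this trial's hold start to the
#' halfway point on the other side. The first block extends to the trace
#' start and the last to the trace end, so the blocks tile the trace.
#'
#' @param timing [taskTiming()] table.
#' @param labels per-trial quality labels from [classifyTrials()].
#' @param grid a [PhysioTrace-class] on the working (10 Hz) grid; block
#'   boundaries are expressed as sample indices on this grid.
#' @param deltas optional per-trial deltas carried into the result.
#' @return A `data.frame` with columns `trial`, `start_sample`,
#'   `end_sample`, `quality`, `delta`.
#' @export
buildBlocks <- function(timing, labels, grid, deltas = NULL) {
  stopifnot(is(grid, "PhysioTrace"))
  n <- nrow(timing)
  if (n < 1) stop("buildBlocks: need at least one trial")
  if (length(labels) != n) stop("buildBlocks: one label per trial required")
  nsamp <- length(grid@samples)
  t_end <- grid@t0 + (nsamp - 1) / grid@fs
  cuts <- numeric(n + 1)
  cuts[1] <- grid@t0
  cuts[n + 1] <- t_end
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      cuts[i + 1] <- (timing$hold_end[i] + timing$hold_start[i + 1]) / 2
    }
  }
  if (any(diff(cuts) <= 0)) stop("buildBlocks: overlapping or out-of-range trials")
  to_idx <- function(t) pmin(pmax(round((t - grid@t0) * grid@fs) + 1, 1), nsamp)
  start <- to_idx(cuts[-(n + 1)])
  end <- to_idx(cuts[-1])
  if (n > 1) start[-1] <- end[-n] + 1L # blocks tile without overlap
  data.frame(
    trial = seq_len(n), start_sample = as.integer(start),
    end_sample = as.integer(end), quality = labels,
    delta = if (is.null(deltas)) NA_real_ else deltas
  )
}

#' Randomly segment eligible blocks into training segments
#'
#' Draws 1 to 4 non-overlapping segments, each a run of at least 2
#' consecutive blocks whose labels are `"high"` or `"skipped"`; low-quality
#' blocks are never included. Deterministic given the seed.
#'
#' @param blocks `data.frame` from [buildBlocks()].
#' @param seed integer RNG seed.
#' @param maxSegments maximum number of segments to draw, default 4.
#' @return A list of data.frames (rows of `blocks`), possibly empty (with a
#'   warning) when no eligible run of length >= 2 exists.
#' @export
segmentForTraining <- function(blocks, seed = 1L, maxSegments = 4L) {
  eligible <- blocks$quality %in% c("high", "skipped")
  r <- rle(eligible)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  runs <- data.frame(start = run_start, end = run_end)[r$values & r$lengths >= 2, , drop = FALSE]
  if (!nrow(runs)) {
    warning("segmentForTraining: no run of >= 2 consecutive eligible blocks")
    return(list())
  }
  pick1 <- function(v) v[sample.int(length(v), 1L)] # safe for length-1 v
  .withSeed(seed, {
    n_seg <- sample.int(min(maxSegments, 4L), 1L)
    segs <- list()
    # candidate sub-runs: track remaining free intervals within eligible runs
    free <- runs
    for (k in seq_len(n_seg)) {
      ok <- free[free$end - free$start + 1 >= 2, , drop = FALSE]
      if (!nrow(ok)) break
      ri <- sample.int(nrow(ok), 1L)
      lo <- ok$start[ri]
      hi <- ok$end[ri]
      len <- pick1(2:(hi - lo + 1))
      s0 <- pick1(lo:(hi - len + 1))
      segs[[length(segs) + 1]] <- blocks[s0:(s0 + len - 1), , drop = FALSE]
      # split the free interval around the drawn segment
      free <- free[free$start != ok$start[ri] | free$end != ok$end[ri], , drop = FALSE]
      if (s0 - lo >= 2) free <- rbind(free, data.frame(start = lo, end = s0 - 1))
      if (hi - (s0 + len - 1) >= 2) free <- rbind(free, data.frame(start = s0 + len, end = hi))
    }
    segs
  })
}

#' Per-trial quality-control report
#'
#' One row per trial (delta, threshold, label) plus a summary row per
#' recording, written as a tidy TSV when `path` is given.
#'
#' @param changes `data.frame` from [trialDeltas()].
#' @param threshold mmHg quality threshold.
#' @param labels labels from [classifyTrials()].
#' @param path optional output TSV path.
#' @return The report `data.frame`, invisibly when written to `path`.
#' @export
qcReport <- function(changes, threshold, labels, path = NULL) {
  rep <- data.frame(
    trial = changes$trial, delta_mmHg = changes$delta,
    threshold_mmHg = threshold, quality = labels
  )
  summary <- data.frame(
    trial = NA_integer_,
    delta_mmHg = mean(changes$delta[!is.na(changes$delta) & changes$delta > 0]),
    threshold_mmHg = threshold,
    quality = sprintf(
      "%d/%d high", sum(labels == "high"),
      sum(!changes$skipped)
    )
  )
  out <- rbind(rep, summary)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}
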