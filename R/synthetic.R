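#' Specification of a synthetic breath-hold physiology session
#'
#' Defines the task and physiology of a simulated breath-hold recording:
#' paced breathing at 3 s in / 3 s out, breath holds of 10-24 s flanked by
#' exhalations, end-tidal peaks rising by a per-hold CO2 delta (mean ~7,
#' SD ~3 mmHg), optional intentionally skipped trials (10% chance),
#' optional low-quality trials whose post-hold exhale peak is attenuated
#' (missed exhale / mouth breathing), and a capnograph measurement delay
#' relative to the respiration belt.
#'
#' Timing layout per trial: paced breathing (`pacedDuration`, ending with a
#' 2 s end-exhale pause), the hold, a 3 s exhale descent with the post-hold
#' exhale, then 12 s of deep recovery breathing. End-tidal values relax
#' back to baseline with time constant `tauEnvelope`.
#'
#' @param nTrials number of breath-hold trials, default 8.
#' @param pacedDuration paced-breathing duration per trial incl. the 2 s
#'   pre-hold exhale pause, s; default 20.
#' @param holdDurations candidate hold durations, s, sampled per trial.
#' @param baseline baseline end-tidal CO2, mmHg, default 38.
#' @param deltaMean,deltaSd per-hold CO2 increase distribution, mmHg.
#' @param skipProbability chance a trial is skipped and replaced by rest.
#' @param lowQualityTrials integer indices of trials with a suppressed
#'   post-hold exhale peak.
#' @param lowDeltaRange attenuated CO2-change range for low-quality trials.
#' @param measurementDelay capnograph delay relative to the belt, s,
#'   default 20 (typical sampling-line transit plus physiological lag).
#' @param tauEnvelope end-tidal relaxation time constant, s, default 20.
#' @param co2Noise,respNoise additive white-noise SD on the two traces.
#' @param fsRaw raw sampling rate, Hz, default 40.
#' @param co2Low inspiratory CO2 floor, mmHg, default 2.
#' @param endPad trailing paced breathing after the last trial, s.
#' @param seed integer RNG seed.
#' @return A classed list (`"SynthSpec"`).
#' @export
synthSpec <- function(nTrials = 8L, pacedDuration = 20, holdDurations = seq(10, 24, 2),
                      baseline = 38, deltaMean = 7, deltaSd = 3,
                      skipProbability = 0.1, lowQualityTrials = integer(),
                      lowDeltaRange = c(0.3, 1.2), measurementDelay = 20,
                      tauEnvelope = 20, co2Noise = 0, respNoise = 0.005,
                      fsRaw = 40, co2Low = 2, endPad = 15, seed = 1L) {
  if (skipProbability < 0 || skipProbability > 1) stop("skipProbability must be in [0,1]")
  if (any(holdDurations <= 0) || pacedDuration <= 0) stop("durations must be > 0")
  if (measurementDelay < 0) stop("measurementDelay must be >= 0")
  # the breathing window between trials must end on (or >= 3 s into) a 6 s
  # breath so the final pre-hold exhalation peak exists on the CO2 trace
  winmod <- (pacedDuration + 8) %% 6
  if (winmod != 0 && winmod < 3) {
    stop("pacedDuration + 8 must be a multiple of 6, or >= 3 modulo 6")
  }
  structure(
    list(
      nTrials = as.integer(nTrials), pacedDuration = pacedDuration,
      holdDurations = holdDurations, baseline = baseline,
      deltaMean = deltaMean, deltaSd = deltaSd,
      skipProbability = skipProbability,
      lowQualityTrials = as.integer(lowQualityTrials),
      lowDeltaRange = lowDeltaRange, measurementDelay = measurementDelay,
      tauEnvelope = tauEnvelope, co2Noise = co2Noise, respNoise = respNoise,
      fsRaw = fsRaw, co2Low = co2Low, endPad = endPad, seed = as.integer(seed)
    ),
    class = "SynthSpec"
  )
}

# Phase-duration constants of the synthetic trial (seconds).
.SYN_PAUSE <- 2      # end-exhale pause before the hold (belt at exhale level)
.SYN_DESCENT <- 3    # post-hold exhale descent on the belt
.SYN_DEEP <- 12      # deep recovery breathing
.SYN_CO2EXHALE <- 5  # width of the post-hold CO2 exhalation hump

#' Generate a synthetic breath-hold physiology session
#'
#' Builds raw exhaled-CO2 and respiration-belt traces with known per-trial
#' ground truth. The belt shows paced sinusoidal breathing, a flat trace
#' during each hold (entered after an exhalation), a deeper post-hold
#' exhale trough with no intervening breath maximum (the two-consecutive-
#' minima situation), and deep recovery breaths. The CO2 trace oscillates
#' between the inspiratory floor and the end-tidal envelope, with the
#' post-hold exhalation peak exceeding the pre-hold peak by the trial's
#' CO2 delta; it is delayed relative to the belt by the measurement delay.
#'
#' Ground-truth labels are obtained by applying the mean-minus-1-SD rule
#' to the constructed deltas, so a perfect extraction pipeline reproduces
#' them exactly.
#'
#' @param spec a [synthSpec()].
#' @return A list: `co2` and `resp` ([PhysioTrace-class], at `fsRaw`),
#'   `timing` ([taskTiming()] table), and `truth` (deltas, labels,
#'   threshold, the undelayed 10 Hz end-tidal envelope `petco2Ideal` in
#'   mmHg, ideal peak times/values, and the measurement delay).
#' @export
genPhysio <- function(spec) {
  stopifnot(inherits(spec, "SynthSpec"))
  .withSeed(spec$seed, .genPhysioImpl(spec))
}

.genPhysioImpl <- function(spec) {
  fs <- spec$fsRaw
  n <- spec$nTrials
  holds <- spec$holdDurations[sample.int(length(spec$holdDurations), n, replace = TRUE)]
  skipped <- stats::runif(n) < spec$skipProbability
  low <- rep(FALSE, n)
  low[spec$lowQualityTrials] <- TRUE
  low[skipped] <- FALSE
  # hypercapnia accumulates with apnea duration (~0.4 mmHg per second of
  # hold); the per-hold CO2 change is that trend plus trial-to-trial noise,
  # with marginal mean/SD matching deltaMean/deltaSd over the hold range
  slope <- spec$deltaMean / mean(spec$holdDurations)
  hold_var <- if (length(spec$holdDurations) > 1) stats::var(spec$holdDurations) else 0
  sd_resid <- sqrt(max(spec$deltaSd^2 - slope^2 * hold_var, 0))
  deltas <- pmax(slope * holds + stats::rnorm(n, 0, sd_resid), 0.5)
  deltas[low] <- stats::runif(sum(low), spec$lowDeltaRange[1], spec$lowDeltaRange[2])
  deltas[skipped] <- NA_real_

  # trial timing (task clock; t = 0 at the first paced-breathing onset)
  paced_start <- hold_start <- hold_end <- recovery_end <- numeric(n)
  t <- 0
  for (i in seq_len(n)) {
    paced_start[i] <- t
    hold_start[i] <- t + spec$pacedDuration
    hold_end[i] <- hold_start[i] + holds[i]
    recovery_end[i] <- hold_end[i] + .SYN_DESCENT + .SYN_DEEP
    t <- recovery_end[i]
  }
  timing <- taskTiming(paced_start, hold_start, hold_end, recovery_end, skipped)
  t_end <- recovery_end[n] + spec$endPad

  # extended clock: pre-roll of paced breathing long enough to cover the
  # measurement delay, rounded to whole breaths
  pre_roll <- 6 * ceiling((spec$measurementDelay + 12) / 6)
  ext_t0 <- -pre_roll
  n_ext <- round((t_end - ext_t0) * fs) + 1L
  tgrid <- ext_t0 + (seq_len(n_ext) - 1) / fs
  idx_of <- function(tt) round((tt - ext_t0) * fs) + 1L

  co2 <- rep(spec$co2Low, n_ext)
  resp <- numeric(n_ext)
  env_t <- ext_t0
  env_v <- spec$baseline
  env <- function(tt) spec$baseline + (env_v - spec$baseline) * exp(-(tt - env_t) / spec$tauEnvelope)
  peak_t <- numeric(0)
  peak_v <- numeric(0)

  # CO2 breathing humps over [a, b): 6 s breaths anchored at a, exhalation
  # peak 3 s into each breath at the current envelope value
  co2_breathe <- function(a, b) {
    s <- a
    while (b - s > 3 + 1e-9) { # partial breaths cut before their peak are
      e <- min(s + 6, b)       # left at the floor (no exhalation happened)
      ii <- idx_of(s):(idx_of(e) - 1L)
      tau <- tgrid[ii] - s
      pk <- env(s + 3)
      co2[ii] <<- spec$co2Low + (pk - spec$co2Low) * sin(pi * tau / 6)^4
      peak_t <<- c(peak_t, s + 3)
      peak_v <<- c(peak_v, pk)
      s <- s + 6
    }
  }
  # belt breathing over [a, b): cosine breaths starting and ending at the
  # exhale trough (3 s in / 3 s out)
  resp_breathe <- function(a, b, amp = 1) {
    ii <- idx_of(a):(idx_of(b) - 1L)
    resp[ii] <<- -amp * cos(2 * pi * (tgrid[ii] - a) / 6)
  }

  # pre-roll breathing up to the first trial's exhale pause
  co2_breathe(ext_t0, hold_start[1] - .SYN_PAUSE)
  resp_breathe(ext_t0, hold_start[1] - .SYN_PAUSE)

  for (i in seq_len(n)) {
    hs <- hold_start[i]
    he <- hold_end[i]
    nxt_pause <- if (i < n) hold_start[i + 1] - .SYN_PAUSE else t_end
    if (skipped[i]) {
      # rest period: breathing continues straight through the trial
      co2_breathe(hs - .SYN_PAUSE, nxt_pause)
      resp_breathe(hs - .SYN_PAUSE, nxt_pause)
      next
    }
    v_pre <- peak_v[length(peak_v)]
    v_post <- v_pre + deltas[i]

    # belt: exhale pause + hold, flat at the exhale trough with mild drift
    ii <- idx_of(hs - .SYN_PAUSE):(idx_of(he) - 1L)
    tau <- tgrid[ii] - (hs - .SYN_PAUSE)
    resp[ii] <- -1 + 0.15 * tau / (he - hs + .SYN_PAUSE)
    # post-hold exhale: smooth descent to a deeper trough
    ii <- idx_of(he):(idx_of(he + .SYN_DESCENT) - 1L)
    tau <- tgrid[ii] - he
    lvl <- -0.85
    resp[ii] <- lvl - (1.4 + lvl) * sin(pi * tau / (2 * .SYN_DESCENT))
    # deep recovery breaths, then paced breathing into the next trial
    resp_breathe(he + .SYN_DESCENT, he + .SYN_DESCENT + .SYN_DEEP, amp = 1.4)
    resp_breathe(he + .SYN_DESCENT + .SYN_DEEP, nxt_pause)

    # CO2: flat floor during pause + hold, then the post-hold exhalation hump
    ii <- idx_of(hs - .SYN_PAUSE):(idx_of(he) - 1L)
    co2[ii] <- spec$co2Low
    ii <- idx_of(he):(idx_of(he + .SYN_CO2EXHALE) - 1L)
    tau <- tgrid[ii] - he
    co2[ii] <- spec$co2Low + (v_post - spec$co2Low) * sin(pi * tau / .SYN_CO2EXHALE)^4
    peak_t <- c(peak_t, he + .SYN_CO2EXHALE / 2)
    peak_v <- c(peak_v, v_post)
    env_t <- he + .SYN_CO2EXHALE / 2
    env_v <- v_post
    # recovery breathing on CO2 resumes after the exhalation hump
    co2_breathe(he + .SYN_CO2EXHALE, nxt_pause)
  }

  # measured traces on the task clock [0, t_end]: CO2 lags by the
  # measurement delay, the belt does not
  i0 <- idx_of(0)
  iT <- idx_of(t_end)
  kdelay <- round(spec$measurementDelay * fs)
  co2_meas <- co2[(i0 - kdelay):(iT - kdelay)]
  resp_meas <- resp[i0:iT]
  if (spec$co2Noise > 0) co2_meas <- co2_meas + stats::rnorm(length(co2_meas), 0, spec$co2Noise)
  if (spec$respNoise > 0) resp_meas <- resp_meas + stats::rnorm(length(resp_meas), 0, spec$respNoise)

  # ground-truth labels via the mean - 1 SD rule on the constructed deltas
  thr <- qualityThreshold(deltas)
  changes <- data.frame(
    trial = seq_len(n), pre_peak = NA_real_, post_peak = NA_real_,
    delta = deltas, skipped = skipped
  )
  labels <- classifyTrials(changes, thr)

  # undelayed end-tidal envelope on the 10 Hz working grid (ground-truth
  # P_ET_CO2 regressor for phantoms)
  t10 <- seq(0, t_end, by = 0.1)
  env10 <- stats::approx(peak_t, peak_v, xout = t10, rule = 2)$y
  petco2_ideal <- physioTrace(env10,
    fs = 10, units = "mmHg", t0 = 0,
    provenance = "measured_petco2"
  )

  list(
    co2 = physioTrace(co2_meas, fs = fs, units = "mmHg", t0 = 0, provenance = "raw_co2"),
    resp = physioTrace(resp_meas, fs = fs, units = "arbitrary", t0 = 0, provenance = "raw_resp"),
    timing = timing,
    truth = list(
      deltas = deltas, labels = labels, threshold = thr,
      petco2Ideal = petco2_ideal, peakTimes = peak_t, peakValues = peak_v,
      measurementDelay = spec$measurementDelay, holds = holds
    )
  )
}

#' Specification of a synthetic BOLD phantom
#'
#' A small 4D BOLD series with voxelwise ground-truth CVR amplitude and
#' delay fields, driven by an end-tidal CO2 trace. The default amplitude
#' field ramps 0.1-0.5 %BOLD/mmHg along x; the default delay field ramps
#' -6..+6 s along y, quantized to the lag grid. The gray-matter mask is
#' the interior of the grid (one-voxel shell excluded).
#'
#' @param dims 3D grid dimensions, default `c(12, 12, 4)`.
#' @param TR repetition time, s, default 1.5.
#' @param nVolumes number of volumes, default 200.
#' @param noiseSd Gaussian noise SD in percent of baseline signal.
#' @param driftCoef Legendre drift coefficients (percent of baseline).
#' @param amplitudeField,delayField optional explicit 3D arrays.
#' @param lagStep delay-field quantization step, s, default 0.3.
#' @param baseline mean signal intensity, default 1000.
#' @param seed RNG seed for the noise.
#' @return A classed list (`"PhantomSpec"`).
#' @export
phantomSpec <- function(dims = c(12L, 12L, 4L), TR = 1.5, nVolumes = 200L,
                        noiseSd = 0, driftCoef = c(0, 0.5, -0.3),
                        amplitudeField = NULL, delayField = NULL,
                        lagStep = 0.3, baseline = 1000, seed = 1L) {
  if (is.null(amplitudeField)) {
    gx <- (seq_len(dims[1]) - 1) / (dims[1] - 1)
    amplitudeField <- array(rep(0.1 + 0.4 * gx, times = dims[2] * dims[3]), dim = dims)
  }
  if (is.null(delayField)) {
    gy <- (seq_len(dims[2]) - 1) / (dims[2] - 1)
    dvals <- round((-6 + 12 * gy) / lagStep) * lagStep
    delayField <- array(rep(rep(dvals, each = dims[1]), times = dims[3]), dim = dims)
  }
  stopifnot(all(dim(amplitudeField) == dims), all(dim(delayField) == dims))
  if (!all(is.finite(amplitudeField))) stop("amplitudeField must be finite")
  structure(
    list(
      dims = as.integer(dims), TR = TR, nVolumes = as.integer(nVolumes),
      noiseSd = noiseSd, driftCoef = driftCoef,
      amplitudeField = amplitudeField, delayField = delayField,
      lagStep = lagStep, baseline = baseline, seed = as.integer(seed)
    ),
    class = "PhantomSpec"
  )
}

#' Generate a synthetic BOLD phantom from an end-tidal CO2 trace
#'
#' Each voxel's signal is
#' `y(t) = B * (1 + a_v/100 * x(t - d_v)) + drift(t) + noise`, where `x` is
#' the HRF-convolved, demeaned end-tidal trace in mmHg, `a_v` the CVR
#' amplitude (%BOLD/mmHg), `d_v` the hemodynamic delay (s) and `B` the
#' baseline intensity. Drift is a Legendre polynomial in scan time scaled
#' to percent of baseline.
#'
#' @param spec a [phantomSpec()].
#' @param petco2 end-tidal CO2 [PhysioTrace-class] in mmHg (unconvolved);
#'   must cover the scan duration plus the largest delay magnitude.
#' @return A list: `bold` (4D array), `mask` and `gmMask` (3D logical),
#'   `truth` (amplitude/delay fields and the convolved regressor used).
#' @export
genPhantom <- function(spec, petco2) {
  stopifnot(inherits(spec, "PhantomSpec"), is(petco2, "PhysioTrace"))
  if (petco2@units != "mmHg") stop("genPhantom: petco2 must be in mmHg")
  d <- spec$dims
  nv <- spec$nVolumes
  tr_scan <- (nv - 1) * spec$TR
  max_d <- max(abs(spec$delayField))
  if (traceDuration(petco2) < tr_scan + max_d) {
    stop("genPhantom: petco2 trace does not cover scan duration + max delay")
  }
  xreg <- convolveTrace(petco2, hrf(petco2@fs))
  xreg@samples <- xreg@samples - mean(xreg@samples)
  tt <- traceTimes(xreg)
  tvol <- (seq_len(nv) - 1) * spec$TR

  dv_all <- unique(as.vector(spec$delayField))
  # injected signal is demeaned over the scan window so the voxel temporal
  # mean equals the baseline and percent signal change is unbiased
  shifted <- vapply(dv_all, function(dd) {
    v <- stats::approx(tt, xreg@samples, xout = tvol - dd, rule = 2)$y
    v - mean(v)
  }, numeric(nv)) # nv x n_delays
  colnames(shifted) <- format(dv_all)

  drift <- rep(0, nv)
  if (length(spec$driftCoef)) {
    P <- .legendreBasis(nv, length(spec$driftCoef) - 1)
    drift <- as.vector(P %*% spec$driftCoef) * spec$baseline / 100
  }

  nvox <- prod(d)
  amp <- as.vector(spec$amplitudeField)
  del <- as.vector(spec$delayField)
  di <- match(del, dv_all)
  bold <- .withSeed(spec$seed, {
    y <- spec$baseline * (1 + outer(seq_len(nv), seq_len(nvox), function(i, v) {
      amp[v] / 100 * shifted[cbind(i, di[v])]
    })) + drift
    if (spec$noiseSd > 0) {
      y <- y + matrix(
        stats::rnorm(nv * nvox, 0, spec$noiseSd * spec$baseline / 100),
        nv, nvox
      )
    }
    y
  })
  bold4d <- array(t(bold), dim = c(d, nv))

  mask <- array(TRUE, dim = d)
  gm <- array(FALSE, dim = d)
  gm[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- TRUE
  list(
    bold = bold4d, mask = mask, gmMask = gm,
    truth = list(
      amplitude = spec$amplitudeField, delay = spec$delayField,
      regressor = xreg
    )
  )
}
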