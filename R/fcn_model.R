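# --- low-level 1D conv machinery -------------------------------------------
#
# Layers operate on matrices X of shape (N x C): time along rows, channels
# along columns. Strided convolution halves N, transposed convolution
# doubles it (kernel 8, stride 2, padding 3). Weights for both layer types
# are stored in "conv geometry": a (k*C_small_side) x C_other matrix whose
# rows are ordered tap-fastest, matching the im2col column order.

.im2col <- function(X, k, s, p) {
  N <- nrow(X)
  C <- ncol(X)
  n_out <- (N + 2 * p - k) %/% s + 1L
  Xp <- rbind(matrix(0, p, C), X, matrix(0, p, C))
  rows <- outer(seq_len(n_out) * s - s, seq_len(k), "+") # (n_out x k)
  M <- Xp[as.vector(rows), , drop = FALSE]
  dim(M) <- c(n_out, k * C)
  M
}

.col2im <- function(dM, N_in, k, s, p) {
  C <- ncol(dM) / k
  n_out <- nrow(dM)
  dXp <- matrix(0, N_in + 2 * p, C)
  base <- seq_len(n_out) * s - s
  for (t in seq_len(k)) {
    rows <- base + t
    dXp[rows, ] <- dXp[rows, ] + dM[, seq(t, by = k, length.out = C), drop = FALSE]
  }
  dXp[(p + 1):(p + N_in), , drop = FALSE]
}

.convFwd <- function(X, layer) {
  M <- .im2col(X, layer$k, 2L, layer$p)
  Y <- M %*% layer$W
  Y <- sweep(Y, 2, layer$b, "+")
  list(Y = Y, M = M)
}

.convBwd <- function(dY, cache, X, layer) {
  dW <- crossprod(cache$M, dY)
  db <- colSums(dY)
  dX <- .col2im(dY %*% t(layer$W), nrow(X), layer$k, 2L, layer$p)
  list(dX = dX, dW = dW, db = db)
}

# transposed conv: the adjoint of .convFwd. W is (k*C_out) x C_in.
.tconvFwd <- function(X, layer) {
  N_out <- nrow(X) * 2L
  P <- X %*% t(layer$W) # (N_in x k*C_out)
  Y <- .col2im(P, N_out, layer$k, 2L, layer$p)
  sweep(Y, 2, layer$b, "+")
}

.tconvBwd <- function(dY, X, layer) {
  M <- .im2col(dY, layer$k, 2L, layer$p) # (N_in x k*C_out)
  list(
    dX = M %*% layer$W,
    dW = crossprod(M, X),
    db = colSums(dY)
  )
}

# Instance normalization (per channel over time, no learned affine).
# Stabilizes batch-1 training of the deep strided stack at the fixed 0.01
# initial learning rate. Applied after every layer except the last.
.inormFwd <- function(Y) {
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2, mu)
  sg <- sqrt(colMeans(Yc^2) + 1e-5)
  list(Y = sweep(Yc, 2, sg, "/"), sg = sg)
}

.inormBwd <- function(dY, Yn, sg) {
  t1 <- sweep(dY, 2, colMeans(dY))
  t2 <- sweep(Yn, 2, colMeans(dY * Yn), "*")
  sweep(t1 - t2, 2, sg, "/")
}

# Build the layer stack: n/2 strided convs (channels 16, 32, ... capped),
# then n/2 transposed convs mirroring back down to a single linear output
# channel. ReLU everywhere except the final layer.
.buildLayers <- function(config, inChannels = 2L) {
  d <- config@nLayers / 2L
  k <- config@kernelSize
  ch <- pmin(16L * 2L^(seq_len(d) - 1L), config@maxChannels)
  layers <- list()
  for (i in seq_len(d)) {
    cin <- if (i == 1) inChannels else ch[i - 1]
    cout <- ch[i]
    layers[[length(layers) + 1]] <- list(
      type = "conv", k = k, p = (k - 2L) %/% 2L,
      W = matrix(stats::rnorm(k * cin * cout, 0, sqrt(2 / (k * cin))), k * cin, cout),
      b = numeric(cout), act = "relu", cin = cin, cout = cout
    )
  }
  for (j in seq_len(d)) {
    cin <- ch[d - j + 1]
    cout <- if (j < d) ch[d - j] else 1L
    layers[[length(layers) + 1]] <- list(
      type = "tconv", k = k, p = (k - 2L) %/% 2L,
      W = matrix(stats::rnorm(k * cout * cin, 0, sqrt(2 / (k * cin))), k * cout, cin),
      b = numeric(cout), act = if (j < d) "relu" else "linear",
      cin = cin, cout = cout
    )
  }
  layers
}

# Forward pass with caches for backprop. X: (N_pad x 2).
.fcnForward <- function(layers, X) {
  acts <- vector("list", length(layers) + 1)
  caches <- vector("list", length(layers))
  acts[[1]] <- X
  for (l in seq_along(layers)) {
    ly <- layers[[l]]
    if (ly$type == "conv") {
      fw <- .convFwd(acts[[l]], ly)
      Y <- fw$Y
      caches[[l]] <- fw$M
    } else {
      Y <- .tconvFwd(acts[[l]], ly)
    }
    norm <- NULL
    if (ly$act == "relu") {
      norm <- .inormFwd(Y)
      Y <- norm$Y
      pre <- Y
      Y <- pmax(Y, 0)
    } else {
      pre <- Y
    }
    caches[[l]] <- list(M = caches[[l]], pre = pre, norm = norm)
    acts[[l + 1]] <- Y
  }
  list(out = acts[[length(acts)]], acts = acts, caches = caches)
}

.fcnBackward <- function(layers, fw, dOut) {
  grads <- vector("list", length(layers))
  dY <- dOut
  for (l in rev(seq_along(layers))) {
    ly <- layers[[l]]
    if (ly$act == "relu") {
      ca <- fw$caches[[l]]
      dY <- dY * (ca$pre > 0)
      dY <- .inormBwd(dY, ca$norm$Y, ca$norm$sg)
    }
    if (ly$type == "conv") {
      g <- .convBwd(dY, fw$caches[[l]], fw$acts[[l]], ly)
    } else {
      g <- .tconvBwd(dY, fw$acts[[l]], ly)
    }
    grads[[l]] <- list(dW = g$dW, db = g$db)
    dY <- g$dX
  }
  grads
}

# --- public FCN surface ------------------------------------------------------

#' Encode model input: RVT plus one-hot subject identity
#'
#' Builds the N x 2 input array: column 1 is the z-normalized RVT trace
#' squashed through `tanh` (all values strictly in (-1, 1)); column 2 is
#' the subject ID one-hot encoded at its vocabulary position and padded
#' with zeros to length N. Unknown subjects get an all-zero identity
#' column.
#'
#' @param rvtZ numeric vector or zscore [PhysioTrace-class].
#' @param subjectId subject identifier (character).
#' @param vocabulary ordered character vector of known subject IDs.
#' @return An N x 2 numeric matrix.
#' @export
encodeInput <- function(rvtZ, subjectId, vocabulary) {
  if (is(rvtZ, "PhysioTrace")) rvtZ <- rvtZ@samples
  n <- length(rvtZ)
  if (n < length(vocabulary)) {
    stop("encodeInput: input shorter than the subject vocabulary")
  }
  onehot <- numeric(n)
  pos <- match(subjectId, vocabulary)
  if (!is.na(pos)) onehot[pos] <- 1
  cbind(tanh(rvtZ), onehot)
}

#' Peak-weighted mean squared error
#'
#' `L = MSE(pred, target) + lambda * MSE(pred[peaks], target[peaks])`.
#' The extra term penalizes underestimation of the end-tidal peaks, whose
#' heights encode the extent of hypercapnia and drive CVR amplitude.
#'
#' @param pred,target equal-length numeric vectors.
#' @param peakIndices indices of automatically detected maxima of the
#'   target trace.
#' @param lambda peak-term weight (0 reduces to plain MSE).
#' @return Scalar loss.
#' @export
peakWeightedLoss <- function(pred, target, peakIndices, lambda = 0.5) {
  stopifnot(length(pred) == length(target))
  if (length(peakIndices) && (min(peakIndices) < 1 || max(peakIndices) > length(target))) {
    stop("peakWeightedLoss: peak indices out of range")
  }
  L <- mean((pred - target)^2)
  if (lambda > 0) {
    if (!length(peakIndices)) {
      warning("peakWeightedLoss: no peaks supplied; falling back to plain MSE")
    } else {
      L <- L + lambda * mean((pred[peakIndices] - target[peakIndices])^2)
    }
  }
  L
}

# Loose sanity check that a segment is on the z-score scale. Segments are
# cut from recording-level z-normalized traces, so their own mean/SD drift
# from (0, 1); the check only guards against raw-unit (e.g. mmHg) input.
.checkZ <- function(x, what) {
  if (abs(mean(x)) > 2 || stats::sd(x) < 0.02 || stats::sd(x) > 10) {
    stop(sprintf("%s does not look z-normalized (mean %.2f, sd %.2f)", what, mean(x), stats::sd(x)))
  }
}

#' Build a training segment
#'
#' Bundles an aligned, z-normalized RVT/P_ET_CO2 pair with its subject ID
#' and the automatically detected end-tidal peak indices used by the
#' peak-weighted loss.
#'
#' @param rvtZ,petco2Z equal-length z-scale numeric vectors (or traces).
#' @param subjectId subject identifier.
#' @param fs sampling rate of the segment, Hz (default 10).
#' @param peakMinProminence,peakMinSeparation peak detection settings on
#'   the z-scored target (defaults 0.5 z and 10 s).
#' @return A classed list (`"TrainingSegment"`).
#' @export
trainingSegment <- function(rvtZ, petco2Z, subjectId, fs = 10,
                            peakMinProminence = 0.5, peakMinSeparation = 10) {
  if (is(rvtZ, "PhysioTrace")) rvtZ <- rvtZ@samples
  if (is(petco2Z, "PhysioTrace")) petco2Z <- petco2Z@samples
  stopifnot(length(rvtZ) == length(petco2Z))
  peaks <- .findPeaks(petco2Z, fs, peakMinProminence, peakMinSeparation)
  structure(
    list(
      rvtZ = rvtZ, petco2Z = petco2Z, subjectId = as.character(subjectId),
      peaks = peaks, fs = fs
    ),
    class = "TrainingSegment"
  )
}

# Adam update applied in place to a layer list; returns list(layers, state).
.adamStep <- function(layers, grads, state, lr, clip,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  gn2 <- 0
  for (l in seq_along(layers)) {
    gn2 <- gn2 + sum(grads[[l]]$dW^2) + sum(grads[[l]]$db^2)
  }
  scale <- if (clip > 0 && sqrt(gn2) > clip) clip / sqrt(gn2) else 1
  state$t <- state$t + 1L
  bc1 <- 1 - 0.9^state$t
  bc2 <- 1 - 0.999^state$t
  for (l in seq_along(layers)) {
    for (par in c("W", "b")) {
      g <- grads[[l]][[paste0("d", par)]] * scale
      state$m[[l]][[par]] <- beta1 * state$m[[l]][[par]] + (1 - beta1) * g
      state$v[[l]][[par]] <- beta2 * state$v[[l]][[par]] + (1 - beta2) * g^2
      mh <- state$m[[l]][[par]] / bc1
      vh <- state$v[[l]][[par]] / bc2
      layers[[l]][[par]] <- layers[[l]][[par]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  list(layers = layers, state = state)
}

.padLen <- function(n, depth) as.integer(2^depth * ceiling(n / 2^depth))

#' Train the 1D fully-convolutional P_ET_CO2 predictor
#'
#' Trains with batch size 1 and Adam on the given segments for exactly
#' `config@epochs` epochs. The learning rate starts at `config@lr0` and is
#' multiplied by `config@plateauFactor` whenever the epoch-mean training
#' loss fails to reach a new minimum for `config@plateauPatience`
#' consecutive epochs. Deterministic given `config@seed`.
#'
#' @param segments list of [trainingSegment()] objects (z-normalized).
#' @param config an [fcnConfig()].
#' @return A list: `model` ([FcnModel-class]) and `history` (data.frame
#'   with per-epoch mean loss and learning rate).
#' @export
fcnTrain <- function(segments, config = fcnConfig()) {
  if (!length(segments)) stop("fcnTrain: no training segments")
  for (sg in segments) {
    .checkZ(sg$rvtZ, "segment RVT")
    .checkZ(sg$petco2Z, "segment P_ET_CO2")
  }
  vocab <- sort(unique(vapply(segments, function(s) s$subjectId, character(1))))
  depth <- config@nLayers / 2L

  .withSeed(config@seed, {
    layers <- .buildLayers(config)
    state <- list(
      t = 0L,
      m = lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0)),
      v = lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
    )
    lr <- config@lr0
    best <- Inf
    stall <- 0L
    history <- data.frame(epoch = integer(), loss = numeric(), lr = numeric())

    for (ep in seq_len(config@epochs)) {
      ord <- sample.int(length(segments))
      losses <- numeric(length(ord))
      for (si in seq_along(ord)) {
        sg <- segments[[ord[si]]]
        n <- length(sg$rvtZ)
        npad <- .padLen(n, depth)
        X <- rbind(encodeInput(sg$rvtZ, sg$subjectId, vocab), matrix(0, npad - n, 2))
        fw <- .fcnForward(layers, X)
        pred <- fw$out[seq_len(n), 1]
        err <- pred - sg$petco2Z
        losses[si] <- mean(err^2)
        g <- 2 * err / n
        if (config@peakWeight > 0 && length(sg$peaks)) {
          pe <- err[sg$peaks]
          losses[si] <- losses[si] + config@peakWeight * mean(pe^2)
          g[sg$peaks] <- g[sg$peaks] + config@peakWeight * 2 * pe / length(sg$peaks)
        }
        dOut <- matrix(0, npad, 1)
        dOut[seq_len(n), 1] <- g
        grads <- .fcnBackward(layers, fw, dOut)
        upd <- .adamStep(layers, grads, state, lr, config@gradClip)
        layers <- upd$layers
        state <- upd$state
      }
      ep_loss <- mean(losses)
      history <- rbind(history, data.frame(epoch = ep, loss = ep_loss, lr = lr))
      if (ep_loss < best - 1e-12) {
        best <- ep_loss
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config@plateauPatience) {
          lr <- lr * config@plateauFactor
          stall <- 0L
        }
      }
    }
    list(
      model = new("FcnModel", layers = layers, config = config, subjects = vocab),
      history = history
    )
  })
}

#' Predict a z-scale P_ET_CO2 trace from RVT
#'
#' Runs the trained network on a z-normalized RVT trace (padded to the
#' stride structure and cropped back, so the output length always equals
#' the input length) and z-normalizes the output: the prediction is in
#' arbitrary units and is rescaled to mmHg downstream.
#'
#' @param model an [FcnModel-class].
#' @param rvtZ z-normalized RVT (numeric vector or zscore trace).
#' @param subjectId subject identifier; unknown IDs get a zero identity.
#' @return A zscore [PhysioTrace-class] (provenance `"predicted_petco2"`)
#'   when the input is a trace, otherwise a numeric vector.
#' @export
fcnPredict <- function(model, rvtZ, subjectId = "unknown") {
  stopifnot(is(model, "FcnModel"))
  istrace <- is(rvtZ, "PhysioTrace")
  x <- if (istrace) rvtZ@samples else rvtZ
  depth <- model@config@nLayers / 2L
  n <- length(x)
  npad <- .padLen(max(n, length(model@subjects)), depth)
  X <- encodeInput(c(x, numeric(npad - n)), subjectId, model@subjects)
  fw <- .fcnForward(model@layers, X)
  pred <- fw$out[seq_len(n), 1]
  s_pop <- sqrt(sum((pred - mean(pred))^2) / n)
  if (s_pop > 0) pred <- (pred - mean(pred)) / s_pop
  if (istrace) {
    physioTrace(pred,
      fs = rvtZ@fs, units = "zscore", t0 = rvtZ@t0,
      provenance = "predicted_petco2"
    )
  } else {
    pred
  }
}

#' Hyperparameter grid search by k-fold cross-validation
#'
#' For every combination of layer count, epoch count and peak weight,
#' trains on 80% of the segments and validates on the held-out 20%, for
#' each of `folds` folds, and reports mean and SD of Fisher-z correlation,
#' MAE, RMSE and RMSE at the target peaks across folds. Rows are ranked by
#' ascending mean RMSE-at-peaks (the quantity most relevant to estimating
#' hypercapnia, hence CVR). Fold assignment is deterministic given `seed`.
#'
#' @param segments list of [trainingSegment()] objects.
#' @param layerOptions,epochOptions,lambdaOptions hyperparameter grids.
#' @param folds number of cross-validation folds, default 5.
#' @param seed RNG seed (fold shuffling; per-fit seeds derive from it).
#' @param baseConfig template [fcnConfig()] supplying the fixed settings.
#' @return A data.frame, one row per combination, ranked by
#'   `rmse_peaks_mean`.
#' @export
fcnGridSearch <- function(segments, layerOptions = c(12L), epochOptions = c(20L),
                          lambdaOptions = c(0.5), folds = 5L, seed = 1L,
                          baseConfig = fcnConfig()) {
  if (length(segments) < folds) stop("fcnGridSearch: fewer segments than folds")
  fold_of <- .withSeed(seed, {
    idx <- sample.int(length(segments))
    f <- integer(length(segments))
    f[idx] <- rep_len(seq_len(folds), length(segments))
    f
  })
  grid <- expand.grid(
    nLayers = layerOptions, epochs = epochOptions,
    lambda = lambdaOptions, KEEP.OUT.ATTRS = FALSE
  )
  res <- lapply(seq_len(nrow(grid)), function(gi) {
    mets <- matrix(NA_real_, folds, 4)
    for (f in seq_len(folds)) {
      tr <- segments[fold_of != f]
      va <- segments[fold_of == f]
      cfg <- fcnConfig(
        nLayers = grid$nLayers[gi], epochs = grid$epochs[gi],
        peakWeight = grid$lambda[gi], lr0 = baseConfig@lr0,
        plateauFactor = baseConfig@plateauFactor,
        plateauPatience = baseConfig@plateauPatience,
        kernelSize = baseConfig@kernelSize,
        maxChannels = baseConfig@maxChannels,
        gradClip = baseConfig@gradClip,
        seed = seed + 1000L * f
      )
      fit <- fcnTrain(tr, cfg)
      per <- vapply(va, function(sg) {
        pred <- fcnPredict(fit$model, sg$rvtZ, sg$subjectId)
        m <- traceMetrics(sg$petco2Z, pred, sg$peaks)
        c(m$fisher_z, m$mae, m$rmse, m$rmse_at_peaks)
      }, numeric(4))
      mets[f, ] <- rowMeans(per, na.rm = TRUE)
    }
    data.frame(
      nLayers = grid$nLayers[gi], epochs = grid$epochs[gi],
      lambda = grid$lambda[gi],
      fisher_z_mean = mean(mets[, 1]), fisher_z_sd = stats::sd(mets[, 1]),
      mae_mean = mean(mets[, 2]), mae_sd = stats::sd(mets[, 2]),
      rmse_mean = mean(mets[, 3]), rmse_sd = stats::sd(mets[, 3]),
      rmse_peaks_mean = mean(mets[, 4]), rmse_peaks_sd = stats::sd(mets[, 4])
    )
  })
  out <- do.call(rbind, res)
  out[order(out$rmse_peaks_mean), , drop = FALSE]
}

#' Save / load an FCN model checkpoint
#'
#' The checkpoint is a self-describing JSON archive holding the layer
#' parameters, configuration and subject vocabulary.
#'
#' @param model an [FcnModel-class].
#' @param path output file path.
#' @return `saveFcnModel()` returns `path` invisibly; `loadFcnModel()`
#'   returns the restored [FcnModel-class].
#' @export
saveFcnModel <- function(model, path) {
  stopifnot(is(model, "FcnModel"))
  cfg <- model@config
  obj <- list(
    config = list(
      nLayers = cfg@nLayers, epochs = cfg@epochs, peakWeight = cfg@peakWeight,
      lr0 = cfg@lr0, plateauFactor = cfg@plateauFactor,
      plateauPatience = cfg@plateauPatience, kernelSize = cfg@kernelSize,
      maxChannels = cfg@maxChannels, gradClip = cfg@gradClip, seed = cfg@seed
    ),
    subjects = model@subjects,
    layers = lapply(model@layers, function(l) {
      list(
        type = l$type, k = l$k, p = l$p, act = l$act,
        cin = l$cin, cout = l$cout,
        dimW = dim(l$W), W = as.vector(l$W), b = l$b
      )
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveFcnModel
#' @export
loadFcnModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(fcnConfig, as.list(obj$config))
  layers <- lapply(seq_len(nrow(obj$layers)), function(i) {
    l <- obj$layers[i, ]
    list(
      type = l$type, k = as.integer(l$k), p = as.integer(l$p),
      W = matrix(l$W[[1]], l$dimW[[1]][1], l$dimW[[1]][2]),
      b = as.numeric(l$b[[1]]), act = l$act,
      cin = as.integer(l$cin), cout = as.integer(l$cout)
    )
  })
  new("FcnModel", layers = layers, config = cfg, subjects = as.character(obj$subjects))
}
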