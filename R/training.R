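#' @include AllClasses.R network.R objectives.R pair_sampling.R evaluation.R
NULL

#' Construct a run configuration
#'
#' Two named profiles are provided.  `"full"` carries the full-scale
#' hyper-parameters: batch size 16, learning rate 1e-5, L2 penalty 1e-6
#' for pre-training and 1e-2 downstream, 5,000 linear-evaluation epochs,
#' 25 fine-tuning epochs, 1,000 baseline epochs (500 are typical for heart
#' sounds — pass `epochsBaseline`), and 5 parallel replicate models (20
#' when only 10% of labels are used).  `"desk"` is a reduced profile sized
#' so complete experiments run in minutes on one CPU: the compact CNN
#' encoder, a larger learning rate, and far fewer epochs.  Any field can
#' be overridden.
#'
#' @param profile `"desk"` or `"full"`.
#' @param ... named overrides of any [RunConfig-class] slot.
#' @return a [RunConfig-class].
#' @export
runConfig <- function(profile = c("desk", "full"), ...) {
  profile <- match.arg(profile)
  base <- if (profile == "full") {
    list(batchSize = 16L, lr = 1e-5, lrFinetune = 1e-5,
         weightDecayPretrain = 1e-6,
         weightDecayDownstream = 1e-2, epochsPretrain = 100L,
         epochsLinear = 5000L, epochsFinetune = 25L, epochsBaseline = 1000L,
         labelFraction = 1.0, nParallel = 5L, temperature = 0.5,
         encoder = "tiny_cnn", embeddingDim = 512L, projectionDim = 256L,
         seed = 1L)
  } else {
    list(batchSize = 16L, lr = 1e-3, lrFinetune = 2e-4,
         weightDecayPretrain = 1e-6,
         weightDecayDownstream = 1e-2, epochsPretrain = 60L,
         epochsLinear = 400L, epochsFinetune = 25L, epochsBaseline = 200L,
         labelFraction = 1.0, nParallel = 5L, temperature = 0.5,
         encoder = "tiny_cnn", embeddingDim = 32L, projectionDim = 32L,
         seed = 1L)
  }
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad)) stop("unknown RunConfig fields: ", paste(bad, collapse = ", "))
  base[names(over)] <- over
  ints <- c("batchSize", "epochsPretrain", "epochsLinear", "epochsFinetune",
            "epochsBaseline", "nParallel", "embeddingDim", "projectionDim",
            "seed")
  for (f in ints) base[[f]] <- as.integer(base[[f]])
  do.call(new, c(list("RunConfig", profile = profile), base))
}

#' Default desk-scale analysis front end
#'
#' A coarse log-mel configuration (64 ms window, 32 ms hop, 32 mel bands)
#' that keeps spectrograms small enough for minute-scale training.
#'
#' @return an [stftConfig()].
#' @export
deskStft <- function() stftConfig(windowSec = 0.064, hopSec = 0.032, nMel = 32L)

#' Subset a cohort by recording index
#'
#' @param cohort a [SoundCohort-class].
#' @param idx integer recording indices.
#' @return a [SoundCohort-class].
#' @export
subsetCohort <- function(cohort, idx) {
  md <- cohort@metadata[idx, , drop = FALSE]
  rownames(md) <- NULL
  soundCohort(cohort@recordings[idx], md)
}

#' Compute and standardize all spectrograms of a cohort
#'
#' Computes the log-mel spectrogram of every recording, fits the
#' quantile-based length rule on the resulting frame counts (unless a rule
#' is supplied, e.g. the one frozen in a checkpoint), and centre
#' pads/crops everything to the common length.
#'
#' @param cohort a [SoundCohort-class].
#' @param stft an [stftConfig()].
#' @param rule optional [StandardizationRule-class] to reuse.
#' @param quantile quantile for [fitStandardization()] when fitting.
#' @return list with `specs` (list of [Spectrogram-class]), `rule`,
#'   `bins`, `frames`.
#' @export
prepareSpectrograms <- function(cohort, stft = deskStft(), rule = NULL,
                                quantile = 0.75) {
  raw <- lapply(cohort@recordings, computeSpectrogram, config = stft)
  if (is.null(rule))
    rule <- fitStandardization(vapply(raw, function(s) ncol(s@values),
                                      numeric(1)), quantile)
  specs <- lapply(raw, standardizeLength, rule = rule)
  list(specs = specs, rule = rule, bins = nrow(specs[[1L]]@values),
       frames = rule@targetFrames)
}

# mask spec calibrated for an augmentation scheme on the cohort geometry
.schemeMask <- function(scheme, targetCoverage = 0.5, bins = 64L,
                        frames = 200L) {
  if (scheme@mode != "augmentation" || scheme@augmentation == "split")
    return(maskSpec(timeBandWidth = 0, freqBandWidth = 0,
                    targetCoverage = targetCoverage))
  kind <- switch(scheme@augmentation,
                 time_mask = "time", freq_mask = "freq", "spec")
  calibrateBandWidths(maskSpec(targetCoverage = targetCoverage), kind,
                      dataBins = bins, dataFrames = frames)
}

#' Contrastive pre-training
#'
#' Trains the encoder and projection head on the pre-train split with the
#' NT-Xent loss (or the supervised-contrastive loss for the weak-label
#' scheme `pos_sim_age`), using Adam with the configured learning rate and
#' L2 penalty.  Deterministic for a fixed `(cfg, scheme, cohort)`: the run
#' seed drives weight initialisation, batch sampling and augmentation
#' draws.
#'
#' @param cohort the pre-train [SoundCohort-class] (labels are ignored).
#' @param scheme a [SchemeConfig-class], see [schemeConfig()].
#' @param cfg a [RunConfig-class].
#' @param stft an [stftConfig()].
#' @return a checkpoint (list of class `soundclrCheckpoint`) holding the
#'   trained encoder and projection head, the frozen standardization rule
#'   and analysis config, the scheme, the per-epoch loss curve and the
#'   seed — sufficient to reproduce any downstream evaluation.
#' @export
pretrain <- function(cohort, scheme, cfg = runConfig("desk"),
                     stft = deskStft()) {
  stopifnot(is(cohort, "SoundCohort"), is(scheme, "SchemeConfig"),
            is(cfg, "RunConfig"))
  set.seed(cfg@seed)
  prep <- prepareSpectrograms(cohort, stft)
  m <- .schemeMask(scheme, bins = prep$bins, frames = prep$frames)
  encCfg <- encoderConfig(cfg@encoder, prep$bins, prep$frames,
                          embeddingDim = cfg@embeddingDim,
                          projectionDim = cfg@projectionDim)
  enc <- encoderInit(encCfg, seed = cfg@seed)
  proj <- projectionInit(cfg@embeddingDim, cfg@projectionDim,
                         seed = cfg@seed + 1L)
  backend <- .getEncoder(cfg@encoder)
  params <- list(enc = enc$params, proj = proj)
  vec <- .packParams(params)
  opt <- adamInit(length(vec), lr = cfg@lr, weightDecay = cfg@weightDecayPretrain)
  nUnits <- if (scheme@mode == "augmentation") nRecordings(cohort)
            else length(unique(cohort@metadata$patient_id))
  stepsPerEpoch <- max(1L, nUnits %/% cfg@batchSize)
  lossHistory <- numeric(cfg@epochsPretrain)
  for (epoch in seq_len(cfg@epochsPretrain)) {
    epochLoss <- 0
    for (s in seq_len(stepsPerEpoch)) {
      batch <- contrastiveBatches(cohort, scheme, prep$specs,
                                  batchSize = cfg@batchSize, nBatches = 1L,
                                  m = m)[[1L]]
      X <- .stackViews(batch@views)
      fw <- backend$forward(enc, X, train = TRUE)
      Z <- project(fw$h, proj)
      cl <- contrastiveLoss(Z, batch@positiveSets, cfg@temperature)
      dW <- crossprod(fw$h, cl$grad)
      db <- colSums(cl$grad)
      dH <- cl$grad %*% t(proj$W)
      encGrads <- backend$backward(enc, fw$cache, dH)
      gvec <- .packParams(list(enc = encGrads, proj = list(W = dW, b = db)))
      st <- adamStep(vec, gvec, opt)
      vec <- st$par; opt <- st$state
      params <- .unpackParams(vec, params)
      enc$params <- params$enc
      proj <- params$proj
      epochLoss <- epochLoss + cl$loss
    }
    lossHistory[epoch] <- epochLoss / stepsPerEpoch
  }
  structure(list(encoder = enc, projection = proj, runConfig = cfg,
                 scheme = scheme, rule = prep$rule, stft = stft,
                 maskSpec = m, lossHistory = lossHistory, seed = cfg@seed),
            class = "soundclrCheckpoint")
}

.stackViews <- function(views) {
  d <- dim(views[[1L]]@values)
  X <- array(0, c(d[1L], d[2L], length(views)))
  for (i in seq_along(views)) X[, , i] <- views[[i]]@values
  X
}

# Adam-trained logistic model on a fixed feature matrix.
.trainLogistic <- function(X, y, epochs, lr, weightDecay, batchSize, seed) {
  set.seed(seed)
  p <- ncol(X)
  w <- numeric(p); b <- 0
  opt <- adamInit(p + 1L, lr = lr, weightDecay = weightDecay)
  n <- nrow(X)
  for (e in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batchSize)) {
      idx <- ord[start:min(n, start + batchSize - 1L)]
      Xb <- X[idx, , drop = FALSE]
      pr <- stats::plogis(drop(Xb %*% w) + b)
      g <- (pr - y[idx]) / length(idx)
      gw <- drop(crossprod(Xb, g))
      st <- adamStep(c(w, b), c(gw, sum(g)), opt)
      w <- st$par[seq_len(p)]; b <- st$par[p + 1L]; opt <- st$state
    }
  }
  list(w = w, b = b)
}

# stratified label-fraction subsample of training indices
.labelSubsample <- function(labels, idx, fraction, seed) {
  if (fraction >= 1) return(idx)
  set.seed(seed)
  sel <- unlist(lapply(split(idx, labels[idx]), function(g)
    sample(g, max(1L, round(fraction * length(g))))))
  sort(unname(sel))
}

#' Linear evaluation of frozen representations
#'
#' Embeds the labelled subset with the frozen pre-trained encoder and
#' trains only the single-unit sigmoid head ([linearHead()]) with the
#' downstream L2 penalty; encoder weights are bit-identical before and
#' after.  Test scores are summarised with a bootstrap AUROC interval.
#'
#' @param checkpoint a `soundclrCheckpoint` from [pretrain()].
#' @param cohort the full [SoundCohort-class].
#' @param trainIdx labelled fine-tune recording indices.
#' @param testIdx test recording indices (disjoint from `trainIdx`).
#' @param cfg a [RunConfig-class]; `labelFraction` subsamples `trainIdx`
#'   stratified by class.
#' @param replicates bootstrap replicates for the CI.
#' @return an [EvalResult-class].
#' @export
linearEvaluate <- function(checkpoint, cohort, trainIdx, testIdx,
                           cfg = checkpoint$runConfig, replicates = 1000L) {
  stopifnot(inherits(checkpoint, "soundclrCheckpoint"),
            length(intersect(trainIdx, testIdx)) == 0L)
  labels <- .asBinary(cohort@metadata$label)
  trainIdx <- .labelSubsample(cohort@metadata$label, trainIdx,
                              cfg@labelFraction, cfg@seed)
  prep <- prepareSpectrograms(cohort, checkpoint$stft, rule = checkpoint$rule)
  H <- encode(prep$specs[c(trainIdx, testIdx)], checkpoint$encoder)
  nTr <- length(trainIdx)
  fit <- .trainLogistic(H[seq_len(nTr), , drop = FALSE], labels[trainIdx],
                        epochs = cfg@epochsLinear, lr = cfg@lr,
                        weightDecay = cfg@weightDecayDownstream,
                        batchSize = cfg@batchSize, seed = cfg@seed)
  scores <- stats::plogis(drop(H[nTr + seq_along(testIdx), , drop = FALSE] %*%
                                 fit$w) + fit$b)
  bootstrapCI(scores, labels[testIdx], replicates = replicates,
              seed = cfg@seed)
}

#' End-to-end fine-tuning (initialization evaluation)
#'
#' Appends the two-layer SSL online evaluator to the encoder and trains
#' \emph{all} parameters with binary cross-entropy.  With
#' `checkpoint = NULL` the encoder is freshly initialised, giving the
#' randomly initialised supervised comparator arm; any supplied
#' checkpoint is then ignored entirely.
#'
#' @inheritParams linearEvaluate
#' @param checkpoint a `soundclrCheckpoint`, or `NULL` for the
#'   random-initialisation arm.
#' @param stft analysis configuration for the random-init arm
#'   (checkpoint runs reuse the checkpoint's frozen configuration).
#' @return an [EvalResult-class] with the per-epoch training loss in the
#'   `"trainLoss"` attribute.
#' @export
fineTune <- function(checkpoint, cohort, trainIdx, testIdx,
                     cfg = runConfig("desk"), stft = deskStft(),
                     replicates = 1000L) {
  stopifnot(length(intersect(trainIdx, testIdx)) == 0L)
  labels <- .asBinary(cohort@metadata$label)
  trainIdx <- .labelSubsample(cohort@metadata$label, trainIdx,
                              cfg@labelFraction, cfg@seed)
  if (is.null(checkpoint)) {
    prep <- prepareSpectrograms(cohort, stft)
    encCfg <- encoderConfig(cfg@encoder, prep$bins, prep$frames,
                            embeddingDim = cfg@embeddingDim,
                            projectionDim = cfg@projectionDim)
    enc <- encoderInit(encCfg, seed = cfg@seed + 17L)
  } else {
    stopifnot(inherits(checkpoint, "soundclrCheckpoint"))
    cfg <- if (missing(cfg)) checkpoint$runConfig else cfg
    prep <- prepareSpectrograms(cohort, checkpoint$stft,
                                rule = checkpoint$rule)
    enc <- checkpoint$encoder
  }
  backend <- .getEncoder(enc$backend)
  ev <- sslEvaluatorInit(cfg@embeddingDim, seed = cfg@seed + 1L)
  params <- list(enc = enc$params, ev = ev$params)
  vec <- .packParams(params)
  opt <- adamInit(length(vec), lr = cfg@lrFinetune,
                  weightDecay = cfg@weightDecayDownstream)
  set.seed(cfg@seed)
  n <- length(trainIdx)
  y <- labels[trainIdx]
  trainLoss <- numeric(cfg@epochsFinetune)
  for (epoch in seq_len(cfg@epochsFinetune)) {
    ord <- sample.int(n)
    eLoss <- 0; nb <- 0L
    for (start in seq(1L, n, by = cfg@batchSize)) {
      idx <- ord[start:min(n, start + cfg@batchSize - 1L)]
      if (length(idx) < 2L) next            # batch norm needs >= 2
      X <- .stackViews(prep$specs[trainIdx[idx]])
      fw <- backend$forward(enc, X, train = TRUE)
      evf <- sslEvaluatorForward(fw$h, ev, train = TRUE)
      ev <- evf$model
      pr <- evf$p
      eLoss <- eLoss - mean(y[idx] * log(pr + 1e-12) +
                              (1 - y[idx]) * log(1 - pr + 1e-12))
      nb <- nb + 1L
      dLogit <- (pr - y[idx]) / length(idx)
      bw <- sslEvaluatorBackward(ev, evf$cache, dLogit)
      encGrads <- backend$backward(enc, fw$cache, bw$dH)
      gvec <- .packParams(list(enc = encGrads, ev = bw$grads))
      st <- adamStep(vec, gvec, opt)
      vec <- st$par; opt <- st$state
      params <- .unpackParams(vec, params)
      enc$params <- params$enc
      ev$params <- params$ev
    }
    trainLoss[epoch] <- eLoss / max(1L, nb)
  }
  Xt <- .stackViews(prep$specs[testIdx])
  hT <- backend$forward(enc, Xt, train = FALSE)$h
  scores <- sslEvaluatorForward(hT, ev, train = FALSE)$p
  res <- bootstrapCI(scores, labels[testIdx], replicates = replicates,
                     seed = cfg@seed)
  attr(res, "trainLoss") <- trainLoss
  res
}

#' Flattened-spectrogram linear baseline
#'
#' A logistic model trained directly on the flattened standardized
#' spectrogram, the comparator for linear evaluation.  Features are
#' centred and scaled by training-set statistics.
#'
#' @inheritParams linearEvaluate
#' @param stft analysis configuration.
#' @return an [EvalResult-class].
#' @export
baselineLinear <- function(cohort, trainIdx, testIdx, cfg = runConfig("desk"),
                           stft = deskStft(), replicates = 1000L) {
  stopifnot(length(intersect(trainIdx, testIdx)) == 0L)
  labels <- .asBinary(cohort@metadata$label)
  trainIdx <- .labelSubsample(cohort@metadata$label, trainIdx,
                              cfg@labelFraction, cfg@seed)
  prep <- prepareSpectrograms(cohort, stft)
  flat <- t(vapply(prep$specs[c(trainIdx, testIdx)],
                   function(s) as.numeric(s@values),
                   numeric(prep$bins * prep$frames)))
  nTr <- length(trainIdx)
  mu <- colMeans(flat[seq_len(nTr), , drop = FALSE])
  sd_ <- apply(flat[seq_len(nTr), , drop = FALSE], 2L, stats::sd)
  sd_[sd_ == 0] <- 1
  flat <- sweep(sweep(flat, 2L, mu), 2L, sd_, "/")
  fit <- .trainLogistic(flat[seq_len(nTr), , drop = FALSE], labels[trainIdx],
                        epochs = cfg@epochsBaseline, lr = cfg@lr,
                        weightDecay = cfg@weightDecayDownstream,
                        batchSize = cfg@batchSize, seed = cfg@seed)
  scores <- stats::plogis(drop(flat[nTr + seq_along(testIdx), , drop = FALSE] %*%
                                 fit$w) + fit$b)
  bootstrapCI(scores, labels[testIdx], replicates = replicates,
              seed = cfg@seed)
}

#' Save / load a checkpoint
#'
#' A checkpoint contains trained weights plus the full configuration,
#' standardization rule and seed, which is sufficient to reproduce an
#' evaluation.
#'
#' @param checkpoint a `soundclrCheckpoint`.
#' @param path file path.
#' @return `readCheckpoint` the checkpoint; `writeCheckpoint` the path,
#'   invisibly.
#' @export
writeCheckpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "soundclrCheckpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname writeCheckpoint
#' @export
readCheckpoint <- function(path) {
  ck <- readRDS(path)
  if (!inherits(ck, "soundclrCheckpoint")) stop("not a checkpoint file: ", path)
  ck
}
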