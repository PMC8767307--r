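#' @include AllClasses.R
NULL

# ---- encoder registry ------------------------------------------------------

.encoders <- new.env(parent = emptyenv())

#' Encoder backend contract
#'
#' The encoder is pluggable: a backend is a list of three functions,
#' `init(cfg, seed)` returning a model, `forward(model, X, train)`
#' returning `list(h, cache)` with `h` a `batch x N` embedding matrix, and
#' `backward(model, cache, dH)` returning gradients with the same
#' structure as the model's `params`.  The package ships the `tiny_cnn`
#' backend (two 3x3 convolutions with ReLU and 2x2 max pooling, then a
#' linear map to the embedding); deeper backbones such as a ResNet can be
#' registered by the user under their own key.
#'
#' @param name backend key.
#' @param backend list with `init`, `forward`, `backward`.
#' @return `registerEncoder` the key invisibly; `encoderBackends` the
#'   registered keys.
#' @export
registerEncoder <- function(name, backend) {
  stopifnot(is.list(backend),
            all(c("init", "forward", "backward") %in% names(backend)))
  assign(name, backend, envir = .encoders)
  invisible(name)
}

#' @rdname registerEncoder
#' @export
encoderBackends <- function() ls(.encoders)

.getEncoder <- function(name) {
  if (!exists(name, envir = .encoders))
    stop("encoder backend '", name, "' is not registered; available: ",
         paste(encoderBackends(), collapse = ", "),
         ". Deep backbones can be added with registerEncoder().")
  get(name, envir = .encoders)
}

#' Encoder configuration
#'
#' @param architecture encoder backend key (see [registerEncoder()]).
#' @param inputBins,inputFrames expected spectrogram geometry.
#' @param embeddingDim latent embedding length `N`.
#' @param projectionDim projection-head output length (default 256).
#' @param channels convolution channel counts of the tiny CNN.
#' @return list of class `encoderConfig`.
#' @export
encoderConfig <- function(architecture = "tiny_cnn", inputBins, inputFrames,
                          embeddingDim = 32L, projectionDim = 256L,
                          channels = c(8L, 8L)) {
  stopifnot(embeddingDim >= 1L, projectionDim >= 1L)
  structure(list(architecture = architecture,
                 inputBins = as.integer(inputBins),
                 inputFrames = as.integer(inputFrames),
                 embeddingDim = as.integer(embeddingDim),
                 projectionDim = as.integer(projectionDim),
                 channels = as.integer(channels)),
            class = "encoderConfig")
}

# ---- parameter pack/unpack and Adam ---------------------------------------

.packParams <- function(params) unlist(params, use.names = FALSE)

.unpackParams <- function(vec, skeleton) {
  pos <- 0L
  walk <- function(s) {
    if (is.list(s)) return(lapply(s, walk))
    k <- length(s)
    out <- vec[pos + seq_len(k)]
    pos <<- pos + k
    if (!is.null(dim(s))) dim(out) <- dim(s)
    out
  }
  walk(skeleton)
}

#' Adam optimiser state
#'
#' @param nPar number of scalar parameters.
#' @param lr learning rate.
#' @param weightDecay L2 penalty added to the gradient.
#' @return list optimiser state; advance it with [adamStep()].
#' @export
adamInit <- function(nPar, lr = 1e-3, weightDecay = 0,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(m = numeric(nPar), v = numeric(nPar), t = 0L, lr = lr,
       wd = weightDecay, beta1 = beta1, beta2 = beta2, eps = eps)
}

#' @rdname adamInit
#' @param par,grad numeric parameter and gradient vectors.
#' @param state state from [adamInit()].
#' @export
adamStep <- function(par, grad, state) {
  g <- grad + state$wd * par
  state$t <- state$t + 1L
  state$m <- state$beta1 * state$m + (1 - state$beta1) * g
  state$v <- state$beta2 * state$v + (1 - state$beta2) * g^2
  mhat <- state$m / (1 - state$beta1^state$t)
  vhat <- state$v / (1 - state$beta2^state$t)
  list(par = par - state$lr * mhat / (sqrt(vhat) + state$eps), state = state)
}

# ---- tiny CNN backend ------------------------------------------------------

# 3x3 same-padding neighbour index map for an H x W grid (column-major),
# NA marks out-of-grid taps.
.convIndex <- function(H, W) {
  rc <- expand.grid(r = seq_len(H), c = seq_len(W))
  idx <- matrix(NA_integer_, H * W, 9L)
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1L
    rr <- rc$r + dr; cc <- rc$c + dc
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    idx[ok, k] <- rr[ok] + (cc[ok] - 1L) * H
  }
  idx
}

# im2col: x is H*W x Cin (columns are channels) -> (H*W) x (9*Cin)
.im2col <- function(x, idx) {
  Cin <- ncol(x)
  out <- matrix(0, nrow(idx), 9L * Cin)
  ok <- !is.na(idx)
  for (c in seq_len(Cin)) {
    block <- matrix(0, nrow(idx), 9L)
    block[ok] <- x[idx[ok], c]
    out[, (c - 1L) * 9L + 1:9] <- block
  }
  out
}

# scatter-add of column gradients back through im2col; for a fixed kernel
# offset the output->input map is injective, so plain indexed addition works
.col2im <- function(dcol, idx, Cin) {
  dx <- matrix(0, nrow(idx), Cin)
  for (c in seq_len(Cin)) for (k in 1:9) {
    ok <- !is.na(idx[, k])
    tgt <- idx[ok, k]
    dx[tgt, c] <- dx[tgt, c] + dcol[ok, (c - 1L) * 9L + k]
  }
  dx
}

# 2x2/stride-2 max pooling over an H x W x C array stored as (H*W) x C.
# Odd trailing rows/columns are dropped. Returns pooled matrix and argmax.
.poolForward <- function(x, H, W) {
  h2 <- H %/% 2L; w2 <- W %/% 2L
  C <- ncol(x)
  cells <- expand.grid(r = seq_len(h2), c = seq_len(w2))
  base <- (2L * cells$r - 1L) + (2L * cells$c - 2L) * H
  offs <- c(0L, 1L, H, H + 1L)
  vals <- array(0, c(h2 * w2, C, 4L))
  for (k in 1:4) vals[, , k] <- x[base + offs[k], , drop = FALSE]
  arg <- matrix(1L, h2 * w2, C)
  best <- vals[, , 1L, drop = FALSE][, , 1L]
  if (is.null(dim(best))) best <- matrix(best, h2 * w2, C)
  for (k in 2:4) {
    v <- vals[, , k]
    if (is.null(dim(v))) v <- matrix(v, h2 * w2, C)
    upd <- v > best
    best[upd] <- v[upd]
    arg[upd] <- k
  }
  list(y = best, arg = arg, base = base, offs = offs, h2 = h2, w2 = w2)
}

.poolBackward <- function(dy, pool, H, W, C) {
  dx <- matrix(0, H * W, C)
  for (c in seq_len(C)) {
    tgt <- pool$base + pool$offs[pool$arg[, c]]
    dx[tgt, c] <- dx[tgt, c] + dy[, c]
  }
  dx
}

.tinyCnnInit <- function(cfg, seed) {
  set.seed(seed)
  H <- cfg$inputBins; W <- cfg$inputFrames
  c1 <- cfg$channels[1L]; c2 <- cfg$channels[2L]
  h1 <- H %/% 2L; w1 <- W %/% 2L
  h2 <- h1 %/% 2L; w2 <- w1 %/% 2L
  if (h2 < 1L || w2 < 1L) stop("input geometry too small for two 2x2 poolings")
  # head: per (frequency row, channel) mean and max over time, so the
  # embedding is invariant to where in the recording an event falls
  flat <- 2L * h2 * c2
  he <- function(nr, nc, fan) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan)), nr, nc)
  list(
    cfg = cfg,
    params = list(
      conv1 = list(W = he(9L, c1, 9), b = numeric(c1)),
      conv2 = list(W = he(9L * c1, c2, 9 * c1), b = numeric(c2)),
      fc = list(W = he(flat, cfg$embeddingDim, flat), b = numeric(cfg$embeddingDim))),
    geom = list(H = H, W = W, c1 = c1, c2 = c2, h1 = h1, w1 = w1,
                h2 = h2, w2 = w2, flat = flat,
                idx1 = .convIndex(H, W), idx2 = .convIndex(h1, w1))
  )
}

# X: array (H, W, B) single-channel batch
.tinyCnnForward <- function(model, X, train = FALSE) {
  g <- model$geom; p <- model$params
  B <- dim(X)[3L]
  hOut <- matrix(0, B, model$cfg$embeddingDim)
  cache <- if (train) vector("list", B) else NULL
  for (b in seq_len(B)) {
    x0 <- matrix(X[, , b], g$H * g$W, 1L)
    xc1 <- .im2col(x0, g$idx1)
    a1 <- sweep(xc1 %*% p$conv1$W, 2L, p$conv1$b, "+")
    r1 <- pmax(a1, 0)
    p1 <- .poolForward(r1, g$H, g$W)
    xc2 <- .im2col(p1$y, g$idx2)
    a2 <- sweep(xc2 %*% p$conv2$W, 2L, p$conv2$b, "+")
    r2 <- pmax(a2, 0)
    p2 <- .poolForward(r2, g$h1, g$w1)
    arr <- array(p2$y, c(g$h2, g$w2, g$c2))
    meanT <- matrix(0, g$h2, g$c2)
    maxT <- matrix(-Inf, g$h2, g$c2)
    argT <- matrix(1L, g$h2, g$c2)
    for (cc in seq_len(g$w2)) {
      slice <- matrix(arr[, cc, ], g$h2, g$c2)
      meanT <- meanT + slice
      upd <- slice > maxT
      maxT[upd] <- slice[upd]
      argT[upd] <- cc
    }
    meanT <- meanT / g$w2
    fl <- c(meanT, maxT)
    hOut[b, ] <- drop(crossprod(p$fc$W, fl)) + p$fc$b
    if (train) cache[[b]] <- list(xc1 = xc1, a1 = a1, p1 = p1,
                                  xc2 = xc2, a2 = a2, p2 = p2, fl = fl,
                                  argT = argT)
  }
  list(h = hOut, cache = cache)
}

.tinyCnnBackward <- function(model, cache, dH) {
  g <- model$geom; p <- model$params
  B <- nrow(dH)
  dW1 <- matrix(0, 9L, g$c1); db1 <- numeric(g$c1)
  dW2 <- matrix(0, 9L * g$c1, g$c2); db2 <- numeric(g$c2)
  dWf <- matrix(0, g$flat, model$cfg$embeddingDim)
  dbf <- numeric(model$cfg$embeddingDim)
  for (b in seq_len(B)) {
    cb <- cache[[b]]
    dh <- dH[b, ]
    dWf <- dWf + outer(cb$fl, dh)
    dbf <- dbf + dh
    dfl <- drop(p$fc$W %*% dh)
    nStat <- g$h2 * g$c2
    dMean <- array(dfl[seq_len(nStat)], c(g$h2, g$c2))
    dMax <- array(dfl[nStat + seq_len(nStat)], c(g$h2, g$c2))
    dp2arr <- array(0, c(g$h2, g$w2, g$c2))
    for (ch in seq_len(g$c2)) {
      dp2arr[, , ch] <- dMean[, ch] / g$w2
      for (r in seq_len(g$h2))
        dp2arr[r, cb$argT[r, ch], ch] <- dp2arr[r, cb$argT[r, ch], ch] +
          dMax[r, ch]
    }
    dp2 <- matrix(dp2arr, g$h2 * g$w2, g$c2)
    dr2 <- .poolBackward(dp2, cb$p2, g$h1, g$w1, g$c2)
    da2 <- dr2 * (cb$a2 > 0)
    dW2 <- dW2 + crossprod(cb$xc2, da2)
    db2 <- db2 + colSums(da2)
    dp1 <- .col2im(da2 %*% t(p$conv2$W), g$idx2, g$c1)
    dr1 <- .poolBackward(dp1, cb$p1, g$H, g$W, g$c1)
    da1 <- dr1 * (cb$a1 > 0)
    dW1 <- dW1 + crossprod(cb$xc1, da1)
    db1 <- db1 + colSums(da1)
  }
  list(conv1 = list(W = dW1, b = db1),
       conv2 = list(W = dW2, b = db2),
       fc = list(W = dWf, b = dbf))
}

registerEncoder("tiny_cnn", list(init = .tinyCnnInit,
                                 forward = .tinyCnnForward,
                                 backward = .tinyCnnBackward))

#' Initialise an encoder model
#'
#' @param cfg an [encoderConfig()].
#' @param seed integer seed for weight initialisation.
#' @return encoder model (list with `params`).
#' @export
encoderInit <- function(cfg, seed = 1L) {
  backend <- .getEncoder(cfg$architecture)
  model <- backend$init(cfg, seed)
  model$backend <- cfg$architecture
  model
}

#' Embed spectrograms with an encoder
#'
#' Deterministic (evaluation-mode) forward pass.  The spectrogram geometry
#' must match the encoder's configured input geometry.
#'
#' @param specs a [Spectrogram-class] or list of them.
#' @param model encoder model from [encoderInit()].
#' @return numeric matrix, one length-`N` embedding row per spectrogram.
#' @export
encode <- function(specs, model) {
  if (is(specs, "Spectrogram")) specs <- list(specs)
  cfg <- model$cfg
  for (s in specs) {
    d <- dim(s@values)
    if (d[1L] != cfg$inputBins || d[2L] != cfg$inputFrames)
      stop(sprintf("spectrogram is %d x %d but the encoder expects %d x %d",
                   d[1L], d[2L], cfg$inputBins, cfg$inputFrames))
  }
  X <- array(0, c(cfg$inputBins, cfg$inputFrames, length(specs)))
  for (i in seq_along(specs)) X[, , i] <- specs[[i]]@values
  .getEncoder(model$backend)$forward(model, X, train = FALSE)$h
}

# ---- heads -----------------------------------------------------------------

#' Projection head
#'
#' A single linear map from the embedding space (length `N`) to the
#' projection space used by the contrastive losses.
#'
#' @param N input dimension.
#' @param projectionDim output dimension (default 256).
#' @param seed integer.
#' @return list with `W` (`N x projectionDim`) and `b`.
#' @export
projectionInit <- function(N, projectionDim = 256L, seed = 1L) {
  set.seed(seed)
  list(W = matrix(stats::rnorm(N * projectionDim, sd = sqrt(1 / N)),
                  N, projectionDim),
       b = numeric(projectionDim))
}

#' @rdname projectionInit
#' @param h numeric matrix of embeddings (rows) or a single vector.
#' @param head projection head from `projectionInit`.
#' @export
project <- function(h, head) {
  if (is.null(dim(h))) h <- matrix(h, 1L)
  sweep(h %*% head$W, 2L, head$b, "+")
}

#' Linear evaluation head
#'
#' A single linear unit with sigmoid output used for linear evaluation on
#' frozen embeddings.
#'
#' @param N embedding dimension.
#' @param seed integer.
#' @return list with `w`, `b`.
#' @export
linearHeadInit <- function(N, seed = 1L) {
  set.seed(seed)
  list(w = numeric(N), b = 0)
}

#' @rdname linearHeadInit
#' @param h embedding matrix (rows) or vector.
#' @param head head from `linearHeadInit`.
#' @return probabilities in (0, 1).
#' @export
linearHead <- function(h, head) {
  if (is.null(dim(h))) h <- matrix(h, 1L)
  stats::plogis(drop(h %*% head$w) + head$b)
}

#' Two-layer SSL online evaluator
#'
#' The fine-tuning head: linear (`N -> N`), batch normalisation, ReLU,
#' linear (`N -> 1`), sigmoid.  In training mode batch statistics are used
#' (a batch of one is an error); in evaluation mode the running statistics
#' are used, making the forward pass deterministic.
#'
#' @param N embedding dimension.
#' @param seed integer.
#' @return evaluator model list.
#' @export
sslEvaluatorInit <- function(N, seed = 1L) {
  set.seed(seed)
  list(params = list(
         fc1 = list(W = matrix(stats::rnorm(N * N, sd = sqrt(2 / N)), N, N),
                    b = numeric(N)),
         bn = list(gamma = rep(1, N), beta = numeric(N)),
         fc2 = list(w = numeric(N), b = 0)),
       running = list(mean = numeric(N), var = rep(1, N)),
       momentum = 0.1, eps = 1e-5, N = N)
}

#' @rdname sslEvaluatorInit
#' @param h embedding matrix, one row per example.
#' @param model evaluator from `sslEvaluatorInit`.
#' @param train logical; batch statistics (training) or running
#'   statistics (evaluation).
#' @return list with `p` (probabilities), updated `model`, and `cache`
#'   for [sslEvaluatorBackward()].
#' @export
sslEvaluatorForward <- function(h, model, train = FALSE) {
  if (is.null(dim(h))) h <- matrix(h, 1L)
  p <- model$params
  B <- nrow(h)
  a1 <- sweep(h %*% p$fc1$W, 2L, p$fc1$b, "+")
  if (train) {
    if (B < 2L) stop("batch normalisation needs a batch of at least 2 in training mode")
    mu <- colMeans(a1)
    va <- colMeans(sweep(a1, 2L, mu)^2)
    model$running$mean <- (1 - model$momentum) * model$running$mean + model$momentum * mu
    model$running$var <- (1 - model$momentum) * model$running$var +
      model$momentum * va * B / max(1L, B - 1L)
  } else {
    mu <- model$running$mean
    va <- model$running$var
  }
  xhat <- sweep(sweep(a1, 2L, mu), 2L, sqrt(va + model$eps), "/")
  bnOut <- sweep(sweep(xhat, 2L, p$bn$gamma, "*"), 2L, p$bn$beta, "+")
  r <- pmax(bnOut, 0)
  logit <- drop(r %*% p$fc2$w) + p$fc2$b
  prob <- stats::plogis(logit)
  list(p = prob, model = model,
       cache = list(h = h, a1 = a1, mu = mu, va = va, xhat = xhat,
                    bnOut = bnOut, r = r, train = train))
}

#' Backward pass of the SSL evaluator
#'
#' @param model evaluator model.
#' @param cache forward cache from [sslEvaluatorForward()].
#' @param dLogit gradient of the loss w.r.t. the pre-sigmoid output.
#' @return list with `grads` (same shape as `params`) and `dH`, the
#'   gradient w.r.t. the input embeddings.
#' @export
sslEvaluatorBackward <- function(model, cache, dLogit) {
  p <- model$params
  B <- nrow(cache$h)
  dr <- outer(dLogit, p$fc2$w)
  dw2 <- drop(crossprod(cache$r, dLogit))
  db2 <- sum(dLogit)
  dbn <- dr * (cache$bnOut > 0)
  dgamma <- colSums(dbn * cache$xhat)
  dbeta <- colSums(dbn)
  dxhat <- sweep(dbn, 2L, p$bn$gamma, "*")
  if (cache$train) {
    istd <- 1 / sqrt(cache$va + model$eps)
    xc <- sweep(cache$a1, 2L, cache$mu)
    da1 <- sweep(dxhat -
                   matrix(colMeans(dxhat), B, length(cache$mu), byrow = TRUE) -
                   sweep(xc, 2L, colMeans(dxhat * xc) / (cache$va + model$eps), "*"),
                 2L, istd, "*")
  } else {
    da1 <- sweep(dxhat, 2L, sqrt(cache$va + model$eps), "/")
  }
  dW1 <- crossprod(cache$h, da1)
  db1 <- colSums(da1)
  dH <- da1 %*% t(p$fc1$W)
  list(grads = list(fc1 = list(W = dW1, b = db1),
                    bn = list(gamma = dgamma, beta = dbeta),
                    fc2 = list(w = dw2, b = db2)),
       dH = dH)
}

#' Count model parameters
#'
#' @param params nested list of numeric arrays.
#' @return integer total number of scalar parameters.
#' @export
countParameters <- function(params) length(.packParams(params))
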