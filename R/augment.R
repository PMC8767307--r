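#' @include AllClasses.R AllGenerics.R signal_io.R
NULL

#' Construct a MaskSpec
#'
#' @param nTimeBands,nFreqBands number of masked bands per axis
#'   (defaults 5 and 2).
#' @param timeBandWidth,freqBandWidth band widths as fractions of the data
#'   region; usually produced by [calibrateBandWidths()].
#' @param targetCoverage expected masked fraction of the data region the
#'   calibrated scheme should achieve (default 0.5).
#' @return a [MaskSpec-class].
#' @export
maskSpec <- function(nTimeBands = 5L, nFreqBands = 2L,
                     timeBandWidth = 0.1, freqBandWidth = 0.25,
                     targetCoverage = 0.5) {
  new("MaskSpec", nTimeBands = as.integer(nTimeBands),
      nFreqBands = as.integer(nFreqBands),
      timeBandWidth = timeBandWidth, freqBandWidth = freqBandWidth,
      targetCoverage = targetCoverage)
}

#' Augmentation scheme keys
#'
#' The five stochastic spectrogram augmentations: `split` (keep a random
#' contiguous half of the data region), `time_mask`, `freq_mask`,
#' `spec_mask` (time and frequency masking composed) and `spec_mask_split`
#' (spectrogram masking followed by splitting).
#'
#' @return character vector of the five keys.
#' @export
augmentationNames <- function() {
  c("split", "time_mask", "freq_mask", "spec_mask", "spec_mask_split")
}

# Re-centre a data-region matrix into a grid of `total` frames,
# extra padding frame on the right.
.recentre <- function(dataVals, total) {
  L <- ncol(dataVals)
  padL <- (total - L) %/% 2L
  padR <- total - L - padL
  nb <- nrow(dataVals)
  spectrogram(cbind(matrix(0, nb, padL), dataVals, matrix(0, nb, padR)),
              padL, padR)
}

#' Splitting augmentation
#'
#' Keeps a uniformly random contiguous section of half the duration
#' (`floor(D/2)`, minimum 1 frame) of the data region and re-centres it in
#' a grid of the same total frame count, so batch tensors stay rectangular.
#'
#' @param spec a [Spectrogram-class] whose data region has >= 2 frames.
#' @return a [Spectrogram-class].
#' @export
augmentSplit <- function(spec) {
  stopifnot(is(spec, "Spectrogram"))
  idx <- dataFrames(spec)
  D <- length(idx)
  if (D < 2L) stop("split needs a data region of at least 2 frames")
  L <- max(1L, D %/% 2L)
  off <- sample.int(D - L + 1L, 1L) - 1L
  .recentre(spec@values[, idx[off + seq_len(L)], drop = FALSE],
            ncol(spec@values))
}

# Draw `k` integer band starts (0-based within a region of size n) for
# integer width w; uniform over admissible starts, overlaps allowed.
.drawBands <- function(n, w, k) {
  if (k == 0L || w == 0L) return(integer())
  sample.int(n - w + 1L, k, replace = TRUE) - 1L
}

.bandWidthFrames <- function(frac, n, axis) {
  w <- as.integer(floor(frac * n + 0.5))
  if (w > n)
    stop(sprintf("%s band width (%d) exceeds the data region (%d)", axis, w, n))
  w
}

#' Time and frequency band masking
#'
#' `timeMask` zeroes `nTimeBands` bands of frames, `freqMask` zeroes
#' `nFreqBands` bands of frequency bins; `specMask` composes the two.
#' Bands are placed independently and uniformly at random (overlaps
#' allowed) strictly inside the non-padded data region; padding cells are
#' never touched.  Band widths are `round(width * size)` cells of the
#' respective axis.
#'
#' @param spec a [Spectrogram-class].
#' @param m a [MaskSpec-class].
#' @return a [Spectrogram-class] with the same geometry and padding.
#' @export
timeMask <- function(spec, m) {
  stopifnot(is(spec, "Spectrogram"), is(m, "MaskSpec"))
  idx <- dataFrames(spec)
  D <- length(idx)
  if (D < m@nTimeBands) stop("data region smaller than the number of time bands")
  w <- .bandWidthFrames(m@timeBandWidth, D, "time")
  vals <- spec@values
  for (s in .drawBands(D, w, m@nTimeBands))
    vals[, idx[s + seq_len(w)]] <- 0
  spectrogram(vals, spec@padLeft, spec@padRight)
}

#' @rdname timeMask
#' @export
freqMask <- function(spec, m) {
  stopifnot(is(spec, "Spectrogram"), is(m, "MaskSpec"))
  idx <- dataFrames(spec)
  nb <- nrow(spec@values)
  if (nb < m@nFreqBands) stop("fewer frequency bins than frequency bands")
  w <- .bandWidthFrames(m@freqBandWidth, nb, "frequency")
  vals <- spec@values
  for (s in .drawBands(nb, w, m@nFreqBands))
    vals[s + seq_len(w), idx] <- 0
  spectrogram(vals, spec@padLeft, spec@padRight)
}

#' @rdname timeMask
#' @export
specMask <- function(spec, m) {
  freqMask(timeMask(spec, m), m)
}

#' Spectrogram masking followed by splitting
#'
#' @inheritParams timeMask
#' @return a [Spectrogram-class].
#' @export
specMaskSplit <- function(spec, m) {
  augmentSplit(specMask(spec, m))
}

# Exact expected covered fraction of an n-cell axis under k independent
# uniformly-placed bands of integer width w (overlaps allowed, edge
# effects included).
.unionCoverage <- function(w, k, n) {
  if (k == 0L || w <= 0L) return(0)
  if (w >= n) return(1)
  c_ <- seq_len(n)
  m <- pmin(c_, n - w + 1L) - pmax(1L, c_ - w + 1L) + 1L
  mean(1 - (1 - m / (n - w + 1L))^k)
}

# Integer band width whose exact expected union coverage on an n-cell
# axis is closest to the target.
.solveWidth <- function(target, k, n, axis) {
  if (target <= 0) return(0)
  if (k == 0L)
    stop(sprintf("cannot reach coverage %.3f on the %s axis with 0 bands",
                 target, axis))
  cov <- vapply(0:n, .unionCoverage, numeric(1), k = k, n = n)
  w <- which.min(abs(cov - target)) - 1L
  if (w == 0L && target > 0)
    stop(sprintf("target coverage %.3f infeasible on the %s axis (%d cells)",
                 target, axis, n))
  w / n
}

#' Calibrate band widths to a target expected masking fraction
#'
#' Solves for band widths such that the expected fraction of data-region
#' cells zeroed by the scheme equals `m@targetCoverage`.  Bands are placed
#' independently and uniformly, so the expected union coverage of `k`
#' width-`t` bands (edge effects included) is inverted numerically.  For
#' the combined scheme the per-axis coverage `a` solves
#' `a + a - a^2 = target` (i.e. `a = 1 - sqrt(1 - target)`), and each
#' axis's band width is then calibrated to union coverage `a`.  The exact
#' expected-union function is evaluated on a reference grid
#' (`dataBins x dataFrames`, default 64 x 200) and inverted over integer
#' band widths, so the returned fractions survive the integer rounding
#' applied at masking time.
#'
#' @param m a [MaskSpec-class] carrying band counts and `targetCoverage`.
#' @param scheme `"time"`, `"freq"` or `"spec"` (combined).
#' @param dataBins,dataFrames reference data-region geometry used for the
#'   calibration.
#' @return a [MaskSpec-class] with calibrated widths.
#' @export
calibrateBandWidths <- function(m, scheme = c("spec", "time", "freq"),
                                dataBins = 64L, dataFrames = 200L) {
  stopifnot(is(m, "MaskSpec"))
  scheme <- match.arg(scheme)
  target <- m@targetCoverage
  if (target < 0 || target >= 1) stop("targetCoverage must lie in [0, 1)")
  if (scheme == "time") {
    m@timeBandWidth <- .solveWidth(target, m@nTimeBands, dataFrames, "time")
    m@freqBandWidth <- 0
  } else if (scheme == "freq") {
    m@freqBandWidth <- .solveWidth(target, m@nFreqBands, dataBins, "frequency")
    m@timeBandWidth <- 0
  } else {
    # balanced per-axis coverage a with a + a - a^2 = target; on the
    # integer grid, consider the widths bracketing a on each axis and
    # pick the combination whose exact combined coverage
    # A + B - A*B is closest to the target
    if (target > 0 && (m@nTimeBands == 0L || m@nFreqBands == 0L))
      stop("combined masking needs at least one band on each axis")
    a <- 1 - sqrt(1 - target)
    bracket <- function(k, n) {
      cov <- vapply(0:n, .unionCoverage, numeric(1), k = k, n = n)
      w <- which.min(abs(cov - a)) - 1L
      unique(pmin(n, pmax(0L, c(w - 1L, w, w + 1L))))
    }
    wt <- bracket(m@nTimeBands, dataFrames)
    wf <- bracket(m@nFreqBands, dataBins)
    A <- vapply(wt, .unionCoverage, numeric(1), k = m@nTimeBands, n = dataFrames)
    B <- vapply(wf, .unionCoverage, numeric(1), k = m@nFreqBands, n = dataBins)
    comb <- outer(A, B, function(x, y) x + y - x * y)
    best <- arrayInd(which.min(abs(comb - target)), dim(comb))
    m@timeBandWidth <- wt[best[1L]] / dataFrames
    m@freqBandWidth <- wf[best[2L]] / dataBins
  }
  validObject(m)
  m
}

#' Apply an augmentation scheme by key
#'
#' @param spec a [Spectrogram-class].
#' @param scheme one of [augmentationNames()].
#' @param m a [MaskSpec-class] (ignored by `split`).
#' @return a [Spectrogram-class].
#' @export
applyAugmentation <- function(spec, scheme, m = maskSpec()) {
  switch(scheme,
    split = augmentSplit(spec),
    time_mask = timeMask(spec, m),
    freq_mask = freqMask(spec, m),
    spec_mask = specMask(spec, m),
    spec_mask_split = specMaskSplit(spec, m),
    stop("unknown augmentation scheme '", scheme, "'; valid keys: ",
         paste(augmentationNames(), collapse = ", "))
  )
}

#' Fraction of data-region cells zeroed by an augmentation
#'
#' Compares an augmented spectrogram against its source and returns the
#' fraction of originally non-zero data-region cells that the augmentation
#' set to zero.
#'
#' @param original,augmented [Spectrogram-class] objects with identical
#'   geometry.
#' @return numeric fraction in \[0, 1\].
#' @export
maskedFraction <- function(original, augmented) {
  idx <- dataFrames(original)
  o <- original@values[, idx, drop = FALSE]
  a <- augmented@values[, idx, drop = FALSE]
  nz <- o != 0
  if (!any(nz)) stop("original data region is entirely zero")
  sum(a[nz] == 0) / sum(nz)
}
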