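#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a Spectrogram
#'
#' @param values numeric matrix, frequency bins x time frames.
#' @param padLeft,padRight number of zero frames on either side of the data
#'   region.
#' @return a [Spectrogram-class].
#' @export
spectrogram <- function(values, padLeft = 0L, padRight = 0L) {
  new("Spectrogram", values = as.matrix(values),
      padLeft = as.integer(padLeft), padRight = as.integer(padRight))
}

#' Construct an AudioRecording
#'
#' @param recordingId,patientId identifiers.
#' @param waveform numeric amplitude sequence.
#' @param sampleRate Hz.
#' @return an [AudioRecording-class].
#' @export
audioRecording <- function(recordingId, patientId, waveform, sampleRate) {
  new("AudioRecording", recordingId = as.character(recordingId),
      patientId = as.character(patientId), waveform = as.numeric(waveform),
      sampleRate = as.numeric(sampleRate))
}

#' Construct a SoundCohort
#'
#' @param recordings list of [AudioRecording-class] objects.
#' @param metadata data.frame with one row per recording (columns
#'   `recording_id`, `patient_id`, `age_band`, `sex`, `location`, `label`).
#' @return a [SoundCohort-class].
#' @export
soundCohort <- function(recordings, metadata) {
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  for (col in c("recording_id", "patient_id", "age_band", "sex", "location", "label"))
    if (col %in% names(metadata)) metadata[[col]] <- as.character(metadata[[col]])
  new("SoundCohort", recordings = recordings, metadata = metadata)
}

#' Short-time analysis configuration
#'
#' Analysis parameters for [computeSpectrogram()].  The time-frequency
#' front end is a Hann-windowed short-time Fourier transform followed by a
#' triangular mel filterbank and log compression.
#'
#' @param windowSec analysis window length in seconds (default 0.025).
#' @param hopSec hop between successive frames in seconds (default 0.010).
#' @param nMel number of mel bands (default 64); `0` keeps linear
#'   frequency bins.
#' @param fftSize FFT length; defaults to the next power of two at or above
#'   the window length.
#' @return a list of class `stftConfig`.
#' @export
stftConfig <- function(windowSec = 0.025, hopSec = 0.010, nMel = 64L,
                       fftSize = NULL) {
  stopifnot(windowSec > 0, hopSec > 0, hopSec <= windowSec, nMel >= 0)
  structure(list(windowSec = windowSec, hopSec = hopSec,
                 nMel = as.integer(nMel), fftSize = fftSize),
            class = "stftConfig")
}

# Triangular mel filterbank, HTK mel scale: mel(f) = 2595 log10(1 + f/700).
melFilterbank <- function(nMel, nFftBins, sampleRate) {
  hz2mel <- function(f) 2595 * log10(1 + f / 700)
  mel2hz <- function(m) 700 * (10^(m / 2595) - 1)
  nyquist <- sampleRate / 2
  melPts <- seq(hz2mel(0), hz2mel(nyquist), length.out = nMel + 2L)
  hzPts <- mel2hz(melPts)
  # rows of the power spectrum are k * Fs / nfft, k = 0 .. nfft/2 - 1
  binHz <- (seq_len(nFftBins) - 1L) * sampleRate / (2L * nFftBins)
  fb <- matrix(0, nMel, nFftBins)
  for (m in seq_len(nMel)) {
    lo <- hzPts[m]; ce <- hzPts[m + 1L]; hi <- hzPts[m + 2L]
    up <- (binHz - lo) / (ce - lo)
    dn <- (hi - binHz) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, dn))
  }
  fb
}

#' Compute a log-power (mel) spectrogram
#'
#' Hann-windowed short-time Fourier transform of the waveform, power
#' spectrum, optional mel filterbank, and log compression
#' (`10 * log10(power + 1e-10)`).  The returned spectrogram has no padding
#' (`padLeft = padRight = 0`); padding is introduced later by
#' [standardizeLength()].
#'
#' @param recording an [AudioRecording-class].
#' @param config an [stftConfig()].
#' @return a [Spectrogram-class], deterministic in its inputs.
#' @export
computeSpectrogram <- function(recording, config = stftConfig()) {
  stopifnot(is(recording, "AudioRecording"), inherits(config, "stftConfig"))
  x <- recording@waveform
  sr <- recording@sampleRate
  win <- max(2L, as.integer(round(config$windowSec * sr)))
  hop <- max(1L, as.integer(round(config$hopSec * sr)))
  if (length(x) < win)
    stop(sprintf(
      "waveform has %d samples but one analysis window needs at least %d",
      length(x), win))
  nfft <- config$fftSize
  if (is.null(nfft)) nfft <- 2L^ceiling(log2(win))
  sg <- signal::specgram(x, n = nfft, Fs = sr,
                         window = signal::hanning(win), overlap = win - hop)
  power <- Mod(sg$S)^2
  if (config$nMel > 0L) {
    fb <- melFilterbank(config$nMel, nrow(power), sr)
    power <- fb %*% power
  }
  spectrogram(10 * log10(power + 1e-10))
}

#' Fit the cohort length-standardization rule
#'
#' The target frame count is an upper quantile (default the 75th
#' percentile) of the cohort's per-recording frame counts, computed by
#' linear interpolation between order statistics and rounded half-up to an
#' integer.
#'
#' @param lengths integer vector of per-recording frame counts.
#' @param quantile quantile of the length distribution, default 0.75.
#' @return a [StandardizationRule-class].
#' @export
fitStandardization <- function(lengths, quantile = 0.75) {
  if (length(lengths) == 0L) stop("need at least one recording length")
  if (any(lengths < 1)) stop("all lengths must be >= 1 frame")
  q <- stats::quantile(as.numeric(lengths), probs = quantile,
                       type = 7, names = FALSE)
  new("StandardizationRule", targetFrames = as.integer(floor(q + 0.5)),
      quantile = quantile)
}

#' Centre pad/crop a spectrogram to the standard length
#'
#' Shorter spectrograms are zero-padded symmetrically (the extra frame of
#' an odd deficit goes on the right); longer ones keep a centred window
#' (the extra frame of an odd excess is dropped on the right).  Pad counts
#' are tracked exactly so downstream augmentations can confine themselves
#' to the data region.
#'
#' @param spec a [Spectrogram-class].
#' @param rule a [StandardizationRule-class].
#' @return a [Spectrogram-class] with exactly `rule@targetFrames` frames.
#' @export
standardizeLength <- function(spec, rule) {
  stopifnot(is(spec, "Spectrogram"), is(rule, "StandardizationRule"))
  target <- rule@targetFrames
  n <- ncol(spec@values)
  if (n == target) return(spec)
  if (n > target) {
    e <- n - target
    dropL <- e %/% 2L
    keep <- seq.int(dropL + 1L, dropL + target)
    padL <- max(0L, spec@padLeft - dropL)
    padR <- max(0L, spec@padRight - (e - dropL))
    if (padL + padR >= target)
      stop("cropping to ", target, " frames would leave no data region")
    spectrogram(spec@values[, keep, drop = FALSE], padL, padR)
  } else {
    d <- target - n
    addL <- d %/% 2L
    addR <- d - addL
    nb <- nrow(spec@values)
    vals <- cbind(matrix(0, nb, addL), spec@values, matrix(0, nb, addR))
    spectrogram(vals, spec@padLeft + addL, spec@padRight + addR)
  }
}

# Statistical mode of a character vector ignoring NA; deterministic
# tie-break by sorted order.
.fieldMode <- function(x) {
  x <- x[!is.na(x)]
  tab <- sort(table(x), decreasing = TRUE)
  nm <- names(tab)[tab == max(tab)]
  sort(nm)[1L]
}

.fitPredictCat <- function(response, predictors, missing) {
  obs <- !missing & !is.na(response)
  if (length(unique(response[obs])) < 2L) return(rep(.fieldMode(response), sum(missing)))
  df <- data.frame(.y = factor(response), predictors, stringsAsFactors = TRUE)
  fit <- suppressWarnings(nnet::multinom(.y ~ ., data = df[obs, , drop = FALSE],
                                         trace = FALSE))
  as.character(stats::predict(fit, newdata = df[missing, , drop = FALSE]))
}

#' Impute missing demographics by chained categorical regressions
#'
#' Missing `age_band`, `sex` and `location` values are filled in by a small
#' chained-equations scheme: each field is initialised with its mode and
#' then re-estimated for five sweeps by a categorical regression
#' (multinomial logit) on the other two fields, fitted on originally
#' observed rows.  Age band and sex are modelled at the patient level;
#' location at the recording level.  A patient with no observed metadata at
#' all receives the per-field mode of the rest of the cohort.
#'
#' @param x a [SoundCohort-class] or its metadata data.frame.
#' @param iterations number of chained sweeps, default 5.
#' @param seed integer seed (the fit itself is deterministic; the seed
#'   fixes any downstream use of the imputed table).
#' @return object of the same type as `x` with no missing `age_band`,
#'   `sex` or `location`; imputed positions are recorded in the
#'   `"imputed"` attribute of the metadata.
#' @export
imputeMetadata <- function(x, iterations = 5L, seed = 1L) {
  md <- if (is(x, "SoundCohort")) x@metadata else as.data.frame(x)
  fields <- c("age_band", "sex", "location")
  for (f in fields) {
    md[[f]][!is.na(md[[f]]) & md[[f]] == ""] <- NA
    if (all(is.na(md[[f]])))
      stop("field '", f, "' is missing for every recording; cannot impute")
  }
  set.seed(seed)
  wasMissing <- is.na(md[, fields])

  # patient-level view for demographics
  pat <- stats::aggregate(md[, c("age_band", "sex")],
                          by = list(patient_id = md$patient_id),
                          FUN = function(v) {
                            v <- v[!is.na(v)]
                            if (length(v)) v[1L] else NA_character_
                          })
  patMiss <- is.na(pat[, c("age_band", "sex")])

  # initialise with modes
  for (f in c("age_band", "sex")) pat[[f]][is.na(pat[[f]])] <- .fieldMode(pat[[f]])
  md$location[is.na(md$location)] <- .fieldMode(md$location)

  for (it in seq_len(iterations)) {
    if (any(patMiss[, "age_band"]))
      pat$age_band[patMiss[, "age_band"]] <-
        .fitPredictCat(pat$age_band, data.frame(sex = factor(pat$sex)),
                       patMiss[, "age_band"])
    if (any(patMiss[, "sex"]))
      pat$sex[patMiss[, "sex"]] <-
        .fitPredictCat(pat$sex, data.frame(age_band = factor(pat$age_band)),
                       patMiss[, "sex"])
    idx <- match(md$patient_id, pat$patient_id)
    md$age_band <- pat$age_band[idx]
    md$sex <- pat$sex[idx]
    if (any(wasMissing[, "location"]))
      md$location[wasMissing[, "location"]] <-
        .fitPredictCat(md$location,
                       data.frame(age_band = factor(md$age_band),
                                  sex = factor(md$sex)),
                       wasMissing[, "location"])
  }
  attr(md, "imputed") <- wasMissing
  if (is(x, "SoundCohort")) {
    x@metadata <- md
    validObject(x)
    x
  } else md
}

#' Write / read a cohort in the on-disk interchange format
#'
#' `writeCohort` writes one 16-bit PCM WAV file per recording, a
#' `metadata.csv` table (missing values as empty fields) and a JSON-lines
#' `manifest.jsonl` with one record per recording.  `readCohort` reads the
#' directory back into a [SoundCohort-class].
#'
#' @param cohort a [SoundCohort-class].
#' @param dir directory to write to / read from.
#' @return `writeCohort` the directory invisibly; `readCohort` a
#'   [SoundCohort-class].
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "SoundCohort"))
  dir.create(file.path(dir, "audio"), recursive = TRUE, showWarnings = FALSE)
  md <- cohort@metadata
  md$file <- file.path("audio", paste0(md$recording_id, ".wav"))
  md$sample_rate <- vapply(cohort@recordings, function(r) r@sampleRate, numeric(1))
  for (i in seq_along(cohort@recordings)) {
    r <- cohort@recordings[[i]]
    writeWav(r@waveform, r@sampleRate, file.path(dir, md$file[i]))
  }
  out <- md
  out[is.na(out)] <- ""
  utils::write.csv(out, file.path(dir, "metadata.csv"), row.names = FALSE)
  man <- file(file.path(dir, "manifest.jsonl"), "w")
  for (i in seq_len(nrow(md)))
    writeLines(jsonlite::toJSON(as.list(md[i, ]), auto_unbox = TRUE, na = "null"),
               man)
  close(man)
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  md <- utils::read.csv(file.path(dir, "metadata.csv"),
                        colClasses = "character")
  for (f in c("age_band", "sex", "location", "label"))
    md[[f]][md[[f]] == ""] <- NA
  recs <- vector("list", nrow(md))
  for (i in seq_len(nrow(md))) {
    w <- readWav(file.path(dir, md$file[i]))
    recs[[i]] <- audioRecording(md$recording_id[i], md$patient_id[i],
                                w$waveform, w$sampleRate)
  }
  soundCohort(recs, md[, c("recording_id", "patient_id", "age_band",
                           "sex", "location", "label")])
}
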