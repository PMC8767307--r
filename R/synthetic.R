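#' @include AllClasses.R signal_io.R
NULL

#' Construct a synthetic cohort specification
#'
#' Defaults describe the benchmark cohort used throughout the package's
#' tests: 120 patients with a realistic paediatric fraction, three
#' recordings per patient at locations drawn from the seven-site
#' vocabulary, a logistic
#' label model in which childhood and female sex raise the probability of
#' an abnormal diagnosis, and recording durations drawn from a
#' right-skewed log-normal law so the quantile pad/crop rule both pads and
#' crops.
#'
#' Acoustically, normal recordings are sustained harmonic tones under a
#' slow breathing envelope; abnormal recordings gate the same harmonics
#' into short bursts (crackle-like transients) with power equalised to the
#' sustained case, so class membership is carried by temporal texture
#' rather than by average band energy.  `signalEffect` interpolates the
#' gating depth between 0 (classes acoustically identical) and 1 (full
#' gating).  Each patient also carries a patient-specific tone shared
#' across that patient's recordings (`patientEffect`), and each location
#' applies a fixed spectral tilt.
#'
#' @param nPatients number of patients (default 120).
#' @param pChild probability a patient is a child (default 0.4).
#' @param pFemale probability a patient is female (default 0.5).
#' @param recordingsPerPatient recordings per patient (default 3);
#'   locations are drawn with replacement, so repeat sites occur.
#' @param labelModel logistic coefficients
#'   `c(intercept, beta_age, beta_sex)` with child and female coded 1;
#'   default `c(-1.2, 1.8, 0.6)`.
#' @param signalEffect class-signature gating depth in \[0, 1\] (default 0.8).
#' @param patientEffect amplitude of the patient-specific tone (default 0.5).
#' @param noiseSd white-noise standard deviation (default 0.1).
#' @param durationMeanlog,durationSdlog log-normal duration law in seconds
#'   (defaults `log(2)` and 0.35).
#' @param sampleRate Hz (default 2000).
#' @param seed master seed (default 1).
#' @return a [CohortSpec-class].
#' @export
cohortSpec <- function(nPatients = 120L, pChild = 0.4, pFemale = 0.5,
                       recordingsPerPatient = 3L,
                       labelModel = c(intercept = -1.2, beta_age = 1.8,
                                      beta_sex = 0.6),
                       signalEffect = 0.8, patientEffect = 0.5,
                       noiseSd = 0.1, durationMeanlog = log(2),
                       durationSdlog = 0.35, sampleRate = 2000,
                       seed = 1L) {
  new("CohortSpec", nPatients = as.integer(nPatients), pChild = pChild,
      pFemale = pFemale, recordingsPerPatient = as.integer(recordingsPerPatient),
      labelModel = as.numeric(labelModel), signalEffect = signalEffect,
      patientEffect = patientEffect, noiseSd = noiseSd,
      durationMeanlog = durationMeanlog, durationSdlog = durationSdlog,
      sampleRate = sampleRate, seed = as.integer(seed))
}

.subSeed <- function(seed, a, b = 0L) {
  as.integer((as.numeric(seed) * 48271 + a * 7919 + b * 104729) %% 2147483647)
}

#' Generate the patient-level cohort table
#'
#' Age band and sex are drawn independently per patient; the binary label
#' is Bernoulli with
#' `logit(p) = intercept + beta_age * child + beta_sex * female`.
#' Deterministic for a fixed `spec@seed`.
#'
#' @param spec a [CohortSpec-class].
#' @return data.frame with columns `patient_id`, `age_band`, `sex`,
#'   `label`.
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  set.seed(spec@seed)
  n <- spec@nPatients
  child <- stats::rbinom(n, 1L, spec@pChild)
  female <- stats::rbinom(n, 1L, spec@pFemale)
  eta <- spec@labelModel[1L] + spec@labelModel[2L] * child +
    spec@labelModel[3L] * female
  abnormal <- stats::rbinom(n, 1L, stats::plogis(eta))
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age_band = ifelse(child == 1L, "child", "adult"),
    sex = ifelse(female == 1L, "female", "male"),
    label = ifelse(abnormal == 1L, "abnormal", "normal"),
    stringsAsFactors = FALSE)
}

# patient-level latent acoustics, deterministic per (spec, patient index)
.patientAcoustics <- function(spec, patIdx) {
  set.seed(.subSeed(spec@seed, patIdx))
  list(f0 = stats::runif(1, 110, 190),
       patientTone = stats::runif(1, 300, 550),
       burstRate = stats::runif(1, 6, 10),
       locations = sample(AUSCULTATION_LOCATIONS, spec@recordingsPerPatient,
                          replace = TRUE))
}

.locationTilt <- stats::setNames(seq(-0.6, 0.6, length.out = 7L),
                                 AUSCULTATION_LOCATIONS)

#' Generate one synthetic recording
#'
#' Waveform = class signature (harmonic stack, gated into bursts for
#' abnormal patients) + patient-specific tone + location spectral tilt +
#' white noise; duration drawn from the configured log-normal law.
#' Deterministic per `(patient index, recording index, spec@seed)`.
#'
#' @param patient one row of [generateCohort()]'s table.
#' @param spec a [CohortSpec-class].
#' @param patIdx integer patient index.
#' @param recIdx integer recording index within the patient.
#' @param location auscultation location of the recording.
#' @return an [AudioRecording-class].
#' @export
generateRecording <- function(patient, spec, patIdx, recIdx, location) {
  acous <- .patientAcoustics(spec, patIdx)
  set.seed(.subSeed(spec@seed, patIdx, recIdx))
  sr <- spec@sampleRate
  dur <- min(8, max(0.5, exp(stats::rnorm(1, spec@durationMeanlog,
                                          spec@durationSdlog))))
  t <- seq(0, dur, by = 1 / sr)[-1L]
  harm <- function(f, a) a * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
  sig <- harm(acous$f0, 1) + harm(2 * acous$f0, 0.5) + harm(3 * acous$f0, 0.25)
  breath <- 0.75 + 0.25 * sin(2 * pi * 0.3 * t + stats::runif(1, 0, 2 * pi))
  if (patient$label == "abnormal") {
    # burst gating applied as a zero-mean log-amplitude envelope: the
    # mean log-power of every pixel matches the sustained class exactly,
    # so class membership is carried by temporal texture, not level
    duty <- 0.25
    phase <- (t * acous$burstRate + stats::runif(1)) %% 1
    # raised-cosine edges (8% of the cycle) keep the AM sidebands close
    # to the carrier instead of splattering broadband
    wEdge <- 0.08
    pulse <- ifelse(phase < wEdge, 0.5 * (1 - cos(pi * phase / wEdge)),
             ifelse(phase < duty, 1,
             ifelse(phase < duty + wEdge,
                    0.5 * (1 + cos(pi * (phase - duty) / wEdge)), 0)))
    logRange <- 1.4                    # log amplitude swing of the bursts
    env <- breath * exp(spec@signalEffect * logRange * (pulse - mean(pulse)))
  } else {
    env <- breath
  }
  gain <- exp(stats::rnorm(1, 0, 0.3))     # per-recording level (probe pressure)
  x <- gain * (sig * env + spec@patientEffect * harm(acous$patientTone, 1)) +
    stats::rnorm(length(t), sd = spec@noiseSd)
  tilt <- .locationTilt[[location]]
  x <- x + tilt * c(0, x[-length(x)])         # first-order spectral tilt
  x <- x / 6                                  # fixed scale into PCM range
                                              # (class-independent by design)
  audioRecording(sprintf("%s_R%02d", patient$patient_id, recIdx),
                 patient$patient_id, x, sr)
}

#' Generate a full synthetic dataset
#'
#' Draws the patient table with [generateCohort()], assigns each patient
#' `recordingsPerPatient` auscultation locations (with replacement), synthesises all
#' waveforms, and returns them as a [SoundCohort-class].  Writing the
#' cohort to disk ([writeCohort()]) produces WAV files, a metadata CSV and
#' a JSON-lines manifest that round-trip through [readCohort()] at 16-bit
#' PCM precision.
#'
#' @param spec a [CohortSpec-class].
#' @return a [SoundCohort-class].
#' @export
generateDataset <- function(spec) {
  pats <- generateCohort(spec)
  recs <- list()
  rows <- list()
  for (p in seq_len(nrow(pats))) {
    acous <- .patientAcoustics(spec, p)
    for (r in seq_len(spec@recordingsPerPatient)) {
      loc <- acous$locations[r]
      rec <- generateRecording(pats[p, ], spec, p, r, loc)
      recs[[length(recs) + 1L]] <- rec
      rows[[length(rows) + 1L]] <- data.frame(
        recording_id = rec@recordingId, patient_id = pats$patient_id[p],
        age_band = pats$age_band[p], sex = pats$sex[p], location = loc,
        label = pats$label[p], stringsAsFactors = FALSE)
    }
  }
  soundCohort(recs, do.call(rbind, rows))
}
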