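#' @import methods
NULL

#' Spectrogram with explicit padding bookkeeping
#'
#' A log-power time-frequency grid (frequency bins in rows, time frames in
#' columns) together with the number of all-zero frames that were added on
#' the left and right when the recording was centre-padded to a common
#' length.  The frames between the pads are the \emph{data region}; every
#' augmentation in the package touches only that region.
#'
#' @slot values numeric matrix, frequency bins x time frames (dB-like units).
#' @slot padLeft integer, number of zero frames preceding the data region.
#' @slot padRight integer, number of zero frames following the data region.
#'
#' @seealso [computeSpectrogram()], [standardizeLength()], [dataRegion()]
#' @export
setClass("Spectrogram",
  representation(values = "matrix", padLeft = "integer", padRight = "integer"),
  prototype(values = matrix(0, 1, 1), padLeft = 0L, padRight = 0L)
)

setValidity("Spectrogram", function(object) {
  msg <- character()
  nt <- ncol(object@values)
  if (object@padLeft < 0L || object@padRight < 0L)
    msg <- c(msg, "pad counts must be non-negative")
  if (object@padLeft + object@padRight >= nt)
    msg <- c(msg, sprintf(
      "padLeft + padRight (%d) must be < total frames (%d)",
      object@padLeft + object@padRight, nt))
  if (object@padLeft > 0L &&
      any(object@values[, seq_len(object@padLeft), drop = FALSE] != 0))
    msg <- c(msg, "left padding frames must be exactly zero")
  if (object@padRight > 0L &&
      any(object@values[, nt - seq_len(object@padRight) + 1L, drop = FALSE] != 0))
    msg <- c(msg, "right padding frames must be exactly zero")
  if (length(msg)) msg else TRUE
})

#' Length-standardization rule
#'
#' Target frame count derived from the cohort's recording-length
#' distribution: the interpolated quantile (default the 75th percentile) of
#' the per-recording frame counts, rounded half-up.
#'
#' @slot targetFrames integer target number of frames.
#' @slot quantile numeric, the quantile of the length distribution used.
#' @export
setClass("StandardizationRule",
  representation(targetFrames = "integer", quantile = "numeric"),
  prototype(targetFrames = 1L, quantile = 0.75)
)

setValidity("StandardizationRule", function(object) {
  msg <- character()
  if (object@targetFrames < 1L) msg <- c(msg, "targetFrames must be >= 1")
  if (object@quantile <= 0 || object@quantile > 1)
    msg <- c(msg, "quantile must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Band-masking specification
#'
#' Describes the stochastic band-masking augmentation: how many bands are
#' zeroed along each axis, the band widths as fractions of the data region,
#' and the expected fraction of data-region cells the calibrated scheme
#' should mask on average.
#'
#' @slot nTimeBands integer, bands zeroed along the time axis (default 5).
#' @slot nFreqBands integer, bands zeroed along the frequency axis (default 2).
#' @slot timeBandWidth numeric, band width as a fraction of data frames.
#' @slot freqBandWidth numeric, band width as a fraction of frequency bins.
#' @slot targetCoverage numeric, expected masked fraction of the data region.
#' @seealso [calibrateBandWidths()], [specMask()]
#' @export
setClass("MaskSpec",
  representation(nTimeBands = "integer", nFreqBands = "integer",
                 timeBandWidth = "numeric", freqBandWidth = "numeric",
                 targetCoverage = "numeric"),
  prototype(nTimeBands = 5L, nFreqBands = 2L,
            timeBandWidth = 0.1, freqBandWidth = 0.25, targetCoverage = 0.5)
)

setValidity("MaskSpec", function(object) {
  msg <- character()
  if (object@nTimeBands < 0L || object@nFreqBands < 0L)
    msg <- c(msg, "band counts must be non-negative")
  if (object@timeBandWidth < 0 || object@timeBandWidth >= 1 ||
      object@freqBandWidth < 0 || object@freqBandWidth >= 1)
    msg <- c(msg, "band widths must lie in [0, 1)")
  if (object@targetCoverage < 0 || object@targetCoverage >= 1)
    msg <- c(msg, "targetCoverage must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' A single auscultation recording
#'
#' @slot recordingId character, unique within a cohort.
#' @slot patientId character, the patient the recording belongs to.
#' @slot waveform numeric amplitude sequence (arbitrary units).
#' @slot sampleRate numeric sampling rate in Hz.
#' @export
setClass("AudioRecording",
  representation(recordingId = "character", patientId = "character",
                 waveform = "numeric", sampleRate = "numeric")
)

setValidity("AudioRecording", function(object) {
  msg <- character()
  if (length(object@waveform) < 1L) msg <- c(msg, "waveform must be non-empty")
  if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' The seven auscultation locations recognised by the package
#' @export
AUSCULTATION_LOCATIONS <- c(
  "trachea", "anterior left", "anterior right",
  "posterior left", "posterior right", "lateral left", "lateral right")

#' A cohort of recordings with per-recording metadata
#'
#' The central data container: a list of [AudioRecording-class] objects and
#' a metadata table with one row per recording (columns `recording_id`,
#' `patient_id`, `age_band`, `sex`, `location`, `label`).  Age band and sex
#' are patient-level attributes repeated on each of the patient's rows;
#' location is per-recording; `label` is the downstream binary diagnosis
#' (`"normal"`/`"abnormal"`) and is never used during self-supervised
#' pre-training.
#'
#' @slot recordings list of [AudioRecording-class].
#' @slot metadata data.frame, one row per recording.
#' @export
setClass("SoundCohort",
  representation(recordings = "list", metadata = "data.frame")
)

setValidity("SoundCohort", function(object) {
  msg <- character()
  need <- c("recording_id", "patient_id", "age_band", "sex", "location", "label")
  missing_cols <- setdiff(need, names(object@metadata))
  if (length(missing_cols))
    msg <- c(msg, paste("metadata lacks columns:", paste(missing_cols, collapse = ", ")))
  if (length(object@recordings) != nrow(object@metadata))
    msg <- c(msg, "one metadata row per recording required")
  ids <- vapply(object@recordings, function(r) r@recordingId, character(1))
  if (anyDuplicated(ids)) msg <- c(msg, "recording ids must be unique")
  if (length(ids) && !identical(ids, as.character(object@metadata$recording_id)))
    msg <- c(msg, "metadata rows must be in recording order")
  loc <- object@metadata$location
  bad <- !is.na(loc) & !(loc %in% AUSCULTATION_LOCATIONS)
  if (any(bad))
    msg <- c(msg, paste("unknown auscultation location:",
                        paste(unique(loc[bad]), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Configuration of one pre-training scheme
#'
#' Twelve schemes are supported: five augmentation-based ones, where the two
#' views of a positive pair are independent stochastic transforms of the same
#' spectrogram, and seven metadata-based ones, where the two views are two
#' different recordings of the same patient (no augmentation) and batches may
#' be constrained so all members share a negative-selection trait.
#'
#' @slot name scheme key, see [schemeNames()].
#' @slot mode `"augmentation"` or `"metadata"`.
#' @slot augmentation augmentation key for augmentation mode, otherwise NA.
#' @slot positiveRule `"augmented_pair"`, `"same_patient"`,
#'   `"same_patient_same_loc"` or `"same_patient_diff_loc"`.
#' @slot negativeTrait character vector, subset of
#'   `c("age_band", "sex", "location")`; empty when batches are unconstrained.
#' @slot weakLabelField metadata field used as a weak label with the
#'   supervised-contrastive loss (only `pos_sim_age` sets it), otherwise NA.
#' @export
setClass("SchemeConfig",
  representation(name = "character", mode = "character",
                 augmentation = "character", positiveRule = "character",
                 negativeTrait = "character", weakLabelField = "character")
)

setValidity("SchemeConfig", function(object) {
  msg <- character()
  if (!object@mode %in% c("augmentation", "metadata"))
    msg <- c(msg, "mode must be 'augmentation' or 'metadata'")
  if (object@mode == "augmentation" && is.na(object@augmentation))
    msg <- c(msg, "augmentation mode requires an augmentation key")
  if (object@mode == "metadata" && !is.na(object@augmentation))
    msg <- c(msg, "metadata mode must not carry an augmentation key")
  if (!is.na(object@weakLabelField) && object@name != "pos_sim_age")
    msg <- c(msg, "weakLabelField is only used by pos_sim_age")
  if (length(msg)) msg else TRUE
})

#' A contrastive batch of paired views
#'
#' Holds `2 * batchSize` spectrogram views.  For each anchor `i` the
#' candidate set `A(i)` is every other view in the batch; `P(i)` is the
#' positive set, always containing the anchor's partner view (its augmented
#' twin, or the second recording of the same patient) and, under a weak-label
#' scheme, every same-label view.
#'
#' @slot views list of [Spectrogram-class] objects, length `2 * batchSize`.
#' @slot recordingIds character, the source recording of each view.
#' @slot patientIds character, the source patient of each view.
#' @slot partner integer, index of each view's paired positive.
#' @slot positiveSets list of integer vectors, `P(i)` per anchor.
#' @slot traitName character, negative-selection trait or NA.
#' @slot traitValue character, shared trait value of the batch or NA.
#' @export
setClass("ContrastiveBatch",
  representation(views = "list", recordingIds = "character",
                 patientIds = "character", partner = "integer",
                 positiveSets = "list", traitName = "character",
                 traitValue = "character")
)

setValidity("ContrastiveBatch", function(object) {
  msg <- character()
  n <- length(object@views)
  if (n %% 2L != 0L) msg <- c(msg, "a batch must hold an even number of views")
  if (length(object@partner) != n || length(object@positiveSets) != n ||
      length(object@recordingIds) != n || length(object@patientIds) != n)
    msg <- c(msg, "per-view slots must all have length(views)")
  if (n && any(object@partner == seq_len(n)))
    msg <- c(msg, "a view cannot be its own partner")
  for (i in seq_len(n)) {
    P <- object@positiveSets[[i]]
    if (length(P) == 0L) { msg <- c(msg, sprintf("P(%d) is empty", i)); break }
    if (i %in% P) { msg <- c(msg, sprintf("P(%d) contains the anchor", i)); break }
    if (!(object@partner[i] %in% P)) {
      msg <- c(msg, sprintf("P(%d) lacks the partner view", i)); break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Result of one downstream evaluation
#'
#' @slot auroc numeric point estimate on the test set.
#' @slot ciLow,ciHigh numeric percentile bootstrap interval bounds.
#' @slot level numeric confidence level.
#' @slot bootstrapValues numeric, one AUROC per bootstrap replicate.
#' @slot perReplicateModelValues numeric, AUROCs of parallel replicate
#'   models when several were trained (possibly empty).
#' @export
setClass("EvalResult",
  representation(auroc = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 level = "numeric", bootstrapValues = "numeric",
                 perReplicateModelValues = "numeric"),
  prototype(level = 0.95, perReplicateModelValues = numeric())
)

setValidity("EvalResult", function(object) {
  msg <- character()
  if (length(object@auroc) != 1L) msg <- c(msg, "auroc must be scalar")
  if (length(object@ciLow) == 1L && length(object@ciHigh) == 1L &&
      (object@ciLow > object@auroc + 1e-12 || object@ciHigh < object@auroc - 1e-12))
    msg <- c(msg, "CI must contain the point estimate")
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic auscultation cohort
#'
#' Defines the statistical structure the contrastive framework exploits:
#' patient-level demographics correlated with a binary diagnosis through a
#' logistic model, several recordings per patient at named auscultation
#' locations, a patient-specific acoustic component shared across a
#' patient's recordings, and a class-dependent temporal signature
#' (sustained tonal sounds for normal patients, burst-gated sounds for
#' abnormal ones).
#'
#' @slot nPatients integer number of patients.
#' @slot pChild numeric probability a patient is a child.
#' @slot pFemale numeric probability a patient is female.
#' @slot recordingsPerPatient integer, recordings per patient (1..7).
#' @slot labelModel named numeric `c(intercept, beta_age, beta_sex)` for the
#'   logistic label model (child and female coded 1).
#' @slot signalEffect numeric in \[0, 1\], depth of the class-specific burst
#'   gating that separates abnormal from normal recordings.
#' @slot patientEffect numeric, amplitude of the patient-specific component
#'   shared across a patient's recordings.
#' @slot noiseSd numeric, white-noise standard deviation.
#' @slot durationMeanlog,durationSdlog numeric, log-normal law of recording
#'   durations in seconds (right-skewed so the quantile pad/crop rule is
#'   exercised on both sides).
#' @slot sampleRate numeric Hz.
#' @slot seed integer master seed.
#' @export
setClass("CohortSpec",
  representation(nPatients = "integer", pChild = "numeric", pFemale = "numeric",
                 recordingsPerPatient = "integer", labelModel = "numeric",
                 signalEffect = "numeric", patientEffect = "numeric",
                 noiseSd = "numeric", durationMeanlog = "numeric",
                 durationSdlog = "numeric", sampleRate = "numeric",
                 seed = "integer")
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nPatients < 1L) msg <- c(msg, "nPatients must be >= 1")
  for (p in c("pChild", "pFemale"))
    if (slot(object, p) < 0 || slot(object, p) > 1)
      msg <- c(msg, paste(p, "must lie in [0, 1]"))
  if (object@recordingsPerPatient < 1L)
    msg <- c(msg, "recordingsPerPatient must be >= 1")
  if (length(object@labelModel) != 3L)
    msg <- c(msg, "labelModel must be c(intercept, beta_age, beta_sex)")
  if (object@signalEffect < 0 || object@signalEffect > 1)
    msg <- c(msg, "signalEffect must lie in [0, 1]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Training-run configuration
#'
#' Carries the hyper-parameters of the three pipelines.  The `"full"`
#' profile holds the full-scale settings (batch 16, learning rate 1e-5, L2
#' 1e-6 pre-train / 1e-2 downstream, 5,000 linear-evaluation epochs, 25
#' fine-tuning epochs, 500/1,000 baseline epochs); the `"desk"` profile is a
#' reduced configuration sized so complete experiments run in minutes on one
#' CPU.  See [runConfig()].
#'
#' @slot profile character, `"desk"` or `"full"`.
#' @slot batchSize integer contrastive/downstream batch size.
#' @slot lr numeric learning rate (Adam) for pre-training, linear
#'   evaluation and the baseline.
#' @slot lrFinetune numeric learning rate for end-to-end fine-tuning
#'   (equal to `lr` in the full-scale profile).
#' @slot weightDecayPretrain,weightDecayDownstream numeric L2 penalties.
#' @slot epochsPretrain,epochsLinear,epochsFinetune,epochsBaseline integers.
#' @slot labelFraction numeric fraction of fine-tune labels used.
#' @slot nParallel integer parallel replicate models.
#' @slot temperature numeric softmax temperature of the contrastive losses.
#' @slot encoder character encoder architecture key.
#' @slot embeddingDim,projectionDim integers.
#' @slot seed integer.
#' @export
setClass("RunConfig",
  representation(profile = "character", batchSize = "integer", lr = "numeric",
                 lrFinetune = "numeric",
                 weightDecayPretrain = "numeric", weightDecayDownstream = "numeric",
                 epochsPretrain = "integer", epochsLinear = "integer",
                 epochsFinetune = "integer", epochsBaseline = "integer",
                 labelFraction = "numeric", nParallel = "integer",
                 temperature = "numeric", encoder = "character",
                 embeddingDim = "integer", projectionDim = "integer",
                 seed = "integer")
)

setValidity("RunConfig", function(object) {
  msg <- character()
  if (object@labelFraction <= 0 || object@labelFraction > 1)
    msg <- c(msg, "labelFraction must lie in (0, 1]")
  counts <- c(object@batchSize, object@epochsPretrain, object@epochsLinear,
              object@epochsFinetune, object@epochsBaseline, object@nParallel)
  if (any(counts < 1L)) msg <- c(msg, "all counts must be positive")
  if (object@temperature <= 0) msg <- c(msg, "temperature must be > 0")
  if (length(msg)) msg else TRUE
})
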