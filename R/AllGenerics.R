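#' @include AllClasses.R
NULL

#' Accessors for Spectrogram objects
#'
#' `specValues` returns the full grid, `padLeft`/`padRight` the pad frame
#' counts, `nFramesTotal` the total frame count, `dataFrames` the column
#' indices of the non-padded data region, and `dataRegion` the data-region
#' sub-matrix.
#'
#' @param x a [Spectrogram-class].
#' @return See details; `dataFrames` returns an integer vector of column
#'   indices, `dataRegion` a matrix.
#' @aliases specValues padLeft padRight nFramesTotal dataFrames dataRegion
#' @name spectrogram-accessors
#' @export
setGeneric("specValues", function(x) standardGeneric("specValues"))
#' @rdname spectrogram-accessors
#' @export
setGeneric("padLeft", function(x) standardGeneric("padLeft"))
#' @rdname spectrogram-accessors
#' @export
setGeneric("padRight", function(x) standardGeneric("padRight"))
#' @rdname spectrogram-accessors
#' @export
setGeneric("nFramesTotal", function(x) standardGeneric("nFramesTotal"))
#' @rdname spectrogram-accessors
#' @export
setGeneric("dataFrames", function(x) standardGeneric("dataFrames"))
#' @rdname spectrogram-accessors
#' @export
setGeneric("dataRegion", function(x) standardGeneric("dataRegion"))

#' @rdname spectrogram-accessors
setMethod("specValues", "Spectrogram", function(x) x@values)
#' @rdname spectrogram-accessors
setMethod("padLeft", "Spectrogram", function(x) x@padLeft)
#' @rdname spectrogram-accessors
setMethod("padRight", "Spectrogram", function(x) x@padRight)
#' @rdname spectrogram-accessors
setMethod("nFramesTotal", "Spectrogram", function(x) ncol(x@values))
#' @rdname spectrogram-accessors
setMethod("dataFrames", "Spectrogram", function(x) {
  seq.int(x@padLeft + 1L, ncol(x@values) - x@padRight)
})
#' @rdname spectrogram-accessors
setMethod("dataRegion", "Spectrogram", function(x) {
  x@values[, dataFrames(x), drop = FALSE]
})

#' Accessors for SoundCohort objects
#'
#' @param x a [SoundCohort-class].
#' @aliases recordings cohortMetadata nRecordings
#' @name cohort-accessors
#' @export
setGeneric("recordings", function(x) standardGeneric("recordings"))
#' @rdname cohort-accessors
#' @export
setGeneric("cohortMetadata", function(x) standardGeneric("cohortMetadata"))
#' @rdname cohort-accessors
#' @export
setGeneric("nRecordings", function(x) standardGeneric("nRecordings"))

#' @rdname cohort-accessors
setMethod("recordings", "SoundCohort", function(x) x@recordings)
#' @rdname cohort-accessors
setMethod("cohortMetadata", "SoundCohort", function(x) x@metadata)
#' @rdname cohort-accessors
setMethod("nRecordings", "SoundCohort", function(x) length(x@recordings))

#' Accessors for EvalResult objects
#'
#' @param x an [EvalResult-class].
#' @aliases auroc aurocCI bootstrapValues
#' @name evalresult-accessors
#' @export
setGeneric("auroc", function(x) standardGeneric("auroc"))
#' @rdname evalresult-accessors
#' @export
setGeneric("aurocCI", function(x) standardGeneric("aurocCI"))
#' @rdname evalresult-accessors
#' @export
setGeneric("bootstrapValues", function(x) standardGeneric("bootstrapValues"))

#' @rdname evalresult-accessors
setMethod("auroc", "EvalResult", function(x) x@auroc)
#' @rdname evalresult-accessors
setMethod("aurocCI", "EvalResult", function(x) c(low = x@ciLow, high = x@ciHigh))
#' @rdname evalresult-accessors
setMethod("bootstrapValues", "EvalResult", function(x) x@bootstrapValues)

setMethod("show", "Spectrogram", function(object) {
  cat(sprintf("Spectrogram: %d bins x %d frames (pad %d|%d, data %d frames)\n",
              nrow(object@values), ncol(object@values),
              object@padLeft, object@padRight,
              ncol(object@values) - object@padLeft - object@padRight))
})

setMethod("show", "SoundCohort", function(object) {
  md <- object@metadata
  cat(sprintf("SoundCohort: %d recordings from %d patients\n",
              nrow(md), length(unique(md$patient_id))))
  if (nrow(md)) {
    lab <- table(md$label, useNA = "ifany")
    cat("  labels:", paste(sprintf("%s=%d", names(lab), lab), collapse = ", "), "\n")
  }
})

setMethod("show", "SchemeConfig", function(object) {
  cat(sprintf("SchemeConfig '%s' (%s mode)\n", object@name, object@mode))
  if (!is.na(object@augmentation))
    cat("  augmentation:", object@augmentation, "\n")
  cat("  positive rule:", object@positiveRule, "\n")
  if (length(object@negativeTrait))
    cat("  negative trait:", paste(object@negativeTrait, collapse = " + "), "\n")
  if (!is.na(object@weakLabelField))
    cat("  weak-label field:", object@weakLabelField, "\n")
})

setMethod("show", "ContrastiveBatch", function(object) {
  cat(sprintf("ContrastiveBatch: %d views (%d pairs)",
              length(object@views), length(object@views) %/% 2L))
  if (!is.na(object@traitName))
    cat(sprintf("; shared %s = %s", object@traitName, object@traitValue))
  cat("\n")
})

setMethod("show", "EvalResult", function(object) {
  cat(sprintf("EvalResult: AUROC %.3f (%.0f%% CI %.3f-%.3f, %d bootstrap replicates)\n",
              object@auroc, 100 * object@level, object@ciLow, object@ciHigh,
              length(object@bootstrapValues)))
})

setMethod("show", "RunConfig", function(object) {
  cat(sprintf(
    "RunConfig '%s': batch %d, lr %g/%g, T %g, encoder %s (N=%d, proj=%d)\n",
    object@profile, object@batchSize, object@lr, object@lrFinetune,
    object@temperature,
    object@encoder, object@embeddingDim, object@projectionDim))
  cat(sprintf(
    "  epochs: pretrain %d, linear %d, finetune %d, baseline %d; wd %g/%g; label fraction %g x%d\n",
    object@epochsPretrain, object@epochsLinear, object@epochsFinetune,
    object@epochsBaseline, object@weightDecayPretrain,
    object@weightDecayDownstream, object@labelFraction, object@nParallel))
})
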