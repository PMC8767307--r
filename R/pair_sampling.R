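#' @include AllClasses.R AllGenerics.R augment.R
NULL

#' The twelve pre-training scheme keys
#'
#' Five augmentation schemes (two independent stochastic transforms of one
#' recording form the positive pair) and seven metadata schemes (the
#' positive pair is two different recordings of one patient, with optional
#' positive rules on auscultation location and optional negative-selection
#' traits that constrain batch composition).
#'
#' @return character vector of the twelve keys.
#' @export
schemeNames <- function() {
  c(augmentationNames(),
    "pos_sim_age", "neg_sim_age", "neg_sim_sex", "neg_sim_age_sex",
    "pos_same_loc", "pos_dif_loc", "pos_same_loc_neg_same_loc")
}

#' Build the configuration of a pre-training scheme
#'
#' For `neg_*` schemes the positive rule is "any two recordings of the same
#' patient"; the negative trait lists the metadata fields every batch
#' member must share.  `pos_sim_age` uses the age band as a weak label with
#' the supervised-contrastive loss.  `pos_same_loc_neg_same_loc` takes the
#' positive pair at one location and constrains the whole batch to that
#' location.
#'
#' @param name one of [schemeNames()].
#' @return a [SchemeConfig-class].
#' @export
schemeConfig <- function(name) {
  if (!name %in% schemeNames())
    stop("unknown scheme '", name, "'; the 12 valid schemes are: ",
         paste(schemeNames(), collapse = ", "))
  if (name %in% augmentationNames())
    return(new("SchemeConfig", name = name, mode = "augmentation",
               augmentation = name, positiveRule = "augmented_pair",
               negativeTrait = character(), weakLabelField = NA_character_))
  cfg <- switch(name,
    pos_sim_age = list(rule = "same_patient", trait = character(),
                       weak = "age_band"),
    neg_sim_age = list(rule = "same_patient", trait = "age_band", weak = NA),
    neg_sim_sex = list(rule = "same_patient", trait = "sex", weak = NA),
    neg_sim_age_sex = list(rule = "same_patient",
                           trait = c("age_band", "sex"), weak = NA),
    pos_same_loc = list(rule = "same_patient_same_loc", trait = character(),
                        weak = NA),
    pos_dif_loc = list(rule = "same_patient_diff_loc", trait = character(),
                       weak = NA),
    pos_same_loc_neg_same_loc = list(rule = "same_patient_same_loc",
                                     trait = "location", weak = NA))
  new("SchemeConfig", name = name, mode = "metadata",
      augmentation = NA_character_, positiveRule = cfg$rule,
      negativeTrait = cfg$trait, weakLabelField = as.character(cfg$weak))
}

# All eligible same-patient recording-index pairs under a positive rule.
# Returns a list keyed by patient id; each element a 2-column index matrix.
.eligiblePairs <- function(metadata, positiveRule, location = NULL) {
  split_idx <- split(seq_len(nrow(metadata)), metadata$patient_id)
  out <- lapply(split_idx, function(idx) {
    if (length(idx) < 2L) return(matrix(integer(), 0L, 2L))
    cmb <- t(utils::combn(idx, 2L))
    loc <- metadata$location
    keep <- switch(positiveRule,
      same_patient = rep(TRUE, nrow(cmb)),
      same_patient_same_loc = !is.na(loc[cmb[, 1L]]) &
        loc[cmb[, 1L]] == loc[cmb[, 2L]],
      same_patient_diff_loc = !is.na(loc[cmb[, 1L]]) & !is.na(loc[cmb[, 2L]]) &
        loc[cmb[, 1L]] != loc[cmb[, 2L]],
      stop("unknown positive rule ", positiveRule))
    if (!is.null(location))
      keep <- keep & !is.na(loc[cmb[, 1L]]) & loc[cmb[, 1L]] == location &
        loc[cmb[, 2L]] == location
    cmb[keep, , drop = FALSE]
  })
  out[vapply(out, nrow, integer(1)) > 0L]
}

#' Sample same-patient positive view pairs
#'
#' Emits positive pairs for the metadata schemes: two distinct recordings
#' of one patient satisfying the scheme's positive rule, with no
#' augmentation applied.  Patients with no eligible pair are skipped (a
#' single warning reports how many); a cohort with no eligible patient is
#' an error.  Patients are drawn uniformly with replacement; the eligible
#' pair within a patient is drawn uniformly.
#'
#' @param cohort a [SoundCohort-class].
#' @param scheme a metadata-mode [SchemeConfig-class].
#' @param nPairs number of pairs to emit.
#' @return list of length `nPairs`; each element an integer vector of two
#'   recording indices into `recordings(cohort)`.
#' @export
positiveViewsSamePatient <- function(cohort, scheme, nPairs) {
  stopifnot(is(cohort, "SoundCohort"), is(scheme, "SchemeConfig"),
            scheme@mode == "metadata")
  md <- cohort@metadata
  pairs <- .eligiblePairs(md, scheme@positiveRule)
  nPatients <- length(unique(md$patient_id))
  nSkipped <- nPatients - length(pairs)
  if (length(pairs) == 0L)
    stop("no patient has an eligible positive pair under scheme '",
         scheme@name, "'")
  if (nSkipped > 0L)
    warning(nSkipped, " patient(s) without an eligible pair under scheme '",
            scheme@name, "' were skipped")
  who <- sample(names(pairs), nPairs, replace = TRUE)
  lapply(who, function(pid) {
    pm <- pairs[[pid]]
    pm[sample.int(nrow(pm), 1L), ]
  })
}

# Trait value of each patient: single value for age/sex traits, joined by
# "|" for compound traits.
.patientTraitValues <- function(metadata, trait) {
  pat <- unique(metadata[, c("patient_id", intersect(trait, c("age_band", "sex"))),
                         drop = FALSE])
  vals <- do.call(paste, c(pat[, setdiff(names(pat), "patient_id"), drop = FALSE],
                           sep = "|"))
  stats::setNames(vals, pat$patient_id)
}

#' Generate negative-trait-constrained contrastive batches
#'
#' Implements constrained batch generation for the `neg_*` schemes: every
#' recording in a batch shares the value of the negative-selection trait,
#' so all in-batch negatives are "hard" with respect to that trait.
#'
#' Sampling law: a trait value is admissible if at least `batchSize`
#' distinct patients hold it and have an eligible positive pair; each
#' batch first draws a trait value with probability proportional to its
#' eligible-patient count, then `batchSize` distinct patients uniformly
#' without replacement, then one eligible pair per patient uniformly.
#' Patients are re-sampled with replacement across batches, so small trait
#' cells can still fill batches of 16.
#'
#' @param cohort a [SoundCohort-class].
#' @param scheme a [SchemeConfig-class] with a non-empty negative trait.
#' @param specs list of standardized [Spectrogram-class] views, one per
#'   recording of the cohort.
#' @param batchSize patients (= positive pairs) per batch.
#' @param nBatches number of batches to generate.
#' @return list of [ContrastiveBatch-class] objects.
#' @export
buildNegativeConstrainedBatches <- function(cohort, scheme, specs,
                                            batchSize = 16L, nBatches = 1L) {
  stopifnot(is(scheme, "SchemeConfig"), length(scheme@negativeTrait) > 0L)
  md <- cohort@metadata
  trait <- scheme@negativeTrait
  if (identical(trait, "location")) {
    locs <- unique(md$location[!is.na(md$location)])
    cells <- lapply(stats::setNames(locs, locs), function(v)
      .eligiblePairs(md, scheme@positiveRule, location = v))
  } else {
    pv <- .patientTraitValues(md, trait)
    allPairs <- .eligiblePairs(md, scheme@positiveRule)
    vals <- unique(pv)
    cells <- lapply(stats::setNames(vals, vals), function(v)
      allPairs[names(allPairs) %in% names(pv)[pv == v]])
  }
  counts <- vapply(cells, length, integer(1))
  ok <- counts >= batchSize
  if (!any(ok))
    stop("no trait value has >= ", batchSize,
         " eligible patients under scheme '", scheme@name, "'; counts: ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  traitName <- paste(trait, collapse = "+")
  out <- vector("list", nBatches)
  pool <- counts[ok] / sum(counts[ok])
  for (b in seq_len(nBatches)) {
    v <- sample(names(pool), 1L, prob = pool)
    patients <- sample(names(cells[[v]]), batchSize)
    pairIdx <- lapply(patients, function(pid) {
      pm <- cells[[v]][[pid]]
      pm[sample.int(nrow(pm), 1L), ]
    })
    out[[b]] <- .assembleBatch(pairIdx, cohort, specs,
                               traitName = traitName, traitValue = v)
  }
  out
}

# interleave pairs into a batch object: views 2k-1 and 2k are pair k
.assembleBatch <- function(pairIdx, cohort, specs, traitName = NA_character_,
                           traitValue = NA_character_) {
  md <- cohort@metadata
  idx <- unlist(lapply(pairIdx, as.integer))
  n <- length(idx)
  partner <- as.integer(seq_len(n) + c(1L, -1L))
  new("ContrastiveBatch",
      views = specs[idx],
      recordingIds = md$recording_id[idx],
      patientIds = md$patient_id[idx],
      partner = partner,
      positiveSets = as.list(partner),
      traitName = traitName, traitValue = traitValue)
}

#' Weak-label positive sets
#'
#' For the supervised-contrastive scheme: sets `P(i)` to every other view
#' whose patient shares the anchor's value of `field`, always including the
#' anchor's same-patient partner view (so `P(i)` can never be empty).
#'
#' @param batch a [ContrastiveBatch-class].
#' @param field metadata field used as weak label (e.g. `"age_band"`).
#' @param cohort the [SoundCohort-class] the batch was drawn from.
#' @return the batch with updated `positiveSets`.
#' @export
weakLabelPositives <- function(batch, field, cohort) {
  md <- cohort@metadata
  pat <- unique(md[, c("patient_id", field)])
  vals <- stats::setNames(pat[[field]], pat$patient_id)[batch@patientIds]
  if (anyNA(vals)) stop("field '", field, "' missing for some batch members")
  n <- length(batch@views)
  batch@positiveSets <- lapply(seq_len(n), function(i) {
    P <- setdiff(which(vals == vals[i]), i)
    sort(unique(c(P, batch@partner[i])))
  })
  validObject(batch)
  batch
}

#' Generate contrastive batches for any scheme
#'
#' Unified batch stream used by [pretrain()].  Augmentation schemes draw
#' `batchSize` distinct recordings and emit two independent stochastic
#' views of each; metadata schemes draw `batchSize` distinct patients
#' (trait-constrained for `neg_*` schemes) and emit two recordings of each
#' patient; `pos_sim_age` additionally expands the positive sets with the
#' age-band weak label.
#'
#' @inheritParams buildNegativeConstrainedBatches
#' @param m [MaskSpec-class] used by masking augmentations.
#' @return list of [ContrastiveBatch-class].
#' @export
contrastiveBatches <- function(cohort, scheme, specs, batchSize = 16L,
                               nBatches = 1L, m = maskSpec()) {
  stopifnot(is(scheme, "SchemeConfig"))
  md <- cohort@metadata
  if (scheme@mode == "augmentation") {
    if (nrow(md) < batchSize)
      stop("cohort has fewer recordings than one batch")
    out <- vector("list", nBatches)
    for (b in seq_len(nBatches)) {
      idx <- sample.int(nrow(md), batchSize)
      views <- vector("list", 2L * batchSize)
      vidx <- integer(2L * batchSize)
      for (k in seq_along(idx)) {
        views[[2L * k - 1L]] <- applyAugmentation(specs[[idx[k]]],
                                                  scheme@augmentation, m)
        views[[2L * k]] <- applyAugmentation(specs[[idx[k]]],
                                             scheme@augmentation, m)
        vidx[c(2L * k - 1L, 2L * k)] <- idx[k]
      }
      n <- 2L * batchSize
      partner <- as.integer(seq_len(n) + c(1L, -1L))
      out[[b]] <- new("ContrastiveBatch", views = views,
                      recordingIds = md$recording_id[vidx],
                      patientIds = md$patient_id[vidx],
                      partner = partner, positiveSets = as.list(partner),
                      traitName = NA_character_, traitValue = NA_character_)
    }
    return(out)
  }
  if (length(scheme@negativeTrait) > 0L) {
    out <- buildNegativeConstrainedBatches(cohort, scheme, specs,
                                           batchSize, nBatches)
  } else {
    pairs <- .eligiblePairs(md, scheme@positiveRule)
    if (length(pairs) == 0L)
      stop("no patient has an eligible positive pair under scheme '",
           scheme@name, "'")
    if (length(pairs) < batchSize)
      stop("only ", length(pairs), " eligible patients for batch size ",
           batchSize, " under scheme '", scheme@name, "'")
    out <- vector("list", nBatches)
    for (b in seq_len(nBatches)) {
      patients <- sample(names(pairs), batchSize)
      pairIdx <- lapply(patients, function(pid) {
        pm <- pairs[[pid]]
        pm[sample.int(nrow(pm), 1L), ]
      })
      out[[b]] <- .assembleBatch(pairIdx, cohort, specs)
    }
  }
  if (!is.na(scheme@weakLabelField))
    out <- lapply(out, weakLabelPositives, field = scheme@weakLabelField,
                  cohort = cohort)
  out
}

#' Validate a contrastive batch against its scheme
#'
#' Checks the structural invariants of [ContrastiveBatch-class] (even view
#' count, mutual partners, non-empty `P(i)` containing the partner and not
#' the anchor) plus the scheme's constraints: distinct patients across
#' pairs, the positive rule on each pair, and trait uniformity for `neg_*`
#' schemes.  Returns a machine-readable violation table.
#'
#' @param batch a [ContrastiveBatch-class].
#' @param scheme a [SchemeConfig-class].
#' @param cohort the source [SoundCohort-class].
#' @return data.frame with columns `index`, `check`, `detail`; zero rows
#'   when the batch is valid.
#' @export
validateBatch <- function(batch, scheme, cohort) {
  md <- cohort@metadata
  v <- list()
  add <- function(index, check, detail)
    v[[length(v) + 1L]] <<- data.frame(index = index, check = check,
                                       detail = detail)
  n <- length(batch@views)
  if (n %% 2L != 0L) add(NA_integer_, "even_views", sprintf("%d views", n))
  for (i in seq_len(n)) {
    if (batch@partner[batch@partner[i]] != i)
      add(i, "partner_mutual", "partner relation not mutual")
    P <- batch@positiveSets[[i]]
    if (length(P) == 0L) add(i, "positive_nonempty", "P(i) empty")
    if (i %in% P) add(i, "anchor_not_positive", "P(i) contains anchor")
    if (!(batch@partner[i] %in% P)) add(i, "partner_in_P", "partner not in P(i)")
    if (length(setdiff(P, setdiff(seq_len(n), i))))
      add(i, "P_subset_A", "P(i) outside A(i)")
  }
  ridx <- match(batch@recordingIds, md$recording_id)
  if (scheme@mode == "metadata") {
    pairPat <- batch@patientIds[seq(1L, n, by = 2L)]
    if (anyDuplicated(pairPat))
      add(NA_integer_, "distinct_patients",
          paste("duplicated:", paste(unique(pairPat[duplicated(pairPat)]),
                                     collapse = ", ")))
    for (k in seq_len(n %/% 2L)) {
      i <- 2L * k - 1L; j <- 2L * k
      if (batch@patientIds[i] != batch@patientIds[j])
        add(i, "same_patient_pair", "pair spans two patients")
      if (batch@recordingIds[i] == batch@recordingIds[j])
        add(i, "distinct_recordings", "pair reuses one recording")
      li <- md$location[ridx[i]]; lj <- md$location[ridx[j]]
      if (scheme@positiveRule == "same_patient_same_loc" &&
          (is.na(li) || is.na(lj) || li != lj))
        add(i, "positive_rule", "pair not at the same location")
      if (scheme@positiveRule == "same_patient_diff_loc" &&
          (is.na(li) || is.na(lj) || li == lj))
        add(i, "positive_rule", "pair not at different locations")
    }
  }
  if (length(scheme@negativeTrait)) {
    if (identical(scheme@negativeTrait, "location")) {
      vals <- md$location[ridx]
    } else {
      vals <- do.call(paste, c(md[ridx, scheme@negativeTrait, drop = FALSE],
                               sep = "|"))
    }
    bad <- which(vals != vals[1L])
    for (i in bad)
      add(i, "trait_uniform",
          sprintf("%s is '%s' but batch value is '%s'",
                  paste(scheme@negativeTrait, collapse = "+"), vals[i], vals[1L]))
  }
  if (length(v)) do.call(rbind, v)
  else data.frame(index = integer(), check = character(), detail = character())
}

#' Write a batch manifest for audit
#'
#' Serialises a list of batches as JSON-lines, one record per batch with
#' the recording ids, patient ids and (when constrained) the shared
#' negative-selection trait value, so every pre-training step can be
#' audited after the fact.
#'
#' @param batches list of [ContrastiveBatch-class] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeBatchManifest <- function(batches, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (b in seq_along(batches)) {
    bt <- batches[[b]]
    rec <- list(batch = b, recording_ids = bt@recordingIds,
                patient_ids = unique(bt@patientIds),
                trait = bt@traitName, trait_value = bt@traitValue)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null"), con)
  }
  invisible(path)
}
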