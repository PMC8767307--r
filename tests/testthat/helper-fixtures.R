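# Shared fixtures, all built in code.

# Spectrogram with a non-zero data region and explicit padding.
toySpec <- function(bins = 8L, dataFrames = 20L, padLeft = 2L, padRight = 3L,
                    fill = NULL) {
  if (is.null(fill)) fill <- matrix(rnorm(bins * dataFrames) + 5, bins, dataFrames)
  vals <- cbind(matrix(0, bins, padLeft), fill, matrix(0, bins, padRight))
  spectrogram(vals, padLeft, padRight)
}

# Cohort with hand-specified metadata and trivial waveforms (for sampling
# and validation tests that never look at audio).
toyCohort <- function(metadata) {
  recs <- lapply(seq_len(nrow(metadata)), function(i)
    audioRecording(metadata$recording_id[i], metadata$patient_id[i],
                   sin(seq_len(64) / 3), 100))
  soundCohort(recs, metadata)
}

# metadata table: one row per (patient, location); demographics repeated
makeMetadata <- function(patients, locations, ageBands, sexes, labels = NULL) {
  rows <- list()
  for (p in seq_along(patients)) {
    locs <- locations[[p]]
    for (r in seq_along(locs)) {
      rows[[length(rows) + 1L]] <- data.frame(
        recording_id = sprintf("%s_r%d", patients[p], r),
        patient_id = patients[p], age_band = ageBands[p], sex = sexes[p],
        location = locs[r],
        label = if (is.null(labels)) "normal" else labels[p],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

dummySpecs <- function(n) replicate(n, toySpec(2L, 4L, 0L, 0L), simplify = FALSE)

# independent per-anchor contrastive loss oracle: plain scalar arithmetic,
# no shared code with the package implementation
oracleAnchorLoss <- function(z, i, P, temperature) {
  cosv <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  n <- nrow(z)
  A <- setdiff(seq_len(n), i)
  num <- 0
  for (p in P) num <- num + exp(cosv(z[i, ], z[p, ]) / temperature)
  num <- num / length(P)
  den <- 0
  for (a in A) den <- den + exp(cosv(z[i, ], z[a, ]) / temperature)
  -log(num / den)
}

# exhaustive concordant-pair AUROC oracle
oracleAuroc <- function(scores, labels01) {
  pos <- which(labels01 == 1L); neg <- which(labels01 == 0L)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}
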