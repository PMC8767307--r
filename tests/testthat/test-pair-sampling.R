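test_that("the twelve schemes are recognised and configured", {
  expect_length(schemeNames(), 12L)
  for (nm in schemeNames()) {
    sc <- schemeConfig(nm)
    expect_s4_class(sc, "SchemeConfig")
    expect_identical(sc@name, nm)
  }
  expect_identical(schemeConfig("pos_sim_age")@weakLabelField, "age_band")
  expect_identical(schemeConfig("neg_sim_age_sex")@negativeTrait,
                   c("age_band", "sex"))
  expect_error(schemeConfig("neg_sim_height"), "12 valid schemes")
})

test_that("location positive rules match pairwise eligibility", {
  md <- makeMetadata(
    paste0("p", 1:3),
    list(c("anterior left", "anterior left"),
         c("trachea", "posterior right"),
         c("trachea", "trachea", "lateral left")),
    rep("adult", 3L), rep("male", 3L))
  cohort <- toyCohort(md)
  sameLoc <- schemeConfig("pos_same_loc")
  set.seed(1)
  expect_warning(pairs <- positiveViewsSamePatient(cohort, sameLoc, 50L),
                 "skipped")
  # p2 has no same-location pair; p1 and p3 do
  pats <- vapply(pairs, function(pr) md$patient_id[pr[1L]], character(1))
  expect_setequal(unique(pats), c("p1", "p3"))
  for (pr in pairs)
    expect_identical(md$location[pr[1L]], md$location[pr[2L]])

  onlySingletons <- toyCohort(makeMetadata("q1", list("trachea"),
                                           "adult", "male"))
  expect_error(suppressWarnings(
    positiveViewsSamePatient(onlySingletons, sameLoc, 1L)), "no patient")
})

test_that("eligible-pair counts equal exhaustive enumeration on a toy cohort", {
  set.seed(42)
  locsets <- replicate(10, sample(AUSCULTATION_LOCATIONS,
                                  sample(2:4, 1L), replace = TRUE),
                       simplify = FALSE)
  md <- makeMetadata(sprintf("p%02d", 1:10), locsets,
                     rep("adult", 10L), rep("male", 10L))
  for (rule in c("pos_same_loc", "pos_dif_loc")) {
    sc <- schemeConfig(rule)
    got <- SoundCLR:::.eligiblePairs(md, sc@positiveRule)
    nGot <- sum(vapply(got, nrow, integer(1)))
    # brute force over all recording pairs
    nManual <- 0L
    for (i in seq_len(nrow(md) - 1L)) for (j in (i + 1L):nrow(md)) {
      if (md$patient_id[i] != md$patient_id[j]) next
      same <- md$location[i] == md$location[j]
      if ((rule == "pos_same_loc" && same) || (rule == "pos_dif_loc" && !same))
        nManual <- nManual + 1L
    }
    expect_identical(nGot, nManual)
  }
})

test_that("negative-constrained batches share the trait and distinct patients", {
  md <- makeMetadata(
    sprintf("p%02d", 1:40),
    rep(list(c("trachea", "anterior left")), 40L),
    rep(c("adult", "child"), each = 20L),
    rep(c("female", "male"), 20L))
  cohort <- toyCohort(md)
  specs <- dummySpecs(nrow(md))
  sc <- schemeConfig("neg_sim_age_sex")
  set.seed(2)
  batches <- buildNegativeConstrainedBatches(cohort, sc, specs,
                                             batchSize = 8L, nBatches = 100L)
  for (b in batches) {
    expect_identical(nrow(validateBatch(b, sc, cohort)), 0L)
    idx <- match(b@recordingIds, md$recording_id)
    cells <- paste(md$age_band[idx], md$sex[idx])
    expect_identical(length(unique(cells)), 1L)
    expect_false(anyDuplicated(b@patientIds[seq(1, length(b@views), 2)]) > 0)
  }
})

test_that("batch origins follow the documented sampling law", {
  # cells: adult-F 20 eligible, adult-M 3, child-F 17, child-M 0 patients
  nn <- c("adult female" = 20L, "adult male" = 3L, "child female" = 17L)
  pats <- sprintf("p%02d", seq_len(sum(nn)))
  ages <- rep(c("adult", "adult", "child"), times = nn)
  sexes <- rep(c("female", "male", "female"), times = nn)
  md <- makeMetadata(pats, rep(list(c("trachea", "trachea")), length(pats)),
                     ages, sexes)
  cohort <- toyCohort(md)
  sc <- schemeConfig("neg_sim_age_sex")
  set.seed(3)
  batches <- buildNegativeConstrainedBatches(cohort, sc, dummySpecs(nrow(md)),
                                             batchSize = 16L, nBatches = 400L)
  origin <- vapply(batches, function(b) b@traitValue, character(1))
  # only the two cells with >= 16 eligible patients can host batches
  expect_setequal(unique(origin), c("adult|female", "child|female"))
  # law: value drawn with probability proportional to eligible counts
  pAF <- 20 / 37
  se <- sqrt(pAF * (1 - pAF) / 400)
  expect_lt(abs(mean(origin == "adult|female") - pAF), 4 * se)

  tooSmall <- toyCohort(md[md$age_band == "adult" & md$sex == "male", ])
  expect_error(
    buildNegativeConstrainedBatches(tooSmall, sc, dummySpecs(6L), 16L, 1L),
    "counts")
})

test_that("weak-label positive sets enumerate same-band views", {
  md <- makeMetadata(sprintf("p%02d", 1:16),
                     rep(list(c("trachea", "trachea")), 16L),
                     rep(c("adult", "child"), 8L), rep("female", 16L))
  cohort <- toyCohort(md)
  sc <- schemeConfig("pos_sim_age")
  set.seed(4)
  batch <- contrastiveBatches(cohort, sc, dummySpecs(nrow(md)),
                              batchSize = 16L, nBatches = 1L)[[1L]]
  idx <- match(batch@recordingIds, md$recording_id)
  bands <- md$age_band[idx]
  for (i in seq_along(batch@views)) {
    manual <- sort(setdiff(which(bands == bands[i]), i))
    expect_identical(batch@positiveSets[[i]],
                     sort(unique(c(manual, batch@partner[i]))))
    # 8 + 8 patients per band -> 16 same-band views, minus the anchor
    expect_identical(length(batch@positiveSets[[i]]), 15L)
  }
  # constant field: P(i) = A(i) for every anchor
  allAdult <- makeMetadata(sprintf("q%02d", 1:8),
                           rep(list(c("trachea", "trachea")), 8L),
                           rep("adult", 8L), rep("female", 8L))
  cohortA <- toyCohort(allAdult)
  bA <- contrastiveBatches(cohortA, sc, dummySpecs(nrow(allAdult)),
                           batchSize = 8L, nBatches = 1L)[[1L]]
  for (i in seq_along(bA@views))
    expect_identical(bA@positiveSets[[i]], setdiff(seq_along(bA@views), i))
})

test_that("the validator flags exactly the corrupted member", {
  md <- makeMetadata(sprintf("p%02d", 1:20),
                     rep(list(c("trachea", "trachea")), 20L),
                     rep("adult", 20L), rep(c("female", "male"), each = 10L))
  cohort <- toyCohort(md)
  sc <- schemeConfig("neg_sim_sex")
  set.seed(5)
  batch <- buildNegativeConstrainedBatches(cohort, sc, dummySpecs(nrow(md)),
                                           batchSize = 6L, nBatches = 1L)[[1L]]
  expect_identical(nrow(validateBatch(batch, sc, cohort)), 0L)
  # corrupt one view to a recording of the opposite sex
  other <- which(md$sex != md$sex[match(batch@recordingIds[1L],
                                        md$recording_id)])[1L]
  bad <- batch
  bad@recordingIds[3L] <- md$recording_id[other]
  bad@patientIds[3L] <- md$patient_id[other]
  rep <- validateBatch(bad, sc, cohort)
  traitRows <- rep[rep$check == "trait_uniform", ]
  expect_identical(traitRows$index, 3L)
})

test_that("fuzzed batches: validator agrees with a brute-force pairwise check", {
  md <- makeMetadata(sprintf("p%02d", 1:30),
                     rep(list(c("trachea", "anterior left")), 30L),
                     sample(c("adult", "child"), 30L, replace = TRUE),
                     sample(c("female", "male"), 30L, replace = TRUE))
  cohort <- toyCohort(md)
  sc <- schemeConfig("neg_sim_age")
  set.seed(6)
  adults <- sum(tapply(md$age_band, md$patient_id, `[`, 1L) == "adult")
  bs <- min(6L, adults)
  for (trial in 1:40) {
    batch <- buildNegativeConstrainedBatches(cohort, sc, dummySpecs(nrow(md)),
                                             batchSize = bs, 1L)[[1L]]
    if (trial %% 2L == 0L) {  # corrupt a random view
      k <- sample(length(batch@views), 1L)
      r <- sample(nrow(md), 1L)
      batch@recordingIds[k] <- md$recording_id[r]
      batch@patientIds[k] <- md$patient_id[r]
    }
    rep <- validateBatch(batch, sc, cohort)
    idx <- match(batch@recordingIds, md$recording_id)
    uniform <- TRUE
    for (i in seq_along(idx)) for (j in seq_along(idx))
      if (md$age_band[idx[i]] != md$age_band[idx[j]]) uniform <- FALSE
    expect_identical(uniform, !any(rep$check == "trait_uniform"))
  }
})

test_that("batch generation replays identically under a fixed seed", {
  md <- makeMetadata(sprintf("p%02d", 1:20),
                     rep(list(c("trachea", "anterior left")), 20L),
                     rep("adult", 20L), rep("female", 20L))
  cohort <- toyCohort(md)
  specs <- dummySpecs(nrow(md))
  bigSpecs <- replicate(nrow(md), toySpec(8L, 20L, 0L, 0L), simplify = FALSE)
  for (nm in c("neg_sim_age", "pos_dif_loc", "time_mask")) {
    sc <- schemeConfig(nm)
    m <- maskSpec(timeBandWidth = 0.2, freqBandWidth = 0)
    set.seed(9)
    a <- contrastiveBatches(cohort, sc, bigSpecs, batchSize = 4L,
                            nBatches = 3L, m = m)
    set.seed(9)
    b <- contrastiveBatches(cohort, sc, bigSpecs, batchSize = 4L,
                            nBatches = 3L, m = m)
    expect_identical(lapply(a, function(x) x@recordingIds),
                     lapply(b, function(x) x@recordingIds))
    expect_identical(lapply(a, function(x) lapply(x@views, specValues)),
                     lapply(b, function(x) lapply(x@views, specValues)))
  }
})

test_that("batch manifests serialise one auditable record per batch", {
  md <- makeMetadata(sprintf("p%02d", 1:12),
                     rep(list(c("trachea", "trachea")), 12L),
                     rep("adult", 12L), rep("female", 12L))
  cohort <- toyCohort(md)
  set.seed(10)
  batches <- buildNegativeConstrainedBatches(cohort, schemeConfig("neg_sim_age"),
                                             dummySpecs(nrow(md)),
                                             batchSize = 4L, nBatches = 3L)
  path <- tempfile(fileext = ".jsonl")
  writeBatchManifest(batches, path)
  lines <- readLines(path)
  expect_length(lines, 3L)
  rec <- jsonlite::fromJSON(lines[2L])
  expect_identical(rec$batch, 2L)
  expect_length(rec$recording_ids, 8L)
  expect_identical(rec$trait_value, batches[[2L]]@traitValue)
})
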