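test_that("a pure sine concentrates energy in one frequency row", {
  sr <- 1000
  rec <- audioRecording("r1", "p1", sin(2 * pi * 125 * seq(0, 2, by = 1 / sr)),
                        sr)
  sp <- computeSpectrogram(rec, stftConfig(0.064, 0.032, nMel = 0L))
  expect_s4_class(sp, "Spectrogram")
  expect_identical(padLeft(sp), 0L)
  expect_identical(padRight(sp), 0L)
  rowEnergy <- rowMeans(specValues(sp))
  # bin frequencies are k * Fs / nfft; the 125 Hz tone sits exactly on one
  binHz <- (seq_len(nrow(specValues(sp))) - 1L) * sr / 64
  expect_equal(which.max(rowEnergy), which.min(abs(binHz - 125)))
})

test_that("an all-zero waveform yields a uniform floor-valued grid", {
  rec <- audioRecording("r1", "p1", numeric(500), 1000)
  sp <- computeSpectrogram(rec, stftConfig(0.05, 0.025, nMel = 8L))
  expect_true(all(abs(specValues(sp) - specValues(sp)[1L]) < 1e-8))
})

test_that("chirp energy ridge is monotone and matches a direct DFT oracle", {
  sr <- 1000
  t <- seq(0, 2, by = 1 / sr)[-1]
  x <- sin(2 * pi * (50 * t + 50 * t^2))   # 50 -> 250 Hz linear chirp
  rec <- audioRecording("r1", "p1", x, sr)
  cfgS <- stftConfig(0.064, 0.032, nMel = 0L, fftSize = 64L)
  sp <- computeSpectrogram(rec, cfgS)
  ridge <- apply(specValues(sp), 2L, which.max)
  expect_true(all(diff(ridge) >= 0))
  # direct windowed DFT on three frames, independent of the stft library
  win <- 64L; hop <- 32L
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, win - 1) / (win - 1))
  for (fr in c(5L, 25L, 50L)) {
    seg <- x[(fr - 1L) * hop + seq_len(win)] * w
    mag <- abs(vapply(0:(win / 2), function(k)
      sum(seg * exp(-2i * pi * k * seq(0, win - 1) / win)), complex(1)))
    expect_equal(which.max(specValues(sp)[, fr]), which.max(mag))
  }
})

test_that("too-short waveforms raise an error naming the minimum length", {
  rec <- audioRecording("r1", "p1", rnorm(10), 1000)
  expect_error(computeSpectrogram(rec, stftConfig(0.05, 0.025)), "at least 50")
})

test_that("length standardization uses the interpolated quantile, rounded half-up", {
  expect_identical(fitStandardization(c(5, 5, 5, 5))@targetFrames, 5L)
  # oracle: order statistics x=(2,4,6,8), h=(n-1)q+1=3.25 -> 6.5 -> 7
  expect_identical(fitStandardization(c(2, 4, 6, 8))@targetFrames, 7L)
  expect_identical(fitStandardization(10)@targetFrames, 10L)
  expect_error(fitStandardization(numeric()), "at least one")
  # permutation invariance
  set.seed(1)
  lens <- sample(5:60, 20, replace = TRUE)
  expect_identical(fitStandardization(lens)@targetFrames,
                   fitStandardization(sample(lens))@targetFrames)
})

test_that("centre pad/crop follows the stated conventions exactly", {
  rule8 <- new("StandardizationRule", targetFrames = 8L, quantile = 0.75)
  s4 <- spectrogram(matrix(1:12, 3, 4))
  p4 <- standardizeLength(s4, rule8)
  expect_identical(padLeft(p4), 2L)
  expect_identical(padRight(p4), 2L)
  expect_equal(dataRegion(p4), matrix(as.numeric(1:12), 3, 4))

  s3 <- spectrogram(matrix(1:9, 3, 3))
  p3 <- standardizeLength(s3, rule8)
  expect_identical(padLeft(p3), 2L)     # odd deficit: extra frame on right
  expect_identical(padRight(p3), 3L)

  s10 <- spectrogram(matrix(rep(1:10, each = 3), 3, 10))
  c10 <- standardizeLength(s10, rule8)
  # index oracle: excess 2, drop floor(2/2)=1 left -> keep columns 2..9
  expect_equal(specValues(c10)[1L, ], as.numeric(2:9))
  # odd excess: extra frame dropped on the right
  c7 <- standardizeLength(s10, new("StandardizationRule", targetFrames = 7L,
                                   quantile = 0.75))
  expect_equal(specValues(c7)[1L, ], as.numeric(2:8))
})

test_that("standardization is idempotent and preserves data-region energy", {
  rule <- new("StandardizationRule", targetFrames = 13L, quantile = 0.75)
  s <- toySpec(5L, 7L, 1L, 1L)
  once <- standardizeLength(s, rule)
  twice <- standardizeLength(once, rule)
  expect_identical(specValues(once), specValues(twice))
  expect_identical(padLeft(once), padLeft(twice))
  expect_equal(sum(dataRegion(once)^2), sum(dataRegion(s)^2))
})

test_that("imputation returns complete tables and respects observed data", {
  md <- makeMetadata(paste0("p", 1:6),
                     rep(list(c("trachea", "anterior left")), 6L),
                     rep(c("adult", "child"), 3L), rep(c("female", "male"), 3L))
  out <- imputeMetadata(md)
  expect_identical(out$age_band, md$age_band)
  expect_identical(out$sex, md$sex)
  expect_identical(out$location, md$location)
})

test_that("an all-missing patient receives the per-field mode", {
  md <- makeMetadata(paste0("p", 1:10),
                     rep(list("trachea"), 10L),
                     c(rep("adult", 9L), NA), c(rep("female", 9L), NA))
  md$location[10L] <- NA
  out <- imputeMetadata(md)
  expect_identical(out$age_band[10L], "adult")
  expect_identical(out$sex[10L], "female")
  expect_identical(out$location[10L], "trachea")
})

test_that("a field missing everywhere cannot be imputed", {
  md <- makeMetadata(paste0("p", 1:4), rep(list("trachea"), 4L),
                     rep(NA_character_, 4L), rep("male", 4L))
  expect_error(imputeMetadata(md), "age_band")
})

test_that("missing-at-random sex is recovered above chance", {
  set.seed(7)
  n <- 150L
  sexTrue <- ifelse(rbinom(n, 1, 0.65) == 1L, "female", "male")
  md <- makeMetadata(sprintf("p%03d", 1:n), rep(list("trachea"), n),
                     sample(c("adult", "child"), n, replace = TRUE), sexTrue)
  miss <- sample(n, 30L)
  md$sex[miss] <- NA
  out <- imputeMetadata(md, seed = 3L)
  acc <- mean(out$sex[miss] == sexTrue[miss])
  expect_gt(acc, 0.5)
})

test_that("WAV files round-trip at 16-bit PCM precision", {
  x <- sin(2 * pi * 40 * seq(0, 0.2, by = 1 / 800)) * 0.8
  path <- tempfile(fileext = ".wav")
  writeWav(x, 800, path)
  back <- readWav(path)
  expect_identical(back$sampleRate, 800L)
  expect_lt(max(abs(back$waveform - x)), 1 / 32767)
})

test_that("cohorts round-trip through the on-disk interchange format", {
  spec <- cohortSpec(nPatients = 3L, recordingsPerPatient = 2L, seed = 9L)
  cohort <- generateDataset(spec)
  dir <- tempfile()
  writeCohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  expect_true(file.exists(file.path(dir, "manifest.jsonl")))
  expect_identical(length(readLines(file.path(dir, "manifest.jsonl"))), 6L)
  back <- readCohort(dir)
  expect_identical(cohortMetadata(back)$patient_id,
                   cohortMetadata(cohort)$patient_id)
  for (i in seq_len(nRecordings(cohort)))
    expect_lt(max(abs(recordings(back)[[i]]@waveform -
                        recordings(cohort)[[i]]@waveform)), 1 / 32767 + 1e-9)
})
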