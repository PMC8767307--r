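# A tiny shared cohort keeps the training tests fast: the expensive parts
# (spectrograms, pretraining) are computed once per file.
tinyCohort <- generateDataset(cohortSpec(nPatients = 24L,
                                         recordingsPerPatient = 2L,
                                         seed = 51L))
tinySplits <- makeSplits(cohortMetadata(tinyCohort)$label,
                         testSize = 12L, valSize = 8L, fineTuneSize = 12L,
                         seed = 51L)
tinyCfg <- runConfig("desk", seed = 51L, batchSize = 4L, epochsPretrain = 4L,
                     epochsLinear = 40L, epochsFinetune = 4L,
                     epochsBaseline = 40L, embeddingDim = 16L,
                     projectionDim = 16L)

test_that("run configurations carry the full-scale and desk hyperparameters", {
  full <- runConfig("full")
  expect_identical(full@batchSize, 16L)
  expect_equal(full@lr, 1e-5)
  expect_equal(full@weightDecayPretrain, 1e-6)
  expect_equal(full@weightDecayDownstream, 1e-2)
  expect_identical(full@epochsLinear, 5000L)
  expect_identical(full@epochsFinetune, 25L)
  expect_identical(full@epochsBaseline, 1000L)
  desk <- runConfig("desk", labelFraction = 0.5)
  expect_identical(desk@profile, "desk")
  expect_equal(desk@labelFraction, 0.5)
  expect_error(runConfig("desk", nonsense = 1), "unknown RunConfig")
})

test_that("pretraining reduces the contrastive loss and is reproducible", {
  pre <- subsetCohort(tinyCohort, tinySplits$preTrain)
  ck <- pretrain(pre, schemeConfig("neg_sim_age"), tinyCfg)
  expect_s3_class(ck, "soundclrCheckpoint")
  expect_length(ck$lossHistory, 4L)
  expect_lt(tail(ck$lossHistory, 1L), ck$lossHistory[1L])
  ck2 <- pretrain(pre, schemeConfig("neg_sim_age"), tinyCfg)
  expect_identical(ck$lossHistory, ck2$lossHistory)
  expect_identical(SoundCLR:::.packParams(ck$encoder$params),
                   SoundCLR:::.packParams(ck2$encoder$params))
})

test_that("pretraining separates positives from negatives on an easy cohort", {
  easy <- generateDataset(cohortSpec(nPatients = 16L,
                                     recordingsPerPatient = 2L,
                                     patientEffect = 1.2, noiseSd = 0.05,
                                     seed = 52L))
  cfg <- runConfig("desk", seed = 52L, batchSize = 8L, epochsPretrain = 10L,
                   embeddingDim = 16L, projectionDim = 16L)
  ck <- pretrain(easy, schemeConfig("neg_sim_age"), cfg)
  prep <- prepareSpectrograms(easy, ck$stft, rule = ck$rule)
  z <- project(encode(prep$specs, ck$encoder), ck$projection)
  u <- z / sqrt(rowSums(z^2))
  S <- u %*% t(u)
  pid <- cohortMetadata(easy)$patient_id
  same <- outer(pid, pid, "==") & upper.tri(S)
  diff <- outer(pid, pid, "!=") & upper.tri(S)
  expect_gt(mean(S[same]), mean(S[diff]))
})

test_that("linear evaluation freezes the encoder and matches the null under permutation", {
  pre <- subsetCohort(tinyCohort, tinySplits$preTrain)
  ck <- pretrain(pre, schemeConfig("split"), tinyCfg)
  before <- SoundCLR:::.packParams(ck$encoder$params)
  res <- linearEvaluate(ck, tinyCohort, tinySplits$fineTune, tinySplits$test,
                        tinyCfg, replicates = 50L)
  expect_s4_class(res, "EvalResult")
  expect_identical(SoundCLR:::.packParams(ck$encoder$params), before)
  # label permutation null: AUROC near one half on a larger test set
  permCohort <- tinyCohort
  set.seed(53)
  permCohort@metadata$label <- sample(permCohort@metadata$label)
  resPerm <- linearEvaluate(ck, permCohort, tinySplits$fineTune,
                            tinySplits$test, tinyCfg, replicates = 50L)
  expect_lt(abs(auroc(resPerm) - 0.5), 0.35)
  expect_error(linearEvaluate(ck, tinyCohort, tinySplits$fineTune,
                              tinySplits$fineTune, tinyCfg), "")
})

test_that("the logistic trainer drives separable features to a perfect AUROC", {
  set.seed(54)
  X <- rbind(matrix(rnorm(40, -2), 20), matrix(rnorm(40, 2), 20))
  y <- rep(c(0, 1), each = 20L)
  fit <- SoundCLR:::.trainLogistic(X, y, epochs = 100L, lr = 0.05,
                                   weightDecay = 1e-3, batchSize = 8L,
                                   seed = 1L)
  expect_equal(aurocScore(drop(X %*% fit$w) + fit$b, y), 1)
})

test_that("fine-tuning runs both arms, logs losses, and ignores checkpoints when random", {
  pre <- subsetCohort(tinyCohort, tinySplits$preTrain)
  ck <- pretrain(pre, schemeConfig("neg_sim_age"), tinyCfg)
  resP <- fineTune(ck, tinyCohort, tinySplits$fineTune, tinySplits$test,
                   tinyCfg, replicates = 50L)
  expect_s4_class(resP, "EvalResult")
  expect_length(attr(resP, "trainLoss"), tinyCfg@epochsFinetune)
  resR1 <- fineTune(NULL, tinyCohort, tinySplits$fineTune, tinySplits$test,
                    tinyCfg, replicates = 50L)
  resR2 <- fineTune(NULL, tinyCohort, tinySplits$fineTune, tinySplits$test,
                    tinyCfg, replicates = 50L)
  # the random arm is a pure function of (cfg, data): reruns agree exactly
  expect_identical(auroc(resR1), auroc(resR2))
})

test_that("the flattened baseline matches degenerate and separable fixtures", {
  # constant input: identical recordings with mixed labels -> AUROC 1/2
  wave <- sin(2 * pi * 60 * seq(0, 1, by = 1 / 800))[-1]
  recs <- lapply(1:16, function(i)
    audioRecording(sprintf("r%02d", i), sprintf("p%02d", i), wave, 800))
  md <- data.frame(recording_id = sprintf("r%02d", 1:16),
                   patient_id = sprintf("p%02d", 1:16),
                   age_band = "adult", sex = "female", location = "trachea",
                   label = rep(c("normal", "abnormal"), 8L))
  flatCohort <- soundCohort(recs, md)
  cfgB <- runConfig("desk", seed = 55L, epochsBaseline = 20L)
  resC <- baselineLinear(flatCohort, trainIdx = 1:8, testIdx = 9:16,
                         cfg = cfgB, stft = stftConfig(0.05, 0.05, 8L),
                         replicates = 50L)
  expect_equal(auroc(resC), 0.5)

  # linearly separable fixture: two tones far apart in frequency
  recs2 <- lapply(1:24, function(i) {
    f <- if (i %% 2L) 60 else 240
    audioRecording(sprintf("s%02d", i), sprintf("q%02d", i),
                   sin(2 * pi * f * seq(0, 1, by = 1 / 800))[-1] +
                     rnorm(800, sd = 0.05), 800)
  })
  md2 <- data.frame(recording_id = sprintf("s%02d", 1:24),
                    patient_id = sprintf("q%02d", 1:24),
                    age_band = "adult", sex = "female", location = "trachea",
                    label = rep(c("normal", "abnormal"), 12L))
  sepCohort <- soundCohort(recs2, md2)
  cfgS <- runConfig("desk", seed = 56L, epochsBaseline = 100L)
  resS <- baselineLinear(sepCohort, trainIdx = 1:12, testIdx = 13:24,
                         cfg = cfgS, stft = stftConfig(0.05, 0.05, 8L),
                         replicates = 50L)
  expect_equal(auroc(resS), 1)
  # independent convex fit agrees
  if (requireNamespace("glmnet", quietly = TRUE)) {
    prep <- prepareSpectrograms(sepCohort, stftConfig(0.05, 0.05, 8L))
    F <- t(vapply(prep$specs, function(s) as.numeric(specValues(s)),
                  numeric(prep$bins * prep$frames)))
    fit <- glmnet::glmnet(F[1:12, ],
                          as.integer(md2$label[1:12] == "abnormal"),
                          family = "binomial", alpha = 0, lambda = 0.1)
    pr <- drop(predict(fit, F[13:24, ]))
    expect_lt(abs(aurocScore(pr, md2$label[13:24]) - auroc(resS)), 0.02)
  }
})

test_that("label-fraction subsampling is stratified and reproducible", {
  labels <- rep(c("normal", "abnormal"), each = 50L)
  idx <- seq_along(labels)
  a <- SoundCLR:::.labelSubsample(labels, idx, 0.2, seed = 3L)
  b <- SoundCLR:::.labelSubsample(labels, idx, 0.2, seed = 3L)
  expect_identical(a, b)
  expect_identical(sum(labels[a] == "normal"), 10L)
  expect_identical(sum(labels[a] == "abnormal"), 10L)
  expect_identical(SoundCLR:::.labelSubsample(labels, idx, 1, seed = 3L), idx)
})
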