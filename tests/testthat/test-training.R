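# Two-phase training pipeline at miniature scale.

miniSplit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set <- generatePhantomSet(tinyPhantomConfig(seed = 21L,
                                                  nPatients = 5L,
                                                  imagesPerPatient = 6L,
                                                  imageSize = 16L))
      cache <<- splitByPatient(set, c(3, 1, 1), seed = 2)
    }
    cache
  }
})

test_that("learning-rate schedule halves every period", {
  cfg <- trainConfig()
  expect_equal(learningRateAt(cfg, 1), 0.001)
  expect_equal(learningRateAt(cfg, 39), 0.001)
  expect_equal(learningRateAt(cfg, 40), 0.0005)
  expect_equal(learningRateAt(cfg, 80), 0.00025)  # two halvings
  expect_equal(learningRateAt(cfg, 200), 0.001 * 0.5^5)
})

test_that("pretraining stops by threshold semantics and reports curves", {
  spec <- tinySpec("both")
  # a zero target stops after the first epoch
  cfg0 <- trainConfig(phase = "pretrain", epochs = 5,
                      pretrainTargetAccuracy = 0, seed = 1)
  run0 <- pretrainEncoder(miniSplit(), spec, cfg0)
  expect_equal(nrow(run0$report@curves), 1)
  # an unreachable target exhausts the budget and leaves a note; two
  # identical validation images with opposite labels cap accuracy at 1/2
  img <- miniSplit()@train[[1]]@image
  m1 <- matrix(0, nrow(img), ncol(img)); m1[8, 8] <- 1
  ambiguous <- list(
    new("PhantomSample", image = img, mask = m1 * 0, label = 0,
        patientId = 98, index = 900),
    new("PhantomSample", image = img, mask = m1, label = 1,
        patientId = 98, index = 901))
  hardSplit <- new("DatasetSplit", train = miniSplit()@train,
                   validation = ambiguous, test = list(),
                   patients = list(train = miniSplit()@patients$train,
                                   validation = 98, test = integer()))
  cfg1 <- trainConfig(phase = "pretrain", epochs = 2,
                      pretrainTargetAccuracy = 1, seed = 1)
  run1 <- pretrainEncoder(hardSplit, spec, cfg1)
  expect_equal(nrow(run1$report@curves), 2)
  expect_true(length(run1$report@notes) > 0)
  # learning-rate column follows the schedule
  expect_equal(run1$report@curves$lr, learningRateAt(cfg1, 1:2))
  expect_error(pretrainEncoder(miniSplit(), spec,
                               trainConfig(phase = "segment")),
               "pretrain")
})

test_that("imbalanced labels make the 80% accuracy target reachable", {
  # ~90% of images are lesion-positive, so the stopping accuracy is
  # attainable within a small epoch budget
  spec <- tinySpec("both")
  cfg <- trainConfig(phase = "pretrain", epochs = 6, seed = 3)
  run <- pretrainEncoder(miniSplit(), spec, cfg)
  expect_gte(run$report@achievedAccuracy, 0.80)
  expect_lte(nrow(run$report@curves), 6)
})

test_that("training runs are bit-reproducible under a fixed seed", {
  spec <- tinySpec("trainable-only")
  cfg <- trainConfig(phase = "segment", epochs = 2, seed = 9)
  a <- trainSegmentation(miniSplit(), spec, NULL, cfg)
  b <- trainSegmentation(miniSplit(), spec, NULL, cfg)
  expect_identical(a$report@curves$trainLoss, b$report@curves$trainLoss)
  expect_identical(a$net@params, b$net@params)
})

test_that("zero-epoch segmentation returns the initialised network", {
  spec <- tinySpec("trainable-only")
  cfg <- trainConfig(phase = "segment", epochs = 0, seed = 1)
  run <- trainSegmentation(miniSplit(), spec, NULL, cfg)
  expect_equal(nrow(run$report@curves), 0)
  init <- buildSmartCA(spec, NULL, seed = iplfseg:::deriveSeed(1, 31L))
  expect_identical(run$net@params, init@params)
  expect_error(trainSegmentation(miniSplit(), spec, NULL,
                                 trainConfig(phase = "pretrain")),
               "segment")
})

test_that("the frozen encoder is byte-identical after training", {
  spec <- tinySpec("both")
  pre <- pretrainEncoder(miniSplit(), spec,
                         trainConfig(phase = "pretrain", epochs = 2,
                                     seed = 4))
  before <- paramDigest(pre$net$params$encoder)
  run <- trainSegmentation(miniSplit(), spec, pre$net,
                           trainConfig(phase = "segment", epochs = 2,
                                       seed = 4))
  expect_identical(paramDigest(run$net@pretrained$encoder), before)
  # and the trainable parts did change
  expect_false(identical(run$net@params$encoder, pre$net$params$encoder))
})

test_that("short training reduces the loss on a learnable fixture", {
  spec <- tinySpec("trainable-only")
  cfg <- trainConfig(phase = "segment", loss = "iplf", epochs = 4,
                     seed = 6)
  run <- trainSegmentation(miniSplit(), spec, NULL, cfg)
  curves <- run$report@curves
  expect_equal(nrow(curves), 4)
  expect_lt(curves$trainLoss[4], curves$trainLoss[1])
  expect_true(all(is.finite(curves$valDice)))
})

test_that("cross-validation folds partition patients exactly once", {
  folds <- patientFolds(1:35, 5, seed = 3)
  expect_length(folds, 5)
  expect_true(all(lengths(folds) == 7))
  expect_equal(sort(unname(unlist(folds))), 1:35)
  expect_error(patientFolds(1:3, 5), "more folds")
  # uneven counts use largest-remainder sizes
  f2 <- patientFolds(1:11, 3, seed = 1)
  expect_equal(sort(unname(lengths(f2))), c(3, 4, 4))
})

test_that("crossval rotates roles and aggregates scores", {
  set <- generatePhantomSet(tinyPhantomConfig(seed = 31L, nPatients = 5L,
                                              imagesPerPatient = 4L,
                                              imageSize = 16L))
  spec <- tinySpec("trainable-only")
  cfg <- trainConfig(phase = "segment", epochs = 1, seed = 2, folds = 5)
  cv <- crossval(set, spec, cfg)
  expect_length(cv$reports, 5)
  # the union of test folds covers every patient exactly once
  expect_equal(sort(unname(unlist(cv$folds))), 1:5)
  expect_true(is.finite(cv$summary["meanDice"]))
})

test_that("robustness sweep reproduces the clean evaluation and layout", {
  spec <- tinySpec("trainable-only")
  cfg <- trainConfig(phase = "segment", epochs = 1, seed = 5)
  run <- trainSegmentation(miniSplit(), spec, NULL, cfg)
  base <- evaluateNetwork(run$net, miniSplit()@test)
  empty <- robustnessSweep(run$net, miniSplit()@test, numeric(0))
  expect_equal(nrow(empty), 1)
  expect_equal(empty$level, "clean")
  expect_equal(empty$meanDice, base$meanDice, tolerance = 1e-12)
  sw <- robustnessSweep(run$net, miniSplit()@test, c(15, 10), seed = 1)
  expect_equal(sw$level, c("clean", "psnr15", "psnr10"))
  expect_true(all(is.finite(sw$meanDice)))
})
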