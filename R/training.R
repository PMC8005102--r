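#' Learning rate at a given epoch
#'
#' The step schedule `lrInitial * 0.5^floor(epoch / lrHalvingPeriod)`:
#' at the defaults the rate is halved every 40 epochs, so epoch 80 runs at
#' a quarter of the initial rate.
#'
#' @param cfg A [TrainConfig-class].
#' @param epoch Epoch number (1-based); may be a vector.
#' @return Learning rate(s).
#' @export
learningRateAt <- function(cfg, epoch) {
  cfg@lrInitial * 0.5^floor(epoch / cfg@lrHalvingPeriod)
}

batchIndices <- function(n, batchSize) {
  ord <- sample.int(n)
  split(ord, ceiling(seq_along(ord) / batchSize))
}

samplesImages <- function(samples) lapply(samples, function(s) s@image)
samplesMasks <- function(samples) lapply(samples, function(s) s@mask)
samplesLabels <- function(samples) vapply(samples, function(s) s@label,
                                          numeric(1))

#' Pre-train the classification encoder
#'
#' Phase one of the two-phase pipeline: the classification encoder is
#' optimised on image-level lesion-presence labels (with the IPLF by
#' default, since the image-level labels are imbalanced too) and training
#' stops at the first epoch whose validation accuracy reaches
#' `cfg@pretrainTargetAccuracy`. Training the classifier further has been
#' observed to degrade downstream segmentation, so the stop is part of the
#' protocol. If the target is never reached within the epoch budget, the
#' parameters of the best-accuracy epoch are returned and a warning is
#' recorded in the report.
#'
#' @param data A [DatasetSplit-class] with labelled samples.
#' @param spec An [ArchitectureSpec-class].
#' @param cfg A [TrainConfig-class] with `phase = "pretrain"`.
#' @return A list: `net` (trained classifier) and `report`
#'   (a [TrainReport-class]).
#' @export
pretrainEncoder <- function(data, spec, cfg) {
  stopifnot(is(data, "DatasetSplit"), is(spec, "ArchitectureSpec"),
            is(cfg, "TrainConfig"))
  if (cfg@phase != "pretrain") stopDomain("cfg@phase must be 'pretrain'")
  t0 <- proc.time()[3]
  net <- buildPretrainedEncoder(spec, seed = deriveSeed(cfg@seed, 21L))
  trainImg <- samplesImages(data@train)
  trainLab <- samplesLabels(data@train)
  valImg <- samplesImages(data@validation)
  valLab <- samplesLabels(data@validation)
  valX <- if (length(valImg)) stackImages(valImg) else NULL

  state <- adamInit(net$params)
  curves <- data.frame()
  bestAcc <- -Inf; bestParams <- net$params
  notes <- character()
  stopped <- FALSE

  withSeed(deriveSeed(cfg@seed, 22L), {
    for (epoch in seq_len(cfg@epochs)) {
      lr <- learningRateAt(cfg, epoch)
      epochLoss <- 0; nb <- 0
      for (idx in batchIndices(length(trainImg), cfg@batchSize)) {
        x <- stackImages(trainImg[idx])
        y <- trainLab[idx]
        fw <- classifierForward(net$params, x, spec@groups,
                                dropout = cfg@dropout, training = TRUE)
        epochLoss <- epochLoss + baselineLoss(cfg@loss, y, fw$p,
                                              cfg@lossParams)
        dp <- as.vector(lossGradientMap(cfg@loss, y, fw$p, cfg@lossParams))
        bw <- classifierBackward(net$params, fw$cache, dp, spec@groups)
        st <- adamStep(net$params, bw$grads, state, lr, cfg@adamDecays)
        net$params <- st$params; state <- st$state
        nb <- nb + 1
      }
      valAcc <- if (is.null(valX)) NA_real_ else {
        pv <- classifierForward(net$params, valX, spec@groups)$p
        mean((pv >= 0.5) == (valLab == 1))
      }
      curves <- rbind(curves, data.frame(
        epoch = epoch, lr = lr, trainLoss = epochLoss / max(nb, 1),
        valAccuracy = valAcc))
      if (!is.na(valAcc) && valAcc > bestAcc) {
        bestAcc <- valAcc; bestParams <- net$params
      }
      if (!is.na(valAcc) && valAcc >= cfg@pretrainTargetAccuracy) {
        stopped <- TRUE
        break
      }
      if (cfg@pretrainTargetAccuracy == 0) { stopped <- TRUE; break }
    }
  })
  if (!stopped && cfg@epochs > 0) {
    notes <- c(notes, sprintf(
      "validation accuracy target %.2f not reached; returning best epoch (%.3f)",
      cfg@pretrainTargetAccuracy, bestAcc))
    net$params <- bestParams
  }
  report <- new("TrainReport", phase = "pretrain", curves = curves,
                finalScores = list(valAccuracy = bestAcc),
                achievedAccuracy = if (is.finite(bestAcc)) bestAcc else NA_real_,
                seed = cfg@seed, wallClock = proc.time()[3] - t0,
                notes = notes)
  list(net = net, report = report)
}

#' Mean Dice and pooled scores of a network on a sample set
#'
#' @param net A [SegNetwork-class].
#' @param samples List of [PhantomSample-class] (or a [PhantomSet-class]).
#' @param threshold Binarisation threshold (default 0.5).
#' @param batchSize Forward-pass batch size.
#' @return List with `meanDice`, `pooled` ([SegmentationScores-class]) and
#'   `perImageDice`.
#' @export
evaluateNetwork <- function(net, samples, threshold = 0.5, batchSize = 8L) {
  ss <- samplesOf(samples)
  dices <- numeric(length(ss))
  pooled <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  i <- 1
  while (i <= length(ss)) {
    j <- min(i + batchSize - 1, length(ss))
    x <- stackImages(samplesImages(ss[i:j]))
    p <- segForward(net, x)$p
    for (k in i:j) {
      pred <- binarizeMask(p[, , k - i + 1], threshold)
      cc <- confusionCounts(pred, ss[[k]]@mask)
      pooled <- pooled + c(cc@tp, cc@fp, cc@fn, cc@tn)
      dices[k] <- segmentationScores(cc)@dice
    }
    i <- j + 1
  }
  list(meanDice = mean(dices),
       pooled = segmentationScores(new("ConfusionCounts",
                                       tp = pooled[["tp"]], fp = pooled[["fp"]],
                                       fn = pooled[["fn"]], tn = pooled[["tn"]])),
       perImageDice = dices)
}

#' Train the segmentation network
#'
#' Phase two of the pipeline: the trainable encoder and decoder are
#' optimised on per-pixel masks with the configured loss evaluated on the
#' foreground-class probability; the pre-trained encoder (if the fusion
#' policy uses one) is frozen — its parameters are byte-identical before
#' and after training. Adam with the configured moment decays and the
#' halving learning-rate schedule drives the updates; per-epoch validation
#' Dice is recorded in the report.
#'
#' @param data A [DatasetSplit-class] with masks.
#' @param spec An [ArchitectureSpec-class].
#' @param pretrained Classifier (or parameter list) for the frozen encoder;
#'   `NULL` for `fusion = "trainable-only"`.
#' @param cfg A [TrainConfig-class] with `phase = "segment"`.
#' @return A list: `net` (trained [SegNetwork-class]) and `report`.
#' @export
trainSegmentation <- function(data, spec, pretrained, cfg) {
  stopifnot(is(data, "DatasetSplit"), is(spec, "ArchitectureSpec"),
            is(cfg, "TrainConfig"))
  if (cfg@phase != "segment") stopDomain("cfg@phase must be 'segment'")
  t0 <- proc.time()[3]
  net <- buildSmartCA(spec, pretrained, seed = deriveSeed(cfg@seed, 31L))
  frozenBefore <- paramDigest(net@pretrained)
  trainImg <- samplesImages(data@train)
  trainMsk <- samplesMasks(data@train)
  valSamples <- data@validation

  # the frozen encoder never changes, so its features are computed once
  useFrozen <- spec@fusion != "trainable-only"
  trainFro <- if (useFrozen) encodeFrozen(net, trainImg, cfg@batchSize)
  valFro <- if (useFrozen && length(valSamples))
    encodeFrozen(net, samplesImages(valSamples), cfg@batchSize)

  state <- adamInit(net@params)
  curves <- data.frame()
  withSeed(deriveSeed(cfg@seed, 32L), {
    for (epoch in seq_len(cfg@epochs)) {
      lr <- learningRateAt(cfg, epoch)
      epochLoss <- 0; nb <- 0
      for (idx in batchIndices(length(trainImg), cfg@batchSize)) {
        x <- stackImages(trainImg[idx])
        y <- stackMasks(trainMsk[idx])
        fw <- segForward(net, x, keepCache = TRUE,
                         frozen = if (useFrozen) gatherFrozen(trainFro, idx))
        epochLoss <- epochLoss + baselineLoss(cfg@loss, y, fw$p,
                                              cfg@lossParams)
        dp <- lossGradientMap(cfg@loss, y, fw$p, cfg@lossParams)
        dim(dp) <- dim(fw$p)
        grads <- segBackward(net, fw$cache, dp)
        st <- adamStep(net@params, grads, state, lr, cfg@adamDecays)
        net@params <- st$params; state <- st$state
        nb <- nb + 1
      }
      valDice <- if (length(valSamples))
        meanDiceCached(net, valSamples, valFro, cfg@batchSize)
      else NA_real_
      curves <- rbind(curves, data.frame(
        epoch = epoch, lr = lr, trainLoss = epochLoss / max(nb, 1),
        valDice = valDice))
    }
  })
  frozenAfter <- paramDigest(net@pretrained)
  notes <- character()
  if (!identical(frozenBefore, frozenAfter))
    notes <- "frozen-encoder digest changed during training"  # never expected
  finalScores <- list()
  if (length(data@test)) {
    ev <- evaluateNetwork(net, data@test, batchSize = cfg@batchSize)
    finalScores <- list(testDice = ev$meanDice, pooled = ev$pooled)
  }
  report <- new("TrainReport", phase = "segment", curves = curves,
                finalScores = finalScores, achievedAccuracy = NA_real_,
                seed = cfg@seed, wallClock = proc.time()[3] - t0,
                notes = notes)
  list(net = net, report = report)
}

# mean per-image Dice with optional cached frozen features
meanDiceCached <- function(net, samples, frozenFeats, batchSize) {
  dices <- numeric(length(samples))
  i <- 1
  while (i <= length(samples)) {
    j <- min(i + batchSize - 1, length(samples))
    x <- stackImages(samplesImages(samples[i:j]))
    fro <- if (!is.null(frozenFeats)) gatherFrozen(frozenFeats, i:j)
    p <- segForward(net, x, frozen = fro)$p
    for (k in i:j) {
      cc <- confusionCounts(binarizeMask(p[, , k - i + 1]),
                            samples[[k]]@mask)
      dices[k] <- segmentationScores(cc)@dice
    }
    i <- j + 1
  }
  mean(dices)
}

stackMasks <- function(masks) {
  H <- nrow(masks[[1]]); W <- ncol(masks[[1]])
  y <- array(0, c(H, W, length(masks)))
  for (n in seq_along(masks)) y[, , n] <- masks[[n]]
  y
}

#' Patient-level cross-validation folds
#'
#' @param patients Vector of patient ids.
#' @param folds Number of folds.
#' @param seed Shuffle seed.
#' @return List of integer vectors, one per fold (largest-remainder sizes).
#' @export
patientFolds <- function(patients, folds, seed = 1L) {
  patients <- sort(unique(patients))
  if (folds > length(patients))
    stopDomain("more folds than patients")
  shuffled <- withSeed(deriveSeed(seed, 41L), sample(patients))
  sizes <- rep(length(patients) %/% folds, folds)
  rem <- length(patients) %% folds
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1
  split(shuffled, rep(seq_len(folds), times = sizes))
}

#' Patient-level k-fold cross-validation of the two-phase pipeline
#'
#' Builds `cfg@folds` patient-level folds; in fold i the i-th patient group
#' is the test partition, the next group the validation partition and the
#' remaining groups the training partition (a 3:1:1 rotation at the default
#' five folds over 35 patients: 7 patients, 280 images per fold). Each fold
#' runs classification pre-training (unless the fusion policy is
#' "trainable-only") followed by segmentation training.
#'
#' @param dataset A [PhantomSet-class] or list of samples.
#' @param spec An [ArchitectureSpec-class].
#' @param cfg A [TrainConfig-class] (`phase = "segment"`); its `folds`,
#'   seed and optimisation settings apply per fold.
#' @param pretrainCfg Optional [TrainConfig-class] for the pre-training
#'   phase; defaults to `cfg` with `phase = "pretrain"` and the same seed.
#' @return List with `reports` (one [TrainReport-class] per fold), `folds`
#'   (patient ids per fold) and `summary` (mean and sd of test Dice).
#' @export
crossval <- function(dataset, spec, cfg, pretrainCfg = NULL) {
  ss <- samplesOf(dataset)
  pid <- vapply(ss, function(s) s@patientId, numeric(1))
  folds <- patientFolds(pid, cfg@folds, seed = cfg@seed)
  k <- length(folds)
  reports <- vector("list", k)
  dices <- numeric(k)
  for (i in seq_len(k)) {
    testP <- folds[[i]]
    valP <- folds[[i %% k + 1]]
    trainP <- setdiff(unlist(folds), c(testP, valP))
    split <- new("DatasetSplit",
                 train = ss[pid %in% trainP],
                 validation = ss[pid %in% valP],
                 test = ss[pid %in% testP],
                 patients = list(train = trainP, validation = valP,
                                 test = testP))
    pre <- NULL
    if (spec@fusion != "trainable-only") {
      pcfg <- if (is.null(pretrainCfg)) {
        tc <- cfg; tc@phase <- "pretrain"; tc
      } else pretrainCfg
      pcfg@seed <- deriveSeed(cfg@seed, 50L + i)
      pre <- pretrainEncoder(split, spec, pcfg)$net
    }
    scfg <- cfg
    scfg@seed <- deriveSeed(cfg@seed, 60L + i)
    run <- trainSegmentation(split, spec, pre, scfg)
    reports[[i]] <- run$report
    dices[i] <- if (length(run$report@finalScores))
      run$report@finalScores$testDice else NA_real_
  }
  list(reports = reports, folds = folds,
       summary = c(meanDice = mean(dices), sdDice = stats::sd(dices)))
}

#' Robustness of a trained network to calibrated speckle noise
#'
#' Re-evaluates a trained segmentation network on test images corrupted at
#' each requested PSNR operating point (masks untouched), returning a score
#' table with one row per noise level plus the clean row.
#'
#' @param net A trained [SegNetwork-class].
#' @param samples Test samples ([PhantomSet-class] or list).
#' @param psnrLevels Numeric vector of target PSNRs in dB (may be empty);
#'   the canonical sweep is `c(15, 12, 10)`.
#' @param seed Integer seed for the noise fields.
#' @param tolerance Calibration tolerance in dB (default 0.1).
#' @return Data frame with columns `level` ("clean" or "psnrXX"),
#'   `targetPsnr`, `meanDice`, `precision`, `recall`, `dice` (pooled).
#' @export
robustnessSweep <- function(net, samples, psnrLevels = c(15, 12, 10),
                            seed = 1L, tolerance = 0.1) {
  ss <- samplesOf(samples)
  rows <- list()
  evalRow <- function(label, target, samples) {
    ev <- evaluateNetwork(net, samples)
    data.frame(level = label, targetPsnr = target, meanDice = ev$meanDice,
               precision = ev$pooled@precision, recall = ev$pooled@recall,
               dice = ev$pooled@dice, stringsAsFactors = FALSE)
  }
  rows[[1]] <- evalRow("clean", NA_real_, ss)
  for (lv in psnrLevels) {
    noisy <- lapply(seq_along(ss), function(i) {
      cfg <- speckleConfig(lv, tolerance = tolerance,
                           seed = deriveSeed(seed, round(lv * 100), i))
      s <- ss[[i]]
      img <- addSpeckle(s@image, cfg)
      attributes(img) <- list(dim = dim(img))
      new("PhantomSample", image = img, mask = s@mask, label = s@label,
          patientId = s@patientId, index = s@index)
    })
    rows[[length(rows) + 1]] <- evalRow(sprintf("psnr%g", lv), lv, noisy)
  }
  do.call(rbind, rows)
}
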