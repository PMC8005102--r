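#' Hyperparameters of the integrated-on-positive loss family
#'
#' Holds the gradient-weight constants of the IPLF together with the focusing
#' exponent used by the focal-loss baseline and the probability clipping bound
#' applied before any logarithm is taken.
#'
#' @slot alpha Gradient-weight constant for the positive (lesion) term;
#'   must be positive. Default 0.5.
#' @slot beta Gradient-weight constant for the negative (background) term;
#'   must lie in (0, 1) so that log(1 - beta * p) stays finite on [0, 1].
#'   Default 0.95.
#' @slot focalGamma Focusing exponent of the focal-loss baseline
#'   (non-negative, default 2).
#' @slot eps Symmetric clipping bound: predictions are evaluated on
#'   [eps, 1 - eps]. Default 1e-7.
#' @seealso [lossParams()], [iplfValue()]
#' @export
setClass("LossParams", representation(
  alpha = "numeric", beta = "numeric", focalGamma = "numeric", eps = "numeric"
))

setValidity("LossParams", function(object) {
  msg <- character()
  if (length(object@alpha) != 1 || !is.finite(object@alpha) || object@alpha <= 0)
    msg <- c(msg, "alpha must be a single positive number")
  if (length(object@beta) != 1 || !is.finite(object@beta) ||
      object@beta <= 0 || object@beta >= 1)
    msg <- c(msg, "beta must lie strictly in (0, 1)")
  if (length(object@focalGamma) != 1 || object@focalGamma < 0)
    msg <- c(msg, "focalGamma must be >= 0")
  if (length(object@eps) != 1 || object@eps <= 0 || object@eps >= 0.5)
    msg <- c(msg, "eps must lie strictly in (0, 0.5)")
  if (length(msg)) msg else TRUE
})

#' Construct loss hyperparameters
#'
#' @param alpha,beta Gradient-weight constants (defaults 0.5 and 0.95).
#' @param focalGamma Focal-loss focusing exponent (default 2).
#' @param eps Probability clipping bound (default 1e-7).
#' @return A [LossParams-class] object.
#' @examples
#' lossParams()
#' lossParams(alpha = 0.95, beta = 0.5)
#' @export
lossParams <- function(alpha = 0.5, beta = 0.95, focalGamma = 2, eps = 1e-7) {
  new("LossParams", alpha = alpha, beta = beta,
      focalGamma = focalGamma, eps = eps)
}

setMethod("show", "LossParams", function(object) {
  cat(sprintf("LossParams: alpha=%g beta=%g focalGamma=%g eps=%g\n",
              object@alpha, object@beta, object@focalGamma, object@eps))
})

#' Pixel-level confusion counts between a predicted and a reference mask
#'
#' @slot tp,fp,fn,tn Non-negative pixel tallies of true positives, false
#'   positives, false negatives and true negatives.
#' @seealso [confusionCounts()], [segmentationScores()]
#' @export
setClass("ConfusionCounts", representation(
  tp = "numeric", fp = "numeric", fn = "numeric", tn = "numeric"
))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@fn, object@tn)
  if (length(v) != 4 || any(!is.finite(v)) || any(v < 0) ||
      any(v != round(v)))
    "tp, fp, fn, tn must be single non-negative integers"
  else TRUE
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d FP=%d FN=%d TN=%d (total %d)\n",
              as.integer(object@tp), as.integer(object@fp),
              as.integer(object@fn), as.integer(object@tn),
              as.integer(object@tp + object@fp + object@fn + object@tn)))
})

#' Segmentation quality scores derived from confusion counts
#'
#' Precision, recall, Dice coefficient, accuracy, specificity and balanced
#' accuracy, each in [0, 1].
#'
#' @slot precision,recall,dice,accuracy,specificity,balancedAccuracy
#'   Numeric scalars in [0, 1].
#' @seealso [segmentationScores()]
#' @export
setClass("SegmentationScores", representation(
  precision = "numeric", recall = "numeric", dice = "numeric",
  accuracy = "numeric", specificity = "numeric", balancedAccuracy = "numeric"
))

setValidity("SegmentationScores", function(object) {
  v <- c(object@precision, object@recall, object@dice, object@accuracy,
         object@specificity, object@balancedAccuracy)
  if (any(!is.finite(v)) || any(v < -1e-12) || any(v > 1 + 1e-12))
    "all scores must lie in [0, 1]" else TRUE
})

setMethod("show", "SegmentationScores", function(object) {
  cat(sprintf(paste0("SegmentationScores: precision=%.4f recall=%.4f ",
                     "dice=%.4f accuracy=%.4f specificity=%.4f B.A.=%.4f\n"),
              object@precision, object@recall, object@dice, object@accuracy,
              object@specificity, object@balancedAccuracy))
})

#' Configuration for PSNR-calibrated speckle-noise injection
#'
#' @slot targetPsnr Target peak signal-to-noise ratio in dB (positive).
#' @slot tolerance Acceptable deviation of the achieved PSNR in dB.
#' @slot seed Integer seed for the noise field.
#' @slot maxValue Dynamic-range maximum used in the PSNR formula (1.0 for
#'   images normalised to [0, 1]).
#' @seealso [addSpeckle()], [psnr()]
#' @export
setClass("SpeckleConfig", representation(
  targetPsnr = "numeric", tolerance = "numeric", seed = "numeric",
  maxValue = "numeric"
))

setValidity("SpeckleConfig", function(object) {
  msg <- character()
  if (object@targetPsnr <= 0) msg <- c(msg, "targetPsnr must be > 0")
  if (object@tolerance <= 0) msg <- c(msg, "tolerance must be > 0")
  if (object@maxValue <= 0) msg <- c(msg, "maxValue must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a speckle-noise configuration
#'
#' @param targetPsnr Target PSNR in dB.
#' @param tolerance Calibration tolerance in dB (default 0.1).
#' @param seed Integer RNG seed (default 1).
#' @param maxValue Dynamic-range maximum (default 1).
#' @return A [SpeckleConfig-class] object.
#' @export
speckleConfig <- function(targetPsnr, tolerance = 0.1, seed = 1L,
                          maxValue = 1) {
  new("SpeckleConfig", targetPsnr = targetPsnr, tolerance = tolerance,
      seed = seed, maxValue = maxValue)
}

#' Configuration of the synthetic ultrasound phantom generator
#'
#' The defaults mirror the structure of a musculoskeletal ultrasound study
#' corpus: 35 patient groups of 40 images each (1400 images), roughly 91%
#' of images containing a lesion, and lesion regions covering at most 10%
#' of the pixels of an image.
#'
#' @slot nPatients Number of patient groups (>= 3 so a 3:1:1 split exists).
#' @slot imagesPerPatient Images generated per patient.
#' @slot imageSize Integer pair, image height and width in pixels.
#' @slot lesionImageFraction Fraction of images that contain a lesion.
#' @slot maxLesionAreaFraction Upper bound on the lesion pixel fraction of
#'   any single image (default 0.10).
#' @slot textureScale Gaussian smoothing radius (pixels) of the speckle
#'   texture field.
#' @slot intensityContrast Relative darkening of the hypoechoic lesion
#'   interior, in (0, 1).
#' @slot seed Integer root seed; every sample derives its own stream from it.
#' @seealso [phantomConfig()], [generatePhantom()]
#' @export
setClass("PhantomConfig", representation(
  nPatients = "numeric", imagesPerPatient = "numeric", imageSize = "numeric",
  lesionImageFraction = "numeric", maxLesionAreaFraction = "numeric",
  textureScale = "numeric", intensityContrast = "numeric", seed = "numeric"
))

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (object@nPatients < 3)
    msg <- c(msg, "nPatients must be >= 3 for a 3:1:1 patient split")
  if (object@imagesPerPatient < 1) msg <- c(msg, "imagesPerPatient must be >= 1")
  if (length(object@imageSize) != 2 || any(object@imageSize < 8))
    msg <- c(msg, "imageSize must be a pair of dimensions >= 8")
  if (object@lesionImageFraction < 0 || object@lesionImageFraction > 1)
    msg <- c(msg, "lesionImageFraction must lie in [0, 1]")
  if (object@maxLesionAreaFraction <= 0 || object@maxLesionAreaFraction >= 1)
    msg <- c(msg, "maxLesionAreaFraction must lie in (0, 1)")
  if (object@intensityContrast <= 0 || object@intensityContrast >= 1)
    msg <- c(msg, "intensityContrast must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct a phantom-generator configuration
#'
#' @param nPatients Number of patient groups (default 35).
#' @param imagesPerPatient Images per patient (default 40).
#' @param imageSize Height/width in pixels (default c(64, 64)).
#' @param lesionImageFraction Fraction of lesion-positive images
#'   (default 1280/1400).
#' @param maxLesionAreaFraction Maximum lesion pixel fraction per image
#'   (default 0.10).
#' @param textureScale Speckle texture smoothing radius in pixels (default 1.5).
#' @param intensityContrast Lesion darkening factor (default 0.35).
#' @param seed Root seed (default 1).
#' @return A [PhantomConfig-class] object.
#' @examples
#' cfg <- phantomConfig(nPatients = 5, imagesPerPatient = 4)
#' @export
phantomConfig <- function(nPatients = 35L, imagesPerPatient = 40L,
                          imageSize = c(64L, 64L),
                          lesionImageFraction = 1280 / 1400,
                          maxLesionAreaFraction = 0.10,
                          textureScale = 1.5, intensityContrast = 0.35,
                          seed = 1L) {
  new("PhantomConfig", nPatients = nPatients,
      imagesPerPatient = imagesPerPatient, imageSize = imageSize,
      lesionImageFraction = lesionImageFraction,
      maxLesionAreaFraction = maxLesionAreaFraction,
      textureScale = textureScale, intensityContrast = intensityContrast,
      seed = seed)
}

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf(paste0("PhantomConfig: %d patients x %d images, %dx%d px, ",
                     "lesion fraction %.3f, max area %.2f, seed %d\n"),
              as.integer(object@nPatients), as.integer(object@imagesPerPatient),
              as.integer(object@imageSize[1]), as.integer(object@imageSize[2]),
              object@lesionImageFraction, object@maxLesionAreaFraction,
              as.integer(object@seed)))
})

#' One synthetic phantom: image, lesion mask, class label, patient id
#'
#' @slot image Numeric matrix in [0, 1].
#' @slot mask Binary matrix (same shape) marking the lesion.
#' @slot label 1 if the image contains a lesion, else 0; always consistent
#'   with the mask.
#' @slot patientId Integer patient group of the sample.
#' @slot index Integer index of the sample within its dataset.
#' @export
setClass("PhantomSample", representation(
  image = "matrix", mask = "matrix", label = "numeric",
  patientId = "numeric", index = "numeric"
))

setValidity("PhantomSample", function(object) {
  msg <- character()
  if (!all(dim(object@image) == dim(object@mask)))
    msg <- c(msg, "image and mask dimensions differ")
  if (!all(object@mask %in% c(0, 1)))
    msg <- c(msg, "mask must be binary")
  if (any(object@image < 0 | object@image > 1))
    msg <- c(msg, "image values must lie in [0, 1]")
  if (!(object@label %in% c(0, 1)))
    msg <- c(msg, "label must be 0 or 1")
  if ((object@label == 1) != any(object@mask > 0))
    msg <- c(msg, "label must be 1 iff the mask has a positive pixel")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PhantomSample", function(object) {
  cat(sprintf("PhantomSample #%d: patient %d, label %d, %dx%d, lesion %.1f%%\n",
              as.integer(object@index), as.integer(object@patientId),
              as.integer(object@label), nrow(object@image), ncol(object@image),
              100 * mean(object@mask)))
})

#' A collection of phantom samples with its generating configuration
#'
#' @slot samples List of [PhantomSample-class] objects.
#' @slot config The [PhantomConfig-class] that produced them.
#' @export
setClass("PhantomSet", representation(samples = "list",
                                      config = "PhantomConfig"))

setMethod("show", "PhantomSet", function(object) {
  labs <- vapply(object@samples, function(s) s@label, numeric(1))
  cat(sprintf("PhantomSet: %d samples, %d patients, %.1f%% lesion-positive\n",
              length(object@samples),
              length(unique(vapply(object@samples, function(s) s@patientId,
                                   numeric(1)))),
              100 * mean(labs)))
})

#' @describeIn PhantomSet-class Number of samples.
#' @param x A PhantomSet.
#' @export
setMethod("length", "PhantomSet", function(x) length(x@samples))

#' Patient-level train / validation / test partition
#'
#' @slot train,validation,test Lists of [PhantomSample-class] objects.
#' @slot patients Named list of integer patient-id vectors per partition.
#' @export
setClass("DatasetSplit", representation(
  train = "list", validation = "list", test = "list", patients = "list"
))

setValidity("DatasetSplit", function(object) {
  p <- object@patients
  all.p <- c(p$train, p$validation, p$test)
  if (anyDuplicated(all.p))
    "a patient id appears in more than one partition" else TRUE
})

setMethod("show", "DatasetSplit", function(object) {
  cat(sprintf("DatasetSplit: %d / %d / %d images (%d / %d / %d patients)\n",
              length(object@train), length(object@validation),
              length(object@test), length(object@patients$train),
              length(object@patients$validation),
              length(object@patients$test)))
})

#' Architecture of the dual-encoder segmentation network
#'
#' Both encoders follow a VGG-style pattern (two stacked 3x3 convolutions
#' per resolution level followed by 2x2 max-pooling); the decoder is
#' U-Net-style (nearest-neighbour upsampling plus skip concatenation). The
#' classification head of the pre-trained encoder applies global average
#' pooling, dropout and a 2-class softmax.
#'
#' @slot inputSize Integer pair, must be divisible by 2^nLevels.
#' @slot baseWidth Channels of the first level; level l uses
#'   baseWidth * 2^(l-1).
#' @slot nLevels Number of downsampling stages.
#' @slot fusion Skip-source policy: "both", "trainable-only" or
#'   "pretrained-only". "trainable-only" degenerates to a plain single-encoder
#'   U-Net.
#' @slot groups Group count of group normalisation.
#' @slot classifierDropout Dropout rate of the classification head during
#'   pre-training (inference never applies dropout).
#' @seealso [architectureSpec()], [buildSmartCA()]
#' @export
setClass("ArchitectureSpec", representation(
  inputSize = "numeric", baseWidth = "numeric", nLevels = "numeric",
  fusion = "character", groups = "numeric", classifierDropout = "numeric"
))

setValidity("ArchitectureSpec", function(object) {
  msg <- character()
  if (length(object@inputSize) != 2 ||
      any(object@inputSize %% 2^object@nLevels != 0))
    msg <- c(msg, "inputSize must be divisible by 2^nLevels")
  if (!(object@fusion %in% c("both", "trainable-only", "pretrained-only")))
    msg <- c(msg, "fusion must be both / trainable-only / pretrained-only")
  if (object@baseWidth < 1 || object@nLevels < 1)
    msg <- c(msg, "baseWidth and nLevels must be >= 1")
  if (object@classifierDropout < 0 || object@classifierDropout >= 1)
    msg <- c(msg, "classifierDropout must lie in [0, 1)")
  if (object@baseWidth %% object@groups != 0)
    msg <- c(msg, "baseWidth must be a multiple of the group-norm group count")
  if (length(msg)) msg else TRUE
})

#' Construct an architecture specification
#'
#' Desk-scale defaults (64x64 input, 8 base channels, 4 levels) keep a full
#' forward pass under a second on one CPU; full VGG19-like widths are
#' reachable via `baseWidth = 64`.
#'
#' @param inputSize Height/width pair (default c(64, 64)).
#' @param baseWidth First-level channel count (default 8).
#' @param nLevels Downsampling stages (default 4).
#' @param fusion Skip-source policy (default "both").
#' @param groups Group-normalisation groups (default 4).
#' @param classifierDropout Pre-training head dropout (default 0.75).
#' @return An [ArchitectureSpec-class] object.
#' @export
architectureSpec <- function(inputSize = c(64L, 64L), baseWidth = 8L,
                             nLevels = 4L, fusion = "both", groups = 4L,
                             classifierDropout = 0.75) {
  new("ArchitectureSpec", inputSize = inputSize, baseWidth = baseWidth,
      nLevels = nLevels, fusion = fusion, groups = groups,
      classifierDropout = classifierDropout)
}

setMethod("show", "ArchitectureSpec", function(object) {
  cat(sprintf(paste0("ArchitectureSpec: %dx%d input, base width %d, ",
                     "%d levels, fusion=%s, %d-group norm\n"),
              as.integer(object@inputSize[1]), as.integer(object@inputSize[2]),
              as.integer(object@baseWidth), as.integer(object@nLevels),
              object@fusion, as.integer(object@groups)))
})

#' Two-phase training configuration
#'
#' Phase "pretrain" optimises the classification encoder and stops at the
#' first epoch whose validation accuracy reaches
#' `pretrainTargetAccuracy` (training the classifier beyond that point has
#' been observed to hurt downstream segmentation, hence the stop). Phase
#' "segment" optimises the trainable encoder and decoder with the
#' pre-trained encoder frozen.
#'
#' @slot phase "pretrain" or "segment".
#' @slot loss Loss name: "iplf", "bce", "focal" or "f1".
#' @slot lossParams A [LossParams-class].
#' @slot batchSize Mini-batch size (default 8).
#' @slot epochs Epoch budget.
#' @slot lrInitial Initial Adam learning rate (default 0.001).
#' @slot lrHalvingPeriod Epochs between halvings of the learning rate
#'   (default 40).
#' @slot adamDecays First and second moment decay rates (default 0.99, 0.999).
#' @slot pretrainTargetAccuracy Validation-accuracy stopping threshold of the
#'   pre-training phase (default 0.80).
#' @slot dropout Classifier-head dropout during pre-training (default 0.75;
#'   segmentation training uses none).
#' @slot seed Integer seed.
#' @slot folds Cross-validation fold count (default 5).
#' @seealso [trainConfig()], [pretrainEncoder()], [trainSegmentation()]
#' @export
setClass("TrainConfig", representation(
  phase = "character", loss = "character", lossParams = "LossParams",
  batchSize = "numeric", epochs = "numeric", lrInitial = "numeric",
  lrHalvingPeriod = "numeric", adamDecays = "numeric",
  pretrainTargetAccuracy = "numeric", dropout = "numeric", seed = "numeric",
  folds = "numeric"
))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (!(object@phase %in% c("pretrain", "segment")))
    msg <- c(msg, "phase must be 'pretrain' or 'segment'")
  if (!(object@loss %in% c("iplf", "bce", "focal", "f1")))
    msg <- c(msg, "loss must be one of iplf, bce, focal, f1")
  if (object@batchSize < 1) msg <- c(msg, "batchSize must be >= 1")
  if (object@epochs < 0) msg <- c(msg, "epochs must be >= 0")
  if (object@pretrainTargetAccuracy < 0 || object@pretrainTargetAccuracy > 1)
    msg <- c(msg, "pretrainTargetAccuracy must lie in [0, 1]")
  if (length(object@adamDecays) != 2 ||
      any(object@adamDecays <= 0 | object@adamDecays >= 1))
    msg <- c(msg, "adamDecays must be two rates in (0, 1)")
  if (object@lrHalvingPeriod < 1) msg <- c(msg, "lrHalvingPeriod must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a training configuration
#'
#' @param phase "pretrain" or "segment".
#' @param loss Loss name (default "iplf").
#' @param lossParams Loss hyperparameters (default [lossParams()]).
#' @param batchSize Mini-batch size (default 8).
#' @param epochs Epoch budget (default 30; the full-scale protocol of 250
#'   epochs is configuration, not a requirement).
#' @param lrInitial Initial learning rate (default 0.001).
#' @param lrHalvingPeriod Learning-rate halving period in epochs (default 40).
#' @param adamDecays Adam moment decays (default c(0.99, 0.999)).
#' @param pretrainTargetAccuracy Pre-training early-stop threshold
#'   (default 0.80).
#' @param dropout Classifier-head dropout for pre-training (default 0.75).
#' @param seed Integer seed (default 1).
#' @param folds Cross-validation folds (default 5).
#' @return A [TrainConfig-class] object.
#' @export
trainConfig <- function(phase = "segment", loss = "iplf",
                        lossParams = iplfseg::lossParams(), batchSize = 8L,
                        epochs = 30L, lrInitial = 0.001,
                        lrHalvingPeriod = 40L, adamDecays = c(0.99, 0.999),
                        pretrainTargetAccuracy = 0.80, dropout = 0.75,
                        seed = 1L, folds = 5L) {
  new("TrainConfig", phase = phase, loss = loss, lossParams = lossParams,
      batchSize = batchSize, epochs = epochs, lrInitial = lrInitial,
      lrHalvingPeriod = lrHalvingPeriod, adamDecays = adamDecays,
      pretrainTargetAccuracy = pretrainTargetAccuracy, dropout = dropout,
      seed = seed, folds = folds)
}

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(paste0("TrainConfig: phase=%s loss=%s batch=%d epochs=%d ",
                     "lr=%g (halved every %d) seed=%d\n"),
              object@phase, object@loss, as.integer(object@batchSize),
              as.integer(object@epochs), object@lrInitial,
              as.integer(object@lrHalvingPeriod), as.integer(object@seed)))
})

#' Record of one training run
#'
#' @slot phase Training phase the report belongs to.
#' @slot curves Data frame of per-epoch learning curves (epoch, learning
#'   rate, training loss, validation metric).
#' @slot finalScores Named list of final evaluation results.
#' @slot achievedAccuracy Best validation accuracy (pre-training phase).
#' @slot seed Seed of the run.
#' @slot wallClock Elapsed seconds.
#' @slot notes Character vector of warnings recorded during the run.
#' @export
setClass("TrainReport", representation(
  phase = "character", curves = "data.frame", finalScores = "list",
  achievedAccuracy = "numeric", seed = "numeric", wallClock = "numeric",
  notes = "character"
))

setMethod("show", "TrainReport", function(object) {
  cat(sprintf("TrainReport (%s): %d epochs run, %.1fs wall clock\n",
              object@phase, nrow(object@curves), object@wallClock))
  if (length(object@notes)) cat(" notes:", object@notes, sep = "\n  ")
})

#' A segmentation network (parameters plus architecture)
#'
#' @slot spec The [ArchitectureSpec-class] of the network.
#' @slot params Trainable parameters (nested list of arrays): the trainable
#'   encoder, the decoder and the output head.
#' @slot pretrained Parameters of the frozen pre-trained encoder, or an empty
#'   list for a plain single-encoder U-Net.
#' @seealso [buildSmartCA()], [predictMask()]
#' @export
setClass("SegNetwork", representation(
  spec = "ArchitectureSpec", params = "list", pretrained = "list"
))

setMethod("show", "SegNetwork", function(object) {
  np <- sum(unlist(rapply(object@params, length, how = "list")))
  nf <- sum(unlist(rapply(object@pretrained, length, how = "list")))
  cat(sprintf(paste0("SegNetwork: fusion=%s, %d trainable parameters, ",
                     "%d frozen pre-trained parameters\n"),
              object@spec@fusion, np, nf))
})
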