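#' Pixelwise confusion counts between two binary masks
#'
#' @param predicted Binary matrix/array of predictions.
#' @param truth Binary matrix/array of the reference annotation, same shape.
#' @return A [ConfusionCounts-class] whose four tallies sum to the pixel
#'   total.
#' @examples
#' m <- matrix(c(1, 0, 0, 1), 2)
#' confusionCounts(m, m)
#' @export
confusionCounts <- function(predicted, truth) {
  if (!all(dim(as.array(predicted)) == dim(as.array(truth))))
    stopDomain("predicted and truth masks must have identical dimensions")
  assertBinary(predicted, "predicted mask")
  assertBinary(truth, "truth mask")
  tp <- sum(predicted == 1 & truth == 1)
  fp <- sum(predicted == 1 & truth == 0)
  fn <- sum(predicted == 0 & truth == 1)
  tn <- sum(predicted == 0 & truth == 0)
  new("ConfusionCounts", tp = tp, fp = fp, fn = fn, tn = tn)
}

# ratio with the both-empty convention: when a foreground denominator is
# zero and there is no foreground signal at all (tp = fp = fn = 0), the
# prediction of "no lesion" is correct and scores 1; a zero denominator with
# foreground present elsewhere scores 0.
emptyAwareRatio <- function(num, den, anyForeground) {
  if (den > 0) num / den else if (anyForeground) 0 else 1
}

#' Segmentation scores from confusion counts
#'
#' Computes precision TP/(TP+FP), recall TP/(TP+FN), Dice coefficient
#' 2TP/(2TP+FP+FN), accuracy (TP+TN)/total, specificity TN/(FP+TN) and
#' balanced accuracy (recall + specificity)/2. Degenerate 0/0 ratios follow
#' the both-empty convention: an image with no lesion anywhere and no
#' predicted lesion scores 1 on precision, recall and Dice.
#'
#' @param counts A [ConfusionCounts-class].
#' @return A [SegmentationScores-class].
#' @examples
#' segmentationScores(new("ConfusionCounts", tp = 2, fp = 1, fn = 1, tn = 6))
#' @export
segmentationScores <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  tp <- counts@tp; fp <- counts@fp; fn <- counts@fn; tn <- counts@tn
  total <- tp + fp + fn + tn
  if (total == 0) stopDomain("confusion counts sum to zero pixels")
  fg <- (tp + fp + fn) > 0
  precision <- emptyAwareRatio(tp, tp + fp, fg)
  recall <- emptyAwareRatio(tp, tp + fn, fg)
  dice <- emptyAwareRatio(2 * tp, 2 * tp + fp + fn, fg)
  specificity <- if (fp + tn > 0) tn / (fp + tn) else 1
  accuracy <- (tp + tn) / total
  new("SegmentationScores", precision = precision, recall = recall,
      dice = dice, accuracy = accuracy, specificity = specificity,
      balancedAccuracy = (recall + specificity) / 2)
}

#' False-positive ratio of two systems from their precision and recall
#'
#' For two segmentation systems evaluated against the same ground truth the
#' number of actual positives cancels from
#' `FP = (1 - Precision) / Precision * Recall * Positive`, so the ratio
#' `FP_a : FP_b` is computable from the four printed scores alone. The
#' result is reported in b-normalised form (x : 1).
#'
#' @param precisionA,recallA Precision and recall of system a.
#' @param precisionB,recallB Precision and recall of system b.
#' @return The scalar ratio FP_a / FP_b.
#' @examples
#' fpRatio(0.3600, 0.8913, 0.4763, 0.8849)  # 1.63
#' @export
fpRatio <- function(precisionA, recallA, precisionB, recallB) {
  v <- c(precisionA, recallA, precisionB, recallB)
  if (any(v <= 0 | v > 1))
    stopDomain("precision and recall values must lie in (0, 1]")
  fpA <- (1 - precisionA) / precisionA * recallA
  fpB <- (1 - precisionB) / precisionB * recallB
  if (fpB == 0) stopDomain("system b has no false positives; ratio undefined")
  fpA / fpB
}

#' Binarize a probability map
#'
#' @param prob Numeric array of foreground probabilities.
#' @param threshold Decision threshold in (0, 1); values greater than or
#'   equal to the threshold are foreground (default 0.5).
#' @return A binary array of the same shape.
#' @export
binarizeMask <- function(prob, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stopDomain("threshold must lie in (0, 1)")
  out <- (prob >= threshold) * 1
  if (!is.null(dim(prob))) dim(out) <- dim(prob)
  out
}

#' Evaluate directories of predicted masks against reference masks
#'
#' Reads matching PNG mask pairs from two directories, tallies per-image
#' confusion counts and returns per-image scores together with aggregate
#' scores from pooled counts and the mean of per-image Dice values.
#'
#' @param predDir Directory of predicted masks (PNG, any nonzero = positive).
#' @param truthDir Directory of reference masks with matching relative
#'   file names.
#' @return A list with elements `perImage` (data frame), `pooled`
#'   (a [SegmentationScores-class] from summed counts) and `meanDice`.
#' @export
evaluateMaskDirs <- function(predDir, truthDir) {
  files <- list.files(truthDir, pattern = "\\.png$", recursive = TRUE)
  if (!length(files)) stopDomain("no PNG masks found under ", truthDir)
  missing <- !file.exists(file.path(predDir, files))
  if (any(missing))
    stopDomain("prediction missing for: ", paste(files[missing][1], "..."))
  pooled <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  rows <- lapply(files, function(f) {
    pr <- (readGrayPNG(file.path(predDir, f)) > 0.5) * 1
    tr <- (readGrayPNG(file.path(truthDir, f)) > 0.5) * 1
    cc <- confusionCounts(pr, tr)
    pooled <<- pooled + c(cc@tp, cc@fp, cc@fn, cc@tn)
    s <- segmentationScores(cc)
    data.frame(file = f, tp = cc@tp, fp = cc@fp, fn = cc@fn, tn = cc@tn,
               precision = s@precision, recall = s@recall, dice = s@dice,
               accuracy = s@accuracy, specificity = s@specificity,
               balancedAccuracy = s@balancedAccuracy,
               stringsAsFactors = FALSE)
  })
  perImage <- do.call(rbind, rows)
  pooledScores <- segmentationScores(new("ConfusionCounts",
                                         tp = pooled[["tp"]],
                                         fp = pooled[["fp"]],
                                         fn = pooled[["fn"]],
                                         tn = pooled[["tn"]]))
  list(perImage = perImage, pooled = pooledScores,
       meanDice = mean(perImage$dice))
}
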