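#' Integrated-on-positive loss function (IPLF)
#'
#' Asymmetric per-pixel training loss for heavily imbalanced binary
#' segmentation. For a ground-truth-positive pixel (y = 1) the loss is
#' `log(1 - (alpha + 1/p)^2 * log(p))`, which grows without bound as the
#' prediction p approaches 0 and carries amplified gradients everywhere; for
#' a background pixel (y = 0) the loss is `-(beta * p)^2 * log(1 - beta * p)`,
#' which is bounded above by `-beta^2 * log(1 - beta)` on the whole unit
#' interval, so confident false positives are penalised far more gently than
#' under cross-entropy or focal loss. All logarithms are natural.
#'
#' Predictions are clipped to `[eps, 1 - eps]` before evaluation, making
#' every output finite.
#'
#' @param y Binary ground truth (scalar or array of 0/1).
#' @param yHat Predicted probabilities in [0, 1], same shape as `y` or scalar.
#' @param params A [LossParams-class] (default [lossParams()]).
#' @return Loss values, elementwise, same shape as the broadcast inputs.
#' @examples
#' iplfValue(1, 0.5)        # 1.6739...
#' iplfValue(0, 0.5)        # 0.1454...
#' @export
iplfValue <- function(y, yHat, params = lossParams()) {
  checkLossInputs(y, yHat)
  p <- pmin(1 - params@eps, pmax(params@eps, yHat))
  a <- params@alpha; b <- params@beta
  y * log(1 - (a + 1 / p)^2 * log(p)) - (b * p)^2 * (1 - y) * log(1 - b * p)
}

#' Analytic gradient of the IPLF
#'
#' Closed-form derivative of [iplfValue()] with respect to the predicted
#' probability. For y = 1 the derivative is `-g'(p) / (1 - g(p))` with
#' `g(p) = (alpha + 1/p)^2 log(p)`; for y = 0 it is
#' `-2 beta^2 p log(1 - beta p) + (beta p)^2 beta / (1 - beta p)`.
#'
#' @inheritParams iplfValue
#' @return Elementwise d(loss)/d(prediction).
#' @examples
#' iplfGradient(1, 1)   # -(alpha + 1)^2 = -2.25 at the default alpha
#' @export
iplfGradient <- function(y, yHat, params = lossParams()) {
  checkLossInputs(y, yHat)
  p <- pmin(1 - params@eps, pmax(params@eps, yHat))
  a <- params@alpha; b <- params@beta
  g  <- (a + 1 / p)^2 * log(p)
  gp <- -2 * (a + 1 / p) * log(p) / p^2 + (a + 1 / p)^2 / p
  pos <- -gp / (1 - g)
  neg <- -2 * b^2 * p * log(1 - b * p) + (b * p)^2 * b / (1 - b * p)
  y * pos + (1 - y) * neg
}

checkLossInputs <- function(y, yHat) {
  assertBinary(y, "ground truth y")
  if (any(yHat < 0 | yHat > 1))
    stopDomain("predictions must lie in [0, 1]; clipping applies only inside")
  invisible(TRUE)
}

# elementwise values of the baseline pointwise losses
pointwiseLossValue <- function(name, y, p, params) {
  g <- params@focalGamma
  switch(name,
    iplf = iplfValue(y, p, params),
    bce = -y * log(p) - (1 - y) * log(1 - p),
    focal = -y * (1 - p)^g * log(p) - (1 - y) * p^g * log(1 - p),
    stopDomain("unknown pointwise loss: ", name))
}

pointwiseLossGradient <- function(name, y, p, params) {
  g <- params@focalGamma
  switch(name,
    iplf = iplfGradient(y, p, params),
    bce = -y / p + (1 - y) / (1 - p),
    focal = y * (g * (1 - p)^(g - 1) * log(p) - (1 - p)^g / p) +
            (1 - y) * (-g * p^(g - 1) * log(1 - p) + p^g / (1 - p)),
    stopDomain("unknown pointwise loss: ", name))
}

#' Baseline losses compared against the IPLF
#'
#' Binary cross-entropy (`bce`) and focal loss (`focal`) are evaluated
#' per element and reduced by the arithmetic mean; the F1 loss (`f1`) is the
#' soft-Dice complement `1 - 2 * sum(y * p) / (sum(y) + sum(p))`, a statistic
#' of the whole batch.
#'
#' @param name One of "bce", "focal", "f1" (or "iplf" for convenience).
#' @param y Binary ground truth, scalar or batch.
#' @param yHat Predicted probabilities, same shape.
#' @param params A [LossParams-class]; `focalGamma` governs the focal loss.
#' @return A single loss value.
#' @examples
#' baselineLoss("bce", 1, 0.5)                  # log(2)
#' baselineLoss("f1", c(1, 0, 1), c(1, 0, 1))   # 0
#' @export
baselineLoss <- function(name, y, yHat, params = lossParams()) {
  if (!(name %in% c("bce", "focal", "f1", "iplf")))
    stopDomain("unknown loss name: ", name)
  checkLossInputs(y, yHat)
  if (name == "f1") {
    if (length(y) == 0) stopDomain("f1 loss requires a non-empty batch")
    denom <- sum(y) + sum(yHat)
    if (denom == 0) return(0)  # both empty: perfect overlap
    return(1 - 2 * sum(y * yHat) / denom)
  }
  p <- pmin(1 - params@eps, pmax(params@eps, yHat))
  mean(pointwiseLossValue(name, y, p, params))
}

# gradient of a loss over a prediction array (mean reduction for pointwise
# losses; exact gradient of the soft-Dice complement for f1)
lossGradientMap <- function(name, y, p, params) {
  if (name == "f1") {
    denom <- sum(y) + sum(p)
    if (denom == 0) return(array(0, dim = dim(as.array(p))))
    s <- sum(y * p)
    return((-2 * y * denom + 2 * s) / denom^2)
  }
  pc <- pmin(1 - params@eps, pmax(params@eps, p))
  pointwiseLossGradient(name, y, pc, params) / length(p)
}

#' Tabulate loss and gradient curves over a probability grid
#'
#' Produces the loss-versus-probability and gradient-versus-probability
#' curves used to compare the IPLF against the pointwise baselines at a
#' fixed ground-truth value. Gradients are analytic for every loss.
#'
#' @param y Binary ground truth (0 or 1).
#' @param grid Strictly increasing probabilities inside `[eps, 1 - eps]`.
#' @param losses Character vector of loss names among "iplf", "bce", "focal"
#'   (the F1 loss is a set statistic and has no pointwise curve).
#' @param params A [LossParams-class].
#' @return A data frame with columns `ground_truth`, `probability`,
#'   `loss_name`, `value`, `gradient` — one row per (loss, grid point).
#' @examples
#' head(tabulateCurves(1, c(0.25, 0.5, 0.75)))
#' @export
tabulateCurves <- function(y, grid, losses = c("iplf", "bce", "focal"),
                           params = lossParams()) {
  if (length(grid) == 0) stopDomain("probability grid must be non-empty")
  if (is.unsorted(grid, strictly = TRUE))
    stopDomain("probability grid must be strictly increasing")
  if (any(grid < params@eps | grid > 1 - params@eps))
    stopDomain("grid must lie within [eps, 1 - eps]")
  if (!(y %in% c(0, 1))) stopDomain("ground truth y must be 0 or 1")
  if ("f1" %in% losses)
    stopDomain("the f1 loss is a batch statistic and has no pointwise curve")
  do.call(rbind, lapply(losses, function(nm) {
    data.frame(ground_truth = y, probability = grid, loss_name = nm,
               value = pointwiseLossValue(nm, y, grid, params),
               gradient = pointwiseLossGradient(nm, y, grid, params),
               stringsAsFactors = FALSE)
  }))
}

#' Gradient surface of the IPLF over its hyperparameters
#'
#' Dense tabulation of the analytic IPLF gradient over a grid of
#' (alpha, beta, probability) triples at a fixed ground truth, the raw
#' material of hyperparameter-selection studies. Note that the y = 1 branch
#' of the loss involves only alpha and the y = 0 branch only beta.
#'
#' @param y Binary ground truth (0 or 1).
#' @param alphaGrid Positive alpha values.
#' @param betaGrid Beta values in (0, 1).
#' @param probGrid Probabilities in (0, 1).
#' @param params Base [LossParams-class] supplying `eps`.
#' @return A data frame with columns `ground_truth`, `alpha`, `beta`,
#'   `probability`, `gradient`.
#' @export
gradientSurface <- function(y, alphaGrid, betaGrid, probGrid,
                            params = lossParams()) {
  if (!length(alphaGrid) || !length(betaGrid) || !length(probGrid))
    stopDomain("hyperparameter and probability grids must be non-empty")
  if (any(alphaGrid <= 0)) stopDomain("alpha values must be positive")
  if (any(betaGrid <= 0 | betaGrid >= 1))
    stopDomain("beta values must lie in (0, 1)")
  if (any(probGrid <= 0 | probGrid >= 1))
    stopDomain("probabilities must lie in (0, 1)")
  if (!(y %in% c(0, 1))) stopDomain("ground truth y must be 0 or 1")
  tab <- expand.grid(probability = probGrid, beta = betaGrid,
                     alpha = alphaGrid, KEEP.OUT.ATTRS = FALSE)
  tab$ground_truth <- y
  tab$gradient <- mapply(function(a, b, p) {
    iplfGradient(y, p, lossParams(alpha = a, beta = b,
                                  focalGamma = params@focalGamma,
                                  eps = params@eps))
  }, tab$alpha, tab$beta, tab$probability)
  tab[, c("ground_truth", "alpha", "beta", "probability", "gradient")]
}

#' Write loss curves to CSV
#'
#' @param curves Data frame from [tabulateCurves()] or [gradientSurface()].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
writeLossCurves <- function(curves, file) {
  write.csv(curves, file, row.names = FALSE)
  invisible(file)
}
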