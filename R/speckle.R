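#' Peak signal-to-noise ratio between two images
#'
#' `10 * log10(maxValue^2 / MSE)` in decibels, where MSE is the mean squared
#' pixel difference. Identical images give `Inf`.
#'
#' @param clean,noisy Numeric matrices of identical shape.
#' @param maxValue Dynamic-range maximum (1 for images normalised to [0, 1]).
#' @return PSNR in dB.
#' @examples
#' psnr(matrix(0, 2, 2), matrix(0.1, 2, 2))  # 20 dB
#' @export
psnr <- function(clean, noisy, maxValue = 1) {
  if (!all(dim(as.array(clean)) == dim(as.array(noisy))))
    stopDomain("clean and noisy images must have identical dimensions")
  mse <- mean((clean - noisy)^2)
  if (mse == 0) return(Inf)
  10 * log10(maxValue^2 / mse)
}

#' Add PSNR-calibrated multiplicative speckle noise
#'
#' Corrupts an image with the multiplicative Gaussian speckle model
#' `out = in * (1 + n)`, `n ~ N(0, sigma^2)`, the granular interference
#' pattern characteristic of coherent ultrasound imaging. The noise
#' amplitude `sigma` is calibrated by bisection so that the PSNR of the
#' returned image (after clipping to [0, 1]) lies within
#' `cfg@tolerance` of `cfg@targetPsnr`. The noise field is drawn once from
#' the configured seed, making the output bit-reproducible; regions of
#' exactly zero intensity are untouched by the multiplicative model.
#'
#' @param image Numeric matrix in [0, 1]; must be nonconstant so a finite
#'   PSNR is attainable.
#' @param cfg A [SpeckleConfig-class].
#' @return The noisy image in [0, 1], with attributes `psnr` (achieved
#'   PSNR in dB) and `sigma` (calibrated noise standard deviation).
#' @examples
#' img <- matrix(runif(64 * 64, 0.2, 0.8), 64)
#' noisy <- addSpeckle(img, speckleConfig(15))
#' attr(noisy, "psnr")
#' @export
addSpeckle <- function(image, cfg) {
  stopifnot(is(cfg, "SpeckleConfig"))
  if (all(image == image[1]))
    stopDomain("image is constant; speckle PSNR cannot be calibrated")
  z <- withSeed(cfg@seed,
                matrix(rnorm(length(image)), nrow(image), ncol(image)))
  achieved <- function(sigma) {
    psnr(image, clip01(image * (1 + sigma * z)), cfg@maxValue)
  }
  # PSNR decreases monotonically in sigma; bracket then bisect.
  lo <- 0; hi <- 0.5
  steps <- 0
  while (achieved(hi) > cfg@targetPsnr && steps < 60) {
    hi <- hi * 2; steps <- steps + 1
  }
  if (achieved(hi) > cfg@targetPsnr)
    stopDomain("speckle calibration failed: target PSNR unreachable")
  sigma <- NA_real_
  for (i in seq_len(100)) {
    mid <- (lo + hi) / 2
    a <- achieved(mid)
    if (abs(a - cfg@targetPsnr) <= cfg@tolerance) { sigma <- mid; break }
    if (a > cfg@targetPsnr) lo <- mid else hi <- mid
  }
  if (is.na(sigma))
    stopDomain("speckle calibration did not converge within 100 bisections")
  out <- clip01(image * (1 + sigma * z))
  attr(out, "psnr") <- achieved(sigma)
  attr(out, "sigma") <- sigma
  out
}
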