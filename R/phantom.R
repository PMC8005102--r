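#' Generate one synthetic ultrasound phantom
#'
#' Emulates the statistical structure of musculoskeletal ultrasound frames:
#' horizontally layered bands of band-limited speckle texture (tendon-like
#' strata) and, for lesion-positive samples, a single darker hypoechoic blob
#' of irregular elliptical shape placed in the central band. The phantom is
#' deterministic given `(cfg@seed, index)`; lesion placement is retried up
#' to 100 times until its pixel fraction respects
#' `cfg@maxLesionAreaFraction`.
#'
#' @param cfg A [PhantomConfig-class].
#' @param index Sample index (1-based); also determines the patient id via
#'   `cfg@imagesPerPatient`.
#' @return A [PhantomSample-class].
#' @examples
#' s <- generatePhantom(phantomConfig(nPatients = 3, imagesPerPatient = 2), 1)
#' @export
generatePhantom <- function(cfg, index) {
  stopifnot(is(cfg, "PhantomConfig"))
  H <- as.integer(cfg@imageSize[1]); W <- as.integer(cfg@imageSize[2])
  withSeed(deriveSeed(cfg@seed, 7919L, index), {
    lesioned <- runif(1) < cfg@lesionImageFraction
    r <- matrix(seq_len(H), H, W)
    p1 <- runif(1, H / 3, H / 1.5); p2 <- runif(1, H / 8, H / 4)
    base <- 0.45 + 0.18 * sin(2 * pi * r / p1 + runif(1, 0, 2 * pi)) +
      0.08 * sin(2 * pi * r / p2 + runif(1, 0, 2 * pi))
    tex <- gaussSmooth(matrix(rnorm(H * W), H, W), cfg@textureScale)
    tex <- tex / max(stats::sd(tex), 1e-8)
    img <- clip01(base * (1 + 0.35 * tex))
    mask <- matrix(0, H, W)
    if (lesioned) {
      placed <- FALSE
      for (attempt in seq_len(100)) {
        frac <- runif(1, 0.015, 0.9 * cfg@maxLesionAreaFraction)
        ab <- frac * H * W / pi
        k <- runif(1, 1, 2.5)
        a <- sqrt(ab * k); b <- ab / a
        cy <- runif(1, 0.30 * H, 0.70 * H); cx <- runif(1, 0.20 * W, 0.80 * W)
        th <- runif(1, 0, pi)
        ps1 <- runif(1, 0, 2 * pi); ps2 <- runif(1, 0, 2 * pi)
        yy <- matrix(seq_len(H), H, W) - cy
        xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
        u <- (xx * cos(th) + yy * sin(th)) / a
        v <- (-xx * sin(th) + yy * cos(th)) / b
        phi <- atan2(v, u)
        rad <- 1 + 0.15 * sin(3 * phi + ps1) + 0.10 * sin(5 * phi + ps2)
        cand <- (sqrt(u^2 + v^2) <= rad) * 1
        if (sum(cand) >= 4 && mean(cand) <= cfg@maxLesionAreaFraction) {
          mask <- cand; placed <- TRUE; break
        }
      }
      if (!placed)
        stopDomain("lesion placement failed the area bound after 100 attempts")
      img <- clip01(img * (1 - cfg@intensityContrast * mask))
    }
    new("PhantomSample", image = img, mask = mask,
        label = as.numeric(any(mask > 0)),
        patientId = (index - 1) %/% cfg@imagesPerPatient + 1,
        index = index)
  })
}

#' Generate a full phantom dataset
#'
#' @param cfg A [PhantomConfig-class]; produces
#'   `cfg@nPatients * cfg@imagesPerPatient` samples.
#' @return A [PhantomSet-class].
#' @export
generatePhantomSet <- function(cfg) {
  n <- as.integer(cfg@nPatients * cfg@imagesPerPatient)
  new("PhantomSet", samples = lapply(seq_len(n), function(i)
    generatePhantom(cfg, i)), config = cfg)
}

samplesOf <- function(x) {
  if (is(x, "PhantomSet")) x@samples
  else if (is.list(x)) x
  else stopDomain("expected a PhantomSet or a list of PhantomSample")
}

#' Split a dataset by patient
#'
#' Shuffles patient ids and partitions them at the given ratio using
#' largest-remainder assignment, so no patient contributes images to more
#' than one partition. The default 3:1:1 ratio applied to 35 patient groups
#' of 40 images reproduces the 840 / 280 / 280 image partition.
#'
#' @param samples A [PhantomSet-class] or list of [PhantomSample-class].
#' @param ratio Integer triple train:validation:test (default c(3, 1, 1)).
#' @param seed Integer shuffle seed.
#' @return A [DatasetSplit-class].
#' @export
splitByPatient <- function(samples, ratio = c(3, 1, 1), seed = 1L) {
  ss <- samplesOf(samples)
  if (length(ratio) != 3 || any(ratio < 0) || sum(ratio) == 0)
    stopDomain("ratio must be three non-negative numbers, not all zero")
  pid <- vapply(ss, function(s) s@patientId, numeric(1))
  patients <- sort(unique(pid))
  if (length(patients) < sum(ratio > 0))
    stopDomain("fewer patients than non-empty ratio parts")
  shuffled <- withSeed(deriveSeed(seed, 104729L), sample(patients))
  quota <- length(patients) * ratio / sum(ratio)
  sizes <- floor(quota)
  rem <- length(patients) - sum(sizes)
  if (rem > 0) {
    extra <- order(quota - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  ends <- cumsum(sizes)
  pTrain <- shuffled[seq_len(sizes[1])]
  pVal <- if (sizes[2] > 0) shuffled[(ends[1] + 1):ends[2]] else integer()
  pTest <- if (sizes[3] > 0) shuffled[(ends[2] + 1):ends[3]] else integer()
  new("DatasetSplit",
      train = ss[pid %in% pTrain],
      validation = ss[pid %in% pVal],
      test = ss[pid %in% pTest],
      patients = list(train = pTrain, validation = pVal, test = pTest))
}

flipH <- function(m) m[, ncol(m):1, drop = FALSE]

applyAugment <- function(sample, doFlip, jitterFactor, cropBox) {
  img <- sample@image; mask <- sample@mask
  H <- nrow(img); W <- ncol(img)
  if (!is.null(cropBox)) {
    if (cropBox$h < 1 || cropBox$w < 1) stopDomain("degenerate zero-area crop")
    rows <- cropBox$r0:(cropBox$r0 + cropBox$h - 1)
    cols <- cropBox$c0:(cropBox$c0 + cropBox$w - 1)
    img <- resizeImage(img[rows, cols, drop = FALSE], H, W)
    mask <- resizeImage(mask[rows, cols, drop = FALSE], H, W, nearest = TRUE)
    mask <- (mask > 0.5) * 1
  }
  if (doFlip) { img <- flipH(img); mask <- flipH(mask) }
  if (!is.null(jitterFactor)) img <- clip01(img * jitterFactor)
  new("PhantomSample", image = clip01(img), mask = mask,
      label = as.numeric(any(mask > 0)), patientId = sample@patientId,
      index = sample@index)
}

#' Augment a phantom sample
#'
#' Returns the original sample plus `variantsPerImage - 1` transformed
#' copies drawn from horizontal flips, multiplicative intensity jitter and
#' random crops resized back to the original frame, and their compositions.
#' Masks undergo exactly the geometric transforms (nearest-neighbour
#' interpolation keeps them binary); intensity jitter never touches the
#' mask. The default of six variants turns an 840-image training partition
#' into the 5040 images of the full augmentation protocol.
#'
#' @param sample A [PhantomSample-class].
#' @param variantsPerImage Total variants including the original (>= 1).
#' @param seed Integer seed.
#' @return List of [PhantomSample-class] of length `variantsPerImage`.
#' @export
augmentSample <- function(sample, variantsPerImage = 6L, seed = 1L) {
  stopifnot(is(sample, "PhantomSample"))
  if (variantsPerImage < 1) stopDomain("variantsPerImage must be >= 1")
  out <- vector("list", variantsPerImage)
  out[[1]] <- sample
  if (variantsPerImage == 1) return(out)
  H <- nrow(sample@image); W <- ncol(sample@image)
  withSeed(deriveSeed(seed, 15485863L, sample@index), {
    for (v in 2:variantsPerImage) {
      doFlip <- runif(1) < 0.5
      doJit <- runif(1) < 0.7
      doCrop <- runif(1) < 0.7
      if (!doFlip && !doJit && !doCrop) doFlip <- TRUE
      jit <- if (doJit) runif(1, 0.8, 1.2) else NULL
      box <- NULL
      if (doCrop) {
        s <- runif(1, 0.70, 0.95)
        ch <- max(1L, round(H * s)); cw <- max(1L, round(W * s))
        box <- list(r0 = sample.int(H - ch + 1, 1),
                    c0 = sample.int(W - cw + 1, 1), h = ch, w = cw)
      }
      out[[v]] <- applyAugment(sample, doFlip, jit, box)
    }
  })
  out
}

#' Augment every sample of a collection
#'
#' @param samples A [PhantomSet-class] or list of samples.
#' @param variantsPerImage Variants per input sample (default 6).
#' @param seed Integer seed.
#' @return A flat list of [PhantomSample-class], length
#'   `variantsPerImage * length(samples)`.
#' @export
augmentAll <- function(samples, variantsPerImage = 6L, seed = 1L) {
  ss <- samplesOf(samples)
  unlist(lapply(ss, augmentSample, variantsPerImage = variantsPerImage,
                seed = seed), recursive = FALSE)
}

#' Distribution of lesion area fractions
#'
#' Histogram over the positive-pixel fraction per image, the standard
#' dataset-imbalance report for sparse-lesion corpora.
#'
#' @param samples A [PhantomSet-class] or list of samples.
#' @param breaks Histogram break points on [0, 1] (default 1% bins).
#' @return An object of class `histogram`, with the raw per-image fractions
#'   attached as attribute `fractions`.
#' @export
areaDistribution <- function(samples, breaks = seq(0, 1, by = 0.01)) {
  ss <- samplesOf(samples)
  fr <- vapply(ss, function(s) mean(s@mask), numeric(1))
  h <- graphics::hist(fr, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  attr(h, "fractions") <- fr
  h
}

#' Write a phantom dataset to disk
#'
#' Layout: `images/<patient>/<index>.png` (8-bit grayscale),
#' `masks/<patient>/<index>.png` (0/255) and `labels.csv` with columns
#' `patient_id, image_id, label`.
#'
#' @param set A [PhantomSet-class] or list of samples.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writePhantomSet <- function(set, dir) {
  ss <- samplesOf(set)
  rows <- lapply(ss, function(s) {
    rel <- file.path(sprintf("p%03d", as.integer(s@patientId)),
                     sprintf("%05d.png", as.integer(s@index)))
    writeGrayPNG(s@image, file.path(dir, "images", rel))
    writeGrayPNG(s@mask, file.path(dir, "masks", rel))
    data.frame(patient_id = as.integer(s@patientId),
               image_id = as.integer(s@index),
               label = as.integer(s@label))
  })
  write.csv(do.call(rbind, rows), file.path(dir, "labels.csv"),
            row.names = FALSE)
  invisible(dir)
}
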