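# Synthetic phantom generation, patient splitting, augmentation.

test_that("phantom generation is deterministic and respects invariants", {
  cfg <- tinyPhantomConfig()
  s1 <- generatePhantom(cfg, 3)
  s2 <- generatePhantom(cfg, 3)
  expect_identical(s1@image, s2@image)
  expect_identical(s1@mask, s2@mask)
  set <- tinySet()
  for (s in set@samples) {
    expect_true(all(s@image >= 0 & s@image <= 1))
    expect_true(all(s@mask %in% c(0, 1)))
    expect_identical(s@label == 1, any(s@mask > 0))
    expect_lte(mean(s@mask), cfg@maxLesionAreaFraction)
  }
})

test_that("lesion-free configuration yields only negative samples", {
  cfg <- tinyPhantomConfig()
  cfg@lesionImageFraction <- 0
  set <- generatePhantomSet(cfg)
  expect_true(all(vapply(set@samples, function(s) s@label, numeric(1)) == 0))
  expect_true(all(vapply(set@samples, function(s) sum(s@mask),
                         numeric(1)) == 0))
})

test_that("corpus statistics mirror the imbalance structure", {
  cfg <- phantomConfig(nPatients = 10L, imagesPerPatient = 20L,
                       imageSize = c(32L, 32L), seed = 11L)
  set <- generatePhantomSet(cfg)
  labs <- vapply(set@samples, function(s) s@label, numeric(1))
  # ~91% lesion-positive at the default fraction
  expect_gt(mean(labs), 0.82)
  frac <- vapply(set@samples, function(s) mean(s@mask), numeric(1))
  expect_lt(mean(frac[labs == 1]), 0.10)
  # corpus-level pixel imbalance: positives are a sparse class
  expect_lt(mean(frac), 0.10)
  h <- areaDistribution(set)
  expect_equal(sum(h$counts), length(set@samples))
  expect_true(all(attr(h, "fractions") <= 0.10))
  # all mass below the 10% bin boundary
  expect_true(all(h$counts[h$breaks[-1] > 0.101] == 0))
})

test_that("area distribution handles degenerate inputs", {
  cfg <- tinyPhantomConfig()
  cfg@lesionImageFraction <- 0
  set <- generatePhantomSet(cfg)
  h <- areaDistribution(set)
  expect_equal(h$counts[1], length(set@samples))
  expect_true(all(h$counts[-1] == 0))
})

test_that("patient split is leak-free with largest-remainder sizes", {
  set <- tinySet()
  sp <- splitByPatient(set, c(3, 1, 1), seed = 2)
  expect_s4_class(sp, "DatasetSplit")
  expect_length(sp@patients$train, 3)
  expect_length(sp@patients$validation, 1)
  expect_length(sp@patients$test, 1)
  # every image of a patient stays in one partition, across seeds
  for (seed in 1:10) {
    spi <- splitByPatient(set, c(3, 1, 1), seed = seed)
    all.p <- c(spi@patients$train, spi@patients$validation,
               spi@patients$test)
    expect_equal(sort(all.p), 1:5)
    parts <- list(spi@train, spi@validation, spi@test)
    declared <- list(spi@patients$train, spi@patients$validation,
                     spi@patients$test)
    for (k in 1:3) {
      pids <- unique(vapply(parts[[k]], function(s) s@patientId,
                            numeric(1)))
      expect_setequal(pids, declared[[k]])
    }
    expect_equal(length(spi@train) + length(spi@validation) +
                   length(spi@test), length(set))
  }
  # degenerate ratio: everything lands in train
  spAll <- splitByPatient(set, c(1, 0, 0), seed = 1)
  expect_length(spAll@train, length(set))
  expect_length(spAll@validation, 0)
  expect_error(splitByPatient(set@samples[1:4], c(3, 1, 1)), "fewer patients")
})

test_that("default corpus splits into the canonical partition sizes", {
  # 35 patients x 40 images at 3:1:1 -> 840 / 280 / 280; label-only
  # facsimile keeps this cheap
  fake <- lapply(seq_len(1400), function(i)
    new("PhantomSample", image = matrix(0.5, 8, 8), mask = matrix(0, 8, 8),
        label = 0, patientId = (i - 1) %/% 40 + 1, index = i))
  sp <- splitByPatient(fake, c(3, 1, 1), seed = 1)
  expect_equal(length(sp@train), 840)
  expect_equal(length(sp@validation), 280)
  expect_equal(length(sp@test), 280)
})

test_that("augmentation multiplies samples and preserves registration", {
  s <- tinySet()@samples[[1]]
  expect_equal(s@label, 1)
  out <- augmentSample(s, 6L, seed = 3)
  expect_length(out, 6)
  expect_identical(out[[1]], s)
  for (v in out[-1]) {
    expect_true(all(dim(v@image) == dim(s@image)))
    expect_true(all(v@mask %in% c(0, 1)))
    expect_identical(v@label == 1, any(v@mask > 0))
  }
  # determinism
  out2 <- augmentSample(s, 6L, seed = 3)
  expect_identical(lapply(out, function(x) x@image),
                   lapply(out2, function(x) x@image))
  # 840 x 6 = 5040 at the full-scale protocol; checked arithmetically on
  # a small multiple
  expect_length(augmentAll(tinySet()@samples[1:5], 6L, seed = 1), 30)
})

test_that("flip is an involution and jitter never touches the mask", {
  s <- tinySet()@samples[[1]]
  flipped <- iplfseg:::applyAugment(s, TRUE, NULL, NULL)
  back <- iplfseg:::applyAugment(flipped, TRUE, NULL, NULL)
  expect_identical(back@image, s@image)
  expect_identical(back@mask, s@mask)
  # flip registration: positive pixels map to mirrored columns
  expect_identical(flipped@mask, s@mask[, ncol(s@mask):1])
  jit <- iplfseg:::applyAugment(s, FALSE, 0.9, NULL)
  expect_identical(jit@mask, s@mask)
  expect_false(identical(jit@image, s@image))
  # degenerate crop errors
  expect_error(iplfseg:::applyAugment(s, FALSE, NULL,
                                      list(r0 = 1, c0 = 1, h = 0, w = 5)),
               "degenerate")
})

test_that("crop+resize keeps the mask binary and roughly registered", {
  s <- tinySet()@samples[[1]]
  box <- list(r0 = 3, c0 = 3, h = 24, w = 24)
  v <- iplfseg:::applyAugment(s, FALSE, NULL, box)
  expect_true(all(v@mask %in% c(0, 1)))
  expect_true(all(dim(v@image) == dim(s@image)))
  # the cropped-in lesion area grows by ~(32/24)^2 under nearest resize
  if (s@label == 1 && v@label == 1) {
    inCrop <- s@mask[box$r0:(box$r0 + 23), box$c0:(box$c0 + 23)]
    expect_equal(sum(v@mask) / max(sum(inCrop), 1), (32 / 24)^2,
                 tolerance = 0.25)
  }
})

test_that("phantom sets round-trip through the on-disk PNG layout", {
  dir <- withr::local_tempdir()
  set <- generatePhantomSet(tinyPhantomConfig(nPatients = 3L,
                                              imagesPerPatient = 2L,
                                              imageSize = 16L))
  writePhantomSet(set, dir)
  labs <- read.csv(file.path(dir, "labels.csv"))
  expect_equal(nrow(labs), 6)
  expect_identical(names(labs), c("patient_id", "image_id", "label"))
  f <- file.path(dir, "images", "p001", "00001.png")
  expect_true(file.exists(f))
  img <- iplfseg:::readGrayPNG(f)
  # 8-bit quantisation on write
  expect_lt(max(abs(img - set@samples[[1]]@image)), 1 / 255 + 1e-9)
  msk <- iplfseg:::readGrayPNG(file.path(dir, "masks", "p001", "00001.png"))
  expect_identical((msk > 0.5) * 1, set@samples[[1]]@mask)
})
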