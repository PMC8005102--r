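# Architecture contracts: shapes, softmax normalisation, parameter
# disjointness, frozen encoder, fusion policies.

test_that("architecture spec validates divisibility and fusion policy", {
  expect_error(architectureSpec(inputSize = c(60, 60), nLevels = 3),
               "divisible")
  expect_error(architectureSpec(fusion = "sideways"), "fusion")
  expect_error(architectureSpec(baseWidth = 6, groups = 4), "multiple")
  s <- tinySpec()
  expect_s4_class(s, "ArchitectureSpec")
})

test_that("classifier output is a normalised 2-class probability", {
  spec <- tinySpec("both")
  net <- buildPretrainedEncoder(spec, seed = 1)
  imgs <- lapply(tinySet()@samples[1:3], function(s)
    s@image[1:16, 1:16])
  p <- classifierPredict(net, imgs)
  expect_equal(dim(p), c(3, 2))
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  # inference applies no dropout: repeated passes are identical
  expect_identical(p, classifierPredict(net, imgs))
  # same structure, different parameter values across seeds
  net2 <- buildPretrainedEncoder(spec, seed = 2)
  expect_identical(rapply(net$params, dim, how = "list"),
                   rapply(net2$params, dim, how = "list"))
  expect_false(identical(net$params, net2$params))
})

test_that("segmentation output matches input size with unit channel sums", {
  spec <- tinySpec("both")
  pre <- buildPretrainedEncoder(spec, seed = 1)
  net <- buildSmartCA(spec, pre, seed = 2)
  img <- tinySet()@samples[[1]]@image[1:16, 1:16]
  prob <- predictProb(net, img)
  expect_equal(dim(prob), dim(img))
  expect_true(all(prob > 0 & prob < 1))  # softmax probabilities
  mask <- predictMask(net, img)
  expect_true(all(mask %in% c(0, 1)))
  expect_equal(dim(mask), dim(img))
  # threshold tie rule: probability exactly at threshold is positive
  expect_equal(binarizeMask(matrix(0.5, 2, 2), 0.5), matrix(1, 2, 2))
})

test_that("the two encoders share no parameters and pretrained is frozen", {
  spec <- tinySpec("both")
  pre <- buildPretrainedEncoder(spec, seed = 1)
  net <- buildSmartCA(spec, pre, seed = 2)
  # identical layer structure, disjoint values
  expect_identical(rapply(net@params$encoder, dim, how = "list"),
                   rapply(net@pretrained$encoder, dim, how = "list"))
  expect_false(identical(net@params$encoder, net@pretrained$encoder))
  # backward never produces gradients for the pre-trained encoder
  x <- iplfseg:::stackImages(tinySet()@samples[[1]]@image[1:16, 1:16])
  fw <- iplfseg:::segForward(net, x, keepCache = TRUE)
  g <- iplfseg:::segBackward(net, fw$cache,
                             array(1, dim(fw$p)) / length(fw$p))
  expect_named(g, c("decoder", "encoder"))
  # gradient tree mirrors the trainable tree exactly
  expect_identical(rapply(g$encoder, dim, how = "list"),
                   rapply(net@params$encoder, dim, how = "list"))
})

test_that("parameter counts decompose as trainable encoder + decoder", {
  spec <- tinySpec("both")
  pre <- buildPretrainedEncoder(spec, seed = 1)
  dual <- buildSmartCA(spec, pre, seed = 2)
  cnt <- function(p) sum(unlist(rapply(p, length, how = "unlist")))
  n <- parameterCount(dual)
  expect_equal(unname(n["trainable"]),
               cnt(dual@params$encoder) + cnt(dual@params$decoder))
  expect_equal(unname(n["frozen"]), cnt(pre$params$encoder))
})

test_that("trainable-only fusion degenerates to a plain U-Net", {
  spec <- tinySpec("trainable-only")
  net <- buildSmartCA(spec, NULL, seed = 3)
  expect_length(net@pretrained, 0)
  img <- tinySet()@samples[[2]]@image[1:16, 1:16]
  expect_equal(dim(predictProb(net, img)), dim(img))
  # requesting a fused network without pretrained parameters errors
  expect_error(buildSmartCA(tinySpec("both"), NULL), "requires")
  # structurally incompatible pretrained parameters are rejected
  wrong <- buildPretrainedEncoder(tinySpec("both", bw = 8L), seed = 1)
  expect_error(buildSmartCA(tinySpec("both"), wrong), "incompatible")
})

test_that("forward pass stays deterministic and fast at desk scale", {
  spec <- architectureSpec(inputSize = c(64, 64), baseWidth = 8,
                           nLevels = 4, fusion = "trainable-only")
  net <- buildSmartCA(spec, NULL, seed = 4)
  img <- matrix(runif(64 * 64), 64, 64)
  t0 <- proc.time()[3]
  p1 <- predictProb(net, img)
  expect_lt(proc.time()[3] - t0, 1)
  expect_identical(p1, predictProb(net, img))
})

test_that("checkpoints round-trip parameters and architecture", {
  dir <- withr::local_tempdir()
  spec <- tinySpec("both")
  pre <- buildPretrainedEncoder(spec, seed = 1)
  net <- buildSmartCA(spec, pre, seed = 2)
  path <- file.path(dir, "ck.rds")
  saveCheckpoint(net, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- loadCheckpoint(path)
  expect_s4_class(back, "SegNetwork")
  expect_equal(back@spec@fusion, "both")
  img <- tinySet()@samples[[1]]@image[1:16, 1:16]
  expect_identical(predictProb(net, img), predictProb(back, img))
})

test_that("compiled conv kernels agree with the double-precision reference", {
  set.seed(31)
  x <- array(rnorm(10 * 8 * 3 * 2), c(10, 8, 3, 2))
  wm <- matrix(rnorm(27 * 4, sd = 0.2), 27, 4)
  b <- rnorm(4)
  fast <- iplfseg:::conv3x3Forward(x, wm, b)
  ref <- iplfseg:::convRefForward(x, wm, b)
  expect_lt(max(abs(fast - ref)), 1e-5)
  dy <- array(rnorm(10 * 8 * 4 * 2), c(10, 8, 4, 2))
  bf <- iplfseg:::conv3x3Backward(x, wm, dy)
  br <- iplfseg:::convRefBackward(x, wm, dy)
  expect_lt(max(abs(bf$dx - br$dx)), 1e-4)
  expect_lt(max(abs(bf$dw - br$dw)), 1e-4)
  expect_lt(max(abs(bf$db - br$db)), 1e-4)
})

test_that("network gradients match finite differences (double path)", {
  withr::local_options(iplfseg.referenceConv = TRUE)
  spec <- tinySpec("both", size = 8L)
  pre <- buildPretrainedEncoder(spec, seed = 5)
  net <- buildSmartCA(spec, pre, seed = 7)
  set.seed(1)
  x <- array(runif(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  fw <- iplfseg:::segForward(net, x, keepCache = TRUE)
  tgt <- array(rnorm(length(fw$p)), dim(fw$p))
  grads <- iplfseg:::segBackward(net, fw$cache, tgt)
  obj <- function(n) sum(iplfseg:::segForward(n, x)$p * tgt)
  assignIn <- function(l, ks, val) {
    if (length(ks) == 1) { l[[ks[[1]]]] <- val; l }
    else { l[[ks[[1]]]] <- assignIn(l[[ks[[1]]]], ks[-1], val); l }
  }
  paths <- list(list("decoder", "head", "w"),
                list("decoder", "levels", 1, "w1"),
                list("decoder", "levels", 2, "g2"),
                list("encoder", "levels", 1, "w1"),
                list("encoder", "bottom", "b2"))
  for (path in paths) {
    leaf <- net@params
    for (k in path) leaf <- leaf[[k]]
    i <- length(leaf)  # last element of each tensor
    eps <- 1e-5
    up <- leaf; up[i] <- up[i] + eps
    dn <- leaf; dn[i] <- dn[i] - eps
    n1 <- net; n1@params <- assignIn(net@params, path, up)
    n2 <- net; n2@params <- assignIn(net@params, path, dn)
    num <- (obj(n1) - obj(n2)) / (2 * eps)
    g <- grads
    for (k in path) g <- g[[k]]
    expect_equal(g[i], num, tolerance = 1e-6)
  }
})
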