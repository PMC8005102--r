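# Dual-encoder segmentation network. Both encoders are VGG-style stacks
# (two 3x3 convolutions + group norm + SeLU per level, 2x2 max pooling
# between levels, one bottleneck block after the last pool). The decoder is
# U-Net-style: nearest-neighbour upsampling, concatenation of the skip
# features of the selected encoder(s), then a convolution block per level,
# and a 1x1 convolution + pixelwise 2-class softmax head.

encoderChannels <- function(spec) {
  bw <- as.integer(spec@baseWidth); L <- as.integer(spec@nLevels)
  list(levels = bw * 2^(seq_len(L) - 1), bottom = bw * 2^L)
}

encoderInit <- function(spec, inChannels = 1L) {
  ch <- encoderChannels(spec)
  L <- as.integer(spec@nLevels)
  levels <- vector("list", L)
  cin <- inChannels
  for (l in seq_len(L)) {
    levels[[l]] <- blockInit(cin, ch$levels[l], spec@groups)
    cin <- ch$levels[l]
  }
  list(levels = levels, bottom = blockInit(cin, ch$bottom, spec@groups))
}

encoderForward <- function(enc, x, G) {
  L <- length(enc$levels)
  skips <- vector("list", L)
  caches <- vector("list", L)
  pools <- vector("list", L)
  for (l in seq_len(L)) {
    bf <- blockForward(enc$levels[[l]], x, G)
    skips[[l]] <- bf$y
    caches[[l]] <- bf$cache
    mp <- maxpool2Forward(bf$y)
    pools[[l]] <- list(idx = mp$idx, xdim = dim(bf$y))
    x <- mp$y
  }
  bf <- blockForward(enc$bottom, x, G)
  list(skips = skips, bottom = bf$y,
       cache = list(blocks = caches, pools = pools, bottomCache = bf$cache))
}

# dSkips: list (may hold NULL for levels without incoming skip gradient)
encoderBackward <- function(enc, cache, dBottom, dSkips, G) {
  L <- length(enc$levels)
  grads <- list(levels = vector("list", L), bottom = NULL)
  bb <- blockBackward(enc$bottom, cache$bottomCache, dBottom)
  grads$bottom <- bb$grads
  dpool <- bb$dx
  for (l in rev(seq_len(L))) {
    dskip <- maxpool2Backward(dpool, cache$pools[[l]]$idx,
                              cache$pools[[l]]$xdim)
    if (!is.null(dSkips[[l]])) dskip <- dskip + dSkips[[l]]
    lb <- blockBackward(enc$levels[[l]], cache$blocks[[l]], dskip)
    grads$levels[[l]] <- lb$grads
    dpool <- lb$dx
  }
  list(dx = dpool, grads = grads)
}

#' Build a classification encoder
#'
#' Constructs the VGG-style convolutional trunk at the configured scale,
#' topped with global average pooling, dropout (pre-training only) and a
#' 2-class softmax — the network whose trained trunk later serves as the
#' frozen pre-trained encoder of the dual-encoder segmentation model.
#'
#' @param spec An [ArchitectureSpec-class].
#' @param seed Integer seed for parameter initialisation (LeCun-normal,
#'   matching the SeLU self-normalising regime).
#' @return A list with elements `spec` and `params`
#'   (`params$encoder`, `params$head`).
#' @seealso [classifierPredict()], [pretrainEncoder()]
#' @export
buildPretrainedEncoder <- function(spec, seed = 1L) {
  stopifnot(is(spec, "ArchitectureSpec"))
  ch <- encoderChannels(spec)
  params <- withSeed(deriveSeed(seed, 11L), {
    list(encoder = encoderInit(spec),
         head = list(w = matrix(rnorm(ch$bottom * 2, sd = sqrt(1 / ch$bottom)),
                                ch$bottom, 2),
                     b = numeric(2)))
  })
  list(spec = spec, params = params)
}

# forward pass of the classifier; images: (H, W, 1, N)
classifierForward <- function(params, images, G, dropout = 0,
                              training = FALSE) {
  ef <- encoderForward(params$encoder, images, G)
  d <- dim(ef$bottom)
  feats <- ef$bottom; dim(feats) <- c(d[1] * d[2], d[3], d[4])
  gap <- t(colMeans(feats))               # N x C
  dropMask <- NULL
  if (training && dropout > 0) {
    keep <- 1 - dropout
    dropMask <- matrix((runif(length(gap)) < keep) / keep,
                       nrow(gap), ncol(gap))
    gap <- gap * dropMask
  }
  logits <- gap %*% params$head$w +
    matrix(params$head$b, nrow(gap), 2, byrow = TRUE)
  p <- 1 / (1 + exp(logits[, 1] - logits[, 2]))   # foreground probability
  list(p = p, cache = list(enc = ef, gap = gap, dropMask = dropMask,
                           bottomDim = d, p = p))
}

classifierBackward <- function(params, cache, dp, G) {
  p <- cache$p
  dz1 <- dp * p * (1 - p)
  dlogits <- cbind(-dz1, dz1)
  dw <- t(cache$gap) %*% dlogits
  db <- colSums(dlogits)
  dgap <- dlogits %*% t(params$head$w)
  if (!is.null(cache$dropMask)) dgap <- dgap * cache$dropMask
  d <- cache$bottomDim
  dBottom <- array(0, d)
  per <- 1 / (d[1] * d[2])
  for (n in seq_len(d[4]))
    dBottom[, , , n] <- rep(dgap[n, ] * per, each = d[1] * d[2])
  eb <- encoderBackward(params$encoder, cache$enc$cache, dBottom,
                        vector("list", length(params$encoder$levels)), G)
  list(grads = list(encoder = eb$grads, head = list(w = dw, b = db)))
}

#' Class probabilities from a classification encoder
#'
#' Dropout is never applied at inference, so repeated calls are identical.
#'
#' @param net A classifier from [buildPretrainedEncoder()] or
#'   [pretrainEncoder()].
#' @param images A single image matrix or a list of image matrices.
#' @return A matrix with columns `p0`, `p1` (rows sum to 1).
#' @export
classifierPredict <- function(net, images) {
  x <- stackImages(images)
  p1 <- classifierForward(net$params, x, net$spec@groups)$p
  cbind(p0 = 1 - p1, p1 = p1)
}

decoderInit <- function(spec) {
  ch <- encoderChannels(spec)
  L <- as.integer(spec@nLevels)
  two <- if (spec@fusion == "both") 2L else 1L
  levels <- vector("list", L)
  zc <- two * ch$bottom
  for (l in rev(seq_len(L))) {
    cin <- zc + two * ch$levels[l]
    levels[[l]] <- blockInit(cin, ch$levels[l], spec@groups)
    zc <- ch$levels[l]
  }
  list(levels = levels,
       head = list(w = matrix(rnorm(ch$levels[1] * 2,
                                    sd = sqrt(1 / ch$levels[1])),
                              ch$levels[1], 2),
                   b = numeric(2)))
}

#' Build the dual-encoder segmentation network
#'
#' Assembles the segmentation model: a trainable encoder and (depending on
#' the fusion policy) a frozen classification-pretrained encoder feed one
#' U-Net-style decoder, which receives the channel concatenation of both
#' encoders' feature maps at every resolution level. The pre-trained
#' encoder's parameters are stored separately and never updated by
#' training. With `fusion = "trainable-only"` the network degenerates to a
#' plain single-encoder U-Net baseline and no pre-trained parameters are
#' required.
#'
#' @param spec An [ArchitectureSpec-class].
#' @param pretrained A classifier from [pretrainEncoder()] /
#'   [buildPretrainedEncoder()], or its parameter list; may be `NULL` when
#'   `spec@fusion == "trainable-only"`.
#' @param seed Integer seed for the trainable parameters.
#' @return A [SegNetwork-class].
#' @export
buildSmartCA <- function(spec, pretrained = NULL, seed = 1L) {
  stopifnot(is(spec, "ArchitectureSpec"))
  pre <- list()
  if (spec@fusion != "trainable-only") {
    if (is.null(pretrained))
      stopDomain("fusion policy ", spec@fusion,
                 " requires pre-trained encoder parameters")
    pp <- if (!is.null(pretrained$params)) pretrained$params else pretrained
    if (is.null(pp$encoder))
      stopDomain("pretrained parameters lack an encoder component")
    chk <- encoderChannels(spec)
    got <- ncol(pp$encoder$bottom$w2)
    if (got != chk$bottom)
      stopDomain("pretrained encoder is structurally incompatible: ",
                 "bottleneck width ", got, " != ", chk$bottom)
    pre <- list(encoder = pp$encoder)
  }
  params <- withSeed(deriveSeed(seed, 13L), {
    ps <- list(decoder = decoderInit(spec))
    if (spec@fusion != "pretrained-only")
      ps$encoder <- encoderInit(spec)
    ps
  })
  new("SegNetwork", spec = spec, params = params, pretrained = pre)
}

# full forward pass; images (H, W, 1, N) -> foreground prob (H, W, N).
# `frozen` may carry precomputed pre-trained-encoder features (skips/bottom)
# for this batch; the frozen encoder never changes during segmentation
# training, so its features per image can be computed once and reused.
segForward <- function(net, images, keepCache = FALSE, frozen = NULL) {
  spec <- net@spec; G <- spec@groups; L <- as.integer(spec@nLevels)
  fusion <- spec@fusion
  et <- ep <- NULL
  if (fusion != "pretrained-only")
    et <- encoderForward(net@params$encoder, images, G)
  if (fusion != "trainable-only")
    ep <- if (!is.null(frozen)) frozen
          else encoderForward(net@pretrained$encoder, images, G)
  z <- switch(fusion,
    "both" = concatC(et$bottom, ep$bottom),
    "trainable-only" = et$bottom,
    "pretrained-only" = ep$bottom)
  dec <- net@params$decoder
  blockCaches <- vector("list", L)
  zinC <- integer(L)
  for (l in rev(seq_len(L))) {
    zu <- upsample2Forward(z)
    skip <- switch(fusion,
      "both" = concatC(et$skips[[l]], ep$skips[[l]]),
      "trainable-only" = et$skips[[l]],
      "pretrained-only" = ep$skips[[l]])
    zin <- concatC(zu, skip)
    zinC[l] <- dim(zu)[3]
    bf <- blockForward(dec$levels[[l]], zin, G)
    blockCaches[[l]] <- bf$cache
    z <- bf$y
  }
  hf <- conv1x1Forward(z, dec$head$w, dec$head$b)
  sf <- softmax2Forward(hf$y)
  out <- list(p = sf$p)
  if (keepCache)
    out$cache <- list(et = et, ep = ep, blocks = blockCaches, zinC = zinC,
                      head = hf$cache, soft = sf$cache)
  out
}

# backward from d(loss)/d(foreground prob); returns grads for net@params
segBackward <- function(net, cache, dp) {
  spec <- net@spec; G <- spec@groups; L <- as.integer(spec@nLevels)
  fusion <- spec@fusion
  dec <- net@params$decoder
  dlogits <- softmax2Backward(cache$soft, dp)
  hb <- conv1x1Backward(cache$head, dec$head$w, dlogits)
  grads <- list(decoder = list(levels = vector("list", L),
                               head = list(w = hb$dw, b = hb$db)))
  dz <- hb$dx
  dSkipsT <- vector("list", L)
  for (l in seq_len(L)) {
    bb <- blockBackward(dec$levels[[l]], cache$blocks[[l]], dz)
    grads$decoder$levels[[l]] <- bb$grads
    sp <- splitC(bb$dx, cache$zinC[l])
    dz <- upsample2Backward(sp$a)
    if (fusion != "pretrained-only") {
      dskipFull <- sp$b
      if (fusion == "both") {
        ct <- dim(cache$et$skips[[l]])[3]
        dSkipsT[[l]] <- splitC(dskipFull, ct)$a
      } else {
        dSkipsT[[l]] <- dskipFull
      }
    }
  }
  if (fusion != "pretrained-only") {
    dBottomT <- if (fusion == "both") {
      ct <- dim(cache$et$bottom)[3]
      splitC(dz, ct)$a
    } else dz
    eb <- encoderBackward(net@params$encoder, cache$et$cache, dBottomT,
                          dSkipsT, G)
    grads$encoder <- eb$grads
  }
  grads
}

#' Predict a binary lesion mask
#'
#' Runs the segmentation network and thresholds the foreground-class
#' probability map. Probabilities exactly at the threshold are positive.
#'
#' @param net A [SegNetwork-class].
#' @param image A single image matrix in [0, 1], or a list of them.
#' @param threshold Decision threshold in (0, 1), default 0.5.
#' @return A binary mask matrix (or list of masks for list input).
#' @export
predictMask <- function(net, image, threshold = 0.5) {
  single <- is.matrix(image)
  x <- stackImages(image)
  p <- segForward(net, x)$p
  masks <- lapply(seq_len(dim(p)[3]), function(n)
    binarizeMask(p[, , n], threshold))
  if (single) masks[[1]] else masks
}

#' Foreground probability map(s) of a segmentation network
#'
#' @param net A [SegNetwork-class].
#' @param image A single image matrix or list of image matrices.
#' @return Probability matrix, or list of matrices.
#' @export
predictProb <- function(net, image) {
  single <- is.matrix(image)
  x <- stackImages(image)
  p <- segForward(net, x)$p
  maps <- lapply(seq_len(dim(p)[3]), function(n) p[, , n])
  if (single) maps[[1]] else maps
}

# per-image features of the frozen pre-trained encoder
encodeFrozen <- function(net, images, batchSize = 8L) {
  out <- vector("list", length(images))
  i <- 1
  while (i <= length(images)) {
    j <- min(i + batchSize - 1, length(images))
    x <- stackImages(images[i:j])
    ef <- encoderForward(net@pretrained$encoder, x, net@spec@groups)
    for (k in i:j) {
      n <- k - i + 1
      out[[k]] <- list(
        skips = lapply(ef$skips, function(s) s[, , , n, drop = FALSE]),
        bottom = ef$bottom[, , , n, drop = FALSE])
    }
    i <- j + 1
  }
  out
}

gatherFrozen <- function(feats, idx) {
  L <- length(feats[[1]]$skips)
  skips <- vector("list", L)
  for (l in seq_len(L)) {
    ds <- dim(feats[[idx[1]]]$skips[[l]])
    arr <- array(0, c(ds[1], ds[2], ds[3], length(idx)))
    for (n in seq_along(idx)) arr[, , , n] <- feats[[idx[n]]]$skips[[l]]
    skips[[l]] <- arr
  }
  db <- dim(feats[[idx[1]]]$bottom)
  bottom <- array(0, c(db[1], db[2], db[3], length(idx)))
  for (n in seq_along(idx)) bottom[, , , n] <- feats[[idx[n]]]$bottom
  list(skips = skips, bottom = bottom)
}

stackImages <- function(images) {
  if (is.matrix(images)) images <- list(images)
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  x <- array(0, c(H, W, 1, length(images)))
  for (n in seq_along(images)) x[, , 1, n] <- images[[n]]
  x
}

#' Byte-level digest of a parameter tree
#'
#' MD5 of the serialised parameter values, used to verify that the frozen
#' pre-trained encoder is untouched by segmentation training.
#'
#' @param params A parameter list (e.g. `net@pretrained`).
#' @return A character MD5 digest.
#' @export
paramDigest <- function(params) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(params, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

#' Count parameters of a network
#'
#' @param net A [SegNetwork-class] or classifier list.
#' @return Named vector with trainable and frozen parameter counts.
#' @export
parameterCount <- function(net) {
  cnt <- function(p) sum(unlist(rapply(p, length, how = "unlist")))
  if (is(net, "SegNetwork"))
    c(trainable = cnt(net@params), frozen = cnt(net@pretrained))
  else c(trainable = cnt(net$params), frozen = 0)
}

#' Save / load a network checkpoint
#'
#' The checkpoint is an RDS file of the parameters accompanied by a JSON
#' manifest of the architecture, so pre-trained encoders are transplantable
#' across runs.
#'
#' @param net A [SegNetwork-class] or classifier list.
#' @param path Checkpoint path (`.rds`); the manifest is written next to it.
#' @return `path`, invisibly.
#' @export
saveCheckpoint <- function(net, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (is(net, "SegNetwork")) {
    saveRDS(list(kind = "segnet", params = net@params,
                 pretrained = net@pretrained), path)
    spec <- net@spec
  } else {
    saveRDS(list(kind = "classifier", params = net$params), path)
    spec <- net$spec
  }
  manifest <- list(inputSize = as.integer(spec@inputSize),
                   baseWidth = as.integer(spec@baseWidth),
                   nLevels = as.integer(spec@nLevels), fusion = spec@fusion,
                   groups = as.integer(spec@groups),
                   classifierDropout = spec@classifierDropout)
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  m <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spec <- architectureSpec(inputSize = m$inputSize, baseWidth = m$baseWidth,
                           nLevels = m$nLevels, fusion = m$fusion,
                           groups = m$groups,
                           classifierDropout = m$classifierDropout)
  obj <- readRDS(path)
  if (obj$kind == "segnet")
    new("SegNetwork", spec = spec, params = obj$params,
        pretrained = obj$pretrained)
  else list(spec = spec, params = obj$params)
}
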