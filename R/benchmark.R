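#' Desk-scale loss and architecture benchmark
#'
#' Runs the full scaled-down experimental pipeline on synthetic phantoms:
#' generate a dataset, split it by patient at 3:1:1, train a plain U-Net
#' baseline with each requested loss, optionally pre-train a classification
#' encoder and train the dual-encoder network with the IPLF, evaluate all
#' models on the test partition, and sweep the final models across the
#' speckle-noise operating points. Repeated over several seeds this yields
#' directional analogues of the full-scale loss-comparison and
#' noise-robustness tables.
#'
#' @param seeds Integer vector of replicate seeds.
#' @param nPatients,imagesPerPatient Dataset size (default 15 x 20 = 300
#'   images).
#' @param imageSize Square image side in pixels (default 64).
#' @param losses Losses for the U-Net baseline (default c("bce", "iplf")).
#' @param includeSmartCA Train the dual-encoder model too (default TRUE).
#' @param epochs Segmentation epochs per model (default 30).
#' @param pretrainEpochs Epoch budget of the classification pre-training
#'   (default 10; early-stops at 80% validation accuracy).
#' @param psnrLevels Speckle sweep targets in dB (default c(15, 12, 10)).
#' @param baseWidth,nLevels Architecture scale (defaults 4, 3).
#' @param verbose Print per-model progress.
#' @return A list with data frames `lossTable` (model, loss, seed, test
#'   scores) and `noiseTable` (model, noise level, seed, Dice), plus
#'   `models` (the trained networks of the last seed).
#' @export
runBenchmark <- function(seeds = 1:3, nPatients = 15L, imagesPerPatient = 20L,
                         imageSize = 64L, losses = c("bce", "iplf"),
                         includeSmartCA = TRUE, epochs = 30L,
                         pretrainEpochs = 10L, psnrLevels = c(15, 12, 10),
                         baseWidth = 4L, nLevels = 3L, verbose = FALSE) {
  lossRows <- list(); noiseRows <- list(); models <- list()
  say <- function(...) if (verbose) message(sprintf(...))
  for (s in seeds) {
    pcfg <- phantomConfig(nPatients = nPatients,
                          imagesPerPatient = imagesPerPatient,
                          imageSize = c(imageSize, imageSize),
                          seed = deriveSeed(s, 71L))
    dataset <- generatePhantomSet(pcfg)
    split <- splitByPatient(dataset, c(3, 1, 1), seed = deriveSeed(s, 72L))
    specU <- architectureSpec(inputSize = c(imageSize, imageSize),
                              baseWidth = baseWidth, nLevels = nLevels,
                              fusion = "trainable-only")
    addLossRow <- function(model, loss, rep) {
      ev <- rep@finalScores
      lossRows[[length(lossRows) + 1]] <<- data.frame(
        model = model, loss = loss, seed = s, dice = ev$testDice,
        precision = ev$pooled@precision, recall = ev$pooled@recall,
        pooledDice = ev$pooled@dice, stringsAsFactors = FALSE)
    }
    addSweep <- function(model, net) {
      sw <- robustnessSweep(net, split@test, psnrLevels,
                            seed = deriveSeed(s, 73L))
      sw$model <- model; sw$seed <- s
      noiseRows[[length(noiseRows) + 1]] <<- sw
    }
    unets <- list()
    for (lo in losses) {
      say("seed %d: U-Net with %s", s, lo)
      cfg <- trainConfig(phase = "segment", loss = lo, epochs = epochs,
                         seed = deriveSeed(s, 74L))
      run <- trainSegmentation(split, specU, NULL, cfg)
      addLossRow("unet", lo, run$report)
      unets[[lo]] <- run$net
    }
    if ("iplf" %in% names(unets)) addSweep("unet", unets[["iplf"]])
    if (includeSmartCA) {
      say("seed %d: dual-encoder with iplf", s)
      specD <- architectureSpec(inputSize = c(imageSize, imageSize),
                                baseWidth = baseWidth, nLevels = nLevels,
                                fusion = "both")
      pcfgT <- trainConfig(phase = "pretrain", loss = "iplf",
                           epochs = pretrainEpochs,
                           seed = deriveSeed(s, 75L))
      pre <- pretrainEncoder(split, specD, pcfgT)
      cfg <- trainConfig(phase = "segment", loss = "iplf", epochs = epochs,
                         seed = deriveSeed(s, 76L))
      run <- trainSegmentation(split, specD, pre$net, cfg)
      addLossRow("smartca", "iplf", run$report)
      addSweep("smartca", run$net)
      models$smartca <- run$net
    }
    models$unet <- unets
  }
  list(lossTable = do.call(rbind, lossRows),
       noiseTable = do.call(rbind, noiseRows),
       models = models)
}
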