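# Shared fixtures, built in code. Kept tiny: the heavy directional
# benchmarks live in test-acceptance.R.

tinyPhantomConfig <- function(seed = 7L, nPatients = 5L,
                              imagesPerPatient = 4L, imageSize = 32L) {
  phantomConfig(nPatients = nPatients, imagesPerPatient = imagesPerPatient,
                imageSize = c(imageSize, imageSize), seed = seed)
}

# memoised small phantom set used across test files
tinySet <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generatePhantomSet(tinyPhantomConfig())
    cache
  }
})

tinySpec <- function(fusion = "trainable-only", size = 16L, bw = 4L,
                     nLevels = 2L) {
  architectureSpec(inputSize = c(size, size), baseWidth = bw,
                   nLevels = nLevels, fusion = fusion)
}

# central finite difference of a scalar function
centralDiff <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

# build a DatasetSplit directly from a sample list (single patient pool)
quickSplit <- function(samples, ratio = c(3, 1, 1), seed = 1L) {
  splitByPatient(samples, ratio, seed = seed)
}
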