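# PNG plumbing via EBImage: 8-bit grayscale in [0, 1] on the R side.

readGrayPNG <- function(path) {
  img <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

writeGrayPNG <- function(m, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  EBImage::writeImage(m, path, type = "png", bits.per.sample = 8L)
  invisible(path)
}

gaussSmooth <- function(m, sigma) {
  EBImage::imageData(EBImage::gblur(m, sigma = sigma))
}

resizeImage <- function(m, h, w, nearest = FALSE) {
  out <- EBImage::resize(m, w = h, h = w,
                         filter = if (nearest) "none" else "bilinear")
  EBImage::imageData(out)
}
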