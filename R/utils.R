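#' @useDynLib iplfseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm runif setNames
#' @importFrom utils write.csv read.csv head modifyList
NULL

# Evaluate `expr` under a private RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All randomness in the package flows through this.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically fork a root seed into per-component streams, staying
# inside 32-bit integer range.
deriveSeed <- function(seed, ...) {
  ks <- c(seed, ...)
  h <- 0
  for (k in ks) h <- (h * 69069 + as.numeric(k) + 1) %% 2147483647
  as.integer(h)
}

clip01 <- function(x) {
  y <- pmin(1, pmax(0, x))
  dim(y) <- dim(x)
  y
}

stopDomain <- function(...) stop(..., call. = FALSE)

assertBinary <- function(x, what) {
  if (!all(x %in% c(0, 1)))
    stopDomain(what, " must be binary (0/1)")
  invisible(TRUE)
}
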