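# Shared fixtures, built lazily and cached for the whole test run. Small
# phantoms keep per-file cost low; the full-size default phantom is only
# built where the end-to-end behaviour is under test.

.fixtures <- new.env(parent = emptyenv())

smallPhantomSpec <- function(seed = 11, ...) {
  phantomSpec(shape = c(32, 72, 72), spacing = c(2.5, 1.5, 1.5),
              vesselCount = 40, nLandmarks = 8, seed = seed, ...)
}

getSmallPhantom <- function() {
  if (is.null(.fixtures$smallPhantom))
    .fixtures$smallPhantom <- makePhantom(smallPhantomSpec())
  .fixtures$smallPhantom
}

# a textured 2-D slice for flow tests: band-limited noise, full contrast
texturedSlice <- function(n = 128, seed = 5, sigma = 1.5) {
  set.seed(seed)
  m <- matrix(rnorm(n * n), n)
  g <- lungstrain:::.gaussKernel(sigma)
  m <- lungstrain:::.sepConv2d(m, g, g)
  (m - min(m)) / diff(range(m)) * 255
}

randomVolume <- function(dims = c(6, 7, 8), seed = 1, lo = -1000, hi = 100) {
  set.seed(seed)
  CTVolume(array(runif(prod(dims), lo, hi), dims),
           spacing = c(2.5, 1.5, 1.5), origin = c(4, -3, 12))
}
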