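#' Apply the camera noise model and quantize
#'
#' Applies Poisson photon noise (if enabled), additive Gaussian read
#' noise, clipping at the bit-depth ceiling and integer quantization, in
#' that order. With photon noise off and zero read noise the result is
#' the input rounded to integers.
#'
#' @param grid a \linkS4class{VoxelGrid} holding expected (un-quantized)
#'   counts.
#' @param optics an \linkS4class{OpticsModel}.
#' @param seed optional integer; when given, seeds the RNG for a
#'   reproducible draw. When \code{NULL} the current RNG stream is used
#'   (as inside \code{\link{simulateField}}).
#' @return a quantized \linkS4class{VoxelGrid} of integer-valued counts in
#'   \code{[0, 2^bitDepth - 1]}.
#' @examples
#' g <- VoxelGrid(values = array(400, c(8, 8, 3)))
#' gn <- applyNoise(g, OpticsModel(), seed = 1)
#' mean(intensityValues(gn))  # ~400, unbiased
#' @export
setMethod("applyNoise", "VoxelGrid",
function(grid, optics, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  v <- grid@values
  n <- length(v)
  if (optics@photonNoise)
    v <- array(stats::rpois(n, lambda = v), dim = dim(v))
  if (optics@readNoiseSD > 0)
    v <- v + array(stats::rnorm(n, sd = optics@readNoiseSD), dim = dim(v))
  ceiling <- 2^grid@bitDepth - 1
  v <- round(pmin(pmax(v, 0), ceiling))
  grid@values <- v
  grid
})

# diffuse background with optional linear gradient, as an array
backgroundField <- function(d, optics) {
  g <- optics@bgGradient
  bg <- array(optics@bgLevel, dim = d)
  if (any(g != 0)) {
    iy <- (seq_len(d[1]) - 1) * g[1]
    ix <- (seq_len(d[2]) - 1) * g[2]
    iz <- (seq_len(d[3]) - 1) * g[3]
    bg <- bg + outer(outer(iy, ix, "+"), iz, "+")
    if (any(bg < 0)) kqConfigError("background gradient drives counts negative")
  }
  bg
}
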