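#' Construct a VoxelGrid
#'
#' @param values 3D numeric array indexed \code{[y, x, z]}, or \code{NULL}
#'   to create an empty grid of the given size.
#' @param ny,nx,nz grid size when \code{values} is \code{NULL}; the default
#'   axial extent is 17 slices.
#' @param dx,dy lateral voxel size in um (default 0.205).
#' @param dz axial slice spacing in um (default 0.4).
#' @param bitDepth camera bit depth (default 16).
#' @param channel fluorophore label.
#'
#' @return a \linkS4class{VoxelGrid}.
#' @examples
#' g <- VoxelGrid(ny = 64, nx = 64)
#' dim(intensityValues(g))
#' voxelDims(g)
#' @export
VoxelGrid <- function(values = NULL, ny = 64L, nx = 64L, nz = 17L,
                      dx = 0.205, dy = 0.205, dz = 0.4,
                      bitDepth = 16L, channel = "GFP") {
  if (is.null(values))
    values <- array(0, dim = c(ny, nx, nz))
  methods::new("VoxelGrid", values = values, dx = dx, dy = dy, dz = dz,
               bitDepth = as.integer(bitDepth), channel = channel)
}

#' @rdname VoxelGrid-class
#' @export
setMethod("intensityValues", "VoxelGrid", function(x) x@values)

#' @rdname VoxelGrid-class
#' @export
setMethod("voxelDims", "VoxelGrid",
  function(x) c(dx = x@dx, dy = x@dy, dz = x@dz))

#' @rdname VoxelGrid-class
#' @export
setMethod("channelName", "VoxelGrid", function(x) x@channel)

#' @rdname VoxelGrid-class
#' @export
setMethod("dim", "VoxelGrid", function(x) dim(x@values))

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "VoxelGrid: %d x %d x %d (y, x, z), voxel %.3f x %.3f x %.3f um\n",
    d[1], d[2], d[3], object@dy, object@dx, object@dz))
  cat(sprintf("  channel %s, %d-bit, intensity range [%.1f, %.1f]\n",
              object@channel, object@bitDepth,
              min(object@values), max(object@values)))
})

setMethod("show", "OpticsModel", function(object) {
  cat(sprintf(
    "OpticsModel: PSF sigma_xy %.3f um, sigma_z %.3f um\n",
    object@sigmaXY, object@sigmaZ))
  cat(sprintf(
    "  background %.1f counts (gradient %s), read noise %.2f, photon noise %s\n",
    object@bgLevel, paste(signif(object@bgGradient, 3), collapse = "/"),
    object@readNoiseSD, if (object@photonNoise) "on" else "off"))
})

setMethod("show", "GenotypeScenario", function(object) {
  cat(sprintf("GenotypeScenario '%s' (%s mode, %d foci/arm)\n",
              object@name, object@mode, object@nFoci))
  cat(sprintf("  channels: %s\n", paste(object@channels, collapse = " + ")))
  a <- object@arms
  for (i in seq_len(nrow(a))) {
    if (object@mode == "intensity")
      cat(sprintf("  %-24s intensity fold %.2f (cv %.3f)\n",
                  a$genotype[i], a$intensityFold[i], a$cv[i]))
    else
      cat(sprintf("  %-24s peak height fold %.2f (cv %.3f), FWHM fold %.2f (cv %.3f)\n",
                  a$genotype[i], a$peakHeightFold[i], a$phCV[i],
                  a$fwhmFold[i], a$fwhmCV[i]))
  }
  cat(sprintf("  source: %s\n", object@source))
})

setMethod("show", "KinetochoreROI", function(object) {
  vol <- roiVolume(object)
  cat(sprintf(
    "KinetochoreROI at (z=%d, y=%d, x=%d): box %d voxels (%.4f um^3), shell %d voxels (%.4f um^3), gap %g\n",
    object@center[1], object@center[2], object@center[3],
    nrow(object@kinVoxels), vol[["kin"]],
    nrow(object@bgVoxels), vol[["bg"]], object@gap))
})

#' Construct an OpticsModel
#'
#' @param sigmaXY,sigmaZ PSF standard deviations, um.
#' @param bgLevel mean diffuse background, counts.
#' @param bgGradient length-3 linear background trend (counts/voxel along
#'   y, x, z).
#' @param readNoiseSD additive Gaussian read noise s.d., counts.
#' @param photonNoise apply Poisson photon noise?
#' @return an \linkS4class{OpticsModel}.
#' @examples
#' OpticsModel(readNoiseSD = 0, photonNoise = FALSE)  # noiseless camera
#' @export
OpticsModel <- function(sigmaXY = 0.12, sigmaZ = 0.35, bgLevel = 100,
                        bgGradient = c(0, 0, 0), readNoiseSD = 2,
                        photonNoise = TRUE) {
  methods::new("OpticsModel", sigmaXY = sigmaXY, sigmaZ = sigmaZ,
               bgLevel = bgLevel, bgGradient = as.numeric(bgGradient),
               readNoiseSD = readNoiseSD, photonNoise = photonNoise)
}
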