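#' VoxelGrid: a 3D fluorescence intensity lattice
#'
#' The container every stage of the pipeline consumes: a non-negative 3D
#' intensity array indexed \code{[y, x, z]} (1-based) together with the
#' physical voxel dimensions in micrometres. Defaults match a widefield
#' system with 0.205 um lateral pixels and 17 z-slices at 0.4 um spacing.
#'
#' @slot values numeric 3D array of intensities, dim \code{c(ny, nx, nz)};
#'   all finite and >= 0.
#' @slot dx,dy lateral voxel size, um.
#' @slot dz axial slice spacing, um.
#' @slot bitDepth camera quantization limit in bits (ceiling is
#'   \code{2^bitDepth - 1} counts after \code{\link{applyNoise}}).
#' @slot channel fluorophore label ("GFP", "YFP", "CFP", "RFP", ...).
#'
#' @seealso [VoxelGrid()] for the constructor, [renderFocus()],
#'   [applyNoise()], [findFoci()], [measureFocus()].
#' @export
setClass("VoxelGrid",
  representation(
    values = "array",
    dx = "numeric",
    dy = "numeric",
    dz = "numeric",
    bitDepth = "integer",
    channel = "character"
  ),
  prototype(
    dx = 0.205, dy = 0.205, dz = 0.4,
    bitDepth = 16L, channel = "GFP"
  )
)

setValidity("VoxelGrid", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L)
    return("'values' must be a 3D array (y, x, z)")
  if (!is.numeric(v))
    return("'values' must be numeric")
  if (anyNA(v) || any(!is.finite(v)))
    return("all intensities must be finite")
  if (any(v < 0))
    return("all intensities must be >= 0")
  if (length(object@dx) != 1L || object@dx <= 0 ||
      length(object@dy) != 1L || object@dy <= 0 ||
      length(object@dz) != 1L || object@dz <= 0)
    return("voxel dimensions dx, dy, dz must be positive scalars")
  if (length(object@bitDepth) != 1L || object@bitDepth < 1L ||
      object@bitDepth > 32L)
    return("bitDepth must be a single integer in [1, 32]")
  if (length(object@channel) != 1L)
    return("channel must be a single label")
  TRUE
})

#' OpticsModel: point-spread function and camera model
#'
#' Describes the imaging system used by the synthetic-stack generator: an
#' anisotropic 3D Gaussian PSF, a diffuse cellular background (optionally
#' with a linear spatial gradient), Poisson photon noise and additive
#' Gaussian read noise. PSF defaults approximate a diffraction-limited
#' 1.4 NA widefield objective at the default voxel size.
#'
#' @slot sigmaXY lateral PSF standard deviation, um.
#' @slot sigmaZ axial PSF standard deviation, um.
#' @slot bgLevel mean diffuse background, counts.
#' @slot bgGradient length-3 numeric (counts per voxel along y, x, z); a
#'   linear trend added to the background, default zero.
#' @slot readNoiseSD read noise standard deviation, counts.
#' @slot photonNoise logical; apply Poisson noise?
#'
#' @seealso [OpticsModel()], [simulateField()], [applyNoise()].
#' @export
setClass("OpticsModel",
  representation(
    sigmaXY = "numeric",
    sigmaZ = "numeric",
    bgLevel = "numeric",
    bgGradient = "numeric",
    readNoiseSD = "numeric",
    photonNoise = "logical"
  ),
  prototype(
    sigmaXY = 0.12, sigmaZ = 0.35,
    bgLevel = 100, bgGradient = c(0, 0, 0),
    readNoiseSD = 2, photonNoise = TRUE
  )
)

setValidity("OpticsModel", function(object) {
  if (object@sigmaXY <= 0 || object@sigmaZ <= 0)
    return("PSF sigmas must be positive")
  if (object@bgLevel < 0)
    return("bgLevel must be >= 0")
  if (length(object@bgGradient) != 3L)
    return("bgGradient must have length 3 (y, x, z)")
  if (object@readNoiseSD < 0)
    return("readNoiseSD must be >= 0")
  TRUE
})

#' GenotypeScenario: a named simulation preset
#'
#' Encodes the per-genotype observable effect sizes a simulated experiment
#' plants as ground truth. Scenarios come in two modes: \code{"intensity"}
#' scenarios set a fold-change of integrated focus brightness (focus width
#' held at the control value), while \code{"morphometry"} scenarios set
#' fold-changes of the fitted marginal peak height and FWHM, with the
#' generator solving the underlying 3D amplitude so the planted
#' peak-height fold is realised in the marginal profile. The first arm is
#' always the control/reference population.
#'
#' @slot name preset label, e.g. \code{"fig2a_psh1del"}.
#' @slot mode \code{"intensity"} or \code{"morphometry"}.
#' @slot arms data.frame with one row per genotype arm and columns
#'   \code{genotype}, \code{intensityFold}, \code{cv},
#'   \code{fwhmFold}, \code{fwhmCV}, \code{peakHeightFold}, \code{phCV},
#'   plus one \code{frac_<channel>} column per channel (expression
#'   fractions, each row summing to 1).
#' @slot channels character vector of fluorophore labels; length 2 for
#'   dual-tag competition scenarios.
#' @slot nFoci default number of foci per arm.
#' @slot baselinePhotons integrated photon count of the mean control
#'   focus (arbitrary but fixed; all downstream comparisons are ratios).
#' @slot source free-text provenance of the planted effect sizes.
#'
#' @seealso [GenotypeScenario()], [scenarioLibrary()], [simulateField()].
#' @export
setClass("GenotypeScenario",
  representation(
    name = "character",
    mode = "character",
    arms = "data.frame",
    channels = "character",
    nFoci = "integer",
    baselinePhotons = "numeric",
    source = "character"
  )
)

setValidity("GenotypeScenario", function(object) {
  a <- object@arms
  need <- c("genotype", "intensityFold", "cv", "fwhmFold", "fwhmCV",
            "peakHeightFold", "phCV")
  if (!all(need %in% names(a)))
    return(paste("arms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) < 1L)
    return("at least one arm (the control) is required")
  if (!object@mode %in% c("intensity", "morphometry"))
    return("mode must be 'intensity' or 'morphometry'")
  if (any(a$intensityFold <= 0) || any(a$fwhmFold <= 0) ||
      any(a$peakHeightFold <= 0))
    return("all fold-changes must be > 0")
  if (any(a$cv < 0) || any(a$fwhmCV < 0) || any(a$phCV < 0))
    return("coefficients of variation must be >= 0")
  if (length(object@channels) < 1L)
    return("at least one channel required")
  fcols <- paste0("frac_", object@channels)
  if (!all(fcols %in% names(a)))
    return("arms must carry a frac_<channel> column per channel")
  fr <- as.matrix(a[, fcols, drop = FALSE])
  if (any(fr < 0) || any(abs(rowSums(fr) - 1) > 1e-8))
    return("per-arm channel fractions must be >= 0 and sum to 1")
  if (object@nFoci < 2L)
    return("nFoci must be >= 2")
  if (object@baselinePhotons <= 0)
    return("baselinePhotons must be positive")
  TRUE
})

#' KinetochoreROI: paired kinetochore-box / background-shell voxel sets
#'
#' The dual region of interest used for background-subtracted intensity
#' measurement: an axis-aligned box of fixed voxel dimensions centred on a
#' focus, and a fixed-count shell of the nearest voxels (anisotropic
#' Euclidean distance in um) outside the box dilated by a gap distance.
#' With the default geometry (3x3 px laterally, 9 slices axially; gap
#' 2 voxels; 1399 shell voxels) the box volume is 1.36 um^3 and the shell
#' volume 23.52 um^3 at the default voxel size.
#'
#' @slot center integer (z, y, x) voxel, 1-based.
#' @slot kinVoxels integer matrix, one (z, y, x) row per kinetochore voxel.
#' @slot bgVoxels integer matrix, one (z, y, x) row per background voxel.
#' @slot gap gap distance in voxels between box and shell.
#' @slot dims voxel dimensions \code{c(dx, dy, dz)} in um.
#'
#' @seealso [buildROI()], [roiGeometry()], [measureFocus()], [roiVolume()].
#' @export
setClass("KinetochoreROI",
  representation(
    center = "integer",
    kinVoxels = "matrix",
    bgVoxels = "matrix",
    gap = "numeric",
    dims = "numeric"
  )
)

setValidity("KinetochoreROI", function(object) {
  if (length(object@center) != 3L)
    return("center must be (z, y, x)")
  if (ncol(object@kinVoxels) != 3L || ncol(object@bgVoxels) != 3L)
    return("voxel matrices must have 3 columns (z, y, x)")
  kk <- paste(object@kinVoxels[, 1], object@kinVoxels[, 2],
              object@kinVoxels[, 3])
  bb <- paste(object@bgVoxels[, 1], object@bgVoxels[, 2],
              object@bgVoxels[, 3])
  if (length(intersect(kk, bb)) > 0L)
    return("kinetochore and background voxel sets must be disjoint")
  if (length(object@dims) != 3L || any(object@dims <= 0))
    return("dims must be positive (dx, dy, dz)")
  if (object@gap < 0)
    return("gap must be >= 0")
  TRUE
})
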