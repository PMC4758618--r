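# deterministic cell layout: cells on a square lattice, two foci per
# cell paired along x, so paired anaphase foci resolve separately and
# no two ROIs overlap
fieldLayout <- function(nFoci, margin = 20, cellSpacing = 26,
                        pairOffset = 6.5, nz = 17L) {
  if (margin < 12)
    kqConfigError("grid too small for default ROIs: margin must be >= 12 voxels")
  if (cellSpacing < 2 * pairOffset + 12)
    kqConfigError("cellSpacing too small: foci of neighbouring cells would fall within 12 voxels")
  nCells <- ceiling(nFoci / 2)
  cols <- ceiling(sqrt(nCells))
  rows <- ceiling(nCells / cols)
  nx <- as.integer(2 * margin + (cols - 1) * cellSpacing)
  ny <- as.integer(2 * margin + (rows - 1) * cellSpacing)
  cell <- seq_len(nCells) - 1L
  cx <- margin + (cell %% cols) * cellSpacing
  cy <- margin + (cell %/% cols) * cellSpacing
  # two foci per cell at +/- pairOffset along x; trim to nFoci
  fx <- as.numeric(rbind(cx - pairOffset, cx + pairOffset))[seq_len(nFoci)]
  fy <- as.numeric(rbind(cy, cy))[seq_len(nFoci)]
  cellId <- as.integer(rbind(cell + 1L, cell + 1L))[seq_len(nFoci)]
  list(nx = nx, ny = ny, nz = as.integer(nz),
       centerSlice = (nz + 1) / 2,
       x = fx, y = fy, cell = cellId)
}

#' Simulate a synthetic imaging field for a scenario
#'
#' Generates one noisy 16-bit z-stack per channel and per genotype arm,
#' with known per-focus ground truth. Cells carry two diffraction-limited
#' foci each (post-anaphase clusters) over a diffuse background;
#' per-focus brightness is lognormal with the arm's planted fold and CV,
#' positions get sub-voxel jitter, and the camera model of the optics is
#' applied. For \code{"morphometry"} scenarios the generator solves the
#' 3D amplitude per focus so the planted marginal peak-height fold is
#' realised in the 5-px patch profile (see
#' \code{\link{fitGaussian1D}}).
#'
#' Identical \code{(scenario, optics, seed)} give bit-identical stacks
#' and ground-truth tables.
#'
#' @param scenario a \linkS4class{GenotypeScenario} or preset name.
#' @param seed integer RNG seed (mandatory: no silent nondeterminism).
#' @param optics an \linkS4class{OpticsModel}.
#' @param nFoci foci per arm; defaults to the scenario's setting.
#' @param nz number of z-slices (default 17).
#' @return a \code{FieldSimulation}: list with \code{scenario},
#'   \code{seed}, \code{arms} (per arm: \code{grids}, a named list of
#'   \linkS4class{VoxelGrid} per channel, and \code{truth}) and the
#'   combined \code{truth} table (columns \code{focus_id},
#'   \code{cell_id}, \code{z}, \code{y}, \code{x}, \code{photons},
#'   \code{sigma_xy_um}, \code{height_au} (planted marginal peak height,
#'   morphometry mode only), \code{channel}, \code{genotype}).
#' @examples
#' sim <- simulateField(scenarioPreset("wt_reference"), seed = 1, nFoci = 10)
#' sim$arms$wild_type$grids$GFP
#' head(sim$truth)
#' @export
simulateField <- function(scenario, seed, optics = OpticsModel(),
                          nFoci = NULL, nz = 17L) {
  if (is.character(scenario)) scenario <- scenarioPreset(scenario)
  stopifnot(methods::is(scenario, "GenotypeScenario"))
  if (missing(seed) || is.null(seed))
    kqConfigError("simulateField requires an explicit seed")
  n <- as.integer(nFoci %||% scenario@nFoci)
  arms <- scenario@arms
  channels <- scenario@channels
  lay <- fieldLayout(n, nz = nz)
  set.seed(as.integer(seed))

  hppCache <- new.env(parent = emptyenv())
  hpp <- function(sxy) {
    key <- sprintf("%.12g", sxy)
    if (is.null(hppCache[[key]]))
      hppCache[[key]] <- marginalHeightPerPhoton(sxy, optics@sigmaZ,
                                                 dx = 0.205, dz = 0.4)
    hppCache[[key]]
  }

  armOut <- vector("list", nrow(arms))
  names(armOut) <- arms$genotype
  for (ai in seq_len(nrow(arms))) {
    arm <- arms[ai, ]
    # sub-voxel jitter around the layout positions
    x <- lay$x + stats::runif(n, -0.5, 0.5)
    y <- lay$y + stats::runif(n, -0.5, 0.5)
    z <- lay$centerSlice + stats::runif(n, -0.5, 0.5)
    sigmaXY <- optics@sigmaXY * arm$fwhmFold *
      rlnormMeanCV(n, 1, arm$fwhmCV)
    heightAU <- rep(NA_real_, n)
    if (scenario@mode == "intensity") {
      photons <- rlnormMeanCV(n, scenario@baselinePhotons * arm$intensityFold,
                              arm$cv)
    } else {
      # planted fitted marginal peak heights, in units of the control
      # mean; solve photons per focus through the forward model
      heightScale <- scenario@baselinePhotons * hpp(optics@sigmaXY)
      h <- rlnormMeanCV(n, arm$peakHeightFold, arm$phCV) * heightScale
      photons <- vapply(seq_len(n),
                        function(i) h[i] / hpp(sigmaXY[i]), numeric(1))
      heightAU <- h
    }
    grids <- list()
    truth <- NULL
    for (ch in channels) {
      frac <- arm[[paste0("frac_", ch)]]
      g <- VoxelGrid(ny = lay$ny, nx = lay$nx, nz = lay$nz, channel = ch)
      if (frac > 0) {
        for (i in seq_len(n))
          g <- renderFocus(g, center = c(z[i], y[i], x[i]),
                           photons = photons[i] * frac,
                           sigmaXY = sigmaXY[i], sigmaZ = optics@sigmaZ)
      }
      g@values <- g@values + backgroundField(dim(g@values), optics)
      g <- applyNoise(g, optics, seed = NULL)
      grids[[ch]] <- g
      truth <- rbind(truth, data.frame(
        focus_id = sprintf("%s_%03d", arm$genotype, seq_len(n)),
        cell_id = lay$cell,
        z = z, y = y, x = x,
        photons = photons * frac,
        sigma_xy_um = sigmaXY,
        height_au = heightAU,
        channel = ch,
        genotype = arm$genotype))
    }
    armOut[[ai]] <- list(genotype = arm$genotype, grids = grids,
                         truth = truth)
  }
  structure(
    list(scenario = scenario, seed = as.integer(seed), nFoci = n,
         optics = optics,
         arms = armOut,
         truth = do.call(rbind, lapply(armOut, `[[`, "truth"))),
    class = "FieldSimulation")
}

#' @export
print.FieldSimulation <- function(x, ...) {
  cat(sprintf("FieldSimulation of '%s' (seed %d): %d arms x %d foci, channels %s\n",
              x$scenario@name, x$seed, length(x$arms), x$nFoci,
              paste(x$scenario@channels, collapse = "+")))
  invisible(x)
}
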