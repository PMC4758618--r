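#' ROI geometry configuration
#'
#' Defines the dual-ROI used for background-subtracted intensity: an
#' axis-aligned kinetochore box of fixed voxel dimensions and a
#' fixed-count background shell separated from the box by a gap. The
#' default box is 3 x 3 px laterally by 9 slices axially (81 voxels =
#' 1.3616 um^3 at the default voxel size; the 9 x 9 x 1 factorization is
#' available via \code{boxDim}). The background shell holds the
#' \code{N} nearest voxels (anisotropic Euclidean distance in um, ties
#' broken lexicographically by (z, y, x)) outside the box dilated by
#' \code{gap} voxels, with \code{N} chosen so its physical volume best
#' approximates \code{bgVolume} (default 23.51 um^3 giving N = 1399 =
#' 23.517 um^3).
#'
#' @param boxDim integer (z, y, x) box dimensions in voxels (odd).
#' @param gap gap distance in voxels between box and shell (default 2).
#' @param bgVolume target background volume, um^3.
#' @return an \code{ROIGeometry} list.
#' @export
roiGeometry <- function(boxDim = c(9L, 3L, 3L), gap = 2, bgVolume = 23.51) {
  boxDim <- as.integer(boxDim)
  if (length(boxDim) != 3L || any(boxDim < 1L) || any(boxDim %% 2L == 0L))
    kqConfigError("boxDim must be three odd positive integers (z, y, x)")
  if (gap < 0) kqConfigError("gap must be >= 0")
  if (bgVolume <= 0) kqConfigError("bgVolume must be positive")
  structure(list(boxDim = boxDim, gap = gap, bgVolume = bgVolume),
            class = "ROIGeometry")
}

.kqCache <- new.env(parent = emptyenv())

# (z, y, x) voxel offsets of the background shell for a geometry and
# voxel size; deterministic, cached. The enumeration extent grows until
# the selected shell provably contains the N nearest outside voxels.
shellOffsets <- function(geometry, dims) {
  key <- paste(c(geometry$boxDim, geometry$gap, geometry$bgVolume, dims),
               collapse = "|")
  if (!is.null(.kqCache[[key]])) return(.kqCache[[key]])
  dx <- dims[1]; dy <- dims[2]; dz <- dims[3]
  voxVol <- dx * dy * dz
  bgCount <- round(geometry$bgVolume / voxVol)
  if (bgCount < 1) kqConfigError("bgVolume smaller than one voxel")
  hw <- (geometry$boxDim - 1L) %/% 2L          # (z, y, x)
  dil <- hw + geometry$gap
  ext <- c(z = dil[1] + 4L, y = dil[2] + 8L, x = dil[3] + 8L)
  pitch <- c(z = dz, y = dy, x = dx)
  repeat {
    off <- expand.grid(oz = -ext[1]:ext[1], oy = -ext[2]:ext[2],
                       ox = -ext[3]:ext[3])
    inDil <- abs(off$oz) <= dil[1] & abs(off$oy) <= dil[2] &
             abs(off$ox) <= dil[3]
    off <- off[!inDil, , drop = FALSE]
    d <- sqrt((off$oz * dz)^2 + (off$oy * dy)^2 + (off$ox * dx)^2)
    if (nrow(off) >= bgCount) {
      o <- order(d, off$oz, off$oy, off$ox)[seq_len(bgCount)]
      dmax <- max(d[o])
      # every voxel beyond the enumeration extent is farther than dmax
      if (dmax < min((ext + 1) * pitch)) {
        res <- as.matrix(off[o, c("oz", "oy", "ox")])
        dimnames(res) <- NULL
        .kqCache[[key]] <- res
        return(res)
      }
    }
    ext <- ext + 4L
  }
}

boxOffsets <- function(boxDim) {
  hw <- (boxDim - 1L) %/% 2L
  g <- expand.grid(oz = -hw[1]:hw[1], oy = -hw[2]:hw[2], ox = -hw[3]:hw[3])
  m <- as.matrix(g)
  dimnames(m) <- NULL
  m
}

#' Build the paired kinetochore/background ROI for a focus
#'
#' @param center integer (z, y, x) focus voxel, 1-based (the detected
#'   peak).
#' @param grid a \linkS4class{VoxelGrid} (provides grid size and voxel
#'   dimensions).
#' @param geometry an \code{\link{roiGeometry}} configuration.
#' @return a \linkS4class{KinetochoreROI}; raises an out-of-bounds error
#'   naming the focus when either voxel set would cross a grid boundary.
#' @examples
#' g <- VoxelGrid(ny = 48, nx = 48, nz = 17)
#' roi <- buildROI(c(9, 24, 24), g)
#' roiVolume(roi)
#' @export
buildROI <- function(center, grid, geometry = roiGeometry()) {
  center <- as.integer(round(center))
  d <- dim(grid@values)                        # (ny, nx, nz)
  dims <- unname(voxelDims(grid))              # (dx, dy, dz)
  kin <- sweep(boxOffsets(geometry$boxDim), 2L, center, "+")
  bg <- sweep(shellOffsets(geometry, dims), 2L, center, "+")
  lims <- c(d[3], d[1], d[2])                  # (z, y, x)
  inGrid <- function(m) all(m >= 1L) && all(t(t(m) <= lims))
  if (!inGrid(kin) || !inGrid(bg))
    kqOutOfBounds(sprintf(
      "ROI for focus at (z=%d, y=%d, x=%d) crosses a grid boundary",
      center[1], center[2], center[3]))
  methods::new("KinetochoreROI", center = center,
               kinVoxels = kin, bgVoxels = bg,
               gap = geometry$gap, dims = dims)
}

#' Physical volumes of an ROI's voxel sets
#'
#' Voxel count times physical voxel volume, per set.
#'
#' @param roi a \linkS4class{KinetochoreROI}.
#' @return named numeric: \code{kin} and \code{bg} volumes in um^3.
#' @export
setMethod("roiVolume", "KinetochoreROI", function(roi) {
  voxVol <- prod(roi@dims)
  c(kin = nrow(roi@kinVoxels) * voxVol,
    bg = nrow(roi@bgVoxels) * voxVol)
})
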