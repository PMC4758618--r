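#' Background-subtracted focus intensity
#'
#' The per-focus measurement: mean intensity over the kinetochore box
#' minus mean intensity over the background shell. Negative corrected
#' values (a dim focus over a bright background) are preserved, not
#' clipped, so population means stay unbiased.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param roi a \linkS4class{KinetochoreROI} built for this grid.
#' @return a \code{FocusMeasurement}: list with \code{meanKin},
#'   \code{meanBg}, \code{corrected} (\code{meanKin - meanBg}).
#' @export
setMethod("measureFocus", signature("VoxelGrid", "KinetochoreROI"),
function(grid, roi) {
  d <- dim(grid@values)
  mk <- mean(grid@values[voxelIndex(d, roi@kinVoxels)])
  mb <- mean(grid@values[voxelIndex(d, roi@bgVoxels)])
  structure(list(meanKin = mk, meanBg = mb, corrected = mk - mb),
            class = "FocusMeasurement")
})

#' Measure a set of foci
#'
#' Builds the dual ROI at each centre and measures it.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param centers data.frame with integer \code{z}, \code{y}, \code{x}
#'   peak voxels (e.g. from \code{\link{findFoci}}).
#' @param geometry an \code{\link{roiGeometry}}.
#' @return data.frame: \code{focus_id}, \code{z}, \code{y}, \code{x},
#'   \code{mean_kin}, \code{mean_bg}, \code{corrected}.
#' @export
measureFoci <- function(grid, centers, geometry = roiGeometry()) {
  n <- nrow(centers)
  out <- data.frame(
    focus_id = if (!is.null(centers$focus_id)) centers$focus_id else seq_len(n),
    z = centers$z, y = centers$y, x = centers$x,
    mean_kin = NA_real_, mean_bg = NA_real_, corrected = NA_real_)
  for (i in seq_len(n)) {
    m <- measureFocus(grid, buildROI(c(centers$z[i], centers$y[i],
                                       centers$x[i]), grid, geometry))
    out$mean_kin[i] <- m$meanKin
    out$mean_bg[i] <- m$meanBg
    out$corrected[i] <- m$corrected
  }
  out
}

#' Normalize corrected values to a reference population
#'
#' Divides every value by the mean of the reference population's
#' corrected values, the convention used for all published comparisons;
#' normalizing the reference against itself yields mean exactly 1.
#'
#' @param values numeric corrected values.
#' @param reference numeric corrected values of the control population
#'   (nonempty, nonzero mean).
#' @return numeric normalized values.
#' @examples
#' normalizePopulation(c(2, 4), reference = c(1, 3))  # 1 and 2
#' @export
normalizePopulation <- function(values, reference) {
  if (!length(reference))
    kqDataError("reference population is empty")
  m <- mean(reference)
  if (m == 0)
    kqDataError("degenerate reference: mean corrected value is zero")
  values / m
}

#' Per-channel contributions in a dual-tag strain
#'
#' For a strain carrying the same protein tagged with two fluorophores,
#' normalizes each channel's corrected focus intensities to the mean of
#' its own haploid single-tag reference, and sums the two per-focus
#' relative levels. Under equal competition each channel contributes
#' about 0.5 and the total is about 1.
#'
#' @param yfp,cfp corrected values of the two channels in the dual-tag
#'   strain (same foci, same order).
#' @param yfpRef,cfpRef corrected values of the haploid single-tag
#'   reference strains.
#' @return list with \code{perFocus} (data.frame \code{yfp_rel},
#'   \code{cfp_rel}, \code{total}) and \code{means} (named numeric).
#' @export
dualTagContributions <- function(yfp, cfp, yfpRef, cfpRef) {
  relY <- normalizePopulation(yfp, yfpRef)
  relC <- normalizePopulation(cfp, cfpRef)
  per <- data.frame(yfp_rel = relY, cfp_rel = relC, total = relY + relC)
  list(perFocus = per,
       means = c(yfp = mean(relY), cfp = mean(relC),
                 total = mean(relY + relC)))
}
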