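#' Extract the 5-px patch and its marginal sums
#'
#' Takes a square window (default 5x5) centred on a focus from the
#' z-slice containing its peak voxel, subtracts a local background (the
#' median of the window's border ring) from every pixel, and computes the
#' row and column marginal sums that the 1D Gaussian fits consume.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param center integer (z, y, x) peak voxel, 1-based.
#' @param halfWidth half-width of the square window in pixels (default 2,
#'   giving the 5-px box).
#' @return a \code{PatchProfile}: list with \code{patch} (background-
#'   subtracted matrix), \code{rowSums} (marginal along y), \code{colSums}
#'   (marginal along x), \code{localBg} and \code{center}.
#' @export
setMethod("extractPatch", "VoxelGrid",
function(grid, center, halfWidth = 2L) {
  d <- dim(grid@values)
  z <- as.integer(round(center[1]))
  y <- as.integer(round(center[2]))
  x <- as.integer(round(center[3]))
  h <- as.integer(halfWidth)
  if (z < 1L || z > d[3])
    kqOutOfBounds("patch z-slice outside the stack")
  if (y - h < 1L || y + h > d[1] || x - h < 1L || x + h > d[2])
    kqOutOfBounds(sprintf(
      "5-px patch at (z=%d, y=%d, x=%d) crosses a lateral boundary", z, y, x))
  patch <- grid@values[(y - h):(y + h), (x - h):(x + h), z]
  n <- 2L * h + 1L
  border <- c(patch[1, ], patch[n, ], patch[2:(n - 1), 1], patch[2:(n - 1), n])
  localBg <- stats::median(border)
  patch <- patch - localBg
  structure(
    list(patch = patch, rowSums = rowSums(patch), colSums = colSums(patch),
         localBg = localBg, center = c(z = z, y = y, x = x)),
    class = "PatchProfile")
})

#' Fit a 1D Gaussian to a marginal profile
#'
#' Nonlinear least squares on the 4-parameter model
#' \deqn{y = a + (b - a)\,\exp(-(x - c)^2 / (2 d^2))}
#' (baseline \code{a}, peak value \code{b}, centre \code{c}, s.d.
#' \code{d}), initialised at \code{a = min}, \code{b = max},
#' \code{c = argmax}, \code{d = 1} px, with bounds \code{0.3 <= d <= 5} px
#' and \code{c} inside the window. A fit is flagged unconverged when the
#' optimizer fails or \code{d} is pinned at a bound; such foci are
#' excluded from population summaries (and counted), never clamped.
#'
#' @param profile numeric marginal-sum vector (length >= 4; typically 5).
#' @return a \code{GaussianFit1D}: list with \code{a}, \code{b}, \code{c},
#'   \code{d}, \code{fwhm} (\code{2 sqrt(2 ln 2) d}, px),
#'   \code{height} (\code{b - a}), \code{converged}, \code{residual}.
#' @examples
#' x <- 1:5
#' y <- 10 + 90 * exp(-(x - 3)^2 / 2)
#' f <- fitGaussian1D(y)
#' c(f$d, f$height)  # 1 and 90 recovered
#' @export
fitGaussian1D <- function(profile) {
  x <- seq_along(profile)
  n <- length(x)
  failed <- list(a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
                 fwhm = NA_real_, height = NA_real_,
                 converged = FALSE, residual = NA_real_)
  class(failed) <- "GaussianFit1D"
  if (n < 4L || all(profile == profile[1])) return(failed)
  # Levenberg-Marquardt on the residuals directly (nls.lm); parameter
  # order (a, b, c, d)
  model <- function(p) p[1] + (p[2] - p[1]) * exp(-(x - p[3])^2 / (2 * p[4]^2))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(min(profile), max(profile), as.numeric(which.max(profile)), 1),
      fn = function(p) profile - model(p),
      lower = c(-Inf, -Inf, 1, 0.3), upper = c(Inf, Inf, n, 5),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) return(failed)
  p <- fit$par
  pinned <- p[4] <= 0.3 + 1e-9 || p[4] >= 5 - 1e-9
  out <- list(a = p[1], b = p[2], c = p[3], d = p[4],
              fwhm = fwhmFactor() * p[4],
              height = p[2] - p[1],
              converged = !pinned,
              residual = sqrt(fit$deviance))
  class(out) <- "GaussianFit1D"
  out
}

#' Focus size from the two marginal fits
#'
#' Averages the per-axis FWHM values (\code{2 sqrt(2 ln 2) d}) from the
#' row (vertical) and column (horizontal) Gaussian fits, and the two
#' baseline-to-peak amplitudes, giving the per-focus size and brightness
#' statistics that population comparisons normalize.
#'
#' @param rowFit,colFit converged \code{GaussianFit1D} objects.
#' @param dx lateral pixel size in um (for the um-scale FWHM).
#' @return a \code{FocusSize}: list with \code{fwhmPx}, \code{fwhmUm},
#'   \code{peakHeight}, \code{converged}.
#' @examples
#' f <- fitGaussian1D(100 * exp(-((1:5) - 3)^2 / 2))
#' focusSize(f, f)$fwhmPx  # 2.3548 for d = 1
#' @export
focusSize <- function(rowFit, colFit, dx = 0.205) {
  conv <- isTRUE(rowFit$converged) && isTRUE(colFit$converged)
  if (!conv)
    return(structure(list(fwhmPx = NA_real_, fwhmUm = NA_real_,
                          peakHeight = NA_real_, converged = FALSE),
                     class = "FocusSize"))
  fwhmPx <- mean(c(rowFit$fwhm, colFit$fwhm))
  structure(
    list(fwhmPx = fwhmPx, fwhmUm = fwhmPx * dx,
         peakHeight = mean(c(rowFit$height, colFit$height)),
         converged = TRUE),
    class = "FocusSize")
}

#' Measure focus sizes for a set of candidate peaks
#'
#' Runs patch extraction and the two marginal Gaussian fits for each
#' focus; foci whose fits fail are retained in the table with
#' \code{converged = FALSE} (and \code{NA} size) so failures are logged,
#' never silently dropped.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param centers data.frame with columns \code{z}, \code{y}, \code{x}
#'   (integer peak voxels), e.g. from \code{\link{findFoci}}.
#' @return data.frame with one row per focus: \code{focus_id}, \code{z},
#'   \code{y}, \code{x}, \code{fwhm_px}, \code{fwhm_um},
#'   \code{peak_height}, \code{converged}.
#' @export
measureFocusSizes <- function(grid, centers) {
  n <- nrow(centers)
  out <- data.frame(
    focus_id = if (!is.null(centers$focus_id)) centers$focus_id else seq_len(n),
    z = centers$z, y = centers$y, x = centers$x,
    fwhm_px = NA_real_, fwhm_um = NA_real_, peak_height = NA_real_,
    converged = FALSE)
  for (i in seq_len(n)) {
    prof <- extractPatch(grid, c(centers$z[i], centers$y[i], centers$x[i]))
    sz <- focusSize(fitGaussian1D(prof$rowSums),
                    fitGaussian1D(prof$colSums), dx = grid@dx)
    out$fwhm_px[i] <- sz$fwhmPx
    out$fwhm_um[i] <- sz$fwhmUm
    out$peak_height[i] <- sz$peakHeight
    out$converged[i] <- sz$converged
  }
  out
}
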