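#' Detection parameters
#'
#' @param edgeMargin voxels: candidates within this distance of any x, y
#'   or z boundary are removed (default 3, the published exclusion rule).
#' @param minSeparation minimum Euclidean distance in voxel units between
#'   accepted peaks (default 5, about one ROI half-width, so the paired
#'   anaphase foci of one cell resolve separately).
#' @param maxSpots cap on the number of candidates returned.
#' @param threshold optional absolute smoothed-intensity threshold;
#'   \code{NULL} keeps every local maximum above the grid minimum.
#' @param smoothSigma s.d. (voxels) of the Gaussian pre-smoothing applied
#'   before maxima detection; 0 disables smoothing.
#' @return a \code{DetectionParams} list.
#' @export
detectionParams <- function(edgeMargin = 3L, minSeparation = 5,
                            maxSpots = Inf, threshold = NULL,
                            smoothSigma = 1) {
  if (edgeMargin < 0) kqConfigError("edgeMargin must be >= 0")
  if (minSeparation < 1) kqConfigError("minSeparation must be >= 1")
  structure(list(edgeMargin = as.integer(edgeMargin),
                 minSeparation = minSeparation,
                 maxSpots = maxSpots, threshold = threshold,
                 smoothSigma = smoothSigma),
            class = "DetectionParams")
}

# separable Gaussian smoothing with a truncated, per-position
# renormalized kernel (3-sigma support); sigma in voxels, same on all axes
smoothArray <- function(v, sigma) {
  if (sigma <= 0) return(v)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  bandMatrix <- function(L) {
    S <- matrix(0, L, L)
    for (o in seq(-r, r)) {
      i <- seq_len(L)
      j <- i + o
      ok <- j >= 1L & j <= L
      S[cbind(i[ok], j[ok])] <- k[o + r + 1]
    }
    S / rowSums(S)
  }
  d <- dim(v)
  smooth1 <- function(a, axis) {
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- bandMatrix(d[axis]) %*% matrix(ap, nrow = d[axis])
    aperm(array(m, d[perm]), order(perm))
  }
  for (axis in 1:3) v <- smooth1(v, axis)
  v
}

# logical array marking voxels whose value is >= all 26 neighbours
localMaxima3D <- function(v) {
  d <- dim(v)
  pad <- array(-Inf, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- v
  ok <- array(TRUE, d)
  for (oy in -1:1) for (ox in -1:1) for (oz in -1:1) {
    if (oy == 0 && ox == 0 && oz == 0) next
    nb <- pad[(2:(d[1] + 1L)) + oy, (2:(d[2] + 1L)) + ox,
              (2:(d[3] + 1L)) + oz]
    ok <- ok & (v >= nb)
  }
  ok
}

#' Find candidate kinetochore foci
#'
#' Detects the brightest spots of a stack: Gaussian pre-smoothing, then
#' local maxima (26-neighbourhood), edge exclusion (candidates within
#' \code{edgeMargin} voxels of any x, y, z boundary are removed), then
#' greedy selection in descending smoothed intensity with non-maximum
#' suppression at \code{minSeparation}. Ties are broken
#' lexicographically by (z, y, x), so ordering is deterministic. An
#' empty or constant grid yields an empty table.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param params a \code{\link{detectionParams}} list.
#' @return data.frame of candidates in rank order: \code{focus_id},
#'   \code{z}, \code{y}, \code{x} (1-based peak voxel), \code{peak_value}
#'   (raw intensity), \code{smoothed_value}, \code{rank}.
#' @examples
#' g <- renderFocus(VoxelGrid(ny = 40, nx = 40), c(9, 20, 20), 5000,
#'                  0.12, 0.35)
#' findFoci(g, detectionParams(maxSpots = 1))
#' @export
setMethod("findFoci", "VoxelGrid",
function(grid, params = detectionParams()) {
  v <- grid@values
  d <- dim(v)
  m <- params$edgeMargin
  empty <- data.frame(focus_id = integer(0), z = integer(0),
                      y = integer(0), x = integer(0),
                      peak_value = numeric(0),
                      smoothed_value = numeric(0), rank = integer(0))
  if (any(d <= 2L * m))
    kqConfigError("grid no larger than twice the edge margin on some axis")
  if (max(v) == min(v)) return(empty)   # constant grid: no spots
  sm <- smoothArray(v, params$smoothSigma)
  cand <- which(localMaxima3D(sm) & (sm > min(sm)))
  if (!is.null(params$threshold))
    cand <- cand[sm[cand] >= params$threshold]
  if (!length(cand)) return(empty)
  iy <- ((cand - 1L) %% d[1]) + 1L
  ix <- (((cand - 1L) %/% d[1]) %% d[2]) + 1L
  iz <- ((cand - 1L) %/% (d[1] * d[2])) + 1L
  inb <- iy > m & iy <= d[1] - m & ix > m & ix <= d[2] - m &
         iz > m & iz <= d[3] - m
  cand <- cand[inb]; iy <- iy[inb]; ix <- ix[inb]; iz <- iz[inb]
  if (!length(cand)) return(empty)
  o <- order(-sm[cand], iz, iy, ix)
  cand <- cand[o]; iy <- iy[o]; ix <- ix[o]; iz <- iz[o]
  accZ <- numeric(0); accY <- numeric(0); accX <- numeric(0)
  keep <- integer(0)
  minSep2 <- params$minSeparation^2
  for (i in seq_along(cand)) {
    if (length(accZ)) {
      d2 <- (accZ - iz[i])^2 + (accY - iy[i])^2 + (accX - ix[i])^2
      if (any(d2 < minSep2)) next
    }
    keep <- c(keep, i)
    accZ <- c(accZ, iz[i]); accY <- c(accY, iy[i]); accX <- c(accX, ix[i])
    if (length(keep) >= params$maxSpots) break
  }
  data.frame(focus_id = seq_along(keep),
             z = iz[keep], y = iy[keep], x = ix[keep],
             peak_value = v[cand[keep]],
             smoothed_value = sm[cand[keep]],
             rank = seq_along(keep))
})

#' Match detected candidates to ground truth
#'
#' One-to-one greedy matching by Euclidean distance in voxel units:
#' candidate-truth pairs are accepted in ascending distance while both
#' members are unused and the distance is within \code{tol}.
#'
#' @param candidates data.frame with \code{z}, \code{y}, \code{x}.
#' @param truth data.frame with \code{z}, \code{y}, \code{x} (one row per
#'   focus; sub-voxel positions allowed).
#' @param tol match tolerance in voxels (>= 1).
#' @return list with \code{recall} (matched/true), \code{precision}
#'   (matched/candidates) and \code{matches} (data.frame of candidate row,
#'   truth row, distance).
#' @export
matchToTruth <- function(candidates, truth, tol = 2) {
  if (tol < 1) kqConfigError("tol must be >= 1")
  nc <- nrow(candidates); nt <- nrow(truth)
  matches <- data.frame(candidate = integer(0), truth = integer(0),
                        distance = numeric(0))
  if (nc > 0L && nt > 0L) {
    dz <- outer(candidates$z, truth$z, "-")
    dy <- outer(candidates$y, truth$y, "-")
    dx <- outer(candidates$x, truth$x, "-")
    dist <- sqrt(dz^2 + dy^2 + dx^2)
    ord <- order(dist)
    usedC <- logical(nc); usedT <- logical(nt)
    for (k in ord) {
      if (dist[k] > tol) break
      i <- ((k - 1L) %% nc) + 1L
      j <- ((k - 1L) %/% nc) + 1L
      if (usedC[i] || usedT[j]) next
      usedC[i] <- TRUE; usedT[j] <- TRUE
      matches <- rbind(matches, data.frame(candidate = i, truth = j,
                                           distance = dist[k]))
    }
  }
  list(recall = if (nt > 0) nrow(matches) / nt else NA_real_,
       precision = if (nc > 0) nrow(matches) / nc else NA_real_,
       matches = matches)
}
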