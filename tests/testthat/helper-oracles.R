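# Independent reference computations ("oracles") used to validate the
# implementation. These deliberately use different algorithms from the
# package code paths: direct per-voxel summation instead of band-matrix
# convolution, midpoint quadrature instead of error functions, textbook
# formulas instead of stats::t.test.

# fine-grid midpoint quadrature of a 3D Gaussian over each voxel;
# center is (z, y, x) in 1-based voxel coordinates, sigmas in um
oracleRenderQuadrature <- function(ny, nx, nz, center, photons,
                                   sigmaXY, sigmaZ,
                                   dx = 0.205, dy = 0.205, dz = 0.4,
                                   nsub = 100L) {
  axisWeights <- function(nvox, c0, sigmaVox) {
    w <- numeric(nvox)
    h <- 1 / nsub
    for (i in seq_len(nvox)) {
      pts <- i - 0.5 + (seq_len(nsub) - 0.5) * h
      w[i] <- sum(exp(-(pts - c0)^2 / (2 * sigmaVox^2))) * h /
        (sigmaVox * sqrt(2 * pi))
    }
    w
  }
  wz <- axisWeights(nz, center[1], sigmaZ / dz)
  wy <- axisWeights(ny, center[2], sigmaXY / dy)
  wx <- axisWeights(nx, center[3], sigmaXY / dx)
  photons * (wy %o% wx %o% wz)
}

# direct shift-accumulate Gaussian smoothing with truncated,
# per-position renormalized kernel (3-sigma support)
oracleSmooth <- function(v, sigma) {
  if (sigma <= 0) return(v)
  r <- ceiling(3 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  d <- dim(v)
  smoothAxis <- function(a, axis) {
    num <- array(0, d)
    den <- array(0, d)
    n <- d[axis]
    for (o in seq(-r, r)) {
      srcIdx <- seq_len(n) + o
      ok <- srcIdx >= 1L & srcIdx <= n
      dst <- which(ok)
      src <- srcIdx[ok]
      w <- k[o + r + 1]
      if (axis == 1L) {
        num[dst, , ] <- num[dst, , ] + w * a[src, , ]
        den[dst, , ] <- den[dst, , ] + w
      } else if (axis == 2L) {
        num[, dst, ] <- num[, dst, ] + w * a[, src, ]
        den[, dst, ] <- den[, dst, ] + w
      } else {
        num[, , dst] <- num[, , dst] + w * a[, , src]
        den[, , dst] <- den[, , dst] + w
      }
    }
    num / den
  }
  for (axis in 1:3) v <- smoothAxis(v, axis)
  v
}

# exhaustive local-maximum scan + greedy descending-intensity selection;
# returns a data.frame(z, y, x) in selection order
oracleFindFoci <- function(v, sigma = 1, margin = 3L, minSep = 5,
                           maxSpots = Inf) {
  sm <- oracleSmooth(v, sigma)
  d <- dim(sm)
  hits <- NULL
  for (z in seq_len(d[3])) for (y in seq_len(d[1])) for (x in seq_len(d[2])) {
    val <- sm[y, x, z]
    if (val <= min(sm)) next
    nb <- sm[max(1, y - 1):min(d[1], y + 1),
             max(1, x - 1):min(d[2], x + 1),
             max(1, z - 1):min(d[3], z + 1)]
    if (val < max(nb)) next
    if (y <= margin || y > d[1] - margin) next
    if (x <= margin || x > d[2] - margin) next
    if (z <= margin || z > d[3] - margin) next
    hits <- rbind(hits, data.frame(z = z, y = y, x = x, val = val))
  }
  if (is.null(hits)) return(data.frame(z = integer(0), y = integer(0),
                                       x = integer(0)))
  hits <- hits[order(-hits$val, hits$z, hits$y, hits$x), ]
  acc <- NULL
  for (i in seq_len(nrow(hits))) {
    if (!is.null(acc)) {
      d2 <- (acc$z - hits$z[i])^2 + (acc$y - hits$y[i])^2 +
        (acc$x - hits$x[i])^2
      if (any(d2 < minSep^2)) next
    }
    acc <- rbind(acc, hits[i, c("z", "y", "x")])
    if (nrow(acc) >= maxSpots) break
  }
  acc
}

# textbook Welch (or pooled) two-sample t test, two-sided
oracleWelch <- function(x, y, equalVar = FALSE) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  if (equalVar) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  t <- (mean(x) - mean(y)) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# maximum-cardinality matching within tolerance by brute force over all
# candidate-to-truth assignments (small instances only)
oracleMaxMatching <- function(candidates, truth, tol) {
  nc <- nrow(candidates); nt <- nrow(truth)
  if (nc == 0L || nt == 0L) return(0L)
  dist <- sqrt(outer(candidates$z, truth$z, "-")^2 +
               outer(candidates$y, truth$y, "-")^2 +
               outer(candidates$x, truth$x, "-")^2)
  feasible <- dist <= tol
  best <- 0L
  recurse <- function(ci, usedT, count) {
    if (count + (nc - ci + 1L) <= best) return()
    if (ci > nc) { best <<- max(best, count); return() }
    for (tj in seq_len(nt))
      if (!usedT[tj] && feasible[ci, tj]) {
        usedT[tj] <- TRUE
        recurse(ci + 1L, usedT, count + 1L)
        usedT[tj] <- FALSE
      }
    recurse(ci + 1L, usedT, count)
  }
  recurse(1L, logical(nt), 0L)
  best
}

# noiseless optics for deterministic fixtures
noiselessOptics <- function(bgLevel = 100)
  OpticsModel(bgLevel = bgLevel, readNoiseSD = 0, photonNoise = FALSE)
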