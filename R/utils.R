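# classed conditions so callers (and the CLI) can distinguish
# configuration problems from data problems
kqStop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "kq_error"),
                      call = call))
}

kqConfigError <- function(msg) kqStop(msg, "kq_config_error")
kqDataError <- function(msg) kqStop(msg, "kq_data_error")
kqOutOfBounds <- function(msg) kqStop(msg, c("kq_out_of_bounds", "kq_data_error"))

# linear index into a (ny, nx, nz) array from (z, y, x) rows (1-based)
voxelIndex <- function(dim, zyx) {
  zyx <- matrix(as.integer(zyx), ncol = 3L)
  ny <- dim[1L]; nx <- dim[2L]
  zyx[, 2L] + (zyx[, 3L] - 1L) * ny + (zyx[, 1L] - 1L) * ny * nx
}

# lognormal parameterized by mean and coefficient of variation;
# cv = 0 degenerates to the constant `mean`
rlnormMeanCV <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
}

fwhmFactor <- function() 2 * sqrt(2 * log(2))
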