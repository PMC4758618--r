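#' Write a VoxelGrid as a multi-page TIFF
#'
#' One 16-bit little-endian page per z-slice, z-ascending. Integer
#' intensities round-trip exactly through \code{\link{readStack}}.
#'
#' @param grid a \linkS4class{VoxelGrid} with values in
#'   \code{[0, 2^bitDepth - 1]}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeStack <- function(grid, path) {
  v <- grid@values
  top <- 2^16 - 1
  if (any(v > top))
    kqDataError("intensities exceed the 16-bit ceiling; quantize first")
  pages <- lapply(seq_len(dim(v)[3]), function(z) v[, , z] / top)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF as a VoxelGrid
#'
#' @param path TIFF file (one page per z-slice, z-ascending).
#' @param dx,dy,dz physical voxel dimensions, um.
#' @param channel fluorophore label.
#' @return a \linkS4class{VoxelGrid} of integer counts.
#' @export
readStack <- function(path, dx = 0.205, dy = 0.205, dz = 0.4,
                      channel = "GFP") {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  v <- array(0, dim = c(d[1], d[2], length(pages)))
  for (z in seq_along(pages)) v[, , z] <- pages[[z]]
  VoxelGrid(values = v, dx = dx, dy = dy, dz = dz, channel = channel)
}

#' Run configuration
#'
#' A fully serializable description of one pipeline run; written next to
#' the outputs it produced so any run can be reproduced bit-exactly from
#' its own directory.
#'
#' @param scenario preset name.
#' @param seed integer seed (mandatory).
#' @param nFoci foci per arm; \code{NULL} for the preset default.
#' @param optics named list of \code{\link{OpticsModel}} overrides.
#' @param geometry named list of \code{\link{roiGeometry}} overrides.
#' @param detection named list of \code{\link{detectionParams}} overrides.
#' @param outDir output directory, or \code{NULL} for in-memory results.
#' @return a \code{RunConfig} list.
#' @export
runConfig <- function(scenario, seed, nFoci = NULL, optics = list(),
                      geometry = list(), detection = list(),
                      outDir = NULL) {
  if (missing(seed) || is.null(seed))
    kqConfigError("a seed is mandatory")
  structure(list(scenario = scenario, seed = as.integer(seed),
                 nFoci = nFoci, optics = optics, geometry = geometry,
                 detection = detection, outDir = outDir),
            class = "RunConfig")
}

#' @rdname runConfig
#' @param config a \code{RunConfig}.
#' @param path YAML file path.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  runConfig(scenario = cfg$scenario, seed = cfg$seed, nFoci = cfg$nFoci,
            optics = cfg$optics %||% list(),
            geometry = cfg$geometry %||% list(),
            detection = cfg$detection %||% list(),
            outDir = cfg$outDir)
}
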