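#' Construct a GenotypeScenario
#'
#' @param name preset label.
#' @param arms data.frame, one row per genotype arm. Recognised columns
#'   (all optional except \code{genotype}): \code{intensityFold},
#'   \code{cv}, \code{fwhmFold}, \code{fwhmCV}, \code{peakHeightFold},
#'   \code{phCV}, and per-channel expression fractions
#'   \code{frac_<channel>}. Missing folds default to 1, missing CVs to 0,
#'   and a single-channel scenario defaults to fraction 1.
#' @param mode \code{"intensity"} or \code{"morphometry"}; see
#'   \linkS4class{GenotypeScenario}.
#' @param channels fluorophore labels (length 2 for dual-tag scenarios).
#' @param nFoci default foci per arm.
#' @param baselinePhotons integrated photons of the mean control focus.
#' @param source provenance note for the planted effect sizes.
#' @return a \linkS4class{GenotypeScenario}.
#' @examples
#' GenotypeScenario("demo",
#'   arms = data.frame(genotype = c("wt", "mut"),
#'                     intensityFold = c(1, 1.5), cv = c(0.2, 0.25)))
#' @export
GenotypeScenario <- function(name, arms, mode = "intensity",
                             channels = "GFP", nFoci = 150L,
                             baselinePhotons = 5000,
                             source = "user-defined") {
  fill <- function(col, default) {
    if (is.null(arms[[col]])) arms[[col]] <<- default
  }
  fill("intensityFold", 1)
  fill("cv", 0)
  fill("fwhmFold", 1)
  fill("fwhmCV", 0)
  fill("peakHeightFold", 1)
  fill("phCV", 0)
  for (ch in channels) {
    col <- paste0("frac_", ch)
    if (is.null(arms[[col]]))
      arms[[col]] <- if (length(channels) == 1L) 1 else NA_real_
  }
  methods::new("GenotypeScenario", name = name, mode = mode,
               arms = arms, channels = channels,
               nFoci = as.integer(nFoci),
               baselinePhotons = baselinePhotons, source = source)
}

scenarioFile <- function() {
  system.file("extdata", "scenarios.yaml", package = "kinetoquant",
              mustWork = TRUE)
}

parsePreset <- function(name, spec, defaults) {
  rows <- lapply(spec$arms, function(a) {
    data.frame(
      genotype = a$genotype,
      intensityFold = a$intensity_fold %||% 1,
      cv = a$cv %||% 0,
      fwhmFold = a$fwhm_fold %||% 1,
      fwhmCV = a$fwhm_cv %||% 0,
      peakHeightFold = a$peak_height_fold %||% 1,
      phCV = a$ph_cv %||% 0)
  })
  arms <- do.call(rbind, rows)
  for (ch in spec$channels) {
    col <- paste0("frac_", ch)
    arms[[col]] <- vapply(spec$arms, function(a)
      a[[col]] %||% (if (length(spec$channels) == 1L) 1 else NA_real_),
      numeric(1))
  }
  GenotypeScenario(
    name = name, arms = arms, mode = spec$mode,
    channels = unlist(spec$channels),
    nFoci = defaults$n_foci %||% 150L,
    baselinePhotons = defaults$baseline_photons %||% 5000,
    source = spec$source)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scenario preset library
#'
#' Loads the packaged, versioned library of simulation presets. Each
#' preset plants the effect sizes of one published comparison (fold
#' changes and population CVs) as simulation ground truth; its
#' \code{source} slot documents the panel it encodes.
#'
#' @return named list of \linkS4class{GenotypeScenario} objects.
#' @examples
#' names(scenarioLibrary())
#' scenarioPreset("fig2a_psh1del")
#' @export
scenarioLibrary <- function() {
  cfg <- yaml::read_yaml(scenarioFile())
  out <- lapply(names(cfg$presets), function(nm)
    parsePreset(nm, cfg$presets[[nm]], cfg$defaults))
  names(out) <- names(cfg$presets)
  out
}

#' @rdname scenarioLibrary
#' @param name preset name.
#' @export
scenarioPreset <- function(name) {
  lib <- scenarioLibrary()
  if (!name %in% names(lib))
    kqConfigError(sprintf(
      "unknown scenario preset '%s'; available: %s",
      name, paste(names(lib), collapse = ", ")))
  lib[[name]]
}
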