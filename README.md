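# kinetoquant

Quantitation of kinetochore fluorescence foci in 3D widefield z-stacks
of budding yeast — and a ground-truth simulator to validate every stage
of the measurement.

## The problem

Kinetochore proteins tagged with GFP/YFP/CFP appear as diffraction-
limited foci (one or two per post-anaphase cell). Comparing protein
levels between genotypes — e.g. wild type versus deletions of the
ubiquitin ligases Psh1 and Ubr2, which restrict Cse4 and Dsn1 levels —
requires per-focus measurements that are robust to diffuse cellular
background and comparable across strains:

* **Intensity**: mean intensity in a fixed kinetochore box
  (81 voxels = 1.36 µm³ at 0.205 × 0.205 × 0.4 µm voxels) minus the
  mean of a surrounding 1399-voxel background shell (23.52 µm³)
  separated from the box by a 2-voxel gap:
  `corrected = mean(box) − mean(shell)`.
* **Size and brightness of the profile**: a 5 × 5 px patch at the peak
  slice, local background subtracted, row/column sums each fitted with
  `y = a + (b − a)·exp(−(x − c)²/(2d²))`; per-focus
  FWHM = 2√(2 ln 2)·d and peak height (b − a) averaged over the two
  axes.
* **Population comparison**: every value divided by the mean of the
  control population (so controls read 1.00), summarized as mean ± s.d.
  and compared with a two-sided Welch t test (`***` iff p < 0.0001).

No raw micrographs exist to rerun, so the package ships a seeded
simulator (`simulateField()`, presets in `scenarioLibrary()`) that
plants published effect sizes — fold changes and population CVs — as
ground truth, and the test suite validates the pipeline by recovering
them.

## Worked example

```r
library(kinetoquant)

## the published ROI geometry, exactly
g <- VoxelGrid(ny = 48, nx = 48)          # 0.205 um pixels, 17 x 0.4 um slices
roiVolume(buildROI(c(9, 24, 24), g))
#>      kin       bg
#>  1.36161 23.51719

## simulate + detect + quantify a two-arm comparison (150 foci/arm)
run <- runScenario("fig2a_psh1del", seed = 42, nFoci = 150)
run
#> ScenarioRun 'fig2a_psh1del' (seed 42)
#>   GFP wild_type                1.00±0.24
#>   GFP psh1del                  1.86±0.61***

run$comparisons[["GFP:psh1del"]]
#> t = 16.15, df = 194.7, p = 8.51e-38

mindCopies(6.5, 1.30)   # complexes implied by a 30% rise on a 6.5 baseline
#> [1] 2
```

The preset plants a 1.83-fold brighter mutant arm (CVs 0.25/0.31); the
pipeline recovers 1.86 ± the sampling error of a 150-focus lognormal
population, and the Welch test flags the difference at the p < 0.0001
convention. Scenario presets are read from a versioned config
(`inst/extdata/scenarios.yaml`); `runScenario(..., outDir = ...)`
writes the stacks (multi-page 16-bit TIFF), truth/measurement CSVs, a
legend-style report, the exact run config and a log, and re-running a
config reproduces all outputs byte-identically. A thin CLI over these
functions is installed at `inst/cli/kinetoquant.R`
(`simulate`, `run-scenario`, `presets`).

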