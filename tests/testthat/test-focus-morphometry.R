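test_that("patch extraction subtracts the local background and sums margins", {
  # uniform slice: all zero after local background subtraction
  u <- VoxelGrid(values = array(55, c(20, 20, 9)))
  p <- extractPatch(u, c(5, 10, 10))
  expect_true(all(p$patch == 0))
  # marginal totals agree for any patch
  set.seed(4)
  g <- VoxelGrid(values = array(rpois(20 * 20 * 9, 80), c(20, 20, 9)))
  p <- extractPatch(g, c(5, 10, 10))
  expect_equal(sum(p$rowSums), sum(p$colSums))
  expect_equal(sum(p$rowSums), sum(p$patch))
  expect_error(extractPatch(g, c(5, 2, 10)), class = "kq_out_of_bounds")
  # planted noiseless focus: margins equal brute-force row/column sums
  g <- renderFocus(VoxelGrid(ny = 20, nx = 20, nz = 9), c(5, 10, 10),
                   4000, 0.12, 0.35)
  g@values <- g@values + 100
  p <- extractPatch(g, c(5, 10, 10))
  v <- intensityValues(g)
  win <- v[8:12, 8:12, 5]
  bg <- median(c(win[1, ], win[5, ], win[2:4, 1], win[2:4, 5]))
  rows <- cols <- numeric(5)
  for (i in 1:5) for (j in 1:5) {
    rows[i] <- rows[i] + win[i, j] - bg
    cols[j] <- cols[j] + win[i, j] - bg
  }
  expect_equal(p$rowSums, rows, tolerance = 1e-12)
  expect_equal(p$colSums, cols, tolerance = 1e-12)
})

test_that("the 1D Gaussian fit recovers exact and scaled profiles", {
  x <- 1:5
  y <- 0 + (100 - 0) * exp(-(x - 2)^2 / (2 * 1^2))
  f <- fitGaussian1D(y)
  expect_true(f$converged)
  expect_equal(f$a, 0, tolerance = 1e-6)
  expect_equal(f$b, 100, tolerance = 1e-6)
  expect_equal(f$c, 2, tolerance = 1e-6)
  expect_equal(f$d, 1, tolerance = 1e-6)
  # model evaluated at the centre equals b by construction
  expect_equal(f$a + (f$b - f$a) * exp(0), f$b)
  # scaling the profile scales the height, not the width
  fk <- fitGaussian1D(3.7 * y)
  expect_equal(fk$height, 3.7 * f$height, tolerance = 1e-6)
  expect_equal(fk$d, f$d, tolerance = 1e-6)
  # flat profile: flagged, not fabricated
  expect_false(fitGaussian1D(rep(5, 5))$converged)
})

test_that("noiseless sampled Gaussians give FWHM within 1% across widths", {
  x <- 1:5
  for (sigma in c(0.5, 0.8, 1.0, 1.5, 2.0)) {
    y <- 20 + 150 * exp(-(x - 3)^2 / (2 * sigma^2))
    f <- fitGaussian1D(y)
    expect_true(f$converged)
    expect_lt(abs(f$fwhm - 2 * sqrt(2 * log(2)) * sigma) /
                (2 * sqrt(2 * log(2)) * sigma), 0.01)
  }
})

test_that("mean fitted width is within 3% of truth under 2% read noise", {
  set.seed(77)
  x <- 1:5
  truth <- 1.2
  d <- replicate(200, {
    y <- 10 + 500 * exp(-(x - 3)^2 / (2 * truth^2)) + rnorm(5, sd = 10)
    fitGaussian1D(y)$d
  })
  d <- d[!is.na(d)]
  expect_lt(abs(mean(d) - truth) / truth, 0.03)
})

test_that("focusSize averages the per-axis FWHM and heights", {
  mk <- function(d) fitGaussian1D(100 * exp(-((1:5) - 3)^2 / (2 * d^2)))
  f1 <- mk(1)
  expect_equal(focusSize(f1, f1)$fwhmPx, 2.3548, tolerance = 1e-4)
  f2 <- mk(2)
  expect_equal(focusSize(f1, f2)$fwhmPx, 3.5322, tolerance = 1e-4)
  expect_equal(focusSize(f1, f1, dx = 0.205)$fwhmUm, 2.3548 * 0.205,
               tolerance = 1e-4)
  bad <- fitGaussian1D(rep(1, 5))
  expect_false(focusSize(f1, bad)$converged)
})

test_that("fit failures are rare in default stacks and never silently dropped", {
  sim <- simulateField(scenarioPreset("wt_reference"), seed = 13, nFoci = 60)
  arm <- sim$arms$wild_type
  hits <- findFoci(arm$grids$GFP, detectionParams(maxSpots = 60))
  sz <- measureFocusSizes(arm$grids$GFP, hits)
  expect_equal(nrow(sz), nrow(hits))      # failures retained as rows
  expect_lt(mean(!sz$converged), 0.02)
})

test_that("morphometry recovers the planted size population (generator oracle)", {
  run <- runScenario("fig3c_psh1del", seed = 11, nFoci = 100)
  tr <- run$simulation$truth
  sz <- run$sizes
  # planted sample folds from the ground-truth table
  plantedH <- mean(tr$height_au[tr$genotype == "psh1del"]) /
    mean(tr$height_au[tr$genotype == "wild_type"])
  plantedW <- mean(tr$sigma_xy_um[tr$genotype == "psh1del"]) /
    mean(tr$sigma_xy_um[tr$genotype == "wild_type"])
  recH <- mean(sz$height_normalized[sz$genotype == "psh1del"], na.rm = TRUE)
  recW <- mean(sz$fwhm_normalized[sz$genotype == "psh1del"], na.rm = TRUE)
  expect_lt(abs(recH - plantedH) / plantedH, 0.05)
  expect_lt(abs(recW - plantedW) / plantedW, 0.05)
})
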