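test_that("rendering conserves photons and handles degenerate inputs", {
  g <- VoxelGrid(ny = 40, nx = 40, nz = 17)
  # zero photons: grid unchanged
  expect_identical(intensityValues(renderFocus(g, c(9, 20, 20), 0, 0.12, 0.35)),
                   intensityValues(g))
  # invalid parameters
  expect_error(renderFocus(g, c(9, 20, 20), -1, 0.12, 0.35),
               class = "kq_config_error")
  expect_error(renderFocus(g, c(9, 20, 20), 100, 0, 0.35),
               class = "kq_config_error")
  expect_error(renderFocus(g, c(50, 20, 20), 100, 0.12, 0.35),
               class = "kq_out_of_bounds")
  # focus >= 5 sigma from every edge: total mass = photons within 0.1%
  g2 <- renderFocus(g, c(8.7, 19.3, 21.2), 5000, 0.12, 0.35)
  expect_lt(abs(sum(intensityValues(g2)) - 5000) / 5000, 1e-3)
})

test_that("voxel values match fine-grid midpoint quadrature of the Gaussian", {
  # 7 x 7 x 5 grid, sigma_xy = 1 px, sigma_z = 1 slice, centered focus
  g <- VoxelGrid(values = array(0, c(7, 7, 5)))
  g <- renderFocus(g, c(3, 4, 4), 1000, sigmaXY = 0.205, sigmaZ = 0.4)
  want <- oracleRenderQuadrature(7, 7, 5, c(3, 4, 4), 1000,
                                 sigmaXY = 0.205, sigmaZ = 0.4)
  # bound reflects the oracle's own midpoint discretization error at
  # 100x per-axis oversampling (~h^2/24 * f'' ~ 1e-5 of the peak)
  expect_lt(max(abs(intensityValues(g) - want)) / max(want), 1e-4)
  # off-center, anisotropic case near an edge: in-grid mass agrees too
  g <- VoxelGrid(values = array(0, c(7, 7, 5)))
  g <- renderFocus(g, c(2, 2.4, 5.8), 1000, sigmaXY = 0.3, sigmaZ = 0.5)
  want <- oracleRenderQuadrature(7, 7, 5, c(2, 2.4, 5.8), 1000,
                                 sigmaXY = 0.3, sigmaZ = 0.5)
  expect_lt(max(abs(intensityValues(g) - want)) / max(want), 1e-4)
  expect_lt(abs(sum(intensityValues(g)) - sum(want)) / sum(want), 1e-4)
})

test_that("camera model is unbiased with the expected variance", {
  opt <- OpticsModel(readNoiseSD = 2)
  g <- VoxelGrid(values = array(400, c(4, 4, 2)))
  # rounding only when noise is fully disabled
  gq <- applyNoise(VoxelGrid(values = array(123.4, c(3, 3, 2))),
                   OpticsModel(readNoiseSD = 0, photonNoise = FALSE))
  expect_true(all(intensityValues(gq) == 123))
  # quantization invariants: integers within the bit-depth ceiling
  gn <- applyNoise(g, opt, seed = 11)
  v <- intensityValues(gn)
  expect_true(all(v == round(v)))
  expect_true(all(v >= 0 & v <= 2^16 - 1))
  hot <- VoxelGrid(values = array(300, c(3, 3, 1)), bitDepth = 8L)
  expect_true(all(intensityValues(
    applyNoise(hot, OpticsModel(photonNoise = FALSE, readNoiseSD = 0))) == 255))
  # mean of repeated draws within 3 s.e. of the constant,
  # variance ~ v + read_noise^2 (Monte Carlo over 1e4 voxel draws)
  set.seed(42)
  draws <- replicate(2000, intensityValues(applyNoise(g, opt)))
  nTot <- length(draws)
  se <- sqrt((400 + 4) / nTot)
  expect_lt(abs(mean(draws) - 400), 3 * se)
  vse <- (400 + 4) * sqrt(2 / (nTot - 1))
  expect_lt(abs(var(as.numeric(draws)) - 404), 3 * vse)
})

test_that("simulateField is seed-deterministic and matches its population model", {
  sc <- scenarioPreset("fig2a_psh1del")
  a <- simulateField(sc, seed = 5, nFoci = 6)
  b <- simulateField(sc, seed = 5, nFoci = 6)
  expect_identical(lapply(a$arms, function(x) lapply(x$grids, intensityValues)),
                   lapply(b$arms, function(x) lapply(x$grids, intensityValues)))
  expect_identical(a$truth, b$truth)
  # degenerate population: fold 1, cv 0, no noise -> identical foci
  deg <- GenotypeScenario("deg",
    arms = data.frame(genotype = "wt", intensityFold = 1, cv = 0))
  sim <- simulateField(deg, seed = 3, nFoci = 6,
                       optics = noiselessOptics(bgLevel = 0))
  expect_true(all(sim$truth$photons == sim$truth$photons[1]))
  # planted brightness distribution: sample mean within 3 s.e. of the
  # configured lognormal mean, cross-checked by direct sampling
  sim <- simulateField(scenarioPreset("wt_reference"), seed = 9, nFoci = 600)
  ph <- sim$truth$photons
  se <- 5000 * 0.25 / sqrt(600)
  expect_lt(abs(mean(ph) - 5000), 3 * se)
  set.seed(1234)
  sdlog <- sqrt(log1p(0.25^2))
  oracle <- rlnorm(20000, log(5000) - sdlog^2 / 2, sdlog)
  expect_lt(abs(mean(ph) - mean(oracle)),
            3 * sqrt(se^2 + (5000 * 0.25)^2 / 20000))
})

test_that("scenario presets carry the published effect sizes", {
  lib <- scenarioLibrary()
  f2a <- lib$fig2a_psh1del
  expect_equal(f2a@arms$intensityFold[f2a@arms$genotype == "psh1del"], 1.83)
  expect_equal(f2a@arms$cv[f2a@arms$genotype == "wild_type"], 0.25)
  expect_true(all(lib$wt_reference@arms$intensityFold == 1))
  dt <- lib$fig1b_dualtag
  dual <- dt@arms[dt@arms$genotype == "dual_tag", ]
  expect_equal(dual$frac_YFP, 0.5)
  expect_equal(dual$frac_CFP, 0.5)
  f3c <- lib$fig3c_psh1del
  expect_equal(f3c@arms$peakHeightFold[2], 1.71)
  expect_equal(f3c@arms$fwhmFold[2], 1.16)
  f5b <- lib$fig5b_dsn1dd
  expect_equal(f5b@arms$intensityFold[f5b@arms$genotype == "psh1del_ubr2del"],
               1.48)
  expect_error(scenarioPreset("no_such_panel"), class = "kq_config_error")
})

test_that("layout rejects configurations whose ROIs cannot fit", {
  expect_error(kinetoquant:::fieldLayout(10, margin = 8),
               class = "kq_config_error")
  expect_error(kinetoquant:::fieldLayout(10, cellSpacing = 18),
               class = "kq_config_error")
})
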