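refGrid <- function(ny = 48, nx = 48, nz = 17) VoxelGrid(ny = ny, nx = nx, nz = nz)

test_that("default ROI geometry reproduces the published volumes", {
  roi <- buildROI(c(9, 24, 24), refGrid())
  vol <- roiVolume(roi)
  expect_equal(round(vol[["kin"]], 4), 1.3616)
  expect_equal(nrow(roi@kinVoxels), 81L)
  expect_lt(abs(vol[["bg"]] - 23.51) / 23.51, 1e-3)
  expect_equal(nrow(roi@bgVoxels), 1399L)
  # single-voxel unit case
  g1 <- roiGeometry(boxDim = c(1, 1, 1), gap = 2, bgVolume = 23.51)
  expect_equal(round(prod(voxelDims(refGrid())), 5), 0.01681)
  # independent recount: members x voxel volume
  expect_equal(vol[["bg"]], nrow(roi@bgVoxels) * 0.205 * 0.205 * 0.4)
  # 9 x 9 x 1 factorization gives the same 81-voxel box volume
  alt <- buildROI(c(9, 24, 24), refGrid(),
                  roiGeometry(boxDim = c(1, 9, 9)))
  expect_equal(roiVolume(alt)[["kin"]], vol[["kin"]])
})

test_that("degenerate gap-0 geometry yields the immediate equal-count shell", {
  kinVol <- 81 * 0.205 * 0.205 * 0.4
  roi <- buildROI(c(9, 24, 24), refGrid(),
                  roiGeometry(gap = 0, bgVolume = kinVol))
  expect_equal(nrow(roi@bgVoxels), 81L)
  # every shell voxel touches the box: within one voxel of it laterally
  # (in um terms, nearest-first selection keeps it adjacent)
  off <- sweep(roi@bgVoxels, 2L, roi@center, "-")
  d <- sqrt((off[, 1] * 0.4)^2 + (off[, 2] * 0.205)^2 + (off[, 3] * 0.205)^2)
  expect_lt(max(d), 1.0)
  expect_error(buildROI(c(9, 4, 24), refGrid()), class = "kq_out_of_bounds")
})

test_that("corrected intensity is offset-invariant and scale-equivariant", {
  set.seed(8)
  g <- renderFocus(refGrid(), c(9, 24, 24), 4000, 0.12, 0.35)
  g@values <- g@values + 100 + array(rnorm(length(g@values), sd = 3)^2,
                                     dim = dim(g@values))
  roi <- buildROI(c(9, 24, 24), g)
  base <- measureFocus(g, roi)$corrected
  expect_equal(base, measureFocus(g, roi)$meanKin - measureFocus(g, roi)$meanBg)
  gplus <- g; gplus@values <- g@values + 57.3
  expect_lt(abs(measureFocus(gplus, roi)$corrected - base) / abs(base), 1e-9)
  gscale <- g; gscale@values <- g@values * 3.5
  expect_equal(measureFocus(gscale, roi)$corrected, 3.5 * base,
               tolerance = 1e-12)
  # uniform grid: corrected exactly 0
  u <- VoxelGrid(values = array(42, c(48, 48, 17)))
  expect_equal(measureFocus(u, buildROI(c(9, 24, 24), u))$corrected, 0)
})

test_that("measurement equals direct summation over the stored voxel sets", {
  g <- renderFocus(refGrid(), c(9, 24, 24), 4000, 0.12, 0.35)
  g@values <- g@values + 100
  roi <- buildROI(c(9, 24, 24), g)
  v <- intensityValues(g)
  sumOver <- function(m) {
    tot <- 0
    for (i in seq_len(nrow(m))) tot <- tot + v[m[i, 2], m[i, 3], m[i, 1]]
    tot
  }
  want <- sumOver(roi@kinVoxels) / 81 - sumOver(roi@bgVoxels) / 1399
  expect_equal(measureFocus(g, roi)$corrected, want, tolerance = 1e-12)
})

test_that("population normalization has mean 1 on its own reference", {
  set.seed(31)
  ref <- rlnorm(100, 5, 0.3)
  expect_equal(mean(normalizePopulation(ref, ref)), 1)
  vals <- rlnorm(50, 5.5, 0.3)
  expect_equal(normalizePopulation(2 * vals, ref),
               2 * normalizePopulation(vals, ref))
  expect_error(normalizePopulation(vals, c(-1, 1)), class = "kq_data_error")
  expect_error(normalizePopulation(vals, numeric(0)), class = "kq_data_error")
})

test_that("recovered intensity folds are unbiased over replicates", {
  # planted fold vs pipeline estimate, averaged over seeded replicates:
  # agreement within 2 Monte-Carlo s.e.
  folds <- vapply(1:20, function(s) {
    run <- runScenario("fig2a_psh1del", seed = 200 + s, nFoci = 40)
    sm <- run$summaries
    sm$mean[sm$genotype == "psh1del"]
  }, numeric(1))
  se <- sd(folds) / sqrt(length(folds))
  expect_lt(abs(mean(folds) - 1.83), 2 * se + 1e-9)
})

test_that("dual-tag contributions recover planted channel fractions", {
  run <- runScenario("fig1b_dualtag", seed = 1, nFoci = 60)
  m <- run$measurements
  pick <- function(gt, ch) m$corrected[m$genotype == gt & m$channel == ch]
  dt <- dualTagContributions(pick("dual_tag", "YFP"), pick("dual_tag", "CFP"),
                             pick("haploid_yfp", "YFP"),
                             pick("haploid_cfp", "CFP"))
  expect_true(dt$means[["yfp"]] > 0.4 && dt$means[["yfp"]] < 0.6)
  expect_true(dt$means[["cfp"]] > 0.4 && dt$means[["cfp"]] < 0.6)
  expect_lt(abs(dt$means[["total"]] - 1), 0.05)
  # single-tag strain against its own reference: ~1 / ~0 / total ~1
  st <- dualTagContributions(pick("haploid_yfp", "YFP"),
                             pick("haploid_yfp", "CFP"),
                             pick("haploid_yfp", "YFP"),
                             pick("haploid_cfp", "CFP"))
  expect_lt(abs(st$means[["yfp"]] - 1), 1e-9)
  expect_lt(abs(st$means[["cfp"]]), 0.05)
  # skewed competition: planted 0.7/0.3 recovered within 5%
  arms <- data.frame(
    genotype = c("haploid_yfp", "haploid_cfp", "skewed"),
    intensityFold = 1, cv = 0.2,
    frac_YFP = c(1, 0, 0.7), frac_CFP = c(0, 1, 0.3))
  sk <- GenotypeScenario("skewed_competition", arms, channels = c("YFP", "CFP"))
  run2 <- runScenario(sk, seed = 2, nFoci = 60)
  m <- run2$measurements
  dt2 <- dualTagContributions(pick("skewed", "YFP"), pick("skewed", "CFP"),
                              pick("haploid_yfp", "YFP"),
                              pick("haploid_cfp", "CFP"))
  # generator oracle: planted sample contributions from the truth table
  tr <- run2$simulation$truth
  planted <- function(gt, ch, refGt)
    mean(tr$photons[tr$genotype == gt & tr$channel == ch]) /
      mean(tr$photons[tr$genotype == refGt & tr$channel == ch])
  expect_lt(abs(dt2$means[["yfp"]] - planted("skewed", "YFP", "haploid_yfp")) /
              0.7, 0.05)
  expect_lt(abs(dt2$means[["cfp"]] - planted("skewed", "CFP", "haploid_cfp")) /
              0.3, 0.05)
})

test_that("moving the background shell further out barely shifts the result", {
  fold <- function(gap) {
    run <- runScenario("fig2a_psh1del", seed = 7, nFoci = 60,
                       geometry = roiGeometry(gap = gap))
    sm <- run$summaries
    sm$mean[sm$genotype == "psh1del"]
  }
  expect_lt(abs(fold(4) / fold(2) - 1), 0.02)
})
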