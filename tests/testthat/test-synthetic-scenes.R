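# Generator behaviour: forward model, determinism, mass conservation,
# bleaching, and the screen dataset.

test_that("zero signal and zero noise render the bare camera offset", {
  op <- OpticsModel(smallDim, vignetting = 0.3, readNoiseSd = 0,
                    autofluorescenceNMEquiv = 0)
  sc <- makeCalibrationScene(smallGeometry(), op, bathNM = 0,
                             trueConc = c(P0 = 0), seed = 1)
  expect_true(all(sceneImage(sc) == op@cameraOffset))
})

test_that("noise-free rendering is linear in concentration", {
  op <- OpticsModel(smallDim, vignetting = 0, readNoiseSd = 0,
                    autofluorescenceNMEquiv = 0)
  sc <- makeCalibrationScene(smallGeometry(), op, 300, c(P0 = 150),
                             seed = 1, noise = FALSE)
  img <- sceneImage(sc) - op@cameraOffset
  msk <- sceneMasks(sc)
  expect_equal(mean(img[embryoMask(msk)]) / mean(img[bathMask(msk)]), 0.5,
               tolerance = 1e-12)
  # doubling every true concentration doubles the offset-corrected image
  sc2 <- makeCalibrationScene(smallGeometry(), op, 600, c(P0 = 300),
                              seed = 1, noise = FALSE)
  expect_equal(sceneImage(sc2) - op@cameraOffset, 2 * img, tolerance = 1e-12)
})

test_that("noisy bath counts match Poisson moments", {
  op <- OpticsModel(smallDim, vignetting = 0, readNoiseSd = 5,
                    autofluorescenceNMEquiv = 0)
  sc <- makeCalibrationScene(smallGeometry(), op, 300, c(P0 = 0), seed = 42)
  bath <- sceneImage(sc)[bathMask(sceneMasks(sc))]
  expected <- op@photonsPerNM * 300 + op@cameraOffset
  se <- sqrt(op@photonsPerNM * 300 + op@readNoiseSd^2 + 1 / 12) / sqrt(length(bath))
  expect_lt(abs(mean(bath) - expected), 3 * se)
})

test_that("identical parameters and seed give bit-identical scenes", {
  op <- smallOptics()
  a <- makeCalibrationScene(smallGeometry(), op, 300, c(P0 = 92), seed = 7)
  b <- makeCalibrationScene(smallGeometry(), op, 300, c(P0 = 92), seed = 7)
  d <- makeCalibrationScene(smallGeometry(), op, 300, c(P0 = 92), seed = 8)
  expect_identical(sceneImage(a), sceneImage(b))
  expect_false(identical(sceneImage(a), sceneImage(d)))
})

test_that("unknown compartment names are rejected by name", {
  expect_error(
    makeCalibrationScene(smallGeometry(), smallOptics(), 300,
                         c(P7 = 10), seed = 1),
    "P7")
})

test_that("amounts are conserved across divisions without synthesis or decay", {
  for (f in c(0.3, 0.5, 0.58, 0.8)) {
    par <- LineageParams(92, c(P0 = 26.88, AB = 14.7, P1 = 10.1,
                               ABa = 7.35, ABp = 7.35, EMS = 6.1, P2 = 4.2),
      divisions = data.frame(time_s = c(60, 150), mother = c("P0", "P1"),
                             germ = c("P1", "P2"), soma = c("AB", "EMS"),
                             f = c(f, f), stringsAsFactors = FALSE))
    tl <- standardTimelapse(seed = 1, intervalS = 30, durationS = 240,
                            params = par, render = FALSE)
    tr <- truthTraces(tl)
    tot <- tapply(tr$mat_amount + tr$syn_amount, tr$time_s, sum)
    expect_equal(unname(diff(range(tot))), 0, tolerance = 1e-9)
    # traces constant between events
    p0 <- tr$conc_visible_nM[tr$cell == "P0"]
    expect_true(all(abs(p0 - p0[1]) < 1e-12))
  }
})

test_that("division partitions amount by f and volume sets concentration", {
  par <- LineageParams(92, c(P0 = 26.88, AB = 14.7, P1 = 10.1),
    divisions = data.frame(time_s = 60, mother = "P0", germ = "P1",
                           soma = "AB", f = 0.58, stringsAsFactors = FALSE))
  geos <- list(smallGeometry("1cell", nuclei = FALSE),
               smallGeometry("2cell", nuclei = FALSE))
  tl <- makeLineageTimelapse(geos, par, smallOptics(), 30, 120,
                             seed = 1, render = FALSE)
  tr <- truthTraces(tl)
  last <- tr[tr$time_s == 120, ]
  ratio <- last$conc_visible_nM[last$cell == "P1"] /
    last$conc_visible_nM[last$cell == "AB"]
  # hand mass balance: (0.58/10.1) / (0.42/14.7)
  expect_equal(ratio, (0.58 / 10.1) / (0.42 / 14.7), tolerance = 1e-12)
})

test_that("a bleach scales the fluorescent amount inside the circle only", {
  geos <- list(smallGeometry("2cell", nuclei = FALSE))
  geo <- geos[[1]]
  # circle centred deep in the posterior, sized to cover all of P1 and no AB
  msk <- computeMasks(geo)
  par <- LineageParams(92, c(AB = 14.7, P1 = 10.1),
    bleaches = data.frame(time_s = 45,
                          cx = geo@center[1] + 0.8 * geo@semiAxes[1], cy = geo@center[2],
                          diameter_um = 2 * geo@semiAxes[1] * geo@pixelSizeUm,
                          survival = 0.4))
  tl <- makeLineageTimelapse(geos, par, smallOptics(), 30, 90,
                             seed = 1, render = FALSE)
  tr <- truthTraces(tl)
  before <- tr[tr$time_s == 30, ]; after <- tr[tr$time_s == 60, ]
  g <- pieQuant:::.pixelGrid(geo@dim)
  rpx <- geo@semiAxes[1]
  circ <- (g$x - (geo@center[1] + 0.8 * geo@semiAxes[1]))^2 +
    (g$y - geo@center[2])^2 <= rpx^2
  pP1 <- sum(msk@cells$P1 & circ) / sum(msk@cells$P1)
  pAB <- sum(msk@cells$AB & circ) / sum(msk@cells$AB)
  expAmt <- function(cell, p) {
    a0 <- before$mat_amount[before$cell == cell]
    a0 * (1 - p + 0.4 * p)
  }
  expect_equal(after$mat_amount[after$cell == "P1"], expAmt("P1", pP1),
               tolerance = 1e-12)
  expect_equal(after$mat_amount[after$cell == "AB"], expAmt("AB", pAB),
               tolerance = 1e-12)
  # P1 is fully covered, so its amount drops to the survival fraction
  expect_equal(pP1, 1)
  expect_equal(after$mat_amount[after$cell == "P1"] /
                 before$mat_amount[before$cell == "P1"], 0.4,
               tolerance = 1e-12)
})

test_that("a bleach entirely outside the embryo is rejected", {
  geo <- smallGeometry("1cell", nuclei = FALSE)
  par <- LineageParams(92, c(P0 = 26.88),
    bleaches = data.frame(time_s = 30, cx = 1, cy = 1,
                          diameter_um = 0.8, survival = 0.4))
  expect_error(
    makeLineageTimelapse(list(geo), par, smallOptics(), 30, 60,
                         seed = 1, render = FALSE),
    "outside the embryo")
})

test_that("membrane stacks carry analytic ground-truth volumes", {
  op <- OpticsModel(c(60, 60), vignetting = 0)
  # 10 um radius sphere: 4/3 pi 10^3 = 4188.79 um^3 = 4.19 pL
  ms <- makeMembraneStack(
    list(ball = list(center = c(15, 15, 15), semiAxes = c(10, 10, 10))),
    voxelSizeUm = c(0.5, 0.5, 0.5), dim = c(60, 60, 60), optics = op, seed = 1)
  expect_equal(unname(ms$trueVolumesPL["ball"]), 4 / 3 * pi * 1000 / 1000,
               tolerance = 1e-12)
  expect_equal(unname(volumesFromLabels(ms$labels)["ball"]),
               unname(ms$trueVolumesPL["ball"]), tolerance = 0.02)
  # two equal ellipsoids have equal true volumes
  ms2 <- makeMembraneStack(
    list(a = list(center = c(15, 15, 10), semiAxes = c(6, 6, 6)),
         b = list(center = c(15, 15, 24), semiAxes = c(6, 6, 6))),
    voxelSizeUm = c(0.5, 0.5, 0.5), dim = c(60, 60, 70), optics = op, seed = 1)
  expect_equal(unname(ms2$trueVolumesPL["a"]), unname(ms2$trueVolumesPL["b"]))
  expect_error(
    makeMembraneStack(list(a = list(center = c(1, 1, 1), semiAxes = c(2, 2, 2))),
                      voxelSizeUm = c(0, 1, 1), dim = c(10, 10, 10),
                      optics = op, seed = 1),
    "voxel")
})

test_that("screen datasets encode true effects and reject bad multipliers", {
  tab <- makeScreenDataset(4, c(5, 11), 500, effectSizes = c(clone_002 = 0),
                           seed = 3)
  hits <- callHits(tab, alpha = 0.05)
  expect_true(hits$hit_stage2[hits$clone == "clone_002"])
  expect_error(makeScreenDataset(4, 5, 500, effectSizes = c(clone_001 = -1)),
               ">= 0")
  expect_error(makeScreenDataset(4, 1, 500), ">= 2")
})
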