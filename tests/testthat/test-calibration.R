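# Calibration chain: flat-field reference, background and autofluorescence
# corrections, the ratio estimator, and the posterior:anterior split.

test_that("illumination references average pixel-wise and record the max", {
  cimg <- matrix(7, 4, 5)
  ref <- buildIlluminationReference(list(cimg))
  expect_equal(ref@meanBathImage, cimg)
  expect_equal(ref@maxValue, 7)
  a <- matrix(1:12, 3, 4); b <- matrix(13:24, 3, 4)
  ref2 <- buildIlluminationReference(list(a, b))
  expect_equal(ref2@meanBathImage, (a + b) / 2)
  expect_error(buildIlluminationReference(list(a, matrix(0, 2, 2))),
               "identical dimensions")
})

test_that("averaging ten bath images shrinks reference noise about sqrt(10)", {
  op <- OpticsModel(smallDim, vignetting = 0, autofluorescenceNMEquiv = 0)
  imgs <- makeBathReferenceImages(op, 300, n = 10L, seed = 1)
  single <- imgs[[1]]
  avg <- buildIlluminationReference(imgs)@meanBathImage
  ratio <- sd(avg) / sd(single)
  expect_gt(ratio, 1 / sqrt(10) * 0.8)
  expect_lt(ratio, 1 / sqrt(10) * 1.25)
})

test_that("flat-field correction is identity for a uniform reference and
           flattens its own reference image", {
  img <- matrix(runif(20, 100, 200), 4, 5)
  refC <- buildIlluminationReference(list(matrix(3, 4, 5)))
  expect_equal(flatfieldCorrect(img, refC), img, tolerance = 1e-12)
  vign <- matrix(runif(20, 0.5, 1), 4, 5)
  ref <- buildIlluminationReference(list(vign))
  expect_equal(flatfieldCorrect(vign, ref),
               matrix(max(vign), 4, 5), tolerance = 1e-12)
  refZ <- buildIlluminationReference(list(matrix(c(0, 1, 1, 1), 2, 2)))
  expect_error(flatfieldCorrect(matrix(1, 2, 2), refZ), "zero")
})

test_that("flat-field correction removes vignetting from a noise-free bath", {
  op <- OpticsModel(smallDim, vignetting = 0.3, autofluorescenceNMEquiv = 0)
  bath <- makeBathReferenceImages(op, 300, n = 1L, seed = 1, noise = FALSE)[[1]]
  expect_gt(sd(bath) / mean(bath), 0.05)  # vignetting visible before
  ref <- buildIlluminationReference(
    makeBathReferenceImages(op, 300, n = 1L, seed = 2, noise = FALSE))
  corr <- flatfieldCorrect(bath, ref)
  expect_lt(sd(corr) / mean(corr), 0.01)
})

test_that("camera background modes are distinct and correctly averaged", {
  op <- OpticsModel(smallDim, vignetting = 0, readNoiseSd = 0,
                    autofluorescenceNMEquiv = 0)
  blank <- makeBathReferenceImages(op, 0, n = 1L, seed = 1)[[1]]
  expect_equal(measureCameraBackground(blank, "m9_blank"), op@cameraOffset)
  # outside-embryo mode on a bath-containing frame returns bath + offset
  sc <- makeCalibrationScene(smallGeometry(), op, 300, c(P0 = 0),
                             seed = 1, noise = FALSE)
  out <- measureCameraBackground(sceneImage(sc), "outside_embryo",
                                 mask = bathMask(sceneMasks(sc)))
  expect_equal(out, op@photonsPerNM * 300 + op@cameraOffset, tolerance = 1e-9)
  expect_error(measureCameraBackground(blank, "outside_embryo"), "mask")
  expect_error(measureCameraBackground(blank, "m9_blank",
                                       mask = matrix(FALSE, smallDim[1], smallDim[2])),
               "empty")
})

test_that("noisy blank background is within 3 SE of the offset", {
  op <- OpticsModel(c(100L, 100L), vignetting = 0, readNoiseSd = 5,
                    autofluorescenceNMEquiv = 0)
  blank <- makeBathReferenceImages(op, 0, n = 1L, seed = 9)[[1]]
  se <- sqrt(op@readNoiseSd^2 + 1 / 12) / sqrt(length(blank))
  expect_lt(abs(measureCameraBackground(blank, "m9_blank") - op@cameraOffset),
            3 * se)
})

test_that("autofluorescence measurement matches the generator and ignores
           the bath", {
  geo <- smallGeometry()
  op0 <- OpticsModel(smallDim, vignetting = 0, readNoiseSd = 0,
                     autofluorescenceNMEquiv = 0)
  scZ <- makeCalibrationScene(geo, op0, 300, c(P0 = 0), seed = 1, noise = FALSE)
  expect_equal(measureAutofluorescence(sceneImage(scZ), sceneMasks(scZ),
                                       op0@cameraOffset), 0, tolerance = 1e-9)
  op <- OpticsModel(smallDim, vignetting = 0, readNoiseSd = 0,
                    photonsPerNM = 10, autofluorescenceNMEquiv = 20)
  scA <- makeCalibrationScene(geo, op, 300, c(P0 = 0), seed = 1, noise = FALSE)
  af <- measureAutofluorescence(sceneImage(scA), sceneMasks(scA), op@cameraOffset)
  expect_equal(af, 200, tolerance = 1e-9)  # 20 nM-equiv x 10 counts/nM
  scB <- makeCalibrationScene(geo, op, 0, c(P0 = 0), seed = 1, noise = FALSE)
  afB <- measureAutofluorescence(sceneImage(scB), sceneMasks(scB), op@cameraOffset)
  expect_equal(af, afB, tolerance = 1e-12)
  expect_error(measureAutofluorescence(
    sceneImage(scA),
    new("CompartmentMasks", embryo = matrix(FALSE, smallDim[1], smallDim[2]),
        bath = matrix(TRUE, smallDim[1], smallDim[2]), cells = list(),
        nuclei = list(), pixelSizeUm = 0.4),
    op@cameraOffset), "empty")
})

test_that("the estimator recovers known concentrations", {
  geo <- smallGeometry()
  op <- OpticsModel(smallDim, vignetting = 0, readNoiseSd = 0,
                    autofluorescenceNMEquiv = 0)
  sc <- makeCalibrationScene(geo, op, 300, c(P0 = 150), seed = 1, noise = FALSE)
  est <- estimateConcentration(sceneImage(sc), sceneMasks(sc), 300,
                               op@cameraOffset)
  expect_equal(est$conc_nM[est$compartment == "total"], 150, tolerance = 1e-2)
  # zero intracellular intensity maps to zero concentration
  sc0 <- makeCalibrationScene(geo, op, 300, c(P0 = 0), seed = 1, noise = FALSE)
  est0 <- estimateConcentration(sceneImage(sc0), sceneMasks(sc0), 300,
                                op@cameraOffset)
  expect_equal(est0$conc_nM, rep(0, nrow(est0)), tolerance = 1e-9)
  # a bath at background level cannot calibrate
  expect_error(estimateConcentration(sceneImage(sc0), sceneMasks(sc0), 300,
                                     cameraBg = 1e6), "uncalibratable")
})

test_that("zygote concentration is recovered within 5% across 20 seeds in
           the 150 nM bath protocol", {
  geo <- smallGeometry()
  op <- smallOptics()
  errs <- vapply(1:20, function(i) {
    cor <- measuredCorrections(op, geo, bathNM = 150, seed = childSeed(11, i))
    sc <- makeCalibrationScene(geo, op, 150, c(P0 = 92),
                               seed = childSeed(13, i))
    est <- estimateConcentration(sceneImage(sc), sceneMasks(sc), 150,
                                 cor$bg, cor$af, cor$ref)
    tru <- sceneTruth(sc)$conc$P0$total
    est$conc_nM[est$compartment == "total"] / tru - 1
  }, numeric(1))
  expect_true(all(abs(errs) < 0.05))
})

test_that("estimates scale with bath and true concentration (equivariance)", {
  geo <- smallGeometry()
  op <- OpticsModel(smallDim, vignetting = 0.2, readNoiseSd = 0,
                    autofluorescenceNMEquiv = 0)
  ref <- buildIlluminationReference(
    makeBathReferenceImages(op, 300, n = 1L, seed = 1, noise = FALSE))
  estAt <- function(k) {
    sc <- makeCalibrationScene(geo, op, k * 300, c(P0 = k * 100),
                               seed = 1, noise = FALSE)
    e <- estimateConcentration(sceneImage(sc), sceneMasks(sc), k * 300,
                               op@cameraOffset, 0, ref)
    e$conc_nM[e$compartment == "total"]
  }
  # the camera offset sits inside the flat-field ratio, so scaling is exact
  # only up to an O(offset/signal) remainder of order 1e-4
  expect_equal(estAt(2), 2 * estAt(1), tolerance = 1e-3)
  expect_equal(estAt(4), 4 * estAt(1), tolerance = 1e-3)
})

test_that("cytoplasm and nucleus estimates recombine into the whole-cell
           estimate", {
  geo <- smallGeometry()   # P0 with a nucleus
  op <- OpticsModel(smallDim, vignetting = 0, readNoiseSd = 0,
                    autofluorescenceNMEquiv = 0)
  sc <- makeCalibrationScene(geo, op, 300,
                             c("P0:cytoplasm" = 90, "P0:nucleus" = 500),
                             seed = 1, noise = FALSE)
  est <- estimateConcentration(sceneImage(sc), sceneMasks(sc), 300,
                               op@cameraOffset)
  tot <- est[est$compartment == "total", ]
  cyt <- est[est$compartment == "cytoplasm", ]
  nuc <- est[est$compartment == "nucleus", ]
  weighted <- (cyt$conc_nM * cyt$n_pixels + nuc$conc_nM * nuc$n_pixels) /
    (cyt$n_pixels + nuc$n_pixels)
  expect_equal(weighted, tot$conc_nM, tolerance = 0.005)
})

test_that("saturated pixels are excluded with a warning", {
  geo <- smallGeometry()
  op <- OpticsModel(smallDim, vignetting = 0, readNoiseSd = 0,
                    autofluorescenceNMEquiv = 0)
  sc <- makeCalibrationScene(geo, op, 300, c(P0 = 150), seed = 1, noise = FALSE)
  img <- sceneImage(sc)
  img[which(embryoMask(sceneMasks(sc)))[1:5]] <- 65535
  expect_warning(
    est <- estimateConcentration(img, sceneMasks(sc), 300, op@cameraOffset),
    "saturated")
  expect_equal(est$conc_nM[est$compartment == "total"], 150, tolerance = 0.01)
})

test_that("posterior:anterior ratio matches symmetry, step and gradient
           oracles", {
  geo <- smallGeometry("1cell", nuclei = FALSE)
  msk <- computeMasks(geo)
  uni <- matrix(200, smallDim[1], smallDim[2])
  expect_equal(posteriorAnteriorRatio(uni, embryoMask(msk), 0, 100), 1,
               tolerance = 1e-6)
  # posterior half twice the anterior half
  g <- pieQuant:::.pixelGrid(smallDim)
  img2 <- matrix(100, smallDim[1], smallDim[2])
  img2[embryoMask(msk) & g$x > geo@center[1]] <- 300
  img2[embryoMask(msk) & g$x <= geo@center[1]] <- 200
  expect_equal(posteriorAnteriorRatio(img2, embryoMask(msk), 0, 100), 2,
               tolerance = 0.02)
  # linear AP gradient: half-ellipse mean of x is 4a/(3*pi) off centre
  b <- 2
  img3 <- matrix(0, smallDim[1], smallDim[2])
  img3[] <- 500 + b * (g$x - geo@center[1])
  a <- geo@semiAxes[1]
  expected <- (500 + b * 4 * a / (3 * pi)) / (500 - b * 4 * a / (3 * pi))
  expect_equal(posteriorAnteriorRatio(img3, embryoMask(msk), 0, 0), expected,
               tolerance = 0.01)
  expect_error(posteriorAnteriorRatio(uni, embryoMask(msk), 0, 1e6),
               "anterior")
})
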