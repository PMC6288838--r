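# Small-scene fixtures shared across tests; everything is generated in code.

smallDim <- c(60L, 90L)

smallOptics <- function(dim = smallDim, vignetting = 0.25, readNoiseSd = 5,
                        autofluorescenceNMEquiv = 20, ...) {
  OpticsModel(dim, vignetting = vignetting, readNoiseSd = readNoiseSd,
              autofluorescenceNMEquiv = autofluorescenceNMEquiv, ...)
}

smallGeometry <- function(stage = "1cell", dim = smallDim, nuclei = TRUE) {
  standardEmbryoGeometry(stage, dim = dim, nuclei = nuclei)
}

# measured flat-field reference + camera background + autofluorescence for a
# given optics model, obtained the way an experiment would obtain them
measuredCorrections <- function(op, geometry, bathNM = 300, seed = 1L,
                                noise = TRUE) {
  ref <- buildIlluminationReference(
    makeBathReferenceImages(op, bathNM, n = 10L, seed = seed, noise = noise))
  blank <- makeBathReferenceImages(op, 0, n = 1L, seed = childSeed(seed, 50),
                                   noise = noise)[[1]]
  bg <- measureCameraBackground(blank, "m9_blank")
  n2 <- makeCalibrationScene(geometry, op, 0,
                             stats::setNames(numeric(length(geometry@cells)),
                                             cellNames(geometry)),
                             seed = childSeed(seed, 51), noise = noise)
  af <- measureAutofluorescence(sceneImage(n2), sceneMasks(n2), bg, ref = ref)
  list(ref = ref, bg = bg, af = af)
}

# ellipsoid semi-axes (z, y, x) for a target volume in pL with mild anisotropy
ellipsoidAxes <- function(volumePL, aniso = c(0.9, 1, 1.1)) {
  s <- (volumePL * 1000 * 3 / (4 * pi * prod(aniso)))^(1/3)
  aniso * s
}

# side-by-side two-cell membrane phantom used by the volumetrics tests
twoCellPhantom <- function(vLeft, vRight, seed = 1L, voxel = c(1, 0.5, 0.5)) {
  axL <- ellipsoidAxes(vLeft); axR <- ellipsoidAxes(vRight)
  nx <- ceiling((2 * (axL[3] + axR[3]) + 12) / voxel[3])
  ny <- ceiling((2 * max(axL[2], axR[2]) + 8) / voxel[2])
  nz <- ceiling((2 * max(axL[1], axR[1]) + 8) / voxel[1])
  cxL <- axL[3] + 3; cxR <- 2 * axL[3] + axR[3] + 9
  cy <- ny * voxel[2] / 2; cz <- nz * voxel[1] / 2
  ell <- list(left = list(center = c(cz, cy, cxL), semiAxes = axL),
              right = list(center = c(cz, cy, cxR), semiAxes = axR))
  op <- OpticsModel(c(ny, nx), vignetting = 0.1)
  ms <- makeMembraneStack(ell, voxelSizeUm = voxel, dim = c(nz, ny, nx),
                          optics = op, seed = seed)
  seeds <- list(left = round(c(cz / voxel[1], cy / voxel[2], cxL / voxel[3])),
                right = round(c(cz / voxel[1], cy / voxel[2], cxR / voxel[3])))
  c(ms, list(seeds = seeds, voxel = voxel))
}

# standard three-stage lineage simulation at a chosen seed
standardTimelapse <- function(seed = 1L, dim = smallDim, intervalS = 60,
                              durationS = 2700, params = NULL, op = NULL,
                              render = TRUE) {
  if (is.null(op)) op <- smallOptics(dim)
  geos <- list(smallGeometry("1cell", dim, nuclei = FALSE),
               smallGeometry("2cell", dim, nuclei = FALSE),
               smallGeometry("4cell", dim, nuclei = FALSE))
  if (is.null(params)) params <- standardLineageParams()
  makeLineageTimelapse(geos, params, op, intervalS = intervalS,
                       durationS = durationS, seed = seed, render = render)
}
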