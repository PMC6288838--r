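#' @import methods
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' OpticsModel: imaging model for synthetic confocal scenes
#'
#' Describes the microscope/camera forward model used by every synthetic
#' scene: a multiplicative illumination gain field (vignetting, peak 1.0), an
#' additive camera offset, Gaussian read noise, a linear photons-per-nM
#' conversion, and embryo autofluorescence expressed in nM-equivalents of the
#' calibration fluorophore. Pixel values are generated as
#' \deqn{I = Poisson(k (C + C_{af})) g + o + N(0, \sigma_r)}
#' where \eqn{k} is \code{photonsPerNM}, \eqn{g} the local illumination gain,
#' \eqn{o} the camera offset, and \eqn{C_{af}} is nonzero only inside the
#' embryo.
#'
#' @slot illuminationField numeric matrix, multiplicative gain, > 0 everywhere,
#'   maximum 1.
#' @slot cameraOffset additive counts.
#' @slot readNoiseSd Gaussian read noise SD in counts (>= 0).
#' @slot photonsPerNM expected counts per nM per pixel at unit gain (> 0).
#' @slot autofluorescenceNMEquiv embryo-interior autofluorescence in
#'   nM-equivalents.
#' @exportClass OpticsModel
setClass("OpticsModel", representation(
  illuminationField = "matrix",
  cameraOffset = "numeric",
  readNoiseSd = "numeric",
  photonsPerNM = "numeric",
  autofluorescenceNMEquiv = "numeric"
))

setValidity("OpticsModel", function(object) {
  msg <- character()
  if (any(object@illuminationField <= 0)) msg <- c(msg, "illuminationField must be > 0 everywhere")
  if (length(object@readNoiseSd) != 1L || object@readNoiseSd < 0) msg <- c(msg, "readNoiseSd must be a scalar >= 0")
  if (length(object@photonsPerNM) != 1L || object@photonsPerNM <= 0) msg <- c(msg, "photonsPerNM must be a scalar > 0")
  if (length(object@cameraOffset) != 1L || object@cameraOffset < 0) msg <- c(msg, "cameraOffset must be a scalar >= 0")
  if (length(object@autofluorescenceNMEquiv) != 1L || object@autofluorescenceNMEquiv < 0)
    msg <- c(msg, "autofluorescenceNMEquiv must be a scalar >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an OpticsModel
#'
#' Builds the default imaging model: a radially symmetric vignetting field
#' \eqn{g(r) = 1 - v (r/r_{max})^2} peaking at 1 in the image centre.
#'
#' @param dim image dimensions c(nrow, ncol).
#' @param vignetting fractional fall-off at the image corner (0 = flat field).
#' @param cameraOffset additive camera offset in counts.
#' @param readNoiseSd Gaussian read-noise SD in counts.
#' @param photonsPerNM linear conversion, expected counts per nM per pixel.
#' @param autofluorescenceNMEquiv embryo autofluorescence, nM-equivalents.
#' @param illuminationField optional explicit gain matrix (overrides
#'   \code{vignetting}); will be rescaled to peak at 1.
#' @return an \linkS4class{OpticsModel}.
#' @examples
#' op <- OpticsModel(c(60, 90), vignetting = 0.2)
#' range(illuminationField(op))
#' @export
OpticsModel <- function(dim = c(100L, 150L), vignetting = 0.25,
                        cameraOffset = 100, readNoiseSd = 5,
                        photonsPerNM = 5, autofluorescenceNMEquiv = 20,
                        illuminationField = NULL) {
  if (is.null(illuminationField)) {
    g <- .pixelGrid(dim)
    cx <- dim[2] / 2; cy <- dim[1] / 2
    r2 <- ((g$x - cx)^2 + (g$y - cy)^2) / (cx^2 + cy^2)
    illuminationField <- 1 - vignetting * r2
  }
  illuminationField <- illuminationField / max(illuminationField)
  new("OpticsModel", illuminationField = illuminationField,
      cameraOffset = cameraOffset, readNoiseSd = readNoiseSd,
      photonsPerNM = photonsPerNM,
      autofluorescenceNMEquiv = autofluorescenceNMEquiv)
}

#' EmbryoGeometry: midplane geometry of an early embryo
#'
#' An elliptical embryo outline in pixel coordinates, with the
#' anteroposterior (AP) axis along the ellipse's major axis, plus a partition
#' of the embryo into named blastomeres. Each cell occupies the band of
#' normalized AP coordinate \code{[lo, hi)} assigned to it, so the cells tile
#' the embryo exactly without overlap. Nuclei are circles centred on the AP
#' axis. Each cell carries its (3D) volume in pL for mass-balance work; the
#' 2D raster is only used for intensity means and noise statistics.
#'
#' @slot dim image dimensions c(nrow, ncol).
#' @slot center ellipse centre (x, y) in pixels.
#' @slot semiAxes semi-axes (a along AP, b transverse) in pixels.
#' @slot thetaRad AP-axis orientation in radians (0 = +x, posterior at high x).
#' @slot pixelSizeUm pixel edge length in micrometres.
#' @slot cells named list of AP-fraction intervals c(lo, hi).
#' @slot nuclei named list (subset of cells) of c(u = AP fraction of centre,
#'   r = radius in pixels).
#' @slot volumesPL named numeric, per-cell volume in picolitres.
#' @exportClass EmbryoGeometry
setClass("EmbryoGeometry", representation(
  dim = "integer", center = "numeric", semiAxes = "numeric",
  thetaRad = "numeric", pixelSizeUm = "numeric",
  cells = "list", nuclei = "list", volumesPL = "numeric"
))

setValidity("EmbryoGeometry", function(object) {
  msg <- character()
  iv <- object@cells
  if (length(iv) == 0L) msg <- c(msg, "at least one cell required")
  if (is.null(names(iv)) || any(names(iv) == "")) msg <- c(msg, "cells must be named")
  lo <- vapply(iv, `[`, numeric(1), 1L); hi <- vapply(iv, `[`, numeric(1), 2L)
  o <- order(lo)
  if (any(hi <= lo)) msg <- c(msg, "each cell interval must have hi > lo")
  if (length(iv) >= 1L && (abs(min(lo) - 0) > 1e-9 || abs(max(hi) - 1) > 1e-9))
    msg <- c(msg, "cell intervals must cover [0, 1]")
  if (length(iv) > 1L && any(abs(hi[o][-length(iv)] - lo[o][-1L]) > 1e-9))
    msg <- c(msg, "cell intervals must tile without gaps or overlap")
  if (!all(names(object@nuclei) %in% names(iv)))
    msg <- c(msg, "every nucleus must belong to a named cell")
  if (length(object@volumesPL) && (!all(names(iv) %in% names(object@volumesPL)) ||
      any(object@volumesPL <= 0)))
    msg <- c(msg, "volumesPL must name every cell with a positive volume")
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct an EmbryoGeometry
#'
#' @param dim image dimensions c(nrow, ncol).
#' @param center ellipse centre (x, y), pixels; default image centre.
#' @param semiAxes semi-axes (a, b), pixels.
#' @param thetaRad AP-axis orientation, radians.
#' @param pixelSizeUm pixel size, micrometres.
#' @param cells named list of AP intervals c(lo, hi), fractions of embryo
#'   length; must tile [0, 1].
#' @param nuclei named list of c(u, r): nucleus centre AP fraction and radius
#'   in pixels.
#' @param volumesPL named per-cell volumes (pL).
#' @return an \linkS4class{EmbryoGeometry}.
#' @export
EmbryoGeometry <- function(dim, semiAxes, cells, center = c(dim[2] / 2, dim[1] / 2),
                           thetaRad = 0, pixelSizeUm = 0.4,
                           nuclei = list(), volumesPL = numeric()) {
  new("EmbryoGeometry", dim = as.integer(dim), center = center,
      semiAxes = semiAxes, thetaRad = thetaRad, pixelSizeUm = pixelSizeUm,
      cells = cells, nuclei = nuclei, volumesPL = volumesPL)
}

#' CompartmentMasks: boolean compartment layers over one image
#'
#' Rasterized masks for a single midplane image: embryo interior, the
#' extracellular bath (complement of the embryo), one whole-cell mask per
#' blastomere and optional nucleus masks. Cytoplasm is derived as whole-cell
#' minus nucleus, so cytoplasm and nucleus partition the cell exactly and a
#' pixel belongs to exactly one compartment.
#'
#' @slot embryo logical matrix.
#' @slot bath logical matrix, disjoint from embryo.
#' @slot cells named list of logical matrices (whole-cell).
#' @slot nuclei named list of logical matrices (subset of cells).
#' @slot pixelSizeUm pixel size in micrometres.
#' @exportClass CompartmentMasks
setClass("CompartmentMasks", representation(
  embryo = "matrix", bath = "matrix", cells = "list", nuclei = "list",
  pixelSizeUm = "numeric"
))

setValidity("CompartmentMasks", function(object) {
  msg <- character()
  if (any(object@embryo & object@bath)) msg <- c(msg, "bath and embryo masks must be disjoint")
  for (nm in names(object@cells)) {
    if (any(object@cells[[nm]] & !object@embryo))
      msg <- c(msg, sprintf("cell '%s' extends outside the embryo", nm))
  }
  for (nm in names(object@nuclei)) {
    if (!nm %in% names(object@cells)) { msg <- c(msg, sprintf("nucleus '%s' has no cell", nm)); next }
    if (any(object@nuclei[[nm]] & !object@cells[[nm]]))
      msg <- c(msg, sprintf("nucleus '%s' extends outside its cell", nm))
  }
  if (length(msg)) msg else TRUE
})

#' IlluminationReference: averaged flat-field reference
#'
#' The mean of repeated images of a uniform fluorophore solution, together
#' with its maximum pixel value. Flat-field correction divides a specimen
#' image by the mean bath image and multiplies by the recorded maximum, so a
#' perfectly uniform reference leaves images unchanged.
#'
#' @slot meanBathImage pixel-wise mean of the reference images (counts).
#' @slot maxValue maximum pixel of \code{meanBathImage}.
#' @slot nImagesAveraged number of images averaged (>= 1).
#' @exportClass IlluminationReference
setClass("IlluminationReference", representation(
  meanBathImage = "matrix", maxValue = "numeric", nImagesAveraged = "integer"
))

setValidity("IlluminationReference", function(object) {
  msg <- character()
  if (!isTRUE(all.equal(object@maxValue, max(object@meanBathImage))))
    msg <- c(msg, "maxValue must equal max(meanBathImage)")
  if (object@nImagesAveraged < 1L) msg <- c(msg, "nImagesAveraged must be >= 1")
  if (length(msg)) msg else TRUE
})

#' CalibrationScene: synthetic bath-calibration image with ground truth
#'
#' One rendered midplane image of an embryo in a fluorophore bath, the
#' compartment masks used to rasterize it, and a truth record holding every
#' ground-truth concentration, for validating the concentration estimator.
#'
#' @slot image numeric matrix of camera counts.
#' @slot masks a \linkS4class{CompartmentMasks}.
#' @slot truth list: bath_nM, per-compartment true concentrations, optics
#'   parameters, seed.
#' @exportClass CalibrationScene
setClass("CalibrationScene", representation(
  image = "matrix", masks = "CompartmentMasks", truth = "list"
))

#' LineageParams: parameters of the germline-lineage simulation
#'
#' @slot initialConcentrationNM zygote concentration at time 0 (nM).
#' @slot volumesPL named per-cell volumes (pL) for every cell ever alive.
#' @slot divisions data.frame(time_s, mother, germ, soma, f): at each division
#'   the mother's amount splits, fraction f to the germline daughter.
#' @slot kSyn named synthesis rates (nM/s), missing cells = 0.
#' @slot kDeg named degradation rates (1/s), missing cells = 0.
#' @slot maturationDelayS delay before newly synthesized protein fluoresces.
#' @slot bleaches data.frame(time_s, cx, cy, diameter_um, survival).
#' @exportClass LineageParams
setClass("LineageParams", representation(
  initialConcentrationNM = "numeric", volumesPL = "numeric",
  divisions = "data.frame", kSyn = "numeric", kDeg = "numeric",
  maturationDelayS = "numeric", bleaches = "data.frame"
))

setValidity("LineageParams", function(object) {
  msg <- character()
  d <- object@divisions
  if (nrow(d)) {
    if (any(d$f <= 0 | d$f >= 1)) msg <- c(msg, "segregation fractions must lie strictly in (0, 1)")
    if (is.unsorted(d$time_s, strictly = TRUE)) msg <- c(msg, "division times must be strictly increasing")
  }
  if (any(object@kSyn < 0) || any(object@kDeg < 0)) msg <- c(msg, "rates must be >= 0")
  if (object@maturationDelayS < 0) msg <- c(msg, "maturationDelayS must be >= 0")
  if (object@initialConcentrationNM < 0) msg <- c(msg, "initial concentration must be >= 0")
  if (nrow(object@bleaches) && any(object@bleaches$survival < 0 | object@bleaches$survival > 1))
    msg <- c(msg, "bleach survival must lie in [0, 1]")
  if (any(object@volumesPL <= 0)) msg <- c(msg, "volumes must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct LineageParams
#'
#' @param initialConcentrationNM zygote concentration (nM).
#' @param volumesPL named per-cell volumes (pL).
#' @param divisions data.frame(time_s, mother, germ, soma, f).
#' @param kSyn,kDeg named rates (nM/s and 1/s); unnamed cells default to 0.
#' @param maturationDelayS fluorophore maturation delay (s).
#' @param bleaches data.frame(time_s, cx, cy, diameter_um, survival);
#'   cx, cy in pixels.
#' @return a \linkS4class{LineageParams}.
#' @export
LineageParams <- function(initialConcentrationNM, volumesPL,
                          divisions = data.frame(time_s = numeric(), mother = character(),
                                                 germ = character(), soma = character(),
                                                 f = numeric()),
                          kSyn = numeric(), kDeg = numeric(),
                          maturationDelayS = 0,
                          bleaches = data.frame(time_s = numeric(), cx = numeric(),
                                                cy = numeric(), diameter_um = numeric(),
                                                survival = numeric())) {
  new("LineageParams", initialConcentrationNM = initialConcentrationNM,
      volumesPL = volumesPL, divisions = divisions, kSyn = kSyn, kDeg = kDeg,
      maturationDelayS = maturationDelayS, bleaches = bleaches)
}

#' LineageTimelapse: simulated time-lapse with per-cell ground truth
#'
#' @slot times frame times (s).
#' @slot frames list of count matrices (empty when rendering was skipped).
#' @slot masks list of \linkS4class{CompartmentMasks}, one per frame.
#' @slot truth data.frame of per-frame, per-cell ground truth: visible and
#'   total concentration (nM), maternal and synthesized amounts (nM pL),
#'   autofluorescence bleach factor, volume.
#' @slot params the \linkS4class{LineageParams} used.
#' @slot optics the \linkS4class{OpticsModel} used.
#' @slot geometries list of per-stage \linkS4class{EmbryoGeometry}.
#' @exportClass LineageTimelapse
setClass("LineageTimelapse", representation(
  times = "numeric", frames = "list", masks = "list", truth = "data.frame",
  params = "LineageParams", optics = "OpticsModel", geometries = "list"
))

#' LabeledVolume: labelled 3D voxel volume
#'
#' An integer label array (0 = background) over an anisotropic voxel grid,
#' with a map from cell names to label values. Cell volumes follow by voxel
#' counting: volume = count x voxel volume, 1 pL = 1000 um^3.
#'
#' @slot labels 3D integer array (z, y, x), labels >= 0.
#' @slot voxelSizeUm voxel edge lengths (z, y, x) in micrometres, all > 0.
#' @slot cellMap named integer vector, cell name -> label value.
#' @exportClass LabeledVolume
setClass("LabeledVolume", representation(
  labels = "array", voxelSizeUm = "numeric", cellMap = "integer"
))

setValidity("LabeledVolume", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L) msg <- c(msg, "labels must be a 3D array")
  if (any(object@labels < 0)) msg <- c(msg, "labels must be >= 0")
  if (length(object@voxelSizeUm) != 3L || any(object@voxelSizeUm <= 0))
    msg <- c(msg, "voxelSizeUm must be three positive lengths (z, y, x)")
  if (is.null(names(object@cellMap)) || anyDuplicated(object@cellMap))
    msg <- c(msg, "cellMap must be a named vector of distinct labels")
  if (length(msg)) msg else TRUE
})

#' @param labels 3D integer array (z, y, x).
#' @param voxelSizeUm voxel sizes (z, y, x) in micrometres.
#' @param cellMap named integer vector, cell -> label.
#' @rdname LabeledVolume-class
#' @export
LabeledVolume <- function(labels, voxelSizeUm, cellMap) {
  storage.mode(labels) <- "integer"
  new("LabeledVolume", labels = labels, voxelSizeUm = as.numeric(voxelSizeUm),
      cellMap = structure(as.integer(cellMap), names = names(cellMap)))
}

## ---- show methods ----------------------------------------------------------

setMethod("show", "OpticsModel", function(object) {
  cat(sprintf("OpticsModel %dx%d | gain %.2f-%.2f | offset %g | read SD %g | %g counts/nM | AF %g nM-eq\n",
              nrow(object@illuminationField), ncol(object@illuminationField),
              min(object@illuminationField), max(object@illuminationField),
              object@cameraOffset, object@readNoiseSd, object@photonsPerNM,
              object@autofluorescenceNMEquiv))
})

setMethod("show", "EmbryoGeometry", function(object) {
  cat(sprintf("EmbryoGeometry %dx%d px (%.2g um/px), cells: %s\n",
              object@dim[1], object@dim[2], object@pixelSizeUm,
              paste(names(object@cells), collapse = ", ")))
})

setMethod("show", "CompartmentMasks", function(object) {
  cat(sprintf("CompartmentMasks %dx%d: embryo %d px, bath %d px, cells: %s\n",
              nrow(object@embryo), ncol(object@embryo), sum(object@embryo),
              sum(object@bath), paste(names(object@cells), collapse = ", ")))
})

setMethod("show", "CalibrationScene", function(object) {
  cat(sprintf("CalibrationScene %dx%d, bath %g nM, cells: %s\n",
              nrow(object@image), ncol(object@image), object@truth$bath_nM,
              paste(names(object@masks@cells), collapse = ", ")))
})

setMethod("show", "LineageTimelapse", function(object) {
  cat(sprintf("LineageTimelapse: %d frames (%s), %d division(s), %d bleach(es), cells: %s\n",
              length(object@times),
              if (length(object@frames)) "rendered" else "truth only",
              nrow(object@params@divisions), nrow(object@params@bleaches),
              paste(unique(object@truth$cell), collapse = ", ")))
})

setMethod("show", "LabeledVolume", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabeledVolume %dx%dx%d voxels (%.2gx%.2gx%.2g um), cells: %s\n",
              d[1], d[2], d[3], object@voxelSizeUm[1], object@voxelSizeUm[2],
              object@voxelSizeUm[3], paste(names(object@cellMap), collapse = ", ")))
})

setMethod("show", "IlluminationReference", function(object) {
  cat(sprintf("IlluminationReference %dx%d, %d image(s) averaged, max %.4g counts\n",
              nrow(object@meanBathImage), ncol(object@meanBathImage),
              object@nImagesAveraged, object@maxValue))
})

## ---- accessors -------------------------------------------------------------

#' Accessors for image-model and mask objects
#'
#' @param x an object of the matching class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
illuminationField <- function(x) x@illuminationField

#' @rdname accessors
#' @export
sceneImage <- function(x) x@image

#' @rdname accessors
#' @export
sceneTruth <- function(x) x@truth

#' @rdname accessors
#' @export
sceneMasks <- function(x) x@masks

#' @rdname accessors
#' @export
embryoMask <- function(x) x@embryo

#' @rdname accessors
#' @export
bathMask <- function(x) x@bath

#' @rdname accessors
#' @export
cellNames <- function(x) {
  if (is(x, "CompartmentMasks")) names(x@cells)
  else if (is(x, "EmbryoGeometry")) names(x@cells)
  else if (is(x, "LabeledVolume")) names(x@cellMap)
  else stop("no cells in object of class ", class(x))
}

#' Extract a compartment mask for one cell
#'
#' @param x a \linkS4class{CompartmentMasks}.
#' @param cell cell name.
#' @param compartment one of "total", "cytoplasm", "nucleus".
#' @return logical matrix.
#' @export
cellMask <- function(x, cell, compartment = c("total", "cytoplasm", "nucleus")) {
  compartment <- match.arg(compartment)
  if (!cell %in% names(x@cells)) stop("unknown cell: ", cell)
  tot <- x@cells[[cell]]
  if (compartment == "total") return(tot)
  nuc <- x@nuclei[[cell]]
  if (is.null(nuc)) {
    if (compartment == "nucleus") stop("no nucleus mask for cell ", cell)
    return(tot)
  }
  if (compartment == "nucleus") nuc else (tot & !nuc)
}

#' Truth traces of a simulated time-lapse
#'
#' @param x a \linkS4class{LineageTimelapse}.
#' @return data.frame of per-frame, per-cell ground truth.
#' @export
truthTraces <- function(x) x@truth

#' @rdname accessors
#' @export
frameTimes <- function(x) x@times

#' Frame image / masks of a simulated time-lapse
#'
#' @param x a \linkS4class{LineageTimelapse}.
#' @param i frame index.
#' @export
frameImage <- function(x, i) {
  if (!length(x@frames)) stop("time-lapse was simulated without rendering")
  x@frames[[i]]
}

#' @rdname frameImage
#' @export
frameMasks <- function(x, i) x@masks[[i]]
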