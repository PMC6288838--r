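## Absolute concentration estimation from bath-calibrated images:
## flat-field correction against an averaged bath reference, camera
## background and autofluorescence correction, then ratio conversion
## C_in = C_bath x I_in / I_bath.

#' Build an illumination reference from repeated bath images
#'
#' Averages repeated images of a uniform fluorophore solution pixel-wise and
#' records the maximum pixel of the average. Ten such images are typically
#' averaged, shrinking the reference noise by about sqrt(10).
#'
#' @param bathImages list of numeric matrices of identical dimensions.
#' @return an \linkS4class{IlluminationReference}.
#' @export
buildIlluminationReference <- function(bathImages) {
  if (!is.list(bathImages) || length(bathImages) < 1L)
    stop("need at least one bath image")
  d <- dim(bathImages[[1]])
  for (im in bathImages) if (!identical(dim(im), d))
    stop("bath images must all have identical dimensions")
  m <- Reduce(`+`, bathImages) / length(bathImages)
  new("IlluminationReference", meanBathImage = m, maxValue = max(m),
      nImagesAveraged = length(bathImages))
}

#' Flat-field correct an image
#'
#' Divides the image pixel-wise by the mean bath image and multiplies by the
#' recorded maximum pixel of that reference, so a perfectly uniform
#' reference acts as the identity.
#'
#' @param image numeric matrix (counts).
#' @param ref an \linkS4class{IlluminationReference} with matching
#'   dimensions and no zero pixels.
#' @return corrected image.
#' @export
flatfieldCorrect <- function(image, ref) {
  if (!identical(dim(image), dim(ref@meanBathImage)))
    stop("image and reference dimensions differ")
  if (any(ref@meanBathImage == 0))
    stop("reference contains zero pixels; division undefined")
  image / ref@meanBathImage * ref@maxValue
}

#' Measure camera background
#'
#' Two modes matching the two experimental designs: `m9_blank` averages a
#' blank (buffer-only) image, appropriate when the specimen frame contains a
#' fluorescent bath; `outside_embryo` averages a region outside the embryo
#' within the specimen frame itself, appropriate only when the surrounding
#' medium is non-fluorescent. In a bath-calibration frame the outside-embryo
#' region contains the bath and so does NOT return the pure camera offset.
#'
#' @param image numeric matrix.
#' @param mode "m9_blank" or "outside_embryo".
#' @param mask logical matrix selecting the region; required for
#'   `outside_embryo`, optional for `m9_blank` (default: whole frame).
#' @return mean counts over the designated region (scalar).
#' @export
measureCameraBackground <- function(image, mode = c("m9_blank", "outside_embryo"),
                                    mask = NULL) {
  mode <- match.arg(mode)
  if (mode == "outside_embryo") {
    if (is.null(mask)) stop("outside_embryo mode requires a mask")
  } else if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  if (!any(mask)) stop("background region is empty")
  mean(image[mask])
}

#' Measure embryo autofluorescence
#'
#' Mean embryo-interior counts of a non-fluorescent (wild-type) embryo image
#' minus the camera background. The value is propagated as-is; it may be
#' slightly negative from noise and is not clamped. If a reference is
#' supplied the image is flat-field corrected first, matching the
#' correction order used by [estimateConcentration()].
#'
#' @param image counts matrix of a wild-type embryo bathed in fluorophore.
#' @param masks a \linkS4class{CompartmentMasks} (embryo layer used).
#' @param cameraBg camera background counts.
#' @param ref optional \linkS4class{IlluminationReference}.
#' @return autofluorescence in counts (scalar).
#' @export
measureAutofluorescence <- function(image, masks, cameraBg, ref = NULL) {
  if (!any(masks@embryo)) stop("embryo mask is empty")
  if (!is.null(ref)) image <- flatfieldCorrect(image, ref)
  mean(image[masks@embryo]) - cameraBg
}

#' Estimate absolute intracellular concentrations
#'
#' The image is flat-field corrected, then the bath intensity is corrected
#' for camera background and each intracellular compartment for camera
#' background and autofluorescence; concentration is the bath concentration
#' times the intensity ratio:
#' \deqn{C_{in} = C_{bath} (I_{in} - bg - af) / (I_{bath} - bg).}
#' Estimates are emitted for the total cell, cytoplasm and (where a nucleus
#' mask exists) nucleus of every cell. Saturated pixels are excluded from
#' means with a warning.
#'
#' @param image counts matrix.
#' @param masks a \linkS4class{CompartmentMasks} with a non-empty bath and
#'   at least one cell.
#' @param bathNM bath concentration (nM), > 0.
#' @param cameraBg camera background counts (from an M9 blank).
#' @param autofluorCounts autofluorescence in counts (from a wild-type
#'   embryo), default 0.
#' @param ref optional \linkS4class{IlluminationReference}; if NULL the
#'   image is used as-is.
#' @param satLevel saturation level in counts (16-bit default).
#' @return data.frame(cell, compartment, conc_nM, n_pixels,
#'   corrected_mean_counts).
#' @examples
#' geo <- standardEmbryoGeometry("1cell", dim = c(60, 90))
#' op <- OpticsModel(c(60, 90), vignetting = 0, autofluorescenceNMEquiv = 0)
#' sc <- makeCalibrationScene(geo, op, 150, c(P0 = 92), seed = 1, noise = FALSE)
#' estimateConcentration(sceneImage(sc), sceneMasks(sc), 150,
#'                       cameraBg = op@cameraOffset)
#' @export
estimateConcentration <- function(image, masks, bathNM, cameraBg,
                                  autofluorCounts = 0, ref = NULL,
                                  satLevel = 65535) {
  .assertScalarNum(bathNM, "bathNM", min = 0, strict = TRUE)
  if (!any(masks@bath)) stop("bath mask is empty")
  if (!length(masks@cells)) stop("no cell masks")
  if (!is.null(ref)) image <- flatfieldCorrect(image, ref)
  ok <- image < satLevel
  if (!all(ok)) warning(sum(!ok), " saturated pixel(s) excluded from means")

  regionMean <- function(mask) {
    m <- mask & ok
    if (!any(m)) stop("compartment mask empty after saturation exclusion")
    c(mean(image[m]), sum(m))
  }
  iBath <- regionMean(masks@bath)[1] - cameraBg
  if (iBath <= 0) stop("bath intensity <= background; scene is uncalibratable")

  rows <- list()
  for (cell in names(masks@cells)) {
    comps <- c("total", "cytoplasm")
    if (cell %in% names(masks@nuclei)) comps <- c(comps, "nucleus")
    for (cp in comps) {
      rm <- regionMean(cellMask(masks, cell, cp))
      iIn <- rm[1] - cameraBg - autofluorCounts
      rows[[length(rows) + 1L]] <- data.frame(
        cell = cell, compartment = cp, conc_nM = bathNM * iIn / iBath,
        n_pixels = as.integer(rm[2]), corrected_mean_counts = iIn,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Posterior:anterior intensity ratio
#'
#' Splits the embryo by the perpendicular bisector of the AP axis and
#' returns the ratio of background-corrected mean intensities,
#' (posterior - bg) / (anterior - bg). The bisector is placed at the
#' midpoint of the embryo's extent along the axis.
#'
#' @param image counts matrix.
#' @param embryoMask logical matrix.
#' @param thetaRad AP-axis orientation (radians); posterior in the +axis
#'   direction.
#' @param cameraBg camera background counts.
#' @return posterior:anterior ratio (scalar).
#' @export
posteriorAnteriorRatio <- function(image, embryoMask, thetaRad, cameraBg) {
  if (!any(embryoMask)) stop("embryo mask is empty")
  g <- .pixelGrid(dim(image))
  s <- g$x * cos(thetaRad) + g$y * sin(thetaRad)
  sIn <- s[embryoMask]
  mid <- (min(sIn) + max(sIn)) / 2
  post <- embryoMask & s > mid
  ant <- embryoMask & s <= mid
  aMean <- mean(image[ant]) - cameraBg
  if (aMean <= 0) stop("anterior mean does not exceed background")
  (mean(image[post]) - cameraBg) / aMean
}
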