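## Mass-balance arithmetic of asymmetric inheritance down the P lineage:
## segregation fractions from daughter concentrations and volumes, the
## predicted maternally inherited concentration, and the decomposition of
## the observed concentration into inheritance and synthesis.

#' Segregation fraction from daughter concentrations and volumes
#'
#' The fraction of the mother's protein amount inherited by the germline
#' daughter, f = c_g v_g / (c_g v_g + c_s v_s). Concentrations may be
#' relative (only their ratio matters).
#'
#' @param cGerm,cSoma daughter concentrations (relative units), > 0 in sum.
#' @param vGerm,vSoma daughter volumes (pL), > 0.
#' @return segregation fraction in (0, 1).
#' @examples
#' segregationFraction(2.03, 1, 10.1, 14.7)  # 0.582 -> 58%
#' segregationFraction(1.91, 1, 4.2, 6.1)    # 0.568 -> 57%
#' @export
segregationFraction <- function(cGerm, cSoma, vGerm, vSoma) {
  .assertScalarNum(cGerm, "cGerm", 0); .assertScalarNum(cSoma, "cSoma", 0)
  .assertScalarNum(vGerm, "vGerm", 0, strict = TRUE)
  .assertScalarNum(vSoma, "vSoma", 0, strict = TRUE)
  aG <- cGerm * vGerm; aS <- cSoma * vSoma
  if (aG + aS <= 0) stop("both daughter amounts are zero")
  aG / (aG + aS)
}

#' Report a segregation fraction as a rounded percentage
#'
#' @param f fraction in (0, 1).
#' @return integer percent, rounded half-up.
#' @export
segregationPercent <- function(f) as.integer(roundHalfUp(100 * f))

#' Predicted concentration from asymmetric inheritance alone
#'
#' Starting from zygote concentration c0, the concentration attributable to
#' maternal protein after a volume fold-decrease phi and successive
#' divisions with segregation fractions f_i is c0 x phi x prod(f_i):
#' amounts shrink by each f_i while the volume shrinks phi-fold.
#'
#' @param c0NM zygote concentration (nM), >= 0.
#' @param phi volume fold-decrease (>= 1).
#' @param fractions numeric vector of segregation fractions, each in (0, 1);
#'   may be empty.
#' @return predicted concentration (nM).
#' @examples
#' predictInheritedConcentration(92, 6.4, c(0.58, 0.57))  # ~195 nM
#' @export
predictInheritedConcentration <- function(c0NM, phi, fractions = numeric()) {
  .assertScalarNum(c0NM, "c0NM", 0)
  .assertScalarNum(phi, "phi", 1)
  if (length(fractions) && any(fractions <= 0 | fractions >= 1))
    stop("segregation fractions must lie strictly in (0, 1)")
  c0NM * phi * prod(fractions)
}

#' Fraction of the observed concentration attributable to synthesis
#'
#' 1 - predicted/observed, clamped to [0, 1]; the result carries an
#' attribute `clamped` when clamping occurred (i.e. the prediction exceeded
#' the observation).
#'
#' @param predictedNM inheritance-only prediction (nM), >= 0.
#' @param observedNM observed concentration (nM), > 0.
#' @return synthesized fraction in [0, 1].
#' @examples
#' synthesizedFraction(195, 424)  # ~0.54: roughly half is newly made
#' @export
synthesizedFraction <- function(predictedNM, observedNM) {
  .assertScalarNum(predictedNM, "predictedNM", 0)
  .assertScalarNum(observedNM, "observedNM", 0, strict = TRUE)
  raw <- 1 - predictedNM / observedNM
  out <- min(max(raw, 0), 1)
  attr(out, "clamped") <- (raw != out)
  out
}

#' Concentration fold change
#'
#' @param cStartNM starting concentration (nM), > 0.
#' @param cEndNM final concentration (nM).
#' @return cEnd / cStart, unrounded.
#' @examples
#' concentrationFoldChange(92, 424)  # 4.61
#' @export
concentrationFoldChange <- function(cStartNM, cEndNM) {
  .assertScalarNum(cStartNM, "cStartNM", 0, strict = TRUE)
  .assertScalarNum(cEndNM, "cEndNM")
  cEndNM / cStartNM
}

#' Fit partitioning measurements from a time-lapse
#'
#' For each division, takes the first frame at which both daughter masks
#' exist ("just after division"), measures background-corrected daughter
#' mean intensities, normalizes so the somatic daughter is 1, and converts
#' to a segregation fraction with the daughters' volumes via
#' [segregationFraction()].
#'
#' @param tl a rendered \linkS4class{LineageTimelapse}.
#' @param ref optional \linkS4class{IlluminationReference} for flat-field
#'   correction of each frame.
#' @param autofluorCounts autofluorescence counts to subtract (as measured
#'   from a wild-type embryo under the same optics), default 0.
#' @param volumesPL named daughter volumes (pL); defaults to the volumes
#'   recorded in the time-lapse parameters.
#' @return data.frame(mother, germ, soma, time_s, rel_conc_germ,
#'   rel_conc_soma, volume_germ_pL, volume_soma_pL, fraction).
#' @export
fitPartitioning <- function(tl, ref = NULL, autofluorCounts = 0,
                            volumesPL = NULL) {
  if (!length(tl@frames)) stop("time-lapse has no rendered frames")
  div <- tl@params@divisions
  if (!nrow(div)) stop("no divisions annotated")
  if (is.null(volumesPL)) volumesPL <- tl@params@volumesPL
  rows <- list()
  for (i in seq_len(nrow(div))) {
    d <- div[i, ]
    idx <- which(vapply(tl@masks, function(m)
      all(c(d$germ, d$soma) %in% names(m@cells)), logical(1)) &
      tl@times >= d$time_s)
    if (!length(idx)) stop("no post-division frame with both daughter masks for ",
                           d$mother)
    j <- idx[1]
    img <- tl@frames[[j]]
    if (!is.null(ref)) img <- flatfieldCorrect(img, ref)
    msk <- tl@masks[[j]]
    for (nm in c(d$germ, d$soma)) if (!nm %in% names(msk@cells))
      stop("missing daughter mask: ", nm)
    bg <- measureCameraBackground(img, "outside_embryo", mask = !msk@embryo)
    mGerm <- mean(img[msk@cells[[d$germ]]]) - bg - autofluorCounts
    mSoma <- mean(img[msk@cells[[d$soma]]]) - bg - autofluorCounts
    relG <- mGerm / mSoma
    f <- segregationFraction(relG, 1, volumesPL[[d$germ]], volumesPL[[d$soma]])
    rows[[i]] <- data.frame(
      mother = d$mother, germ = d$germ, soma = d$soma, time_s = tl@times[j],
      rel_conc_germ = relG, rel_conc_soma = 1,
      volume_germ_pL = volumesPL[[d$germ]], volume_soma_pL = volumesPL[[d$soma]],
      fraction = f, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
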