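## End-to-end orchestration: configuration, the printed-number arithmetic of
## the inheritance model, and a self-validating synthetic suite tying
## generation -> calibration -> partitioning -> screen statistics together.

#' Default run configuration
#'
#' A validated flat list of every tunable the pipeline uses. Unknown keys
#' are rejected so that typos in overrides fail loudly.
#'
#' @param seed master seed; every stochastic stage derives child seeds from
#'   it via [childSeed()].
#' @param ... overrides of default entries.
#' @return named list with class "pieQuantConfig".
#' @export
defaultRunConfig <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # measured inputs of the inheritance arithmetic
    c0_nM = 92, phi = 6.4, observed_p2_nM = 424,
    conc_ratio_div1 = 2.03, conc_ratio_div2 = 1.91,
    vol_germ_div1 = 10.1, vol_soma_div1 = 14.7,
    vol_germ_div2 = 4.2, vol_soma_div2 = 6.1,
    # imaging model
    dim = c(100L, 150L), vignetting = 0.25, camera_offset = 100,
    read_noise_sd = 5, photons_per_nM = 5, autofluorescence_nM_equiv = 20,
    bath_1cell_nM = 150, bath_late_nM = 300,
    # analysis options
    alpha = 0.05, min_n_stage1 = 5, min_n_stage2 = 11,
    normalization = "prebleach", ratio_decimals = 2)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "pieQuantConfig"
  cfg
}

#' Reproduce the inheritance-model arithmetic and its synthetic check
#'
#' Runs the mass-balance arithmetic on the measured inputs (daughter
#' concentration ratios and volumes, zygote concentration, volume fold
#' decrease): segregation fractions and percentages for both divisions,
#' the somatic:germline volume ratios, the inheritance-only P2 prediction,
#' the synthesized fraction of the observed concentration, and the overall
#' fold change. Also renders one synthetic zygote calibration scene at the
#' configured conditions and reports the estimator's recovery error as an
#' end-to-end check. A `phi_provenance` field flags non-default volume
#' fold-decrease inputs.
#'
#' @param config a configuration from [defaultRunConfig()].
#' @param jsonPath optional path to write the report as JSON.
#' @return report list.
#' @export
reproduceFigure1 <- function(config = defaultRunConfig(), jsonPath = NULL) {
  stopifnot(inherits(config, "pieQuantConfig"))
  f1 <- segregationFraction(config$conc_ratio_div1, 1,
                            config$vol_germ_div1, config$vol_soma_div1)
  f2 <- segregationFraction(config$conc_ratio_div2, 1,
                            config$vol_germ_div2, config$vol_soma_div2)
  pct1 <- segregationPercent(f1); pct2 <- segregationPercent(f2)
  vr1 <- volumeRatio(config$vol_germ_div1, config$vol_soma_div1, config$ratio_decimals)
  vr2 <- volumeRatio(config$vol_germ_div2, config$vol_soma_div2, config$ratio_decimals)
  predicted <- predictInheritedConcentration(config$c0_nM, config$phi,
                                             c(pct1, pct2) / 100)
  synth <- synthesizedFraction(predicted, config$observed_p2_nM)
  fold <- concentrationFoldChange(config$c0_nM, config$observed_p2_nM)

  # end-to-end synthetic check: render a zygote at c0 in the 1-cell bath and
  # recover its concentration through the full correction chain
  op <- OpticsModel(config$dim, vignetting = config$vignetting,
                    cameraOffset = config$camera_offset,
                    readNoiseSd = config$read_noise_sd,
                    photonsPerNM = config$photons_per_nM,
                    autofluorescenceNMEquiv = config$autofluorescence_nM_equiv)
  geo <- standardEmbryoGeometry("1cell", dim = config$dim)
  rec <- .recoverScene(geo, op, config$bath_1cell_nM,
                       c(P0 = config$c0_nM), seed = childSeed(config$seed, 101))
  report <- list(
    segregation_fraction_div1 = f1, segregation_fraction_div2 = f2,
    segregation_percent_div1 = pct1, segregation_percent_div2 = pct2,
    volume_ratio_div1 = vr1, volume_ratio_div2 = vr2,
    predicted_inherited_p2_nM = predicted,
    observed_p2_nM = config$observed_p2_nM,
    synthesized_fraction = as.numeric(synth),
    fold_change_p0_to_p2 = fold,
    phi = config$phi,
    phi_provenance = if (identical(config$phi, 6.4)) "default"
                     else sprintf("user-supplied phi = %g", config$phi),
    synthetic_recovery = rec,
    seed = config$seed)
  if (!is.null(jsonPath))
    jsonlite::write_json(report, jsonPath, auto_unbox = TRUE, digits = NA)
  report
}

# render one scene under the given truth and run the full estimator chain;
# returns truth, estimate and relative error for the whole-cell compartment
.recoverScene <- function(geometry, optics, bathNM, trueConc, seed,
                          nBathImages = 10L) {
  ref <- buildIlluminationReference(
    makeBathReferenceImages(optics, bathNM, n = nBathImages, seed = seed))
  blank <- .renderImage(matrix(0, geometry@dim[1], geometry@dim[2]), optics,
                        seed = childSeed(seed, 90), noise = TRUE)
  bg <- measureCameraBackground(blank, "m9_blank")
  n2 <- makeCalibrationScene(geometry, optics, bathNM,
                             setNames(numeric(length(geometry@cells)),
                                      names(geometry@cells)),
                             seed = childSeed(seed, 91))
  af <- measureAutofluorescence(sceneImage(n2), sceneMasks(n2), bg, ref = ref)
  sc <- makeCalibrationScene(geometry, optics, bathNM, trueConc,
                             seed = childSeed(seed, 92))
  est <- estimateConcentration(sceneImage(sc), sceneMasks(sc), bathNM, bg, af, ref)
  cell <- names(trueConc)[1]
  true <- sceneTruth(sc)$conc[[cell]]$total
  got <- est$conc_nM[est$cell == cell & est$compartment == "total"]
  list(cell = cell, true_nM = true, estimated_nM = got,
       relative_error = (got - true) / true)
}

#' Run the synthetic validation suite
#'
#' Executes four module-level recovery studies at reduced problem sizes:
#' estimator recovery over seeded noisy calibration scenes, the partitioning
#' round-trip at the measured segregation fractions, the power and type-I
#' behaviour of the paired synthesis test, and the two-stage screen's
#' false-discovery and sensitivity. Each metric is compared with its
#' declared tolerance; the returned list carries per-metric values and pass
#' flags plus an overall `pass`.
#'
#' @param config a configuration from [defaultRunConfig()].
#' @param nRecovery number of calibration scenes.
#' @param nPower,nNull replicates for the synthesis-test power and null
#'   studies.
#' @param nScreens replicate screens for the two-stage study.
#' @param jsonPath optional path to write metrics JSON.
#' @return metrics list with element `pass`.
#' @export
runSyntheticSuite <- function(config = defaultRunConfig(), nRecovery = 25L,
                              nPower = 60L, nNull = 60L, nScreens = 2L,
                              jsonPath = NULL) {
  stopifnot(inherits(config, "pieQuantConfig"))
  seed <- config$seed
  op <- OpticsModel(config$dim, vignetting = config$vignetting,
                    cameraOffset = config$camera_offset,
                    readNoiseSd = config$read_noise_sd,
                    photonsPerNM = config$photons_per_nM,
                    autofluorescenceNMEquiv = config$autofluorescence_nM_equiv)
  geo <- standardEmbryoGeometry("1cell", dim = config$dim)

  errs <- vapply(seq_len(nRecovery), function(i) {
    .recoverScene(geo, op, config$bath_1cell_nM, c(P0 = config$c0_nM),
                  seed = childSeed(seed, 1000 + i))$relative_error
  }, numeric(1))
  recovery <- list(bias = mean(errs), sd = stats::sd(errs),
                   pass = abs(mean(errs)) < 0.02 && stats::sd(errs) < 0.05)

  rt <- .partitioningRoundTrip(config, f = 0.58, seed = childSeed(seed, 2000))
  roundTrip <- list(true_f = 0.58, fitted_f = rt,
                    pass = abs(rt - 0.58) < 0.03)

  pw <- .synthesisPowerStudy(config, nPower = nPower, nNull = nNull,
                             seed = childSeed(seed, 3000))
  synth <- c(pw, list(pass = pw$power > 0.9 && pw$type1 <= 0.1))

  scr <- .screenStudy(config, nScreens = nScreens, seed = childSeed(seed, 4000))
  screen <- c(scr, list(pass = scr$fdr < 0.1 && scr$sensitivity > 0.9))

  metrics <- list(estimator_recovery = recovery, partitioning_round_trip = roundTrip,
                  synthesis_test = synth, screen = screen,
                  pass = recovery$pass && roundTrip$pass && synth$pass && screen$pass,
                  seed = seed)
  if (!is.null(jsonPath))
    jsonlite::write_json(metrics, jsonPath, auto_unbox = TRUE, digits = NA)
  metrics
}

# simulate one division with fraction f, render, and fit it back
.partitioningRoundTrip <- function(config, f, seed, noise = TRUE,
                                   kSyn = 0, kDeg = 0) {
  dim <- config$dim
  op <- OpticsModel(dim, vignetting = config$vignetting,
                    cameraOffset = config$camera_offset,
                    readNoiseSd = if (noise) config$read_noise_sd else 0,
                    photonsPerNM = config$photons_per_nM,
                    autofluorescenceNMEquiv = config$autofluorescence_nM_equiv)
  geos <- list(standardEmbryoGeometry("1cell", dim = dim, nuclei = FALSE),
               standardEmbryoGeometry("2cell", dim = dim, nuclei = FALSE))
  par <- LineageParams(
    initialConcentrationNM = config$c0_nM,
    volumesPL = c(P0 = 26.88, AB = 14.7, P1 = 10.1),
    divisions = data.frame(time_s = 60, mother = "P0", germ = "P1",
                           soma = "AB", f = f, stringsAsFactors = FALSE),
    kSyn = c(P0 = kSyn), kDeg = c(AB = kDeg))
  tl <- .simulateTimelapse(geos, par, op, intervalS = 30, durationS = 90,
                           seed = seed, render = TRUE, noise = noise)
  ref <- .opticsReference(op, seed = childSeed(seed, 7))
  af <- op@photonsPerNM * op@autofluorescenceNMEquiv *
    mean(op@illuminationField[computeMasks(geos[[1]])@embryo])
  fitPartitioning(tl, ref = ref, autofluorCounts = af)$fraction[1]
}

# noise-free-capable wrapper around makeLineageTimelapse
.simulateTimelapse <- function(geos, par, op, intervalS, durationS, seed,
                               render, noise = TRUE) {
  tl <- makeLineageTimelapse(geos, par, op, intervalS = intervalS,
                             durationS = durationS, seed = seed, render = FALSE)
  if (!render) return(tl)
  frames <- vector("list", length(tl@times))
  for (i in seq_along(tl@times)) {
    msk <- tl@masks[[i]]
    tr <- tl@truth[tl@truth$time_s == tl@times[i], ]
    nmMap <- matrix(0, nrow(msk@embryo), ncol(msk@embryo))
    for (j in seq_len(nrow(tr))) {
      cm <- msk@cells[[tr$cell[j]]]
      nmMap[cm] <- tr$conc_visible_nM[j] +
        op@autofluorescenceNMEquiv * tr$af_factor[j]
    }
    frames[[i]] <- .renderImage(nmMap, op, seed = childSeed(seed, i), noise = noise)
  }
  tl@frames <- frames
  tl
}

# noise-free flat-field reference matching an optics model: the expected
# image of a uniform 1-nM bath (any level cancels in the ratio)
.opticsReference <- function(op, seed = 1L, noise = FALSE, bathNM = 300) {
  img <- .renderImage(matrix(bathNM, nrow(op@illuminationField),
                             ncol(op@illuminationField)), op,
                      seed = seed, noise = noise)
  buildIlluminationReference(list(img))
}

# FRAP synthesis-test power and type-I error at trace level
.synthesisPowerStudy <- function(config, nPower, nNull, seed,
                                 nEmbryos = 6L) {
  op <- OpticsModel(config$dim, vignetting = 0,
                    cameraOffset = config$camera_offset,
                    readNoiseSd = config$read_noise_sd,
                    photonsPerNM = config$photons_per_nM,
                    autofluorescenceNMEquiv = config$autofluorescence_nM_equiv)
  geo1 <- standardEmbryoGeometry("1cell", dim = config$dim, nuclei = FALSE)
  geos <- list(geo1,
               standardEmbryoGeometry("2cell", dim = config$dim, nuclei = FALSE))
  # ground truth is deterministic per synthesis rate; simulate it once and
  # draw per-embryo measurement noise around it in each replicate
  truthFor <- function(kSyn) {
    par <- LineageParams(
      initialConcentrationNM = config$c0_nM,
      volumesPL = c(P0 = 26.88, AB = 14.7, P1 = 10.1),
      divisions = data.frame(time_s = 600, mother = "P0", germ = "P1",
                             soma = "AB", f = 0.58, stringsAsFactors = FALSE),
      kSyn = c(P0 = kSyn, P1 = kSyn), kDeg = numeric(),
      bleaches = frapBleachEvent(geo1, survival = 0.4, timeS = 75))
    makeLineageTimelapse(geos, par, op, intervalS = 15, durationS = 1500,
                         seed = 1L, render = FALSE)
  }
  oneRep <- function(tl, s) {
    traces <- lapply(seq_len(nEmbryos), function(e)
      simulateTraceMeasurements(tl, nPixels = 1500, seed = childSeed(s, e)))
    synthesisTest(traces, "P1")$p_value
  }
  kSynDefault <- tuneSynthesisRate(
    config$c0_nM, c(P0 = 26.88, P1 = 10.1, P2 = 4.2),
    data.frame(time_s = c(600, 1500), f = c(0.58, 0.57)), 2700, share = 0.5)
  tlSyn <- truthFor(kSynDefault)
  tlNull <- truthFor(0)
  pPow <- vapply(seq_len(nPower), function(i)
    oneRep(tlSyn, childSeed(seed, i)), numeric(1))
  pNull <- vapply(seq_len(nNull), function(i)
    oneRep(tlNull, childSeed(seed, 10000 + i)), numeric(1))
  list(power = mean(pPow < config$alpha), type1 = mean(pNull < config$alpha),
       n_embryos = nEmbryos)
}

# pooled two-stage screen confusion over replicate screens
.screenStudy <- function(config, nScreens, seed, nClones = 249L,
                         trueFrac = 0.05, multRange = c(0.35, 0.65),
                         noiseCv = 0.15) {
  tp <- fp <- fn <- 0
  nTrue <- round(trueFrac * nClones)
  for (r in seq_len(nScreens)) {
    s <- childSeed(seed, r)
    set.seed(s)
    eff <- stats::runif(nTrue, multRange[1], multRange[2])
    names(eff) <- sprintf("clone_%03d", sample.int(nClones, nTrue))
    tab <- makeScreenDataset(nClones, c(config$min_n_stage1, config$min_n_stage2),
                             controlMean = 500, effectSizes = eff,
                             noiseCv = noiseCv, seed = childSeed(s, 1))
    hits <- callHits(tab, alpha = config$alpha,
                     minNStage1 = config$min_n_stage1,
                     minNStage2 = config$min_n_stage2)
    isTrue <- hits$clone %in% names(eff)
    tp <- tp + sum(hits$hit_stage2 & isTrue)
    fp <- fp + sum(hits$hit_stage2 & !isTrue)
    fn <- fn + sum(!hits$hit_stage2 & isTrue)
  }
  list(fdr = if (tp + fp > 0) fp / (tp + fp) else 0,
       sensitivity = tp / (tp + fn), n_screens = nScreens,
       n_clones = nClones)
}
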