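## Synthetic scene generation: calibration images, lineage time-lapses,
## membrane z-stacks and screen datasets, all with known ground truth.

#' Rasterize an embryo geometry into compartment masks
#'
#' Pixels inside the embryo ellipse are assigned to cells by their normalized
#' AP coordinate, so the cells tile the embryo exactly; the bath is the
#' complement of the embryo within the frame.
#'
#' @param geometry an \linkS4class{EmbryoGeometry}.
#' @return a \linkS4class{CompartmentMasks}.
#' @export
computeMasks <- function(geometry) {
  dim <- geometry@dim
  emb <- .ellipseMask(dim, geometry@center[1], geometry@center[2],
                      geometry@semiAxes[1], geometry@semiAxes[2], geometry@thetaRad)
  u <- .apCoordinate(dim, geometry@center[1], geometry@center[2],
                     geometry@semiAxes[1], geometry@thetaRad)
  cells <- lapply(geometry@cells, function(iv) {
    hi <- if (iv[2] >= 1 - 1e-9) Inf else iv[2]
    emb & u >= iv[1] & u < hi
  })
  names(cells) <- names(geometry@cells)
  nuclei <- list()
  for (nm in names(geometry@nuclei)) {
    sp <- geometry@nuclei[[nm]]
    pos <- geometry@center + (2 * sp[["u"]] - 1) * geometry@semiAxes[1] *
      c(cos(geometry@thetaRad), sin(geometry@thetaRad))
    nuc <- .ellipseMask(dim, pos[1], pos[2], sp[["r"]], sp[["r"]])
    if (any(nuc & !cells[[nm]]))
      stop("nucleus of cell '", nm, "' is not strictly inside the cell")
    nuclei[[nm]] <- nuc
  }
  new("CompartmentMasks", embryo = emb, bath = !emb, cells = cells,
      nuclei = nuclei, pixelSizeUm = geometry@pixelSizeUm)
}

# forward model: expected photon signal ppn*nM, Poisson shot noise, then
# illumination gain, camera offset, Gaussian read noise; counts are rounded
# and clamped to the 16-bit camera range
.renderImage <- function(nmMap, optics, seed = NULL, noise = TRUE) {
  lambda <- optics@photonsPerNM * nmMap
  if (noise) {
    if (!is.null(seed)) set.seed(seed)
    sig <- matrix(stats::rpois(length(lambda), lambda), nrow(lambda), ncol(lambda))
    img <- sig * optics@illuminationField + optics@cameraOffset +
      matrix(stats::rnorm(length(lambda), 0, optics@readNoiseSd), nrow(lambda), ncol(lambda))
    img <- round(img)
  } else {
    img <- lambda * optics@illuminationField + optics@cameraOffset
  }
  pmin(pmax(img, 0), 65535)
}

#' Generate a synthetic bath-calibration scene
#'
#' Renders a midplane image of an embryo bathed in a fluorophore solution of
#' known concentration. Each pixel is drawn as
#' Poisson(photonsPerNM x (local nM + autofluorescence inside the embryo))
#' x illumination gain + camera offset + Gaussian read noise. The truth
#' record stores every ground-truth concentration.
#'
#' @param geometry an \linkS4class{EmbryoGeometry}.
#' @param optics an \linkS4class{OpticsModel} whose field matches the
#'   geometry's dimensions.
#' @param bathNM bath concentration (nM), >= 0.
#' @param trueConc named numeric of true intracellular concentrations (nM).
#'   Names are cell names (uniform across the cell) or "cell:cytoplasm" /
#'   "cell:nucleus" for compartment-specific values.
#' @param seed integer seed; identical inputs and seed give identical scenes.
#' @param noise simulate shot and read noise (default TRUE); FALSE renders
#'   the expected image.
#' @return a \linkS4class{CalibrationScene}.
#' @examples
#' geo <- standardEmbryoGeometry("1cell", dim = c(60, 90))
#' op <- OpticsModel(c(60, 90))
#' sc <- makeCalibrationScene(geo, op, bathNM = 150, c(P0 = 92), seed = 1)
#' @export
makeCalibrationScene <- function(geometry, optics, bathNM, trueConc, seed,
                                 noise = TRUE) {
  .assertScalarNum(bathNM, "bathNM", min = 0)
  if (!identical(dim(optics@illuminationField), as.integer(geometry@dim)))
    stop("optics illumination field does not match the geometry's dimensions")
  masks <- computeMasks(geometry)
  known <- c(names(geometry@cells),
             paste0(rep(names(geometry@cells), each = 2), ":",
                    c("cytoplasm", "nucleus")))
  bad <- setdiff(names(trueConc), known)
  if (length(bad))
    stop("unknown compartment name(s): ", paste(bad, collapse = ", "))

  nmMap <- matrix(0, geometry@dim[1], geometry@dim[2])
  nmMap[masks@bath] <- bathNM
  truthConc <- list()
  for (cell in names(geometry@cells)) {
    base <- if (cell %in% names(trueConc)) unname(trueConc[[cell]]) else 0
    cyt <- if (paste0(cell, ":cytoplasm") %in% names(trueConc))
      unname(trueConc[[paste0(cell, ":cytoplasm")]]) else base
    nuc <- if (paste0(cell, ":nucleus") %in% names(trueConc))
      unname(trueConc[[paste0(cell, ":nucleus")]]) else base
    cytMask <- cellMask(masks, cell, "cytoplasm")
    nmMap[cytMask] <- cyt
    hasNuc <- cell %in% names(masks@nuclei)
    if (hasNuc) nmMap[cellMask(masks, cell, "nucleus")] <- nuc
    nCyt <- sum(cytMask)
    nNuc <- if (hasNuc) sum(masks@nuclei[[cell]]) else 0L
    truthConc[[cell]] <- list(
      cytoplasm = cyt, nucleus = if (hasNuc) nuc else NA_real_,
      total = (cyt * nCyt + nuc * nNuc) / (nCyt + nNuc))
  }
  nmMap[masks@embryo] <- nmMap[masks@embryo] + optics@autofluorescenceNMEquiv

  img <- .renderImage(nmMap, optics, seed = seed, noise = noise)
  new("CalibrationScene", image = img, masks = masks,
      truth = list(bath_nM = bathNM, conc = truthConc,
                   autofluorescence_nM_equiv = optics@autofluorescenceNMEquiv,
                   photons_per_nM = optics@photonsPerNM,
                   camera_offset = optics@cameraOffset, seed = seed))
}

# advance one pool amount A (nM pL) over dt with source kSyn*V and decay kDeg
.advanceAmount <- function(A, kSyn, kDeg, V, dt) {
  if (kDeg == 0) A + kSyn * V * dt
  else A * exp(-kDeg * dt) + (kSyn * V / kDeg) * (1 - exp(-kDeg * dt))
}

#' Simulate a lineage time-lapse with divisions, synthesis and bleaching
#'
#' Per-cell concentration follows dC/dt = kSyn - kDeg C between events. At a
#' division the mother's amount A splits into f A for the germline daughter
#' and (1 - f) A for the somatic daughter; daughter concentrations are
#' amount / volume with the daughters' own volumes. A bleach event multiplies
#' the fluorescent (matured) amount of each cell by 1 - p + p s, where p is
#' the fraction of the cell's area inside the bleach circle and s the
#' survival fraction; embryo autofluorescence inside the circle is bleached
#' by the same factor. Cells are treated as well mixed. A nonzero maturation
#' delay makes newly synthesized protein invisible until the delay elapses.
#'
#' @param geometries list of \linkS4class{EmbryoGeometry}, one per stage
#'   (length = number of divisions + 1, in temporal order).
#' @param params a \linkS4class{LineageParams}.
#' @param optics an \linkS4class{OpticsModel}.
#' @param intervalS frame interval (s), > 0.
#' @param durationS total duration (s).
#' @param seed integer seed.
#' @param render render noisy image frames (TRUE) or produce ground-truth
#'   traces only (FALSE).
#' @return a \linkS4class{LineageTimelapse}.
#' @export
makeLineageTimelapse <- function(geometries, params, optics, intervalS,
                                 durationS, seed = 1L, render = TRUE) {
  .assertScalarNum(intervalS, "intervalS", min = 0, strict = TRUE)
  div <- params@divisions
  if (length(geometries) != nrow(div) + 1L)
    stop("need one geometry per stage: ", nrow(div) + 1L, " expected")
  masksByStage <- lapply(geometries, computeMasks)

  frameTimes <- seq(0, durationS, by = intervalS)
  events <- data.frame(time = numeric(), type = character(), idx = integer())
  if (nrow(div)) events <- rbind(events, data.frame(time = div$time_s, type = "division", idx = seq_len(nrow(div))))
  bl <- params@bleaches
  if (nrow(bl)) events <- rbind(events, data.frame(time = bl$time_s, type = "bleach", idx = seq_len(nrow(bl))))
  events <- rbind(events, data.frame(time = frameTimes, type = "frame", idx = seq_along(frameTimes)))
  # at equal times process divisions, then bleaches, then record the frame
  events <- events[order(events$time, match(events$type, c("division", "bleach", "frame"))), ]

  V <- params@volumesPL
  firstCells <- names(geometries[[1]]@cells)
  state <- list(
    stage = 1L,
    cells = firstCells,
    matA = structure(params@initialConcentrationNM * V[firstCells], names = firstCells),
    synA = structure(rep(0, length(firstCells)), names = firstCells),
    afFac = structure(rep(1, length(firstCells)), names = firstCells),
    immature = list()  # entries: list(cell, amount0, t0)
  )
  rateOf <- function(tbl, cell) if (cell %in% names(tbl)) unname(tbl[[cell]]) else 0

  advance <- function(state, t0, t1) {
    if (t1 <= t0) return(state)
    delay <- params@maturationDelayS
    for (cell in state$cells) {
      ks <- rateOf(params@kSyn, cell); kd <- rateOf(params@kDeg, cell)
      dt <- t1 - t0
      state$matA[cell] <- .advanceAmount(state$matA[cell], 0, kd, V[cell], dt)
      if (delay == 0) {
        state$synA[cell] <- .advanceAmount(state$synA[cell], ks, kd, V[cell], dt)
      } else {
        state$synA[cell] <- .advanceAmount(state$synA[cell], 0, kd, V[cell], dt)
        if (ks > 0)  # book synthesis in sub-steps; it matures `delay` later
          for (ts in seq(t0, t1 - 1e-9, by = min(intervalS / 10, t1 - t0)))
            state$immature[[length(state$immature) + 1L]] <-
              list(cell = cell, amount = ks * V[cell] * min(intervalS / 10, t1 - ts),
                   t0 = ts)
      }
    }
    if (delay > 0 && length(state$immature)) {
      keep <- logical(length(state$immature))
      for (i in seq_along(state$immature)) {
        e <- state$immature[[i]]
        if (!e$cell %in% state$cells) next  # divided away; handled at division
        if (e$t0 + delay <= t1) {
          kd <- rateOf(params@kDeg, e$cell)
          state$synA[e$cell] <- state$synA[e$cell] + e$amount * exp(-kd * delay)
        } else keep[i] <- TRUE
      }
      state$immature <- state$immature[keep]
    }
    state
  }

  applyDivision <- function(state, i) {
    d <- div[i, ]
    if (!d$mother %in% state$cells) stop("division of absent cell: ", d$mother)
    for (nm in c(d$germ, d$soma)) if (!nm %in% names(V))
      stop("no volume for daughter cell: ", nm)
    f <- d$f
    split <- function(vec) {
      vec[d$germ] <- f * vec[[d$mother]]
      vec[d$soma] <- (1 - f) * vec[[d$mother]]
      vec[setdiff(names(vec), d$mother)]
    }
    state$matA <- split(state$matA)
    state$synA <- split(state$synA)
    af <- state$afFac
    af[c(d$germ, d$soma)] <- af[[d$mother]]
    state$afFac <- af[setdiff(names(af), d$mother)]
    state$immature <- lapply(state$immature, function(e) {
      if (e$cell == d$mother) {
        # split immature pool: emit germ share here, soma share appended later
        e$soma_amount <- (1 - f) * e$amount
        e$amount <- f * e$amount; e$cell <- d$germ
      }
      e
    })
    extra <- Filter(function(e) !is.null(e$soma_amount), state$immature)
    state$immature <- lapply(state$immature, function(e) { e$soma_amount <- NULL; e })
    for (e in extra) {
      e$cell <- d$soma; e$amount <- e$soma_amount; e$soma_amount <- NULL
      state$immature[[length(state$immature) + 1L]] <- e
    }
    state$cells <- c(setdiff(state$cells, d$mother), d$germ, d$soma)
    state$stage <- state$stage + 1L
    state
  }

  applyBleach <- function(state, i) {
    b <- bl[i, ]
    msk <- masksByStage[[state$stage]]
    geo <- geometries[[state$stage]]
    g <- .pixelGrid(geo@dim)
    rpx <- (b$diameter_um / 2) / geo@pixelSizeUm
    circle <- (g$x - b$cx)^2 + (g$y - b$cy)^2 <= rpx^2
    if (!any(circle & msk@embryo))
      stop("bleach event at t=", b$time_s, " lies entirely outside the embryo")
    for (cell in state$cells) {
      cm <- msk@cells[[cell]]
      p <- sum(cm & circle) / sum(cm)
      fac <- 1 - p + p * b$survival
      state$matA[cell] <- state$matA[cell] * fac
      state$synA[cell] <- state$synA[cell] * fac
      state$afFac[cell] <- state$afFac[cell] * fac
    }
    state
  }

  truth <- vector("list", length(frameTimes))
  frames <- if (render) vector("list", length(frameTimes)) else list()
  masksOut <- vector("list", length(frameTimes))
  tNow <- 0
  for (r in seq_len(nrow(events))) {
    ev <- events[r, ]
    state <- advance(state, tNow, ev$time)
    tNow <- ev$time
    if (ev$type == "division") state <- applyDivision(state, ev$idx)
    else if (ev$type == "bleach") state <- applyBleach(state, ev$idx)
    else {
      i <- ev$idx
      immByCell <- structure(rep(0, length(state$cells)), names = state$cells)
      for (e in state$immature)
        if (e$cell %in% state$cells)
          immByCell[e$cell] <- immByCell[e$cell] + e$amount
      cells <- state$cells
      visC <- (state$matA[cells] + state$synA[cells]) / V[cells]
      totC <- visC + immByCell[cells] / V[cells]
      truth[[i]] <- data.frame(
        time_s = tNow, cell = cells, conc_visible_nM = unname(visC),
        conc_total_nM = unname(totC), mat_amount = unname(state$matA[cells]),
        syn_amount = unname(state$synA[cells] + immByCell[cells]),
        af_factor = unname(state$afFac[cells]), volume_pL = unname(V[cells]),
        stringsAsFactors = FALSE)
      msk <- masksByStage[[state$stage]]
      masksOut[[i]] <- msk
      if (render) {
        geo <- geometries[[state$stage]]
        nmMap <- matrix(0, geo@dim[1], geo@dim[2])
        for (cell in cells) {
          cm <- msk@cells[[cell]]
          nmMap[cm] <- visC[[cell]] +
            optics@autofluorescenceNMEquiv * state$afFac[[cell]]
        }
        frames[[i]] <- .renderImage(nmMap, optics,
                                    seed = childSeed(seed, i), noise = TRUE)
      }
    }
  }
  new("LineageTimelapse", times = frameTimes, frames = frames,
      masks = masksOut, truth = do.call(rbind, truth), params = params,
      optics = optics, geometries = geometries)
}

#' Render repeated images of a uniform fluorophore bath
#'
#' Full-frame images of fluorophore solution only (no embryo), the raw
#' material for [buildIlluminationReference()]. Averaging n of them shrinks
#' the reference noise by about sqrt(n).
#'
#' @param optics an \linkS4class{OpticsModel}.
#' @param bathNM bath concentration (nM).
#' @param n number of images.
#' @param seed integer seed.
#' @param noise simulate noise (default TRUE).
#' @return list of counts matrices.
#' @export
makeBathReferenceImages <- function(optics, bathNM, n = 10L, seed = 1L,
                                    noise = TRUE) {
  d <- dim(optics@illuminationField)
  lapply(seq_len(n), function(i)
    .renderImage(matrix(bathNM, d[1], d[2]), optics,
                 seed = childSeed(seed, i), noise = noise))
}

#' Generate a synthetic membrane-marker z-stack
#'
#' Cells are 3D ellipsoids rendered into an anisotropic voxel grid: a bright
#' membrane band on each ellipsoid surface over a dim interior, with Poisson
#' shot noise, per-slice illumination gain, camera offset and read noise.
#' Ground truth is the analytic ellipsoid volume 4/3 pi a b c (1 pL =
#' 1000 um^3) and the exact voxel label volume.
#'
#' @param ellipsoids named list; each element a list with `center` (z, y, x)
#'   and `semiAxes` (z, y, x), micrometres.
#' @param voxelSizeUm voxel sizes (z, y, x), micrometres, all > 0.
#' @param dim grid size (nz, ny, nx).
#' @param optics an \linkS4class{OpticsModel}; its illumination field must be
#'   (ny, nx). Autofluorescence is ignored here.
#' @param seed integer seed.
#' @param membraneNM,interiorNM nM-equivalent brightness of the membrane band
#'   and the cell interior.
#' @param bandUm half-thickness of the membrane band (micrometres).
#' @return list with `stack` (3D counts array), `labels` (a
#'   \linkS4class{LabeledVolume} ground-truth segmentation) and
#'   `trueVolumesPL` (named numeric, analytic volumes).
#' @export
makeMembraneStack <- function(ellipsoids, voxelSizeUm, dim, optics, seed = 1L,
                              membraneNM = 300, interiorNM = 15, bandUm = 0.5) {
  if (any(voxelSizeUm <= 0)) stop("voxel sizes must be > 0")
  nz <- dim[1]; ny <- dim[2]; nx <- dim[3]
  zc <- (seq_len(nz) - 0.5) * voxelSizeUm[1]
  yc <- (seq_len(ny) - 0.5) * voxelSizeUm[2]
  xc <- (seq_len(nx) - 0.5) * voxelSizeUm[3]
  Z <- array(rep(zc, times = ny * nx), c(nz, ny, nx))
  Y <- array(rep(rep(yc, each = nz), times = nx), c(nz, ny, nx))
  X <- array(rep(xc, each = nz * ny), c(nz, ny, nx))

  labels <- array(0L, c(nz, ny, nx))
  nmMap <- array(0, c(nz, ny, nx))
  trueV <- numeric(0)
  for (i in seq_along(ellipsoids)) {
    e <- ellipsoids[[i]]
    rho <- sqrt(((Z - e$center[1]) / e$semiAxes[1])^2 +
                ((Y - e$center[2]) / e$semiAxes[2])^2 +
                ((X - e$center[3]) / e$semiAxes[3])^2)
    inside <- rho <= 1
    if (any(labels[inside] != 0L)) stop("ellipsoids overlap: ", names(ellipsoids)[i])
    labels[inside] <- i
    # band half-width in rho units: requested thickness, but never thinner
    # than a voxel step anywhere on the surface (else the shell would have
    # holes at the poles of an anisotropic grid)
    eps <- max(bandUm / mean(e$semiAxes), 0.6 * max(voxelSizeUm / e$semiAxes))
    band <- abs(rho - 1) <= eps
    nmMap[inside] <- interiorNM
    nmMap[band] <- membraneNM
    trueV[names(ellipsoids)[i]] <- 4 / 3 * pi * prod(e$semiAxes) / 1000
  }

  set.seed(seed)
  stack <- array(stats::rpois(length(nmMap), optics@photonsPerNM * nmMap),
                 c(nz, ny, nx))
  gain <- array(rep(optics@illuminationField, times = nz), c(ny, nx, nz))
  gain <- aperm(gain, c(3, 1, 2))
  stack <- round(stack * gain + optics@cameraOffset +
                 array(stats::rnorm(length(nmMap), 0, optics@readNoiseSd), c(nz, ny, nx)))
  stack <- pmin(pmax(stack, 0), 65535)

  lv <- LabeledVolume(labels, voxelSizeUm,
                      structure(seq_along(ellipsoids), names = names(ellipsoids)))
  list(stack = stack, labels = lv, trueVolumesPL = trueV)
}

#' Generate a synthetic RNAi-screen dataset
#'
#' Per-embryo P2 mean intensities are drawn around controlMean x multiplier
#' with the stated coefficient of variation; a clone with multiplier 1 is a
#' true null. Camera background is generated per image. Both screen stages
#' are generated so that stage-2 retesting of stage-1 hits can be simulated.
#'
#' @param nClones number of RNAi clones (control excluded).
#' @param embryosPerClone embryos per clone, either one number for both
#'   stages or c(stage1, stage2); each >= 2.
#' @param controlMean control net P2 intensity (counts above background).
#' @param effectSizes named numeric of multipliers (clone id -> multiplier);
#'   clones not named get multiplier 1. All multipliers must be >= 0.
#' @param noiseCv between-embryo coefficient of variation.
#' @param seed integer seed.
#' @param cameraBg camera offset (counts).
#' @param controlId id of the negative-control clone.
#' @param controlEmbryos control embryos per stage (one number or
#'   c(stage1, stage2)). The negative control is imaged alongside every
#'   session of a screen, so its pooled sample is larger than any single
#'   clone's; default 20 per stage.
#' @return data.frame with columns clone, stage, embryo, p2_mean_counts,
#'   camera_bg_counts, multiplier, and attributes `control_clone`.
#' @export
makeScreenDataset <- function(nClones, embryosPerClone, controlMean,
                              effectSizes = numeric(), noiseCv = 0.15,
                              seed = 1L, cameraBg = 100,
                              controlId = "L4440", controlEmbryos = 20L) {
  if (length(embryosPerClone) == 1L) embryosPerClone <- rep(embryosPerClone, 2L)
  if (length(controlEmbryos) == 1L) controlEmbryos <- rep(controlEmbryos, 2L)
  if (any(embryosPerClone < 2) || any(controlEmbryos < 2))
    stop("embryosPerClone and controlEmbryos must be >= 2")
  if (any(effectSizes < 0)) stop("effect-size multipliers must be >= 0")
  clones <- sprintf("clone_%03d", seq_len(nClones))
  bad <- setdiff(names(effectSizes), clones)
  if (length(bad)) stop("effectSizes name unknown clones: ", paste(bad, collapse = ", "))
  mult <- structure(rep(1, nClones), names = clones)
  mult[names(effectSizes)] <- effectSizes

  set.seed(seed)
  rows <- list()
  for (stage in 1:2) {
    for (cl in c(controlId, clones)) {
      n <- if (cl == controlId) controlEmbryos[stage] else embryosPerClone[stage]
      m <- if (cl == controlId) 1 else mult[[cl]]
      mu <- controlMean * m
      sig <- pmax(stats::rnorm(n, mu, noiseCv * controlMean * max(m, 0.2)), 0)
      rows[[length(rows) + 1L]] <- data.frame(
        clone = cl, stage = stage, embryo = seq_len(n),
        p2_mean_counts = cameraBg + sig,
        camera_bg_counts = cameraBg + stats::rnorm(n, 0, 0.5),
        multiplier = m, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "control_clone") <- controlId
  out
}

## ---- standard study conditions --------------------------------------------

#' Standard embryo geometries for the 1-, 2- and 4-cell stages
#'
#' Canonical midplane geometry: a 50 x 30 um embryo ellipse with the AP axis
#' horizontal (posterior to the right), blastomeres occupying AP bands, and
#' per-cell volumes matching the measured blastomere volumes (AB 14.7, P1
#' 10.1, EMS 6.1, P2 4.2 pL; the zygote volume is taken as 26.9 pL so the
#' P0:P2 volume fold decrease is 6.4). Nuclei are drawn for P-lineage cells.
#'
#' @param stage one of "1cell", "2cell", "4cell".
#' @param dim image dimensions c(nrow, ncol).
#' @param pixelSizeUm pixel size (micrometres).
#' @param nuclei include nucleus masks (default TRUE).
#' @return an \linkS4class{EmbryoGeometry}.
#' @export
standardEmbryoGeometry <- function(stage = c("1cell", "2cell", "4cell"),
                                   dim = c(100L, 150L), pixelSizeUm = 0.4,
                                   nuclei = TRUE) {
  stage <- match.arg(stage)
  a <- 0.42 * dim[2]; b <- 0.30 * dim[1]
  vols <- c(P0 = 26.88, AB = 14.7, P1 = 10.1,
            ABa = 7.35, ABp = 7.35, EMS = 6.1, P2 = 4.2)
  rNuc <- 0.22 * b
  spec <- switch(stage,
    "1cell" = list(cells = list(P0 = c(0, 1)),
                   nuc = list(P0 = c(u = 0.5, r = rNuc))),
    "2cell" = list(cells = list(AB = c(0, 0.55), P1 = c(0.55, 1)),
                   nuc = list(AB = c(u = 0.28, r = rNuc), P1 = c(u = 0.76, r = rNuc * 0.9))),
    "4cell" = list(cells = list(ABa = c(0, 0.28), ABp = c(0.28, 0.55),
                                EMS = c(0.55, 0.80), P2 = c(0.80, 1)),
                   nuc = list(EMS = c(u = 0.67, r = rNuc * 0.75),
                              P2 = c(u = 0.89, r = rNuc * 0.6))))
  EmbryoGeometry(dim = dim, semiAxes = c(a, b), cells = spec$cells,
                 pixelSizeUm = pixelSizeUm,
                 nuclei = if (nuclei) spec$nuc else list(),
                 volumesPL = vols[names(spec$cells)])
}

#' Standard lineage parameters for the P0 -> P2 study window
#'
#' Defaults encode the measured study conditions: zygote concentration 92 nM,
#' segregation fractions 0.58 (P0 division) and 0.57 (P1 division), the
#' measured blastomere volumes, germline-restricted synthesis at a rate that
#' makes maternal inheritance account for about half of the final P2 signal
#' (matching the observed ~195 of 424 nM), and somatic degradation in ABa and
#' ABp only. Divisions at 600 s and 1500 s after pronuclear meeting, 2700 s
#' total.
#'
#' @param c0 zygote concentration (nM).
#' @param f1,f2 segregation fractions at the P0 and P1 divisions.
#' @param kSynGermline synthesis rate (nM/s) applied to P0, P1, P2; the
#'   default is tuned analytically so synthesized protein makes up half of
#'   the final P2 amount (see [tuneSynthesisRate()]).
#' @param kDegSomatic degradation rate (1/s) in ABa and ABp.
#' @param t1,t2,duration division times and total duration (s).
#' @param bleaches bleach-event data.frame (time_s, cx, cy, diameter_um,
#'   survival); default none.
#' @param maturationDelayS fluorophore maturation delay (s).
#' @return a \linkS4class{LineageParams}.
#' @export
standardLineageParams <- function(c0 = 92, f1 = 0.58, f2 = 0.57,
                                  kSynGermline = NULL, kDegSomatic = 0.0015,
                                  t1 = 600, t2 = 1500, duration = 2700,
                                  bleaches = NULL, maturationDelayS = 0) {
  vols <- c(P0 = 26.88, AB = 14.7, P1 = 10.1,
            ABa = 7.35, ABp = 7.35, EMS = 6.1, P2 = 4.2)
  div <- data.frame(time_s = c(t1, t2), mother = c("P0", "P1"),
                    germ = c("P1", "P2"), soma = c("AB", "EMS"),
                    f = c(f1, f2), stringsAsFactors = FALSE)
  if (is.null(kSynGermline))
    kSynGermline <- tuneSynthesisRate(c0, vols, div, duration, share = 0.5)
  if (is.null(bleaches))
    bleaches <- data.frame(time_s = numeric(), cx = numeric(), cy = numeric(),
                           diameter_um = numeric(), survival = numeric())
  LineageParams(
    initialConcentrationNM = c0, volumesPL = vols, divisions = div,
    kSyn = c(P0 = kSynGermline, P1 = kSynGermline, P2 = kSynGermline),
    kDeg = c(ABa = kDegSomatic, ABp = kDegSomatic),
    maturationDelayS = maturationDelayS, bleaches = bleaches)
}

#' Synthesis rate giving a target synthesized share of the final P2 amount
#'
#' For a germline-restricted constant synthesis rate k (nM/s, active in P0,
#' P1, P2) with no germline degradation, the synthesized amount reaching P2
#' by time T is k (V0 t1 f1 f2 + V_P1 (t2 - t1) f2 + V_P2 (T - t2)) because
#' protein synthesized before a division partitions like maternal protein.
#' Setting this equal to share/(1-share) x the maternal amount
#' c0 V0 f1 f2 and solving gives the returned rate.
#'
#' @param c0 zygote concentration (nM).
#' @param vols named volumes (pL) including P0, P1, P2.
#' @param div divisions data.frame (time_s, mother, germ, soma, f) for the
#'   P0 and P1 divisions.
#' @param duration end time T (s).
#' @param share target synthesized fraction of the final P2 amount.
#' @return synthesis rate in nM/s.
#' @export
tuneSynthesisRate <- function(c0, vols, div, duration, share = 0.5) {
  f1 <- div$f[1]; f2 <- div$f[2]; t1 <- div$time_s[1]; t2 <- div$time_s[2]
  matA <- c0 * vols[["P0"]] * f1 * f2
  w <- vols[["P0"]] * t1 * f1 * f2 + vols[["P1"]] * (t2 - t1) * f2 +
    vols[["P2"]] * (duration - t2)
  unname(share / (1 - share) * matA / w)
}

#' Bleach-event table for the standard FRAP protocol
#'
#' Five frames are acquired before the bleach, so with a 15 s interval the
#' bleach lands at 75 s. By default the bleach circle covers the whole
#' embryo, emulating the repeated spot bleaching that reduced total embryo
#' fluorescence to the survival fraction; pass a diameter (e.g. 8) and a
#' centre for a localized spot bleach.
#'
#' @param geometry the 1-cell \linkS4class{EmbryoGeometry} being imaged.
#' @param survival fraction of fluorescence surviving the bleach.
#' @param timeS bleach time (s).
#' @param diameterUm bleach-circle diameter; default spans the embryo.
#' @param center circle centre (x, y) in pixels; default embryo centre.
#' @return one-row data.frame suitable for [LineageParams()].
#' @export
frapBleachEvent <- function(geometry, survival = 0.4, timeS = 75,
                            diameterUm = NULL, center = NULL) {
  if (is.null(center)) center <- geometry@center
  if (is.null(diameterUm))
    diameterUm <- 2.2 * geometry@semiAxes[1] * geometry@pixelSizeUm
  data.frame(time_s = timeS, cx = center[1], cy = center[2],
             diameter_um = diameterUm, survival = survival)
}

#' Measurement-noise model for per-cell mean intensities
#'
#' Converts ground-truth traces into noisy measured traces without rendering
#' images: the measured background-corrected mean of a cell with n pixels has
#' expectation photonsPerNM x C and SD sqrt(photonsPerNM x C + readNoiseSd^2)
#' / sqrt(n) under the Poisson + Gaussian camera model (uniform
#' illumination). Used for large simulation studies where rendering every
#' frame would be wasteful; the rendered path is validated separately.
#'
#' @param tl a \linkS4class{LineageTimelapse} (render = FALSE is fine).
#' @param nPixels representative per-cell pixel count used for the SE of the
#'   mean.
#' @param seed integer seed.
#' @return data.frame(cell, time_s, intensity, normalized) with attribute
#'   `bleach_time_s`; normalized values are relative to the mean of the five
#'   pre-bleach whole-embryo values (or the first frame when no bleach).
#' @export
simulateTraceMeasurements <- function(tl, nPixels = 1500, seed = 1L) {
  tr <- tl@truth
  op <- tl@optics
  set.seed(seed)
  mu <- op@photonsPerNM * (tr$conc_visible_nM +
                           op@autofluorescenceNMEquiv * tr$af_factor)
  se <- sqrt(pmax(mu, 0) + op@readNoiseSd^2) / sqrt(nPixels)
  meas <- mu + stats::rnorm(nrow(tr), 0, se)
  out <- data.frame(cell = tr$cell, time_s = tr$time_s, intensity = meas,
                    stringsAsFactors = FALSE)
  bt <- if (nrow(tl@params@bleaches)) min(tl@params@bleaches$time_s) else NA_real_
  # whole-embryo (volume-weighted) reference trace for normalization
  embTimes <- sort(unique(tr$time_s))
  embMean <- vapply(embTimes, function(t) {
    i <- tr$time_s == t
    sum(meas[i] * tr$volume_pL[i]) / sum(tr$volume_pL[i])
  }, numeric(1))
  if (is.na(bt)) baseline <- embMean[1] else {
    pre <- embTimes < bt
    baseline <- mean(utils::tail(embMean[pre], 5))
  }
  out$normalized <- out$intensity / baseline
  attr(out, "bleach_time_s") <- bt
  attr(out, "baseline") <- baseline
  out
}
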