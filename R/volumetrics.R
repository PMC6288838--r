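## Per-cell volumes (pL) from labelled membrane-marker z-stacks, with a
## seeded region-growing segmentation standing in for interactive
## segmentation tools. Voxel assignment is winner-take-all, so split labels
## conserve voxels exactly.

#' Cell volumes from a labelled volume
#'
#' Volume = voxel count x voxel volume; 1 pL = 1000 um^3. Cells in the map
#' whose label has no voxels are absent from the output; a nonzero label in
#' the array that is missing from the map is an error.
#'
#' @param lv a \linkS4class{LabeledVolume}.
#' @return named numeric, cell -> volume in pL.
#' @examples
#' arr <- array(0L, c(10, 10, 10)); arr[1:10, 1:10, 1:10] <- 1L
#' lv <- LabeledVolume(arr, c(1, 1, 1), c(cell = 1))
#' volumesFromLabels(lv)  # 1000 voxels of 1 um^3 = 1 pL
#' @export
volumesFromLabels <- function(lv) {
  labs <- lv@labels
  present <- sort(unique(labs[labs > 0L]))
  if (!length(present)) stop("no nonzero labels in volume")
  unmapped <- setdiff(present, lv@cellMap)
  if (length(unmapped))
    stop("labels without a cell name: ", paste(unmapped, collapse = ", "))
  voxVol <- prod(lv@voxelSizeUm)  # um^3
  counts <- tabulate(labs, nbins = max(present))
  keep <- lv@cellMap[lv@cellMap %in% present]
  structure(counts[keep] * voxVol / 1000, names = names(keep))
}

#' Ratio of somatic to germline daughter volume
#'
#' @param vGerm germline daughter volume (pL), > 0.
#' @param vSoma somatic daughter volume (pL), > 0.
#' @param decimals decimal places; rounding is half-up.
#' @return vSoma / vGerm rounded half-up.
#' @examples
#' volumeRatio(10.1, 14.7)  # 1.46
#' volumeRatio(4.2, 6.1)    # 1.45
#' @export
volumeRatio <- function(vGerm, vSoma, decimals = 2) {
  .assertScalarNum(vGerm, "vGerm", 0, strict = TRUE)
  .assertScalarNum(vSoma, "vSoma", 0, strict = TRUE)
  roundHalfUp(vSoma / vGerm, decimals)
}

# one BFS sweep: propagate labels into unlabelled voxels allowed by `allow`;
# returns updated labels and whether anything changed
.bfsSweep <- function(L, allow) {
  d <- dim(L)
  changed <- FALSE
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  for (s in shifts) {
    src <- array(0L, d)
    iz <- seq_len(d[1]); iy <- seq_len(d[2]); ix <- seq_len(d[3])
    gz <- iz - s[1]; gy <- iy - s[2]; gx <- ix - s[3]
    vz <- gz >= 1 & gz <= d[1]; vy <- gy >= 1 & gy <= d[2]; vx <- gx >= 1 & gx <= d[3]
    src[iz[vz], iy[vy], ix[vx]] <- L[gz[vz], gy[vy], gx[vx]]
    fill <- L == 0L & allow & src > 0L
    if (any(fill)) { L[fill] <- src[fill]; changed <- TRUE }
  }
  list(L = L, changed = changed)
}

#' Segment a membrane-marker z-stack from interior seeds
#'
#' Seeded region growing: cell interiors (voxels below the membrane
#' threshold) are flooded from the seeds first; the bright membrane shell is
#' then assigned to the nearest grown region, winner-take-all, leaving the
#' dark exterior as background. Two seeds falling in one connected interior
#' basin are rejected by name. This replaces interactive membrane
#' segmentation with a reproducible equivalent.
#'
#' @param zstack 3D counts array (z, y, x).
#' @param seeds named list of seed voxel coordinates c(z, y, x), one per
#'   cell, each inside its cell.
#' @param voxelSizeUm voxel sizes (z, y, x), micrometres.
#' @param threshold membrane/interior intensity threshold; default midway
#'   between the stack's 5th and 99.5th percentiles.
#' @return a \linkS4class{LabeledVolume}.
#' @export
segmentMembraneStack <- function(zstack, seeds, voxelSizeUm, threshold = NULL) {
  if (any(voxelSizeUm <= 0)) stop("voxel sizes must be > 0")
  if (is.null(threshold)) {
    q <- stats::quantile(zstack, c(0.05, 0.995))
    threshold <- mean(q)
  }
  d <- dim(zstack)
  interior <- zstack < threshold
  L <- array(0L, d)
  for (i in seq_along(seeds)) {
    s <- seeds[[i]]
    if (!interior[s[1], s[2], s[3]])
      stop("seed '", names(seeds)[i], "' does not lie in a sub-threshold interior")
    L[s[1], s[2], s[3]] <- i
  }
  # phase 1: flood interiors only
  repeat {
    r <- .bfsSweep(L, interior)
    L <- r$L
    if (!r$changed) break
  }
  # reject seeds sharing one basin: adjacent interior voxels with
  # different labels mean the flood fronts met inside one component
  conflict <- .labelContacts(L, interior)
  if (!is.null(conflict))
    stop("seeds '", names(seeds)[conflict[1]], "' and '",
         names(seeds)[conflict[2]], "' lie in the same basin")
  # phase 2: the membrane shell is contested between the grown cells and the
  # dark exterior; fronts advance at equal speed so they meet mid-shell,
  # splitting the band at the true surface (winner-take-all)
  bgLabel <- length(seeds) + 1L
  L[L == 0L & interior] <- bgLabel
  membrane <- !interior
  repeat {
    r <- .bfsSweep(L, membrane)
    L <- r$L
    if (!r$changed) break
  }
  L[L == bgLabel] <- 0L
  LabeledVolume(L, voxelSizeUm,
                structure(seq_along(seeds), names = names(seeds)))
}

# find a pair of labels in face contact through `allow` voxels; NULL if none
.labelContacts <- function(L, allow) {
  d <- dim(L)
  for (ax in 1:3) {
    idxA <- lapply(d, seq_len); idxB <- idxA
    idxA[[ax]] <- seq_len(d[ax] - 1L); idxB[[ax]] <- seq_len(d[ax] - 1L) + 1L
    A <- do.call(`[`, c(list(L), idxA, list(drop = FALSE)))
    B <- do.call(`[`, c(list(L), idxB, list(drop = FALSE)))
    aA <- do.call(`[`, c(list(allow), idxA, list(drop = FALSE)))
    aB <- do.call(`[`, c(list(allow), idxB, list(drop = FALSE)))
    bad <- A > 0L & B > 0L & A != B & aA & aB
    if (any(bad)) {
      i <- which(bad)[1]
      return(sort(c(A[i], B[i])))
    }
  }
  NULL
}
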