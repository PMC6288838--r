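## TIFF / CSV / JSON interchange: 16-bit grayscale images (single- or
## multi-page), 16-bit label masks, truth records as JSON, traces as CSV.

#' Read and write 16-bit grayscale TIFF images
#'
#' Images are stored as 16-bit counts (0..65535). `writeImageTIFF` accepts a
#' matrix (single page) or a list/3D array of matrices (multi-page, e.g. a
#' z-stack, written as (z, y, x)).
#'
#' @param image numeric matrix, list of matrices, or 3D array (z, y, x).
#' @param path file path.
#' @return `readImageTIFF`: a counts matrix, or a 3D array (z, y, x) for a
#'   multi-page file.
#' @export
writeImageTIFF <- function(image, path) {
  toPage <- function(m) {
    m <- pmin(pmax(round(m), 0), 65535)
    m / 65535
  }
  pages <- if (is.matrix(image)) list(toPage(image))
  else if (is.list(image)) lapply(image, toPage)
  else lapply(seq_len(dim(image)[1]), function(z) toPage(image[z, , ]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname writeImageTIFF
#' @export
readImageTIFF <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(p) round(p * 65535))
  if (length(pages) == 1L) return(pages[[1]])
  arr <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  arr
}

#' Write / read a labelled volume as multi-page 16-bit label TIFF + JSON
#'
#' The label array is written one z-slice per page; voxel sizes and the
#' cell-name map go to a JSON sidecar `<path>.json`.
#'
#' @param lv a \linkS4class{LabeledVolume}.
#' @param path TIFF path.
#' @return `readLabeledVolume`: a \linkS4class{LabeledVolume}.
#' @export
writeLabeledVolume <- function(lv, path) {
  writeImageTIFF(lv@labels, path)
  jsonlite::write_json(
    list(voxel_size_um = lv@voxelSizeUm, cell_map = as.list(lv@cellMap)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param path TIFF path written by `writeLabeledVolume`.
#' @rdname writeLabeledVolume
#' @export
readLabeledVolume <- function(path) {
  arr <- readImageTIFF(path)
  if (is.matrix(arr)) arr <- array(arr, c(1L, nrow(arr), ncol(arr)))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  LabeledVolume(arr, meta$voxel_size_um, unlist(meta$cell_map))
}

#' Write per-cell traces to CSV
#'
#' Columns time_s, cell, plus every value column present (intensity,
#' normalized, true concentrations).
#'
#' @param traces trace data.frame.
#' @param path CSV path.
#' @export
writeTracesCSV <- function(traces, path) {
  utils::write.csv(traces, path, row.names = FALSE)
  invisible(path)
}

#' Write a calibration-scene truth record as JSON
#'
#' @param scene a \linkS4class{CalibrationScene}.
#' @param path JSON path.
#' @export
writeTruthJSON <- function(scene, path) {
  jsonlite::write_json(scene@truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
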