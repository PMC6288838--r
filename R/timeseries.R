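## FRAP-style per-cell time-series analysis: trace extraction with
## pre-bleach or control-embryo normalization, paired synthesis testing
## (final vs first post-bleach timepoint), and endpoint slopes.

#' Extract per-cell intensity traces from a time-lapse
#'
#' Per frame and per cell, the background-corrected mean intensity (camera
#' background from an outside-embryo region of the same frame). Two
#' normalization modes: `prebleach` divides by the mean whole-embryo
#' intensity of the five frames before the (first) bleach event, matching
#' the standard FRAP protocol of five pre-bleach acquisitions; `control`
#' divides by a supplied scalar, typically the whole-embryo mean of an
#' unbleached control embryo at its first frame.
#'
#' @param tl a rendered \linkS4class{LineageTimelapse}.
#' @param mode "prebleach" or "control".
#' @param controlScalar normalization scalar for `control` mode.
#' @param ref optional \linkS4class{IlluminationReference}.
#' @param cells cells to extract; default all cells ever present. A cell
#'   absent from every frame is an error.
#' @param autofluorCounts autofluorescence counts subtracted from every
#'   cell mean (as measured from a wild-type embryo), default 0.
#' @return data.frame(cell, time_s, intensity, normalized) with attributes
#'   `bleach_time_s` and `baseline`.
#' @export
extractTraces <- function(tl, mode = c("prebleach", "control"),
                          controlScalar = NULL, ref = NULL, cells = NULL,
                          autofluorCounts = 0) {
  mode <- match.arg(mode)
  if (!length(tl@frames)) stop("time-lapse has no rendered frames")
  if (length(tl@times) < 2L) stop("need at least two frames")
  allCells <- unique(unlist(lapply(tl@masks, function(m) names(m@cells))))
  if (is.null(cells)) cells <- allCells
  missing <- setdiff(cells, allCells)
  if (length(missing))
    stop("cell(s) absent from every frame: ", paste(missing, collapse = ", "))

  rows <- list()
  embMeans <- numeric(length(tl@times))
  for (i in seq_along(tl@times)) {
    img <- tl@frames[[i]]
    if (!is.null(ref)) img <- flatfieldCorrect(img, ref)
    msk <- tl@masks[[i]]
    bg <- measureCameraBackground(img, "outside_embryo", mask = !msk@embryo)
    embMeans[i] <- mean(img[msk@embryo]) - bg - autofluorCounts
    for (cell in intersect(cells, names(msk@cells))) {
      rows[[length(rows) + 1L]] <- data.frame(
        cell = cell, time_s = tl@times[i],
        intensity = mean(img[msk@cells[[cell]]]) - bg - autofluorCounts,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)

  bleachT <- if (nrow(tl@params@bleaches)) min(tl@params@bleaches$time_s) else NA_real_
  baseline <- if (mode == "control") {
    if (is.null(controlScalar)) stop("control mode requires controlScalar")
    controlScalar
  } else if (is.na(bleachT)) embMeans[1]
  else mean(utils::tail(embMeans[tl@times < bleachT], 5))
  out$normalized <- out$intensity / baseline
  attr(out, "bleach_time_s") <- bleachT
  attr(out, "baseline") <- baseline
  out
}

#' Normalize a trace to its pre-bleach baseline
#'
#' Divides the chosen column by the mean of the last five values before the
#' bleach time. Applying it to an already-normalized trace is the identity,
#' since the pre-bleach mean of a normalized trace is 1.
#'
#' @param trace data.frame with time_s and the value column, with attribute
#'   `bleach_time_s` (or pass `bleachTimeS`).
#' @param value column to normalize (default "normalized").
#' @param bleachTimeS bleach time override (s).
#' @return the trace with the column divided by its pre-bleach mean.
#' @export
normalizePrebleach <- function(trace, value = "normalized", bleachTimeS = NULL) {
  bt <- if (!is.null(bleachTimeS)) bleachTimeS else attr(trace, "bleach_time_s")
  pre <- if (is.null(bt) || is.na(bt)) trace$time_s == min(trace$time_s)
         else trace$time_s < bt
  base <- mean(utils::tail(trace[[value]][pre], 5))
  trace[[value]] <- trace[[value]] / base
  trace
}

# first post-bleach and final value of one cell in one embryo's trace
.endpointPair <- function(trace, cell, value = "normalized") {
  bt <- attr(trace, "bleach_time_s")
  tr <- trace[trace$cell == cell, ]
  if (!nrow(tr)) return(NULL)
  tr <- tr[order(tr$time_s), ]
  post <- if (is.null(bt) || is.na(bt)) tr else tr[tr$time_s >= bt, ]
  if (!nrow(post)) return(NULL)
  c(first = post[[value]][1], final = post[[value]][nrow(post)])
}

#' Paired test for post-bleach synthesis in one cell
#'
#' For each embryo, compares the cell's final timepoint to its first
#' post-bleach timepoint (for cells born after the bleach, their first
#' timepoint); a two-tailed paired t-test across embryos asks whether
#' fluorescence increased, i.e. whether new protein was made after the
#' pre-existing signal was bleached away.
#'
#' @param traces list of per-embryo trace data.frames (as produced by
#'   [extractTraces()] or [simulateTraceMeasurements()]), each with
#'   attribute `bleach_time_s`.
#' @param cell cell name.
#' @param value trace column to compare (default "normalized").
#' @return list(mean_difference, p_value, n, differences).
#' @export
synthesisTest <- function(traces, cell, value = "normalized") {
  pairs <- lapply(traces, .endpointPair, cell = cell, value = value)
  pairs <- Filter(Negate(is.null), pairs)
  if (length(pairs) < 2L) stop("need at least two embryos with both timepoints for ", cell)
  d <- vapply(pairs, function(p) p[["final"]] - p[["first"]], numeric(1))
  if (stats::sd(d) == 0) {
    p <- if (mean(d) == 0) 1 else 0
  } else {
    p <- stats::t.test(d)$p.value
  }
  list(mean_difference = mean(d), p_value = p, n = length(d), differences = d)
}

#' Least-squares slope of a trace over a time window
#'
#' @param trace data.frame with time_s and the value column (one cell).
#' @param window c(t0, t1) in seconds; needs >= 3 points inside.
#' @param value column to regress (default "normalized").
#' @return slope in value units per second.
#' @export
endpointSlope <- function(trace, window, value = "normalized") {
  sel <- trace$time_s >= window[1] & trace$time_s <= window[2]
  if (sum(sel) < 3L) stop("window contains fewer than 3 trace points")
  unname(stats::coef(stats::lm(trace[[value]][sel] ~ trace$time_s[sel]))[2])
}
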