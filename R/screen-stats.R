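## Two-stage RNAi-screen statistics: background-subtracted per-embryo P2
## means, normalization to the empty-vector control, per-clone t-tests and
## stage-1/stage-2 hit calling.

.screenCheck <- function(table) {
  need <- c("clone", "stage", "embryo", "p2_mean_counts", "camera_bg_counts")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("screen table lacks column(s): ", paste(miss, collapse = ", "))
  ctrl <- attr(table, "control_clone")
  if (is.null(ctrl)) stop("screen table lacks a control_clone attribute")
  if (!ctrl %in% table$clone) stop("control clone '", ctrl, "' absent from table")
  ctrl
}

#' Normalize screen measurements to the control clone
#'
#' Per embryo, net intensity = P2 mean minus its per-image camera
#' background; every net value is divided by the mean net value of the
#' control clone at the same stage.
#'
#' @param table screen data.frame (see [makeScreenDataset()]) with attribute
#'   `control_clone`.
#' @param stage screen stage (1 or 2).
#' @return data.frame(clone, n, mean_normalized, sd_normalized).
#' @export
normalizeToControl <- function(table, stage = 1) {
  ctrl <- .screenCheck(table)
  tb <- table[table$stage == stage, ]
  if (!nrow(tb)) stop("no rows for stage ", stage)
  net <- tb$p2_mean_counts - tb$camera_bg_counts
  ctrlMean <- mean(net[tb$clone == ctrl])
  if (!is.finite(ctrlMean) || ctrlMean <= 0) stop("control mean <= 0; cannot normalize")
  norm <- net / ctrlMean
  agg <- split(norm, tb$clone)
  data.frame(clone = names(agg),
             n = vapply(agg, length, integer(1)),
             mean_normalized = vapply(agg, mean, numeric(1)),
             sd_normalized = vapply(agg, stats::sd, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

# two-sample t-test p-value robust to the zero-variance corner:
# equal means with no variance anywhere is defined as p = 1
.screenP <- function(x, y, var.equal = TRUE) {
  if (stats::sd(c(x, y)) == 0) return(if (mean(x) == mean(y)) 1 else 0)
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(if (mean(x) == mean(y)) 1 else 0)
  stats::t.test(x, y, var.equal = var.equal)$p.value
}

#' Two-stage hit calling against the control clone
#'
#' Stage 1: every clone's net P2 values are compared to the control's with a
#' two-tailed two-sample t-test (pooled-variance Student's test by default).
#' Stage 2 is evaluated only for stage-1 hits, using the stage-2
#' measurements. Clones with fewer embryos than the stage minimum are
#' flagged, not dropped. No multiple-testing correction is applied by
#' default, matching the retest design; Benjamini-Hochberg adjustment of the
#' stage-1 p-values is available.
#'
#' @param table screen data.frame with attribute `control_clone`.
#' @param alpha significance level per test.
#' @param minNStage1,minNStage2 minimum embryos per clone at each stage.
#' @param varEqual pooled-variance (Student's) t-test if TRUE, Welch's
#'   otherwise.
#' @param adjust "none" (default) or "BH" applied to stage-1 p-values.
#' @return data.frame(clone, multiplier?, n1, p1, hit_stage1, low_n_stage1,
#'   n2, p2, hit_stage2, low_n_stage2), one row per non-control clone.
#' @export
callHits <- function(table, alpha = 0.05, minNStage1 = 5, minNStage2 = 11,
                     varEqual = TRUE, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (minNStage1 < 2 || minNStage2 < 2) stop("stage minimum n must be >= 2")
  ctrl <- .screenCheck(table)
  net <- table$p2_mean_counts - table$camera_bg_counts
  clones <- setdiff(unique(table$clone), ctrl)

  stageNet <- function(cl, st) net[table$clone == cl & table$stage == st]
  ctrl1 <- stageNet(ctrl, 1); ctrl2 <- stageNet(ctrl, 2)
  if (!length(ctrl1)) stop("control has no stage-1 embryos")

  n1 <- integer(length(clones)); p1 <- numeric(length(clones))
  for (i in seq_along(clones)) {
    x <- stageNet(clones[i], 1)
    if (length(x) < 2) stop("clone ", clones[i], " has < 2 stage-1 embryos")
    n1[i] <- length(x)
    p1[i] <- .screenP(x, ctrl1, var.equal = varEqual)
  }
  if (adjust == "BH") p1 <- stats::p.adjust(p1, "BH")
  hit1 <- p1 < alpha

  n2 <- rep(NA_integer_, length(clones)); p2 <- rep(NA_real_, length(clones))
  hit2 <- rep(FALSE, length(clones))
  for (i in which(hit1)) {
    x <- stageNet(clones[i], 2)
    if (length(x) < 2) next  # flagged below
    n2[i] <- length(x)
    p2[i] <- .screenP(x, ctrl2, var.equal = varEqual)
    hit2[i] <- p2[i] < alpha
  }
  out <- data.frame(clone = clones, n1 = n1, p1 = p1, hit_stage1 = hit1,
                    low_n_stage1 = n1 < minNStage1,
                    n2 = n2, p2 = p2, hit_stage2 = hit2,
                    low_n_stage2 = !is.na(n2) & n2 < minNStage2,
                    row.names = NULL, stringsAsFactors = FALSE)
  if ("multiplier" %in% names(table)) {
    mlt <- table[!duplicated(table$clone), c("clone", "multiplier")]
    out$multiplier <- mlt$multiplier[match(out$clone, mlt$clone)]
  }
  out
}
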