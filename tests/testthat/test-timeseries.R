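# FRAP-style trace analysis: extraction, normalization, the paired
# synthesis test and endpoint slopes.

frapTimelapse <- function(seed = 1L, kSyn = 0.05, survival = 0.4,
                          render = FALSE, durationS = 1200, kDeg = 0) {
  geo1 <- smallGeometry("1cell", nuclei = FALSE)
  geos <- list(geo1, smallGeometry("2cell", nuclei = FALSE))
  par <- LineageParams(92, c(P0 = 26.88, AB = 14.7, P1 = 10.1),
    divisions = data.frame(time_s = 600, mother = "P0", germ = "P1",
                           soma = "AB", f = 0.58, stringsAsFactors = FALSE),
    kSyn = c(P0 = kSyn, P1 = kSyn), kDeg = c(AB = kDeg),
    bleaches = frapBleachEvent(geo1, survival = survival, timeS = 75))
  makeLineageTimelapse(geos, par, smallOptics(vignetting = 0), 15, durationS,
                       seed = seed, render = render)
}

test_that("a constant stack yields constant traces", {
  geo <- smallGeometry("1cell", nuclei = FALSE)
  op <- OpticsModel(smallDim, vignetting = 0, readNoiseSd = 0,
                    autofluorescenceNMEquiv = 0)
  par <- LineageParams(92, c(P0 = 26.88))
  tl <- pieQuant:::.simulateTimelapse(list(geo), par, op, 30, 120, seed = 1,
                                      render = TRUE, noise = FALSE)
  tr <- extractTraces(tl)
  p0 <- tr$intensity[tr$cell == "P0"]
  expect_lt(diff(range(p0)) / mean(p0), 1e-6)
  expect_equal(tr$normalized[1], 1, tolerance = 1e-6)
})

test_that("post-bleach traces start near the survival fraction under
           pre-bleach normalization", {
  tl <- frapTimelapse(seed = 2, render = TRUE, durationS = 300)
  tr <- extractTraces(tl, mode = "prebleach")
  first <- tr$normalized[tr$cell == "P0" & tr$time_s == 75]
  expect_equal(first, 0.4, tolerance = 0.02)
})

test_that("extracted synthesis slope matches the generator rate", {
  geo <- smallGeometry("1cell", nuclei = FALSE)
  op <- OpticsModel(smallDim, vignetting = 0, readNoiseSd = 0,
                    autofluorescenceNMEquiv = 0)
  kSyn <- 0.05
  par <- LineageParams(92, c(P0 = 26.88), kSyn = c(P0 = kSyn))
  tl <- pieQuant:::.simulateTimelapse(list(geo), par, op, 30, 600, seed = 1,
                                      render = TRUE, noise = FALSE)
  tr <- extractTraces(tl)
  # intensity slope in counts/s is photonsPerNM x kSyn; normalized slope
  # divides by the baseline
  slopeI <- endpointSlope(tr[tr$cell == "P0", ], c(0, 600), value = "intensity")
  expect_equal(slopeI, op@photonsPerNM * kSyn, tolerance = 0.05)
  slopeN <- endpointSlope(tr[tr$cell == "P0", ], c(0, 600))
  expect_equal(slopeN, op@photonsPerNM * kSyn / attr(tr, "baseline"),
               tolerance = 0.05)
  # exactly linear and constant traces
  lin <- data.frame(cell = "x", time_s = 0:10, normalized = 2 + 3 * (0:10))
  expect_equal(endpointSlope(lin, c(0, 10)), 3, tolerance = 1e-12)
  con <- data.frame(cell = "x", time_s = 0:10, normalized = rep(5, 11))
  expect_equal(endpointSlope(con, c(0, 10)), 0, tolerance = 1e-12)
  expect_error(endpointSlope(lin, c(20, 30)), "fewer than 3")
})

test_that("pre-bleach normalization is idempotent", {
  tl <- frapTimelapse(seed = 3, render = FALSE, durationS = 300)
  m <- simulateTraceMeasurements(tl, seed = 4)
  p0 <- m[m$cell == "P0", ]
  attr(p0, "bleach_time_s") <- attr(m, "bleach_time_s")
  once <- normalizePrebleach(p0)
  twice <- normalizePrebleach(once)
  expect_equal(twice$normalized, once$normalized, tolerance = 1e-9)
})

test_that("the paired synthesis test behaves at both extremes", {
  mkTrace <- function(vals, times = seq_along(vals) * 15) {
    tr <- data.frame(cell = "P1", time_s = times, normalized = vals)
    attr(tr, "bleach_time_s") <- 0
    tr
  }
  # all differences zero -> p = 1
  flat <- lapply(1:4, function(i) mkTrace(rep(0.4, 10)))
  res <- synthesisTest(flat, "P1")
  expect_equal(res$p_value, 1)
  expect_equal(res$mean_difference, 0)
  expect_error(synthesisTest(flat[1], "P1"), "at least two")
})

test_that("synthesis is detected in P1 and absent in AB across embryos", {
  tlSyn <- frapTimelapse(seed = 5, kSyn = 0.05)
  tlNull <- frapTimelapse(seed = 5, kSyn = 0)
  embryos <- function(tl, s) lapply(1:6, function(e)
    simulateTraceMeasurements(tl, seed = childSeed(s, e)))
  resP1 <- synthesisTest(embryos(tlSyn, 10), "P1")
  expect_gt(resP1$mean_difference, 0)
  expect_lt(resP1$p_value, 0.05)
  # without synthesis the AB endpoint difference is numerically tiny
  resAB <- synthesisTest(embryos(tlNull, 11), "AB")
  expect_lt(abs(resAB$mean_difference), 0.02)
  expect_gt(resAB$p_value, 0.05)
})

test_that("estimated synthesis rate is invariant to bleach depth", {
  slopes <- vapply(c(0.3, 0.4, 0.5), function(sv) {
    tl <- frapTimelapse(seed = 6, kSyn = 0.05, survival = sv)
    m <- simulateTraceMeasurements(tl, seed = 7)
    p1 <- m[m$cell == "P1", ]
    endpointSlope(p1, c(615, 1200), value = "intensity")
  }, numeric(1))
  expect_lt(diff(range(slopes)) / mean(slopes), 0.1)
})

test_that("somatic degradation gives non-increasing somatic traces", {
  par <- standardLineageParams(kDegSomatic = 0.002)
  tl <- standardTimelapse(seed = 8, params = par, render = FALSE)
  tr <- truthTraces(tl)
  for (cell in c("ABa", "ABp")) {
    v <- tr$conc_visible_nM[tr$cell == cell]
    expect_true(all(diff(v) <= 1e-12))
  }
  # EMS has no active degradation pathway here: constant after birth
  ems <- tr$conc_visible_nM[tr$cell == "EMS"]
  expect_lt(diff(range(ems)) / mean(ems), 1e-9)
})

test_that("extractTraces validates cells and control mode", {
  tl <- frapTimelapse(seed = 9, render = TRUE, durationS = 150)
  expect_error(extractTraces(tl, cells = "P9"), "absent")
  expect_error(extractTraces(tl, mode = "control"), "controlScalar")
  ctl <- extractTraces(tl, mode = "control", controlScalar = 500)
  expect_equal(attr(ctl, "baseline"), 500)
})
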