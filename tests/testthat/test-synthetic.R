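test_that("packaged signature panel loads with the printed signature values", {
  expect_gte(length(thePanel$templates), 20)
  expect_identical(peakTimes(thePanel$templates[["Hof1"]]), c(-5, -1, 6))
  expect_identical(peakTimes(thePanel$templates[["Chs2"]]), 2)
  cts1 <- thePanel$templates[["Cts1"]]
  expect_equal(peakTimes(cts1)[which.max(cts1@amplitudes)], 25)
  expect_equal(arrivalTime(cts1), 5)
  expect_equal(peakTimes(thePanel$templates[["Iqg1"]]), -2)
  expect_equal(arrivalTime(thePanel$templates[["Iqg1"]]), -40)
  # every entry carries provenance notes and a module label
  for (tm in thePanel$templates) {
    expect_gt(length(tm@provenance), 0)
    expect_true(tm@module %in% names(thePanel$modules))
  }
})

test_that("malformed panel configs are rejected with the offending entry named", {
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("defaults: {jitter_sd: 1}", "modules: {AMR: ring}",
               "proteins:", "  BadProt:", "    module: AMR",
               "    bumps:", "      - {peak: 0, amplitude: 5, rise: 1}",
               "    arrival: -5", "    departure: 5"), bad)
  expect_error(loadSignaturePanel(bad), "BadProt")
  expect_error(loadSignaturePanel(tempfile()), "not found")
})

test_that("template invariants hold and violations are caught", {
  tm <- thePanel$templates[["Chs2"]]
  tt <- seq(-45, 45, by = 0.25)
  expect_true(all(templateValue(tm, tt) >= tm@baseline))
  expect_error(new("TemplateCurve", protein = "x", module = "m",
                   baseline = 0, peakTimes = 0, amplitudes = -1,
                   riseWidths = 1, fallWidths = 1, arrivalTime = -5,
                   departureTime = 5), "amplitudes")
  expect_error(new("TemplateCurve", protein = "x", module = "m",
                   baseline = 0, peakTimes = 0, amplitudes = 1,
                   riseWidths = 1, fallWidths = 1, arrivalTime = 2,
                   departureTime = 5), "arrivalTime")
})

test_that("noiseless trace equals the template sampled on the grid", {
  tm <- thePanel$templates[["Myo1"]]
  tr <- simulateTrace(tm, jitterSd = 0, noiseCv = 0, seed = 5)
  expect_equal(tr@intensity, templateValue(tm, defaultGrid()),
               tolerance = 1e-12)
})

test_that("trace simulation is bit-identical under a fixed seed", {
  tm <- thePanel$templates[["Hof1"]]
  a <- simulateTrace(tm, seed = 42)
  b <- simulateTrace(tm, seed = 42)
  expect_identical(a@intensity, b@intensity)
  c <- simulateTrace(tm, seed = 43)
  expect_false(identical(a@intensity, c@intensity))
})

test_that("a 30-cell Hof1 mean trace shows three local maxima", {
  sim <- simulatePanel(thePanel, proteins = "Hof1", seed = 1)
  mk <- aggOf(sim$traces$Hof1)
  sg <- extractSignature(mk)
  expect_length(sg@peakTimes, 3)
})

test_that("zero-variance constriction matches the closed-form defaults", {
  tr <- simulateConstriction(noiselessParams(), seed = 1)
  tru <- attr(tr, "truth")
  # breakpoint at onset + slowDrop/slowRate = -6 + 5 = -1 min
  expect_equal(tru$breakpoint, -1)
  expect_equal(tru$d0, 1.02)
  t <- tr@times
  expect_true(all(tr@diameter[t < -6] == 1.02))
  # slow slope -0.02, fast slope -0.18, ring gone after closure
  expect_equal(tr@diameter[t == -3], 1.02 - 0.02 * 3, tolerance = 1e-12)
  expect_equal(tr@diameter[t == 2], 0.92 - 0.18 * 3, tolerance = 1e-12)
  expect_equal(tru$endTime, -1 + 0.92 / 0.18, tolerance = 1e-12)
  expect_true(all(tr@diameter[t >= 6] == 0))
  # diameter non-increasing over the whole trace
  expect_true(all(diff(tr@diameter) <= 1e-12))
})

test_that("fast-segment slope is exact when rate/drop SDs are zero", {
  p <- defaultConstrictionParams(fastRateSd = 0, fastDropSd = 0,
                                 noiseSd = 0)
  tr <- simulateConstriction(p, seed = 9)
  tru <- attr(tr, "truth")
  t <- tr@times
  inFast <- t > tru$breakpoint + 1e-9 & t < tru$endTime - 1
  slopes <- diff(tr@diameter[inFast]) / diff(t[inFast])
  expect_equal(unique(round(slopes, 12)), -0.18, tolerance = 1e-9)
})

test_that("non-constricting (actin-disrupted) mode yields a constant diameter and linear disassembly", {
  p <- defaultConstrictionParams(constrict = FALSE, noiseSd = 0)
  tr <- simulateConstriction(p, seed = 4)
  expect_equal(length(unique(tr@diameter)), 1L)
  t <- tr@times
  lin <- t > -6 & t < -6 + 12
  slopes <- diff(tr@intensity[lin]) / diff(t[lin])
  expect_equal(unique(round(slopes, 9)), round(slopes[1], 9))
  expect_lt(slopes[1], 0)
  expect_true(all(tr@intensity[t >= -6 + 12] == 0))
})

test_that("sampled ensembles reproduce the configured moments within Monte-Carlo error", {
  ens <- simulateConstrictionEnsemble(500, defaultConstrictionParams(),
                                      seed = 77)
  rf <- ens$truth$fastRate
  expect_lt(abs(mean(rf) - 0.18), 3 * sd(rf) / sqrt(length(rf)))
  rs <- ens$truth$slowRate
  expect_lt(abs(mean(rs) - 0.02), 3 * sd(rs) / sqrt(length(rs)))
  expect_true(all(rs > 0) && all(rf > 0))
  expect_true(all(ens$truth$slowDrop > 0) && all(ens$truth$fastDrop > 0))
})

test_that("panel simulation writes one truth row per cell and truth round-trips through CSV", {
  sim <- simulatePanel(thePanel, proteins = c("Myo1", "Chs2"), nCells = 5,
                       seed = 3)
  expect_equal(nrow(sim$truth), 10)
  expect_setequal(sim$truth$cell_id,
                  vapply(unlist(sim$traces, recursive = FALSE),
                         function(tr) tr@cellId, ""))
  f <- tempfile(fileext = ".csv")
  utils::write.csv(sim$truth, f, row.names = FALSE)
  back <- utils::read.csv(f)
  expect_equal(back$jitter, sim$truth$jitter, tolerance = 1e-12)
  expect_identical(back$cell_id, sim$truth$cell_id)
})

test_that("condition effects transform templates as configured", {
  tm <- thePanel$templates[["Mlc1"]]
  eff <- conditionEffect(amplitudeFactor = 0.66, peakShift = -3)
  tt <- applyConditionEffect(tm, eff)
  expect_equal(peakTimes(tt), peakTimes(tm) - 3)
  expect_equal(max(tt@amplitudes), 0.66 * max(tm@amplitudes))
  # rate factor scales the measured 5-min window slope of the mean curve
  eff2 <- conditionEffect(rateFactor = 0.37)
  tm2 <- thePanel$templates[["Chs2"]]
  tt2 <- applyConditionEffect(tm2, eff2)
  r <- cytokinetics:::templateWindowSlope(tt2) /
    cytokinetics:::templateWindowSlope(tm2)
  expect_equal(r, 0.37, tolerance = 0.01)
  # constriction params only react to the constrict flag
  p <- applyConditionEffect(defaultConstrictionParams(),
                            conditionEffect(constrict = FALSE))
  expect_false(p@constrict)
})
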