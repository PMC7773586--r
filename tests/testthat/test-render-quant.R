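# rendering and image quantification: flux conservation, geometry,
# background/scale behaviour, diameter and event recovery

scene <- defaultSceneConfig()
roi15 <- neckRoi(center = c(32, 32), halfWidth = 10, halfHeight = 10)

ringTrace <- simulateConstriction(noiselessParams(), seed = 3)
cleanMovie <- renderMovie(ringTrace, scene, ringTrace = ringTrace,
                          breakFrame = 46, noise = FALSE)
cleanTruth <- attr(cleanMovie, "truth")
noisyMovie <- renderMovie(ringTrace, scene, ringTrace = ringTrace,
                          breakFrame = 46, noise = TRUE, seed = 7)

test_that("rendered integrated intensity matches the driving trace (noise off)", {
  sums <- vapply(seq_along(cleanMovie@times),
                 function(i) sum(cleanMovie@channels$gfp[, , i]), 0)
  rel <- abs(sums - cleanTruth$intensity) / pmax(cleanTruth$intensity, 1e-9)
  expect_lt(max(rel), 1e-2)
})

test_that("coincident puncta collapse to a single punctum", {
  flat <- new("KineticTrace", cellId = "c", protein = "X",
              condition = "control", times = defaultGrid(),
              intensity = rep(50, 91), diameter = rep(0, 91), t0 = 0)
  mv <- renderMovie(flat, scene, breakFrame = 46, noise = FALSE)
  fr <- mv@channels$gfp[, , 1]
  lens <- cytokinetics:::componentLengths(fr >= max(fr) / 2, scene@pixelSize)
  expect_length(lens, 1)
  # symmetric single blob centered at the neck
  expect_equal(which(fr == max(fr), arr.ind = TRUE)[1, ],
               c(row = 33, col = 33))
})

test_that("a ring wider than the field of view is rejected", {
  wide <- new("KineticTrace", cellId = "c", protein = "X",
              condition = "control", times = defaultGrid(),
              intensity = rep(50, 91), diameter = rep(7, 91), t0 = 0)
  expect_error(renderMovie(wide, scene, breakFrame = 46),
               "field of view")
})

test_that("spindle channel has one component before breakage, two or none after", {
  arr <- cleanMovie@channels$spindle
  bf <- cleanTruth$breakFrame
  nComp <- vapply(seq_along(cleanMovie@times), function(i) {
    fr <- arr[, , i]
    if (max(fr) < 0.05 * max(arr)) return(0L)
    length(cytokinetics:::componentLengths(fr >= max(fr) / 2,
                                           scene@pixelSize))
  }, 0L)
  expect_true(all(nComp[seq_len(bf - 1)] == 1))
  expect_true(all(nComp[bf:length(nComp)] %in% c(0L, 2L)))
})

test_that("ROI intensity is zero on a uniform image and invariant to added constants", {
  mv <- cleanMovie
  mv@channels$gfp <- array(3.7, dim(mv@channels$gfp))
  expect_equal(measureRoiIntensity(mv, "gfp", roi15),
               rep(0, length(mv@times)))
  shifted <- cleanMovie
  shifted@channels$gfp <- shifted@channels$gfp + 11.3
  expect_equal(measureRoiIntensity(shifted, "gfp", roi15),
               measureRoiIntensity(cleanMovie, "gfp", roi15),
               tolerance = 1e-9)
})

test_that("scaling the image scales ROI intensity and leaves diameter and breakage unchanged", {
  scaled <- cleanMovie
  for (ch in names(scaled@channels))
    scaled@channels[[ch]] <- scaled@channels[[ch]] * 2.5
  expect_equal(measureRoiIntensity(scaled, "gfp", roi15),
               2.5 * measureRoiIntensity(cleanMovie, "gfp", roi15),
               tolerance = 1e-9)
  expect_identical(detectSpindleBreakage(scaled),
                   detectSpindleBreakage(cleanMovie))
  f <- 40  # mid-constriction frame
  expect_equal(measureRingDiameter(scaled, "ring", roi15,
                                   frames = f)$diameter_um,
               measureRingDiameter(cleanMovie, "ring", roi15,
                                   frames = f)$diameter_um,
               tolerance = 1e-3)
})

test_that("an ROI without room for a background margin is rejected", {
  big <- neckRoi(center = c(32, 32), halfWidth = 31, halfHeight = 31)
  expect_error(measureRoiIntensity(cleanMovie, "gfp", big), "margin")
  expect_error(measureRoiIntensity(cleanMovie, "nope", roi15), "channel")
})

test_that("measured ROI series tracks the generator trace", {
  m <- measureRoiIntensity(cleanMovie, "gfp", roi15)
  expect_gt(cor(m, cleanTruth$intensity), 0.99)
  mN <- measureRoiIntensity(noisyMovie, "gfp", roi15)
  expect_gt(cor(mN, cleanTruth$intensity), 0.99)
  # optional bleach correction multiplies by the exponential recovery
  mB <- measureRoiIntensity(cleanMovie, "gfp", roi15, bleachTau = 50)
  expect_equal(mB,
               m * exp((cleanMovie@times - cleanMovie@times[1]) / 50),
               tolerance = 1e-12)
})

test_that("puncta rendered 10 px apart give a 1.0 um diameter", {
  tenPx <- new("KineticTrace", cellId = "c", protein = "X",
               condition = "control", times = defaultGrid(),
               intensity = rep(60, 91), diameter = rep(1.0, 91), t0 = 0)
  mv <- renderMovie(tenPx, scene, breakFrame = 46, noise = FALSE)
  dm <- measureRingDiameter(mv, "gfp", roi15, frames = c(10, 45))
  expect_true(all(dm$resolved))
  expect_equal(dm$diameter_um, c(1, 1), tolerance = 0.02)
})

test_that("coincident puncta are flagged below resolution", {
  flat <- new("KineticTrace", cellId = "c", protein = "X",
              condition = "control", times = defaultGrid(),
              intensity = rep(60, 91), diameter = rep(0, 91), t0 = 0)
  mv <- renderMovie(flat, scene, breakFrame = 46, noise = FALSE)
  dm <- measureRingDiameter(mv, "gfp", roi15, frames = 20)
  expect_false(dm$resolved)
  expect_true(is.na(dm$diameter_um))
})

test_that("diameter series recovered from a noisy movie matches the truth", {
  dm <- measureRingDiameter(noisyMovie, "ring", roi15)
  dHat <- ifelse(dm$resolved, dm$diameter_um, 0)
  rmse <- sqrt(mean((dHat - cleanTruth$diameter)^2))
  expect_lt(rmse, 0.1)
})

test_that("diameter estimate is unbiased for separations at least 3 PSF sigma (noise off)", {
  for (sep in c(0.5, 0.7, 1.0)) {   # >= 3 * 0.15 um
    tr <- new("KineticTrace", cellId = "c", protein = "X",
              condition = "control", times = defaultGrid(),
              intensity = rep(60, 91), diameter = rep(sep, 91), t0 = 0)
    mv <- renderMovie(tr, scene, breakFrame = 46, noise = FALSE)
    dm <- measureRingDiameter(mv, "gfp", roi15, frames = 30)
    expect_true(dm$resolved)
    expect_lt(abs(dm$diameter_um - sep), 0.05)
  }
})

test_that("spindle breakage is exact on noiseless movies and within 2 frames under noise", {
  expect_identical(detectSpindleBreakage(cleanMovie), 46L)
  errs <- vapply(1:50, function(s) {
    ring <- simulateConstriction(defaultConstrictionParams(),
                                 seed = cytokinetics:::childSeed(s, 9))
    bf <- 40L + (s %% 12L)
    mv <- renderMovie(ring, scene, breakFrame = bf, noise = TRUE, seed = s)
    detectSpindleBreakage(mv) - bf
  }, 0L)
  expect_gte(mean(abs(errs) <= 2), 0.95)
})

test_that("spindle error branches name the failure", {
  tr <- simulateConstriction(noiselessParams(), seed = 1)
  neverElongates <- renderMovie(tr, scene, breakFrame = 200, noise = FALSE)
  expect_error(detectSpindleBreakage(neverElongates), "no anaphase spindle")
  neverBreaks <- renderMovie(tr, scene, breakFrame = 95, noise = FALSE)
  expect_error(detectSpindleBreakage(neverBreaks), "never breaks")
  # abrupt disappearance without splitting is called at the vanishing frame
  gone <- cleanMovie
  gone@channels$spindle[, , 40:91] <- 0
  expect_identical(detectSpindleBreakage(gone), 40L)
})

test_that("intensity-diameter relation behaves across the designed cases", {
  tr <- simulateConstriction(noiselessParams(), seed = 1)
  ok <- tr@diameter > 0
  r <- intensityDiameterRelation(tr@intensity[ok], tr@diameter[ok])
  expect_equal(r$r, 1, tolerance = 1e-6)
  # pooled noisy cells stay strongly correlated
  ens <- simulateConstrictionEnsemble(30, defaultConstrictionParams(),
                                      seed = 15)
  I <- unlist(lapply(ens$traces, function(x) x@intensity))
  D <- unlist(lapply(ens$traces, function(x) x@diameter))
  keep <- D > 0.05
  expect_gt(intensityDiameterRelation(I[keep], D[keep])$r, 0.9)
  # constant diameter (no constriction) has no defined correlation
  flatI <- seq_len(20); flatD <- rep(1, 20)
  expect_error(intensityDiameterRelation(flatI, flatD), "zero variance")
  expect_error(intensityDiameterRelation(1:3, c(1, 2, 3)), "fewer than")
})

test_that("constriction symmetry scoring recovers the generator asymmetry", {
  # analytic positions: edges of a ring closing with asymmetry a
  closing <- function(a, d0 = 1, steps = 11) {
    d <- seq(d0, 0.2, length.out = steps)
    mid <- (a / 2) * (d0 - d)
    list(p1 = mid - d / 2, p2 = mid + d / 2)
  }
  sym <- closing(0)
  expect_equal(scoreConstrictionSymmetry(sym$p1, sym$p2)$index, 0)
  expect_identical(scoreConstrictionSymmetry(sym$p1, sym$p2)$classification,
                   "symmetric")
  sweep <- closing(1)
  expect_equal(scoreConstrictionSymmetry(sweep$p1, sweep$p2)$index, 1)
  expect_identical(
    scoreConstrictionSymmetry(sweep$p1, sweep$p2)$classification,
    "asymmetric")
  # rendered movie with asymmetry 0.5, measured via the two-peak fit
  mv <- renderMovie(ringTrace, scene, breakFrame = 46, asymmetry = 0.5,
                    noise = FALSE)
  dm <- measureRingDiameter(mv, "gfp", roi15)
  sc <- scoreConstrictionSymmetry(dm$pos1_um, dm$pos2_um)
  expect_lt(abs(sc$index - 0.5), 0.1)
  expect_error(scoreConstrictionSymmetry(c(1, NA, NA), c(2, NA, NA)),
               "3 frames")
})

test_that("movies round-trip through TIFF + sidecar", {
  d <- tempfile()
  writeMovie(noisyMovie, d, "cell1")
  back <- readMovie(d, "cell1")
  expect_equal(back@channels$gfp, noisyMovie@channels$gfp,
               tolerance = 1e-6)
  expect_equal(back@times, noisyMovie@times)
  expect_equal(back@pixelSize, noisyMovie@pixelSize)
  expect_error(readMovie(d, "missing"), "sidecar")
})
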