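# kinetic signatures, biphasic constriction fits, condition comparisons

test_that("signature extraction finds the printed multi-peak and single-peak signatures", {
  hof <- aggOf(simulatePanel(thePanel, proteins = "Hof1",
                             seed = 1)$traces$Hof1)
  sg <- extractSignature(hof)
  expect_length(sg@peakTimes, 3)
  expect_true(all(abs(sg@peakTimes - c(-5, -1, 6)) <= 1))
  chs2 <- aggOf(simulatePanel(thePanel, proteins = "Chs2",
                              seed = 1)$traces$Chs2)
  sg2 <- extractSignature(chs2)
  expect_lte(abs(sg2@peakTimes[which.max(sg2@peakValues)] - 2), 1)
})

test_that("a noiseless unimodal template peaks exactly at its on-grid mu", {
  for (p in c("Iqg1", "Cts1", "Fks1")) {
    tm <- thePanel$templates[[p]]
    v <- templateValue(tm, defaultGrid())
    sg <- extractSignature(mkOf(v, protein = p))
    primary <- sg@peakTimes[which.max(sg@peakValues)]
    expect_equal(primary, tm@peakTimes[which.max(tm@amplitudes)])
  }
})

test_that("signature extraction rejects flat or short curves", {
  expect_error(extractSignature(mkOf(rep(1, 91))), "flat")
  short <- mkOf(c(1:5, rep(NA, 86)))
  expect_error(extractSignature(short), "unmasked")
})

test_that("arrival and departure bracket the peaks at the onset threshold", {
  tm <- thePanel$templates[["Cts1"]]
  sg <- extractSignature(mkOf(templateValue(tm, defaultGrid()),
                              protein = "Cts1"))
  expect_lt(sg@arrivalTime, min(sg@peakTimes))
  expect_gt(sg@departureTime, max(sg@peakTimes))
  # threshold crossing: baseline ~0, 15% of peak
  v <- templateValue(tm, defaultGrid())
  thr <- 0.15 * max(v)
  expect_lt(abs(v[which(defaultGrid() == round(sg@arrivalTime))] - thr),
            0.1 * max(v))
})

test_that("noiseless piecewise input is recovered exactly", {
  t <- seq(-6, 4)
  d <- ifelse(t <= -2, 1.16 - 0.02 * (t + 6), 1.08 - 0.18 * (t + 2))
  f <- fitBiphasic(t, d, requireClosure = FALSE)
  expect_equal(f@breakpoint, -2)
  expect_equal(f@slowRate, 0.02, tolerance = 1e-9)
  expect_equal(f@fastRate, 0.18, tolerance = 1e-9)
  expect_lt(f@sse, 1e-18)
})

test_that("a single-slope line gives equal rates and the earliest breakpoint", {
  t <- seq(-6, 6)
  d <- 2 - 0.1 * (t + 6)
  f <- fitBiphasic(t, d, requireClosure = FALSE)
  expect_equal(f@slowRate, 0.1, tolerance = 1e-9)
  expect_equal(f@fastRate, 0.1, tolerance = 1e-9)
  expect_equal(f@breakpoint, t[2])   # tie -> earliest candidate
})

test_that("fit equals the brute-force breakpoint-enumeration oracle on random instances", {
  set.seed(91)
  for (i in 1:100) {
    n <- sample(8:25, 1)
    t <- seq(0, n - 1)
    tb <- sample(3:(n - 4), 1)
    d <- 3 - cumsum(c(0, ifelse(seq_len(n - 1) <= tb, runif(1, 0, 0.1),
                                runif(1, 0.1, 0.3))))
    d <- d + rnorm(n, 0, 0.05)
    f <- fitBiphasic(t, d, requireClosure = FALSE, d0Frac = 0.99)
    idx <- which(t == f@onset):which(t == f@end)
    oracle <- bruteForceBiphasic(t[idx], d[idx])
    expect_equal(f@sse, oracle$sse, tolerance = 1e-9)
    expect_equal(f@breakpoint, oracle$tau, tolerance = 1e-9)
  }
})

test_that("per-phase drops conserve the fitted diameter change exactly", {
  ens <- simulateConstrictionEnsemble(10, defaultConstrictionParams(),
                                      seed = 5)
  on <- estimateConstrictionOnset(ens$traces)
  for (tr in ens$traces) {
    f <- tryCatch(fitBiphasic(tr, onset = on), error = function(e) NULL)
    if (is.null(f)) next
    t <- tr@times
    # fitted model values at the window ends reconstruct the drops
    predDrop <- f@slowRate * (f@breakpoint - f@onset) +
      f@fastRate * (f@end - f@breakpoint)
    expect_equal(f@slowDrop + f@fastDrop, predDrop, tolerance = 1e-9)
    expect_equal(f@percentFast,
                 100 * f@fastDrop / (f@slowDrop + f@fastDrop),
                 tolerance = 1e-9)
  }
})

test_that("breakpoint error is monotone-ish in diameter noise", {
  medErr <- vapply(c(0.005, 0.02, 0.06), function(ns) {
    errs <- vapply(1:50, function(s) {
      p <- defaultConstrictionParams(noiseSd = ns)
      tr <- simulateConstriction(p, seed = cytokinetics:::childSeed(s, 3))
      tru <- attr(tr, "truth")
      f <- tryCatch(fitBiphasic(tr, onset = -6), error = function(e) NULL)
      if (is.null(f)) return(NA_real_)
      abs(f@breakpoint - tru$breakpoint)
    }, 0)
    median(errs, na.rm = TRUE)
  }, 0)
  expect_true(all(diff(medErr) >= -1))   # tolerance: one grid step
})

test_that("constriction summaries behave across ensemble sizes", {
  # zero-variance ensemble: fold ratio exactly 9
  ens0 <- simulateConstrictionEnsemble(5, noiselessParams(), seed = 1)
  fits0 <- lapply(ens0$traces, fitBiphasic)
  sm0 <- summarizeConstriction(fits0)
  expect_equal(sm0$foldRatio, 0.18 / 0.02, tolerance = 1e-9)
  # single fit: SDs are NA markers
  sm1 <- summarizeConstriction(fits0[1])
  expect_true(all(is.na(sm1$stats$sd)))
  expect_error(summarizeConstriction(list()), "no fits")
})

test_that("non-closing rings are refused unless explicitly allowed", {
  p <- defaultConstrictionParams(slowRate = 0.002, slowRateSd = 0,
                                 slowDropSd = 0, noiseSd = 0.01)
  tr <- simulateConstriction(p, seed = 2)   # breakpoint far beyond grid
  expect_error(fitBiphasic(tr), "incomplete")
  f <- fitBiphasic(tr, requireClosure = FALSE)
  expect_s4_class(f, "BiphasicFit")
  latA <- simulateConstriction(defaultConstrictionParams(constrict = FALSE),
                               seed = 2)
  expect_error(fitBiphasic(latA), "never declines")
})

test_that("comparing a curve with itself is the identity tuple", {
  mk <- aggOf(simulatePanel(thePanel, proteins = "Mlc1",
                            seed = 2)$traces$Mlc1)
  cc <- compareConditions(mk, mk)
  expect_equal(cc@peakRatioPct, 100)
  expect_equal(cc@peakShift, 0)
  expect_equal(cc@rateRatioPct, 100)
  expect_equal(cc@magnitudeRatioPct, 100)
})

test_that("amplitude scaling and peak shifts are recovered from synthetic treatments", {
  ctrl <- aggOf(simulatePanel(thePanel, proteins = "Mlc1",
                              seed = 1)$traces$Mlc1)
  eff <- conditionEffect(amplitudeFactor = 0.66, peakShift = -3)
  treat <- aggOf(simulatePanel(thePanel, proteins = "Mlc1", seed = 1001,
                               effect = eff,
                               conditionName = "LatA")$traces$Mlc1)
  cc <- compareConditions(treat, ctrl)
  expect_lt(abs(cc@peakRatioPct - 66), 5)
  expect_lte(abs(cc@peakShift - (-3)), 1)
})

test_that("rate reduction is recovered as percent of the control rate", {
  ctrl <- aggOf(simulatePanel(thePanel, proteins = "Chs2",
                              seed = 1)$traces$Chs2)
  eff <- conditionEffect(rateFactor = 0.37)
  treat <- aggOf(simulatePanel(thePanel, proteins = "Chs2", seed = 2001,
                               effect = eff,
                               conditionName = "LatA")$traces$Chs2)
  cc <- compareConditions(treat, ctrl)
  expect_lt(abs(cc@rateRatioPct - 37), 6)
})

test_that("condition comparisons enforce their preconditions", {
  a <- aggOf(simulatePanel(thePanel, proteins = "Chs2",
                           seed = 3)$traces$Chs2)
  b <- aggOf(simulatePanel(thePanel, proteins = "Mlc1",
                           seed = 3)$traces$Mlc1)
  expect_error(compareConditions(a, b), "different proteins")
  zero <- mkOf(rep(0, 91), protein = "Chs2")
  expect_error(compareConditions(a, zero), "control peak")
})

test_that("step drops are computed as percent of the window start", {
  expect_equal(measureStepDrop(mkOf(rep(5, 91)), -6, -1), 0)
  v <- rep(100, 91); v[defaultGrid() == -1] <- 77.4
  expect_equal(measureStepDrop(mkOf(v), -6, -1), 22.6, tolerance = 1e-12)
  expect_error(measureStepDrop(mkOf(rep(0, 91)), -6, -1), "zero value")
  expect_error(measureStepDrop(mkOf(rep(1, 91)), -60, -1), "gridpoint")
})

test_that("recovered primary peak times match the generator for the whole panel", {
  sim <- simulatePanel(thePanel, seed = 1)
  mks <- lapply(sim$traces, aggOf)
  for (p in names(mks)) {
    sg <- extractSignature(mks[[p]])
    tm <- thePanel$templates[[p]]
    expect_lte(abs(sg@peakTimes[which.max(sg@peakValues)] -
                     tm@peakTimes[which.max(tm@amplitudes)]), 1,
               label = paste("primary peak error for", p))
  }
})

test_that("recovered rates stay within 20% of the per-ensemble truth at default noise", {
  ens <- simulateConstrictionEnsemble(30, defaultConstrictionParams(),
                                      seed = 42)
  on <- estimateConstrictionOnset(ens$traces)
  fits <- list(); truthRs <- c(); truthRf <- c()
  for (i in seq_along(ens$traces)) {
    f <- tryCatch(fitBiphasic(ens$traces[[i]], onset = on),
                  error = function(e) NULL)
    if (is.null(f) || f@slowRate >= f@fastRate) next
    fits <- c(fits, f)
    truthRs <- c(truthRs, ens$truth$slowRate[i])
    truthRf <- c(truthRf, ens$truth$fastRate[i])
  }
  sm <- summarizeConstriction(fits)
  recRf <- sm$stats$mean[sm$stats$quantity == "fastRate"]
  expect_lt(abs(recRf - mean(truthRf)) / mean(truthRf), 0.2)
})
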