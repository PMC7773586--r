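#' @include AllGenerics.R
NULL

#' Protein accumulation template
#'
#' A smooth ground-truth accumulation curve for one protein at the division
#' site, modelled as a baseline plus a sum of asymmetric Gaussian bumps.
#' Each bump has its own peak time, amplitude and distinct rise/fall widths,
#' so both sharp spikes (Hof1) and attenuated, slowly decaying curves (Cyk3)
#' are representable with few parameters, and the peak time is an explicit
#' parameter of the model.
#'
#' @slot protein protein identifier.
#' @slot module functional module label.
#' @slot baseline baseline intensity (a.u.).
#' @slot peakTimes bump peak times (min relative to spindle breakage).
#' @slot amplitudes bump amplitudes (a.u.), all positive.
#' @slot riseWidths left (rise) Gaussian widths (min), all positive.
#' @slot fallWidths right (fall) Gaussian widths (min), all positive.
#' @slot arrivalTime nominal arrival at the division site (min).
#' @slot departureTime nominal departure from the division site (min).
#' @slot provenance named character vector recording, per field group,
#'   whether the value is reported in published results or a package
#'   decision.
#' @export
setClass("TemplateCurve",
  representation(protein = "character", module = "character",
                 baseline = "numeric", peakTimes = "numeric",
                 amplitudes = "numeric", riseWidths = "numeric",
                 fallWidths = "numeric", arrivalTime = "numeric",
                 departureTime = "numeric", provenance = "character"),
  prototype(baseline = 0, provenance = character()))

setValidity("TemplateCurve", function(object) {
  k <- length(object@peakTimes)
  msg <- character()
  if (length(object@amplitudes) != k || length(object@riseWidths) != k ||
      length(object@fallWidths) != k)
    msg <- c(msg, "bump parameter vectors must have equal length")
  if (any(object@amplitudes <= 0)) msg <- c(msg, "amplitudes must be > 0")
  if (any(object@riseWidths <= 0) || any(object@fallWidths <= 0))
    msg <- c(msg, "rise/fall widths must be > 0")
  if (object@baseline < 0) msg <- c(msg, "baseline must be >= 0")
  if (k > 0 && object@arrivalTime >= min(object@peakTimes))
    msg <- c(msg, "arrivalTime must precede the first peak")
  if (k > 0 && object@departureTime <= max(object@peakTimes))
    msg <- c(msg, "departureTime must follow the last peak")
  if (length(msg)) msg else TRUE
})

#' Biphasic ring-constriction parameters
#'
#' Ground-truth parameters of the piecewise-linear actomyosin-ring
#' constriction model: the diameter holds at its initial value until
#' \code{onsetTime}, decreases at the slow rate until the slow-phase
#' diameter drop is spent, then at the fast rate until the fast-phase drop
#' is spent, after which the ring is gone (diameter 0). Per-cell rates and
#' drops are drawn from gamma distributions with the configured means and
#' SDs (exact first two moments on positive support); phase durations are
#' derived as drop/rate.
#'
#' @slot onsetTime constriction onset (min), default -6.
#' @slot slowRate,slowRateSd slow-phase rate mean and SD (um/min).
#' @slot fastRate,fastRateSd fast-phase rate mean and SD (um/min).
#' @slot slowDrop,slowDropSd slow-phase diameter drop mean and SD (um).
#' @slot fastDrop,fastDropSd fast-phase diameter drop mean and SD (um).
#' @slot initialDiameter initial ring diameter (um); \code{NA} means the
#'   per-cell sum of the sampled drops.
#' @slot constrict logical; \code{FALSE} emulates actin depolymerisation
#'   (no constriction, linear marker disassembly).
#' @slot noiseSd additive measurement noise SD on the diameter trace (um).
#' @export
setClass("ConstrictionParams",
  representation(onsetTime = "numeric",
                 slowRate = "numeric", slowRateSd = "numeric",
                 fastRate = "numeric", fastRateSd = "numeric",
                 slowDrop = "numeric", slowDropSd = "numeric",
                 fastDrop = "numeric", fastDropSd = "numeric",
                 initialDiameter = "numeric", constrict = "logical",
                 noiseSd = "numeric"))

setValidity("ConstrictionParams", function(object) {
  msg <- character()
  if (object@slowRate <= 0 || object@fastRate <= 0)
    msg <- c(msg, "rate means must be > 0")
  if (object@slowDrop <= 0 || object@fastDrop <= 0)
    msg <- c(msg, "drop means must be > 0")
  if (any(c(object@slowRateSd, object@fastRateSd, object@slowDropSd,
            object@fastDropSd, object@noiseSd) < 0))
    msg <- c(msg, "SDs must be >= 0")
  if (!is.na(object@initialDiameter) && object@initialDiameter <= 0)
    msg <- c(msg, "initialDiameter must be > 0")
  if (length(msg)) msg else TRUE
})

#' Condition effect on a kinetic template
#'
#' Multiplicative/additive perturbation applied to a control template to
#' emulate drug or deletion experiments: peak amplitude scaling, peak-time
#' shift, accumulation-rate scaling (implemented by widening the rise in
#' proportion to amplitudeFactor/rateFactor, which scales the maximal
#' rising slope by rateFactor), and loss of ring constriction.
#'
#' @slot amplitudeFactor fraction of the control peak value (>= 0).
#' @slot peakShift shift of peak times (min).
#' @slot rateFactor fraction of the control accumulation rate (>= 0).
#' @slot constrict logical, whether the ring still constricts.
#' @export
setClass("ConditionEffect",
  representation(amplitudeFactor = "numeric", peakShift = "numeric",
                 rateFactor = "numeric", constrict = "logical"),
  prototype(amplitudeFactor = 1, peakShift = 0, rateFactor = 1,
            constrict = TRUE))

setValidity("ConditionEffect", function(object) {
  if (object@amplitudeFactor < 0 || object@rateFactor < 0)
    "factors must be >= 0" else TRUE
})

#' Synthetic microscope scene configuration
#'
#' Geometry, optics and noise of the rendered movies. The seed fully
#' determines the rendered output.
#'
#' @slot imageSize image width/height in pixels.
#' @slot pixelSize um per pixel.
#' @slot frameInterval min between frames.
#' @slot psfSigma Gaussian PSF sigma (um).
#' @slot neckCenter neck center, 0-based pixel coordinates (x, y).
#' @slot motherBudAxis unit vector of the mother-bud axis; the ring is
#'   edge-on, its two puncta separated along the perpendicular.
#' @slot gain photon gain (photons per intensity unit) for Poisson noise.
#' @slot readNoiseSd Gaussian read-noise SD (counts).
#' @slot tStart time of the first frame (min).
#' @slot nFrames number of frames.
#' @export
setClass("SceneConfig",
  representation(imageSize = "integer", pixelSize = "numeric",
                 frameInterval = "numeric", psfSigma = "numeric",
                 neckCenter = "numeric", motherBudAxis = "numeric",
                 gain = "numeric", readNoiseSd = "numeric",
                 tStart = "numeric", nFrames = "integer"))

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
  if (abs(sqrt(sum(object@motherBudAxis^2)) - 1) > 1e-8)
    msg <- c(msg, "motherBudAxis must be a unit vector")
  if (any(object@neckCenter < 0) ||
      any(object@neckCenter > object@imageSize - 1))
    msg <- c(msg, "neckCenter must lie within the image")
  if (length(msg)) msg else TRUE
})

#' Single-cell kinetic trace
#'
#' One cell x one channel time series of background-subtracted intensity
#' (and optionally ring diameter) with raw timestamps and the per-cell
#' spindle-breakage clock time t0.
#'
#' @slot cellId cell identifier.
#' @slot protein protein identifier.
#' @slot condition condition label (e.g. "control", "LatA").
#' @slot times raw timestamps (min), strictly increasing.
#' @slot intensity background-subtracted intensity (a.u.).
#' @slot diameter ring diameter (um) or length-0 if absent.
#' @slot t0 spindle-breakage time on the raw time axis (min).
#' @export
setClass("KineticTrace",
  representation(cellId = "character", protein = "character",
                 condition = "character", times = "numeric",
                 intensity = "numeric", diameter = "numeric",
                 t0 = "numeric"),
  prototype(condition = "control", diameter = numeric()))

setValidity("KineticTrace", function(object) {
  msg <- character()
  if (length(object@times) != length(object@intensity))
    msg <- c(msg, "times and intensity must have equal length")
  if (length(object@diameter) &&
      length(object@diameter) != length(object@times))
    msg <- c(msg, "diameter must be empty or match times")
  if (any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(object@t0) == 1 && !is.na(object@t0) &&
      (object@t0 < min(object@times) || object@t0 > max(object@times)))
    msg <- c(msg, "t0 must lie within the observed time range")
  if (length(msg)) msg else TRUE
})

#' Mean aligned kinetics
#'
#' Per-timepoint mean and SD of clock-aligned single-cell traces on a
#' uniform grid. Gridpoints observed in fewer than \code{nMin} cells are
#' masked (NA).
#'
#' @slot protein protein identifier.
#' @slot condition condition label.
#' @slot grid uniform time grid (min relative to spindle breakage).
#' @slot mean per-gridpoint mean intensity (a.u., NA where masked).
#' @slot sd per-gridpoint sample SD (a.u., NA where masked).
#' @slot n number of contributing cells per gridpoint.
#' @slot nMin masking threshold used.
#' @export
setClass("MeanKinetics",
  representation(protein = "character", condition = "character",
                 grid = "numeric", mean = "numeric", sd = "numeric",
                 n = "integer", nMin = "integer"),
  prototype(condition = "control", nMin = 10L))

setValidity("MeanKinetics", function(object) {
  msg <- character()
  len <- length(object@grid)
  if (length(object@mean) != len || length(object@sd) != len ||
      length(object@n) != len)
    msg <- c(msg, "grid, mean, sd, n must have equal length")
  if (len > 1) {
    d <- diff(object@grid)
    if (any(abs(d - d[1]) > 1e-9)) msg <- c(msg, "grid must be uniform")
  }
  if (any(object@sd < 0, na.rm = TRUE)) msg <- c(msg, "sd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Kinetic signature
#'
#' The comparison currency of the analysis: peak time(s), peak value(s),
#' arrival and departure of one protein/condition mean curve.
#'
#' @slot protein protein identifier.
#' @slot condition condition label.
#' @slot peakTimes detected peak times (min), sorted ascending.
#' @slot peakValues mean-curve values at the peaks (a.u.).
#' @slot arrivalTime onset-threshold crossing time (min).
#' @slot departureTime final threshold crossing time (min).
#' @export
setClass("KineticSignature",
  representation(protein = "character", condition = "character",
                 peakTimes = "numeric", peakValues = "numeric",
                 arrivalTime = "numeric", departureTime = "numeric"))

setValidity("KineticSignature", function(object) {
  msg <- character()
  if (is.unsorted(object@peakTimes))
    msg <- c(msg, "peakTimes must be sorted ascending")
  if (length(object@peakTimes) &&
      (object@arrivalTime > min(object@peakTimes) ||
       object@departureTime < max(object@peakTimes)))
    msg <- c(msg, "arrival <= first peak <= last peak <= departure violated")
  if (length(msg)) msg else TRUE
})

#' Two-segment constriction fit
#'
#' Continuous piecewise-linear least-squares fit of a ring-diameter trace:
#' a slow then a fast linear decline joined at a grid breakpoint.
#'
#' @slot breakpoint fitted phase switch time (min).
#' @slot slowRate,fastRate phase rates (um/min, >= 0).
#' @slot slowDrop,fastDrop per-phase diameter decreases (um).
#' @slot percentFast 100 * fastDrop / (slowDrop + fastDrop).
#' @slot sse residual sum of squares (um^2).
#' @slot onset,end fitted constriction window (min).
#' @export
setClass("BiphasicFit",
  representation(breakpoint = "numeric", slowRate = "numeric",
                 fastRate = "numeric", slowDrop = "numeric",
                 fastDrop = "numeric", percentFast = "numeric",
                 sse = "numeric", onset = "numeric", end = "numeric"))

setValidity("BiphasicFit", function(object) {
  msg <- character()
  if (!(object@onset <= object@breakpoint && object@breakpoint <= object@end))
    msg <- c(msg, "onset <= breakpoint <= end violated")
  if (object@slowRate < 0 || object@fastRate < 0)
    msg <- c(msg, "rates must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Condition comparison
#'
#' Treatment-versus-control comparison of two mean curves of the same
#' protein.
#'
#' @slot protein protein identifier.
#' @slot peakRatioPct treated peak as percent of control peak.
#' @slot peakShift primary peak-time difference (min, treated - control).
#' @slot rateRatioPct maximal 5-min rising slope, percent of control.
#' @slot magnitudeRatioPct baseline-subtracted area under the curve,
#'   percent of control.
#' @export
setClass("ConditionComparison",
  representation(protein = "character", peakRatioPct = "numeric",
                 peakShift = "numeric", rateRatioPct = "numeric",
                 magnitudeRatioPct = "numeric"))

setValidity("ConditionComparison", function(object) {
  if (any(c(object@peakRatioPct, object@rateRatioPct,
            object@magnitudeRatioPct) < 0, na.rm = TRUE))
    "ratios must be >= 0" else TRUE
})

#' Pairwise kinetic similarity matrix
#'
#' Pearson correlations of mean kinetic curves over a common time window.
#'
#' @slot r symmetric correlation matrix with unit diagonal (NA for masked
#'   pairs).
#' @slot window correlation window (min, min).
#' @slot nOverlap number of jointly unmasked gridpoints per pair.
#' @export
setClass("SimilarityMatrix",
  representation(r = "matrix", window = "numeric", nOverlap = "matrix"))

setValidity("SimilarityMatrix", function(object) {
  msg <- character()
  r <- object@r
  if (nrow(r) != ncol(r)) msg <- c(msg, "r must be square")
  if (!isTRUE(all.equal(r, t(r), tolerance = 1e-12,
                        check.attributes = FALSE)))
    msg <- c(msg, "r must be symmetric")
  off <- r[!is.na(r)]
  if (length(off) && (max(off) > 1 + 1e-12 || min(off) < -1 - 1e-12))
    msg <- c(msg, "correlations must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Module assignment for a query protein
#'
#' @slot query query protein identifier.
#' @slot neighbors data.frame of ranked neighbors (protein, r, peak-time
#'   distance, module).
#' @slot predictedModule module label maximizing mean correlation.
#' @slot peakTimeModule module label of the nearest peak time.
#' @slot peakTimeDistance peak-time distance to the nearest reference (min).
#' @slot agreement whether the two assignments agree.
#' @export
setClass("ModuleAssignment",
  representation(query = "character", neighbors = "data.frame",
                 predictedModule = "character",
                 peakTimeModule = "character",
                 peakTimeDistance = "numeric", agreement = "logical"))

#' Multi-channel synthetic movie
#'
#' @slot channels named list of x-by-y-by-frame arrays.
#' @slot pixelSize um per pixel.
#' @slot frameInterval min per frame.
#' @slot times frame times (min relative to spindle breakage).
#' @slot meta list of additional metadata.
#' @export
setClass("Movie",
  representation(channels = "list", pixelSize = "numeric",
                 frameInterval = "numeric", times = "numeric",
                 meta = "list"),
  prototype(meta = list()))

## ---- accessors ----

#' Accessors for package classes
#'
#' Simple slot accessors; use these rather than \code{@}.
#'
#' @param object an object of the documented classes.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
setMethod("proteinId", "TemplateCurve", function(object) object@protein)
#' @rdname accessors
setMethod("proteinId", "KineticTrace", function(object) object@protein)
#' @rdname accessors
setMethod("proteinId", "MeanKinetics", function(object) object@protein)
#' @rdname accessors
setMethod("proteinId", "KineticSignature", function(object) object@protein)
#' @rdname accessors
setMethod("moduleLabel", "TemplateCurve", function(object) object@module)
#' @rdname accessors
setMethod("peakTimes", "TemplateCurve", function(object) object@peakTimes)
#' @rdname accessors
setMethod("peakTimes", "KineticSignature", function(object) object@peakTimes)
#' @rdname accessors
setMethod("arrivalTime", "TemplateCurve", function(object) object@arrivalTime)
#' @rdname accessors
setMethod("arrivalTime", "KineticSignature",
          function(object) object@arrivalTime)
#' @rdname accessors
setMethod("departureTime", "TemplateCurve",
          function(object) object@departureTime)
#' @rdname accessors
setMethod("departureTime", "KineticSignature",
          function(object) object@departureTime)
#' @rdname accessors
setMethod("timeGrid", "MeanKinetics", function(object) object@grid)
#' @rdname accessors
setMethod("timeGrid", "KineticTrace", function(object) object@times)
#' @rdname accessors
setMethod("intensity", "KineticTrace", function(object) object@intensity)
#' @rdname accessors
setMethod("diameter", "KineticTrace", function(object) object@diameter)
#' @rdname accessors
setMethod("meanCurve", "MeanKinetics", function(object) object@mean)
#' @rdname accessors
setMethod("sdCurve", "MeanKinetics", function(object) object@sd)
#' @rdname accessors
setMethod("nCells", "MeanKinetics", function(object) object@n)
#' @rdname accessors
setMethod("conditionLabel", "KineticTrace", function(object) object@condition)
#' @rdname accessors
setMethod("conditionLabel", "MeanKinetics",
          function(object) object@condition)

## ---- show methods ----

setMethod("show", "TemplateCurve", function(object) {
  cat("TemplateCurve", object@protein, "[", object@module, "]\n")
  cat("  baseline", object@baseline, "a.u.;",
      length(object@peakTimes), "bump(s) at",
      paste(object@peakTimes, collapse = ", "), "min\n")
  cat("  arrival", object@arrivalTime, "min; departure",
      object@departureTime, "min\n")
})

setMethod("show", "KineticTrace", function(object) {
  cat("KineticTrace", object@cellId, "(", object@protein, ",",
      object@condition, ")\n")
  cat(" ", length(object@times), "frames,",
      sprintf("t = %g..%g min, t0 = %g", min(object@times),
              max(object@times), object@t0),
      if (length(object@diameter)) "(with diameter)" else "", "\n")
})

setMethod("show", "MeanKinetics", function(object) {
  ok <- !is.na(object@mean)
  cat("MeanKinetics", object@protein, "(", object@condition, ")\n")
  cat("  grid", min(object@grid), "..", max(object@grid), "min, step",
      if (length(object@grid) > 1) diff(object@grid)[1] else NA,
      ";", sum(ok), "unmasked gridpoints; max n =", max(object@n), "\n")
})

setMethod("show", "KineticSignature", function(object) {
  cat("KineticSignature", object@protein, "(", object@condition, ")\n")
  cat("  peaks at", paste(round(object@peakTimes, 2), collapse = ", "),
      "min; arrival", round(object@arrivalTime, 2), "; departure",
      round(object@departureTime, 2), "min\n")
})

setMethod("show", "BiphasicFit", function(object) {
  cat("BiphasicFit: breakpoint", object@breakpoint, "min\n")
  cat(sprintf("  rates %.4g / %.4g um/min; drops %.4g / %.4g um (%.1f%% fast)\n",
              object@slowRate, object@fastRate, object@slowDrop,
              object@fastDrop, object@percentFast))
  cat(sprintf("  window %g..%g min, SSE %.3g um^2\n", object@onset,
              object@end, object@sse))
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat("SimilarityMatrix:", nrow(object@r), "proteins, window",
      object@window[1], "..", object@window[2], "min\n")
})

setMethod("show", "ModuleAssignment", function(object) {
  cat("ModuleAssignment for", object@query, "\n")
  cat("  predicted module:", object@predictedModule,
      if (object@agreement) "(peak-time agreement)"
      else paste0("(peak-time suggests ", object@peakTimeModule, ")"), "\n")
  top <- utils::head(object@neighbors, 3)
  cat("  top neighbors:",
      paste(sprintf("%s (r=%.2f)", top$protein, top$r), collapse = ", "),
      "\n")
})

setMethod("show", "Movie", function(object) {
  cat("Movie:", paste(names(object@channels), collapse = "/"), "channels,",
      dim(object@channels[[1]])[3], "frames of",
      dim(object@channels[[1]])[1], "x", dim(object@channels[[1]])[2],
      "px @", object@pixelSize, "um/px,", object@frameInterval,
      "min/frame\n")
})
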