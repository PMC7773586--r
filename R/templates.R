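#' @include AllClasses.R
NULL

asymGauss <- function(t, mu, A, sL, sR) {
  s <- ifelse(t < mu, sL, sR)
  A * exp(-(t - mu)^2 / (2 * s^2))
}

#' @describeIn templateValue baseline plus sum of asymmetric Gaussian bumps;
#'   the value is >= baseline at every time.
#' @export
setMethod("templateValue", "TemplateCurve", function(object, t) {
  v <- rep(object@baseline, length(t))
  for (k in seq_along(object@peakTimes))
    v <- v + asymGauss(t, object@peakTimes[k], object@amplitudes[k],
                       object@riseWidths[k], object@fallWidths[k])
  v
})

#' Load the packaged kinetic-signature panel
#'
#' Reads the structured configuration shipped with the package (or a
#' user-supplied file in the same format) into a list of
#' \linkS4class{TemplateCurve} objects, one per protein, plus the panel
#' defaults (timing jitter, intensity noise, cells per condition).
#'
#' @param configPath path to a panel YAML file; the default is the packaged
#'   25-protein panel.
#' @return a list with elements \code{templates} (named list of
#'   \linkS4class{TemplateCurve}), \code{modules} (named character vector of
#'   module descriptions), and \code{defaults} (list with
#'   \code{jitter_sd}, \code{noise_cv}, \code{n_cells}).
#' @examples
#' panel <- loadSignaturePanel()
#' peakTimes(panel$templates[["Hof1"]])
#' @export
loadSignaturePanel <- function(configPath = system.file(
    "extdata", "signature_panel.yaml", package = "cytokinetics")) {
  if (!nzchar(configPath) || !file.exists(configPath))
    stop("panel config file not found: ", configPath)
  cfg <- tryCatch(yaml::read_yaml(configPath),
                  error = function(e) stop("malformed panel config: ",
                                           conditionMessage(e)))
  for (fld in c("proteins", "defaults", "modules"))
    if (is.null(cfg[[fld]]))
      stop("malformed panel config: missing top-level field '", fld, "'")
  templates <- lapply(names(cfg$proteins), function(nm) {
    p <- cfg$proteins[[nm]]
    for (fld in c("module", "bumps", "arrival", "departure"))
      if (is.null(p[[fld]]))
        stop("malformed panel entry '", nm, "': missing field '", fld, "'")
    bump <- function(fld) vapply(p$bumps, function(b) {
      if (is.null(b[[fld]]))
        stop("malformed panel entry '", nm, "': bump without '", fld, "'")
      as.numeric(b[[fld]])
    }, 0)
    prov <- unlist(p$provenance)
    new("TemplateCurve", protein = nm, module = p$module,
        baseline = as.numeric(p$baseline %||% 0),
        peakTimes = bump("peak"), amplitudes = bump("amplitude"),
        riseWidths = bump("rise"), fallWidths = bump("fall"),
        arrivalTime = as.numeric(p$arrival),
        departureTime = as.numeric(p$departure),
        provenance = if (is.null(prov)) character() else prov)
  })
  names(templates) <- names(cfg$proteins)
  list(templates = templates,
       modules = unlist(cfg$modules),
       defaults = cfg$defaults)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## accumulation rate of a template as it is measured downstream: maximal
## 5-min sliding-window regression slope before the primary peak
templateWindowSlope <- function(object, grid = defaultGrid(),
                                windowMin = 5, jitterSd = 1) {
  v <- if (jitterSd > 0) {
    z <- seq(-4 * jitterSd, 4 * jitterSd, by = jitterSd / 8)
    w <- stats::dnorm(z, sd = jitterSd)
    w <- w / sum(w)
    vapply(grid, function(tt) sum(w * templateValue(object, tt + z)), 0)
  } else templateValue(object, grid)
  primary <- object@peakTimes[which.max(object@amplitudes)]
  maxRisingSlope(grid, v, windowMin = windowMin, tMax = primary)
}

#' @describeIn applyConditionEffect scales bump amplitudes by
#'   \code{amplitudeFactor} and shifts peak times (and arrival/departure)
#'   by \code{peakShift}. The rise widths are then rescaled by a common
#'   factor, solved numerically, so that the accumulation rate as
#'   measured downstream (the maximal 5-min sliding-window slope of the
#'   jitter-convolved mean curve before the primary peak) equals exactly
#'   \code{rateFactor} times that of the control template.
#' @param jitterSd timing-jitter SD (min) assumed when calibrating the
#'   rise-width scale against the measured window slope.
#' @export
setMethod("applyConditionEffect", c("TemplateCurve", "ConditionEffect"),
  function(object, effect, jitterSd = 1) {
    if (effect@amplitudeFactor == 0 || effect@rateFactor == 0)
      stop("zero amplitude/rate factors would degenerate the template")
    target <- effect@rateFactor *
      templateWindowSlope(object, jitterSd = jitterSd)
    object@amplitudes <- object@amplitudes * effect@amplitudeFactor
    object@peakTimes <- object@peakTimes + effect@peakShift
    object@arrivalTime <- object@arrivalTime + effect@peakShift
    object@departureTime <- object@departureTime + effect@peakShift
    widen <- function(s) {
      o <- object
      o@riseWidths <- o@riseWidths * s
      o
    }
    g <- function(s) templateWindowSlope(widen(s), jitterSd = jitterSd) -
      target
    scale0 <- effect@amplitudeFactor / effect@rateFactor
    sol <- tryCatch(
      stats::uniroot(g, lower = scale0 / 8, upper = scale0 * 8,
                     extendInt = "downX", tol = 1e-8)$root,
      error = function(e) scale0)
    object <- widen(sol)
    validObject(object)
    object
  })

#' @describeIn applyConditionEffect switches constriction off when the
#'   effect has \code{constrict = FALSE} (actin depolymerisation); rate
#'   parameters are otherwise untouched.
#' @export
setMethod("applyConditionEffect", c("ConstrictionParams", "ConditionEffect"),
  function(object, effect, ...) {
    object@constrict <- effect@constrict
    validObject(object)
    object
  })

#' Construct a condition effect
#'
#' @param amplitudeFactor peak amplitude as a fraction of control.
#' @param peakShift peak-time shift in minutes.
#' @param rateFactor accumulation rate as a fraction of control.
#' @param constrict whether the actomyosin ring still constricts.
#' @return a \linkS4class{ConditionEffect}.
#' @examples
#' latA <- conditionEffect(amplitudeFactor = 0.66, peakShift = -3,
#'                         constrict = FALSE)
#' @export
conditionEffect <- function(amplitudeFactor = 1, peakShift = 0,
                            rateFactor = 1, constrict = TRUE) {
  new("ConditionEffect", amplitudeFactor = amplitudeFactor,
      peakShift = peakShift, rateFactor = rateFactor, constrict = constrict)
}
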