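#' @include align.R
NULL

## centered moving average (window must be odd); NA-safe at the ends
movAvg <- function(v, window = 3) {
  if (window <= 1) return(v)
  half <- (window - 1) / 2
  n <- length(v)
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - half):min(n, i + half)
    mean(v[idx], na.rm = TRUE)
  }, 0)
}

## topographic prominence of local maxima
peakProminences <- function(v, peaks) {
  vapply(peaks, function(p) {
    lv <- v[seq_len(p)]
    higherL <- which(lv[-length(lv)] > v[p])
    leftMin <- min(lv[(if (length(higherL)) max(higherL) else 1):p])
    rv <- v[p:length(v)]
    higherR <- which(rv[-1] > v[p])
    rightMin <- min(rv[1:(if (length(higherR)) min(higherR) + 1
                          else length(rv))])
    v[p] - max(leftMin, rightMin)
  }, 0)
}

#' Extract the kinetic signature of a mean curve
#'
#' Smooths the mean curve with a centered moving average, detects local
#' maxima with topographic prominence of at least \code{prominenceFrac} of
#' the curve range and mutual separation of at least \code{minSeparation}
#' minutes (greedy, highest first), and refines each peak to the raw-curve
#' argmax within one gridpoint (so a noiseless on-grid peak is recovered
#' exactly). Arrival and departure are the first and last crossings of
#' baseline + \code{onsetFrac} * (primary peak - baseline), where the
#' baseline is the mean of the first 5 unmasked gridpoints.
#'
#' @param mk a \linkS4class{MeanKinetics} with >= 10 unmasked gridpoints.
#' @param prominenceFrac minimal prominence as a fraction of the range.
#' @param onsetFrac arrival/departure threshold fraction.
#' @param minSeparation minimal peak separation (min).
#' @param smoothWindow moving-average window (gridpoints).
#' @return a \linkS4class{KineticSignature}.
#' @export
extractSignature <- function(mk, prominenceFrac = 0.10, onsetFrac = 0.15,
                             minSeparation = 3, smoothWindow = 3) {
  ok <- which(!is.na(mk@mean))
  if (length(ok) < 10) stop("fewer than 10 unmasked gridpoints")
  ## longest contiguous unmasked run
  runs <- split(ok, cumsum(c(1, diff(ok) != 1)))
  seg <- runs[[which.max(lengths(runs))]]
  t <- mk@grid[seg]
  raw <- mk@mean[seg]
  s <- movAvg(raw, smoothWindow)
  rng <- max(s) - min(s)
  if (rng <= 0) stop("flat curve: zero range")
  n <- length(s)
  cand <- which(vapply(seq_len(n), function(i) {
    (i == 1 || s[i] > s[i - 1]) && (i == n || s[i] >= s[i + 1]) &&
      i > 1 && i < n
  }, TRUE))
  if (!length(cand)) stop("no local maxima found")
  prom <- peakProminences(s, cand)
  cand <- cand[prom >= prominenceFrac * rng]
  if (!length(cand)) stop("no peaks above the prominence threshold")
  ## greedy separation filter, highest (smoothed) first
  cand <- cand[order(-s[cand])]
  kept <- integer()
  for (p in cand)
    if (!length(kept) || all(abs(t[p] - t[kept]) >= minSeparation))
      kept <- c(kept, p)
  ## refine to raw argmax within +/- 1 gridpoint
  kept <- vapply(kept, function(p) {
    idx <- max(1, p - 1):min(n, p + 1)
    idx[which.max(raw[idx])]
  }, 0L)
  kept <- sort(unique(kept))
  peakT <- t[kept]
  peakV <- raw[kept]
  baseline <- mean(raw[seq_len(min(5, length(raw)))])
  thr <- baseline + onsetFrac * (max(peakV) - baseline)
  crossUp <- function() {
    if (raw[1] >= thr) return(t[1])
    i <- which(raw[-1] >= thr & raw[-length(raw)] < thr)[1]
    if (is.na(i)) return(t[1])
    t[i] + (thr - raw[i]) / (raw[i + 1] - raw[i]) * (t[i + 1] - t[i])
  }
  crossDown <- function() {
    if (raw[length(raw)] >= thr) return(t[length(raw)])
    below <- which(raw[-length(raw)] >= thr & raw[-1] < thr)
    if (!length(below)) return(t[length(raw)])
    i <- max(below)
    t[i] + (raw[i] - thr) / (raw[i] - raw[i + 1]) * (t[i + 1] - t[i])
  }
  new("KineticSignature", protein = mk@protein, condition = mk@condition,
      peakTimes = peakT, peakValues = peakV,
      arrivalTime = min(crossUp(), min(peakT)),
      departureTime = max(crossDown(), max(peakT)))
}

## exact constrained (slopes <= 0) continuous two-segment LS at breakpoint
## tau over points (t, d): enumerate active sets, solve normal equations.
segfitAt <- function(t, d, tau) {
  x1 <- pmin(t - tau, 0)
  x2 <- pmax(t - tau, 0)
  solveLS <- function(X) {
    XtX <- crossprod(X)
    co <- tryCatch(solve(XtX, crossprod(X, d)),
                   error = function(e) NULL)
    if (is.null(co)) return(NULL)
    res <- d - X %*% co
    list(coef = as.vector(co), sse = sum(res^2))
  }
  ones <- rep(1, length(t))
  best <- NULL
  ## case 1: both slopes free
  f <- solveLS(cbind(ones, x1, x2))
  if (!is.null(f) && f$coef[2] <= 1e-12 && f$coef[3] <= 1e-12)
    best <- list(b0 = f$coef[1], b1 = min(f$coef[2], 0),
                 b2 = min(f$coef[3], 0), sse = f$sse)
  ## case 2: slow slope clamped to 0
  f <- solveLS(cbind(ones, x2))
  if (!is.null(f) && f$coef[2] <= 1e-12) {
    cand <- list(b0 = f$coef[1], b1 = 0, b2 = min(f$coef[2], 0), sse = f$sse)
    if (is.null(best) || cand$sse < best$sse - 1e-15) best <- cand
  }
  ## case 3: fast slope clamped to 0
  f <- solveLS(cbind(ones, x1))
  if (!is.null(f) && f$coef[2] <= 1e-12) {
    cand <- list(b0 = f$coef[1], b1 = min(f$coef[2], 0), b2 = 0, sse = f$sse)
    if (is.null(best) || cand$sse < best$sse - 1e-15) best <- cand
  }
  ## case 4: both clamped (flat)
  cand <- list(b0 = mean(d), b1 = 0, b2 = 0, sse = sum((d - mean(d))^2))
  if (is.null(best) || cand$sse < best$sse - 1e-15) best <- cand
  best
}

## Exact LS changepoint search for the constriction onset: continuous
## plateau + two-segment decline (flat, then two non-positive slopes) over
## the whole pre-closure trace. Used only to delimit the fit window; the
## constriction itself is modelled by the two-segment fit.
plateauOnset <- function(t, d, endIdx) {
  n <- endIdx
  tt <- t[seq_len(n)]; dd <- d[seq_len(n)]
  best <- NULL
  for (c1 in seq_len(n - 3)) {
    for (c2 in (c1 + 1):(n - 1)) {
      u1 <- pmin(pmax(tt - tt[c1], 0), tt[c2] - tt[c1])
      u2 <- pmax(tt - tt[c2], 0)
      X <- cbind(1, u1, u2)
      co <- tryCatch(solve(crossprod(X), crossprod(X, dd)),
                     error = function(e) NULL)
      if (is.null(co)) next
      if (co[2] > 1e-9 || co[3] > 1e-9) next   # decline slopes only
      sse <- sum((dd - X %*% co)^2)
      if (is.null(best) || sse < best$sse - 1e-12)
        best <- list(c1 = c1, sse = sse)
    }
  }
  if (is.null(best)) 1L else best$c1
}

#' Fit the biphasic (two-segment) constriction model
#'
#' First locates the constriction window: the window ends at the first
#' gridpoint at or below \code{floorUm} (else the minimum after the
#' plateau), and the onset (end of the initial plateau) is the exact
#' least-squares changepoint of a continuous plateau-plus-two-segment
#' decline over the pre-closure trace. Then, for every
#' interior grid breakpoint candidate within the window, solves the
#' continuous two-segment linear least-squares problem with both slopes
#' constrained non-positive, and returns the candidate minimizing the SSE
#' (ties: earliest breakpoint). Rates are the negated slopes; per-phase
#' drops are rate times segment duration, so slowDrop + fastDrop equals
#' the fitted diameter change over the window exactly.
#'
#' @param x a \linkS4class{KineticTrace} carrying a diameter, or a numeric
#'   vector of times.
#' @param diameter numeric diameter vector (um) when \code{x} is numeric.
#' @param floorUm resolution floor below which the ring counts as closed.
#' @param d0Frac fraction of the initial diameter used to locate the
#'   definitive start of the decline.
#' @param smoothWindow moving-average window for window detection only
#'   (the fit itself uses the raw trace).
#' @param onset optional known/ensemble-estimated constriction onset time
#'   (min); when supplied (see \code{\link{estimateConstrictionOnset}}),
#'   the per-trace onset search is skipped. A slow phase shorter than the
#'   frame interval cannot be resolved per cell, so ensemble analyses
#'   should estimate the onset from the mean diameter curve.
#' @param requireClosure error (rather than fitting to the observed
#'   minimum) when the diameter never reaches \code{floorUm}: a ring that
#'   does not close within the movie has no measurable fast phase.
#' @return a \linkS4class{BiphasicFit}.
#' @export
fitBiphasic <- function(x, diameter = NULL, floorUm = 0.05, d0Frac = 0.95,
                        smoothWindow = 3, onset = NULL,
                        requireClosure = TRUE) {
  if (is(x, "KineticTrace")) {
    if (!length(x@diameter)) stop("trace carries no diameter")
    t <- x@times - x@t0
    d <- x@diameter
  } else {
    t <- x; d <- diameter
  }
  stopifnot(length(t) == length(d))
  s <- movAvg(d, smoothWindow)
  d0 <- max(s)
  below <- s < d0Frac * d0
  k <- if (!any(below)) NA_integer_ else max(which(!below)) + 1L
  if (is.na(k) || k > length(d))
    stop("no constriction: diameter never declines")
  iMax <- which.max(s)
  after <- which(d <= floorUm & seq_along(d) > iMax)[1]
  if (is.na(after) && requireClosure)
    stop("constriction incomplete: ring does not close within the trace")
  endIdx <- if (!is.na(after)) after
            else iMax + which.min(d[(iMax + 1):length(d)])
  onsetIdx <- if (!is.null(onset)) which.min(abs(t - onset))
              else if (k > 3) plateauOnset(t, d, endIdx) else 1L
  if (endIdx - onsetIdx + 1 < 4) stop("no constriction: window too short")
  win <- onsetIdx:endIdx
  tw <- t[win]; dw <- d[win]
  best <- NULL
  for (ci in 2:(length(win) - 1)) {
    f <- segfitAt(tw, dw, tw[ci])
    if (is.null(best) || f$sse < best$sse - 1e-12) {
      best <- f; best$tau <- tw[ci]
    }
  }
  slowRate <- -best$b1
  fastRate <- -best$b2
  slowDrop <- slowRate * (best$tau - tw[1])
  fastDrop <- fastRate * (tw[length(tw)] - best$tau)
  total <- slowDrop + fastDrop
  new("BiphasicFit", breakpoint = best$tau, slowRate = slowRate,
      fastRate = fastRate, slowDrop = slowDrop, fastDrop = fastDrop,
      percentFast = if (total > 0) 100 * fastDrop / total else NA_real_,
      sse = best$sse, onset = tw[1], end = tw[length(tw)])
}

#' Estimate the constriction onset from an ensemble of diameter traces
#'
#' Averages the diameter traces point-wise (cell-to-cell noise shrinks by
#' sqrt(n)) and locates the end of the initial plateau on the mean curve
#' by the exact plateau-plus-two-segment changepoint search. All cells
#' share the constriction onset up to timing jitter, so the ensemble
#' estimate is far more stable than per-cell onset detection, which cannot
#' resolve slow phases shorter than the frame interval.
#'
#' @param traces list of \linkS4class{KineticTrace} with diameters, on a
#'   common grid.
#' @param floorUm resolution floor (um).
#' @return onset time (min).
#' @export
estimateConstrictionOnset <- function(traces, floorUm = 0.05) {
  if (!length(traces)) stop("no traces")
  t <- traces[[1]]@times - traces[[1]]@t0
  dm <- rowMeans(vapply(traces, function(tr) {
    if (!length(tr@diameter)) stop("trace without diameter")
    tr@diameter
  }, numeric(length(t))))
  s <- movAvg(dm, 3)
  iMax <- which.max(s)
  after <- which(dm <= floorUm & seq_along(dm) > iMax)[1]
  endIdx <- if (!is.na(after)) after
            else iMax + which.min(dm[(iMax + 1):length(dm)])
  t[plateauOnset(t, dm, endIdx)]
}

#' Summarize an ensemble of biphasic fits
#'
#' Sample means and SDs of the rates, per-phase drops and percent-fast
#' (averaged per cell, then across cells), plus the fold ratio
#' mean(fast rate) / mean(slow rate). Fits in which no slow phase was
#' resolved (fitted slow rate >= fast rate, i.e. an effectively
#' monophasic decline at the acquisition resolution) are excluded from
#' the phase statistics and their count reported; fits with a zero slow
#' rate are additionally excluded from the fold ratio.
#'
#' @param fits list of \linkS4class{BiphasicFit}.
#' @param excludeDegenerate exclude monophasic (slow >= fast) fits from
#'   the statistics.
#' @return list with per-quantity \code{mean}/\code{sd} (data.frame
#'   \code{stats}), \code{foldRatio}, \code{nExcludedFromFold},
#'   \code{nDegenerate}, \code{n}.
#' @export
summarizeConstriction <- function(fits, excludeDegenerate = TRUE) {
  if (!length(fits)) stop("no fits to summarize")
  deg <- vapply(fits, function(f) f@slowRate >= f@fastRate, TRUE)
  nDeg <- sum(deg)
  if (excludeDegenerate && any(deg) && !all(deg)) fits <- fits[!deg]
  get <- function(slot) vapply(fits, function(f) methods::slot(f, slot), 0)
  q <- list(slowRate = get("slowRate"), fastRate = get("fastRate"),
            slowDrop = get("slowDrop"), fastDrop = get("fastDrop"),
            percentFast = get("percentFast"))
  stats <- data.frame(
    quantity = names(q),
    mean = vapply(q, mean, 0),
    sd = vapply(q, function(v) if (length(v) > 1) stats::sd(v)
                else NA_real_, 0),
    row.names = NULL)
  slow <- q$slowRate
  excl <- slow == 0
  fold <- if (all(excl)) NA_real_
          else mean(q$fastRate[!excl]) / mean(slow[!excl])
  list(stats = stats, foldRatio = fold, nExcludedFromFold = sum(excl),
       nDegenerate = nDeg, n = length(fits))
}

## max regression slope over sliding windows of `windowMin` minutes ending
## at or before `tMax`
maxRisingSlope <- function(t, v, windowMin = 5, tMax = Inf) {
  ok <- !is.na(v)
  t <- t[ok]; v <- v[ok]
  best <- -Inf
  for (i in seq_along(t)) {
    j <- which(t >= t[i] & t <= t[i] + windowMin)
    if (length(j) < 3 || max(t[j]) > tMax) next
    fit <- stats::lm.fit(cbind(1, t[j]), v[j])
    best <- max(best, fit$coefficients[2])
  }
  if (!is.finite(best)) stop("no usable rising window before the peak")
  best
}

#' Compare a treated mean curve with its control
#'
#' Peak ratio (raw a.u.), primary peak-time shift, rising-rate ratio (the
#' maximal 5-min sliding-window regression slope before the primary peak)
#' and baseline-subtracted area-under-curve ratio, each as percent of the
#' control.
#'
#' @param mkTreat,mkCtrl \linkS4class{MeanKinetics} of the same protein
#'   sharing >= 15 unmasked gridpoints.
#' @param rateWindowMin sliding-window length for the rate (min).
#' @return a \linkS4class{ConditionComparison}.
#' @export
compareConditions <- function(mkTreat, mkCtrl, rateWindowMin = 5) {
  if (mkTreat@protein != mkCtrl@protein)
    stop("curves are from different proteins")
  joint <- !is.na(mkTreat@mean) & !is.na(mkCtrl@mean)
  if (sum(joint) < 15)
    stop("fewer than 15 jointly unmasked gridpoints")
  primary <- function(mk) {
    i <- which.max(mk@mean)
    c(time = mk@grid[i], value = mk@mean[i])
  }
  pc <- primary(mkCtrl); pt <- primary(mkTreat)
  if (pc["value"] <= 0) stop("control peak is zero")
  baselineOf <- function(mk) {
    ok <- which(!is.na(mk@mean))
    mean(mk@mean[utils::head(ok, 5)])
  }
  aucOf <- function(mk) {
    ok <- which(!is.na(mk@mean))
    v <- mk@mean[ok] - baselineOf(mk)
    sum(diff(mk@grid[ok]) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
  }
  rateOf <- function(mk) {
    ok <- !is.na(mk@mean)
    maxRisingSlope(mk@grid[ok], mk@mean[ok], rateWindowMin,
                   tMax = primary(mk)["time"])
  }
  new("ConditionComparison", protein = mkTreat@protein,
      peakRatioPct = 100 * unname(pt["value"] / pc["value"]),
      peakShift = unname(pt["time"] - pc["time"]),
      rateRatioPct = 100 * rateOf(mkTreat) / rateOf(mkCtrl),
      magnitudeRatioPct = 100 * aucOf(mkTreat) / aucOf(mkCtrl))
}

#' Percent intensity drop of a mean curve over a time window
#'
#' 100 * (mean(windowStart) - mean(windowEnd)) / mean(windowStart), e.g.
#' the septin intensity loss across the hourglass-to-double-ring
#' transition.
#'
#' @param mk a \linkS4class{MeanKinetics}.
#' @param windowStart,windowEnd window endpoints (min); must be unmasked
#'   gridpoints.
#' @return percent drop (positive = decrease).
#' @export
measureStepDrop <- function(mk, windowStart, windowEnd) {
  at <- function(tt) {
    i <- which(abs(mk@grid - tt) < 1e-9)
    if (!length(i) || is.na(mk@mean[i]))
      stop("window endpoint ", tt, " is not an unmasked gridpoint")
    mk@mean[i]
  }
  v1 <- at(windowStart); v2 <- at(windowEnd)
  if (v1 == 0) stop("zero value at window start")
  100 * (v1 - v2) / v1
}
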