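#' @include render.R
NULL

#' Division-site region of interest
#'
#' Axis-aligned rectangular ROI centered on the bud neck (the measurement
#' box), with the neck axis along which the edge-on ring puncta separate.
#'
#' @slot center 0-based (x, y) pixel coordinates of the ROI center.
#' @slot halfWidth,halfHeight ROI half-extent (px).
#' @slot axis unit vector of the neck axis (punctum separation direction).
#' @export
setClass("NeckROI",
  representation(center = "numeric", halfWidth = "numeric",
                 halfHeight = "numeric", axis = "numeric"))

setValidity("NeckROI", function(object) {
  if (abs(sqrt(sum(object@axis^2)) - 1) > 1e-8)
    "axis must be a unit vector" else TRUE
})

#' @param center,halfWidth,halfHeight,axis see the class slots.
#' @rdname NeckROI-class
#' @export
neckRoi <- function(center = c(32, 32), halfWidth = 7, halfHeight = 7,
                    axis = c(0, 1)) {
  new("NeckROI", center = center, halfWidth = halfWidth,
      halfHeight = halfHeight, axis = axis / sqrt(sum(axis^2)))
}

roiIndices <- function(roi, nx, ny) {
  xs <- seq(floor(roi@center[1] - roi@halfWidth),
            ceiling(roi@center[1] + roi@halfWidth))
  ys <- seq(floor(roi@center[2] - roi@halfHeight),
            ceiling(roi@center[2] + roi@halfHeight))
  if (min(xs) < 0 || min(ys) < 0 || max(xs) > nx - 1 || max(ys) > ny - 1)
    stop("ROI out of image bounds")
  list(x = xs + 1L, y = ys + 1L)   # 1-based array indices
}

#' Measure background-subtracted ROI intensity
#'
#' Per frame, the background level is the median of the pixels in a
#' concentric margin ring just outside the ROI; the measurement is the sum
#' of (pixel - background) over the ROI, clipped at zero. Adding a constant
#' to every pixel therefore leaves the measurement unchanged, and scaling
#' the image by c scales it by c.
#'
#' @param movie a \linkS4class{Movie}.
#' @param channel channel name.
#' @param roi a \linkS4class{NeckROI}.
#' @param marginPx width of the background margin ring (px).
#' @param bleachTau optional photobleaching time constant (min); when
#'   given, the series is multiplied by exp((t - t_first)/bleachTau) to
#'   undo an exponential decay. No correction is applied by default.
#' @return numeric vector, one background-subtracted sum per frame.
#' @export
measureRoiIntensity <- function(movie, channel, roi, marginPx = 2,
                                bleachTau = NULL) {
  if (!channel %in% names(movie@channels))
    stop("channel '", channel, "' not present in movie")
  arr <- movie@channels[[channel]]
  nx <- dim(arr)[1]; ny <- dim(arr)[2]
  inner <- roiIndices(roi, nx, ny)
  outerRoi <- new("NeckROI", center = roi@center,
                  halfWidth = roi@halfWidth + marginPx,
                  halfHeight = roi@halfHeight + marginPx, axis = roi@axis)
  outer <- tryCatch(roiIndices(outerRoi, nx, ny),
                    error = function(e)
                      stop("no room for a background margin around the ROI"))
  out <- vapply(seq_len(dim(arr)[3]), function(i) {
    fr <- arr[, , i]
    ring <- fr[outer$x, outer$y]
    ring[seq_along(inner$x) + match(inner$x[1], outer$x) - 1L,
         seq_along(inner$y) + match(inner$y[1], outer$y) - 1L] <- NA
    bg <- stats::median(ring, na.rm = TRUE)
    max(sum(fr[inner$x, inner$y] - bg), 0)
  }, 0)
  if (!is.null(bleachTau))
    out <- out * exp((movie@times - movie@times[1]) / bleachTau)
  out
}

## intensity profile along the ROI axis through the ROI center, averaged
## over `stripPx` parallel lines (bilinear interpolation)
axisProfile <- function(frame, roi, halfLenPx, stripPx = 3) {
  nx <- nrow(frame); ny <- ncol(frame)
  perp <- c(-roi@axis[2], roi@axis[1])
  s <- seq(-halfLenPx, halfLenPx)
  offs <- seq(-(stripPx - 1) / 2, (stripPx - 1) / 2)
  interp <- function(x, y) {
    x0 <- floor(x); y0 <- floor(y)
    x0 <- pmin(pmax(x0, 0), nx - 2); y0 <- pmin(pmax(y0, 0), ny - 2)
    fx <- x - x0; fy <- y - y0
    frame[cbind(x0 + 1, y0 + 1)] * (1 - fx) * (1 - fy) +
      frame[cbind(x0 + 2, y0 + 1)] * fx * (1 - fy) +
      frame[cbind(x0 + 1, y0 + 2)] * (1 - fx) * fy +
      frame[cbind(x0 + 2, y0 + 2)] * fx * fy
  }
  prof <- rowMeans(vapply(offs, function(o) {
    x <- roi@center[1] + s * roi@axis[1] + o * perp[1]
    y <- roi@center[2] + s * roi@axis[2] + o * perp[2]
    interp(x, y)
  }, numeric(length(s))))
  list(s = s, value = prof)
}

gauss1 <- function(s, p) p[1] + p[2] * exp(-(s - p[3])^2 / (2 * p[4]^2))
gauss2 <- function(s, p)
  p[1] + p[2] * exp(-(s - p[3])^2 / (2 * p[5]^2)) +
  p[4] * exp(-(s - p[6])^2 / (2 * p[5]^2))

fitProfile <- function(s, v, sigma0) {
  sse <- function(res) sum(res^2)
  b0 <- min(v); a0 <- max(v) - b0
  w <- pmax(v - b0, 0)
  m0 <- if (sum(w) > 0) sum(s * w) / sum(w) else 0
  fit1 <- stats::optim(c(b0, a0, m0, sigma0),
                       function(p) sse(v - gauss1(s, abs(p))),
                       control = list(maxit = 500))
  best2 <- NULL
  for (sep in c(1, 2, 4, 6, 8, 10, 12)) {
    f <- stats::optim(c(b0, a0 / 2, m0 - sep / 2, a0 / 2, sigma0, m0 + sep / 2),
                      function(p) sse(v - gauss2(s, c(p[1], abs(p[2]), p[3],
                                                      abs(p[4]), abs(p[5]),
                                                      p[6]))),
                      control = list(maxit = 800))
    if (is.null(best2) || f$value < best2$value) best2 <- f
  }
  list(sse1 = fit1$value, sse2 = best2$value,
       p1 = best2$par[3], p2 = best2$par[6])
}

#' Measure ring diameter from the intensity profile across the neck
#'
#' Fits a two-Gaussian-plus-constant model (shared width) and a
#' one-Gaussian model to the intensity profile along the neck axis through
#' the ROI center; the ring diameter is the fitted peak separation times
#' the pixel size. The two-peak model is accepted only if it reduces the
#' residual sum of squares by at least \code{rssGain} (default 20\%);
#' otherwise the ring is flagged below resolution (\code{NA} diameter,
#' treated as 0 downstream).
#'
#' @param movie a \linkS4class{Movie}.
#' @param channel channel name.
#' @param roi a \linkS4class{NeckROI}; its axis is the profile direction.
#' @param frames frame indices (default all).
#' @param rssGain required fractional RSS reduction for the two-peak model.
#' @param halfLenPx profile half-length (px).
#' @return data.frame with columns \code{frame}, \code{time_min},
#'   \code{diameter_um} (NA when below resolution or no ring),
#'   \code{resolved} (logical), \code{pos1_um}, \code{pos2_um} (fitted
#'   punctum positions along the axis, NA unless resolved).
#' @export
measureRingDiameter <- function(movie, channel, roi, frames = NULL,
                                rssGain = 0.2, halfLenPx = 15) {
  if (!channel %in% names(movie@channels))
    stop("channel '", channel, "' not present in movie")
  arr <- movie@channels[[channel]]
  if (is.null(frames)) frames <- seq_len(dim(arr)[3])
  sigma0 <- (movie@meta$psfSigma %||% 0.15) / movie@pixelSize
  globalMax <- max(arr)
  res <- lapply(frames, function(i) {
    pr <- axisProfile(arr[, , i], roi, halfLenPx)
    ## no-ring guard: profile must rise clearly above its own background
    ## relative to the channel's global signal (scale-invariant)
    if (max(pr$value) - stats::median(pr$value) < 0.05 * globalMax)
      return(data.frame(frame = i, time_min = movie@times[i],
                        diameter_um = NA_real_, resolved = FALSE,
                        pos1_um = NA_real_, pos2_um = NA_real_))
    f <- fitProfile(pr$s, pr$value, sigma0)
    if (f$sse2 <= (1 - rssGain) * f$sse1) {
      d <- abs(f$p2 - f$p1) * movie@pixelSize
      data.frame(frame = i, time_min = movie@times[i], diameter_um = d,
                 resolved = TRUE,
                 pos1_um = min(f$p1, f$p2) * movie@pixelSize,
                 pos2_um = max(f$p1, f$p2) * movie@pixelSize)
    } else {
      data.frame(frame = i, time_min = movie@times[i],
                 diameter_um = NA_real_, resolved = FALSE,
                 pos1_um = NA_real_, pos2_um = NA_real_)
    }
  })
  do.call(rbind, res)
}

## connected components of mask, lengths in um (max spatial extent)
componentLengths <- function(mask, pixelSize) {
  if (!any(mask)) return(numeric())
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labm <- EBImage::imageData(lab)
  ids <- setdiff(unique(as.vector(labm)), 0)
  vapply(ids, function(id) {
    w <- which(labm == id, arr.ind = TRUE)
    sqrt(diff(range(w[, 1]))^2 + diff(range(w[, 2]))^2) * pixelSize
  }, 0)
}

#' Detect the spindle-breakage frame
#'
#' Thresholds the spindle channel at half of the per-frame maximum and
#' tracks the connected components. After an elongated anaphase spindle
#' (length >= \code{lMinUm}) has been present in at least \code{nConsec}
#' consecutive frames, breakage is called at the first frame where the
#' largest component shortens below half of its running maximum length, or
#' at least two components of >= 25\% of the running maximum remain, or no
#' component remains.
#'
#' @param movie a \linkS4class{Movie}.
#' @param channel spindle channel name.
#' @param lMinUm minimal anaphase spindle length (um).
#' @param nConsec required consecutive elongated frames before breakage.
#' @param floorFrac per-frame maxima below this fraction of the movie-wide
#'   maximum count as empty frames.
#' @return 1-based breakage frame index.
#' @export
detectSpindleBreakage <- function(movie, channel = "spindle", lMinUm = 1.5,
                                  nConsec = 3, floorFrac = 0.05) {
  if (!channel %in% names(movie@channels))
    stop("channel '", channel, "' not present in movie")
  arr <- movie@channels[[channel]]
  nF <- dim(arr)[3]
  globalMax <- max(arr)
  elongRun <- 0L
  armed <- FALSE
  runMax <- 0
  for (i in seq_len(nF)) {
    fr <- arr[, , i]
    mx <- max(fr)
    lens <- if (mx < floorFrac * globalMax) numeric()
            else componentLengths(fr >= mx / 2, movie@pixelSize)
    largest <- if (length(lens)) max(lens) else 0
    if (armed) {
      runMax <- max(runMax, largest)
      nBig <- sum(lens >= 0.25 * runMax)
      if (largest < 0.5 * runMax || nBig >= 2 || length(lens) == 0)
        return(i)
    }
    elongRun <- if (largest >= lMinUm) elongRun + 1L else 0L
    if (elongRun >= nConsec) {
      armed <- TRUE
      runMax <- max(runMax, largest)
    }
  }
  if (!armed) stop("no anaphase spindle found")
  stop("spindle never breaks within the movie")
}

#' Intensity-diameter relation of the constricting ring
#'
#' Pearson correlation and linear fit of background-subtracted ring-marker
#' intensity versus ring diameter over frames with an unflagged diameter.
#'
#' @param intensity numeric vector of per-frame ROI intensities.
#' @param diameter numeric vector of per-frame diameters (NA = flagged).
#' @param minFrames minimal number of usable frames.
#' @return list with \code{r}, \code{slope}, \code{intercept}, \code{n}.
#' @export
intensityDiameterRelation <- function(intensity, diameter, minFrames = 5) {
  ok <- is.finite(intensity) & is.finite(diameter)
  if (sum(ok) < minFrames)
    stop("fewer than ", minFrames, " frames with both intensity and diameter")
  x <- diameter[ok]; y <- intensity[ok]
  if (stats::sd(x) == 0)
    stop("diameter has zero variance; correlation undefined")
  fit <- stats::lm(y ~ x)
  list(r = stats::cor(x, y), slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), n = sum(ok))
}

#' Score constriction symmetry from punctum positions
#'
#' The asymmetry index is the displacement of the two-punctum midpoint
#' from its initial position at the frame of maximal constriction
#' progress, normalized by half of the diameter decrease realized up to
#' that frame, clipped to [0, 1]: 0 for a ring whose edges converge on a
#' fixed center, 1 when one edge stays put while the other sweeps across.
#' Normalizing by the realized (rather than the initial) diameter makes
#' the index insensitive to where the two-punctum resolution limit cuts
#' off the series.
#'
#' @param pos1,pos2 numeric vectors of punctum positions along the neck
#'   axis (um) over frames where both puncta are resolved (NA allowed).
#' @param threshold classification threshold on the index.
#' @param minProgressFrac minimal fractional diameter decrease required
#'   to score.
#' @return list with \code{index}, \code{classification}
#'   ("symmetric"/"asymmetric") and \code{nFrames}.
#' @export
scoreConstrictionSymmetry <- function(pos1, pos2, threshold = 0.25,
                                      minProgressFrac = 0.25) {
  ok <- is.finite(pos1) & is.finite(pos2)
  if (sum(ok) < 3)
    stop("need at least 3 frames with two resolved puncta")
  p1 <- pos1[ok]; p2 <- pos2[ok]
  mid <- (p1 + p2) / 2
  d <- abs(p2 - p1)
  d0 <- d[1]
  if (d0 <= 0) stop("initial diameter is zero")
  progress <- d0 - d
  i <- which.max(progress)
  if (progress[i] < minProgressFrac * d0)
    stop("insufficient constriction progress to score symmetry")
  idx <- min(abs(mid[i] - mid[1]) / (progress[i] / 2), 1)
  list(index = idx,
       classification = if (idx > threshold) "asymmetric" else "symmetric",
       nFrames = sum(ok))
}

#' Quantify a synthetic movie into per-frame measurements
#'
#' Runs ROI intensity measurement on the GFP (and, when present, ring
#' marker) channel, ring-diameter estimation, and spindle-breakage
#' detection, returning one row per frame plus the breakage frame as an
#' attribute.
#'
#' @param movie a \linkS4class{Movie}.
#' @param roi a \linkS4class{NeckROI}; default centered on the scene neck.
#' @param diameterChannel channel used for the ring profile (default the
#'   ring marker if present, else the GFP channel).
#' @return data.frame with columns frame, time_min, roi_intensity,
#'   ring_intensity (NA if no marker channel), diameter_um, resolved,
#'   pos1_um, pos2_um, and attribute \code{"breakFrame"}.
#' @export
quantifyMovie <- function(movie, roi = neckRoi(), diameterChannel = NULL) {
  gfp <- measureRoiIntensity(movie, "gfp", roi)
  ringI <- if ("ring" %in% names(movie@channels))
    measureRoiIntensity(movie, "ring", roi) else rep(NA_real_, length(gfp))
  if (is.null(diameterChannel))
    diameterChannel <- if ("ring" %in% names(movie@channels)) "ring" else "gfp"
  dm <- measureRingDiameter(movie, diameterChannel, roi)
  bf <- detectSpindleBreakage(movie)
  out <- data.frame(frame = dm$frame, time_min = dm$time_min,
                    roi_intensity = gfp, ring_intensity = ringI,
                    diameter_um = dm$diameter_um, resolved = dm$resolved,
                    pos1_um = dm$pos1_um, pos2_um = dm$pos2_um)
  attr(out, "breakFrame") <- bf
  out
}
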