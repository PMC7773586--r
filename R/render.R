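#' @include simulate.R
NULL

#' Default synthetic scene configuration
#'
#' Desk-scale imaging geometry: 64 x 64 px at 0.1 um/px, 1-min frame
#' interval, Gaussian PSF sigma 0.15 um, neck at the image center with the
#' mother-bud axis along x (so the edge-on ring puncta separate along y).
#'
#' @param imageSize image side length (px).
#' @param pixelSize um per pixel.
#' @param frameInterval min between frames.
#' @param psfSigma PSF sigma (um).
#' @param neckCenter 0-based (x, y) pixel coordinates of the bud neck.
#' @param motherBudAxis unit vector of the mother-bud axis.
#' @param gain photons per intensity unit (Poisson noise).
#' @param readNoiseSd read-noise SD (counts).
#' @param tStart time of the first frame (min relative to breakage).
#' @param nFrames number of frames.
#' @return a \linkS4class{SceneConfig}.
#' @export
defaultSceneConfig <- function(imageSize = 64L, pixelSize = 0.1,
                               frameInterval = 1, psfSigma = 0.15,
                               neckCenter = c(32, 32),
                               motherBudAxis = c(1, 0), gain = 50,
                               readNoiseSd = 2, tStart = -45,
                               nFrames = 91L) {
  new("SceneConfig", imageSize = as.integer(c(imageSize, imageSize))[1:2],
      pixelSize = pixelSize, frameInterval = frameInterval,
      psfSigma = psfSigma, neckCenter = neckCenter,
      motherBudAxis = motherBudAxis / sqrt(sum(motherBudAxis^2)),
      gain = gain, readNoiseSd = readNoiseSd, tStart = tStart,
      nFrames = as.integer(nFrames))
}

## Gaussian punctum image integrating exactly to `total` (normalized by the
## realized kernel sum, so rendered flux is conserved to machine precision
## as long as the punctum is inside the field).
punctumImage <- function(nx, ny, cx, cy, sigmaPx, total) {
  gx <- exp(-((0:(nx - 1)) - cx)^2 / (2 * sigmaPx^2))
  gy <- exp(-((0:(ny - 1)) - cy)^2 / (2 * sigmaPx^2))
  img <- outer(gx, gy)
  s <- sum(img)
  if (s <= 0) matrix(0, nx, ny) else img * (total / s)
}

## Capsule (line segment with Gaussian cross-section): peak amplitude `amp`.
segmentImage <- function(nx, ny, p1, p2, sigmaPx, amp) {
  px <- matrix(0:(nx - 1), nx, ny)
  py <- matrix(0:(ny - 1), nx, ny, byrow = TRUE)
  v <- p2 - p1
  len2 <- sum(v^2)
  if (len2 < 1e-12) {
    d2 <- (px - p1[1])^2 + (py - p1[2])^2
  } else {
    tt <- ((px - p1[1]) * v[1] + (py - p1[2]) * v[2]) / len2
    tt <- pmin(pmax(tt, 0), 1)
    d2 <- (px - (p1[1] + tt * v[1]))^2 + (py - (p1[2] + tt * v[2]))^2
  }
  amp * exp(-d2 / (2 * sigmaPx^2))
}

## anaphase spindle geometry (um), relative time t (min); breakage at 0
spindleSpec <- function(t) {
  if (t < 0) {
    L <- if (t <= -20) 1.2 else 1.2 + (6 - 1.2) * (t + 20) / 20
    list(split = FALSE, length = L, amp = 1)
  } else {
    H <- max(2.2 - 0.55 * t, 0)
    amp <- max(1 - t / 5, 0)
    list(split = TRUE, halfLength = H, gap = 0.8 + 0.4 * t, amp = amp)
  }
}

#' Render a synthetic multi-channel movie of one dividing cell
#'
#' Draws, per frame: a GFP channel in which the edge-on ring appears as two
#' 2-D Gaussian puncta separated by the ring diameter along the axis
#' perpendicular to the mother-bud axis, with total integrated signal equal
#' to the driving trace intensity; an optional ring-marker channel with the
#' same geometry; and a spindle channel in which a line segment elongates
#' through anaphase and splits into two shrinking, fading halves from the
#' breakage frame on. Optional Poisson photon noise plus Gaussian read
#' noise.
#'
#' @param gfpTrace a \linkS4class{KineticTrace} on the scene frame grid
#'   (relative times); its \code{intensity} drives the GFP channel and its
#'   \code{diameter} (if present) the punctum separation.
#' @param scene a \linkS4class{SceneConfig}.
#' @param ringTrace optional \linkS4class{KineticTrace} driving a second
#'   marker channel with the same geometry.
#' @param breakFrame 1-based frame index of spindle breakage; frame i is
#'   rendered at relative time \code{(i - breakFrame) * frameInterval}.
#' @param asymmetry constriction asymmetry in [0, 1]: 0 = both puncta
#'   converge on a fixed midpoint, 1 = one punctum stays put while the
#'   other sweeps across.
#' @param noise logical; add Poisson + read noise.
#' @param seed seed for the noise.
#' @return a \linkS4class{Movie}; attribute \code{"truth"} carries the
#'   breakage frame, asymmetry and the driving traces.
#' @export
renderMovie <- function(gfpTrace, scene = defaultSceneConfig(),
                        ringTrace = NULL, breakFrame = NULL,
                        asymmetry = 0, noise = TRUE, seed = 1) {
  nx <- scene@imageSize[1]; ny <- scene@imageSize[2]
  nF <- scene@nFrames
  times <- scene@tStart + (seq_len(nF) - 1) * scene@frameInterval
  if (is.null(breakFrame)) breakFrame <- which.min(abs(times))
  relTimes <- (seq_len(nF) - breakFrame) * scene@frameInterval
  sigmaPx <- scene@psfSigma / scene@pixelSize
  axis <- scene@motherBudAxis
  perp <- c(-axis[2], axis[1])
  ctr <- scene@neckCenter

  intensAt <- function(tr, t) {
    stats::approx(tr@times - tr@t0, tr@intensity, xout = t, rule = 2)$y
  }
  diamAt <- function(tr, t) {
    if (!length(tr@diameter)) return(rep(0, length(t)))
    stats::approx(tr@times - tr@t0, tr@diameter, xout = t, rule = 2)$y
  }
  gfpI <- intensAt(gfpTrace, relTimes)
  d <- diamAt(gfpTrace, relTimes)
  d0 <- d[1]
  ringI <- if (!is.null(ringTrace)) intensAt(ringTrace, relTimes) else NULL

  maxSep <- max(d) / scene@pixelSize
  if (maxSep > min(nx, ny) - 8)
    stop("ring diameter exceeds the field of view")

  puncta <- function(total, dt) {
    mid <- (asymmetry / 2) * (d0 - dt) / scene@pixelSize
    off <- (dt / 2) / scene@pixelSize
    punctumImage(nx, ny, ctr[1] + (mid - off) * perp[1],
                 ctr[2] + (mid - off) * perp[2], sigmaPx, total / 2) +
      punctumImage(nx, ny, ctr[1] + (mid + off) * perp[1],
                   ctr[2] + (mid + off) * perp[2], sigmaPx, total / 2)
  }

  gfp <- array(0, c(nx, ny, nF))
  ring <- if (!is.null(ringI)) array(0, c(nx, ny, nF)) else NULL
  spindle <- array(0, c(nx, ny, nF))
  spindleAmp <- 60
  for (i in seq_len(nF)) {
    gfp[, , i] <- puncta(gfpI[i], d[i])
    if (!is.null(ring)) ring[, , i] <- puncta(ringI[i], d[i])
    sp <- spindleSpec(relTimes[i])
    if (!sp$split) {
      h <- (sp$length / 2) / scene@pixelSize
      spindle[, , i] <- segmentImage(nx, ny, ctr - h * axis, ctr + h * axis,
                                     sigmaPx, spindleAmp * sp$amp)
    } else if (sp$halfLength > 0 && sp$amp > 0) {
      g <- (sp$gap / 2) / scene@pixelSize
      h <- sp$halfLength / scene@pixelSize
      spindle[, , i] <-
        segmentImage(nx, ny, ctr - (g + h) * axis, ctr - g * axis,
                     sigmaPx, spindleAmp * sp$amp) +
        segmentImage(nx, ny, ctr + g * axis, ctr + (g + h) * axis,
                     sigmaPx, spindleAmp * sp$amp)
    }
  }
  channels <- list(gfp = gfp, spindle = spindle)
  if (!is.null(ring)) channels$ring <- ring
  if (noise) {
    set.seed(seed)
    channels <- lapply(channels, function(ch) {
      n <- length(ch)
      counts <- stats::rpois(n, lambda = scene@gain * pmax(ch, 0)) +
        stats::rnorm(n, 0, scene@readNoiseSd)
      array(pmax(counts, 0) / scene@gain, dim(ch))
    })
  }
  mv <- new("Movie", channels = channels, pixelSize = scene@pixelSize,
            frameInterval = scene@frameInterval, times = relTimes,
            meta = list(breakFrame = breakFrame, noise = noise,
                        psfSigma = scene@psfSigma))
  attr(mv, "truth") <- list(breakFrame = breakFrame, asymmetry = asymmetry,
                            intensity = gfpI, diameter = d, times = relTimes)
  mv
}

#' Write / read a movie as multi-page TIFF + JSON sidecar
#'
#' One 32-bit float TIFF per channel plus a JSON sidecar carrying pixel
#' size, frame interval, times and the intensity scale used to map values
#' into [0, 1] for storage.
#'
#' @param movie a \linkS4class{Movie}.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return \code{writeMovie}: invisibly, the sidecar path;
#'   \code{readMovie}: a \linkS4class{Movie}.
#' @export
writeMovie <- function(movie, dir, prefix = "movie") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scale <- max(1e-12, max(vapply(movie@channels, max, 0)))
  for (ch in names(movie@channels)) {
    arr <- movie@channels[[ch]] / scale
    pages <- lapply(seq_len(dim(arr)[3]), function(i) arr[, , i])
    tiff::writeTIFF(pages, file.path(dir, paste0(prefix, "_", ch, ".tif")),
                    bits.per.sample = 32L)
  }
  sidecar <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(
    list(pixel_size_um = movie@pixelSize,
         frame_interval_min = movie@frameInterval,
         times_min = movie@times, channels = names(movie@channels),
         intensity_scale = scale, meta = movie@meta),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' @rdname writeMovie
#' @export
readMovie <- function(dir, prefix = "movie") {
  sidecar <- file.path(dir, paste0(prefix, "_meta.json"))
  if (!file.exists(sidecar)) stop("sidecar metadata not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  channels <- lapply(meta$channels, function(ch) {
    pages <- tiff::readTIFF(file.path(dir, paste0(prefix, "_", ch, ".tif")),
                            all = TRUE)
    arr <- array(0, c(dim(pages[[1]]), length(pages)))
    for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
    arr * meta$intensity_scale
  })
  names(channels) <- meta$channels
  new("Movie", channels = channels, pixelSize = meta$pixel_size_um,
      frameInterval = meta$frame_interval_min, times = meta$times_min,
      meta = as.list(meta$meta))
}
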