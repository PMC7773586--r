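#' @include templates.R
NULL

## Deterministic per-cell seed streams: every cell gets its own seed derived
## from the top-level seed and the cell index, so ensembles are reproducible
## and insensitive to evaluation order.
childSeed <- function(seed, index) {
  m <- 2147483647
  as.integer(((as.numeric(seed) %% m) * 48271 + index * 30269) %% m)
}

## Gamma sampler parameterized by mean and SD: exact first two moments on
## positive support (sd = 0 degenerates to a point mass).
rgammaMS <- function(n, mean, sd) {
  if (mean <= 0) stop("mean must be > 0")
  if (sd == 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, scale = sd^2 / mean)
}

#' Default time grid
#'
#' Uniform acquisition grid in minutes relative to spindle breakage.
#'
#' @param from,to,by grid limits and step (min).
#' @return numeric vector of times.
#' @export
defaultGrid <- function(from = -45, to = 45, by = 1) seq(from, to, by = by)

#' Default biphasic constriction parameter set
#'
#' Means and SDs of the slow/fast constriction rates and per-phase diameter
#' drops of the actomyosin ring, as printed for wild-type cells: slow rate
#' 0.02 +/- 0.02 um/min, fast rate 0.18 +/- 0.05 um/min, slow-phase drop
#' 0.10 +/- 0.07 um, fast-phase drop 0.92 +/- 0.11 um, onset -6 min.
#'
#' @param onsetTime constriction onset (min).
#' @param slowRate,slowRateSd,fastRate,fastRateSd rates (um/min).
#' @param slowDrop,slowDropSd,fastDrop,fastDropSd drops (um).
#' @param initialDiameter initial diameter (um); \code{NA} derives it as
#'   the per-cell sum of sampled drops.
#' @param constrict logical; \code{FALSE} = no constriction (e.g. LatA).
#' @param noiseSd diameter measurement noise SD (um).
#' @return a \linkS4class{ConstrictionParams}.
#' @export
defaultConstrictionParams <- function(onsetTime = -6,
                                      slowRate = 0.02, slowRateSd = 0.02,
                                      fastRate = 0.18, fastRateSd = 0.05,
                                      slowDrop = 0.10, slowDropSd = 0.07,
                                      fastDrop = 0.92, fastDropSd = 0.11,
                                      initialDiameter = NA_real_,
                                      constrict = TRUE, noiseSd = 0.02) {
  new("ConstrictionParams", onsetTime = onsetTime,
      slowRate = slowRate, slowRateSd = slowRateSd,
      fastRate = fastRate, fastRateSd = fastRateSd,
      slowDrop = slowDrop, slowDropSd = slowDropSd,
      fastDrop = fastDrop, fastDropSd = fastDropSd,
      initialDiameter = initialDiameter, constrict = constrict,
      noiseSd = noiseSd)
}

#' Simulate one single-cell intensity trace
#'
#' Evaluates a protein template on the acquisition grid with a per-cell
#' timing jitter and per-frame multiplicative intensity noise:
#' intensity(t) = template(t + delta) * (1 + eps_t), with
#' delta ~ N(0, jitterSd) and eps_t ~ N(0, noiseCv) i.i.d.
#'
#' @param template a \linkS4class{TemplateCurve}.
#' @param jitterSd cell-to-cell timing jitter SD (min).
#' @param noiseCv per-frame multiplicative noise CV.
#' @param seed integer seed; fully determines the trace.
#' @param grid acquisition grid (min relative to spindle breakage).
#' @param t0 absolute spindle-breakage time; raw timestamps are
#'   \code{grid + t0}.
#' @param cellId cell identifier.
#' @param condition condition label.
#' @return a \linkS4class{KineticTrace} with attribute \code{"truth"}
#'   (list with the drawn \code{jitter}).
#' @examples
#' panel <- loadSignaturePanel()
#' tr <- simulateTrace(panel$templates[["Myo1"]], seed = 1)
#' @export
simulateTrace <- function(template, jitterSd = 1, noiseCv = 0.05, seed = 1,
                          grid = defaultGrid(), t0 = 0,
                          cellId = paste0(proteinId(template), "_c1"),
                          condition = "control") {
  stopifnot(jitterSd >= 0, noiseCv >= 0)
  set.seed(seed)
  delta <- stats::rnorm(1, 0, jitterSd)
  eps <- stats::rnorm(length(grid), 0, noiseCv)
  values <- templateValue(template, grid + delta) * (1 + eps)
  tr <- new("KineticTrace", cellId = cellId, protein = proteinId(template),
            condition = condition, times = grid + t0,
            intensity = pmax(values, 0), t0 = t0)
  attr(tr, "truth") <- list(jitter = delta, t0 = t0)
  tr
}

## piecewise-linear biphasic diameter at times t (relative min)
biphasicDiameter <- function(t, onset, d0, rs, rf, ds, df) {
  tb <- onset + ds / rs
  tend <- tb + df / rf
  d <- numeric(length(t))
  d[t < onset] <- d0
  i <- t >= onset & t < tb
  d[i] <- d0 - rs * (t[i] - onset)
  i <- t >= tb & t < tend
  d[i] <- d0 - ds - rf * (t[i] - tb)
  d[t >= tend] <- 0
  pmax(d, 0)
}

#' Simulate one ring-constriction trace
#'
#' Draws per-cell slow/fast rates and per-phase drops from gamma
#' distributions with the configured means and SDs, derives the phase
#' durations as drop/rate, and evaluates the piecewise-linear diameter on
#' the grid with additive measurement noise. The marker intensity is
#' proportional to the ring diameter while the ring constricts (signal and
#' diameter are tightly coupled); with \code{constrict = FALSE} the
#' diameter stays at its initial value and the marker disassembles with a
#' linear kinetic profile instead.
#'
#' @param params a \linkS4class{ConstrictionParams}.
#' @param seed integer seed.
#' @param grid acquisition grid (min).
#' @param cellId cell identifier.
#' @param intensityGain marker intensity per um of ring diameter (a.u.).
#' @param disassemblyMin minutes a non-constricting marker takes to
#'   disassemble linearly from onset.
#' @return a \linkS4class{KineticTrace} carrying both \code{intensity} and
#'   \code{diameter}, with attribute \code{"truth"} (list: onset, d0,
#'   slowRate, fastRate, slowDrop, fastDrop, breakpoint, endTime,
#'   percentFast).
#' @examples
#' p0 <- defaultConstrictionParams(slowRateSd = 0, fastRateSd = 0,
#'                                 slowDropSd = 0, fastDropSd = 0,
#'                                 noiseSd = 0)
#' tr <- simulateConstriction(p0, seed = 1)
#' attr(tr, "truth")$breakpoint   # -1 min
#' @export
simulateConstriction <- function(params = defaultConstrictionParams(),
                                 seed = 1, grid = defaultGrid(),
                                 cellId = "cell_1", intensityGain = 100,
                                 disassemblyMin = 12) {
  set.seed(seed)
  rs <- rgammaMS(1, params@slowRate, params@slowRateSd)
  rf <- rgammaMS(1, params@fastRate, params@fastRateSd)
  ds <- rgammaMS(1, params@slowDrop, params@slowDropSd)
  df <- rgammaMS(1, params@fastDrop, params@fastDropSd)
  d0 <- if (is.na(params@initialDiameter)) ds + df else params@initialDiameter
  onset <- params@onsetTime
  if (params@constrict) {
    d <- biphasicDiameter(grid, onset, d0, rs, rf, ds, df)
    intens <- intensityGain * d
    breakpoint <- onset + ds / rs
    endTime <- breakpoint + df / rf
  } else {
    d <- rep(d0, length(grid))
    intens <- intensityGain * d0 *
      pmax(0, pmin(1, 1 - (grid - onset) / disassemblyMin))
    breakpoint <- NA_real_
    endTime <- NA_real_
  }
  if (params@noiseSd > 0) {
    d <- pmax(d + stats::rnorm(length(grid), 0, params@noiseSd), 0)
    intens <- pmax(intens + stats::rnorm(length(grid),
                                         0, params@noiseSd * intensityGain), 0)
  }
  tr <- new("KineticTrace", cellId = cellId, protein = "Myo1",
            condition = if (params@constrict) "control" else "no-constriction",
            times = grid, intensity = intens, diameter = d, t0 = 0)
  attr(tr, "truth") <- list(onset = onset, d0 = d0, slowRate = rs,
                            fastRate = rf, slowDrop = ds, fastDrop = df,
                            breakpoint = breakpoint, endTime = endTime,
                            percentFast = 100 * df / (ds + df))
  tr
}

#' Simulate a constriction ensemble
#'
#' @param n number of cells.
#' @param params a \linkS4class{ConstrictionParams}.
#' @param seed top-level seed; per-cell streams are derived by cell index.
#' @param grid acquisition grid (min).
#' @return list with \code{traces} (list of \linkS4class{KineticTrace}) and
#'   \code{truth} (data.frame, one row per cell).
#' @export
simulateConstrictionEnsemble <- function(n = 30,
                                         params = defaultConstrictionParams(),
                                         seed = 1, grid = defaultGrid()) {
  if (n < 1) stop("n must be >= 1")
  traces <- lapply(seq_len(n), function(i)
    simulateConstriction(params, seed = childSeed(seed, i), grid = grid,
                         cellId = paste0("cell_", i)))
  truth <- do.call(rbind, lapply(traces, function(tr)
    as.data.frame(attr(tr, "truth"))))
  truth <- cbind(cell_id = vapply(traces, function(tr) tr@cellId, ""), truth)
  list(traces = traces, truth = truth)
}

#' Simulate a full panel experiment
#'
#' Generates \code{nCells} single-cell traces for every protein in the
#' panel (optionally a subset), with per-cell spindle-breakage times drawn
#' on the frame grid so that downstream clock alignment does real work.
#'
#' @param panel result of \code{\link{loadSignaturePanel}}.
#' @param proteins character vector of proteins to simulate (default all).
#' @param nCells cells per protein.
#' @param seed top-level seed.
#' @param jitterSd,noiseCv noise model; \code{NULL} uses panel defaults.
#' @param effect optional \linkS4class{ConditionEffect} applied to every
#'   template (condition label becomes \code{conditionName}).
#' @param conditionName condition label for the generated traces.
#' @param grid acquisition grid (min relative to breakage).
#' @param t0Range range of absolute breakage times (min); per-cell t0 is
#'   drawn uniformly on the frame grid within it.
#' @return list with \code{traces} (named by protein: lists of
#'   \linkS4class{KineticTrace}) and \code{truth} (data.frame: cell_id,
#'   protein, condition, t0, jitter, primary_peak).
#' @export
simulatePanel <- function(panel = loadSignaturePanel(), proteins = NULL,
                          nCells = NULL, seed = 1, jitterSd = NULL,
                          noiseCv = NULL, effect = NULL,
                          conditionName = if (is.null(effect)) "control"
                                          else "treated",
                          grid = defaultGrid(), t0Range = c(45, 60)) {
  templates <- panel$templates
  if (!is.null(proteins)) {
    missing <- setdiff(proteins, names(templates))
    if (length(missing))
      stop("unknown protein(s): ", paste(missing, collapse = ", "))
    templates <- templates[proteins]
  }
  nCells <- nCells %||% panel$defaults$n_cells %||% 30
  if (nCells < 1) stop("nCells must be >= 1")
  jitterSd <- jitterSd %||% panel$defaults$jitter_sd %||% 1
  noiseCv <- noiseCv %||% panel$defaults$noise_cv %||% 0.05
  step <- if (length(grid) > 1) diff(grid)[1] else 1
  out <- list()
  truth <- list()
  for (pi in seq_along(templates)) {
    tmpl <- templates[[pi]]
    if (!is.null(effect)) tmpl <- applyConditionEffect(tmpl, effect)
    cells <- vector("list", nCells)
    for (i in seq_len(nCells)) {
      sd_i <- childSeed(seed, (pi - 1L) * 100000L + i)
      set.seed(sd_i)
      t0 <- t0Range[1] + step * sample.int(
        max(1L, round((t0Range[2] - t0Range[1]) / step)), 1)
      cells[[i]] <- simulateTrace(tmpl, jitterSd = jitterSd,
                                  noiseCv = noiseCv,
                                  seed = childSeed(sd_i, 1), grid = grid,
                                  t0 = t0,
                                  cellId = paste0(tmpl@protein, "_c", i),
                                  condition = conditionName)
      truth[[length(truth) + 1L]] <- data.frame(
        cell_id = cells[[i]]@cellId, protein = tmpl@protein,
        condition = conditionName, t0 = t0,
        jitter = attr(cells[[i]], "truth")$jitter,
        primary_peak = tmpl@peakTimes[which.max(tmpl@amplitudes)])
    }
    out[[tmpl@protein]] <- cells
  }
  list(traces = out, truth = do.call(rbind, truth))
}
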