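#' @include quantify.R
NULL

#' Align a single-cell trace to the spindle-breakage clock
#'
#' Shifts the raw timestamps by -t0 (so that spindle breakage is time 0)
#' and linearly interpolates the intensity (and diameter, if present) onto
#' the common uniform grid. Gridpoints outside the observed time range are
#' marked missing, never extrapolated. Alignment is exactly invariant to a
#' common shift of the timestamps and t0.
#'
#' @param trace a \linkS4class{KineticTrace} with a defined \code{t0}.
#' @param grid target grid (min relative to breakage).
#' @return a \linkS4class{KineticTrace} on the grid with \code{t0 = 0};
#'   unobserved gridpoints carry NA intensity.
#' @export
alignTrace <- function(trace, grid = defaultGrid()) {
  if (length(trace@t0) != 1 || is.na(trace@t0))
    stop("trace has no spindle-breakage time t0")
  rel <- trace@times - trace@t0
  intens <- stats::approx(rel, trace@intensity, xout = grid)$y
  diam <- if (length(trace@diameter))
    stats::approx(rel, trace@diameter, xout = grid)$y else numeric()
  out <- new("KineticTrace", cellId = trace@cellId, protein = trace@protein,
             condition = trace@condition, times = grid,
             intensity = intens, diameter = diam, t0 = 0)
  out
}

#' Aggregate aligned traces to mean +/- SD kinetics
#'
#' Per-gridpoint sample mean and sample SD (denominator n - 1) over the
#' cells observed at that gridpoint; gridpoints observed in fewer than
#' \code{nMin} cells are masked.
#'
#' @param traces list of \linkS4class{KineticTrace}, all of the same
#'   protein/condition; traces not yet on the grid are aligned first.
#' @param nMin masking threshold (cells per gridpoint).
#' @param grid target grid (min).
#' @return a \linkS4class{MeanKinetics}.
#' @export
aggregateTraces <- function(traces, nMin = 10, grid = defaultGrid()) {
  if (!length(traces)) stop("no traces to aggregate")
  mats <- vapply(traces, function(tr) {
    if (length(tr@times) != length(grid) ||
        any(abs(tr@times - tr@t0 - grid) > 1e-9))
      tr <- alignTrace(tr, grid)
    tr@intensity
  }, numeric(length(grid)))
  n <- rowSums(!is.na(mats))
  mu <- rowMeans(mats, na.rm = TRUE)
  sd <- apply(mats, 1, stats::sd, na.rm = TRUE)
  mask <- n < nMin
  mu[mask] <- NA_real_
  sd[mask] <- NA_real_
  mu[n == 0] <- NA_real_
  new("MeanKinetics", protein = traces[[1]]@protein,
      condition = traces[[1]]@condition, grid = grid, mean = mu, sd = sd,
      n = as.integer(n), nMin = as.integer(nMin))
}

#' Normalize mean kinetics
#'
#' \code{"max1"} divides mean and SD by the peak mean;
#' \code{"baseline0_max1"} first subtracts the baseline (mean of the first
#' 5 unmasked gridpoints) and then scales the peak to 1, scaling the SD by
#' the same factor; \code{"none"} returns the input. Pearson correlations
#' downstream are invariant to all modes (affine transforms).
#'
#' @param mk a \linkS4class{MeanKinetics}.
#' @param mode one of \code{"none"}, \code{"max1"}, \code{"baseline0_max1"}.
#' @return a \linkS4class{MeanKinetics}.
#' @export
normalizeKinetics <- function(mk, mode = c("none", "max1",
                                           "baseline0_max1")) {
  mode <- match.arg(mode)
  if (mode == "none") return(mk)
  ok <- which(!is.na(mk@mean))
  if (!length(ok)) stop("all gridpoints masked")
  shift <- 0
  if (mode == "baseline0_max1")
    shift <- mean(mk@mean[utils::head(ok, 5)])
  centered <- mk@mean - shift
  peak <- max(centered, na.rm = TRUE)
  if (peak <= 0)
    stop("zero peak (or zero range) after baseline subtraction; ",
         "cannot normalize")
  mk@mean <- centered / peak
  mk@sd <- mk@sd / peak
  mk
}
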