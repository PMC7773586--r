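#' @include io.R
NULL

logStage <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Simulate a panel experiment and write its artifacts
#'
#' Trace-level entry point of the simulation stage: generates single-cell
#' traces for the requested proteins (plus a Myo1 constriction-diameter
#' ensemble), writes trace, truth and manifest tables, and echoes the
#' resolved configuration next to the outputs so a run can be reproduced
#' bit-identically.
#'
#' @param outDir output directory.
#' @param proteins proteins to simulate (default: full packaged panel).
#' @param nCells cells per protein.
#' @param seed top-level seed (fully determines all outputs).
#' @param jitterSd,noiseCv noise model overrides (NULL = panel defaults).
#' @param verbose log one line per stage.
#' @return invisibly, a list with the written file paths.
#' @export
simulateExperiment <- function(outDir, proteins = NULL, nCells = NULL,
                               seed = 1, jitterSd = NULL, noiseCv = NULL,
                               verbose = TRUE) {
  panel <- loadSignaturePanel()
  if (!is.null(nCells) && nCells < 1) stop("nCells must be >= 1")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulatePanel(panel, proteins = proteins, nCells = nCells,
                       seed = seed, jitterSd = jitterSd, noiseCv = noiseCv)
  logStage(verbose, "simulate", length(sim$traces), " proteins x ",
           length(sim$traces[[1]]), " cells")
  tracesPath <- file.path(outDir, "traces.csv")
  writeTraces(unlist(sim$traces, recursive = FALSE), tracesPath)
  truthPath <- file.path(outDir, "truth.csv")
  utils::write.csv(sim$truth, truthPath, row.names = FALSE)
  ens <- simulateConstrictionEnsemble(n = nCells %||%
                                        panel$defaults$n_cells %||% 30,
                                      seed = seed)
  diamPath <- file.path(outDir, "diameters.csv")
  writeTraces(ens$traces, diamPath)
  diamTruthPath <- file.path(outDir, "diameter_truth.csv")
  utils::write.csv(ens$truth, diamTruthPath, row.names = FALSE)
  manifest <- data.frame(protein = names(sim$traces),
                         n_cells = vapply(sim$traces, length, 0L))
  manifestPath <- file.path(outDir, "manifest.csv")
  utils::write.csv(manifest, manifestPath, row.names = FALSE)
  cfg <- list(proteins = proteins %||% names(panel$templates),
              n_cells = nCells %||% panel$defaults$n_cells,
              seed = seed,
              jitter_sd = jitterSd %||% panel$defaults$jitter_sd,
              noise_cv = noiseCv %||% panel$defaults$noise_cv)
  cfgPath <- file.path(outDir, "resolved_config.json")
  jsonlite::write_json(cfg, cfgPath, auto_unbox = TRUE, digits = NA)
  invisible(list(traces = tracesPath, truth = truthPath,
                 diameters = diamPath, diameterTruth = diamTruthPath,
                 manifest = manifestPath, config = cfgPath))
}

#' Run the full kinetic-landscape analysis
#'
#' Executes align -> aggregate -> signatures -> constriction fitting ->
#' similarity ranking on simulated or user-supplied traces and returns all
#' results plus a machine-readable summary. When \code{outDir} is given,
#' writes mean-kinetics, signature, fit and similarity tables, a summary
#' JSON, the resolved configuration, and (if ggplot2 is available) a
#' landscape figure of stacked normalized mean curves ordered by peak
#' time.
#'
#' @param traces named-by-protein list of lists of
#'   \linkS4class{KineticTrace}, or a path to a trace CSV written by
#'   \code{\link{writeTraces}} (traces are then grouped by protein).
#' @param diameterTraces optional list of \linkS4class{KineticTrace} with
#'   diameters for constriction fitting, or a CSV path.
#' @param nMin gridpoint masking threshold.
#' @param window similarity window (min).
#' @param normalization normalization mode for the landscape figure.
#' @param grid common time grid.
#' @param outDir optional output directory.
#' @param seed echoed into the resolved configuration (the analysis itself
#'   is deterministic given its inputs).
#' @param verbose log one line per stage.
#' @return list with \code{meanKinetics}, \code{signatures},
#'   \code{similarity}, \code{rankings}, \code{constriction},
#'   \code{summary} (the summary is also written as JSON when
#'   \code{outDir} is given).
#' @export
runLandscape <- function(traces, diameterTraces = NULL, nMin = 10,
                         window = c(-20, 30),
                         normalization = "baseline0_max1",
                         grid = defaultGrid(), outDir = NULL, seed = NULL,
                         verbose = TRUE) {
  if (is.character(traces)) {
    flat <- readTraces(traces)
    traces <- split(flat, vapply(flat, function(tr) tr@protein, ""))
    logStage(verbose, "load", length(flat), " traces from file")
  }
  if (is.character(diameterTraces)) diameterTraces <-
    readTraces(diameterTraces)
  logStage(verbose, "align", "aligning and aggregating ",
           length(traces), " proteins")
  mks <- lapply(traces, function(trs)
    aggregateTraces(lapply(trs, alignTrace, grid = grid), nMin = nMin,
                    grid = grid))
  logStage(verbose, "kinetics", "extracting signatures")
  sigs <- lapply(names(mks), function(p)
    tryCatch(extractSignature(mks[[p]]),
             error = function(e)
               stop("signature stage failed for ", p, ": ",
                    conditionMessage(e), call. = FALSE)))
  names(sigs) <- names(mks)
  constriction <- NULL
  fits <- list()
  if (!is.null(diameterTraces)) {
    onsetHat <- tryCatch(estimateConstrictionOnset(diameterTraces),
                         error = function(e) NULL)
    fits <- lapply(diameterTraces, function(tr)
      tryCatch(fitBiphasic(tr, onset = onsetHat),
               error = function(e) NULL))
    failed <- vapply(fits, is.null, TRUE)
    if (any(failed))
      logStage(verbose, "fit", sum(failed), " cell(s) without constriction")
    fits <- fits[!failed]
    if (length(fits)) constriction <- summarizeConstriction(fits)
    logStage(verbose, "fit", length(fits), " biphasic fits")
  }
  sim <- NULL; rankings <- NULL
  if (length(mks) >= 2) {
    logStage(verbose, "signature", "correlation matrix over ",
             window[1], "..", window[2], " min")
    sim <- correlationMatrix(mks, window = window)
    rankings <- lapply(names(mks), function(q)
      tryCatch(rankSimilarity(sim, q, signatures = sigs),
               error = function(e) NULL))
    names(rankings) <- names(mks)
  }
  peakTbl <- data.frame(
    protein = names(sigs),
    primary_peak_min = vapply(sigs, function(s)
      s@peakTimes[which.max(s@peakValues)], 0),
    n_peaks = vapply(sigs, function(s) length(s@peakTimes), 0L),
    arrival_min = vapply(sigs, function(s) s@arrivalTime, 0),
    departure_min = vapply(sigs, function(s) s@departureTime, 0),
    row.names = NULL)
  maskedPts <- sum(vapply(mks, function(m) sum(is.na(m@mean)), 0L))
  summary <- list(
    n_proteins = length(mks),
    peak_times = stats::setNames(as.list(peakTbl$primary_peak_min),
                                 peakTbl$protein),
    n_peaks = stats::setNames(as.list(peakTbl$n_peaks), peakTbl$protein),
    fold_ratio = constriction$foldRatio %||% NA,
    percent_fast = if (!is.null(constriction))
      constriction$stats$mean[constriction$stats$quantity == "percentFast"]
      else NA,
    mean_slow_rate = if (!is.null(constriction))
      constriction$stats$mean[constriction$stats$quantity == "slowRate"]
      else NA,
    mean_fast_rate = if (!is.null(constriction))
      constriction$stats$mean[constriction$stats$quantity == "fastRate"]
      else NA,
    warnings = list(masked_gridpoints = maskedPts,
                    fits_excluded_from_fold =
                      constriction$nExcludedFromFold %||% 0))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (p in names(mks))
      writeMeanKinetics(mks[[p]], file.path(outDir,
                                            paste0("mean_", p, ".csv")))
    utils::write.csv(peakTbl, file.path(outDir, "signatures.csv"),
                     row.names = FALSE)
    if (length(fits)) {
      fitTbl <- do.call(rbind, lapply(seq_along(fits), function(i) {
        f <- fits[[i]]
        data.frame(cell = i, breakpoint_min = f@breakpoint,
                   slow_rate_um_min = f@slowRate,
                   fast_rate_um_min = f@fastRate, slow_drop_um = f@slowDrop,
                   fast_drop_um = f@fastDrop, percent_fast = f@percentFast,
                   sse_um2 = f@sse)
      }))
      utils::write.csv(fitTbl, file.path(outDir, "fits.csv"),
                       row.names = FALSE)
    }
    if (!is.null(sim))
      writeSimilarityMatrix(sim, file.path(outDir, "similarity.csv"))
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    cfg <- list(n_min = nMin, window = window,
                normalization = normalization, seed = seed)
    jsonlite::write_json(cfg, file.path(outDir, "resolved_config.json"),
                         auto_unbox = TRUE, digits = NA)
    fig <- tryCatch(plotLandscape(mks, normalization = normalization),
                    error = function(e) NULL)
    if (!is.null(fig)) {
      grDevices::pdf(file.path(outDir, "landscape.pdf"), width = 6,
                     height = max(4, length(mks) * 0.35))
      print(fig)
      grDevices::dev.off()
    }
  }
  invisible(list(meanKinetics = mks, signatures = sigs, similarity = sim,
                 rankings = rankings, constriction = constriction,
                 summary = summary))
}

#' Landscape figure: stacked normalized mean curves ordered by peak time
#'
#' @param mks named list of \linkS4class{MeanKinetics}.
#' @param normalization normalization mode (see
#'   \code{\link{normalizeKinetics}}).
#' @return a ggplot object (requires ggplot2).
#' @export
plotLandscape <- function(mks, normalization = "baseline0_max1") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for the landscape figure")
  norm <- lapply(mks, normalizeKinetics, mode = normalization)
  peaks <- vapply(norm, function(m) m@grid[which.max(m@mean)], 0)
  ord <- names(sort(peaks))
  df <- do.call(rbind, lapply(seq_along(ord), function(i) {
    m <- norm[[ord[i]]]
    ok <- !is.na(m@mean)
    data.frame(protein = ord[i], t = m@grid[ok],
               y = m@mean[ok] + (length(ord) - i) * 1.2)
  }))
  df$protein <- factor(df$protein, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(x = t, y = y, group = protein)) +
    ggplot2::geom_line(color = "darkgreen") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::scale_y_continuous(
      breaks = (length(ord) - seq_along(ord)) * 1.2,
      labels = ord) +
    ggplot2::labs(x = "time relative to spindle breakage (min)", y = NULL,
                  title = "Kinetic landscape of division-site proteins") +
    ggplot2::theme_minimal()
}
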