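#' @include similarity.R
NULL

#' Write / read single-cell trace tables
#'
#' Long-format CSV with one row per cell x frame. Columns: cell_id,
#' protein, condition, time_min (raw timestamp), t0_min (spindle-breakage
#' time on the raw axis), intensity_au, diameter_um (empty when absent).
#'
#' @param traces list of \linkS4class{KineticTrace}.
#' @param path CSV path.
#' @return \code{writeTraces}: invisibly the path; \code{readTraces}: a
#'   list of \linkS4class{KineticTrace}.
#' @export
writeTraces <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    data.frame(cell_id = tr@cellId, protein = tr@protein,
               condition = tr@condition, time_min = tr@times,
               t0_min = tr@t0, intensity_au = tr@intensity,
               diameter_um = if (length(tr@diameter)) tr@diameter
                             else NA_real_)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTraces
#' @export
readTraces <- function(path) {
  df <- utils::read.csv(path)
  need <- c("cell_id", "protein", "condition", "time_min", "t0_min",
            "intensity_au")
  if (!all(need %in% names(df)))
    stop("trace table must have columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$cell_id)[unique(df$cell_id)], function(g) {
    g <- g[order(g$time_min), ]
    hasD <- "diameter_um" %in% names(g) && !all(is.na(g$diameter_um))
    new("KineticTrace", cellId = as.character(g$cell_id[1]),
        protein = as.character(g$protein[1]),
        condition = as.character(g$condition[1]), times = g$time_min,
        intensity = g$intensity_au,
        diameter = if (hasD) g$diameter_um else numeric(),
        t0 = g$t0_min[1])
  })
}

#' Write / read mean-kinetics tables
#'
#' CSV with columns time_min, mean_au, sd_au, n_cells plus protein,
#' condition and the masking threshold n_min.
#'
#' @param mk a \linkS4class{MeanKinetics}.
#' @param path CSV path.
#' @return \code{writeMeanKinetics}: invisibly the path;
#'   \code{readMeanKinetics}: a \linkS4class{MeanKinetics}.
#' @export
writeMeanKinetics <- function(mk, path) {
  utils::write.csv(
    data.frame(protein = mk@protein, condition = mk@condition,
               time_min = mk@grid, mean_au = mk@mean, sd_au = mk@sd,
               n_cells = mk@n, n_min = mk@nMin),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMeanKinetics
#' @export
readMeanKinetics <- function(path) {
  df <- utils::read.csv(path)
  need <- c("protein", "condition", "time_min", "mean_au", "sd_au",
            "n_cells")
  if (!all(need %in% names(df)))
    stop("mean-kinetics table must have columns: ",
         paste(need, collapse = ", "))
  new("MeanKinetics", protein = as.character(df$protein[1]),
      condition = as.character(df$condition[1]), grid = df$time_min,
      mean = df$mean_au, sd = df$sd_au, n = as.integer(df$n_cells),
      nMin = as.integer(df$n_min[1] %||% 10L))
}

#' Write a similarity matrix as a labeled square CSV
#'
#' @param sim a \linkS4class{SimilarityMatrix}.
#' @param path CSV path.
#' @return invisibly the path.
#' @export
writeSimilarityMatrix <- function(sim, path) {
  utils::write.csv(as.data.frame(sim@r), path, row.names = TRUE)
  invisible(path)
}
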