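#' @include kinetics.R
NULL

#' Pairwise Pearson correlation of mean kinetic curves
#'
#' Pairwise-complete Pearson correlation over the jointly unmasked
#' gridpoints within a common time window. Pairs with fewer than
#' \code{minOverlap} joint gridpoints, and curves with zero variance in
#' the window, are masked (NA) with a warning.
#'
#' @param mks list of \linkS4class{MeanKinetics} (>= 2), all on the same
#'   grid; names default to the protein ids.
#' @param window correlation window (min, min).
#' @param minOverlap minimal number of joint gridpoints per pair.
#' @return a \linkS4class{SimilarityMatrix}.
#' @export
correlationMatrix <- function(mks, window = c(-20, 30), minOverlap = 15) {
  if (length(mks) < 2) stop("need at least 2 curves")
  ids <- names(mks) %||% vapply(mks, function(m) m@protein, "")
  if (is.null(names(mks))) names(mks) <- ids
  grid <- mks[[1]]@grid
  for (m in mks)
    if (length(m@grid) != length(grid) || any(abs(m@grid - grid) > 1e-9))
      stop("all curves must share the same grid")
  inWin <- grid >= window[1] & grid <= window[2]
  vals <- vapply(mks, function(m) ifelse(inWin, m@mean, NA_real_),
                 numeric(length(grid)))
  nP <- length(mks)
  r <- matrix(NA_real_, nP, nP, dimnames = list(ids, ids))
  nov <- matrix(0L, nP, nP, dimnames = list(ids, ids))
  zeroVar <- logical(nP)
  for (i in seq_len(nP)) {
    vi <- vals[!is.na(vals[, i]), i]
    zeroVar[i] <- length(vi) < 2 || stats::sd(vi) == 0
  }
  if (any(zeroVar))
    warning("zero-variance curve(s) in window, masked: ",
            paste(ids[zeroVar], collapse = ", "))
  for (i in seq_len(nP)) {
    r[i, i] <- if (zeroVar[i]) NA_real_ else 1
    nov[i, i] <- sum(!is.na(vals[, i]))
    if (i == nP) break
    for (j in (i + 1):nP) {
      ok <- !is.na(vals[, i]) & !is.na(vals[, j])
      nov[i, j] <- nov[j, i] <- sum(ok)
      if (sum(ok) < minOverlap || zeroVar[i] || zeroVar[j]) next
      if (stats::sd(vals[ok, i]) == 0 || stats::sd(vals[ok, j]) == 0) next
      r[i, j] <- r[j, i] <- stats::cor(vals[ok, i], vals[ok, j])
    }
  }
  new("SimilarityMatrix", r = r, window = window, nOverlap = nov)
}

## deterministic neighbor ordering: descending r, ties by ascending
## peak-time distance, then lexicographic id
orderNeighbors <- function(df) {
  df[order(-df$r, df$peak_dt, df$protein), , drop = FALSE]
}

#' Rank proteins by kinetic similarity to a query
#'
#' All other proteins in the similarity matrix, ordered by descending
#' Pearson r; ties are broken by ascending primary peak-time distance
#' (when signatures are supplied) and then lexicographically. Rank 1 is
#' the most similar protein.
#'
#' @param sim a \linkS4class{SimilarityMatrix}.
#' @param query query protein id.
#' @param signatures optional named list of
#'   \linkS4class{KineticSignature} used for the peak-time tie-break.
#' @return data.frame with columns rank, protein, r, peak_dt.
#' @export
rankSimilarity <- function(sim, query, signatures = NULL) {
  ids <- rownames(sim@r)
  if (!query %in% ids) stop("query '", query, "' not in matrix")
  if (all(is.na(sim@r[query, ]))) stop("query row is masked")
  others <- setdiff(ids, query)
  peakOf <- function(id) {
    if (is.null(signatures) || is.null(signatures[[id]])) return(NA_real_)
    sg <- signatures[[id]]
    sg@peakTimes[which.max(sg@peakValues)]
  }
  qp <- peakOf(query)
  df <- data.frame(protein = others, r = sim@r[query, others],
                   peak_dt = vapply(others, function(id) {
                     p <- peakOf(id)
                     if (is.na(qp) || is.na(p)) Inf else abs(p - qp)
                   }, 0), row.names = NULL)
  df <- df[!is.na(df$r), , drop = FALSE]
  df <- orderNeighbors(df)
  df$rank <- seq_len(nrow(df))
  df[, c("rank", "protein", "r", "peak_dt")]
}

#' Assign a query curve to a functional module
#'
#' The predicted module is the reference module whose members' mean
#' correlation with the query curve is maximal. The peak-time-based
#' assignment (module of the reference with the nearest primary peak) is
#' reported alongside, with a disagreement flag.
#'
#' @param queryMk \linkS4class{MeanKinetics} of the query.
#' @param refMks named list of reference \linkS4class{MeanKinetics}.
#' @param refModules named character vector mapping reference ids to
#'   module labels (>= 2 distinct modules).
#' @param window,minOverlap passed to \code{\link{correlationMatrix}}.
#' @return a \linkS4class{ModuleAssignment}.
#' @export
assignModule <- function(queryMk, refMks, refModules, window = c(-20, 30),
                         minOverlap = 15) {
  if (length(unique(refModules[names(refMks)])) < 2)
    stop("references must cover at least 2 modules")
  qid <- "(query)"
  sim <- correlationMatrix(c(stats::setNames(list(queryMk), qid), refMks),
                           window = window, minOverlap = minOverlap)
  rq <- sim@r[qid, names(refMks)]
  if (all(is.na(rq))) stop("all references masked against the query")
  sigs <- lapply(c(stats::setNames(list(queryMk), qid), refMks),
                 function(m) tryCatch(extractSignature(m),
                                      error = function(e) NULL))
  peakOf <- function(id) {
    sg <- sigs[[id]]
    if (is.null(sg)) NA_real_ else sg@peakTimes[which.max(sg@peakValues)]
  }
  qp <- peakOf(qid)
  nb <- data.frame(protein = names(refMks), r = unname(rq),
                   peak_dt = vapply(names(refMks), function(id) {
                     p <- peakOf(id)
                     if (is.na(qp) || is.na(p)) Inf else abs(p - qp)
                   }, 0),
                   module = unname(refModules[names(refMks)]),
                   row.names = NULL)
  nb <- nb[!is.na(nb$r), , drop = FALSE]
  nb <- orderNeighbors(nb)
  byModule <- tapply(nb$r, nb$module, mean)
  predicted <- names(byModule)[which.max(byModule)]
  peakMod <- if (all(!is.finite(nb$peak_dt))) NA_character_
             else nb$module[which.min(nb$peak_dt)]
  new("ModuleAssignment", query = queryMk@protein, neighbors = nb,
      predictedModule = predicted,
      peakTimeModule = peakMod %||% NA_character_,
      peakTimeDistance = suppressWarnings(min(nb$peak_dt)),
      agreement = identical(predicted, peakMod))
}
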