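# shared fixtures: the packaged panel and small builders used across tests

thePanel <- loadSignaturePanel()

aggOf <- function(traces, nMin = 10, grid = defaultGrid()) {
  aggregateTraces(lapply(traces, alignTrace, grid = grid), nMin = nMin,
                  grid = grid)
}

# zero-variance (fully deterministic) constriction parameter set
noiselessParams <- function(...) {
  defaultConstrictionParams(slowRateSd = 0, fastRateSd = 0, slowDropSd = 0,
                            fastDropSd = 0, noiseSd = 0, ...)
}

# MeanKinetics straight from a numeric vector on the default grid
mkOf <- function(values, grid = defaultGrid(), protein = "X",
                 condition = "control", n = 30L, nMin = 10L) {
  new("MeanKinetics", protein = protein, condition = condition,
      grid = grid, mean = values, sd = rep(0, length(grid)),
      n = rep(n, length(grid)), nMin = nMin)
}

# independent brute-force oracle for the two-segment constrained fit:
# enumerate every breakpoint and every active set, solving each case from
# explicitly assembled normal equations (no shared code with the package
# implementation).
bruteForceBiphasic <- function(t, d) {
  n <- length(t)
  bestSSE <- Inf
  bestTau <- NA
  for (ci in 2:(n - 1)) {
    tau <- t[ci]
    x1 <- pmin(t - tau, 0)
    x2 <- pmax(t - tau, 0)
    cands <- list()
    XtX <- function(X) crossprod(X)
    # both free
    X <- cbind(1, x1, x2)
    beta <- tryCatch(qr.solve(X, d), error = function(e) NULL)
    if (!is.null(beta) && beta[2] <= 1e-12 && beta[3] <= 1e-12)
      cands <- c(cands, list(sum((d - X %*% beta)^2)))
    # slow clamped
    X <- cbind(1, x2)
    beta <- tryCatch(qr.solve(X, d), error = function(e) NULL)
    if (!is.null(beta) && beta[2] <= 1e-12)
      cands <- c(cands, list(sum((d - X %*% beta)^2)))
    # fast clamped
    X <- cbind(1, x1)
    beta <- tryCatch(qr.solve(X, d), error = function(e) NULL)
    if (!is.null(beta) && beta[2] <= 1e-12)
      cands <- c(cands, list(sum((d - X %*% beta)^2)))
    # both clamped
    cands <- c(cands, list(sum((d - mean(d))^2)))
    sse <- min(unlist(cands))
    if (sse < bestSSE - 1e-12) {
      bestSSE <- sse
      bestTau <- tau
    }
  }
  list(sse = bestSSE, tau = bestTau)
}
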