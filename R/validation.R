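## Error quantification against the exact solutions, parameter sweeps,
## and the Crank-Nicolson baseline.

#' Simulation error metric
#'
#' \eqn{\epsilon = (1/F)\max_i |\rho_{sim,i} - \rho_{exact,i}|}.  With this
#' scaling the exact result is O(1), so -log10(eps) is roughly the number of
#' correct significant figures.
#'
#' @param rhoSim,rhoExact profile vectors of equal length.
#' @param F flux factor (> 0).
#' @return the dimensionless error.
#' @export
errorMetric <- function(rhoSim, rhoExact, F = 1) {
  stopifnot(length(rhoSim) == length(rhoExact), F > 0)
  max(abs(rhoSim - rhoExact)) / F
}

## build the prescribed-count grid + matrix for a validation parameter set
.validationSetup <- function(N, NF, INear, IFar, RMax, precisionDigits,
                             cache = NULL) {
  grid <- buildGrid(RMax, nearBase = INear, farBase = IFar, refine = FALSE)
  P <- assemblePropagator(grid, N, NF, precisionDigits, cache = cache)
  P
}

#' Always-on validation protocol
#'
#' Runs the all-on source from rho = 0 in nondimensional units (F = 1) and
#' compares every step k against the closed form erfc(R_i/sqrt(k)).
#' Arbitrary horizons are affordable because the exact evaluation is O(I)
#' per step.  Divergence is reported in the result, not raised.
#'
#' @param N,NF,INear,IFar the parameter set: quadrature order, interpolation
#'   order, and the prescribed near/far grid counts (refinement off, as in
#'   parameter-sweep mode).
#' @param nSteps horizon (>= 1).
#' @param RMax outer boundary of the grid.
#' @param precisionDigits quadrature-build precision.
#' @param P optional pre-assembled [PropagationMatrix-class] matching the
#'   parameter set (skips the build).
#' @param cache optional quadrature cache environment.
#' @return an [ErrorReport-class].
#' @export
validateAlwaysOn <- function(N, NF, INear, IFar, nSteps, RMax = 5148,
                             precisionDigits = 120L, P = NULL, cache = NULL) {
  stopifnot(nSteps >= 1)
  if (is.null(P))
    P <- .validationSetup(N, NF, INear, IFar, RMax, precisionDigits, cache)
  res <- cpp_always_on_error(P@W@p, P@W@i, P@W@x, P@s, P@grid@points,
                             as.integer(nSteps), 1e10)
  eps <- res$eps
  steps <- seq_len(nSteps)
  if (res$diverged) {
    keep <- seq_len(res$step)
    eps <- eps[keep]
    steps <- steps[keep]
  }
  new("ErrorReport", epsTrace = eps, epsSteps = as.integer(steps),
      epsMax = max(eps[is.finite(eps)], if (res$diverged) Inf else NULL),
      nnz = nnzCount(P),
      params = list(N = N, NF = NF, INear = INear, IFar = IFar),
      diverged = res$diverged, protocol = "always_on")
}

#' Random-on validation protocol
#'
#' The source is gated by seeded Bernoulli(pOn) draws and the stepped
#' solution is compared against the exact history sum of e_m basis
#' functions.  The exact evaluation costs O(n) per evaluated step (O(T^2)
#' over a run — which in practice caps such runs at a few 1e5 steps), so
#' the error is evaluated every `checkEvery` steps; contiguous on-runs are
#' telescoped and erf(R_i/sqrt(m)) columns are cached.
#'
#' @inheritParams validateAlwaysOn
#' @param pOn per-step on-probability.
#' @param seed integer seed for the gating draws.
#' @param checkEvery evaluate the error every this many steps (the final
#'   step is always evaluated).
#' @return an [ErrorReport-class].
#' @export
validateRandomOn <- function(N, NF, INear, IFar, nSteps, pOn = 0.5, seed = 1L,
                             checkEvery = 1L, RMax = 5148,
                             precisionDigits = 120L, P = NULL, cache = NULL) {
  stopifnot(nSteps >= 1, pOn >= 0, pOn <= 1)
  if (is.null(P))
    P <- .validationSetup(N, NF, INear, IFar, RMax, precisionDigits, cache)
  if (pOn == 1) {
    chi <- rep(1L, nSteps)
  } else if (pOn == 0) {
    chi <- rep(0L, nSteps)
  } else {
    set.seed(seed)
    chi <- as.integer(rbinom(nSteps, 1L, pOn))
  }
  res <- cpp_random_on_error(P@W@p, P@W@i, P@W@x, P@s, P@grid@points, chi,
                             as.integer(checkEvery), 1e10)
  new("ErrorReport", epsTrace = res$eps, epsSteps = res$steps,
      epsMax = if (length(res$eps))
        max(res$eps, if (res$diverged) Inf else NULL) else
          if (res$diverged) Inf else 0,
      nnz = nnzCount(P),
      params = list(N = N, NF = NF, INear = INear, IFar = IFar),
      diverged = res$diverged, protocol = "random_on")
}

#' Parameter sweep: accuracy versus matrix size
#'
#' Runs the always-on protocol for every row of `paramGrid` and tabulates
#' the maximum error against the nonzero count of W (the per-step cost
#' proxy: one multiplication per stored entry).  Reported errors above 1
#' are truncated to 1 (the plotting convention); the raw maxima are kept in
#' `epsMaxRaw`.  Individual divergences are recorded, not fatal.
#'
#' @param paramGrid data.frame with columns N, NF, INear, IFar.
#' @param nSteps horizon for each run.
#' @param RMax outer boundary.
#' @param targetAccuracy accuracy target for the selection.
#' @param precisionDigits quadrature-build precision.
#' @return a list with `table` (one row per set, columns N, NF, INear,
#'   IFar, I, nnz, epsMax, epsMaxRaw, diverged), `pareto` (row indices of
#'   the accuracy/size Pareto frontier), and `selected` (the minimal-nnz
#'   row achieving `targetAccuracy`, or NA).
#' @export
parameterSweep <- function(paramGrid, nSteps, RMax = 5148,
                           targetAccuracy = 1e-5, precisionDigits = 120L) {
  stopifnot(nrow(paramGrid) >= 1)
  cache <- new.env(parent = emptyenv())
  rows <- lapply(seq_len(nrow(paramGrid)), function(k) {
    p <- paramGrid[k, ]
    rep_k <- validateAlwaysOn(p$N, p$NF, p$INear, p$IFar, nSteps, RMax,
                              precisionDigits, cache = cache)
    raw <- epsMax(rep_k)
    data.frame(N = p$N, NF = p$NF, INear = p$INear, IFar = p$IFar,
               I = p$INear + p$IFar, nnz = nnzCount(rep_k),
               epsMax = min(raw, 1), epsMaxRaw = raw,
               diverged = isDiverged(rep_k))
  })
  tab <- do.call(rbind, rows)
  ok <- !tab$diverged
  pareto <- integer(0)
  for (k in which(ok)) {
    dominated <- any(ok & (tab$nnz <= tab$nnz[k]) &
                       (tab$epsMaxRaw <= tab$epsMaxRaw[k]) &
                       (tab$nnz < tab$nnz[k] | tab$epsMaxRaw < tab$epsMaxRaw[k]))
    if (!dominated) pareto <- c(pareto, k)
  }
  hit <- which(ok & tab$epsMaxRaw <= targetAccuracy)
  selected <- if (length(hit)) hit[which.min(tab$nnz[hit])] else NA_integer_
  list(table = tab, pareto = pareto, selected = selected)
}

#' Crank-Nicolson baseline on a uniform grid
#'
#' Classical comparison point: Crank-Nicolson for the radial diffusion
#' equation, solved in u = r c (which obeys the 1-D heat equation), on a
#' uniform grid with spacing `dr` up to `L`.  The point source enters as
#' the inner Dirichlet value u(0) = chi j/(4 pi D) — the quasi-steady
#' near-field of a point source — and u(L) = 0.  One tridiagonal solve per
#' step.  The error against the closed-form always-on solution uses the
#' same metric as the propagation runs.
#'
#' @param params a [PhysicalParams-class].
#' @param L outer boundary (m).
#' @param dr grid spacing (m); `Nr = ceiling(L/dr)` points.
#' @param nSteps number of steps (always-on source).
#' @param recordSteps steps at which the error is evaluated (default: 10
#'   roughly log-spaced steps plus the last).
#' @return a list with `report` (an [ErrorReport-class] with protocol
#'   "always_on"), `Nr`, and `profile` (data.frame r, c at the final step).
#' @export
crankNicolsonBaseline <- function(params, L, dr, nSteps,
                                  recordSteps = NULL) {
  stopifnot(dr > 0, L / dr <= 1e5, nSteps >= 1)
  Nr <- as.integer(ceiling(L / dr))
  if (is.null(recordSteps))
    recordSteps <- sort(unique(c(round(exp(seq(0, log(nSteps),
                                               length.out = 10L))), nSteps)))
  recordSteps <- as.integer(recordSteps)
  chi <- rep(1L, nSteps)
  res <- cpp_crank_nicolson(params@D, params@dt, dr, Nr, chi, params@j,
                            recordSteps)
  r <- dr * (0:Nr)
  u_scale <- params@j / (4 * pi * params@D) # = 2 sqrt(D dt) * F
  eps <- vapply(seq_along(recordSteps), function(k) {
    tk <- recordSteps[k] * params@dt
    u_exact <- u_scale * .erfc(r / (2 * sqrt(params@D * tk)))
    u_exact[1] <- u_scale # limit r -> 0
    max(abs(res$u[k, ] - u_exact)) / u_scale
  }, numeric(1))
  u_fin <- res$u_final
  c_fin <- c(u_fin[2] / r[2], u_fin[-1] / r[-1])
  report <- new("ErrorReport", epsTrace = eps, epsSteps = recordSteps,
                epsMax = max(eps), nnz = as.integer(3L * (Nr - 1L)),
                params = list(N = NA, NF = NA, INear = NA, IFar = NA,
                              Nr = Nr, dr = dr),
                diverged = FALSE, protocol = "always_on")
  list(report = report, Nr = Nr,
       profile = data.frame(r = r, c = c_fin))
}
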