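## Assembly of the combined-weight sparse matrix and time stepping.

#' Assemble the propagation matrix
#'
#' For each grid point R_i > 0 a Gauss-diffusion quadrature rule
#' `{x_a(R_i), w_a(R_i)}` of order `N` is built (and cached), and the value
#' of the profile at each quadrature point is expressed through an
#' `NF`-point Fornberg stencil, giving the combined weights
#' \eqn{W_{ij} = \sum_a A_j(x_a(R_i))\, w_a(R_i)} and the source vector
#' \eqn{s_i = erfc(R_i)}.  Row 0 (the origin) is identically zero because
#' `W(0, .) = 0`, so together with `s_0 = 1` the update keeps
#' `rho(0) = chi_n F_n` — the exact point-source limit of `R c(r)` at the
#' origin (the concentration diverges like 1/r there, so `R c` has a
#' nonzero limit).  Column 0 carries the interpolation weights on the
#' origin node, which stencils near the source need.
#' Quadrature points beyond R_max use the boundary-clamped stencil (the
#' profile is ~0 there by construction of R_max).  Combined weights below
#' `dropTol` times the row maximum are dropped from storage.
#'
#' Stencil-conditioning guard: where the grid density changes abruptly
#' (the near/far junction of seeded grids), the nearest-subset window can
#' become lopsided and its Lagrange weights explode (observed up to ~1e5),
#' which destabilizes the iteration.  When `max|A| > stencilGuard` the
#' stencil is re-selected centered in index space on the interval
#' containing the quadrature point.  Healthy stencils sit at `max|A| ~ 1`,
#' so the guard never fires on smooth grids.
#'
#' @param grid an [InterpolationGrid-class].
#' @param N quadrature order.
#' @param NF Fornberg interpolation order (stencil size), `NF <= I`.
#' @param precisionDigits starting precision for the quadrature build.
#' @param dropTol relative drop tolerance for stored weights.
#' @param stencilGuard Lagrange-weight bound above which a stencil is
#'   re-centered (set `Inf` to disable the guard).
#' @param cache optional environment used as a quadrature-rule cache
#'   (reused across assemblies that share grid points).
#' @return a [PropagationMatrix-class].
#' @export
assemblePropagator <- function(grid, N, NF, precisionDigits = 120L,
                               dropTol = 1e-16, stencilGuard = 10,
                               cache = NULL) {
  g <- grid@points
  I <- length(g)
  if (NF > I) stop("NF exceeds the grid size")
  if (N < 1) stop("N must be >= 1")
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  worst_overshoot <- 0
  for (i in 2:I) {
    rule <- .buildGDQCached(g[i], N, precisionDigits, cache)
    row <- numeric(I)
    for (a in seq_len(N)) {
      xa <- rule@points[a]
      if (xa > grid@RMax) {
        worst_overshoot <- max(worst_overshoot, xa / grid@RMax - 1)
        st <- (I - NF + 1L):I
      } else {
        st <- selectStencil(xa, g, NF)
      }
      A <- fornbergWeights(xa, g[st])
      if (max(abs(A)) > stencilGuard && xa <= grid@RMax) {
        st <- .balancedStencil(xa, g, NF)
        A <- fornbergWeights(xa, g[st])
      }
      row[st] <- row[st] + A * rule@weights[a]
    }
    keep <- which(abs(row) >= dropTol * max(abs(row)) & row != 0)
    ti <- c(ti, rep.int(i, length(keep)))
    tj <- c(tj, keep)
    tx <- c(tx, row[keep])
  }
  if (worst_overshoot > 0.1)
    warning(sprintf(
      "quadrature points exceed R_max by up to %.1f%%: domain may be too small",
      100 * worst_overshoot))
  W <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(I, I))
  new("PropagationMatrix", W = methods::as(W, "CsparseMatrix"), s = .erfc(g),
      grid = grid, N = as.integer(N), NF = as.integer(NF))
}

#' Create an initial simulation state
#'
#' rho(R_i, 0) = c0 R_i (uniform initial concentration c0).
#'
#' @param P a [PropagationMatrix-class].
#' @param c0 initial concentration (same unit as the flux factors used).
#' @return a [SimulationState-class] at step 0.
#' @export
initialState <- function(P, c0 = 0) {
  new("SimulationState", rho = c0 * P@grid@points, step = 0L,
      chi = integer(0), F = numeric(0), diverged = FALSE)
}

.divergenceScale <- function(state, F) {
  max(abs(F), abs(state@F), 1e-300)
}

#' Advance one diffusion step
#'
#' \eqn{\rho_{n+1} = W \rho_n + \chi F s}.  The origin row of W is empty
#' and `s[1] = 1`, so `rho[1]` becomes `chi F` — the exact origin limit of
#' `R c`.  Raises an error when max|rho|/F exceeds `divergenceThreshold`
#' (a bad (N, NF, I_near, I_far) combination; small changes in N and NF
#' usually cure it).
#'
#' @param state a [SimulationState-class].
#' @param P a [PropagationMatrix-class].
#' @param chi source state for this step (0 or 1).
#' @param F flux factor for this step.
#' @param divergenceThreshold divergence flag level for |rho|/F.
#' @return the advanced [SimulationState-class].
#' @export
stepDiffusion <- function(state, P, chi, F, divergenceThreshold = 1e10) {
  stopifnot(length(state@rho) == length(P@grid@points), chi %in% c(0, 1))
  rho <- as.numeric(P@W %*% state@rho) + chi * F * P@s
  out <- new("SimulationState", rho = rho, step = state@step + 1L,
             chi = c(state@chi, as.integer(chi)), F = c(state@F, F),
             diverged = FALSE)
  if (!all(is.finite(rho)) ||
      max(abs(rho)) > divergenceThreshold * .divergenceScale(state, F)) {
    out@diverged <- TRUE
    stop("diverged at step ", out@step,
         ": try small changes in N and NF (see the error-analysis vignette)")
  }
  out
}

#' Advance one buffered reaction-diffusion step
#'
#' High-buffer limit: binding removes the diffusing species at rate
#' `kOn * bFree` (one-point time quadrature gives the contraction factor
#' `1 - kOn bFree dt`), and unbinding injects it uniformly at rate
#' `kOff * BBound`.  Over one step the heat kernel integrates to exactly 1
#' over space, so the uniform unbinding source adds the concentration
#' `kOff BBound dt`, i.e. `kOff BBound dt R_i` in rho:
#' \deqn{\rho_{n+1} = (1 - k_+ b \Delta t) W \rho_n + \chi F s +
#'       k_- B \Delta t\, R_i.}
#' `bufferSourceFactor` multiplies the unbinding term (default 1, the
#' kernel-normalized convention; see the vignette for why).
#'
#' @inheritParams stepDiffusion
#' @param reaction a [ReactionParams-class].
#' @param dt the time step (s) used to form the rate-per-step products.
#' @param bufferSourceFactor multiplier on the unbinding source term.
#' @return the advanced [SimulationState-class].
#' @export
stepReaction <- function(state, P, chi, F, reaction, dt,
                         bufferSourceFactor = 1,
                         divergenceThreshold = 1e10) {
  stopifnot(is(reaction, "ReactionParams"))
  sink <- reaction@kOn * reaction@bFree * dt
  if (sink >= 1)
    stop("kOn * bFree * dt must be < 1 for the explicit reaction factor ",
         "(got ", sink, "): reduce dt")
  src <- bufferSourceFactor * reaction@kOff * reaction@BBound * dt
  rho <- (1 - sink) * as.numeric(P@W %*% state@rho) + chi * F * P@s +
    src * P@grid@points
  out <- new("SimulationState", rho = rho, step = state@step + 1L,
             chi = c(state@chi, as.integer(chi)), F = c(state@F, F),
             diverged = FALSE)
  if (!all(is.finite(rho)) ||
      max(abs(rho)) > divergenceThreshold *
        max(.divergenceScale(state, F), src / max(sink, 1e-300))) {
    out@diverged <- TRUE
    stop("diverged at step ", out@step)
  }
  out
}

## ---- source processes -----------------------------------------------------

#' Source processes for [runSimulation()]
#'
#' A source process decides, at every step, whether the source is on
#' (`chi`) and with which flux factor (`F`).  `sourceAlwaysOn` is constant
#' on; `sourceSchedule` replays a fixed 0/1 vector; `sourceBernoulli` draws
#' chi ~ Bernoulli(pOn) from the seeded generator; `sourceFeedback` calls
#' `fun(rho, step)` — which sees the current profile — and must return
#' `list(chi = 0 or 1)` (optionally with an `F` element).
#'
#' @param chi 0/1 vector (recycled to the run length).
#' @param pOn on-probability per step.
#' @param fun feedback rule `function(rho, step)`.
#' @return a source-process object consumed by [runSimulation()].
#' @name sources
NULL

#' @rdname sources
#' @export
sourceAlwaysOn <- function() structure(list(kind = "always_on"),
                                       class = "gdq_source")
#' @rdname sources
#' @export
sourceSchedule <- function(chi) {
  stopifnot(all(chi %in% c(0, 1)))
  structure(list(kind = "schedule", chi = as.integer(chi)),
            class = "gdq_source")
}
#' @rdname sources
#' @export
sourceBernoulli <- function(pOn = 0.5) {
  stopifnot(pOn >= 0, pOn <= 1)
  structure(list(kind = "bernoulli", pOn = pOn), class = "gdq_source")
}
#' @rdname sources
#' @export
sourceFeedback <- function(fun) {
  stopifnot(is.function(fun))
  structure(list(kind = "feedback", fun = fun), class = "gdq_source")
}

#' Run a simulation
#'
#' Starts from \eqn{\rho(R_i, 0) = c_0 R_i} and advances `nSteps` steps of
#' \eqn{\rho_{n+1} = W\rho_n + \chi_n F_n s} (with the reaction factors when
#' `reaction` is given), recording every `recordEvery` steps.  Schedule-type
#' sources (always-on, explicit schedule, seeded Bernoulli) run in the
#' compiled loop; feedback sources are stepped in R because the rule must
#' see each profile.  All randomness comes from the single seeded
#' generator, so equal seeds give bit-identical trajectories.
#'
#' @param P a [PropagationMatrix-class].
#' @param source a source process (see [sources]).
#' @param nSteps number of steps (>= 1).
#' @param F flux factor: scalar or one value per step.
#' @param c0 initial uniform concentration (same unit as `F`).
#' @param seed integer seed; required for stochastic sources.
#' @param recordEvery record the profile every this many steps.
#' @param reaction optional [ReactionParams-class].
#' @param dt time step in seconds; required with `reaction`.
#' @param bufferSourceFactor see [stepReaction()].
#' @param divergenceThreshold divergence flag level for |rho|/F.
#' @return a [Trajectory-class].
#' @export
runSimulation <- function(P, source, nSteps, F = 1, c0 = 0, seed = NULL,
                          recordEvery = 1L, reaction = NULL, dt = NULL,
                          bufferSourceFactor = 1,
                          divergenceThreshold = 1e10) {
  stopifnot(inherits(source, "gdq_source"), nSteps >= 1)
  g <- P@grid@points
  I <- length(g)
  Fvec <- rep_len(F, nSteps)
  if (source$kind %in% c("bernoulli") || source$kind == "feedback") {
    if (is.null(seed)) stop("seed is required for stochastic sources")
    set.seed(seed)
  }
  reactFactor <- 1
  reactAdd <- numeric(I)
  if (!is.null(reaction)) {
    if (is.null(dt)) stop("dt is required with reaction parameters")
    sink <- reaction@kOn * reaction@bFree * dt
    if (sink >= 1) stop("kOn * bFree * dt must be < 1")
    reactFactor <- 1 - sink
    reactAdd <- bufferSourceFactor * reaction@kOff * reaction@BBound * dt * g
  }
  divAbs <- divergenceThreshold * max(abs(Fvec), abs(c0), 1e-300)
  if (source$kind != "feedback") {
    chi <- switch(source$kind,
      always_on = rep(1L, nSteps),
      schedule = rep_len(source$chi, nSteps),
      bernoulli = as.integer(rbinom(nSteps, 1L, source$pOn)))
    res <- cpp_propagate(P@W@p, P@W@i, P@W@x, P@s, c0 * g, chi, Fvec,
                         reactFactor, reactAdd, as.integer(recordEvery),
                         divAbs)
    if (res$diverged)
      stop("diverged at step ", res$step,
           ": try small changes in N and NF")
    nrec <- res$n_recorded
    state <- new("SimulationState", rho = res$rho,
                 step = as.integer(nSteps), chi = chi, F = Fvec,
                 diverged = FALSE)
    return(new("Trajectory",
               recorded = res$recorded[seq_len(nrec), , drop = FALSE],
               recSteps = res$rec_steps[seq_len(nrec)], state = state,
               grid = P@grid))
  }
  # feedback: R loop, the rule sees each profile
  state <- initialState(P, c0)
  rec <- list(); recSteps <- integer(0)
  for (n in seq_len(nSteps)) {
    decision <- source$fun(state@rho, n)
    chi_n <- decision$chi
    F_n <- if (!is.null(decision$F)) decision$F else Fvec[n]
    state <- if (is.null(reaction)) {
      stepDiffusion(state, P, chi_n, F_n, divergenceThreshold)
    } else {
      stepReaction(state, P, chi_n, F_n, reaction, dt, bufferSourceFactor,
                   divergenceThreshold)
    }
    if (n %% recordEvery == 0) {
      rec[[length(rec) + 1L]] <- state@rho
      recSteps <- c(recSteps, n)
    }
  }
  new("Trajectory",
      recorded = if (length(rec)) do.call(rbind, rec) else
        matrix(numeric(0), 0, I),
      recSteps = recSteps, state = state, grid = P@grid)
}
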