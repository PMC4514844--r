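## Closed-form solutions and nondimensionalization.
##
## Physical profile c(r, t) and nondimensional profile rho(R, t_n) are
## related by R = r/(2 sqrt(D dt)) and rho = R c.  One on-interval with flux
## j contributes F erfc(R) to rho, where the flux factor is
## F = j / (8 pi D^{3/2} dt^{1/2}) (full space; 2 pi replaces 4 pi in the
## denominator for a half-space source such as a channel in a membrane).

#' Construct physical parameters
#'
#' @param D diffusion coefficient (m^2/s).
#' @param dt time step (s).
#' @param j source flux (particles/s).
#' @param c0 initial (uniform) concentration, default 0.
#' @param c0Unit unit of `c0` (see [convertConcentration()]).
#' @param geometry `"full"` (free space, 4 pi) or `"half"` (membrane, 2 pi).
#' @return a [PhysicalParams-class].
#' @examples
#' p <- physicalParams(D = 1e-9, dt = 1e-7, j = 1e7)
#' fluxFactor(p) # 6.61e-5 M
#' @export
physicalParams <- function(D, dt, j, c0 = 0, c0Unit = "M",
                           geometry = c("full", "half")) {
  geometry <- match.arg(geometry)
  new("PhysicalParams", D = D, dt = dt, j = j, c0 = c0, c0Unit = c0Unit,
      geometry = geometry)
}

#' Diffusion length scale 2 sqrt(D dt)
#'
#' @param params a [PhysicalParams-class].
#' @return the length (m) that one nondimensional unit of R corresponds to.
#' @export
diffusionLength <- function(params) 2 * sqrt(params@D * params@dt)

#' Flux factor F
#'
#' \eqn{F = j / (g \cdot 2 D^{3/2} \Delta t^{1/2})} with g = 4 pi (full
#' space) or 2 pi (half space): the concentration scale such that one
#' on-interval adds `F * erfc(R)` to the nondimensional profile.
#'
#' @param params a [PhysicalParams-class].
#' @param j flux (particles/s); defaults to the one in `params`.
#' @param unit output concentration unit.
#' @return the flux factor in `unit`.
#' @export
fluxFactor <- function(params, j = params@j, unit = "M") {
  stopifnot(j >= 0)
  g <- if (params@geometry == "full") 4 * pi else 2 * pi
  F_per_m3 <- j / (g * 2 * params@D^1.5 * sqrt(params@dt))
  convertConcentration(F_per_m3, from = "per_m3", to = unit)
}

#' Always-on profile after k on-steps
#'
#' The telescoped closed form: starting from rho = 0, k consecutive
#' on-steps give \eqn{\rho_k(R) = F\, erfc(R/\sqrt k)} (0 for k = 0).
#' As k grows this approaches the steady state rho = F, i.e.
#' c = j/(4 pi D r).
#'
#' @param R nondimensional radii (vectorized).
#' @param k number of completed on-steps (>= 0).
#' @param F flux factor (any concentration unit; output shares it).
#' @return rho values.
#' @export
alwaysOnProfile <- function(R, k, F = 1) {
  stopifnot(k >= 0)
  if (k == 0) return(rep(0, length(R)))
  F * .erfc(R / sqrt(k))
}

#' Exact profile for an arbitrary source history
#'
#' \eqn{\rho_n(R) = \sum_{m=0}^{n} \chi_{n-m} F_{n-m}\, e_m(R)} — the exact
#' solution after the realized on/off history.  Cost is O(n) per radius, so
#' this is the per-step oracle, not the production path.
#'
#' @param R nondimensional radii (vectorized).
#' @param chi 0/1 history, `chi[1]` is the first step.
#' @param F flux factors: scalar or one per step.
#' @return rho values at `R`.
#' @export
exactProfile <- function(R, chi, F = 1) {
  n <- length(chi)
  stopifnot(n >= 1)
  F <- rep_len(F, n)
  out <- numeric(length(R))
  for (m in 0:(n - 1)) {
    k <- n - m # history index (1-based): contributes e_m
    if (chi[k] != 0) out <- out + F[k] * eBasis(R, m)
  }
  out
}

#' Map a nondimensional profile to physical concentrations
#'
#' r = 2 sqrt(D dt) R and c(r) = rho(R)/R.  At the origin, where rho = R c
#' forces rho = 0, the concentration is reported as the limit of rho/R,
#' linearly extrapolated from the two innermost nonzero grid points.
#'
#' @param rho nondimensional profile on `grid` (concentration units `unit`).
#' @param grid an [InterpolationGrid-class] (or a numeric vector of radii,
#'   first entry 0).
#' @param params a [PhysicalParams-class].
#' @param unit concentration unit of `rho` (and of the output).
#' @return `data.frame(r, c)` with r in metres and c in `unit`.
#' @export
toPhysical <- function(rho, grid, params, unit = "M") {
  R <- if (is(grid, "InterpolationGrid")) grid@points else grid
  stopifnot(length(rho) == length(R))
  r <- diffusionLength(params) * R
  c_out <- numeric(length(R))
  pos <- which(R > 0)
  c_out[pos] <- rho[pos] / R[pos]
  if (any(R == 0)) {
    i2 <- pos[1]; i3 <- pos[2]
    y2 <- rho[i2] / R[i2]; y3 <- rho[i3] / R[i3]
    c_out[R == 0] <- y2 - R[i2] * (y3 - y2) / (R[i3] - R[i2])
  }
  data.frame(r = r, c = c_out)
}

#' Map physical concentrations to the nondimensional profile
#'
#' The inverse of [toPhysical()]: R = r/(2 sqrt(D dt)), rho = R c.
#'
#' @param c_values concentrations at radii `r`.
#' @param r radii (m).
#' @param params a [PhysicalParams-class].
#' @return `data.frame(R, rho)`.
#' @export
toNondimensional <- function(c_values, r, params) {
  R <- r / diffusionLength(params)
  data.frame(R = R, rho = R * c_values)
}
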