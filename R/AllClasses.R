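## S4 classes for the quadrature/grid/propagation pipeline.

#' MomentTable: moments of the diffusion weight function at radius R
#'
#' Holds \eqn{M_n = \int_0^\infty x^n W(R,x)\,dx} for \eqn{n = 0..n_{max}},
#' computed by parity-split confluent-hypergeometric recurrences at
#' `precisionDigits` decimal digits.  `moments` is the machine-precision
#' downcast; `momentStrings` keeps the high-precision decimal values.
#'
#' @slot R evaluation radius (nondimensional, > 0).
#' @slot nMax highest moment order.
#' @slot moments numeric vector `M_0..M_nMax` (downcast).
#' @slot momentStrings character vector, high-precision decimal values.
#' @slot precisionDigits working decimal precision used.
#' @export
setClass("MomentTable",
  representation(R = "numeric", nMax = "integer", moments = "numeric",
                 momentStrings = "character", precisionDigits = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@moments) != object@nMax + 1L)
      msg <- c(msg, "moments must have nMax + 1 entries")
    if (object@R > 0 && any(object@moments <= 0))
      msg <- c(msg, "all moments must be positive for R > 0")
    if (is.null(msg)) TRUE else msg
  })

#' RecurrenceCoefficients: three-term recurrence for the orthogonal polynomials
#'
#' Coefficients of the monic recurrence
#' \eqn{p_{j+1}(x) = (x - a_j)p_j(x) - b_j p_{j-1}(x)} for polynomials
#' orthogonal under \eqn{\langle f\rangle = \int_0^\infty f(x)W(R,x)dx}.
#'
#' @slot R evaluation radius.
#' @slot N quadrature order.
#' @slot a numeric, `a_0..a_{N-1}`.
#' @slot b numeric, `b_1..b_{N-1}` (all positive).
#' @slot precisionDigits working decimal precision used.
#' @export
setClass("RecurrenceCoefficients",
  representation(R = "numeric", N = "integer", a = "numeric", b = "numeric",
                 precisionDigits = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@a) != object@N)
      msg <- c(msg, "a must have N entries")
    if (length(object@b) != max(object@N - 1L, 0L))
      msg <- c(msg, "b must have N - 1 entries")
    if (any(object@b <= 0))
      msg <- c(msg, "all b_j must be positive (positive-definite measure)")
    if (is.null(msg)) TRUE else msg
  })

#' QuadratureRule: Gauss-diffusion quadrature points and weights at radius R
#'
#' @slot R evaluation radius.
#' @slot N order (number of points).
#' @slot points strictly increasing abscissas in (0, Inf).
#' @slot weights nonnegative weights summing to erf(R).
#' @slot precisionDigits precision used for the construction.
#' @export
setClass("QuadratureRule",
  representation(R = "numeric", N = "integer", points = "numeric",
                 weights = "numeric", precisionDigits = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@points) != object@N || length(object@weights) != object@N)
      msg <- c(msg, "points and weights must have N entries")
    if (is.unsorted(object@points, strictly = TRUE))
      msg <- c(msg, "points must be strictly increasing")
    if (any(object@points <= 0))
      msg <- c(msg, "points must be positive for R > 0")
    if (any(object@weights < -1e-30))
      msg <- c(msg, "weights must be nonnegative")
    if (is.null(msg)) TRUE else msg
  })

#' InterpolationGrid: nonuniform interpolation grid on [0, RMax]
#'
#' Linear in the near interval (R <= 10, where the exact-solution basis
#' functions e_m have their structure), logarithmic in the far interval
#' (10 < R <= RMax), optionally refined by bisection until cubic
#' interpolation of every tested e_m at subinterval midpoints is within
#' `tol`.
#'
#' @slot points strictly increasing, `points[1] = 0`, last point = RMax.
#' @slot RMax outer boundary.
#' @slot tol refinement tolerance (Inf when refinement was disabled).
#' @slot mMax largest e_m index used in refinement.
#' @export
setClass("InterpolationGrid",
  representation(points = "numeric", RMax = "numeric", tol = "numeric",
                 mMax = "integer"),
  validity = function(object) {
    msg <- NULL
    p <- object@points
    if (length(p) < 2L) msg <- c(msg, "grid needs at least 2 points")
    if (p[1] != 0) msg <- c(msg, "grid must start at R = 0")
    if (is.unsorted(p, strictly = TRUE))
      msg <- c(msg, "grid points must be strictly increasing")
    if (abs(p[length(p)] - object@RMax) > 1e-12 * object@RMax)
      msg <- c(msg, "last grid point must equal RMax")
    if (is.null(msg)) TRUE else msg
  })

#' PropagationMatrix: combined-weight sparse matrix and source vector
#'
#' Row i of `W` combines the Gauss-diffusion quadrature at R_i with Fornberg
#' interpolation stencils at the quadrature points:
#' \eqn{W_{ij} = \sum_\alpha A_j(x_\alpha(R_i)) w_\alpha(R_i)}.  `s` is the
#' source vector \eqn{s_i = erfc(R_i)}.  Row 0 (the origin) is empty
#' because `W(0, .) = 0`; with `s_0 = 1` the update then keeps
#' `rho(0) = chi_n F_n`, the exact origin limit of `R c` for a point
#' source.
#'
#' @slot W sparse I x I matrix (`Matrix::dgCMatrix`).
#' @slot s numeric source vector.
#' @slot grid the [InterpolationGrid-class] used.
#' @slot N quadrature order.
#' @slot NF Fornberg interpolation order.
#' @export
setClass("PropagationMatrix",
  representation(W = "dgCMatrix", s = "numeric", grid = "InterpolationGrid",
                 N = "integer", NF = "integer"),
  validity = function(object) {
    msg <- NULL
    I <- length(object@grid@points)
    if (!all(dim(object@W) == c(I, I)))
      msg <- c(msg, "W must be I x I")
    if (length(object@s) != I) msg <- c(msg, "s must have I entries")
    if (any(object@W[1, ] != 0))
      msg <- c(msg, "row 0 (origin) must be identically zero")
    if (is.null(msg)) TRUE else msg
  })

#' PhysicalParams: physical configuration of a simulation
#'
#' @slot D diffusion coefficient (m^2/s).
#' @slot dt time step (s).
#' @slot j source flux (particles/s).
#' @slot c0 initial concentration, in the unit given by `c0Unit`.
#' @slot c0Unit concentration unit tag for `c0` (see [convertConcentration()]).
#' @slot geometry `"full"` (4 pi, source in free space) or `"half"`
#'   (2 pi, flux through a channel on one side of a membrane).
#' @export
setClass("PhysicalParams",
  representation(D = "numeric", dt = "numeric", j = "numeric", c0 = "numeric",
                 c0Unit = "character", geometry = "character"),
  validity = function(object) {
    msg <- NULL
    if (object@D <= 0) msg <- c(msg, "D must be positive")
    if (object@dt <= 0) msg <- c(msg, "dt must be positive")
    if (object@j < 0) msg <- c(msg, "j must be nonnegative")
    if (!object@geometry %in% c("full", "half"))
      msg <- c(msg, "geometry must be 'full' or 'half'")
    if (is.null(msg)) TRUE else msg
  })

#' ReactionParams: high-buffer reaction parameters
#'
#' Buffer binding/unbinding in the high-buffer limit, where the free (b) and
#' bound (B) buffer concentrations are constants: the diffusing species is
#' removed at rate k_on * b and produced at rate k_off * B.
#'
#' @slot kOn on-rate k+ (1/(concentration * s)).
#' @slot kOff off-rate k- (1/s).
#' @slot bFree free buffer concentration b.
#' @slot BBound bound buffer concentration B.
#' @export
setClass("ReactionParams",
  representation(kOn = "numeric", kOff = "numeric", bFree = "numeric",
                 BBound = "numeric"),
  validity = function(object) {
    if (any(c(object@kOn, object@kOff, object@bFree, object@BBound) < 0))
      "all reaction parameters must be nonnegative" else TRUE
  })

#' SimulationState: the profile vector and source history at step n
#'
#' @slot rho nondimensional profile rho(R_i) (concentration units).  At the
#'   origin node `rho[1]` holds the point-source limit of `R c`, which is
#'   `chi_n F_n` after each step (0 only while the source has never fired).
#' @slot step completed step count.
#' @slot chi realized 0/1 source states, one per completed step.
#' @slot F realized flux factors, one per completed step.
#' @slot diverged TRUE when max |rho|/F exceeded the divergence threshold.
#' @export
setClass("SimulationState",
  representation(rho = "numeric", step = "integer", chi = "integer",
                 F = "numeric", diverged = "logical"),
  validity = function(object) {
    msg <- NULL
    if (length(object@chi) != object@step || length(object@F) != object@step)
      msg <- c(msg, "chi and F must have one entry per completed step")
    if (is.null(msg)) TRUE else msg
  })

#' Trajectory: recorded output of [runSimulation()]
#'
#' @slot recorded matrix of recorded profiles (one row per recorded step).
#' @slot recSteps step indices of the recorded rows.
#' @slot state final [SimulationState-class].
#' @slot grid the grid the profiles live on.
#' @export
setClass("Trajectory",
  representation(recorded = "matrix", recSteps = "integer",
                 state = "SimulationState", grid = "InterpolationGrid"))

#' ErrorReport: result of a validation protocol run
#'
#' @slot epsTrace error \eqn{\epsilon_{sim}(t_n)} at the evaluated steps.
#' @slot epsSteps the evaluated step indices.
#' @slot epsMax max of `epsTrace`.
#' @slot nnz nonzero count of the propagation matrix used.
#' @slot params list with N, NF, INear, IFar.
#' @slot diverged whether the run diverged.
#' @slot protocol `"always_on"` or `"random_on"`.
#' @export
setClass("ErrorReport",
  representation(epsTrace = "numeric", epsSteps = "integer", epsMax = "numeric",
                 nnz = "integer", params = "list", diverged = "logical",
                 protocol = "character"),
  validity = function(object) {
    msg <- NULL
    fin <- object@epsTrace[is.finite(object@epsTrace)]
    if (length(fin) && any(fin < 0)) msg <- c(msg, "errors must be nonnegative")
    if (!object@protocol %in% c("always_on", "random_on"))
      msg <- c(msg, "protocol must be always_on or random_on")
    if (is.null(msg)) TRUE else msg
  })
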