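## Gauss-diffusion quadrature construction.
##
## The weight function of the one-dimensional reduced propagation integral is
##   W(R,R') = pi^{-1/2} [exp(-(R-R')^2) - exp(-(R+R')^2)]
##           = 2 pi^{-1/2} exp(-R^2 - R'^2) sinh(2 R R').
## A Gaussian quadrature for this weight is built per evaluation radius R from
## the moments M_n (parity-split recurrences evaluated in arbitrary-precision
## arithmetic), the monic three-term recurrence coefficients a_j, b_j, and the
## eigen-decomposition of the symmetrized Jacobi matrix.

#' Diffusion weight function W(R, R')
#'
#' Numerically stable in both regimes: the difference of Gaussians cancels
#' catastrophically when `2*R*Rp` is small, so the sinh form is used there;
#' the sinh form overflows when `2*R*Rp` is large, so the difference form is
#' used there.  Negative arguments are permitted (the function is
#' antisymmetric in each argument).
#'
#' @param R,Rp nondimensional radii (vectorized, recycled).
#' @return `W(R, Rp)`, dimensionless.
#' @examples
#' weightFunction(1, 1) # (1 - exp(-4))/sqrt(pi)
#' @export
weightFunction <- function(R, Rp) {
  n <- max(length(R), length(Rp))
  R <- rep_len(R, n)
  Rp <- rep_len(Rp, n)
  out <- numeric(n)
  small <- abs(2 * R * Rp) < 1e-4
  if (any(small)) {
    out[small] <- (2 / sqrt(pi)) * exp(-R[small]^2 - Rp[small]^2) *
      sinh(2 * R[small] * Rp[small])
  }
  if (any(!small)) {
    out[!small] <- (exp(-(R[!small] - Rp[!small])^2) -
                      exp(-(R[!small] + Rp[!small])^2)) / sqrt(pi)
  }
  out
}

#' Moments of the diffusion weight function
#'
#' Computes \eqn{M_n = \int_0^\infty x^n W(R,x) dx} for `n = 0..nMax` at
#' `precisionDigits` decimal digits, using the closed-form seeds
#' \eqn{M_0 = erf(R)}, \eqn{M_1 = R},
#' \eqn{M_2 = (R^2 + 1/2) erf(R) + R e^{-R^2}/\sqrt\pi},
#' \eqn{M_3 = R(2R^2+3)/2} and the parity-split recurrences
#' \deqn{M_{2k} = (R^2 + 2k - 3/2) M_{2k-2} + (k-1)(3/2-k) M_{2k-4}}
#' \deqn{M_{2l+1} = (R^2 + 2l - 1/2) M_{2l-1} - (l-1/2)(l-1) M_{2l-3}.}
#'
#' @param R nondimensional radius, must be positive: at R = 0 the measure is
#'   degenerate (all moments vanish) and no quadrature exists; the origin is
#'   handled separately by the grid (its propagation row is identically 0).
#' @param nMax highest order (>= 0).
#' @param precisionDigits working decimal precision (>= 50).
#' @return a [MomentTable-class].
#' @export
momentTable <- function(R, nMax, precisionDigits = 120L) {
  if (!(R > 0))
    stop("R must be > 0: at R = 0 the weight function vanishes identically ",
         "(degenerate measure, all moments 0)")
  if (nMax < 0) stop("nMax must be >= 0")
  if (precisionDigits < 50) stop("precisionDigits must be >= 50")
  res <- cpp_moments(R, as.integer(nMax), as.integer(precisionDigits))
  new("MomentTable", R = R, nMax = as.integer(nMax), moments = res$values,
      momentStrings = as.character(res$strings),
      precisionDigits = as.integer(precisionDigits))
}

#' Brute-force verification of the moment recurrences
#'
#' Recomputes every moment by direct high-precision numerical integration of
#' \eqn{x^n W(R,x)} (spectrally accurate trapezoid for the full-line Gaussian
#' piece plus tanh-sinh quadrature for the incomplete piece near the origin)
#' and returns the relative differences against the recurrence values.
#' This is the independent oracle used by the test suite.
#'
#' @inheritParams momentTable
#' @return numeric vector of |relative difference|, one per order `0..nMax`.
#' @export
momentRecurrenceCheck <- function(R, nMax, precisionDigits = 80L) {
  if (!(R > 0)) stop("R must be > 0")
  cpp_moment_check(R, as.integer(nMax), as.integer(precisionDigits))
}

#' Recurrence coefficients of the orthogonal polynomials
#'
#' Inner products \eqn{\langle x^a p_j^2\rangle} are formed by convolving the
#' polynomial coefficient lists and dotting with the moment vector, all at the
#' working precision of the moment table; `a_j = <x p_j^2>/<p_j^2>` and
#' `b_j = <p_j^2>/<p_{j-1}^2>`.  The map from moments to coefficients loses
#' roughly `2 N log10(R)` digits to cancellation, hence the high working
#' precision; if the precision is insufficient the error
#' `"precision exhausted"` is raised and the caller should retry with more
#' digits (see [buildGDQ()] which does this automatically).
#'
#' @param moments a [MomentTable-class] with `nMax >= 2 N`.
#' @param N quadrature order.
#' @return a [RecurrenceCoefficients-class].
#' @export
recurrenceCoefficients <- function(moments, N) {
  stopifnot(is(moments, "MomentTable"))
  if (moments@nMax < 2 * N)
    stop("moment table must extend to order 2N")
  res <- cpp_gdq_coeffs(moments@R, as.integer(N),
                        as.integer(moments@precisionDigits))
  if (res$status != 0)
    stop("precision exhausted: raise precisionDigits (cancellation in the ",
         "moment inner products at R = ", moments@R, ", N = ", N, ")")
  new("RecurrenceCoefficients", R = moments@R, N = as.integer(N),
      a = res$a, b = res$b,
      precisionDigits = moments@precisionDigits)
}

#' Build a Gauss-diffusion quadrature rule
#'
#' Assembles the symmetric tridiagonal Jacobi matrix (diagonal `a_j`,
#' off-diagonal `sqrt(b_j)` — the symmetrized form whose orthonormal
#' eigenvectors feed the weight formula), solves the eigenproblem, and
#' returns points (eigenvalues) and weights
#' \eqn{w_\alpha = v_{\alpha,0}^2\, erf(R)}.  The recurrence coefficients are
#' computed at high precision and the precision is doubled automatically
#' (up to 480 digits) when cancellation exhausts it; the symmetric
#' tridiagonal eigenproblem itself is perfectly conditioned and is solved in
#' double precision, after which points and weights are machine-precision
#' quantities.
#'
#' @param R evaluation radius (> 0).
#' @param N quadrature order (>= 1).
#' @param precisionDigits starting working precision (default 120).
#' @return a [QuadratureRule-class].
#' @examples
#' r <- buildGDQ(1, 10)
#' sum(quadWeights(r)) - pracma::erf(1) # ~1e-16
#' @export
buildGDQ <- function(R, N, precisionDigits = 120L) {
  if (!(R > 0)) stop("R must be > 0")
  if (N < 1) stop("N must be >= 1")
  prec <- as.integer(precisionDigits)
  repeat {
    res <- cpp_gdq_coeffs(R, as.integer(N), prec)
    if (res$status == 0L) break
    if (prec >= 480L)
      stop("precision exhausted at the 480-digit cap (R = ", R,
           ", N = ", N, ")")
    prec <- min(480L, prec * 2L)
  }
  erfR <- .erf(R)
  if (N == 1L) {
    pts <- res$a
    wts <- erfR
  } else {
    J <- diag(res$a)
    off <- sqrt(res$b)
    idx <- cbind(seq_len(N - 1L), seq_len(N - 1L) + 1L)
    J[idx] <- off
    J[idx[, c(2L, 1L), drop = FALSE]] <- off
    eg <- eigen(J, symmetric = TRUE)
    ord <- order(eg$values)
    pts <- eg$values[ord]
    wts <- (eg$vectors[1L, ord])^2 * erfR
  }
  if (any(wts < -1e-30))
    stop("eigen failure: negative quadrature weight at R = ", R)
  new("QuadratureRule", R = R, N = as.integer(N), points = pts,
      weights = wts, precisionDigits = prec)
}

## In-memory rule cache, keyed by (R to 15 significant digits, N).
.gdqCacheKey <- function(R, N) sprintf("%.15g|%d", R, N)

.buildGDQCached <- function(R, N, precisionDigits, cache) {
  key <- .gdqCacheKey(R, N)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  rule <- buildGDQ(R, N, precisionDigits)
  if (!is.null(cache)) cache[[key]] <- rule
  rule
}

#' Integrate a function against the diffusion weight with a quadrature rule
#'
#' Convenience wrapper: \eqn{\int_0^\infty f(x) W(R,x) dx \approx
#' \sum_\alpha w_\alpha f(x_\alpha)}.
#'
#' @param rule a [QuadratureRule-class].
#' @param f a vectorized function.
#' @return the weighted sum.
#' @export
gdqIntegrate <- function(rule, f) {
  sum(rule@weights * f(rule@points))
}
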