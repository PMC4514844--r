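## Fornberg polynomial-interpolation weights (function values only, i.e.
## derivative order 0), with nearest-subset stencil selection.

#' Select a contiguous stencil of the NF nodes nearest to x0
#'
#' The stencil is forced contiguous in the sorted grid (standard for 1-D
#' polynomial interpolation).  Ties — x0 exactly equidistant from the two
#' candidate extensions — extend toward larger R, where profiles decay and
#' interpolation is benign.  At the domain boundaries the window clamps.
#'
#' @param x0 evaluation abscissa.
#' @param gridPoints strictly increasing abscissas.
#' @param NF stencil size (<= number of grid points).
#' @return integer indices (into `gridPoints`) of the stencil, increasing.
#' @export
selectStencil <- function(x0, gridPoints, NF) {
  I <- length(gridPoints)
  if (NF > I) stop("NF (", NF, ") exceeds the number of grid points (", I, ")")
  l <- findInterval(x0, gridPoints) # gridPoints[l] <= x0 < gridPoints[l+1]
  r <- l + 1L
  for (k in seq_len(NF)) {
    if (l < 1L) {
      r <- r + 1L
    } else if (r > I) {
      l <- l - 1L
    } else {
      dl <- x0 - gridPoints[l]
      dr <- gridPoints[r] - x0
      if (dl < dr) l <- l - 1L else r <- r + 1L # tie extends toward larger R
    }
  }
  (l + 1L):(r - 1L)
}

## Index-centered bracketing stencil: the window is centered (in index
## space) on the interval containing x0.  Identical to the nearest-subset
## window on locally uniform grids; on strongly graded grids it avoids the
## lopsided windows whose interpolants oscillate.  Used by the assembly's
## stencil-conditioning guard.
.balancedStencil <- function(x0, gridPoints, NF) {
  I <- length(gridPoints)
  l <- findInterval(x0, gridPoints)
  l <- min(max(l, 1L), I - 1L)
  start <- l - (NF - 2L) %/% 2L
  start <- max(1L, min(start, I - NF + 1L))
  start:(start + NF - 1L)
}

#' Fornberg interpolation weights on an arbitrary node set
#'
#' Weights `A` such that \eqn{f(x_0) \approx \sum_\nu A_\nu f(nodes_\nu)},
#' exact for polynomials of degree `<= length(nodes) - 1`.  The recursion
#' runs over the `NF` supplied nodes only, never the full grid, so each call
#' is O(NF^2).
#'
#' @param x0 evaluation abscissa.
#' @param nodes pairwise-distinct abscissas (the stencil).
#' @return numeric weights, one per node; they sum to 1.
#' @examples
#' fornbergWeights(0.5, c(0, 1)) # c(0.5, 0.5)
#' @export
fornbergWeights <- function(x0, nodes) {
  n <- length(nodes)
  if (anyDuplicated(nodes)) stop("duplicate interpolation nodes")
  A <- numeric(n)
  A[1] <- 1
  if (n == 1L) return(A)
  c1 <- 1
  for (j in 2:n) {
    c2 <- 1
    diagPrev <- A[j - 1] # previous stage's diagonal, before it is updated
    for (k in 1:(j - 1)) {
      c3 <- nodes[j] - nodes[k]
      c2 <- c2 * c3
      A[k] <- (nodes[j] - x0) * A[k] / c3
    }
    A[j] <- -(c1 / c2) * (nodes[j - 1] - x0) * diagPrev
    c1 <- c2
  }
  A
}

#' Interpolate gridded values at arbitrary points
#'
#' Selects the nearest contiguous `NF`-point stencil for each evaluation
#' point and applies the Fornberg weights.
#'
#' @param values function values on `gridPoints`.
#' @param gridPoints strictly increasing abscissas.
#' @param x0 evaluation abscissas (vectorized).
#' @param NF stencil size.
#' @return interpolated values at `x0`.
#' @export
interpolateValues <- function(values, gridPoints, x0, NF) {
  if (length(values) != length(gridPoints))
    stop("values and gridPoints must have the same length")
  vapply(x0, function(z) {
    st <- selectStencil(z, gridPoints, NF)
    sum(fornbergWeights(z, gridPoints[st]) * values[st])
  }, numeric(1))
}
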