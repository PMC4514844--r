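# Fornberg interpolation weights and stencil selection.

test_that("stencil selection: nearest contiguous window with clamping", {
  g <- c(0, 1, 2, 3, 4)
  expect_equal(selectStencil(2.5, g, 2), c(3L, 4L)) # nodes {2, 3}
  expect_equal(selectStencil(0.1, g, 3), c(1L, 2L, 3L)) # clamps left
  st <- selectStencil(2.0, g, 3)
  expect_true(3L %in% st) # node-coincident case keeps the node
  expect_equal(length(st), 3L)
  expect_equal(diff(st), rep(1L, 2)) # contiguous
  # tie extends toward larger R: at x0 = 1.5 the 3-point window is {1,2,3},
  # not {0,1,2}
  expect_equal(selectStencil(1.5, g, 3), c(2L, 3L, 4L))
  expect_error(selectStencil(1, g, 6), "exceeds")
})

test_that("weights: midpoint, node coincidence, constants, duplicates", {
  expect_equal(fornbergWeights(0.5, c(0, 1)), c(0.5, 0.5))
  nodes <- c(0.1, 0.7, 1.3, 2.9)
  A <- fornbergWeights(nodes[3], nodes)
  expect_equal(A, c(0, 0, 1, 0), tolerance = 1e-13)
  # sum to one on arbitrary well-separated nodes (constant reproduction)
  set.seed(4)
  for (k in 1:20) {
    nd <- sort(runif(7, -3, 3))
    while (min(diff(nd)) < 0.05) nd <- sort(runif(7, -3, 3))
    expect_equal(sum(fornbergWeights(runif(1, -3, 3), nd)), 1,
                 tolerance = 1e-12)
  }
  expect_error(fornbergWeights(0.5, c(0, 1, 1)), "duplicate")
})

test_that("weights equal the Lagrange basis on 1000 random node sets", {
  set.seed(11)
  worst <- 0
  for (k in 1:1000) {
    n <- sample(2:10, 1)
    # keep nodes away from coincidence: both formulas lose accuracy as
    # nodes merge, and the comparison should measure agreement, not
    # shared ill-conditioning
    nd <- sort(runif(n, 0, 10))
    while (min(diff(nd)) < 0.05) nd <- sort(runif(n, 0, 10))
    x0 <- runif(1, 0, 10)
    A_f <- fornbergWeights(x0, nd)
    A_l <- lagrangeWeights(x0, nd)
    # relative to the weight scale: x0 outside the node span makes the
    # weights extrapolation-sized, and absolute agreement scales with them
    worst <- max(worst, max(abs(A_f - A_l)) / max(1, max(abs(A_l))))
  }
  expect_lt(worst, 1e-10)
})

test_that("interpolation reproduces polynomials up to degree NF-1", {
  g <- gridPoints(smallGrid())
  # cubic with NF = 4 on the actual diffusion grid
  vals <- g^3
  for (x0 in c(0.3, 4.7, 9.9, 12.5, 30)) {
    expect_equal(interpolateValues(vals, g, x0, 4), x0^3,
                 tolerance = 1e-12)
  }
  # degree NF-1 for several NF on the diffusion grid
  for (NF in c(2, 5, 8)) {
    vals <- g^(NF - 1)
    for (x0 in c(1.1, 8.3, 20)) {
      expect_equal(interpolateValues(vals, g, x0, NF), x0^(NF - 1),
                   tolerance = 1e-10)
    }
  }
})

test_that("interpolation identities: constants and grid points", {
  g <- gridPoints(smallGrid())
  vals <- rep(3.7, length(g))
  expect_equal(interpolateValues(vals, g, c(0.01, 5, 44), 6),
               rep(3.7, 3), tolerance = 1e-12)
  vals <- sin(g)
  expect_equal(interpolateValues(vals, g, g[7], 5), vals[7],
               tolerance = 1e-13)
})

test_that("balanced stencil agrees with nearest-subset on uniform grids", {
  g <- seq(0, 10, by = 0.5)
  for (x0 in c(0.2, 3.3, 5.01, 9.4)) {
    expect_equal(gdqprop:::.balancedStencil(x0, g, 6),
                 selectStencil(x0, g, 6))
  }
})
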