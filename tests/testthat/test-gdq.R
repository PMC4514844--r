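# Gauss-diffusion quadrature: weight function, moments, recurrence
# coefficients, and the assembled rules.

test_that("weight function: closed form, antisymmetry, origin, stability", {
  expect_equal(weightFunction(1, 1), (1 - exp(-4)) / sqrt(pi))
  expect_equal(weightFunction(0, c(0.3, 2, 7)), c(0, 0, 0))
  # antisymmetric in each argument
  for (R in c(0.3, 1.7)) for (Rp in c(0.2, 2.5)) {
    expect_equal(weightFunction(R, -Rp), -weightFunction(R, Rp))
    expect_equal(weightFunction(-R, Rp), -weightFunction(R, Rp))
  }
  # small-argument branch agrees with the sinh closed form and avoids the
  # cancellation of the difference-of-Gaussians form
  R <- 1e-6; Rp <- 2
  expect_equal(weightFunction(R, Rp),
               2 / sqrt(pi) * exp(-R^2 - Rp^2) * sinh(2 * R * Rp),
               tolerance = 1e-14)
})

test_that("moment seeds match their closed forms", {
  m <- momentTable(2, 3)
  expect_equal(momentValues(m)[2], 2, tolerance = 1e-15) # M_1 = R
  m15 <- momentTable(1.5, 3)
  expect_equal(momentValues(m15)[4], 0.75 * (2 * 2.25 + 3),
               tolerance = 1e-15) # M_3 = R(2R^2+3)/2
  m1 <- momentTable(1, 2)
  expect_equal(momentValues(m1)[1], erf(1), tolerance = 1e-15)
  expect_equal(momentValues(m1)[3],
               (1 + 0.5) * erf(1) + exp(-1) / sqrt(pi), tolerance = 1e-15)
  # degenerate origin measure is refused
  expect_error(momentTable(0, 4), "degenerate")
})

test_that("moment recurrences agree with brute-force integration", {
  # high-precision check at 1e-30 ...
  expect_lt(max(momentRecurrenceCheck(1, 8, 60)), 1e-30)
  # ... and across radii up to order 40
  for (R in c(0.5, 5, 20)) {
    expect_lt(max(momentRecurrenceCheck(R, 40, 80)), 1e-35)
  }
})

test_that("recurrence coefficients: a0 identity, positivity, preconditions", {
  m <- momentTable(1, 2)
  co <- recurrenceCoefficients(m, 1)
  expect_equal(co@a[1], 1 / erf(1), tolerance = 1e-14) # a_0 = M_1/M_0
  m6 <- momentTable(1, 6)
  co3 <- recurrenceCoefficients(m6, 3)
  expect_true(all(co3@b > 0)) # positive measure on (0, Inf)
  expect_error(recurrenceCoefficients(m, 5), "order 2N")
})

test_that("one-point rule is (M1/M0, M0)", {
  for (R in c(0.4, 1, 3)) {
    r <- buildGDQ(R, 1)
    expect_equal(quadPoints(r), R / erf(R), tolerance = 1e-14)
    expect_equal(quadWeights(r), erf(R), tolerance = 1e-14)
  }
})

test_that("rules integrate monomials exactly to degree 2N-1", {
  for (R in c(0.1, 1, 5, 20)) {
    for (N in c(2, 5, 10, 20)) {
      r <- buildGDQ(R, N)
      expect_equal(sum(quadWeights(r)), erf(R), tolerance = 1e-12)
      expect_true(all(diff(quadPoints(r)) > 0))
      expect_true(all(quadPoints(r) > 0))
      M <- momentValues(momentTable(R, 2 * N - 1, r@precisionDigits))
      rel <- vapply(0:(2 * N - 1), function(k) {
        abs(sum(quadWeights(r) * quadPoints(r)^k) - M[k + 1]) / abs(M[k + 1])
      }, numeric(1))
      expect_lt(max(rel), 1e-11)
    }
  }
})

test_that("rule reproduces M_5 at R = 2 from the moment recurrence", {
  r <- buildGDQ(2, 10, 100)
  M <- momentValues(momentTable(2, 5))
  expect_equal(sum(quadWeights(r) * quadPoints(r)^5), M[6],
               tolerance = 1e-12)
})

test_that("N = 20 rules match adaptive integration for smooth functions", {
  for (R in c(0.1, 1, 7, 50)) {
    r <- buildGDQ(R, 20)
    for (f in list(function(x) exp(-x), function(x) 1 / (1 + x^2))) {
      lo <- max(0, R - 13)
      ref <- stats::integrate(function(x) f(x) * weightFunction(R, x),
                              lo, R + 13, rel.tol = 1e-13,
                              abs.tol = 0)$value
      expect_equal(gdqIntegrate(r, f), ref, tolerance = 1e-10)
    }
  }
})

test_that("monomial integration error is non-increasing in N", {
  for (R in c(0.5, 5)) {
    err_at_N <- vapply(c(2, 5, 10, 20), function(N) {
      r <- buildGDQ(R, N)
      M <- momentValues(momentTable(R, 3))
      # common family: degrees 0..3 are integrable by every tested order
      max(vapply(0:3, function(k) {
        abs(sum(quadWeights(r) * quadPoints(r)^k) - M[k + 1]) / abs(M[k + 1])
      }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(err_at_N) <= 1e-13))
  }
})

test_that("results are insensitive to raising the working precision", {
  for (R in c(0.3, 5)) {
    r100 <- buildGDQ(R, 10, 100)
    r150 <- buildGDQ(R, 10, 150)
    expect_equal(quadPoints(r100), quadPoints(r150), tolerance = 1e-13)
    expect_equal(quadWeights(r100), quadWeights(r150), tolerance = 1e-13)
  }
})

test_that("quadrature cache round-trips losslessly through JSON", {
  cache <- new.env(parent = emptyenv())
  g <- smallGrid()
  P <- assemblePropagator(g, 5, 4, cache = cache)
  path <- withr::local_tempfile(fileext = ".json")
  writeQuadratureCache(cache, path)
  cache2 <- readQuadratureCache(path)
  P2 <- assemblePropagator(g, 5, 4, cache = cache2)
  expect_identical(propMatrix(P), propMatrix(P2))
})
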