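# Closed-form solutions, flux factor, nondimensionalization.

test_that("flux factor: zero, scaling laws, and the worked value", {
  p <- physicalParams(D = 1e-9, dt = 1e-7, j = 1e7)
  expect_equal(fluxFactor(p, j = 0), 0)
  # F ~ j and F ~ dt^{-1/2}
  expect_equal(fluxFactor(p, j = 2e7), 2 * fluxFactor(p))
  p4 <- physicalParams(D = 1e-9, dt = 4e-7, j = 1e7)
  expect_equal(fluxFactor(p4), fluxFactor(p) / 2)
  # independent dimensional-analysis oracle: number density first,
  # then a separately-written molar conversion
  F_per_m3 <- 1e7 / (8 * pi * (1e-9)^1.5 * sqrt(1e-7))
  F_M <- F_per_m3 / (6.02214076e23 * 1e3)
  expect_equal(fluxFactor(p), F_M, tolerance = 1e-14)
  expect_equal(fluxFactor(p), 6.61e-5, tolerance = 1e-3)
  # half-space geometry doubles the factor
  ph <- physicalParams(D = 1e-9, dt = 1e-7, j = 1e7, geometry = "half")
  expect_equal(fluxFactor(ph), 2 * fluxFactor(p))
})

test_that("always-on profile: first step, steady state, telescoping", {
  R <- c(0.1, 0.5, 2, 8)
  expect_equal(alwaysOnProfile(R, 0, 3), rep(0, 4))
  expect_equal(alwaysOnProfile(R, 1, 2), 2 * erfc(R))
  expect_equal(alwaysOnProfile(R, 1e12, 5), rep(5, 4), tolerance = 1e-5)
  expect_equal(alwaysOnProfile(R, 2, 1.3), exactProfile(R, c(1, 1), 1.3),
               tolerance = 1e-14)
})

test_that("exact profile: single histories and the telescoping identity", {
  R <- seq(0.05, 10, length.out = 20)
  expect_equal(exactProfile(R, 1, 2), 2 * erfc(R))
  expect_equal(exactProfile(R, c(1, 0), 1),
               erf(R) - erf(R / sqrt(2)), tolerance = 1e-14)
  for (n in c(11, 100, 1000)) {
    expect_equal(exactProfile(R, rep(1, n), 1), alwaysOnProfile(R, n, 1),
                 tolerance = 1e-13)
  }
  # 0 <= rho/F <= 1 for any single-flux history
  set.seed(3)
  for (k in 1:10) {
    rho <- exactProfile(R, rbinom(60, 1, 0.5), 1)
    expect_true(all(rho >= -1e-15 & rho <= 1 + 1e-15))
  }
})

test_that("physical mapping: round trip, uniform profile, worked length", {
  p <- physicalParams(D = 1e-9, dt = 1e-7, j = 1e7)
  g <- smallGrid()
  R <- gridPoints(g)
  # erfc profile maps to the closed-form concentration
  Fv <- fluxFactor(p)
  phys <- toPhysical(Fv * erfc(R), g, p)
  r <- phys$r[-1]
  expect_equal(phys$c[-1],
               convertConcentration(
                 p@j / (4 * pi * p@D * r) * erfc(r / (2 * sqrt(p@D * p@dt))),
                 "per_m3", "M"),
               tolerance = 1e-12)
  # uniform concentration: rho = c0 R maps back to c0 everywhere
  u <- toPhysical(4.2 * R, g, p)
  expect_equal(u$c, rep(4.2, length(R)), tolerance = 1e-12)
  # round trip
  nd <- toNondimensional(phys$c, phys$r, p)
  expect_equal(nd$rho[-1], (Fv * erfc(R))[-1], tolerance = 1e-12)
  # R = 5148 at diffusion length 20 nm is 102.96 um
  expect_equal(diffusionLength(p), 20e-9, tolerance = 1e-12)
  expect_equal(5148 * diffusionLength(p), 102.96e-6, tolerance = 1e-12)
})

test_that("concentration unit conversions are consistent", {
  x <- 3.5e22 # per m^3
  expect_equal(convertConcentration(convertConcentration(x, "per_m3", "M"),
                                    "M", "per_m3"), x)
  expect_equal(convertConcentration(1, "M", "nM"), 1e9)
  expect_equal(convertConcentration(6.61e-5 * 1e-3, "M", "nM"), 66.1)
})
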