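# Propagation matrix assembly and time stepping.

test_that("row 0 is empty; matrix support respects the stencil bound", {
  P <- smallProp()
  W <- propMatrix(P)
  expect_true(all(W[1, ] == 0))
  I <- length(gridPoints(P))
  expect_lte(nnzCount(P), I * (P@NF + P@N))
  # per-row support is one contiguous union of stencils
  expect_true(all(Matrix::rowSums(W != 0)[-1] <= P@NF + P@N))
})

test_that("uniform concentration is a fixed point of W", {
  P <- smallProp()
  g <- gridPoints(P)
  out <- as.numeric(propMatrix(P) %*% (3 * g))
  expect_lt(max(abs(out[-1] - 3 * g[-1])) / (3 * max(g)), 1e-10)
})

test_that("one exact propagation step of the erfc profile", {
  P <- smallProp()
  g <- gridPoints(P)
  Fv <- 2.5
  # the 40-point smoke grid has near spacing 10/14, so its one-step
  # interpolation floor is ~3e-4; the production-scale bound is asserted
  # at full problem size in the acceptance suite
  pred <- as.numeric(propMatrix(P) %*% (Fv * erfc(g))) + Fv * sourceVector(P)
  expect_lt(max(abs(pred - Fv * erfc(g / sqrt(2)))) / Fv, 1e-3)
})

test_that("step identities: first step, off source, origin value, linearity", {
  P <- smallProp()
  st0 <- initialState(P)
  st1 <- stepDiffusion(st0, P, 1, 1.7)
  expect_equal(profileRho(st1), 1.7 * sourceVector(P)) # W 0 = 0, exact
  expect_equal(profileRho(st1)[1], 1.7) # origin = chi F
  st_off <- stepDiffusion(st0, P, 0, 1.7)
  expect_equal(profileRho(st_off), rep(0, length(gridPoints(P))))
  # linearity of the off-source step
  set.seed(8)
  a <- runif(length(gridPoints(P))); b <- runif(length(gridPoints(P)))
  mk <- function(v) new("SimulationState", rho = v, step = 0L,
                        chi = integer(0), F = numeric(0), diverged = FALSE)
  sab <- profileRho(stepDiffusion(mk(a + b), P, 0, 1))
  sa <- profileRho(stepDiffusion(mk(a), P, 0, 1))
  sb <- profileRho(stepDiffusion(mk(b), P, 0, 1))
  expect_equal(sab, sa + sb, tolerance = 1e-13)
})

test_that("ten on-steps track the closed form", {
  P <- smallProp()
  g <- gridPoints(P)
  st <- initialState(P)
  for (k in 1:10) st <- stepDiffusion(st, P, 1, 1)
  expect_lt(max(abs(profileRho(st) - erfc(g / sqrt(10)))), 1e-4)
})

test_that("reaction step: zero rates reduce to pure diffusion", {
  P <- smallProp()
  rp0 <- new("ReactionParams", kOn = 0, kOff = 0, bFree = 0, BBound = 0)
  st0 <- initialState(P)
  s1 <- stepReaction(st0, P, 1, 1.2, rp0, dt = 1e-5)
  s2 <- stepDiffusion(st0, P, 1, 1.2)
  expect_identical(profileRho(s1), profileRho(s2))
})

test_that("reaction step: equilibrium fixed point and kernel normalization", {
  P <- smallProp()
  g <- gridPoints(P)
  rp <- new("ReactionParams", kOn = 1e8, kOff = 10, bFree = 1e-4,
            BBound = 1e-4)
  dt <- 1e-5
  ceq <- rp@kOff * rp@BBound / (rp@kOn * rp@bFree)
  st <- new("SimulationState", rho = ceq * g, step = 0L, chi = integer(0),
            F = numeric(0), diverged = FALSE)
  s1 <- stepReaction(st, P, 0, 0, rp, dt)
  expect_lt(max(abs(profileRho(s1) - ceq * g)) / (ceq * max(g)), 1e-10)
  # from rho = 0 with the source off, one step deposits the uniform
  # concentration kOff * B * dt (the heat kernel integrates to 1)
  sA <- stepReaction(initialState(P), P, 0, 0, rp, dt)
  expect_equal(profileRho(sA), rp@kOff * rp@BBound * dt * g)
})

test_that("reaction step relaxation defect is O(dt^2)", {
  P <- smallProp()
  g <- gridPoints(P)
  rp <- new("ReactionParams", kOn = 1e8, kOff = 10, bFree = 1e-4,
            BBound = 1e-4)
  ceq <- rp@kOff * rp@BBound / (rp@kOn * rp@bFree)
  defect <- vapply(c(1e-5, 5e-6, 2.5e-6), function(d) {
    st <- new("SimulationState", rho = 2 * ceq * g, step = 0L,
              chi = integer(0), F = numeric(0), diverged = FALSE)
    s1 <- stepReaction(st, P, 0, 0, rp, d)
    cex <- ceq + ceq * exp(-rp@kOn * rp@bFree * d)
    max(abs(profileRho(s1)[-1] - cex * g[-1])) / (ceq * max(g))
  }, numeric(1))
  expect_gt(defect[1] / defect[2], 3.5)
  expect_lt(defect[1] / defect[2], 4.5)
  expect_gt(defect[2] / defect[3], 3.5)
  expect_lt(defect[2] / defect[3], 4.5)
})

test_that("reaction precondition: contraction factor must stay positive", {
  P <- smallProp()
  rp <- new("ReactionParams", kOn = 1e8, kOff = 10, bFree = 1e-4,
            BBound = 1e-4)
  expect_error(stepReaction(initialState(P), P, 0, 0, rp, dt = 1), "< 1")
})

test_that("the same W serves any dt: time step enters only through F", {
  # the matrix is built purely from the nondimensional grid, so changing
  # dt rescales F and the physical mapping but leaves W untouched
  p1 <- physicalParams(D = 1e-9, dt = 1e-7, j = 1e7)
  p2 <- physicalParams(D = 1e-9, dt = 1e-3, j = 1e7)
  expect_equal(fluxFactor(p1) / fluxFactor(p2), sqrt(1e-3 / 1e-7))
  expect_equal(diffusionLength(p2) / diffusionLength(p1), 100)
  # identical nondimensional trajectory, different physical meaning
  P <- smallProp()
  t1 <- runSimulation(P, sourceAlwaysOn(), 5, F = fluxFactor(p1))
  expect_equal(recordedProfiles(t1)[5, ] / fluxFactor(p1),
               {
                 t2 <- runSimulation(P, sourceAlwaysOn(), 5,
                                     F = fluxFactor(p2))
                 recordedProfiles(t2)[5, ] / fluxFactor(p2)
               }, tolerance = 1e-13)
})

test_that("runs: schedules, determinism, divergence error, feedback replay", {
  P <- smallProp()
  g <- gridPoints(P)
  tr <- runSimulation(P, sourceAlwaysOn(), 1)
  expect_equal(profileRho(tr), sourceVector(P))
  # bit-identical trajectories from the same seed
  t1 <- runSimulation(P, sourceBernoulli(0.5), 200, seed = 42,
                      recordEvery = 10)
  t2 <- runSimulation(P, sourceBernoulli(0.5), 200, seed = 42,
                      recordEvery = 10)
  expect_identical(recordedProfiles(t1), recordedProfiles(t2))
  expect_identical(sourceHistory(t1)$chi, sourceHistory(t2)$chi)
  t3 <- runSimulation(P, sourceBernoulli(0.5), 200, seed = 43,
                      recordEvery = 10)
  expect_false(identical(sourceHistory(t1)$chi, sourceHistory(t3)$chi))
  # seed is mandatory for stochastic sources
  expect_error(runSimulation(P, sourceBernoulli(0.5), 10), "seed")
  # threshold feedback: gate off once the sensed value exceeds a level;
  # replaying the realized history step-by-step reproduces the trajectory
  sense <- which.min(abs(g - 1))
  gate <- sourceFeedback(function(rho, step) list(chi = as.integer(rho[sense] < 0.4)))
  tf <- runSimulation(P, gate, 50, seed = 1, recordEvery = 1)
  chi <- sourceHistory(tf)$chi
  expect_true(any(chi == 0) && any(chi == 1)) # the gate actually switched
  st <- initialState(P)
  for (k in seq_len(50)) st <- stepDiffusion(st, P, chi[k], 1)
  expect_equal(profileRho(st), profileRho(tf), tolerance = 1e-14)
})

test_that("divergence raises with the offending step index", {
  # an intentionally broken operator: doubling amplifies until the
  # threshold trips
  P <- smallProp()
  Pbad <- P
  Pbad@W <- P@W * 2
  expect_error(runSimulation(Pbad, sourceAlwaysOn(), 1000),
               "diverged at step [0-9]+")
})
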