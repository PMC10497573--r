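p_default <- modelParams()

test_that("one Euler step from a uniform state is the hand-computed update", {
  p <- p_default
  sys <- buildSystem(p, N = 3)
  dt <- 0.1
  tr <- integrateEuler(sys, p@m0, timeGrid(0, dt, 1))
  expect_equal(tr@center[2], p@m0 + dt * (-p@dm * p@m0 + sys@c), tolerance = 1e-14)
})

test_that("uncontrolled density plateaus at c/d_m and full dose decays purely", {
  p <- p_default
  sys <- buildSystem(p, N = 4)
  tr <- integrateEuler(sys, p@m0, timeGrid(0, 400, 10000))
  plateau <- activationConstant(p) / p@dm
  expect_equal(plateau, 0.035177, tolerance = 1e-4)
  expect_lt(abs(tail(centerSeries(tr), 1) - plateau) / plateau, 0.003)
  trFull <- integrateEuler(sys, p@m0, timeGrid(0, 350, 10000), etaT = 1, etaG = 1)
  expect_equal(tail(centerSeries(trFull), 1), p@m0 * exp(-p@dm * 350),
               tolerance = 5e-3)
  expect_equal(p@m0 * exp(-p@dm * 350), 2.547e-5, tolerance = 1e-3)
})

test_that("closed-form uniform solution has the right limits and dose scaling", {
  p <- p_default
  expect_equal(closedFormUniform(p, 0), 8.5e-3)
  expect_equal(closedFormUniform(p, 1e6), activationConstant(p) / p@dm,
               tolerance = 1e-12)
  # equal doses scale the steady state by (1 - eta) via the c-identity
  expect_equal(closedFormUniform(p, 1e6, 0.1, 0.1),
               0.9 * activationConstant(p) / p@dm, tolerance = 1e-12)
  expect_equal(closedFormUniform(p, 1e6, 0.1, 0.1), 0.031659, tolerance = 1e-4)
  expect_equal(closedFormUniform(p, 1e6, 1, 1), 0, tolerance = 1e-18)
})

test_that("Euler converges to the closed form at first order in dt", {
  p <- p_default
  sys <- buildSystem(p, N = 3)
  exact <- closedFormUniform(p, 400)
  errs <- vapply(c(1000, 2000, 4000), function(ns) {
    tr <- integrateEuler(sys, p@m0, timeGrid(0, 400, ns))
    abs(tail(centerSeries(tr), 1) - exact)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_equal(errs[1] / errs[2], 2, tolerance = 0.15)
  expect_equal(errs[2] / errs[3], 2, tolerance = 0.15)
  # same first-order pattern under full dose (pure decay)
  exact1 <- closedFormUniform(p, 350, 1, 1)
  errs1 <- vapply(c(1000, 2000, 4000), function(ns) {
    tr <- integrateEuler(sys, p@m0, timeGrid(0, 350, ns), etaT = 1, etaG = 1)
    abs(tail(centerSeries(tr), 1) - exact1)
  }, numeric(1))
  expect_equal(errs1[1] / errs1[2], 2, tolerance = 0.15)
  expect_equal(errs1[2] / errs1[3], 2, tolerance = 0.15)
})

test_that("uniform initial data stays uniform within each variant's stable range", {
  p <- p_default
  for (N in c(3, 6, 9)) {
    sys <- buildSystem(p, N = N, convention = "laplacian_consistent")
    tr <- integrateEuler(sys, p@m0, timeGrid(0, 400, 500))
    expect_lt(uniformityDefect(tr), 1e-12)
  }
  # the literal tensor stiffness squares the diffusion spectrum, so explicit
  # Euler needs a much smaller step before roundoff modes stop amplifying
  sysLit <- buildSystem(p, N = 3, convention = "paper_literal")
  trLit <- integrateEuler(sysLit, p@m0, timeGrid(0, 400, 8000))
  expect_lt(uniformityDefect(trLit), 1e-12)
})

test_that("RK4 oracle brackets the Euler solution at its first-order accuracy", {
  p <- p_default
  sys <- buildSystem(p, N = 3)
  ref <- rk4_center(sys, p@m0, 400, 4000)
  eul10 <- centerSeries(integrateEuler(sys, p@m0, timeGrid(0, 400, 10000)))
  eul20 <- centerSeries(integrateEuler(sys, p@m0, timeGrid(0, 400, 20000)))
  refi <- approx(seq(0, 400, length.out = 4001), ref,
                 xout = seq(0, 400, length.out = 10001))$y
  err10 <- max(abs(eul10 - refi) / refi)
  refi20 <- approx(seq(0, 400, length.out = 4001), ref,
                   xout = seq(0, 400, length.out = 20001))$y
  err20 <- max(abs(eul20 - refi20) / refi20)
  # RK4 is effectively exact here; Euler error is O(dt) and halves
  expect_lt(err10, 5e-3)
  expect_equal(err10 / err20, 2, tolerance = 0.2)
})

test_that("dose response is monotone with exactly proportional steady levels", {
  p <- p_default
  trajs <- doseResponseStudy(p, N = 3, nSteps = 2000)
  expect_length(trajs, 4)
  finals <- vapply(trajs, function(tr) tail(centerSeries(tr), 1), numeric(1))
  expect_true(all(diff(finals) < 0))  # strictly decreasing in dose
  # (0, 0) identical to the uncontrolled run
  sys <- buildSystem(p, N = 3)
  tr0 <- integrateEuler(sys, p@m0, timeGrid(0, p@tEndSim, 2000))
  expect_identical(centerSeries(trajs[[1]]), centerSeries(tr0))
  # steady level at half blockade is half the uncontrolled steady level
  expect_equal(closedFormUniform(p, 1e6, 0.5, 0.5),
               0.5 * closedFormUniform(p, 1e6), tolerance = 1e-12)
  expect_true(all(finals > 0))  # none reaches zero below full blockade
  expect_warning(doseResponseStudy(p, N = 2, doses = list(c(1.2, 0)), nSteps = 10),
                 "outside")
})

test_that("instability under the anti-dissipative sign is reported with a step index", {
  # a fast-diffusing variant makes the anti-dissipative growth overflow quickly
  pFast <- modelParams(Dm = 1)
  sys <- buildSystem(pFast, N = 8, diffusionSign = "paper_plus_rS")
  ic <- rep(pFast@m0, sys@n)
  ic[1] <- ic[1] * 1.5  # non-uniform seed excites the unstable modes
  expect_error(integrateEuler(sys, ic, timeGrid(0, 400, 500)), "step")
})
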