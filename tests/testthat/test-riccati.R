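p_default <- modelParams()

test_that("with zero input vectors the kernel matches its linear closed form", {
  pNoB <- modelParams(f = 0)  # b_T = b_G = 0, c = 0
  sys <- buildSystem(pNoB, N = 2)
  dm <- pNoB@dm
  closed <- function(t, tf) (1 - exp(2 * dm * (t - tf))) / (2 * dm)
  errs <- vapply(c(1000, 2000, 4000), function(ns) {
    path <- riccatiBackward(sys, timeGrid(0, 350, ns))
    max(abs(path@p - closed(timePoints(path), 350)))
  }, numeric(1))
  path <- riccatiBackward(sys, timeGrid(0, 350, 4000))
  expect_equal(path@p[1], 30.1196, tolerance = 1e-3)
  expect_equal(closed(0, 350), 30.1196, tolerance = 1e-4)
  # first-order convergence: error halves when the backward step count doubles
  expect_equal(errs[1] / errs[2], 2, tolerance = 0.1)
  expect_equal(errs[2] / errs[3], 2, tolerance = 0.1)
})

test_that("terminal conditions and sign of the kernel hold on the sweep", {
  sys <- buildSystem(p_default, N = 2)
  for (mode in c("scalar", "matrix")) {
    path <- riccatiBackward(sys, timeGrid(0, 350, 500), mode = mode)
    K <- length(path@times)
    expect_identical(path@p[K], 0)
    expect_identical(path@g[K], 0)
    expect_true(all(path@p >= 0))
    expect_true(all(path@g >= 0))
  }
  # matrix path stays symmetric PSD at a sampled time
  path <- riccatiBackward(sys, timeGrid(0, 350, 500), mode = "matrix")
  P0 <- path@Pmat[, , 1]
  expect_equal(P0, t(P0), tolerance = 1e-12)
  expect_true(all(eigen(P0, symmetric = TRUE, only.values = TRUE)$values > -1e-10))
})

test_that("matrix-mode projections reproduce the scalar kernel and offset", {
  sys <- buildSystem(p_default, N = 2)
  grid <- timeGrid(0, 350, 1000)
  sc <- riccatiBackward(sys, grid, mode = "scalar")
  mt <- riccatiBackward(sys, grid, mode = "matrix")
  # 1' P 1 and 1' s / c track p and g on the uniform-symmetric subspace
  expect_lt(max(abs(mt@p - sc@p)) / max(sc@p), 1e-8)
  expect_lt(max(abs(mt@g - sc@g)) / max(sc@g), 1e-8)
})

test_that("scalar and matrix closed loops agree on uniform problems", {
  p <- p_default
  for (N in c(2, 4)) {
    solS <- solveRegulator(p, N = N, nSteps = 2000, mode = "scalar")
    solM <- solveRegulator(p, N = N, nSteps = 2000, mode = "matrix")
    relerr <- max(abs(centerSeries(solS) - centerSeries(solM))) /
      max(centerSeries(solS))
    expect_lt(relerr, 1e-6)
    cs <- controlSchedules(solS); cm <- controlSchedules(solM)
    expect_lt(max(abs(cs$etaG - cm$etaG)), 1e-8)
  }
})

test_that("synthesized controls satisfy the stationarity conditions exactly", {
  sys <- buildSystem(p_default, N = 2)
  grid <- timeGrid(0, 350, 500)
  w <- costWeights(rT = 2, rG = 0.5)
  for (mode in c("scalar", "matrix")) {
    path <- riccatiBackward(sys, grid, w, mode = mode)
    for (idx in c(1L, 100L, 400L)) {
      syn <- synthesizeControls(path, p_default@m0, sys, index = idx)
      if (mode == "scalar") {
        resT <- w@rT * syn$etaT + sys@scalar$bT * syn$lambda
        resG <- w@rG * syn$etaG + sys@scalar$bG * syn$lambda
      } else {
        resT <- w@rT * syn$etaT + sum(sys@BT * syn$lambda)
        resG <- w@rG * syn$etaG + sum(sys@BG * syn$lambda)
      }
      expect_lt(abs(resT), 1e-12)
      expect_lt(abs(resG), 1e-12)
      # Hamiltonian convexity in the controls: weights are positive
      expect_gt(w@rT, 0); expect_gt(w@rG, 0)
    }
    # gains/offsets consistent with the kernel: eta = K m + rho
    syn <- synthesizeControls(path, p_default@m0, sys, index = 50L)
    if (mode == "scalar") {
      expect_equal(syn$etaT, syn$KT * p_default@m0 + syn$rhoT, tolerance = 1e-14)
      expect_equal(syn$etaG, syn$KG * p_default@m0 + syn$rhoG, tolerance = 1e-14)
    }
    # proportional input vectors give proportional controls at all times
    expect_equal(syn$etaT / syn$etaG,
                 (sys@scalar$bT / w@rT) / (sys@scalar$bG / w@rG),
                 tolerance = 1e-10)
  }
})

test_that("minimum-principle residuals vanish with the step size", {
  p <- p_default
  res_at <- function(ns) {
    sol <- solveRegulator(p, N = 2, nSteps = ns)
    tt <- timePoints(sol)
    dt <- tt[2] - tt[1]
    m <- centerSeries(sol)
    lam <- sol@lambdaCenter
    eta <- controlSchedules(sol)
    sc <- buildSystem(p, N = 2)@scalar
    # state equation: forward difference equals the dynamics at the left node
    resState <- (m[-1] - m[-length(m)]) / dt -
      (sc$aS * m[-length(m)] + sc$bT * eta$etaT[-length(m)] +
         sc$bG * eta$etaG[-length(m)] + sc$c)
    # costate equation: lambda' = -(q m + a_s lambda), central differences
    inner <- 2:(length(m) - 1)
    dlam <- (lam[inner + 1] - lam[inner - 1]) / (2 * dt)
    resCo <- dlam + m[inner] + sc$aS * lam[inner]
    list(state = max(abs(resState)), costate = max(abs(resCo)))
  }
  r1 <- res_at(1000)
  r2 <- res_at(2000)
  expect_lt(r1$state, 1e-12)  # Euler update is exact by construction
  expect_lt(r2$state, 1e-12)
  expect_lt(r2$costate, 5e-3)
  expect_equal(r1$costate / r2$costate, 2, tolerance = 0.25)  # O(dt) residual
})
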