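#' Uniform time grid
#'
#' @param t0,tEnd start and end times in days.
#' @param nSteps number of uniform explicit-Euler steps.
#' @return a [TimeGrid-class].
#' @export
timeGrid <- function(t0 = 0, tEnd, nSteps) {
  new("TimeGrid", t0 = t0, tEnd = tEnd, nSteps = as.integer(nSteps))
}

gridStep <- function(grid) (grid@tEnd - grid@t0) / grid@nSteps

#' Forward Euler integration of the semi-discrete system
#'
#' Explicit forward Euler with uniform step for
#' \eqn{\dot{\hat m} = A\hat m + B_T \eta_T + B_G \eta_G + C_b} with constant
#' scalar doses. With \eqn{\eta_T = \eta_G = 0} this is the uncontrolled
#' dynamical system. A non-finite state aborts with the offending step index
#' (the symptom of the anti-dissipative stiffness sign on non-uniform data,
#' or of too coarse a step).
#'
#' @param sys a [SemiDiscreteSystem-class].
#' @param ic initial state: either a scalar (spatially uniform density) or a
#'   full nodal vector of length \code{sys@n}.
#' @param grid a [TimeGrid-class].
#' @param etaT,etaG constant dimensionless dose levels.
#' @param keepStates store the full state history (memory proportional to
#'   \code{n * nSteps}); default \code{FALSE}.
#' @param point evaluation point for the center series (default: the center
#'   of the damaged region).
#' @return a [Trajectory-class].
#' @examples
#' p <- modelParams()
#' sys <- buildSystem(p, N = 4)
#' tr <- integrateEuler(sys, p@m0, timeGrid(0, 400, 2000))
#' tail(centerSeries(tr), 1)  # approaches c/d_m ~ 0.035177
#' @export
integrateEuler <- function(sys, ic, grid, etaT = 0, etaG = 0,
                           keepStates = FALSE, point = NULL) {
  n <- sys@n
  m <- if (length(ic) == 1L) rep(ic, n) else ic
  if (length(m) != n) stop("initial state has wrong length")
  if (!all(is.finite(m))) stop("non-finite initial state")
  K <- grid@nSteps
  dt <- gridStep(grid)
  wpt <- systemPointWeights(sys, point)
  forcing <- sys@BT * etaT + sys@BG * etaG + sys@Cb
  center <- mMin <- mMax <- numeric(K + 1L)
  states <- if (keepStates) matrix(NA_real_, n, K + 1L) else matrix(numeric(0), 0, 0)
  defect <- 0
  for (k in 0:K) {
    center[k + 1L] <- sum(wpt * m)
    mMin[k + 1L] <- min(m)
    mMax[k + 1L] <- max(m)
    defect <- max(defect, mMax[k + 1L] - mMin[k + 1L])
    if (keepStates) states[, k + 1L] <- m
    if (k == K) break
    m <- m + dt * (drop(sys@A %*% m) + forcing)
    if (!all(is.finite(m)))
      stop("non-finite state at step ", k + 1L, " (unstable integration)")
  }
  new("Trajectory",
    times = timePoints(grid),
    center = center, mMin = mMin, mMax = mMax,
    etaT = rep(etaT, K + 1L), etaG = rep(etaG, K + 1L),
    finalState = m,
    uniformityDefect = defect,
    states = states
  )
}

#' Closed-form solution of the spatially uniform model
#'
#' Exact solution of the uniform scalar reduction under constant doses:
#' \eqn{m(t) = m_\infty + (m_0 - m_\infty) e^{-d_m t}} with
#' \eqn{m_\infty = (c + b_T\eta_T + b_G\eta_G)/d_m}. Serves as the analytic
#' oracle for the Euler integrator on uniform initial data.
#'
#' @param p a [ModelParams-class].
#' @param t times in days (vectorized).
#' @param etaT,etaG constant dose levels.
#' @return myofibroblast density, g/cm^3.
#' @examples
#' closedFormUniform(modelParams(), 0)      # 8.5e-3
#' closedFormUniform(modelParams(), 1e5)    # ~0.035177 = c/d_m
#' @export
closedFormUniform <- function(p, t, etaT = 0, etaG = 0) {
  b <- controlInputScalars(p)
  cc <- activationConstant(p)
  mInf <- (cc + b[["bT"]] * etaT + b[["bG"]] * etaG) / p@dm
  mInf + (p@m0 - mInf) * exp(-p@dm * t)
}

#' Dose-response study over constant dose pairs
#'
#' Integrates the dosed system for a list of constant dose pairs (default:
#' the four reference pairs (0,0), (0.1,0.1), (0.3,0.3), (0.5,0.5)). With
#' equal doses the steady level is \eqn{(1-\eta)c/d_m}: strictly decreasing
#' in the dose, reaching zero only at full blockade.
#'
#' @param p a [ModelParams-class].
#' @param N spectral order (default 32).
#' @param doses a list of length-2 numeric dose pairs in \eqn{[0, 1]};
#'   doses outside \eqn{[0, 1]} are allowed but flagged with a warning.
#' @param nSteps Euler steps over the simulation horizon.
#' @param dims spatial dimensions.
#' @param ... further arguments to [buildSystem()].
#' @return named list of [Trajectory-class] objects, one per dose pair.
#' @export
doseResponseStudy <- function(p, N = 32,
                              doses = list(c(0, 0), c(0.1, 0.1), c(0.3, 0.3), c(0.5, 0.5)),
                              nSteps = 10000, dims = 2L, ...) {
  flat <- unlist(doses)
  if (any(flat < 0 | flat > 1))
    warning("dose outside [0, 1]; proceeding (flagged)")
  sys <- buildSystem(p, N = N, dims = dims, ...)
  grid <- timeGrid(0, p@tEndSim, nSteps)
  out <- lapply(doses, function(d) {
    integrateEuler(sys, p@m0, grid, etaT = d[1L], etaG = d[2L])
  })
  names(out) <- vapply(doses, function(d) sprintf("etaT=%g,etaG=%g", d[1L], d[2L]), "")
  out
}
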