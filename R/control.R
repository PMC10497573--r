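#' Closed-loop forward solve of the optimal regulator
#'
#' Integrates the closed-loop affine system forward by explicit Euler on the
#' same grid used for the backward Riccati sweep, synthesizing the controls
#' from the stored feedback path at each step, recording the costate at the
#' evaluation point, and accumulating the quadratic objective by trapezoidal
#' quadrature. Setting every stored \eqn{p, g} to zero recovers the
#' uncontrolled forward solve.
#'
#' @param sys a [SemiDiscreteSystem-class].
#' @param path a [RiccatiPath-class] solved on \code{grid}.
#' @param ic initial state (scalar uniform density or full nodal vector).
#' @param grid the [TimeGrid-class] shared with the backward sweep.
#' @param clamp clamp the applied controls to \eqn{[0, 1]} (pharmacological
#'   post-processing; default off — the Riccati sweep itself is never
#'   clamped).
#' @param point evaluation point (default: center of the damaged region).
#' @return a [ControlSolution-class] (durations not yet filled in;
#'   see [solveRegulator()]).
#' @export
closedLoopSolve <- function(sys, path, ic, grid, clamp = FALSE, point = NULL) {
  n <- sys@n
  K <- grid@nSteps
  if (length(path@times) != K + 1L) stop("Riccati path and grid are incompatible")
  dt <- gridStep(grid)
  w <- path@weights
  sc <- sys@scalar
  m <- if (length(ic) == 1L) rep(ic, n) else ic
  if (length(m) != n) stop("initial state has wrong length")
  wpt <- systemPointWeights(sys, point)
  scalarMode <- path@mode == "scalar"
  bt_rT <- sc$bT / w@rT
  bg_rG <- sc$bG / w@rG
  center <- etaT <- etaG <- lamC <- numeric(K + 1L)
  mMin <- mMax <- numeric(K + 1L)
  defect <- 0
  running <- numeric(K + 1L)  # objective integrand samples
  for (k in 0:K) {
    i <- k + 1L
    mC <- sum(wpt * m)
    center[i] <- mC
    mMin[i] <- min(m)
    mMax[i] <- max(m)
    defect <- max(defect, mMax[i] - mMin[i])
    if (scalarMode) {
      lam <- path@p[i] * mC + sys@c * path@g[i]
      eT <- -bt_rT * lam
      eG <- -bg_rG * lam
      lamC[i] <- lam
      stateCost <- w@qM * mC^2
    } else {
      lam <- drop(path@Pmat[, , i] %*% m) + path@svec[, i]
      eT <- -sum(sys@BT * lam) / w@rT
      eG <- -sum(sys@BG * lam) / w@rG
      lamC[i] <- sum(wpt * lam)
      stateCost <- w@qM * mean(m^2)
    }
    if (clamp) {
      eT <- min(max(eT, 0), 1)
      eG <- min(max(eG, 0), 1)
    }
    etaT[i] <- eT
    etaG[i] <- eG
    running[i] <- 0.5 * (stateCost + w@rT * eT^2 + w@rG * eG^2)
    if (k == K) break
    m <- m + dt * (drop(sys@A %*% m) + sys@BT * eT + sys@BG * eG + sys@Cb)
    if (!all(is.finite(m)))
      stop("non-finite state at step ", i, " (unstable integration)")
  }
  J <- trapezoid(timePoints(grid), running)
  traj <- new("Trajectory",
    times = timePoints(grid),
    center = center, mMin = mMin, mMax = mMax,
    etaT = etaT, etaG = etaG,
    finalState = m,
    uniformityDefect = defect,
    states = matrix(numeric(0), 0, 0)
  )
  new("ControlSolution",
    trajectory = traj,
    lambdaCenter = lamC,
    p = path@p, g = path@g,
    objective = J,
    durations = list(),
    thresholds = list(),
    clamp = clamp,
    mode = path@mode
  )
}

trapezoid <- function(x, y) {
  K <- length(x)
  sum((y[-1L] + y[-K]) * diff(x)) / 2
}

#' First time a series settles below a threshold
#'
#' Returns the first grid time at which the series falls below the threshold
#' and remains below it for the rest of the horizon; \code{0} (the first
#' grid time) if the series is below throughout, and \code{Inf}
#' ("never") if the series is still at or above the threshold at the end.
#'
#' @param times time grid (ascending, uniform).
#' @param series numeric series on \code{times}.
#' @param threshold positive threshold.
#' @return a time in days, or \code{Inf}.
#' @examples
#' tt <- seq(0, 400, by = 0.1)
#' durationAboveThreshold(tt, 8.5e-3 * exp(-1.66e-2 * tt), 8.5e-5)  # ~277.4
#' @export
durationAboveThreshold <- function(times, series, threshold) {
  if (!length(series)) stop("empty series")
  stopifnot(threshold > 0, length(times) == length(series))
  above <- series >= threshold
  if (!any(above)) return(times[1L])
  last <- max(which(above))
  if (last == length(series)) return(Inf)
  times[last + 1L]
}

#' Solve the optimal regulator problem end to end
#'
#' Builds the semi-discrete system, runs the backward Riccati sweep over
#' \eqn{[0, t_f]}, solves the closed loop forward, and summarizes the
#' first-crossing durations of the two control schedules (threshold
#' \code{controlThreshold}, default 1e-3 dimensionless) and of the
#' center-point state (threshold \code{stateThresholdFrac * m0}, default 1
#' percent of the initial density).
#'
#' @param p a [ModelParams-class].
#' @param N spectral order (default 32).
#' @param dims spatial dimensions (default 2).
#' @param nSteps Euler steps over the control horizon (default 10000).
#' @param w a [CostWeights-class] (default unit weights).
#' @param mode Riccati mode, \code{"scalar"} (default) or \code{"matrix"}.
#' @param convention,diffusionSign assembly flags (see [buildSystem()]).
#' @param clamp clamp applied controls to \eqn{[0, 1]} (default off).
#' @param controlThreshold small-dose threshold for the duration summaries.
#' @param stateThresholdFrac state threshold as a fraction of \code{m0}.
#' @return a [ControlSolution-class] with durations filled in.
#' @examples
#' sol <- solveRegulator(modelParams(), N = 4, nSteps = 2000)
#' durationSummary(sol)
#' @export
solveRegulator <- function(p, N = 32, dims = 2L, nSteps = 10000,
                           w = costWeights(),
                           mode = c("scalar", "matrix"),
                           convention = c("laplacian_consistent", "paper_literal"),
                           diffusionSign = c("stable_minus_rS", "paper_plus_rS"),
                           clamp = FALSE,
                           controlThreshold = 1e-3,
                           stateThresholdFrac = 0.01) {
  mode <- match.arg(mode)
  sys <- buildSystem(p, N = N, dims = dims,
                     convention = match.arg(convention),
                     diffusionSign = match.arg(diffusionSign))
  grid <- timeGrid(0, p@tf, nSteps)
  path <- riccatiBackward(sys, grid, w, mode = mode)
  sol <- closedLoopSolve(sys, path, p@m0, grid, clamp = clamp)
  tt <- timePoints(grid)
  thr <- list(control = controlThreshold, state = stateThresholdFrac * p@m0)
  sol@thresholds <- thr
  sol@durations <- list(
    etaT = durationAboveThreshold(tt, sol@trajectory@etaT, thr$control),
    etaG = durationAboveThreshold(tt, sol@trajectory@etaG, thr$control),
    state = durationAboveThreshold(tt, sol@trajectory@center, thr$state)
  )
  validObject(sol)
  sol
}
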