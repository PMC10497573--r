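#' Cost weights
#'
#' @param qM state weight (default 1).
#' @param rT,rG control weights (default 1).
#' @return a [CostWeights-class].
#' @export
costWeights <- function(qM = 1, rT = 1, rG = 1) {
  new("CostWeights", qM = qM, rT = rT, rG = rG)
}

#' Backward sweep of the extended Riccati equations
#'
#' Solves the affine-LQR Riccati equations backward from the free-endpoint
#' terminal conditions \eqn{p(t_f) = g(t_f) = 0} by explicit Euler on the
#' given grid.
#'
#' \strong{Scalar mode} (default) uses the exact spatially uniform reduction
#' of the system. With \eqn{\tilde b^2 = b_T^2/r_T + b_G^2/r_G}:
#' \deqn{\dot p = -(2 a_s p - \tilde b^2 p^2 + q_m), \qquad
#'       \dot g = -((a_s - \tilde b^2 p) g + p),}
#' and the costate model is \eqn{\lambda(t) = p(t) m(t) + c\,g(t)}.
#'
#' \strong{Matrix mode} solves the full standard affine form
#' \deqn{\dot P = -(P A + A^T P - P (B_T B_T^T/r_T + B_G B_G^T/r_G) P + Q),
#'       \qquad \dot s = -((A - (\cdot) P)^T s + P C_b),}
#' with the state weight \eqn{Q = (q_m/n) I} — the mean-square nodal
#' penalty, which represents the scalar objective \eqn{\frac{q_m}{2}\int
#' m(t)^2 dt} on spatially uniform fields. With this choice the projections
#' \eqn{1^T P 1} and \eqn{1^T s} obey exactly the scalar equations above, so
#' the two modes agree on uniform problems; matrix mode serves as the
#' independent verification route.
#'
#' @param sys a [SemiDiscreteSystem-class].
#' @param grid a [TimeGrid-class] covering \eqn{[t_0, t_f]}.
#' @param w a [CostWeights-class].
#' @param mode \code{"scalar"} or \code{"matrix"}.
#' @return a [RiccatiPath-class].
#' @examples
#' p <- modelParams()
#' sys <- buildSystem(p, N = 2)
#' path <- riccatiBackward(sys, timeGrid(0, p@tf, 2000))
#' head(path@p, 1)  # ~ (1 - exp(-2 d_m t_f)) / (2 d_m) ~ 30.12
#' @export
riccatiBackward <- function(sys, grid, w = costWeights(),
                            mode = c("scalar", "matrix")) {
  mode <- match.arg(mode)
  K <- grid@nSteps
  dt <- gridStep(grid)
  sc <- sys@scalar
  aS <- sc$aS
  bt2 <- sc$bT^2 / w@rT + sc$bG^2 / w@rG
  if (mode == "scalar") {
    p <- g <- numeric(K + 1L)
    for (k in K:1) {
      pk <- p[k + 1L]
      gk <- g[k + 1L]
      p[k] <- pk + dt * (2 * aS * pk - bt2 * pk^2 + w@qM)
      g[k] <- gk + dt * ((aS - bt2 * pk) * gk + pk)
      if (!is.finite(p[k]) || !is.finite(g[k]))
        stop("non-finite Riccati sweep at time index ", k,
             " (wrong-sign dynamics or too coarse a grid)")
    }
    return(new("RiccatiPath",
      mode = "scalar", times = timePoints(grid),
      p = p, g = g,
      Pmat = array(numeric(0), c(0, 0, 0)), svec = matrix(numeric(0), 0, 0),
      weights = w
    ))
  }
  n <- sys@n
  if (as.double(n)^2 * (K + 1) > 2e8)
    stop("matrix-mode path storage too large (n^2 * steps); use scalar mode or fewer steps")
  A <- sys@A
  Qn <- w@qM / n
  Pmat <- array(0, c(n, n, K + 1L))
  svec <- matrix(0, n, K + 1L)
  P <- matrix(0, n, n)
  s <- numeric(n)
  for (k in K:1) {
    u <- rowSums(P) * sqrt(bt2)  # P B factor: B B^T = bt2 * ones
    PA <- P %*% A
    dP <- PA + t(PA) - tcrossprod(u) + diag(Qn, n)
    ds <- drop(crossprod(A, s)) - bt2 * rowSums(P) * sum(s) + drop(P %*% sys@Cb)
    P <- P + dt * dP
    P <- (P + t(P)) / 2
    s <- s + dt * ds
    if (!all(is.finite(P)) || !all(is.finite(s)))
      stop("non-finite Riccati sweep at time index ", k,
           " (wrong-sign dynamics or too coarse a grid)")
    Pmat[, , k] <- P
    svec[, k] <- s
  }
  cc <- sys@c
  pProj <- apply(Pmat, 3L, sum)
  gProj <- if (cc > 0) colSums(svec) / cc else numeric(K + 1L)
  new("RiccatiPath",
    mode = "matrix", times = timePoints(grid),
    p = pProj, g = gProj,
    Pmat = Pmat, svec = svec,
    weights = w
  )
}

#' Synthesize the optimal controls and costate at a stored time
#'
#' Applies the linear feedback law to a state: the costate is
#' \eqn{\lambda = p\,m + c\,g} (scalar mode) or \eqn{\lambda = P m + s}
#' (matrix mode), and the stationarity conditions give
#' \eqn{\eta_T^* = -B_T^T\lambda / r_T}, \eqn{\eta_G^* = -B_G^T\lambda / r_G}.
#' The feedback gains and offsets are \eqn{K_T = -B_T^T p / r_T},
#' \eqn{\rho_T = -c B_T^T g / r_T} (and analogously for G).
#'
#' @param path a [RiccatiPath-class].
#' @param state the state: a scalar uniform density (scalar mode) or a full
#'   nodal vector.
#' @param sys the [SemiDiscreteSystem-class].
#' @param index time index into the stored path (1-based).
#' @return list with \code{etaT}, \code{etaG}, \code{lambda} (scalar-mode
#'   costate scalar, or full costate vector), and the gains \code{KT},
#'   \code{KG}, \code{rhoT}, \code{rhoG}.
#' @export
synthesizeControls <- function(path, state, sys, index = 1L) {
  w <- path@weights
  sc <- sys@scalar
  if (path@mode == "scalar") {
    mC <- if (length(state) > 1L) mean(state) else state
    lam <- path@p[index] * mC + sys@c * path@g[index]
    list(
      etaT = -sc$bT * lam / w@rT,
      etaG = -sc$bG * lam / w@rG,
      lambda = lam,
      KT = -sc$bT * path@p[index] / w@rT,
      KG = -sc$bG * path@p[index] / w@rG,
      rhoT = -sys@c * sc$bT * path@g[index] / w@rT,
      rhoG = -sys@c * sc$bG * path@g[index] / w@rG
    )
  } else {
    m <- if (length(state) == 1L) rep(state, sys@n) else state
    lam <- drop(path@Pmat[, , index] %*% m) + path@svec[, index]
    list(
      etaT = -sum(sys@BT * lam) / w@rT,
      etaG = -sum(sys@BG * lam) / w@rG,
      lambda = lam,
      KT = -drop(crossprod(sys@BT, path@Pmat[, , index])) / w@rT,
      KG = -drop(crossprod(sys@BG, path@Pmat[, , index])) / w@rG,
      rhoT = -sum(sys@BT * path@svec[, index]) / w@rT,
      rhoG = -sum(sys@BG * path@svec[, index]) / w@rG
    )
  }
}
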