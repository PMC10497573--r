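#' @import methods
NULL

#' Gauss-Legendre-Lobatto basis
#'
#' Nodes, quadrature weights and the nodal differentiation matrix of the
#' order-\code{N} Gauss-Legendre-Lobatto (GLL) scheme on the reference
#' interval \eqn{[-1, 1]}. The nodes are \eqn{\pm 1} together with the roots
#' of \eqn{L_N'}, the derivative of the degree-\eqn{N} Legendre polynomial.
#'
#' @slot order integer spectral order \eqn{N \ge 2}.
#' @slot nodes numeric vector of \eqn{N+1} strictly increasing nodes with
#'   endpoints exactly \eqn{-1} and \eqn{+1}.
#' @slot weights numeric vector of \eqn{N+1} positive quadrature weights
#'   summing to 2.
#' @slot diff \eqn{(N+1)\times(N+1)} differentiation matrix \eqn{d_{ij} =
#'   \phi_j'(\xi_i)}; each row sums to zero.
#'
#' @seealso [gllBasis()]
#' @export
setClass("GLLBasis",
  representation(
    order = "integer",
    nodes = "numeric",
    weights = "numeric",
    diff = "matrix"
  )
)

setValidity("GLLBasis", function(object) {
  N <- object@order
  msg <- character()
  if (length(N) != 1L || N < 2L) msg <- c(msg, "order must be a single integer >= 2")
  if (length(object@nodes) != N + 1L) msg <- c(msg, "nodes must have length order + 1")
  if (length(object@weights) != N + 1L) msg <- c(msg, "weights must have length order + 1")
  if (any(diff(object@nodes) <= 0)) msg <- c(msg, "nodes must be strictly increasing")
  if (object@nodes[1L] != -1 || object@nodes[N + 1L] != 1)
    msg <- c(msg, "endpoint nodes must be exactly -1 and +1")
  if (any(object@weights <= 0)) msg <- c(msg, "weights must be positive")
  if (abs(sum(object@weights) - 2) > 1e-12) msg <- c(msg, "weights must sum to 2")
  if (!all(dim(object@diff) == c(N + 1L, N + 1L)))
    msg <- c(msg, "diff must be (order+1) x (order+1)")
  if (max(abs(rowSums(object@diff))) > 1e-10)
    msg <- c(msg, "rows of diff must sum to 0")
  if (length(msg)) msg else TRUE
})

#' Affine map between the reference interval and a physical interval
#'
#' @slot xa,xb numeric physical interval ends, \code{xa < xb}.
#' @seealso [elementMap()], [mapToPhysical()], [mapToReference()]
#' @export
setClass("ElementMap", representation(xa = "numeric", xb = "numeric"))

setValidity("ElementMap", function(object) {
  if (length(object@xa) != 1L || length(object@xb) != 1L)
    return("xa and xb must be scalars")
  if (!(object@xb > object@xa)) return("xb must exceed xa (h > 0)")
  TRUE
})

#' One-dimensional Galerkin operators on a mapped element
#'
#' Mass, stiffness and load operators of the Lagrange/GLL basis on a physical
#' interval. The mass matrix is diagonal (nodes coincide with quadrature
#' points), the stiffness matrix is symmetric positive semi-definite with the
#' constant vector in its null space, and the load vector is the Galerkin
#' load of the constant-1 function, so \code{load == mass %*% 1} exactly.
#'
#' @slot mass diagonal \eqn{(N+1)\times(N+1)} mass matrix, entries
#'   \eqn{(h/2) w_i}.
#' @slot stiffness \eqn{(N+1)\times(N+1)} stiffness matrix
#'   \eqn{\int \phi_i' \phi_j'}.
#' @slot load numeric load vector, entries \eqn{(h/2) w_i}.
#' @slot map the [ElementMap-class] used.
#' @slot basis the [GLLBasis-class] used.
#' @seealso [assembleGalerkin1D()]
#' @export
setClass("GalerkinOperators1D",
  representation(
    mass = "matrix",
    stiffness = "matrix",
    load = "numeric",
    map = "ElementMap",
    basis = "GLLBasis"
  )
)

setValidity("GalerkinOperators1D", function(object) {
  n <- length(object@load)
  msg <- character()
  if (!all(dim(object@mass) == n) || !all(dim(object@stiffness) == n))
    msg <- c(msg, "operator dimensions disagree")
  if (max(abs(object@mass - diag(diag(object@mass), n))) > 0)
    msg <- c(msg, "mass matrix must be diagonal")
  if (any(diag(object@mass) <= 0)) msg <- c(msg, "mass diagonal must be positive")
  if (max(abs(object@stiffness - t(object@stiffness))) > 1e-10)
    msg <- c(msg, "stiffness must be symmetric")
  if (max(abs(object@stiffness %*% rep(1, n))) > 1e-8)
    msg <- c(msg, "stiffness must annihilate constants")
  if (length(msg)) msg else TRUE
})

#' Tensor-product Galerkin operators in one or two dimensions
#'
#' In two dimensions the operators are Kronecker products of the
#' one-dimensional factors, with the x index varying slowest in the state
#' vector. Two stiffness conventions are supported: \code{"laplacian_consistent"}
#' (default), the Galerkin matrix \eqn{S_x \otimes K_y + K_x \otimes S_y} of
#' the two-dimensional Laplacian, and \code{"paper_literal"},
#' \eqn{S_x \otimes S_y}. Both annihilate spatially constant vectors, so they
#' coincide on spatially uniform states.
#'
#' @slot massDiag numeric diagonal of the (diagonal) mass matrix.
#' @slot stiffness dense stiffness matrix.
#' @slot load numeric load vector (entrywise positive).
#' @slot dims integer, 1 or 2.
#' @slot convention \code{"laplacian_consistent"} or \code{"paper_literal"}.
#' @slot opsX,opsY the one-dimensional factors ([GalerkinOperators1D-class]).
#' @seealso [assembleGalerkin2D()]
#' @export
setClass("GalerkinOperators2D",
  representation(
    massDiag = "numeric",
    stiffness = "matrix",
    load = "numeric",
    dims = "integer",
    convention = "character",
    opsX = "GalerkinOperators1D",
    opsY = "GalerkinOperators1D"
  )
)

setValidity("GalerkinOperators2D", function(object) {
  msg <- character()
  n <- length(object@massDiag)
  if (!object@dims %in% c(1L, 2L)) msg <- c(msg, "dims must be 1 or 2")
  if (!object@convention %in% c("laplacian_consistent", "paper_literal"))
    msg <- c(msg, "unknown stiffness convention")
  if (any(object@massDiag <= 0)) msg <- c(msg, "mass diagonal must be positive")
  if (any(object@load <= 0)) msg <- c(msg, "load vector must be entrywise positive")
  if (!all(dim(object@stiffness) == n)) msg <- c(msg, "operator dimensions disagree")
  if (max(abs(object@stiffness %*% rep(1, n))) > 1e-8)
    msg <- c(msg, "stiffness must annihilate constants")
  if (length(msg)) msg else TRUE
})

#' Biological and numerical parameters of the fibrosis model
#'
#' All constants of the homogenized myofibroblast diffusion model, in the
#' unit system cm / day / g cm^-3. The defaults (see [modelParams()]) are the
#' published estimates for injured alveolar tissue.
#'
#' @slot Dm myofibroblast diffusion coefficient, cm^2/day.
#' @slot dm myofibroblast death (apoptosis) rate, 1/day.
#' @slot lambdaT,lambdaG activation rates of myofibroblasts due to TGF-beta
#'   and PDGF, 1/day.
#' @slot KT,KG saturation constants of the TGF-beta and PDGF activation
#'   kinetics, g/cm^3.
#' @slot f fibroblast density in the damaged region (constant), g/cm^3.
#' @slot m0 initial myofibroblast density, g/cm^3.
#' @slot Tgf0,G0 (constant) TGF-beta and PDGF concentrations, g/cm^3.
#' @slot a,gamma dimensionless homogenization coefficients; the effective
#'   diffusivity is \eqn{r = a D_m / \gamma}.
#' @slot domain numeric length-2 vector, the damaged interval per dimension
#'   (cm).
#' @slot tf control horizon, days.
#' @slot tEndSim forward-simulation horizon, days.
#' @seealso [modelParams()], [homogenizedDiffusivity()], [activationConstant()]
#' @export
setClass("ModelParams",
  representation(
    Dm = "numeric", dm = "numeric",
    lambdaT = "numeric", lambdaG = "numeric",
    KT = "numeric", KG = "numeric",
    f = "numeric", m0 = "numeric",
    Tgf0 = "numeric", G0 = "numeric",
    a = "numeric", gamma = "numeric",
    domain = "numeric",
    tf = "numeric", tEndSim = "numeric"
  )
)

setValidity("ModelParams", function(object) {
  msg <- character()
  nonneg <- c(
    Dm = object@Dm, dm = object@dm, lambdaT = object@lambdaT,
    lambdaG = object@lambdaG, f = object@f, m0 = object@m0,
    Tgf0 = object@Tgf0, G0 = object@G0, a = object@a
  )
  if (any(nonneg < 0))
    msg <- c(msg, paste("negative parameter:", paste(names(nonneg)[nonneg < 0], collapse = ", ")))
  if (object@KT <= 0 || object@KG <= 0) msg <- c(msg, "saturation constants must be positive")
  if (!(object@gamma > 0 && object@gamma <= 1)) msg <- c(msg, "gamma must lie in (0, 1]")
  if (object@tf <= 0) msg <- c(msg, "tf must be positive")
  if (length(object@domain) != 2L || object@domain[1L] >= object@domain[2L])
    msg <- c(msg, "domain must be an increasing length-2 interval")
  if (length(msg)) msg else TRUE
})

#' Semi-discrete state-space system
#'
#' The linear ODE system \eqn{\dot{\hat m} = A \hat m + B_T \eta_T + B_G
#' \eta_G + C_b} obtained by Galerkin projection of the dosed homogenized
#' diffusion model. Because the drug concentrations are held constant, the
#' control input vectors are spatially uniform: every entry of \code{BT}
#' equals the scalar \code{bT} (and likewise \code{BG}, \code{Cb}), and the
#' dynamics restricted to spatially uniform states reduce exactly to the
#' scalar ODE \eqn{\dot m = a_s m + b_T \eta_T + b_G \eta_G + c}.
#'
#' @slot n state dimension \eqn{(N+1)^{dims}}.
#' @slot A dense \eqn{n \times n} system matrix.
#' @slot BT,BG,Cb numeric input/source vectors of length \code{n}.
#' @slot scalar named list with the exact scalar reduction
#'   (\code{aS}, \code{bT}, \code{bG}, \code{c}).
#' @slot r homogenized diffusivity \eqn{a D_m/\gamma}, cm^2/day.
#' @slot c activation constant, g cm^-3 day^-1.
#' @slot dims,order spatial dimensions and spectral order.
#' @slot convention,diffusionSign assembly flags (see [assembleSystem()]).
#' @slot basis the [GLLBasis-class] used (for interpolation).
#' @slot mapX,mapY physical element maps per dimension.
#' @seealso [assembleSystem()], [integrateEuler()]
#' @export
setClass("SemiDiscreteSystem",
  representation(
    n = "integer",
    A = "matrix",
    BT = "numeric", BG = "numeric", Cb = "numeric",
    scalar = "list",
    r = "numeric", c = "numeric",
    dims = "integer", order = "integer",
    convention = "character", diffusionSign = "character",
    basis = "GLLBasis", mapX = "ElementMap", mapY = "ElementMap"
  )
)

setValidity("SemiDiscreteSystem", function(object) {
  msg <- character()
  n <- object@n
  if (!all(dim(object@A) == n)) msg <- c(msg, "A must be n x n")
  if (length(object@BT) != n || length(object@BG) != n || length(object@Cb) != n)
    msg <- c(msg, "input vectors must have length n")
  need <- c("aS", "bT", "bG", "c")
  if (!all(need %in% names(object@scalar)))
    msg <- c(msg, "scalar reduction must contain aS, bT, bG, c")
  if (length(msg)) msg else TRUE
})

#' Uniform time grid
#'
#' @slot t0,tEnd start and end times, days.
#' @slot nSteps positive integer number of uniform explicit-Euler steps.
#' @seealso [timeGrid()]
#' @export
setClass("TimeGrid",
  representation(t0 = "numeric", tEnd = "numeric", nSteps = "integer")
)

setValidity("TimeGrid", function(object) {
  if (!(object@tEnd > object@t0)) return("tEnd must exceed t0")
  if (object@nSteps < 1L) return("nSteps must be >= 1")
  TRUE
})

#' Cost weights of the regulator objective
#'
#' Weights of the quadratic objective \eqn{\frac12 \int q_m m^2 +
#' \frac12 \int (r_T \eta_T^2 + r_G \eta_G^2)}. The defaults are 1, 1, 1.
#'
#' @slot qM state weight (nonnegative).
#' @slot rT,rG control weights (strictly positive, required by the
#'   stationarity solve).
#' @seealso [costWeights()]
#' @export
setClass("CostWeights", representation(qM = "numeric", rT = "numeric", rG = "numeric"))

setValidity("CostWeights", function(object) {
  if (object@qM < 0) return("qM must be nonnegative")
  if (object@rT <= 0 || object@rG <= 0) return("control weights must be positive")
  TRUE
})

#' Backward Riccati path
#'
#' Time-indexed solution of the extended (affine) Riccati equations, swept
#' backward from the free-endpoint terminal conditions
#' \eqn{p(t_f) = 0, g(t_f) = 0} (matrix mode: \eqn{P(t_f) = 0, s(t_f) = 0}).
#' In scalar mode the costate model is \eqn{\lambda = p(t) m + c\, g(t)};
#' matrix mode stores the full \eqn{P(t)} and offset \eqn{s(t) = c\,g(t)}
#' path of the standard affine-LQR sweep.
#'
#' @slot mode \code{"scalar"} or \code{"matrix"}.
#' @slot times time grid (ascending), days.
#' @slot p,g numeric series (scalar mode; in matrix mode \code{p} holds the
#'   projected kernel \eqn{1^T P 1} for inspection and \code{g} the projected
#'   offset).
#' @slot Pmat \eqn{n \times n \times (K+1)} array (matrix mode only).
#' @slot svec \eqn{n \times (K+1)} matrix (matrix mode only).
#' @slot weights the [CostWeights-class] used.
#' @seealso [riccatiBackward()]
#' @export
setClass("RiccatiPath",
  representation(
    mode = "character",
    times = "numeric",
    p = "numeric", g = "numeric",
    Pmat = "array", svec = "matrix",
    weights = "CostWeights"
  )
)

setValidity("RiccatiPath", function(object) {
  msg <- character()
  if (!object@mode %in% c("scalar", "matrix")) msg <- c(msg, "mode must be scalar or matrix")
  K <- length(object@times)
  if (length(object@p) != K || length(object@g) != K)
    msg <- c(msg, "p and g must be stored at every time")
  if (abs(object@p[K]) > 0 || abs(object@g[K]) > 0)
    msg <- c(msg, "terminal conditions p(tf) = g(tf) = 0 violated")
  if (any(object@p < -1e-12)) msg <- c(msg, "p(t) must be nonnegative for t <= tf")
  if (length(msg)) msg else TRUE
})

#' Simulated trajectory of the semi-discrete system
#'
#' @slot times time grid, days.
#' @slot center myofibroblast density interpolated at the evaluation point
#'   (the center of the damaged region by default), g/cm^3.
#' @slot mMin,mMax nodal minimum and maximum at each time.
#' @slot etaT,etaG applied control levels at each time.
#' @slot finalState full nodal state at the final time.
#' @slot uniformityDefect max over time of (max - min) over nodal values.
#' @slot states full state history (column per time) if requested, else a
#'   0 x 0 matrix.
#' @seealso [integrateEuler()]
#' @export
setClass("Trajectory",
  representation(
    times = "numeric",
    center = "numeric",
    mMin = "numeric", mMax = "numeric",
    etaT = "numeric", etaG = "numeric",
    finalState = "numeric",
    uniformityDefect = "numeric",
    states = "matrix"
  )
)

setValidity("Trajectory", function(object) {
  msg <- character()
  K <- length(object@times)
  if (length(object@center) != K) msg <- c(msg, "center series length must match times")
  if (!all(is.finite(object@center))) msg <- c(msg, "non-finite center values")
  if (length(msg)) msg else TRUE
})

#' Optimal regulator solution
#'
#' Closed-loop solve of the regulator problem: optimal state trajectory, the
#' two control schedules, the costate at the evaluation point, the feedback
#' kernel series, the objective value, and first-crossing duration summaries.
#'
#' @slot trajectory the closed-loop [Trajectory-class] (with control series).
#' @slot lambdaCenter costate at the evaluation point over time.
#' @slot p,g Riccati kernel and offset series on the same grid.
#' @slot objective value of the quadratic objective (trapezoidal quadrature).
#' @slot durations named list: first-crossing days for \code{etaT},
#'   \code{etaG} and \code{state} (Inf if the series never settles below its
#'   threshold).
#' @slot thresholds named list of the thresholds used.
#' @slot clamp logical; whether controls were clamped to [0, 1] (post-processing
#'   only).
#' @slot mode Riccati mode used.
#' @seealso [closedLoopSolve()], [solveRegulator()]
#' @export
setClass("ControlSolution",
  representation(
    trajectory = "Trajectory",
    lambdaCenter = "numeric",
    p = "numeric", g = "numeric",
    objective = "numeric",
    durations = "list",
    thresholds = "list",
    clamp = "logical",
    mode = "character"
  )
)

setValidity("ControlSolution", function(object) {
  if (!is.finite(object@objective) || object@objective < 0)
    return("objective must be finite and nonnegative")
  TRUE
})
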