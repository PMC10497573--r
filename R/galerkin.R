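#' Affine element map
#'
#' Affine bijection between the reference interval \eqn{[-1, 1]} and a
#' physical interval \eqn{[x_a, x_b]}:
#' \eqn{x(\xi) = (x_b - x_a)\xi/2 + (x_b + x_a)/2}.
#'
#' @param xa,xb physical interval ends, \code{xa < xb}.
#' @return an [ElementMap-class].
#' @examples
#' em <- elementMap(0.3, 0.6)
#' mapToPhysical(em, 0)  # 0.45, the center of the damaged region
#' @export
elementMap <- function(xa, xb) new("ElementMap", xa = xa, xb = xb)

#' @rdname elementMap
#' @param em an [ElementMap-class].
#' @param xi reference coordinates in \eqn{[-1, 1]}.
#' @export
mapToPhysical <- function(em, xi) {
  if (any(abs(xi) > 1 + 1e-12)) stop("reference coordinate outside [-1, 1]")
  (em@xb - em@xa) * xi / 2 + (em@xb + em@xa) / 2
}

#' @rdname elementMap
#' @param x physical coordinates in \eqn{[x_a, x_b]}.
#' @export
mapToReference <- function(em, x) {
  if (any(x < em@xa - 1e-12) || any(x > em@xb + 1e-12))
    stop("physical coordinate outside the element")
  (2 * x - (em@xb + em@xa)) / (em@xb - em@xa)
}

elementWidth <- function(em) em@xb - em@xa

#' Assemble one-dimensional Galerkin operators
#'
#' Mass, stiffness and load operators of the GLL Lagrange basis on a mapped
#' element of width \eqn{h}: \eqn{K_{ij} = (h/2)\,\delta_{ij} w_i},
#' \eqn{S_{ij} = (2/h) \sum_k d_{ki} d_{kj} w_k = \int \phi_i'\phi_j'}
#' (exact, since the integrand has degree \eqn{2N-2 \le 2N-1}),
#' and \eqn{C_i = (h/2) w_i}, the load of the constant-1 function, so that
#' \eqn{C = K\,1} exactly.
#'
#' @param basis a [GLLBasis-class].
#' @param em an [ElementMap-class].
#' @return a [GalerkinOperators1D-class].
#' @export
assembleGalerkin1D <- function(basis, em) {
  h <- elementWidth(em)
  w <- basis@weights
  d <- basis@diff
  S <- (2 / h) * crossprod(d, d * w)  # t(d) %*% diag(w) %*% d
  S <- (S + t(S)) / 2
  new("GalerkinOperators1D",
    mass = diag((h / 2) * w),
    stiffness = S,
    load = (h / 2) * w,
    map = em,
    basis = basis
  )
}

#' Assemble tensor-product Galerkin operators
#'
#' Builds the operators of the two-dimensional (or, trivially, the
#' one-dimensional) discretization. The mass matrix and load vector are
#' always the Kronecker products \eqn{K = K_x \otimes K_y},
#' \eqn{C = C_x \otimes C_y}. Two stiffness conventions are available:
#' \describe{
#'   \item{\code{"laplacian_consistent"} (default)}{\eqn{S = S_x \otimes K_y +
#'     K_x \otimes S_y}, the Galerkin matrix of the two-dimensional
#'     Laplacian.}
#'   \item{\code{"paper_literal"}}{\eqn{S = S_x \otimes S_y}, the plain
#'     tensor product, selectable for strict replication of the published
#'     discretization.}
#' }
#' Both annihilate spatially constant vectors (because \eqn{S_x 1 = 0}), so
#' on spatially uniform states — the regime of all reference results — the
#' two conventions produce identical dynamics.
#'
#' The state vector ordering has the x index varying slowest:
#' entry \eqn{i_x (N+1) + i_y + 1} holds the value at node
#' \eqn{(x_{i_x}, y_{i_y})}.
#'
#' @param opsX,opsY one-dimensional operators ([GalerkinOperators1D-class])
#'   of equal order.
#' @param convention stiffness convention flag (see above).
#' @return a [GalerkinOperators2D-class].
#' @export
assembleGalerkin2D <- function(opsX, opsY = opsX,
                               convention = c("laplacian_consistent", "paper_literal")) {
  convention <- match.arg(convention)
  if (length(opsX@load) != length(opsY@load))
    stop("mismatched spectral orders between dimensions")
  Kx <- diag(opsX@mass); Ky <- diag(opsY@mass)
  S <- switch(convention,
    paper_literal = kronecker(opsX@stiffness, opsY@stiffness),
    laplacian_consistent =
      kronecker(opsX@stiffness, diag(Ky)) + kronecker(diag(Kx), opsY@stiffness)
  )
  new("GalerkinOperators2D",
    massDiag = as.numeric(kronecker(Kx, Ky)),
    stiffness = S,
    load = as.numeric(kronecker(opsX@load, opsY@load)),
    dims = 2L,
    convention = convention,
    opsX = opsX, opsY = opsY
  )
}

# Wrap 1D operators in the common container used by assembleSystem().
asOperators1D <- function(ops) {
  new("GalerkinOperators2D",
    massDiag = diag(ops@mass),
    stiffness = ops@stiffness,
    load = ops@load,
    dims = 1L,
    convention = "laplacian_consistent",
    opsX = ops, opsY = ops
  )
}

# Row vector of interpolation weights for evaluating the discrete solution at
# a physical point: phi_i(xi(x)) (1D) or the tensor product (2D, x slowest).
interpolationWeights <- function(basis, mapX, mapY = NULL, point) {
  xiX <- mapToReference(mapX, point[1L])
  wx <- vapply(0:basis@order, function(j) lagrangeEval(basis, j, xiX), numeric(1))
  if (is.null(mapY)) return(wx)
  xiY <- mapToReference(mapY, point[2L])
  wy <- vapply(0:basis@order, function(j) lagrangeEval(basis, j, xiY), numeric(1))
  as.numeric(kronecker(wx, wy))
}
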