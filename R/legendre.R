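#' Evaluate a Legendre polynomial by the three-term recurrence
#'
#' Computes \eqn{L_k(\xi)} with the standard normalization \eqn{L_k(1) = 1},
#' using the Bonnet recurrence
#' \eqn{(k+1) L_{k+1} = (2k+1)\xi L_k - k L_{k-1}}.
#'
#' @param k nonnegative integer degree.
#' @param xi evaluation points in \eqn{[-1, 1]} (vectorized).
#' @return numeric vector \eqn{L_k(\xi)}.
#' @examples
#' legendreEval(0, 0.7)  # 1
#' legendreEval(1, 0.7)  # 0.7
#' legendreEval(5, 1.0)  # 1
#' @export
legendreEval <- function(k, xi) {
  stopifnot(length(k) == 1L, k >= 0, k == as.integer(k))
  if (any(!is.finite(xi)) || any(abs(xi) > 1 + 1e-12))
    stop("reference coordinate outside [-1, 1]")
  xi <- pmin(pmax(xi, -1), 1)
  if (k == 0L) return(rep(1, length(xi)))
  if (k == 1L) return(xi)
  Lm1 <- rep(1, length(xi))
  L <- xi
  for (j in 1:(k - 1L)) {
    Lp1 <- ((2 * j + 1) * xi * L - j * Lm1) / (j + 1)
    Lm1 <- L
    L <- Lp1
  }
  L
}

# First derivative L_k'(xi); endpoints handled by the closed form
# L_k'(+-1) = (+-1)^(k-1) k (k+1) / 2.
legendreDeriv <- function(k, xi) {
  stopifnot(length(k) == 1L, k >= 0)
  if (k == 0L) return(rep(0, length(xi)))
  out <- numeric(length(xi))
  edge <- abs(abs(xi) - 1) < 1e-14
  if (any(edge)) {
    s <- sign(xi[edge])
    out[edge] <- s^(k - 1) * k * (k + 1) / 2
  }
  if (any(!edge)) {
    x <- xi[!edge]
    out[!edge] <- k * (x * legendreEval(k, x) - legendreEval(k - 1L, x)) / (x^2 - 1)
  }
  out
}

# Second derivative from the Legendre differential equation
# (1 - xi^2) L'' - 2 xi L' + k(k+1) L = 0 (interior points only).
legendreDeriv2 <- function(k, xi) {
  (2 * xi * legendreDeriv(k, xi) - k * (k + 1) * legendreEval(k, xi)) / (1 - xi^2)
}

#' Gauss-Legendre-Lobatto nodes
#'
#' The \eqn{N+1} GLL nodes on \eqn{[-1, 1]}: the endpoints \eqn{\pm 1} plus
#' the \eqn{N-1} roots of \eqn{L_N'}. Interior roots are found by Newton
#' iteration on \eqn{L_N'} from Chebyshev-Lobatto initial guesses
#' (tolerance 1e-14, at most 100 iterations), then symmetrized.
#'
#' @param N integer spectral order, \eqn{N \ge 2}.
#' @return sorted numeric vector of length \eqn{N+1} with endpoints exactly
#'   \eqn{\pm 1}.
#' @examples
#' gllNodes(2)  # -1, 0, 1
#' gllNodes(4)  # -1, -sqrt(3/7), 0, sqrt(3/7), 1
#' @export
gllNodes <- function(N) {
  stopifnot(length(N) == 1L, N == as.integer(N))
  if (N < 2) stop("spectral order N must be >= 2")
  N <- as.integer(N)
  if (N == 2L) return(c(-1, 0, 1))
  x <- -cos(pi * (1:(N - 1L)) / N)  # Chebyshev-Lobatto interior guesses
  for (it in 1:100) {
    dx <- legendreDeriv(N, x) / legendreDeriv2(N, x)
    x <- x - dx
    if (max(abs(dx)) < 1e-14) break
  }
  x <- (x - rev(x)) / 2  # enforce symmetry about 0
  c(-1, x, 1)
}

#' Gauss-Legendre-Lobatto quadrature weights
#'
#' \eqn{w_k = 2 / (N (N+1) [L_N(\xi_k)]^2)}, evaluated at each node
#' \eqn{\xi_k}. The weights are positive, sum to 2, and the resulting
#' quadrature integrates polynomials up to degree \eqn{2N - 1} exactly.
#'
#' @param N integer spectral order.
#' @param nodes GLL nodes from [gllNodes()]; computed if missing.
#' @return numeric vector of \eqn{N+1} positive weights.
#' @examples
#' gllWeights(2)  # 1/3, 4/3, 1/3
#' @export
gllWeights <- function(N, nodes = gllNodes(N)) {
  2 / (N * (N + 1) * legendreEval(as.integer(N), nodes)^2)
}

#' GLL nodal differentiation matrix
#'
#' The matrix \eqn{d_{ij} = \phi_j'(\xi_i)} mapping nodal samples of a
#' polynomial of degree at most \eqn{N} to exact samples of its derivative:
#' \eqn{d_{00} = -N(N+1)/4}, \eqn{d_{NN} = +N(N+1)/4}, zero on the interior
#' diagonal, and \eqn{d_{ij} = L_N(\xi_i) / (L_N(\xi_j) (\xi_i - \xi_j))}
#' off the diagonal. Rows sum to zero.
#'
#' @inheritParams gllWeights
#' @return \eqn{(N+1)\times(N+1)} numeric matrix.
#' @export
gllDiffMatrix <- function(N, nodes = gllNodes(N)) {
  N <- as.integer(N)
  LN <- legendreEval(N, nodes)
  n1 <- N + 1L
  d <- outer(LN, LN, "/") / (outer(nodes, nodes, "-") + diag(n1))
  diag(d) <- 0
  d[1L, 1L] <- -N * (N + 1) / 4
  d[n1, n1] <- N * (N + 1) / 4
  d
}

#' Construct a GLL basis
#'
#' Bundles nodes, quadrature weights and the differentiation matrix of the
#' order-\code{N} Gauss-Legendre-Lobatto scheme into a validated
#' [GLLBasis-class] object.
#'
#' @param N integer spectral order, \eqn{N \ge 2}.
#' @return a [GLLBasis-class].
#' @examples
#' b <- gllBasis(8)
#' sum(quadWeights(b))  # 2
#' @export
gllBasis <- function(N) {
  N <- as.integer(N)
  x <- gllNodes(N)
  new("GLLBasis",
    order = N, nodes = x,
    weights = gllWeights(N, x),
    diff = gllDiffMatrix(N, x)
  )
}

#' Evaluate a cardinal Lagrange basis function
#'
#' Evaluates the \code{j}-th Lagrange cardinal polynomial of the GLL basis,
#' \eqn{\phi_j(\xi) = (\xi^2 - 1) L_N'(\xi) / (N(N+1) L_N(\xi_j)(\xi - \xi_j))},
#' with the removable singularity at \eqn{\xi = \xi_j} evaluated as 1
#' (cardinality: \eqn{\phi_j(\xi_i) = \delta_{ij}}).
#'
#' @param basis a [GLLBasis-class].
#' @param j node index in \code{0:N} (zero-based, matching the nodal
#'   numbering).
#' @param xi evaluation points in \eqn{[-1, 1]} (vectorized).
#' @return numeric vector \eqn{\phi_j(\xi)}.
#' @export
lagrangeEval <- function(basis, j, xi) {
  N <- basis@order
  if (length(j) != 1L || j < 0 || j > N) stop("basis index out of range")
  xj <- basis@nodes[j + 1L]
  out <- numeric(length(xi))
  at_node <- abs(xi - xj) < 1e-13
  out[at_node] <- 1
  if (any(!at_node)) {
    x <- xi[!at_node]
    out[!at_node] <- (x^2 - 1) * legendreDeriv(N, x) /
      (N * (N + 1) * legendreEval(N, xj) * (x - xj))
  }
  out
}
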