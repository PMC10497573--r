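# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: closed-form sums, product-form polynomials,
# exact polynomial integration, moment equations, and a classical RK4
# integrator.

# Legendre polynomial by the explicit binomial sum (valid for k <= ~8 before
# binomial coefficients lose accuracy).
legendre_sum <- function(k, xi) {
  j <- 0:(k %/% 2)
  sapply(xi, function(x) {
    sum((-1)^j * choose(k, j) * choose(2 * k - 2 * j, k) * x^(k - 2 * j)) / 2^k
  })
}

# Product-form Lagrange cardinal polynomial on arbitrary nodes.
product_lagrange <- function(nds, j, xi) {
  xj <- nds[j + 1]
  others <- nds[-(j + 1)]
  sapply(xi, function(x) prod((x - others) / (xj - others)))
}

# Monomial coefficients (ascending powers) of the j-th Lagrange polynomial,
# via the Vandermonde system p(x_i) = delta_ij. Fine for small orders.
lagrange_coefs <- function(nds, j) {
  n <- length(nds)
  V <- outer(nds, 0:(n - 1), "^")
  rhs <- numeric(n); rhs[j + 1] <- 1
  solve(V, rhs)
}

poly_deriv <- function(coefs) {
  if (length(coefs) <= 1) return(0)
  coefs[-1] * seq_len(length(coefs) - 1)
}

# Exact integral over [lo, hi] of the product of two polynomials given by
# ascending coefficient vectors.
poly_prod_integral <- function(a, b, lo = -1, hi = 1) {
  prod_c <- rep(0, length(a) + length(b) - 1)
  for (i in seq_along(a)) for (j in seq_along(b)) {
    prod_c[i + j - 1] <- prod_c[i + j - 1] + a[i] * b[j]
  }
  k <- seq_along(prod_c)
  sum(prod_c / k * (hi^k - lo^k))
}

# Quadrature weights from the moment equations: exact integration of the
# monomials 1, x, ..., x^N on [-1, 1].
moment_weights <- function(nds) {
  n <- length(nds)
  A <- outer(0:(n - 1), seq_len(n), function(m, i) nds[i]^m)
  b <- ifelse((0:(n - 1)) %% 2 == 0, 2 / ((0:(n - 1)) + 1), 0)
  solve(A, b)
}

# Classical RK4 on the constant-dose semi-discrete system; returns the
# center series. Test-only higher-order oracle.
rk4_center <- function(sys, ic, t_end, n_steps, etaT = 0, etaG = 0) {
  n <- sys@n
  m <- if (length(ic) == 1) rep(ic, n) else ic
  dt <- t_end / n_steps
  forcing <- sys@BT * etaT + sys@BG * etaG + sys@Cb
  rhs <- function(x) drop(sys@A %*% x) + forcing
  cx <- (sys@mapX@xa + sys@mapX@xb) / 2
  em <- elementMap(sys@mapX@xa, sys@mapX@xb)
  xi <- mapToReference(em, cx)
  w1 <- vapply(0:sys@basis@order, function(j) lagrangeEval(sys@basis, j, xi), numeric(1))
  wpt <- if (sys@dims == 2L) as.numeric(kronecker(w1, w1)) else w1
  center <- numeric(n_steps + 1)
  center[1] <- sum(wpt * m)
  for (k in seq_len(n_steps)) {
    k1 <- rhs(m)
    k2 <- rhs(m + dt / 2 * k1)
    k3 <- rhs(m + dt / 2 * k2)
    k4 <- rhs(m + dt * k3)
    m <- m + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    center[k + 1] <- sum(wpt * m)
  }
  center
}

# Shared expensive fixtures, computed once per test run.
.fixtures <- new.env(parent = emptyenv())
fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}
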