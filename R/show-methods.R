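setMethod("show", "GLLBasis", function(object) {
  cat(sprintf("GLLBasis of order %d (%d nodes on [-1, 1])\n",
              object@order, object@order + 1L))
  cat(sprintf("  weight sum: %.15g\n", sum(object@weights)))
})

setMethod("show", "ModelParams", function(object) {
  cat("Homogenized fibrosis model parameters (cm / day / g cm^-3)\n")
  cat(sprintf("  D_m = %g, d_m = %g, lambda_mfT = %g, lambda_mfG = %g\n",
              object@Dm, object@dm, object@lambdaT, object@lambdaG))
  cat(sprintf("  K_TGF = %g, K_G = %g, f = %g, m0 = %g\n",
              object@KT, object@KG, object@f, object@m0))
  cat(sprintf("  T_GF0 = %g, G0 = %g, a = %g, gamma = %.6g\n",
              object@Tgf0, object@G0, object@a, object@gamma))
  cat(sprintf("  domain [%g, %g] cm, t_f = %g d, sim horizon = %g d\n",
              object@domain[1L], object@domain[2L], object@tf, object@tEndSim))
  cat(sprintf("  derived: r = %.5g cm^2/day, c = %.5g g cm^-3 day^-1\n",
              homogenizedDiffusivity(object), activationConstant(object)))
})

setMethod("show", "SemiDiscreteSystem", function(object) {
  cat(sprintf("SemiDiscreteSystem: n = %d (order %d, %dD, %s, %s)\n",
              object@n, object@order, object@dims,
              object@convention, object@diffusionSign))
  sc <- object@scalar
  cat(sprintf("  scalar reduction: a_s = %.5g, b_T = %.6g, b_G = %.6g, c = %.6g\n",
              sc$aS, sc$bT, sc$bG, sc$c))
})

setMethod("show", "Trajectory", function(object) {
  K <- length(object@times)
  cat(sprintf("Trajectory: %d times on [%g, %g] days\n",
              K, object@times[1L], object@times[K]))
  cat(sprintf("  center density: %.6g -> %.6g g/cm^3\n",
              object@center[1L], object@center[K]))
  cat(sprintf("  uniformity defect: %.3g\n", object@uniformityDefect))
})

setMethod("show", "RiccatiPath", function(object) {
  K <- length(object@times)
  cat(sprintf("RiccatiPath (%s mode): %d times, terminal p = g = 0\n",
              object@mode, K))
  cat(sprintf("  p(t0) = %.6g, g(t0) = %.6g\n", object@p[1L], object@g[1L]))
})

setMethod("show", "ControlSolution", function(object) {
  tr <- object@trajectory
  K <- length(tr@times)
  cat(sprintf("ControlSolution (%s mode, clamp = %s)\n", object@mode, object@clamp))
  cat(sprintf("  center density: %.6g -> %.6g g/cm^3 over %g days\n",
              tr@center[1L], tr@center[K], tr@times[K]))
  cat(sprintf("  objective J = %.6g\n", object@objective))
  if (length(object@durations)) {
    d <- object@durations
    fmt <- function(x) if (is.finite(x)) sprintf("%.4g d", x) else "never"
    cat(sprintf("  settle times: eta_T %s, eta_G %s, state %s\n",
                fmt(d$etaT), fmt(d$etaG), fmt(d$state)))
  }
})
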