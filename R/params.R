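#' Model parameter set
#'
#' Constructs a [ModelParams-class] object. The defaults are the published
#' parameter estimates for injured alveolar tissue (unit system: cm, day,
#' g cm^-3): diffusion coefficient \eqn{D_m = 1.47\times 10^{-5}} cm^2/day,
#' death rate \eqn{d_m = 1.66\times 10^{-2}} /day, activation rates
#' \eqn{\lambda_{mfT} = \lambda_{mfG} = 0.12} /day, saturation constants
#' \eqn{K_{TGF} = 10^{-10}} and \eqn{K_G = 1.5\times 10^{-8}} g/cm^3,
#' fibroblast density \eqn{f = 4.75\times 10^{-3}} g/cm^3, initial
#' myofibroblast density \eqn{m_0 = 8.5\times 10^{-3}} g/cm^3, constant
#' TGF-beta and PDGF concentrations \eqn{2.51\times 10^{-12}} and
#' \eqn{0.58\times 10^{-3}} g/cm^3, homogenization coefficients
#' \eqn{a = 0.11} and \eqn{\gamma = 127/343}, damaged interval
#' \eqn{[0.3, 0.6]} cm per dimension, control horizon 350 days, and
#' forward-simulation horizon 400 days.
#'
#' @param Dm,dm,lambdaT,lambdaG,KT,KG,f,m0,Tgf0,G0,a,gamma,domain,tf,tEndSim
#'   see [ModelParams-class] for meanings and units.
#' @return a validated [ModelParams-class].
#' @examples
#' p <- modelParams()
#' homogenizedDiffusivity(p)  # 4.3672e-06 cm^2/day
#' activationConstant(p)      # 5.8394e-04 g cm^-3 day^-1
#' @export
modelParams <- function(Dm = 1.47e-5, dm = 1.66e-2,
                        lambdaT = 0.12, lambdaG = 0.12,
                        KT = 1e-10, KG = 1.5e-8,
                        f = 4.75e-3, m0 = 8.5e-3,
                        Tgf0 = 2.51e-12, G0 = 0.58e-3,
                        a = 0.11, gamma = 127 / 343,
                        domain = c(0.3, 0.6),
                        tf = 350, tEndSim = 400) {
  new("ModelParams",
    Dm = Dm, dm = dm, lambdaT = lambdaT, lambdaG = lambdaG,
    KT = KT, KG = KG, f = f, m0 = m0, Tgf0 = Tgf0, G0 = G0,
    a = a, gamma = gamma, domain = domain, tf = tf, tEndSim = tEndSim
  )
}

#' Saturation (Michaelis-Menten) fraction
#'
#' The occupancy fraction \eqn{c/(K + c)} of the activation kinetics; a
#' dimensionless number in \eqn{[0, 1)}, monotone increasing in the
#' concentration.
#'
#' @param conc ligand concentration, g/cm^3 (nonnegative).
#' @param K saturation constant, g/cm^3 (positive).
#' @return numeric in \eqn{[0, 1)}.
#' @examples
#' saturation(2.51e-12, 1e-10)  # ~0.0244854 (TGF-beta, nearly unsaturated)
#' saturation(0.58e-3, 1.5e-8)  # ~0.9999741 (PDGF, fully saturated)
#' @export
saturation <- function(conc, K) {
  if (any(conc < 0)) stop("negative concentration")
  if (any(K <= 0)) stop("saturation constant must be positive")
  conc / (K + conc)
}

#' Activation constant of the uniform source term
#'
#' With the growth-factor concentrations held constant, the
#' fibroblast-to-myofibroblast activation source reduces to the constant
#' \eqn{c = (\lambda_{mfT}\, T/(K_{TGF}+T) + \lambda_{mfG}\, G/(K_G+G))\, f}
#' in g cm^-3 day^-1. It equals \eqn{|b_T| + |b_G|}, the sum of the control
#' input magnitudes, so full blockade (\eqn{\eta_T = \eta_G = 1}) cancels
#' activation exactly.
#'
#' @param p a [ModelParams-class].
#' @return the activation constant, g cm^-3 day^-1.
#' @export
activationConstant <- function(p) {
  (p@lambdaT * saturation(p@Tgf0, p@KT) + p@lambdaG * saturation(p@G0, p@KG)) * p@f
}

#' Homogenized effective diffusivity
#'
#' \eqn{r = a D_m / \gamma}: the effective diffusivity of myofibroblasts in
#' the homogenized (effective-medium) alveolar tissue, cm^2/day.
#'
#' @param p a [ModelParams-class].
#' @return numeric scalar, cm^2/day.
#' @export
homogenizedDiffusivity <- function(p) {
  if (p@gamma <= 0) stop("gamma must be positive")
  p@a * p@Dm / p@gamma
}

# Control input scalars b_T, b_G (each entry of the input vectors): the
# negated per-pathway activation source at full blockade.
controlInputScalars <- function(p) {
  c(
    bT = -p@lambdaT * p@f * saturation(p@Tgf0, p@KT),
    bG = -p@lambdaG * p@f * saturation(p@G0, p@KG)
  )
}

# Keys accepted in flat parameter config files (Table-style symbol names).
.paramKeys <- c(
  D_m = "Dm", d_m = "dm", lambda_mfT = "lambdaT", lambda_mfG = "lambdaG",
  K_TGF = "KT", K_G = "KG", f = "f", m0 = "m0", T_GF0 = "Tgf0", G0 = "G0",
  a = "a", gamma = "gamma", t_f = "tf", t_end_sim = "tEndSim",
  domain = "domain"
)

#' Read a model parameter set from a flat config file
#'
#' Reads a YAML file of flat key-value pairs using the field's symbol names
#' (\code{D_m}, \code{d_m}, \code{lambda_mfT}, \code{lambda_mfG}, \code{K_G},
#' \code{K_TGF}, \code{f}, \code{m0}, \code{T_GF0}, \code{G0}, \code{a},
#' \code{gamma}, \code{t_f}, \code{t_end_sim}, \code{domain}). Any key not
#' present keeps its default; unknown keys are rejected with the offending
#' key named. A defaults file with the full published set ships in
#' \code{system.file("extdata", "default_params.yaml", package = "fibrocontrol")}.
#'
#' @param file path to a YAML config file.
#' @return a validated [ModelParams-class].
#' @export
readParams <- function(file) {
  cfg <- yaml::read_yaml(file)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), names(.paramKeys))
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  args <- stats::setNames(cfg, .paramKeys[names(cfg)])
  args <- lapply(args, function(v) {
    if (is.character(v)) {
      # allow exact rationals like "127/343" in config files
      parts <- strsplit(v, "/", fixed = TRUE)[[1L]]
      v <- if (length(parts) == 2L) {
        as.numeric(parts[1L]) / as.numeric(parts[2L])
      } else {
        as.numeric(v)
      }
    }
    if (any(is.na(v))) stop("non-numeric parameter value in config")
    as.numeric(v)
  })
  do.call(modelParams, args)
}
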