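---
title: "Methods: spectral simulation and optimal dosing of the fibrosis model"
author: "fibrocontrol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral simulation and optimal dosing of the fibrosis model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrocontrol)
```

# The biological model

The state is the myofibroblast density $m(x, y, t)$ (g cm$^{-3}$) in a
damaged square $D = [0.3, 0.6]^2$ cm of homogenized alveolar tissue, over a
treatment horizon of 350 days. Fibroblasts (constant density $f$) are
activated into myofibroblasts by TGF-β and PDGF through saturating
Michaelis–Menten kinetics; myofibroblasts die at rate $d_m$ and diffuse
slowly. With both growth-factor concentrations held at their initial values
(the model provides no dynamics for them — a modelling choice discussed
below), activation reduces to a constant source

$$c = \left(\lambda_{mfT}\frac{T}{K_{TGF}+T}
  + \lambda_{mfG}\frac{G}{K_G+G}\right) f
  \approx 5.8394\times 10^{-4}\ \mathrm{g\,cm^{-3}\,day^{-1}},$$

dominated by the PDGF pathway ($G \gg K_G$, occupancy $\approx 0.99997$)
while the TGF-β pathway is nearly unsaturated ($T \ll K_{TGF}$, occupancy
$\approx 0.0245$). The drugs enter as dimensionless efficacies
$\eta_T, \eta_G \in [0, 1]$ multiplying $(1-\eta)$ onto each pathway, so the
control input scalars are $b_T = -\lambda_{mfT} f\, T/(K_{TGF}+T)$ and
$b_G$ analogously, with the exact identity $c = |b_T| + |b_G|$: full
blockade cancels activation completely. Untreated, the uniform density
relaxes to the activation/apoptosis balance $c/d_m \approx 0.0352$ with
time constant $1/d_m \approx 60$ days.

The porous alveolar micro-geometry is not resolved; it enters only through
the homogenization coefficients $a = 0.11$ and $\gamma = 127/343$, giving
the effective diffusivity $r = a D_m/\gamma \approx 4.37\times 10^{-6}$
cm$^2$/day. The derivation of those two numbers is outside the package's
scope; they are treated as data.

All parameters ship as defaults of `modelParams()` in the unit system
cm / day / g cm$^{-3}$ with no internal rescaling, and can be overridden
individually or loaded from a flat YAML file (`readParams()`; a defaults
file ships in `inst/extdata/default_params.yaml`).

**Initial condition.** The model statement prescribes the initial density at
a single corner point. Because the reported results show a single density
trajectory whose value is identical across spectral orders to seven decimal
places, the package interprets the initial state as the spatially uniform
field $m_0 = 8.5\times 10^{-3}$ over $D$; `integrateEuler()` also accepts an
arbitrary nodal field.

# Spectral Galerkin discretization

Space is discretized with Lagrange cardinal polynomials on
Gauss–Legendre–Lobatto (GLL) nodes, one spectral element per dimension
mapped affinely onto $[0.3, 0.6]$. Nodes are the endpoints plus the roots of
$L_N'$, found by Newton iteration from Chebyshev–Lobatto initial guesses
(tolerance $10^{-14}$, at most 100 iterations, then symmetrized) — a
self-contained construction reproducible to machine precision. Weights are
$w_k = 2/(N(N+1) L_N(\xi_k)^2)$, evaluated at each node; the quadrature is
exact through degree $2N-1$ (property-tested against symbolic monomial
integrals for $N = 2,\dots,12$).

On an element of width $h$ the operators are the lumped (diagonal) mass
$K_{ii} = (h/2) w_i$, the stiffness
$S_{ij} = \frac{2}{h}\sum_k d_{ki} d_{kj} w_k$ with $d$ the nodal
differentiation matrix, and the load $C_i = (h/2) w_i$. Two exactness
remarks that the test suite relies on:

* the stiffness integrand $\phi_i'\phi_j'$ has degree $2N-2$, so the
  quadrature stiffness *is* the exact Galerkin stiffness (verified
  symbolically at low order);
* the mass integrand has degree $2N$, so the lumped mass is *not* the exact
  mass matrix entrywise; what is exact is the row-sum (partition-of-unity)
  identity $\sum_j \int \phi_i \phi_j = \int \phi_i = K_{ii}$, and
  consequently $C = K\,\mathbf{1}$ exactly.

**Two-dimensional stiffness.** The mass and load are tensor products
$K = K_x \otimes K_y$, $C = C_x \otimes C_y$. For the stiffness the package
offers two conventions. The default, `laplacian_consistent`, is the Galerkin
matrix of the 2D Laplacian, $S_x \otimes K_y + K_x \otimes S_y$. The
alternative `paper_literal` keeps the plain tensor product
$S_x \otimes S_y$, selectable for strict replication of the source
discretization; it is *not* a discrete Laplacian (its energy on a smooth
non-constant field is far from the Dirichlet energy, which a manufactured
solution test demonstrates). Both annihilate constants, so on spatially
uniform fields — the regime of every default study — the two produce
identical dynamics.

**Diffusion sign.** Integration by parts of the weak form yields the
dissipative $-rS$ term in $A = K^{-1}(-d_m K \pm r S)$; the source
discretization prints $+rS$, which is anti-dissipative. The package defaults
to `stable_minus_rS` and keeps `paper_plus_rS` selectable. On uniform states
the choice is irrelevant ($S\mathbf{1}=0$); on non-uniform data only the
stable sign is meaningful.

# Time integration and its stability limits

Time stepping is explicit forward Euler with a uniform step — deliberately,
because that is the method the discrete formulation prescribes; a classical
RK4 integrator exists in the test suite only, as a higher-order oracle. For
uniform fields the exact solution
$m(t) = m_\infty + (m_0 - m_\infty)e^{-d_m t}$,
$m_\infty = (c + b_T\eta_T + b_G\eta_G)/d_m$, is available as
`closedFormUniform()` and the Euler error is verified to converge at first
order (halving when the step count doubles). A note on magnitudes: at the
default 10000 steps the Euler-vs-exact discrepancy is of order $10^{-3}$
relative on the transient — first-order accuracy, not more — so any
comparison against the RK4 oracle is made at that accuracy, never tighter.

Explicit Euler imposes a step restriction from the stiffness spectrum:
$\mathrm{eig}_{\max}(K^{-1}S)$ grows like $N^4/h^2$, so the stable step for
the consistent 2D operator at the default parameters is about 0.68 days at
$N=16$, 0.14 at $N=24$ and 0.045 at $N=32$. Two practical consequences,
both documented because they shape the convergence study:

* every *default* run (10000 steps over 350 or 400 days, i.e. steps of
  0.035–0.04 days) is stable at all configured orders, and uniform initial
  data stays uniform to a defect below $10^{-12}$;
* coarser step counts at $N = 32$ (4000 or 7000 steps) exceed the stability
  limit: rounding noise excites non-uniform modes and the run diverges.
  `convergenceStudy()` records such combinations as `NA` with a warning
  instead of aborting. The `paper_literal` stiffness *squares* the
  spectrum, so its stability limit is astronomically smaller; it is usable
  only at very small orders or steps.

The inter-order convergence study itself measures
$\max_t |m_N(t) - m_{N'}(t)|$ at the region center (the final-time variant
is also emitted; the underlying report leaves the norm configurable because
the reference tables do not name one). Because uniform fields make every
spectral order exactly equivalent, these inter-order differences are
rounding noise ($\sim 10^{-15}$) wherever the integration is stable — the
study is retained as a faithful, machine-readable artifact, but it cannot
exhibit a step-count-dependent error decay in this regime, and the package
makes no claim that it does.

# The optimal regulator

The dosing problem minimizes
$\tfrac12\int_0^{t_f} q_m m^2\,dt + \tfrac12\int_0^{t_f}(r_T\eta_T^2 +
r_G\eta_G^2)\,dt$ (defaults $q_m = r_T = r_G = 1$) subject to the
semi-discrete affine dynamics. The Hamiltonian is taken with the factor
$\tfrac12$ on both quadratic terms — the unique normalization consistent
with the stationarity law $\eta^* = -B^T\lambda/r$ and a unit state weight
in the Riccati flow. Pontryagin's conditions with the affine costate model
$\lambda = p\,m + c\,g$ give the extended Riccati equations

$$\dot p = -(2 a_s p - \tilde b^2 p^2 + q_m), \qquad
  \dot g = -\big((a_s - \tilde b^2 p)\,g + p\big), \qquad
  \tilde b^2 = b_T^2/r_T + b_G^2/r_G,$$

swept backward by explicit Euler from $p(t_f) = g(t_f) = 0$. These terminal
conditions are not stated in the source formulation; they are the standard
free-endpoint, no-terminal-cost conditions implied by the objective, and
are the package's choice. With zero input vectors the sweep has the closed
form $p(t) = (1 - e^{2 d_m (t - t_f)})/(2 d_m)$, used as the test oracle.

**Scalar and matrix modes.** The default `scalar` mode works on the exact
uniform reduction (the lowercase scalar kernel and the commuting
manipulations in the source derivation indicate a scalar implementation).
The `matrix` mode solves the full affine-LQR sweep
$\dot P = -(PA + A^TP - P(B_TB_T^T/r_T + B_GB_G^T/r_G)P + Q)$,
$\dot s = -\big((A - (\cdot)P)^T s + P C_b\big)$, reading the source's
commuted kernel products in the only order that yields a symmetric flow.
The state weight is chosen as $Q = (q_m/n)I$ with $n$ the state dimension —
the mean-square nodal penalty. This is deliberate: it represents the scalar
objective $\tfrac{q_m}{2}\int m^2 dt$ on a uniform field, and it makes the
projections $\mathbf{1}^TP\mathbf{1}$ and $\mathbf{1}^Ts$ obey exactly the
scalar equations, so the two modes agree on uniform problems to rounding
(verified at $N = 2, 4$); with $Q = q_m I$ the matrix mode would instead
solve a problem with state weight inflated by the node count and the two
routes would disagree by construction. The matrix mode stores the full
$P(t)$ path and is intended as the verification oracle at small $n$.

Control admissibility is not enforced in the solve (the formulation imposes
no bounds); an optional clamp of the *applied* controls to $[0,1]$ is
available for pharmacological interpretation and is never used inside the
Riccati sweep. The objective is reported by trapezoidal quadrature — a
presentation choice only.

**Duration summaries.** "How long must each medicine be given" is reported
as the first grid time from which a schedule stays below a small-dose
threshold, $10^{-3}$ by default for the dimensionless controls and 1% of
$m_0$ for the density; both thresholds are configurable and recorded in
every output, because the qualitative phrase "about so-many days" does not
define a criterion.

# The regime the default parameters produce

The default parameter set puts the regulator in a weak-authority regime,
and the package reports it as computed rather than adjusting it. The input
magnitudes $|b_T| \approx 1.4\times 10^{-5}$ and
$|b_G| \approx 5.7\times 10^{-4}$ act on a state of order $10^{-2}$ under a
quadratic dose penalty of weight 1, so the stationary feedback prescribes
doses of order $10^{-3}$ and below: the anti-PDGF schedule exceeds the
$10^{-3}$ threshold from mid-horizon until about day 241, the anti-TGF-β
schedule (whose pathway is 40-fold weaker at these saturations) never
reaches it, and the closed-loop density still rises toward the untreated
plateau, strictly below it at every time but far from vanishing. The
objective nevertheless certifies optimality — it undercuts both the
untreated and the full-blockade constant policies, as the suite checks.
Driving the density toward zero within the horizon would require either a
much larger state weight $q_m$, much cheaper controls, or larger activation
blockade authority than these kinetics provide; exploring that trade-off is
what the `qM`, `rT`, `rG` knobs are for.

# Numerical choices, degenerate inputs, limitations

* Node solves: Newton with tolerance $10^{-14}$; weights validated against
  moment equations; all operators dense (orders ≤ 33 per dimension make
  sparsity irrelevant).
* Evaluation point: the region center $x = y = 0.45$ (a GLL node for even
  $N$, the mapped midpoint); for general points and odd orders the nodal
  field is evaluated by cardinal Lagrange interpolation.
* Landing on report days (50, 100, 150, 250): linear interpolation on the
  raw step counts; the alternative of snapping step counts to multiples of
  70 is intentionally not the default, and the manifest records the grid.
* Degenerate inputs: $f = 0$ gives the sourceless decay model (used by the
  Riccati oracle); $q_m = 0$ gives the zero feedback path and reproduces
  the uncontrolled solve exactly; non-finite states abort with the step
  index; unknown configuration keys are rejected by name.
* The per-run uniformity defect (max–min over nodes, maximized over time)
  is recorded on every trajectory, so departures from the uniform regime
  are visible in the artifacts rather than silent.
* What the default studies do *not* exercise: non-uniform initial data
  (supported by the integrator, but outside the reported regime),
  time-varying growth-factor fields, spatially varying fibroblast density,
  multi-element meshes, and control bounds inside the optimization. Test
  passes on the uniform regime say nothing about spatial accuracy claims
  beyond the manufactured-solution and symbolic checks listed above.
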