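---
title: "Methods: hybrid nanofluid boundary-layer flow in a stenosed artery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid nanofluid boundary-layer flow in a stenosed artery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stenoflow)
```

## The physical problem

`stenoflow` models steady, incompressible, two-dimensional boundary-layer
flow of a hybrid nanofluid — whole blood carrying alumina (Al~2~O~3~) and
copper nanoparticles — through an axisymmetric artery with a cosine-shaped
stenosis. The vessel radius is

$$R(x) = R_0 - \tfrac{\lambda}{2}\left(1 + \cos\tfrac{4\pi x}{L_0}\right)
\quad\text{for } |x| < L_0/4,\qquad R(x) = R_0 \text{ otherwise},$$

so the constriction spans half the reference length $L_0$, reaches maximum
depth $\lambda$ at the throat, and joins the healthy vessel with continuous
slope. The severity $\epsilon = \lambda/R_0 \in [0,1)$ is the only shape
parameter of the dimensionless profile $f(\tilde x) = R/R_0$
(`dimensionless_profile()`).

The blood is treated as a Newtonian fluid. This is the model's central
simplification: real blood is shear-thinning and particulate, and no
pulsatility, vessel compliance, or two- or three-dimensional recirculation
behind the throat is represented. What the package computes is the
attached, quasi-similar boundary layer on the stenosed wall and the wall
shear and heat-transfer groups it implies.

## Mixture laws

Effective properties of the suspension come from the standard two-species
extensions of the classical single-phase laws
(`hybrid_mixture()`):

* density and volumetric heat capacity by two-stage linear volume
  weighting — species 1 into the base fluid, then species 2 into that
  suspension;
* dynamic viscosity by the product of two Brinkman factors,
  $\mu_{hnf}/\mu_f = (1-\phi_1)^{-2.5}(1-\phi_2)^{-2.5}$;
* thermal conductivity by two chained Maxwell (Maxwell–Garnett) factors.
  Chaining needs a definition of the continuous phase of the second
  factor: here it is the mono nanofluid produced by the first factor, i.e.
  its conductivity is $k_f$ times the first Maxwell ratio. Any other
  reading leaves the product ill-defined.

Species order defaults to Al~2~O~3~ first and Cu second, matching the
subscript convention of the source tables; the ordering only matters
through the Maxwell chaining and is configurable. Properties are
room-temperature constants (blood: 1050 kg/m³, 3617 J/kg/K, 0.52 W/m/K;
Al~2~O~3~: 3970, 765, 40; Cu: 8933, 385, 400) shipped as an immutable
registry; user materials can be appended but the built-ins cannot be
overridden. Temperature-dependent properties, particle shape factors and
slip mechanisms (Brownian diffusion, thermophoresis) are out of scope.

The similarity equations consume three derived coefficients:
$C_1 = (1-\phi_1)^{2.5}(1-\phi_2)^{2.5}$ (the inverse viscosity ratio),
$C_2 = \rho_{hnf}/\rho_f$, and
$C_3 = (k_{hnf}/k_f)\,(\rho C_p)_{hnf}/(\rho C_p)_f$.

## Similarity reduction

With the stream-function similarity map
$u = (u_0 x / L_0) F'(\eta)$,
$v = -(R/r)\sqrt{u_0\nu_f/L_0}\,F(\eta)$,
$\theta = (T - T_0)/(T_1 - T_0)$ and the wall-normal coordinate
$\eta \propto (r^2 - R^2)/2R$, the boundary-layer equations reduce to

$$\frac{1}{C_1 C_2}\left[(1+2\gamma\eta)F''' + 2\gamma F''\right]
  + F F'' - F'^2 = 0,$$
$$\frac{1}{Pr\, C_3}\left[(1+2\gamma\eta)\theta'' + 2\gamma\theta'\right]
  + F\theta' - F'\theta = 0,$$

where $\gamma = \sqrt{\nu_f L_0/(u_0 R^2)}$ collects the transverse
curvature. Two sign/convention choices are built in deliberately:

* **Wall-normal coordinate.** The literal similarity map gives
  $\eta \le 0$ inside the vessel while the boundary conditions are posed
  on $[0, f]$. The package resolves this by treating $\eta$ as the
  nonnegative wall-normal coordinate, which keeps the curvature factor
  $1 + 2\gamma\eta$ positive everywhere and the system regular.
* **Prandtl number.** The conventional definition (momentum over thermal
  diffusivity) is used. The reciprocal convention that sometimes appears
  with these equations would make temperature *rise* with Pr inside this
  energy equation, contradicting the physically expected thinning of the
  thermal layer.

One boundary-value problem is solved per axial station $\tilde x$; the
geometry enters only through the domain edge
$\eta_{edge} = f(\tilde x)$ (quasi-similar approximation).

## Boundary-condition closures

The literal boundary set published with these equations — no slip
$F(0)=0$, $F'(0)=0$, heated wall $\theta(0)=1$, and zero shear/heat-flux
gradient at the edge — admits **only** the trivial solution $F \equiv 0$,
$\theta \equiv 1$: with both wall velocity components and the edge shear
zero there is nothing to drive the flow, and every wall group vanishes.
Because nonzero wall quantities are tabulated for this very model, the
package treats the closure as the genuinely open design point and offers
three variants (`similarity_params(closure = ...)`):

* `"stretching-wall"` (default): $F'(0) = 1$, consistent with the wall
  velocity scale $u_0 x/L_0$ that the similarity map itself assigns to
  the wall, with zero-gradient edge conditions;
* `"paper-literal"`: the degenerate set above, retained so the
  degeneracy is demonstrable (the solver reproduces the trivial state to
  10^-10^);
* `"quiescent-edge"`: $F'(0)=1$ with far-field decay $F' = \theta = 0$,
  which on a wide domain is the classical stretching-surface problem —
  its $\gamma = 0$, particle-free limit has the closed form
  $F = 1 - e^{-\eta}$ with $F''(0) = -1$, used as the analytic oracle.

## The two-point solver

`solve_profile()` is a from-scratch fourth-order collocation solver of
the `bvp4c` class: the three-point Lobatto IIIA (Simpson) scheme on each
mesh interval, solved by a damped Newton iteration. The Jacobian is
assembled sparsely from ten finite-difference residual evaluations using
a two-colour scheme (every collocation row depends on at most one mesh
node of each parity). The defect of the cubic Hermite interpolant is
sampled at the quarter points of every interval — the midpoint defect of
the Simpson scheme vanishes identically — scaled by $1 + |y'|$, and
intervals above tolerance are bisected, interpolating the current
solution onto the new mesh. Defaults: tolerance 10^-8^, 50 initial
intervals, at most 2000 nodes; exceeding the budget raises a classed
error with diagnostics rather than returning a partial answer.

The initial guess is deterministic: $F'(\eta) = (1 - \eta/\eta_{edge})^2$
integrated to a cubic for $F$ (it satisfies the active wall and edge
conditions), the same quadratic for $\theta$, and the exact trivial state
under the literal closure. No randomness enters anywhere, so repeated
runs are byte-identical, including CSV output (12 significant digits).

`solve_profile_shooting()` is the independent cross-check: a Newton
iteration (forward differences, step 10^-7^) on the two unknown wall
derivatives, each evaluation an explicit high-order Runge–Kutta
integration (`deSolve::ode`, `ode45`). The test suite demands agreement
with collocation to 10^-6^ on a ten-point parameter grid.

Two analytic identities give further end-to-end checks with no numerics
on the reference side: the trivial state under the literal closure, and
the analogy identity — whenever $Pr = C_1 C_2 / C_3$ the energy equation
is the derivative form of the momentum equation, so
$\theta(\eta) = F'(\eta)$ exactly and
$Re_x^{-1/2} Nu_x = -(k_{hnf}/k_f) F''(0)$.

## Wall quantities and signs

Post-processing reports $Re_x^{1/2} C_f = F''(0)/C_1$ and
$Re_x^{-1/2} Nu_x = -(k_{hnf}/k_f)\,\theta'(0)$, plus dimensional
$\tau_w$ and $q_w$ through the chain rule of the similarity map when
dimensional scales are supplied. All quantities keep the sign the
computation produces; no magnitude or sign flipping is applied to force
agreement with any published convention. Because the published table
header is ambiguous between the mono ($k_{nf}/k_f$) and hybrid
($k_{hnf}/k_f$) conductivity ratios, the mixture object exposes both
(`k_ratio_mono`, `k_ratio`); the Nusselt group uses the hybrid ratio.

## Reproducing the published tables

The published wall-quantity tables state $(\gamma, Pr)$ or
$(\gamma, \phi)$ per row but omit the remaining inputs — the volume
fractions behind the Nusselt table, the Prandtl number behind the
skin-friction table, and the domain edge (equivalently the stenosis
severity at the evaluation station) for both. `reproduce_tables()`
therefore fixes defaults — $\phi_1 = \phi_2 = 0.05$, $Pr = 3$,
$\eta_{edge} = 1$ (the unobstructed radius), the single tabulated
$\phi$ applied to both species — and `identify_unstated_params()`
searches a candidate grid exhaustively for the assignment minimising the
maximum absolute deviation from the printed rows, reporting the full
misfit table and deterministic tie-breaks (skin friction is independent
of Pr, so Pr candidates tie by construction).

What the computation actually finds, as measured by the acceptance
suite: the Prandtl trend (|Nu| increasing in Pr) and the loading trend
(|Cf| increasing in $\phi$) match the tables, and the skin-friction sign
matches. The curvature trend does not — under every closure and every
edge location searched, both |Cf| and |Nu| *increase* with $\gamma$, the
classical transverse-curvature effect on a stretching cylinder, whereas
the tables order them decreasing — and the computed Nusselt group is
positive (heat flows from the heated wall into the fluid) where the
tables print negative values. A sign-definite wall-normal coordinate
cannot reproduce both. These disagreements are reported as computed; the
identification utility quantifies the residual misfit rather than hiding
it.

## Problem sizes and tolerances

Unit tests run the solver at a relaxed defect tolerance of 10^-6^ on
20-interval initial meshes; the acceptance checks use the 10^-8^ default
(the wide-domain oracle then refines to roughly 400 nodes and solves in
about two seconds). The exhaustive identification grids are
$\phi \in \{0, 0.01, 0.02, 0.05, 0.1\}$,
$Pr \in \{2, 3, 5, 21\}$ and
$\eta_{edge} \in \{0.5, 0.6, 0.75, 1, 5, 15\}$, chosen to bracket a
dilute-to-dense loading range, the plausible Prandtl range from water-like
to blood-like, and edge locations from a severe throat to an effectively
unbounded layer.

## Known limitations

* Newtonian rheology; no shear-thinning, no pulsatility, no
  two-dimensional field solve of the stenotic region, hence no
  separation or downstream recirculation.
* The quasi-similar treatment couples stations only through
  $\eta_{edge}$; axial diffusion and upstream influence are absent.
* The boundary-condition closure is a modelling choice, not a derived
  fact; the default is the one consistent with the similarity map's own
  wall velocity scale, and alternatives are one flag away.
* Published-table agreement is limited by the unstated inputs and the
  sign/ordering conflicts described above.
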