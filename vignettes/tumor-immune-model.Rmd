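---
title: "A size- and space-structured model of tumor-immune interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A size- and space-structured model of tumor-immune interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumimm)
```

## The model

`tumimm` simulates the competition between a growing tumor and an immune
response that has both antitumor and protumor arms. The tumor is
structured by cell size, the immune cells by position; the two scales
are coupled only through integral quantities, reflecting the separation
between the micrometer scale of tumor cells and the centimeter scale of
immune-cell trafficking.

**Tumor cells.** The size density $n(t,z)$ obeys a
growth-fragmentation equation
$$\partial_t n + \partial_z\!\big(V(z)(1+\beta(t))\,n\big) = Q(n) - \ell(t)\,n,
\qquad n(t,0)=0,$$
where $V(z)$ is either a constant or the Gompertz law
$V(z) = r z \log(b/z)$ (growth stalls at the maximal size $b$), and
$Q$ is the binary division operator
$Q(n)(z) = 4a(2z)n(2z) - a(z)n(z)$: a mother of size $2z$ yields two
daughters of size $z$, at frequency $a(z)$ (constant, or
$a\,\mathbf 1_{z \ge z_0}$ so the smallest cells cannot divide).
Division conserves the total tumor mass $\mu_1 = \int z\,n\,dz$ while
increasing the cell count $\mu_0 = \int n\,dz$. The kill rate
$\ell(t) = \int_\Omega \delta(x)\,c(t,x)\,dx$ is delivered by the
effector cells weighted by a Gaussian kernel $\delta$ centered on the
tumor; the growth enhancement $\beta(t) = \int_\Omega b_1(x)\,c_r(t,x)\,dx$
is contributed by protumor cells.

Absent immune pressure the population grows like $e^{\lambda t}$ with
size profile $N(z)$, the leading eigenpair of the growth-division
operator. For constant $V$ and $a$ the eigenvalue is exactly
$\lambda = a$, and replacing $V$ by $V(1+\beta)$ only dilates the
profile, $N_\beta(z) = N_1(z/(1+\beta))/(1+\beta)$. `leading_eigenpair()`
computes the pair by a power method: iterate the (linear) stepper,
renormalize to unit mass, and read the growth rate off the per-step mass
ratio. Because the stepper is explicit Euler, the per-step ratio is
$1 + \Delta t\,\lambda_h$, and the estimator inverts that relation; a
raw logarithmic rate would be biased low by
$O(\Delta t\,\lambda^2)$ — several percent at practical steps — while
the inverted estimator is exact for the discrete operator.

**Immune cells.** Effector ($c$), protumor ($c_r$) and, under therapy,
exhausted ($c_a$) concentrations live on the unit disc $\Omega$ and all
drift up the gradient of a chemotactic potential $\phi$ while diffusing
(shared $\chi$ and $D$), with absorbing (Dirichlet) boundary — immune
cells far from the tumor are not activated. The potential solves the
quasi-static Neumann problem $-\nabla\cdot(K\nabla\phi) = f(\mu_1)\sigma$
with the Michaelis–Menten response $f(\mu_1) = \mu_1/(\eta+\mu_1)$.
Effectors are recruited homogeneously at rate $g(\mu_1)S$ (linear
$g(\mu_1)=\mu_1$ by default, quadratic optionally) and die at rate
$\gamma$; they are suppressed by contact with protumor cells
($k_c c c_r$) and converted to the protumor pool near the tumor
($k_r I \theta c$, with $\theta$ a Gaussian kernel). Protumor cells are
recruited from three peripheral source spots $S_r$ and from conversion,
both gated by the cytokine level $I$, and die at rate $\gamma_r$.

**Cytokines.** The lumped immunosuppressive signal obeys
$\partial_t I = \psi(\mu_1) - \tau I$ with the threshold law
$\psi(\mu_1) = \bar\psi\,(\mu_1 - m)_+$: protumor mechanisms switch on
only once the tumor mass exceeds the critical mass $m$, which encodes
the inflammation state of the environment.

## Discretization and numerical choices

* **Size grid.** Uniform finite volumes on $[0, z_{\max}]$, first-order
  upwind transport (the growth velocity is nonnegative), explicit Euler
  with the combined positivity bound
  $\Delta t \le 0.9/(\max V(1+\beta)/h + a + \ell)$. The binary gain
  term $4a(2z)n(2z)$ is linearly interpolated onto the grid and then
  corrected by a single multiplicative factor so the discrete first
  moment of $Q$ vanishes *exactly*: mass conservation under division is
  a structural property of the model, not an approximation target.
* **Size truncation.** For the Gompertz law the domain is $[0,b]$. For
  constant growth the half-line must be truncated; the generic default
  is ten times the support of the initial datum, with the outflowing
  mass accumulated and a warning if it exceeds $10^{-6}$ of the tumor
  mass. The built-in constant-coefficient scenario uses
  $z_{\max} = 12$ with 256 cells instead: the asymptotic profile decays
  on the scale $V/a$ (about $0.15$ size units at $a = 4$), and an
  under-resolved profile quietly *lowers* the discrete eigenvalue — on a
  coarse $[0,50]$ grid an aggressive tumor can appear controlled for
  purely numerical reasons.
* **Disc geometry.** Cartesian cells on $[-1,1]^2$ masked to the unit
  disc (staircase boundary); cells whose center lies inside are kept.
  A one-dimensional radial reduction is ruled out by the three-spot
  protumor source. Dirichlet values are imposed through ghost values at
  mask faces; the Neumann potential uses a zero-flux closure.
* **Transport splitting.** Explicit face-upwind advection (positivity
  under a CFL bound reported by `advection_stable_dt()`), reactions with
  explicit gains and *implicit* cell-local losses, then backward-Euler
  diffusion via a cached sparse Cholesky factor. Every substep is
  monotone, so nonnegativity holds at machine precision throughout.
* **Elliptic compatibility.** The Neumann problem is solvable only for
  zero-mean sources, but the Gaussian $\sigma$ is positive. The source
  is projected to zero mean before solving — the projection subtracts a
  spatial constant, which does not alter the gradient that drives the
  drift — and the gauge is fixed by a zero-mean constraint in a bordered
  linear system. The solver asserts the projection before factorizing.
* **Splitting order.** Each step: moments, potential (re-solved every
  step), immune fields, cytokine (exact exponential update for frozen
  $\mu_1$), tumor density. The kill rate and enhancement are evaluated
  on start-of-step fields, consistent with the first-order splitting
  error.
* **Blow-up proxy.** Escape is asymptotic; integration halts once
  $\mu_1 > 10^6\,\mu_1(0)$ (configurable) and the outcome classifier
  labels a run *escape* when $\mu_1$ exceeds $10^3$ times its initial
  value while still increasing, *equilibrium* when the trailing relative
  slope stays below $10^{-5}$.

## Parameters: what is reference data and what is configuration

The simulation data of the reference setup fix $A = 1$, $\xi^2 = 0.02$
(kill kernel), $A_\sigma = 0.002$, $\xi_\sigma^2 = 0.05$
(chemoattractant source), $a = 0.8$, $V = 0.616$, $r = 0.616$, $b = 10$,
$\chi = 0.864$, $S = 5$, $\gamma = 0.18$, the initial datum
$n_0 = \mathbf 1_{[0.125, 5]}$ with immune-free initial fields, the
threshold $z_0 = 1$, and the therapy protocol (pulses of length 1 every
7 time units, drug decay rates $0.05$ and $0.0105$, exhausted fraction
$\alpha = 0.5$, reference doses $q = 2$ and $q_2 = 0.12$). The reduced
ODE scenario fixes $V = 0.616$, $\delta = 1$, $S = 1.5$, $k_r = 1.25$,
$k_c = 0.1$, $m = 2$.

Everything else is package configuration, carried with a `"default"`
provenance flag in every run manifest. The defaults were chosen once so
that the model exhibits its characteristic regimes, and they encode a
definite mechanistic picture:

* $D = 0.05$, $K = 10^{-3}$, $\eta = 1$: with the reference $\sigma$
  amplitude, $K = 10^{-3}$ makes the chemotactic drift ($\sim 0.1$–$1$
  length/time) comparable to diffusion, so protumor cells recruited at
  the peripheral spots actually reach the tumor. With a weak drift they
  never would, and the protumor arm would be spatially inert.
* $\xi_\theta^2 = 0.08 > \xi^2$: the conversion zone is broader than the
  kill zone. Quasi-steady analysis then caps the deliverable kill rate
  at a finite value $\sim (S\tau/k_r)\int \delta/\theta\,dx$ however
  large the tumor grows, which is what makes escape possible at all.
* $k_c = 2 \gg k_r = 0.3$: contact suppression, not conversion, is the
  dominant drain on effectors. This matters for therapy: the suppression
  flux $k_c c c_r$ feeds the exhausted pool (fraction $\alpha$) and is
  therefore partially recoverable by reactivation, while the conversion
  flux is lost to the protumor side for good. With conversion dominant,
  reactivation therapy would be structurally futile.
* $m = 0.12$: placed between the protumor-free residual masses at
  $a = 0.8$ ($\approx 0.056$) and $a = 4$ ($\approx 0.29$). A mild tumor
  is pushed below the critical mass, the cytokine relay shuts off and a
  protumor-free equilibrium establishes; an aggressive tumor keeps the
  relay on, suppression caps the kill rate below $\lambda = a$, and the
  mass runs away. The critical mass is the bifurcation dial: the smaller
  $m$, the smaller the division rate at which escape begins.
* $\gamma_r = \tau = \bar\psi = 1$, $\gamma_a = \gamma$,
  $S_r$: three spots of amplitude 2 at radius $0.7$, scaled by $1/5$;
  $A_{b_1} = 0.1$, $\xi_{b_1}^2 = 0.02$.

With these defaults the constant-coefficient family reproduces the full
phenomenology: equilibrium at $a = 0.8$ with
$\bar\mu_c \to \lambda$ and vanishing protumor burden, escape at
$a = 4$, therapy rescue that depends on dose and timing, and a combined
regimen that succeeds where both mono-therapies fail at the same doses.

One regime is knowingly not reproduced: in the Gompertz family the
eigenvalue is division-limited ($\lambda \lesssim 1.6$ for the reference
$r$, $b$, $z_0$, for *any* $a$), which is below the suppressed kill cap
of the calibrated defaults, so the aggressive Gompertz tumor settles in
a cytokine-persistent three-population state rather than escaping.
Forcing escape there would require either a much stronger growth
enhancement — whose transient collapses the CFL time step by orders of
magnitude — or a suppression strong enough to break the therapy regime.
We consider the constant-coefficient family, where $\lambda = a$ is
unbounded, the appropriate setting for studying the escape transition,
and the Gompertz family the setting for size-profile effects.

## The reduced ODE model

Dropping space and taking constant $V$, $a$ yields five ODEs for
$(\mu_0, \mu_1, c, c_r, I)$ (`ode_rhs()`). Three equilibria exist in
closed form (`ode_equilibria()`): the healthy state $H = 0$ (always
linearly unstable — eigenvalue $a > 0$: any tumor seed grows); the
protumor-free state NP with
$\mu_1^{NP} = \gamma a/(\delta S)$, admissible while
$\mu_1^{NP} \le m$ and then always stable, with damped return for
$\gamma > 4a$ and oscillatory return for $\gamma < 4a$; and the
three-population state P, whose mass is a rational function of the
competitiveness ratio $x = a/\delta$. The threshold
$X_2$ (the positive root of $S - Q_1 x - Q_2 x^2$) and the boundary
$mS/\gamma$ partition the $x$-axis into admissibility regimes; beyond
the last admissible interval the mass can only blow up. The printed
closed forms correspond to unit $\bar\psi$; the implementation
generalizes them by scaling $Q$, $Q_1$, $Q_2$ with $\bar\psi$, verified
by substitution into the right-hand side. The P-state Jacobian has no
usable closed form, so its spectrum is computed from a central
finite-difference Jacobian. Integration uses `lsodar` with a root
function implementing the blow-up stop.

## Equilibrium-mass prediction

At a steady state with no growth enhancement the kill rate must balance
the Malthus rate, $\int \delta C\,dx = \lambda$. For a frozen tumor mass
the stationary immune fields solve linear elliptic systems (cytokines at
their fixed point $\psi(\mu_1)/\tau$); the $C$–$C_r$ coupling is
resolved by damped fixed-point iteration and the scalar constraint is
bracketed from zero for its smallest positive root
(`predict_equilibrium_mass()`). The predictor and the long-run
simulation are two independent computations of the same number; they
agree to well within 10% at the reference resolutions, and the package
tests hold them to that.

## Therapy

Drug effects follow pulsed linear kinetics
$\partial_t T = \kappa(t) - d\,T$ with $\kappa$ the on/off protocol;
`drug_step()` subdivides each stride at pulse edges and applies the
exact exponential update piecewise, so the drug state is independent of
the simulation step size. Reactivation returns exhausted cells to the
effector pool at rate $T_{\text{react}}$ (and appears as a sink in the
$c_a$ equation); blockade multiplies both cytokine-gated recruitment
terms by the clamp $\max(0, 1 - T_{\text{block}})$ — recruitment can be
shut off but never reversed. In combination both act simultaneously and
the $c_a$ equation keeps its reactivation sink; this literal
superposition of the two single-therapy systems is an interpretation
the package documents rather than a unique reading.

## Problem sizes and what the tests show

The package tests run the coupled model at $64\times 64$ spatial cells
with 256 size cells for the equilibrium/escape and predictor checks, and
at $32\times 32$ with 128 size cells for the therapy sweeps; the
eigenvalue checks use 400 size cells. These resolutions were chosen as
the point where the checked quantities (eigenvalue error, kill-rate
balance, predictor gap) are comfortably inside their tolerances at
desk-scale runtimes; halving the cell size changes the monitored
integrals at first order, as the grid-convergence test verifies.

The simulations are fully deterministic — identical configurations give
bit-identical series, which the round-trip test asserts on the written
CSV. What the synthetic scenarios do *not* emulate is any of the
biology beyond the model's structure: parameters are dimensionless and
uncalibrated, the disc is an idealized tissue, and passing tests show
internal consistency of the scheme and the analysis, not agreement with
experimental tumor growth data.

## Known limitations

* First-order (in space and time) transport schemes: profiles are
  diffused near steep fronts; eigenprofile comparisons carry $O(h)$
  tolerances.
* The staircase disc boundary limits the elliptic and Dirichlet
  accuracy to first order near the rim.
* The Gompertz-family escape regime is not reachable under the single
  default parameter set (see above).
* Scalar potential diffusivity only; a matrix-valued $K$ (anisotropic
  tissue) is out of scope.
* General fragmentation kernels are not implemented; the architecture
  assumes binary division.
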