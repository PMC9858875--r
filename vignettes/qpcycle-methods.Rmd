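---
title: "Methods: a multiscale quiescent/proliferating population model driven by cell-cycle kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a multiscale quiescent/proliferating population model driven by cell-cycle kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcycle)
```

## The model

`qpcycle` simulates a tissue in which dividing cells move between a
*proliferating* compartment, structured by age $a$ (time since the last
division), and an unstructured-in-age *quiescent* ($G_0$) compartment.
Writing $p(a,t)$ and $q(a,t)$ for the two densities, the macroscale is

$$
\begin{aligned}
\partial_t q &= \chi(a, x_1(a))\,p - (\gamma(N) + \mu_q(a))\,q,\\
\partial_t p + \partial_a (g(a)\,p) &= \gamma(N)\,q -
  (\tau(a) + \chi(a, x_1(a)) + \mu_p(a))\,p,
\end{aligned}
$$

with the division (renewal) boundary condition
$g(0)\,p(0,t) = 2\int_0^{a^\star} \tau(a)\,p(a,t)\,da$ — each division
removes the mother at age $a$ and injects two newborns at age $0$ — and
$N(t) = \int_0^{a^\star} (q+p)\,da$. Quiescent cells do not age, so the
$q$ equation has no transport term.

The transition rates are saturating Hill laws:

* $\gamma(N) = \nu\,\theta^\kappa/(\theta^\kappa + N^\kappa)$ — re-entry
  from quiescence, shut down by crowding;
* $\tau(a) = \rho_1\,a^{\gamma_1}/(\rho_2^{\gamma_1} + a^{\gamma_1})$ —
  division, negligible until a minimum age and saturating at $\rho_1$;
* $\chi(a, x_1) = \sigma_1\,
  \frac{\sigma_2^{\gamma_2}}{\sigma_2^{\gamma_2} + x_1^{\gamma_2}}\,
  \frac{\sigma_3^{\gamma_3}}{\sigma_3^{\gamma_3} + a^{\gamma_3}}$ — exit
  to quiescence, available only to young cells ($a \lesssim \sigma_3$,
  the commitment age) whose Cyclin D-CDK4/6 level $x_1$ is still below
  the restriction-point threshold $\sigma_2$.

The microscale is a four-protein cell-cycle network — $x_1$ = Cyclin
D-CDK4/6, $x_2$ = E2F, $x_3$ = Rb, $x_4$ = p21 — integrated over age from
the newborn state $(0,0,0,0)$ at a fixed growth-factor level
$g_f = 1/(1 + k_t N)$. The loop closes in both directions: $N$ sets
$g_f$, $g_f$ drives Cyclin synthesis, and the resulting age profile
$x_1(a)$ gates the quiescence rate $\chi$.

## Parameter choices

Tabulated constants with literature point values are used as printed: the
twenty cell-cycle constants, $\theta = 9.5\times 10^4$, $\kappa = 1$,
$k_t = 1.8\times 10^{-9}$, $\sigma_3 = 16$ h. Constants given only as
ranges are fixed once at representative values: $\nu = 0.55$ (range
0.3–0.8), $\rho_1 = 0.5$ (0.05–1), $\sigma_1 = 0.9$ (0.8–1), Hill
exponents $\gamma_1 = 10$, $\gamma_2 = \gamma_3 = 5$ (ranges 5–10).
Per-day rate constants are used numerically as-is on the hour-based grid;
the config schema records this convention and performs no conversion.

Two constants required a mechanistic decision because the available point
values are inconsistent with the model's own kinetics:

* **Restriction threshold $\sigma_2$.** Under the cell-cycle constants,
  Cyclin synthesis is capped at $k_{1s} = 0.155$ uM/h while its
  Michaelis degradation reaches $k_{1d}\,x_1/(k_1 + x_1)$, so $x_1$ can
  never exceed $\approx 0.155$ uM at any growth-factor level (its
  high-$g_f$ plateau is $\approx 0.118$ uM). A threshold at $0.35$ uM
  would therefore never be crossed and the microscale would have no
  effect on the population at all. We place $\sigma_2 = 0.05$ uM, about
  40% of the high-$g_f$ plateau: growth-factor-rich cells pass the
  restriction point (low $\chi$), starved cells do not.
* **Division half-age $\rho_2$.** $\tau$ is an age law ("almost zero
  until a minimum age"); we center it at $\rho_2 = 35$ h, a mammalian
  cell-cycle length comfortably inside the maximal age
  $a^\star = 50$ h.

With these choices the three scenario presets reproduce the behavior
they are meant to display (homeostasis, extinction, uncontrolled
growth); the tests and the acceptance script compute all quantitative
claims.

One qualitative caveat: at a constant high $g_f$ the Cyclin trajectory
$x_1(a)$ rises monotonically to its plateau rather than pulsing up and
back down within one cycle — the autonomous four-variable network with
these constants has no mechanism for late-age Cyclin degradation at
fixed $g_f$ (interior maxima do occur at low $g_f$, via p21). The
package therefore asserts the verifiable threshold behavior (crossing at
high $g_f$, sub-threshold at low $g_f$, response increasing in $g_f$)
rather than a pulse shape.

## Numerics

**Macroscale.** First-order upwind transport of $g(a)p$ (information
flows toward increasing age) with explicit Euler time stepping on the
shared uniform grid, default $\Delta a = 0.5$ h, $\Delta t = 0.02$ h,
which satisfies the CFL bound $\Delta t\,\max g/\Delta a \le 1$ with a
large margin; configurations violating CFL are rejected before any
computation. The renewal value feeds the age-0 node directly
(Dirichlet-like), computed by composite trapezoid — the same quadrature
used for $N(t)$, so the discrete model is internally consistent. The
final age node uses the same one-sided flux as interior nodes; the $q$
equation is node-local everywhere. Discretization undershoots are
clipped at zero (warning below $-10^{-9}$; the exact solution is
nonnegative). Runs whose population exceeds $10^{300}$ stop and report
the blow-up time — legitimate output for the unstable scenario, not an
error.

**Microscale.** Classical RK4 with fixed internal substeps
($h \le 0.025$ h) recorded at the grid nodes. A single step per grid
interval is unstable here: the p21 phosphorylation term
($k_{41} = 50$/h) puts the locally linearized rate near $60$/h, far
beyond RK4's stability interval at $h = 0.5$. At $h = 0.025$ the
trajectory agrees with an adaptive LSODA reference to $<10^{-6}$
relative. By default the trajectory is recomputed every time step; an
optional cache skips the recompute while $|{\Delta}g_f|$ is below a
tolerance (at $10^{-4}$ this perturbs $N(t)$ by $<10^{-3}$ relative on
the homeostatic preset). Both a compiled (C++) and a pure-R engine
implement the identical scheme; they agree to $10^{-12}$ and the R
engine serves as the reference in tests.

## Steady states

Setting time derivatives to zero makes the quiescent balance algebraic,
$\bar q = \chi \bar p/(\bar\gamma + \mu_q)$, and leaves a linear age-ODE
for $g\bar p$ whose solution is $\bar p(0)$ times a survival profile
$\Pi(a)$. The effective per-age loss combines division, proliferative
death, and the fraction $\mu_q/(\bar\gamma+\mu_q)$ of switched cells
that die in quiescence instead of returning. Self-consistency of the
renewal boundary gives a scalar condition: the reproduction number
$R(\bar N) = (2/g(0))\int_0^{a^\star}\tau\,\Pi\,da$ must equal 1.
`solve_steady_state()` scans a bracket (64 log-spaced points) for sign
changes of $R-1$ — $R$ is continuous but not provably monotone in
$\bar N$, since $\chi$ couples through $x_1$ — solves each by bracketed
root-finding in $\log \bar N$, and reports all roots, assembling the
state at the largest.

A consistency decision matters here. The quiescence window is sharp —
$x_1$ crosses $\sigma_2$ within about half a grid cell — so the
continuous exponential-integral profile and the survival implied by the
upwind scheme differ enough to displace the root visibly. By default the
solver therefore uses the scheme's own product rule
$g_i p_i = g_{i-1} p_{i-1}/(1 + \Delta a\, L_i/g_i)$, which makes the
solved state an **exact fixed point of the simulator**: reinserting
$(\bar p, \bar q)$ reproduces $\bar N$ to machine precision, and the
solved $\bar N$ agrees with the long-time plateau of the homeostatic
preset to $\ll 1\%$. The continuous rule remains available
(`discretization = "continuous"`) and is validated against a refined
quadrature oracle.

## Stability

Perturbing around a steady state (with the population size in $\gamma$
and the microscale profile held at their steady values — the
linearization acts on the densities only) gives a linear
transport-reaction generator with the renewal boundary. Eliminating the
quiescent perturbation through its algebraic balance at spectral
parameter $\lambda$ turns the eigenvalue problem into a renewal
characteristic equation: $\lambda$ belongs to the renewal branch of the
spectrum exactly when the rank-one integral operator $U_\lambda$ with
kernel

$$G_\lambda(\zeta, a) = \frac{2}{g(0)}\,\tau(\zeta)\,P_\lambda(a),
\qquad
P_\lambda(a) = \frac{g(0)}{g(a)}\exp\Big(-\int_0^a
\Psi_\lambda(\xi)\,d\xi\Big),$$
$$\Psi_\lambda = \frac{1}{g}\Big[\lambda + \tau + \chi + \mu_p -
\frac{\bar\gamma\,\chi}{\lambda + \bar\gamma + \mu_q}\Big],$$

has spectral radius 1. The subtracted term is the return flow of
perturbed cells through quiescence. $r(U_\lambda)$ is positive, strictly
decreasing in real $\lambda$, diverges at the domain edge
$\lambda \downarrow -\min(\bar\gamma + \mu_q)$ when $\chi > 0$, and
decays to 0 as $\lambda \to +\infty$, so a unique real root $\lambda_0$
exists; the steady state is locally asymptotically stable iff
$r(U_0) < 1$ (equivalently $\lambda_0 < 0$). At $\lambda = 0$ the
kernel's survival factor is the steady profile, so $r(U_0) = R(\bar N)$
— in particular a solved nontrivial state sits exactly at $r(U_0) = 1$
and is reported as *marginal* under this frozen-population
linearization; the dynamically meaningful verdicts are those of the
trivial state (stable when $R(0) < 1$, unstable when $R(0) > 1$).

Numerically, $U_\lambda$ is discretized by the Nyström method with the
grid's trapezoid weights and its radius computed by power iteration
(dense eigendecomposition as fallback); with the upwind-consistent
survival factor, $\lambda_0$ is an exact eigenvalue of the discretized
generator `linearized_generator()` (upwind transport, trapezoid renewal
row, age-0 node eliminated algebraically), and `classify_stability()`
reports the agreement $|\lambda_0 - \max \mathrm{Re}\,\mathrm{eig}(C)|$
together with a half-spacing refinement of $r(U_0)$. Only real
$\lambda$ are scanned; the dominant eigenvalue is real, which the tests
assert on the discretized generator. The tests also confirm dynamic
consistency: the late-time decay slope of the dying scenario matches its
$\lambda_0$ well within a factor of two, as does the early exponential
growth of a sparse population under the unstable preset.

## Scenario presets

All presets use the published grid ($\Delta a = 0.5$, $\Delta t = 0.02$,
$a^\star = 50$, $g \equiv 1$) and Gaussian initial data
$q = p = k_0/\sqrt{2\pi\sigma^2}\,e^{-(a-\mu)^2/2\sigma^2}$ with
$k_0 = 10^6$, $\mu = 2$ h, $\sigma^2 = 200$ h².

* `case_5_1` (homeostasis): $\mu_p = \mu_q = 0.0014$, $\rho_1 = 1.0$,
  horizon 5000 h. $N$ grows, overshoots its equilibrium by about 10%
  (a damped renewal-delay oscillation; $g_f$ and $\gamma$ decline
  monotonically through the growth phase and rebound only by that small
  overshoot fraction), then plateaus at the solved steady state.
* `case_5_2` (extinction): $\mu_p = \mu_q = 0.020$, $\rho_1 = 0.20$,
  $\nu = 0.1$, horizon 5000 h. $R(0) \approx 0.83 < 1$; the population
  falls below 0.1% of its initial size by $t \approx 1160$ h and $g_f$
  saturates at 1.
* `case_5_3` (instability): as `case_5_1` with $k_{gf} = 10^{-4}$,
  which keeps Cyclin synthesis near-maximal regardless of $g_f$, holds
  $x_1$ above the restriction threshold at all ages past the first
  half-hour, and so disables the quiescence brake. No reproduction root
  exists in $[1, 10^{10}]$ and the trivial state is classified
  unstable ($\lambda_0 \approx +0.02$/h). The default horizon is 600 h:
  growth is exponential until $g_f$ itself falls to the $k_{gf}$ scale
  (around $N \sim 10^{12}$, $t \approx 1500$ h), beyond which the model
  re-saturates; the preset shows the unstable regime. `t_end` is
  configurable for all presets.

## What the tests do and do not show

The test suite runs entirely on synthetic inputs generated by the model
itself — Gaussian initial profiles, the preset parameter sets, and
closed-form or independently integrated references (constant-coefficient
transport, the linear Rb limit, LSODA, refined quadrature). Problem
sizes are the published grid for the scenario runs (125k–250k steps),
$\Delta a \le 0.01$ grids for quadrature-oracle comparisons, and
$\Delta a \in \{1.0, 0.5\}$ for the spectral refinement study. Passing
them shows the *scheme and spectral machinery* are implemented
correctly and are internally consistent; it does not validate the model
against tissue data. The model itself averages away cell-to-cell
variability, represents all growth signaling by a single
population-derived scalar, and ignores space, nutrients and DNA-damage
checkpoints.

## Known limitations

* First-order accuracy in $\Delta a$ and $\Delta t$; the sharp
  $\chi$-window makes coarse-grid equilibria sensitive to the
  discretization (which is why steady-state and stability calculations
  default to upwind-consistent quadrature).
* The stability verdict linearizes with $\gamma(N)$ frozen at
  $\gamma(\bar N)$; feedback of the perturbed population size through
  $\gamma$ and $g_f$ is deliberately outside the linearization, so
  nontrivial solved states are reported marginal rather than
  attracting, even when the full nonlinear dynamics converge to them.
* Only real spectral parameters are scanned; complex spectra enter only
  through the eigendecomposition of the discretized generator.
* The serializer handles constant $\mu_p$, $\mu_q$, $g$; age-dependent
  callables are supported in the engine but not in YAML configs.
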