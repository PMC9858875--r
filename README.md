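# qpcycle

Age-structured dynamics of quiescent and proliferating cell populations
coupled, in both directions, to a cell-cycle protein network.

Tissues maintain themselves by moving cells between a proliferating
compartment — cells progressing through the cycle toward division,
structured by age *a* (time since the last division) — and a quiescent
(G₀) compartment where cells neither age nor divide. Whether a young
proliferating cell may still retreat into quiescence is decided at the
restriction point by its Cyclin D-CDK4/6 level, which in turn is driven
by growth factors derived from the total population. `qpcycle` is for
modelers studying how this molecular gate shapes tissue homeostasis,
extinction, and runaway (tumor-like) growth.

## The model

Macroscale (densities `q(a,t)`, `p(a,t)`; total `N(t) = ∫(q+p) da`):

    ∂t q            = χ(a, x₁(a)) p − (γ(N) + μ_q(a)) q
    ∂t p + ∂a(g(a)p) = γ(N) q − (τ(a) + χ(a, x₁(a)) + μ_p(a)) p
    g(0) p(0, t)     = 2 ∫ τ(a) p(a, t) da          (renewal: 2 newborns/division)

with Hill-type rates: γ(N) = ν θ^κ/(θ^κ + N^κ) (re-entry from
quiescence), τ(a) = ρ₁ a^γ¹/(ρ₂^γ¹ + a^γ¹) (division),
χ(a, x₁) = σ₁ · σ₂^γ²/(σ₂^γ² + x₁^γ²) · σ₃^γ³/(σ₃^γ³ + a^γ³)
(exit to quiescence, gated by age and Cyclin). Microscale: a
four-protein ODE network (Cyclin D-CDK4/6, E2F, Rb, p21) integrated
over age at the growth-factor level g_f = 1/(1 + k_t N), closing the
feedback loop through χ.

The package provides

* `run_simulation()` — explicit upwind/RK4 simulator of the coupled
  loop (compiled core, pure-R reference engine), with the three
  case-study presets `scenario_preset("case_5_1" | "case_5_2" |
  "case_5_3")` (homeostasis / extinction / instability);
* `solve_steady_state()` — closed-form steady profiles plus a scalar
  root solve on the reproduction number R(N̄) = (2/g(0)) ∫ τ Π da;
* `classify_stability()` — spectral verdict from the renewal integral
  operator (Nyström discretization, spectral radius r(U_λ), dominant
  singular point λ₀), cross-checked against the eigenvalues of the
  discretized linearized generator;
* YAML configs, CSV/JSON exports and a thin CLI
  (`inst/cli/qpcycle.R` with subcommands `run`, `steady`, `stability`,
  `fixtures`).

## Worked example: extinction and its spectral explanation

```r
library(qpcycle)

res <- run_simulation(scenario_preset("case_5_2", t_end = 2500))
res
#> Coupled simulation over 2500 h (125001 recorded points)
#>   N: 1.11176e+06 -> 1.91977 cells; g_f: 0.998 -> 1; gamma(N): 0.007872 -> 0.1

which.max(res$N <= 1e-3 * res$N[1])  # first index below 0.1% of N(0)
res$times[58117]
#> [1] 1162.32

cfg <- scenario_preset("case_5_2")
ss <- solve_steady_state(cfg$grid, cfg$macro, cfg$cycle)
ss
#> Trivial steady state (no reproduction-number root in bracket)
#>   R(0) = 0.8270, gamma(0) = 0.1, g_f(0) = 1

classify_stability(ss, cfg$macro, cfg$cycle)
#> Stability report (N_bar = 0 cells): STABLE
#>   r(U_0) = 0.826963 (da/2 refinement: 0.808548)
#>   lambda0 = -0.00475395 /h; max Re eig(C) = -0.00475395 /h (|Im| = 0)
#>   |lambda0 - s(C)| = 2.87e-16
```

Under the extinction parameters each newborn produces on average
R(0) ≈ 0.83 < 1 newborns, so the empty tissue is stable; the dominant
spectral point λ₀ ≈ −0.0048/h predicts the simulated late-time decay
(the population needs ln(1000)/0.0048 ≈ 1450 h to lose three decades,
matching the observed first crossing at t ≈ 1162 h after the faster
initial transient). The growth-factor signal saturates at its maximum
value 1 as the tissue empties.

The homeostatic preset instead plateaus at the solved nontrivial steady
state (`case_5_1`: N̄ ≈ 2.979e8 cells, matching the 5000 h simulation to
better than 0.1%), and the low-`k_gf` preset (`case_5_3`) has no steady
state below 10¹⁰ cells and grows exponentially at λ₀ ≈ +0.02/h.

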