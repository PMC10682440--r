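# bcgrmc

Optimal impulsive dosing of Bacillus Calmette–Guérin (BCG) immunotherapy
for early-stage bladder cancer, built for researchers in computational
oncology and control who want a tested, reproducible implementation of the
whole pipeline: a nonlinear tumor–immune model with impulsive drug
instillations, multiobjective regimen search by three metaheuristics, a
data-driven lifted linear (Koopman/EDMD) surrogate with receding-horizon
dosing, and Monte-Carlo / Sobol robustness analysis of the resulting
regimens.

## The model and the design problem

Four states evolve on a dimensionless scale (populations in 1e6 cells,
BCG in 1e6 c.f.u, time in days):

    B'  = −μ₁B − p₁EB − p₂BTu          (instilled BCG)
    E'  = −μ₂E + αTi + p₄EB − p₅ETi    (effector cells)
    Ti' = −p₃ETi + p₂BTu               (infected tumor cells)
    Tu' = −p₂BTu + r(1 − βTu)Tu        (uninfected tumor cells)

An instillation at time τ jumps `B(τ⁺) = B(τ) + dose` and leaves the other
states untouched.  A dosing regimen is reparameterized as `(d, g, N)` —
dose per treatment, gap in days, number of treatments — and scored by the
multiobjective cost

    J = w₁ Σₖ Tu(k)/Tnorm Δt + λ·d·N + w_N|N − round(N)| + w_t Tu(k_t)/Tnorm

(cumulative tumor burden, cumulative drug, integer relaxation of N, and a
relaxed tumor-free endpoint; `Tnorm` is the maximal untreated tumor load
over the 100-day horizon).  The search runs over the clinical box
2.2 ≤ d ≤ 6.4, 5 ≤ g ≤ 10, 3 ≤ N ≤ 10 with particle swarm, simulated
annealing and ant colony optimizers, and the resulting open-loop regimen is
compared against a closed-loop controller: linear MPC on a 15-dimensional
lifted surrogate (delay embedding of the tumor output plus ten
thin-plate-spline radial basis features, fitted by extended dynamic mode
decomposition) with a Riccati terminal weight and box-constrained
quadratic programs, applied impulsively to the nonlinear plant every
5 days.

## Worked example

Score the weekly-like reference regimen (dose 5.46, every 5 days, 10
treatments), simulate it, and probe its robustness to patient variability:

```r
library(bcgrmc)

w <- cost_weights(tu_norm = untreated_tumor_max())
cost <- evaluate_cost(dosing_scheme(5.46, 5, 10), weights = w)
round(attr(cost, "breakdown"), 2)
#>           stage            dose integer_penalty        terminal
#>           33.35           54.60            0.00            0.18
round(unclass(cost), 1)
#> [1] 88.1

tr <- simulate_bcg(schedule = build_input_signal(dosing_scheme(5.46, 5, 10)))
tr
#> <bcg_trajectory> 10000 steps, dt = 0.01 d, horizon = 100 d
#>   impulses: 10 (total dose 54.6)
#>   final state: B=2.997e-24 E=0.00818 Ti=0.006305 Tu=2.818e-05
settling_time(tr)
#> [1] 20.43

run_uncertainty(build_input_signal(dosing_scheme(5.46, 5, 10)),
                uncertainty_spec("parameters", seed = 1))
#> <uncertainty_result> parameters mode, 200 runs (0 unsettled)
#>   settling time: mean 20.74 d, sd 3.211 d
```

Reading: the regimen costs 88.1 units — 33.4 of accumulated tumor burden,
54.6 of drug, a negligible terminal term because the endpoint is met — and
drives the tumor below 1% of its initial load after 20.4 days.  Across 200
simulated patients with ±10% rate variability the clearance time spreads
to 20.7 ± 3.2 days; under measurement-level uncertainty of the initial
state instead, the spread collapses to ±0.04 days.

Regimen search, surrogate fitting and closed-loop control follow the same
pattern (`optimize_regimen()`, `generate_training_data()` +
`fit_centers()` + `fit_koopman()`, `run_receding_horizon()`); the
`run_all()` driver chains every stage from one master seed, and
`inst/cli/bcgrmc.R` exposes each stage as a shell command.

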