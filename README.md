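# adcontrol

Uncertainty-aware control of biogas production from anaerobic
co-digestion of heterogeneous waste streams.

Centralized co-digestion plants feed food waste (FW), agricultural waste
(AW) and municipal solid waste (MSW) into one digester. Two things make
the biogas rate hard to hold at a target: the biochemical composition of
each delivered load is uncertain (waste is usually characterised only by
elemental analysis), and the upstream supply drifts seasonally. This
package implements the full data-driven chain for that problem, for
process engineers and researchers in waste valorisation and bioprocess
control:

1. **Composition inference** — estimate mass fractions of carbohydrate,
   lipid, protein and lignin from a sample's C/H/O/N ultimate analysis by
   the simplex-constrained least squares

       min ½‖Ax − b‖²   s.t.  Σxᵢ = 1,  xᵢ ≥ 0,

   where the columns of `A` are elemental mass fractions of reference
   compounds (solved exactly by support enumeration).
2. **Feed distribution model** — weighted Gaussian kernel density
   estimates of composition per waste type, with simplex-respecting
   sampling.
3. **Digester simulator** — ADM1 (Anaerobic Digestion Model No. 1): a
   33-state mechanistic model of hydrolysis, acidogenesis, acetogenesis
   and methanogenesis in an ideally mixed reactor with gas headspace, at
   the standard mesophilic benchmark parameterisation, run in semi-batch
   mode. Implemented in C++ with algebraic pH and dissolved-H₂ solves
   (the benchmark DAE practice); COD and nitrogen balances close to
   ~1e-10 relative.
4. **Control** — the digester as a finite-horizon MDP whose state is two
   consecutive biogas observations (level + slope):
   * finite-horizon **backward dynamic programming** for short-term
     target tracking (Bellman recursion `u*ₜ(s) = minₐ {cₜ(s,a) +
     E[u*ₜ₊₁(s′)]}` on a transition model estimated from rollouts),
   * a tuned discrete **PID** baseline,
   * **policy mirror descent** for long-term robust production with feed
     storage tanks, using the closed-form KL update
     `π_{k+1}(a|s) ∝ exp{(log π_k − η_k Q_{π_k}(s,a)) / (η_k τ_k + 1)}`.
5. **Metrics** — accuracy (MAE), precision (CoV across runs), and lag
   (dynamic time warping loss).

A four-term long-horizon cost drives the robust-production case:

    cost = w₀(y⁺ − y*) + w₁‖y* − y⁻‖² + w₂ F_T + w₃ Δx

(mild penalty above the demand target `y*`, dominant quadratic penalty on
shortfall, throughput-proportional operating cost, storage-overflow
penalty `Δx`).

## Worked example

```r
library(adcontrol)

# 1. compositions from elemental analysis (synthetic 268-record table)
rec   <- read_elemental_csv(system.file("extdata/elemental_synthetic_268.csv",
                                        package = "adcontrol"))
comps <- estimate_dataset(rec, build_basis_matrix())
round(head(comps[, c("x_sugar", "x_lipids", "x_proteins", "x_lignin",
                     "residual")], 3), 3)
#>   x_sugar x_lipids x_proteins x_lignin residual
#> 1   0.412    0.264      0.271    0.054    0.000
#> 2   0.480    0.189      0.331    0.000    0.002
#> 3   0.391    0.316      0.229    0.064    0.000

# 2. per-type KDE feed models, and one food-waste composition draw
models <- fit_feed_models(rec)
set.seed(7)
draw <- kde_sample(models$FW, 1)
round(as.numeric(draw[1, 1:4]), 3)
#> [1] 0.424 0.281 0.292 0.003     # carb, lipid, protein, lignin

# 3. ten days of semi-batch digestion at 60 m3/d total feed
comp <- as.list(draw[1, 1:4])
run  <- run_semibatch(adm1_initial_state(),
                      list(flows = c(20, 20, 20),
                           comps = list(comp, comp, comp)),
                      horizon = 10)
round(run$biogas_rate)
#>  [1] 2559 2895 3028 3042 3016 2993 2981 2974 2970 2968   # m3/d
```

The first rows of `comps` are inferred compositions on the simplex with
their fit residuals (a residual of 0.002 means the sample's elemental
vector is 0.2% away from the best convex combination of the reference
compounds). The drawn FW load is lipid-rich (28%), and feeding it at
60 m³/d settles the digester near 3000 m³ biogas per day.

Training and comparing controllers (several minutes):

```r
cfg <- shortterm_config()
env <- digester_env(models[c("FW", "AW", "MSW")], cfg$action_grid,
                    cfg$state_grid, cfg$horizon, target = cfg$target,
                    cost_kind = "tracking")
dp <- backward_dp_sampled(env, cfg$target, n_episodes = 80, seed = 2)
ex <- run_shortterm_experiment(env, dp, pid_default_config(),
                               cfg$target, n_runs = 20, seed = 3)
ex$improvement   # paired (PID - DP)/PID on mae, cov, dtw — positive = DP wins
```

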