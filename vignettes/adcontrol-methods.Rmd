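---
title: "Methods: uncertainty-aware control of anaerobic co-digestion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: uncertainty-aware control of anaerobic co-digestion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its models and the design
choices behind them. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The problem

A centralized co-digestion plant feeds three waste streams — food waste
(FW), agricultural waste (AW), municipal solid waste (MSW) — into one
anaerobic digester and must hold the biogas production rate at a target
despite two layers of uncertainty: the biochemical composition of each
delivered load is unknown (waste is usually characterised only by
elemental analysis), and the upstream supply varies seasonally. The
package covers the full chain: composition inference from elemental data,
a probabilistic feed model, a mechanistic digester simulator, and three
control policies scored by accuracy (MAE), precision (CoV across runs) and
lag (DTW loss).

## Composition from ultimate analysis

A sample's dry-basis C/H/O/N mass fractions `b` are modelled as a convex
combination of four reference compounds with elemental columns `A`
(carbohydrate as anhydroglucose C6H10O5, lipid as glyceryl tripalmitate
C51H98O6, protein as the average residue C4.43H7O1.44N1.16, lignin as a
softwood-type C10H11.6O3.9 monomer). With four unknowns, four elemental
balances and the closure constraint the system is overdetermined, so the
composition is the solution of

    min 1/2 ||A x - b||^2   s.t.  sum(x) = 1,  x >= 0.

Choices made here:

* **Reference formulas.** Published waste characterisations rarely state
  their elemental coefficients; the defaults above are standard biomass
  conventions, are logged with every basis object, and are configurable in
  `build_basis_matrix()`. The framework's behaviour, not the exact basis,
  is the point.
* **Ash handling.** Raw C+H+O+N sums below 1 are renormalised to an
  ash-free basis before solving (otherwise the closure constraint is
  inconsistent with ash-bearing data). A raw-basis flag exists.
* **Solver.** With only four variables the program is solved *exactly* by
  support enumeration: all 15 supports, an equality-constrained KKT solve
  each, keep the feasible candidate with the lowest objective. No
  iterative QP, no convergence tolerance. The test suite checks it
  against a two-stage simplex grid search at 1e-3 resolution.
* **Degenerate records** (all-zero rows) are flagged, never dropped
  silently, and excluded from downstream density fitting.

## The feed distribution model

Per waste type, compositions are modelled by a weighted Gaussian KDE in
the three free coordinates (carbohydrate, lipid, protein; lignin is the
simplex remainder — using all four would make every kernel covariance
singular). Category weights from the input table weight the kernels.
Bandwidth is Scott's rule at the weighted effective sample size
`(Σw)²/Σw²`; the underlying study does not state its rule, so this default
is logged and overridable. Sampling is by kernel choice plus Gaussian
noise with rejection outside the simplex — rejection preserves relative
density where clipping would pile mass on the faces (a clipping mode
exists but is off by default). Compositional closure makes
carbohydrate–protein and carbohydrate–lipid correlations negative in the
fitted models, which the tests assert on the packaged synthetic dataset.

## The digester model

The reactor is ADM1 — the standard mechanistic description of anaerobic
digestion in an ideally mixed CSTR: disintegration, hydrolysis,
acidogenesis, acetogenesis, methanogenesis over 24 liquid-phase
components, 6 ion states, and a 3-component headspace (33 states in
total), with pH, free-ammonia and hydrogen inhibition and
temperature-corrected physical chemistry. The parameter set is the
published mesophilic benchmark parameterisation (35 °C, 3400 m³ liquid /
300 m³ headspace), all in one overridable list (`adm1_params()`).

Numerical choices:

* **No stiff-ODE library exists in this toolchain**, so the simulator uses
  the benchmark community's DAE reformulation instead: pH/ion speciation
  is solved algebraically from the charge balance every right-hand-side
  call (safeguarded Newton; the balance is strictly monotone in H+), and
  dissolved hydrogen — by far the fastest state — is solved as a
  quasi-steady algebraic balance by bisection. What remains is non-stiff
  up to the headspace CO2 coupling (λ ≈ 1.6e3 d⁻¹), integrated with
  fixed-step RK4 at `dt = 1e-3` d (stability bound ≈ 2e-3 d). This is
  deterministic — identical inputs give bit-identical trajectories, which
  a test asserts.
* **Conservation by construction.** The inorganic carbon and nitrogen
  rates are computed as the negatives of the element totals of all other
  reaction rates, so COD, C and N balances close to integration accuracy;
  the acceptance suite requires ≤ 1% closure over 30 days and observes
  ~1e-10.
* **Feed mapping.** Stream compositions are mass fractions of total
  solids; each component enters ADM1 as its particulate pool scaled by a
  theoretical-oxygen-demand factor (1.19 / 2.87 / 1.42 kg COD per kg for
  carbohydrate / lipid / protein). A pure-COD basis would make biogas
  potential composition-invariant; the mass basis is what makes lipid-rich
  food waste the most productive stream, as the underlying study reports.
  Lignin routes to particulate inerts — ADM1 has no lignin pathway.
* **Semi-batch operation** is cycles of continuous feeding then batch
  reaction; the default feeding window is the whole 1-day interval (the
  simplest reading), with the split configurable. During feeding the
  liquid volume is constant (inflow = outflow).

## The control problem

The reactor is only partially observed. Rather than a POMDP belief state,
the MDP state is a *feature*: two consecutive daily observations of the
biogas rate, carried as (level, slope) — an invertible recoding of
(y_prev, y_curr) that lets the slope tolerate a much coarser grid (3 bins
against 10–15 level bins). Observations are window averages over the
control interval, not instantaneous rates (less aliasing from the
feeding cycle). Out-of-grid observations clamp to the boundary bin.
Actions are total-feed-flow levels split equally across the three streams
(0–200 m³ d⁻¹ in steps of 20 by default).

Costs: short-term tracking uses the per-step absolute error |y − y*_t|
(proportional to the MAE). The long-term cost has four terms — a mild
linear penalty on over-production, a dominant quadratic penalty on
shortfall, a throughput-proportional operating cost, and a storage
overflow penalty — with a single production value routed to exactly one
of the first two branches each step. Default weights (w0 = 1,
w1 = 100/y*, w2 = 0.5, w3 = 1.5) were sized a priori: the shortfall term
dominates (robustness is its stated purpose), the other two sit near 10%
of a typical tracking cost. Under these weights the cost-optimal policy
hedges about 1.5 process standard deviations above demand, which caps the
achievable demand-satisfaction rate near 90%; pushing it to 99+% requires
a still more shortfall-averse weighting (set `w1` higher), which is how
the reference study's headline rate should be read.

## Controllers

**Backward dynamic programming** (short-term). The finite-horizon Bellman
recursion is solved exactly on the discretised state space, from the
terminal stage backwards with zero terminal cost, minimising cost (the
reward-maximising form is the same recursion negated; one orientation is
fixed package-wide). The expectation over successor states comes from a
transition model estimated from exploration rollouts. Two estimators
exist:

* `"regression"` (default): next observation ~ quadratic response surface
  in (level, slope, commanded flow) with Gaussian residuals, fitted to
  walk-exploration episodes (persistent random walk on the action grid —
  the operating regimes a controller actually visits — with the first two
  steps of each episode discarded, where the window-average observation is
  still mixed with the instantaneous warm-start value). Stage costs are
  then closed-form folded-normal expected errors, and at run time the
  policy is a one-step lookahead at the *continuous* observation against
  the DP value table, removing feedback quantisation. This is the same
  Monte-Carlo transition data as the tabular route, distilled into a
  smooth estimator; at desk-scale budgets it is what makes DP competitive
  with — and better than — a fairly tuned PID.
* `"tabular"`: empirical transition frequencies with shrinkage toward a
  level-pooled model, assumption-free but data-hungry.

**PID baseline.** Discrete positional PID on the biogas error with output
clamping and integral anti-windup; the scalar flow command maps to the
nearest action-grid total with an equal-thirds mixing ratio. For fairness
the gains are fixed by a coarse grid search minimising MAE on a nominal,
uncertainty-free episode (`scripts/tune_pid.R`); the winning gains are the
package defaults.

**Policy mirror descent** (long-term). Starting from the uniform policy,
PMD alternates Q estimation with the closed-form KL-proximal update
π' ∝ exp{(log π − η Q)/(η τ + 1)} applied row-wise (max-subtraction
guards overflow; τ = 0 recovers classic multiplicative weights, which a
test verifies at machine precision). Q is estimated on-policy: stage-wise
every-visit Monte-Carlo or TD(0) for the finite-horizon form, or — the
long-term default — a *stationary* S×A table by discounted SARSA
(γ = 0.9), since routine production with a fixed demand is stationary and
a shared table gets twenty times the data per entry. Q entries never
visited in a row are imputed with the row mean of visited entries so the
exponential update neither rewards nor punishes untried actions. The
toy-MDP oracle tests check that both exact-evaluation PMD and backward DP
reach the brute-force optimum.

## Experiments and the synthetic world

The synthetic elemental generator draws per-type compositions from
Dirichlet distributions whose means encode the field's qualitative
picture (FW lipid/protein-rich; AW carbohydrate/lignin-dominated; MSW in
between), pushes them through the elemental basis, scales by a drawn ash
fraction and adds ~2% multiplicative noise. It emulates the *schema and
heterogeneity* of a literature ultimate-analysis compilation — not any
particular real dataset — so a green test establishes that the pipeline
recovers what this generator encodes, not that a specific real-world
distribution is reproduced. The packaged
`inst/extdata/elemental_synthetic_268.csv` (synthetic, as named) carries
268 records to mirror the size of the compilation the original study
used, which is not redistributable here.

Short-term experiments run paired DP/PID episodes under common random
numbers: all per-step composition draws are made at episode reset from
the episode seed, so both controllers face byte-identical uncertainty
(asserted per pair). Long-term episodes add sinusoid-plus-uniform-noise
supply per stream and three storage tanks with truncation (feed-limited
actions) and overflow accounting; a mass-bookkeeping invariant closes to
1e-9. Supply baselines (28/22/18 m³ d⁻¹) were chosen so that average
supply roughly sustains demand-level feeding; tank sizes hold one to two
weeks of supply.

Monte-Carlo counts default to desk scale in the tests (tens of episodes
against the study's 10³–10⁵) — the directional conclusions (DP better
than PID on all three metrics; high satisfaction with quiet tanks) are
what the scaled runs check, with the printed reference percentages kept
as context, not gates.

## Known limitations

* ADM1 here omits sulfur/phosphorus extensions, precipitation and
  temperature dynamics; cations/anions are fixed background parameters.
* The two-observation feature state is only near-Markov because the
  benchmark hydrolysis is fast (k_hyd = 10 d⁻¹, response within one
  control interval). With slow hydrolysis (~1 d⁻¹) a third of the feed
  response arrives a day late, the feature state loses the hidden
  particulate inventory, and both model-based DP and tabular DP degrade —
  a real limitation of the feature-state approximation, not of the
  implementations.
* The regression transition model is local to the explored operating
  band; extrapolation far outside the actuator range it was trained on is
  unreliable.
* The conditional-TD variant referenced by the PMD literature is not
  specified at implementation level; the estimator interface isolates
  this choice and the default (batch Monte-Carlo / SARSA) is documented
  as an approximation.
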