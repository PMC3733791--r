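# cyclefit

Bootstrap uncertainty analysis for limit-cycle ODE models.

Mechanistic models of biological oscillators — circadian clocks, the cell
cycle, metabolic and neuronal rhythms — are autonomous ODE systems
`dx/dt = f(x, p)` whose solutions of interest are limit cycles,
`x(t) = x(t + T)`. Their kinetic parameters `p` must be estimated from
periodic time-series data, and the predictions that matter most are
first-order responses to rate perturbations, in particular the relative
period sensitivities `∂ln T / ∂ln p` (dimensionless: fractional period
change per fractional parameter change). Because both the estimates and
the sensitivities depend strongly on measurement noise, `cyclefit` answers
the question modellers actually need answered: *which predicted responses
does my data support, and which are artifacts of the particular parameter
values I happened to fit?*

The pipeline, for people who fit oscillator models:

1. **Estimation by direct collocation.** The weighted least-squares fit
   `p* = argmin Σ_ij (x̂_i(t_j) − x_i(t_j, p))² / σ_ij²` is transcribed
   into a nonlinear program over piecewise Lagrange polynomials on Radau
   points (`N` finite elements of degree `K`: `N(K+1)·NEQ + NP` variables,
   plus a free period), with collocation, continuity and periodicity
   constraints. Because all states are measured, a periodic spline
   through the data provides a near-perfect warm start and the problem
   stays local.
2. **Parametric bootstrap.** Simulated measurements are redrawn from
   `N(x̃_i(t_j), σ_ij)` with `σ_ij = ξ·x̃_i(t_j) + η·max_j x̃_i(t_j)`
   and re-fitted `B` times; trials that fail or collapse to a steady
   state (where a period is undefined) are discarded and counted.
3. **Period sensitivities** per replicate, from the monodromy matrix and
   parametric variational equations via a bordered linear system, with an
   independent central finite-difference oracle for cross-checking.
4. **Practical identifiability.** A response is identifiable when ≥ 95%
   of its bootstrap distribution keeps one sign (a 5th–95th percentile
   interval rule is reported alongside), and reports from two candidate
   model structures can be compared for robust, structure-independent
   predictions.

## Worked example

The package ships a three-state Goodwin-type negative feedback oscillator
(Hill-repressed synthesis, n = 10, period ≈ 24 h) as its test fixture:

```r
library(cyclefit)

model <- goodwinFixture()
cycle <- findLimitCycle(model, x0_guess = c(0.1, 0.2, 0.3), T_guess = 24)
cycle
#> <limit_cycle>: period T = 23.815, residual 7.34e-11
#>   amplitudes: 0.5843, 0.5713, 0.5873

variationalPeriodSensitivities(model, cycle)
#> <period_sensitivity> (variational), T = 23.815
#>         a         b         c         d         e         g
#>  0.030040 -0.363373  0.030040 -0.363373  0.030040 -0.363373
```

The sensitivities sum to −1: every parameter of this fixture is a
multiplicative rate, so scaling all of them by λ rescales time and the
period exactly as `T/λ` — a structural identity the test suite uses as an
exactness check. Faster degradation (`b`, `d`, `g`, negative values)
shortens the period; faster synthesis (`a`, `c`, `e`) lengthens it
slightly.

Bootstrap with 15% relative measurement error on M = 20 samples:

```r
truth <- sampleTrueData(model, M = 20, cycle = cycle)
ens <- runBootstrap(model, truth, noiseModel(xi = 0.15, eta = 0.001),
                    B = 40, master_seed = 1)
ens
#> <bootstrap_ensemble> 'goodwin(n=10)': 40/40 converged (0 failed, 0 steady state)
#>   period: median 23.535 [22.318, 25.486]

classifyIdentifiability(ens, level = 0.95)
#> <identifiability_report>: 40 trials, level 0.95
#>  name param_lo param_median param_hi  sens_lo sens_median  sens_hi
#>     a   0.8364       1.0530   1.8470  0.01664      0.0282  0.03211
#>     b   0.1520       0.1677   0.1877 -0.43390     -0.3858 -0.32960
#>     ...
```

Read this the way a modeller would: parameter `a` is poorly constrained by
this data quality (5th–95th interval 0.84–1.85 around a truth of 0.95),
yet its period sensitivity keeps a consistent positive sign in 100% of
replicates — the *response* is a trustworthy prediction even where the
*parameter* is not. `percentileBand()` gives the matching trajectory
uncertainty bands, and `plotBand()` / `plotDistributions()` draw them.

A command-line driver covers the same pipeline from a shell
(`inst/cli/cyclefit.R`):

```sh
Rscript inst/cli/cyclefit.R fit \
  --model inst/extdata/goodwin.yaml \
  --data inst/extdata/goodwin_demo_M20.csv --out fit.json
Rscript inst/cli/cyclefit.R bootstrap \
  --model inst/extdata/goodwin.yaml --xi 0.15 --trials 200 --seed 1 \
  --out ensemble.json
Rscript inst/cli/cyclefit.R report --ensemble ensemble.json --out report.json
```

Runs are byte-reproducible for a fixed `--seed`; per-trial seeds are
derived with a counter-based scheme so serial and parallel execution
agree.

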