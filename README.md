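# rnaidose

Dose-effect modeling of RNA interference with physiological delays, for
quantitative biologists choosing siRNA dosages and for modelers studying
delay-induced oscillations in gene silencing.

RNAi silences a target gene by directing cleavage of its mRNA; the effect
saturates in the siRNA dosage, and overdosing wastes material and invites
off-target effects. `rnaidose` implements a two-stage gene-expression model
in which silencing adds a Hill-saturating degradation rate
`beta(S) = r S^n / (theta^n + S^n)` to the mRNA balance, together with two
lags — the silencing-processing delay `tau1` and the nuclear-export delay
`tau2`:

    M'(t) = km - dm M(t) - beta M(t - tau1)
    P'(t) = kp M(t - tau2) - dp P(t)

On top of the model the package provides:

* **Simulation** — a fixed-step RK4 method-of-steps integrator with
  cubic-Hermite delay lookups (`simulate_model()`), deterministic and
  bit-reproducible, plus limit-cycle feature extraction
  (`measure_limit_cycle()`).
* **Stability analysis** — closed-form thresholds `beta0` and `beta1`,
  crossing frequency `omega0 = sqrt(beta^2 - dm^2)`, critical delay
  `tau1* = arccos(-dm/beta)/omega0`, critical dosage, regime
  classification, characteristic roots by damped Newton search, the
  transversality sign, and the first-order Hopf period expansion
  `T = 2*pi/(omega0 + sigma)` (`classify_regime()` and friends).
* **Sensitivity** — forward sensitivity delay systems for every model
  parameter (`solve_sensitivity()`) and relative sensitivities of the
  oscillation's amplitude and period
  (`limit_cycle_relative_sensitivities()`).
* **Dosage selection** — minimization of
  `J(S) = Ps*S*T + integral of P(t)` over a dosage box by scan plus
  golden-section refinement, with backward costate integration and an
  adjoint gradient as the optimality check (`optimize_dosage()`,
  `solve_costate()`, `cost_gradient()`).

## Worked example

Classify the high-potency operating point, simulate it, and measure the
oscillation:

```r
library(rnaidose)
p <- rnai_params(km = 10, dm = 0.05, kp = 1, dp = 0.01,
                 r = 0.5062, theta = 10, n = 4, S = 30,
                 tau1 = 3.3594, tau2 = 1)
classify_regime(p)
#> Stability report
#>   beta = 0.500027 (beta0 = 0.0925753, beta1 = 0.499911)
#>   omega0 = 0.497521, tau1* = 3.35857, S_critical = 29.8598
#>   regime: hopf (transversality 1)

tr <- simulate_model(p, initial_condition(160, 10000), horizon = 600)
measure_limit_cycle(tr)
#> Sustained oscillation (24 peaks): period 12.633, amplitude M 157.28 / P 317.87
```

The silencing rate (0.50) sits on the Hopf boundary for this delay: the
equilibrium sheds a stable limit cycle whose measured period (12.633)
matches the linear-theory value `2*pi/omega0 = 12.629` to 0.03%. The
positive transversality sign certifies a genuine (supercritical) crossing.

Choosing a dosage for a low-potency silencer (`r = 0.02`) over a 60-unit
horizon with delays:

```r
pq <- rnai_params(r = 0.02, S = 30, tau1 = 2.5, tau2 = 1)
optimize_dosage(control_problem(pq, delayed = TRUE))
#> Optimal siRNA dosage: S = 30.60 (delay model)
#>   J = 675246 = siRNA 1836.11 + protein accumulation 673410
#>   adjoint gradient at optimum: -1.893e-05 (219 cost evaluations)
```

The optimum sits just past the Hill saturation knee — `beta(30.60) =
0.0198`, within 1% of the ceiling `r = 0.02` — beyond which extra siRNA
buys essentially no further silencing while its cost grows linearly. The
near-zero adjoint gradient confirms first-order optimality.

A thin command-line wrapper is installed at `inst/cli/rnaidose`
(subcommands `simulate`, `stability`, `period`, `sensitivity`, `optimize`;
YAML configuration, JSON reports).

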