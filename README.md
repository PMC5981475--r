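# hcukf

Online estimation of soft-tissue contact parameters from robotic
indentation streams, robust to contact-model error.

## The problem

Robotic palpation (e.g. in minimally invasive surgery) presses an
instrumented indenter into tissue and records displacement `d` and reaction
force `F` at every control step. The nonlinear Hunt-Crossley (H-C)
viscoelastic law

    F = K d^n + B d^n ḋ^p

relates them through a stiffness coefficient `K`, damping coefficient `B`,
and exponents `n`, `p` — quantities that vary by organ, tissue layer and
physiological state, and therefore have to be estimated online. `hcukf`
does this by joint state-parameter filtering: the state
`[d, ḋ, F, K, B, n, p]` is tracked by an unscented Kalman filter (UKF)
from the noisy `[d, F]` stream.

A plain UKF assumes its model is right. Under *contact-model error* —
wrong initial parameters, a simplified force law, or a transient modelling
fault — its estimates degrade badly. The package's core is an adaptive
strong-tracking variant (random-weighting strong-tracking UKF) that:

1. flags model error when the innovation's Mahalanobis distance
   `θ = Zᵀ Pȳ⁻¹ Z` exceeds a χ²-based threshold,
2. estimates the innovation covariance over a sliding window of `M` past
   innovations with random convex (flat Dirichlet) weights,
3. inflates the predicted state covariance by the trace-derived scaling
   factor `γ = (tr(B₀) − tr(R)) / tr(H P̄ Hᵀ)` (computed Jacobian-free via
   `Pȳ − R`), and
4. redoes only the measurement update with the inflated covariance.

When no error is detected the adaptive filter is bitwise identical to the
plain UKF.

## Worked example

Simulate the initial-error regime (true contact `K=10, B=1, n=2, p=1.05`;
filter initialized at `K=150, B=2, n=1, p=1`) and compare both filters on
the same noisy measurement stream:

```r
library(hcukf)
cfg <- scenario_preset("init_error", seed = 1)
ukf <- run_filter_on_scenario(cfg, "ukf")
rw  <- run_filter_on_scenario(cfg, "rwstukf")
print(ukf)
#> <hc_filter_run> UKF on scenario 'init_error' (300 steps)
#>   force-reconstruction error: mean 27.5858  max 309.1383  rmse 74.7186
#>   final parameters: K=6.9000 B=1.2141 n=2.3519 p=3.6253
print(rw)
#> <hc_filter_run> RWSTUKF on scenario 'init_error' (300 steps)
#>   force-reconstruction error: mean 0.8639  max 6.6199  rmse 1.4306
#>   final parameters: K=9.4051 B=0.0004 n=2.0691 p=9.9977
comparison_table(list(ukf = ukf, rwstukf = rw))
#>       metric       ukf   rwstukf
#> 1 mean_error  27.58581 0.8638819
#> 2  max_error 309.13833 6.6199478
#> 3       rmse  74.71863 1.4305851
```

The numbers are force-reconstruction errors in mN: the H-C law is
re-evaluated along the true trajectory with each step's parameter
estimates and compared with the true input force. The plain UKF spends
~150 steps digesting the wrong initialization (transient peak ~309 mN);
the adaptive filter detects the inconsistency early (here 7 corrections,
first at step 26), inflates its covariance, and converges within ~50
steps, cutting the error by more than an order of magnitude. Note the
damping pair: `B` and `p` are not separately identifiable at constant
velocity — only the combination `B·ḋ^p` matters, so their individual
values are arbitrary while the reconstructed force is accurate.

`scenario_preset()` also provides the `simplified` (mis-specified filter
dynamics) and `local_error` (transient prediction offset on steps 200-220)
regimes; `monte_carlo()` replicates any scenario over seeds. For measured
data, `read_indentation_csv()` ingests `time, displacement[, velocity],
force` records and `fit_indentation()` runs either filter on them.

A command-line front end ships at `inst/cli/hcukf`
(`simulate`, `fit`, `report` subcommands); see `?cli_main`.

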