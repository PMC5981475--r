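---
title: "Adaptive strong-tracking unscented Kalman filtering for Hunt-Crossley contact parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive strong-tracking unscented Kalman filtering for Hunt-Crossley contact parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcukf)
```

## The estimation problem

Robotic palpation presses an instrumented indenter into soft tissue and
records displacement $d$ (robot encoder) and reaction force $F$ (force
sensor) at each control step.  The Hunt-Crossley (H-C) law

$$F = K d^n + B d^n \dot d^{\,p}$$

describes the viscoelastic contact without the force discontinuities of
linear spring-damper models: $K$ is the stiffness coefficient
(mN$\cdot$mm$^{-n}$), $B$ the damping coefficient, and $n, p$ dimensionless
exponents on displacement and velocity.  Tissue properties change across
organs, layers and physiological state, so the four parameters must be
estimated *online* from the measurement stream.

`hcukf` treats this as joint state-parameter filtering.  The state stacks
the kinematics with the parameters,

$$x = [d,\ \dot d,\ F,\ K,\ B,\ n,\ p],$$

the transition integrates the (constant) velocity, re-evaluates the force
through the H-C law and carries the parameters (their evolution is modelled
by process noise), and the measurement $y = [d, F]$ selects two state
components, so the measurement map is exactly linear with the constant
selection matrix `hc_measurement_matrix()`.

## Filters

`ukf_step()` implements the standard unscented Kalman filter: the scaled
$2N{+}1$ sigma-point set (centre point plus symmetric pairs at the columns
of the Cholesky factor of $(N+\lambda)P$), the unscented time update with
process noise $Q$, and the measurement update with noise $R$.  Sigma points
are re-drawn from the predicted belief *after* $Q$ is added, before the
measurement update.  This choice makes the unscented moments exact for
linear dynamics (the filter reproduces the closed-form Kalman filter on
linear-Gaussian systems to $10^{-8}$ over 100 steps, one of the test-suite
oracles) and gives the identity $P_y - R = H \bar P H^\top$, which the
adaptive layer exploits.

`rwstukf_step()` adds the adaptation.  Each step:

1. runs the standard predict + update and forms the innovation
   $Z = y - \bar y$ with predicted measurement covariance $P_y$;
2. computes the Mahalanobis distance $\theta = Z^\top P_y^{-1} Z$ and
   declares contact-model error when $\theta > \theta_T$ (strictly; the
   boundary counts as consistent);
3. on detection, estimates the innovation covariance over a sliding window
   of the $M$ most recent innovations with *random weights*
   $B_0 = \sum_j v_j Z_{k-j} Z_{k-j}^\top$, where $v$ is a flat Dirichlet
   draw (uniform-spacings construction: non-negative, sums to one exactly,
   mean $1/M$, so the estimate is unbiased for the equal-weight window
   average while letting individual windows emphasise informative
   innovations);
4. computes the scaling factor from innovation orthogonality through traces,
   $$\gamma = \frac{\operatorname{tr}(B_0) - \operatorname{tr}(R)}
   {\operatorname{tr}(H \bar P H^\top)},$$
   with $H \bar P H^\top$ obtained Jacobian-free as $P_y - R$; and
5. inflates the predicted covariance $\bar P \leftarrow \gamma \bar P$ and
   redoes *only the measurement update* with sigma points re-drawn from the
   inflated prediction.

When no error is detected the adaptive step is bitwise identical to the
plain UKF step (same code path, no random draws), a property the test suite
asserts across whole scenarios with $\theta_T = \infty$.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `theta_T` | $\chi^2_2(0.99) \approx 9.21$ | detection threshold; the innovation is a 2-vector, so under a correct model $\theta$ is asymptotically $\chi^2$ with 2 dof |
| `M` | 4 | innovation-window length (steps) |
| `gamma_max` | 100 | per-step cap on $\gamma$; the raw trace ratio is unbounded at fault onset, and repeated detections still escalate geometrically |
| `var_max` | $10^4$ | eigenvalue ceiling on the belief covariance (see numerics) |
| `alpha, beta, kappa` | 0.01, 2, 0 | unscented-transform constants |

The window stores innovations from completed steps only: the current
$\theta$ uses the current innovation, but $B_0$ uses the stored window.
During startup (fewer than $M$ innovations) all available innovations are
used with a weight vector of matching length; detection is inactive until
at least one innovation is stored.  Whether the current innovation should
enter $B_0$ is ambiguous in the method's definition (the window indices run
over past steps); we exclude it.  Re-detection after the corrected update
is not iterated: one correction pass per step.

## Numerical choices

* **Clamping.**  After every update $K, B \ge 10^{-6}$ and
  $n, p \in [10^{-3}, 10]$.  The floors keep $d^n$ real when an update
  overshoots; the exponent ceiling stops a transiently unidentified
  exponent from overflowing $d^n$ in reconstruction.  Negative
  displacement is clamped to zero (no tension through the contact) and the
  velocity power uses $\mathrm{sign}(\dot d)\,|\dot d|^p$.
* **Scalar inflation and its ceiling.**  Inflation is scalar, as the trace
  form prescribes.  A scalar $\gamma$ also stretches directions the
  measurements cannot contract: with constant indentation velocity, $B$
  and $p$ enter the force only through $B\,\dot d^{\,p}$, so they are not
  separately identifiable, and consecutive detections would compound their
  variance without bound until $d^n$ overflows through the sigma points.
  The belief covariance is therefore clipped to eigenvalues in
  $[0, \mathtt{var\_max}]$ each step, identically for both filters.
* **Scaled solves and factorisations.**  After an inflation the innovation
  covariance can span $\sim$16 orders of magnitude between the displacement
  and force channels; all solves equilibrate to unit diagonal first.
  Cholesky failures are retried with escalating trace-scaled jitter and
  finally repaired by projecting onto the PSD cone (eigenvalue clipping).
  An exactly zero covariance factors to zero (all sigma points at the
  mean).
* **Force lag.**  The discrete state equation evaluates the force from the
  previous-step displacement, as written in its source; the induced
  one-step bias is $\approx K n d^{n-1} \dot d \Delta t$ per step.  The
  test suite verifies that a well-initialised low-noise run converges to
  exactly this analytic floor.  For the gentle velocities of the study
  conditions the bias is far below measurement noise.

## The simulator and the study conditions

`scenario_preset()` encodes three contact-model-error regimes, all driven
by the same true contact $K = 10$, $B = 1$, $n = 2$, $p = 1.05$ under
constant-velocity indentation with noisy $[d, F]$ measurements:

* `init_error` — the filter starts from grossly wrong parameters
  $(K_0, B_0, n_0, p_0) = (150, 2, 1, 1)$; velocity 0.1 mm/s, 300 steps.
* `simplified` — the filter's transition drops the velocity exponent
  ($p$ fixed at 1) while the truth uses the full law; correct initial
  values; velocity 0.01, 500 steps.
* `local_error` — correct model and initialization, but the constant
  vector $[0,0,0,0.8,0.8,0,0]$ is added to the filter's predicted state
  mean during steps 200-220 only.

The truth trajectory is noise-free ($d_k = k\,\dot d\,\Delta t$, force from
the H-C law); $Q$ is purely the filter's tuning.  Estimation quality is
scored by *force reconstruction*: $\hat F_k$ re-evaluates the H-C law with
the step-$k$ parameter estimates along the true $(d, \dot d)$, and the
mean, maximum and root-mean-square absolute deviations from the true force
are reported over all steps, transients included.

### Constants the sources leave unstated, and how they were fixed

The published description of these experiments omits several constants;
they were derived once from the internal evidence and frozen:

* **Step length** $\Delta t = 0.1$.  The error profile of the
  initial-error experiment (mean/max/RMS ratios of a transient ramp
  peaking near step 150) and the spike magnitude of the local-error
  experiment (a 0.8 offset on $K, B$ producing a few-mN force error
  requires $d \approx 2$ mm at step 200) both pin the per-step displacement
  increment near 0.01 mm at the stated 0.1 mm/s velocity.
* **Noise covariances.**  The stated noise levels (0.01 for regimes 1 and
  3; 0.1 for regime 2) are read as noise *magnitudes* (standard
  deviations), i.e. $Q = R = \mathrm{diag}(0.01^2)$ and
  $\mathrm{diag}(0.1^2)$.  Read as variances instead, the parameter
  random walk inflates the predicted innovation covariance so far above
  the actual innovations (the $B$-$p$ ridge is unidentifiable, and $K$-$n$
  only slowly separable) that the Mahalanobis detector can never fire and
  the adaptive filter degenerates to the UKF — contradicting the published
  behaviour in every regime.
* **Initial covariance** matches the actual initialization quality:
  $P_0 = \mathrm{diag}(1)$ when the parameters start grossly wrong,
  $\mathrm{diag}(0.01)$ when they start at the truth.  A loose prior on
  the exponents when they are actually known pushes the filter onto the
  $K$-$n$ ridge (at $d < 1$ mm the exponent has $\sim$300$\times$ the
  stiffness's leverage on the force).
* **UT constants** $\alpha = 0.01$, $\beta = 2$, $\kappa = 0$: a
  small-spread transform, standard practice for strongly nonlinear maps;
  wide spreads push sigma points through $d^n$ into regions that inflate
  the predicted covariance by orders of magnitude.

These choices were calibrated against the *qualitative* published
behaviour (slow UKF convergence under initial error; detector firing only
during faults; bounded recovery) and then frozen; they were not tuned
toward the published error tables.

### What the generator does and does not emulate

The synthetic trajectories capture constant-velocity indentation with
sensor noise and three clean, isolated model-error mechanisms.  Real
palpation data adds unmodelled dynamics (robot compliance, tissue
relaxation and rate dependence beyond H-C, sensor drift, variable
velocity), none of which the generator produces; passing the scenario
tests shows the adaptation logic works as designed, not that the H-C model
fits any particular tissue.  For measured records the package provides
`read_indentation_csv()` + `fit_indentation()`, with velocity recovered by
central differences when the log omits it.

## Known limitations

* With constant velocity the simplified ($p{=}1$) model class *exactly
  nests* the full law ($B' = B \dot d^{\,p-1}$ absorbs the exponent), so
  the model-simplification regime contains no systematic error for the
  detector to find: a consistent UKF and the adaptive filter perform
  identically there, and the package makes no claim of an ordering between
  them in that regime.
* The plain UKF's transient magnitudes under gross initial error depend
  sharply on the unstated prior constants; the regime (large transient,
  convergence within the run) is reproduced, but peak values are
  configuration-sensitive.
* $B$ and $p$ are not separately identifiable from constant-velocity
  records; only their combination is estimated.  Varying-velocity
  protocols would be required to split them.

## Scale of the shipped analyses

The bundled tests run the three scenarios at 20 Monte-Carlo replicates
(300-500 steps each); `scripts/acceptance.R` uses 100 replicates per
scenario and filter.  Both scales were chosen so the Monte-Carlo means of
the error metrics are stable to well under the between-run spread.

```{r example}
cfg <- scenario_preset("init_error", seed = 1)
ukf <- run_filter_on_scenario(cfg, "ukf")
rw  <- run_filter_on_scenario(cfg, "rwstukf")
comparison_table(list(ukf = ukf, rwstukf = rw))
```
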