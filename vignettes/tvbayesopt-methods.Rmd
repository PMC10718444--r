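---
title: "Time-varying Bayesian optimization of phase-locked neurostimulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-varying Bayesian optimization of phase-locked neurostimulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvbayesopt)
```

## The problem

In adaptive neurostimulation for oscillopathies (Parkinson's disease,
Essential Tremor), the stimulation setting that best suppresses the
pathological rhythm is not fixed: disease progression shifts it gradually,
and biological rhythms (circadian cycle, medication schedule) shift it
periodically. A controller that tunes stimulation online must therefore
treat the objective as *time-varying*. This package implements such a
controller — time-varying Bayesian optimization (TV-BayesOpt) — together
with the simulated testbed used to evaluate it: a Kuramoto oscillator model
of a synchronous disease biomarker under phase-locked stimulation.

## The oscillator model of the biomarker

The biomarker is the mean phase-coherence $\rho$ of $N$ coupled phase
oscillators. Oscillator $i$ evolves as

$$\dot\theta_i = \omega_i + \frac{\gamma}{N}\sum_{j=1}^{N}
  \sin(\theta_j - \theta_i) + I\,X(t)\,Z(\theta_i),$$

where $X(t)\in\{0,1\}$ gates stimulation and
$Z(\theta) = -\sin(\theta + \Delta\theta)$ is a type-II phase response
curve (PRC) whose offset $\Delta\theta$ is the handle through which drift
scenarios move the optimal stimulation phase. The order parameter
$\rho e^{i\psi} = \tfrac1N\sum_j e^{i\theta_j}$ supplies both the control
signal ($\rho$, synchrony) and the trigger signal ($\psi$, mean phase).
The pairwise coupling sum factorizes exactly through the order parameter
($\gamma\rho\sin(\psi-\theta_i)$), so the $O(N)$ mean-field drift is used
throughout; both forms are implemented and tested for equality.

Default parameters (`kuramoto_params()`): $N = 50$, $f_0 = 8$ Hz (tremor
band), coupling $\gamma = 0.8$, intensity $I = 30$. Frequencies are
Gaussian about $f_0$ with relative spread $0.0075$ — read as a *fraction*
of $f_0$ (std $0.06$ Hz), the only reading consistent with a population
spanning $8 \pm 0.15$ Hz; draws outside $\pm 0.15$ Hz are redrawn rather
than clamped, avoiding probability mass at the clip boundary. An absolute
interpretation (`sigma_mode = "absolute"`) is available; it produces a
nearly monochromatic population that locks at $\rho \approx 1$ rather than
the $\rho \approx 0.8$ plateau the fractional reading yields.

### Integration

Explicit Euler at $dt = 1$ ms (configurable), the standard choice for
Kuramoto phase models. The compiled integrator (Rcpp) carries the hot loop;
a reference R implementation of a single step (`step_population()`) is kept
and tested against it. Halving $dt$ changes a fixed-seed trial outcome by
less than $10^{-2}$ when the compared trajectories share a short common
history; over hundreds of seconds trajectories decorrelate (the plateau is
an attractor, individual paths are not), so convergence is assessed on
short-horizon trials, not long traces.

### Phase-locked stimulation and the trial protocol

One optimization step simulates 58 s: the first 50 s unstimulated (the
final 25 s forming the baseline), then 8 s of phase-locked stimulation.
The outcome is the normalized change in synchrony,

$$y = \Delta\rho = \frac{\bar\rho_{stim} - \bar\rho_{base}}
 {\bar\rho_{base}},$$

negative when stimulation desynchronizes. A rectangular pulse is delivered
whenever $\psi$ crosses the target phase in the direction of phase
advance, with a refractory of half a mean cycle against re-triggering on
$\psi$ jitter.

Pulse morphology is a free design choice here. Two constraints pin it
down: a single-integration-step pulse (1 ms) at $I = 30$ leaves the
response within the trial-to-trial fluctuation floor (scans then fail to
resolve the response curve's minimum), while long pulses ($\ge 10$ ms)
smear the effective stimulus phase — $\psi$ advances $\sim 0.5$ rad during
a 10 ms pulse — shifting the sign boundaries of the response curve away
from $\pm\pi/2$. The default is a 2 ms pulse, *centered* on the target
phase (the trigger anticipates by half a pulse of mean-phase advance).
With it, the empirical amplitude response curve (ARC) has the expected
structure: stimulation on the outer half of the phase circle
desynchronizes ($\Delta\rho < 0$), the inner half synchronizes, and the
strongest suppression sits at $\psi^* = -\pi$.

The scaled protocol used by the closed-loop test experiments
(`scaled_protocol()`) shortens a step to 12 s (5 s baseline, 4 s
stimulation); it preserves the ARC structure at roughly half the
full-protocol effect size and keeps a 300-step experiment around ten
seconds of compute per controller.

## The surrogate model

The controller's belief about the ARC is a zero-mean Gaussian process over
(phase, step index). Zero prior mean is appropriate because $\Delta\rho$
is a normalized change centered on zero. The covariance is the Hadamard
product $\tilde K = K_s \cdot K_t$ of

* a **spatial** exponential-sine-squared kernel
  $K_s(x,x') = \exp(-2\sin^2(\pi|x-x'|/T_x)/l_x^2)$ with $T_x = 2\pi$
  forced by the periodicity of phase space ($-\pi \equiv \pi$), and
* a **temporal** kernel over step indices, one of: constant 1 (static,
  i.e. time-invariant BayesOpt), forgetting
  $(1-\epsilon)^{|t-t'|/2}$, periodic
  $\exp(-2\sin^2(\pi|t-t'|/T_t)/l_{t,p}^2)$, or their product
  (forgetting-periodic).

### The two decay conventions

The forgetting kernel and the half-life interpretation of $\epsilon$ are
both implemented exactly as defined, and they disagree by roughly a factor
of two in effective decay: the kernel gives a sample of age $\Delta t$
weight $(1-\epsilon)^{\Delta t/2} \approx e^{-\epsilon\Delta t/2}$, while
the half-life mapping $\epsilon = \ln 2 / t_{1/2}$ and its weight
$2^{-\Delta t/t_{1/2}} = e^{-\epsilon\Delta t}$ decay twice as fast. The
package does not silently reconcile them: `temporal_kernel()` implements
the kernel, `half_life_to_epsilon()` / `half_life_weight()` implement the
half-life algebra, and tests freeze both. Users quoting "a half-life of
$n$ samples" should be aware the kernel retains such a sample at
$\sqrt{1/2}$, not $1/2$, of its weight.

### Inference

Exact GP regression: $\mu_* = K_*(K + \sigma_n^2 I)^{-1}y$ and the
corresponding variance, solved by Cholesky factorization with adaptive
jitter ($10^{-10}$ doubling to $10^{-6}$; failure past that raises a
conditioning error). Observation noise defaults to $\sigma_n^2 = 10^{-2}$,
matching the scaled protocol's fluctuation floor ($\sigma \approx 0.1$ on
$\Delta\rho$). Variances within $-10^{-10}$ of zero are clamped. Histories
beyond a sliding window (default 500 most recent samples; `Inf` for
exactness) are dropped from the solve — under forgetting, older samples
are negligible anyway, and the window bounds the $O(n^3)$ cost of
3000-step runs.

## Acquisition

GP-LCB: $\alpha(x) = \mu_*(x) - \kappa\,\sigma_*(x)$, minimized over a
uniform 360-point phase grid (1° resolution, ample for a 1-D periodic
space); exact ties resolve to the smallest phase. The default
$\kappa = 0.3$ is exploitation-leaning, and deliberately so: the ARC basin
is shallow (objective differences of 0.01–0.05 within half a radian of the
optimum) while the posterior sd under $\sigma_n^2 = 10^{-2}$ is
$\sim 0.1$, so at $\kappa = 1$ the exploration term dominates and the
selection hovers several grid spacings off the optimum even for a
stationary objective. At $\kappa = 0.3$ a stationary run locks onto the
optimum (late-run selections within one grid spacing) and drifting runs
track with small lag. $\kappa$ remains configurable for
exploration-heavier use.

Each run starts with 12 equally spaced burn-in phases
($-\pi + 2\pi k/12$), which occupy step indices $0..11$ and age like any
other samples under the temporal kernels.

## Drift scenarios and ground truth

`make_drift()` generates the per-step PRC offset: a linear ramp
$0 \to -\pi$ over the run (gradual), a raised-cosine swing
$0 \to -\pi \to 0$ per period (periodic, canonically 100 steps $\equiv$
one day), their sum (superimposed), and optional Gaussian jitter on the
trajectory (std 0.75 or 1.5 rad in the robustness scenarios). Offsetting
the PRC translates the ARC, so the true optimum is
$\psi^*_k = \mathrm{wrap}(\psi^*_0 - \Delta\theta_k)$ with
$\psi^*_0 = -\pi$; the sign convention is fixed by a brute-force re-scan
oracle test, not assumed. The analytic stand-in
`toy_objective()` ($y = -A\cos(x - \psi^*_k) +$ noise) exercises the
optimizer without ODE cost.

## Regret conventions

Per-step regret is implemented exactly as defined,
$R_k = f(\psi^*_k) - f(\psi^{target}_k)$, which is *non-positive* up to
noise (the optimum value minus an achieved value, for a minimized
objective), and cumulative regret is the running mean
$CR_k = \frac1k\sum_{j\le k} R_j$ (the undivided sum is also exposed).
Controller comparisons use the magnitude of the trapezoidal area under the
$CR$ curve (`auc_mag`); on that scale larger = worse tracking, matching
how sensitivity results are usually displayed. For the oscillator-backed
runs, $f(\psi^*_k)$ is *measured*: a counterfactual trial at the true
optimum is run from a snapshot of the same pre-stimulation state as the
tested trial (the two share the settle/baseline segment, which is
simulated once). A fixed reference value would be biased — the value
achievable at the optimum varies with the carried population state — and
that bias can push a well-tracking controller's cumulative regret
positive.

## Experiment scales

The closed-loop experiments in the test suite run at desk scale: 300
optimization steps, 100-step drift period, the 12 s scaled protocol, five
paired seeds for the controller comparisons and the forgetting-factor
orderings (a single run's AUC varies ~20% between seeds, so orderings are
assessed on condition means), and two paired seeds for the
period-mismatch ordering. Full-scale 3000-step runs with the 58 s
protocol are supported through the same configuration surface (hours of
compute). Scenario-to-kernel pairing follows the anticipated drift:
forgetting ($\epsilon = 0.22$, the best-performing value, corresponding to
a half-life of $\approx 3.15$ samples under the half-life convention) for
gradual drift, periodic ($T_t = 100$) for periodic drift, and their
product for superimposed drift.

## What the simulations do and do not show

The generator emulates: a high-synchrony steady state ($\rho \approx
0.8$), a type-II PRC, phase-dependent stimulation response, and slow
offset drifts with optional trajectory noise. It does not emulate
conduction delays, stochastic dynamics inside the ODE, biophysical DBS
waveforms, electrode geometry, measurement noise on $\rho$, or abrupt
regime switches; passing tests therefore demonstrate the controller's
behavior under slow, structured nonstationarity of a clean biomarker, not
performance on clinical recordings. Sensitivity orderings are assessed at
desk scale with paired seeds; at this scale the periodic component has
only three cycles of history to exploit, so orderings near the equivalence
region of the forgetting factor ($\epsilon \gtrsim 0.02$) are close and
can fluctuate between realizations.

## Known limitations

* Kernel hyperparameters are set a priori (no marginal-likelihood
  optimization), matching the intended embedded use.
* The parameter space is one-dimensional (stimulation phase); the kernel
  composition generalizes, the grid acquisition does not scale past a few
  dimensions.
* The quoted "45-minute" physical interpretation of a 3.15-sample
  half-life is inconsistent with 58 s steps (3.15 steps ≈ 3 minutes) and
  is not reproduced; step indices are the only temporal unit used.
* Euler integration is first-order; $dt$ well below the 125 ms oscillation
  period is required (default 1 ms).
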