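# tvbayesopt

Time-varying Bayesian optimization for closed-loop neurostimulation, with a
Kuramoto oscillator testbed.

## The problem

Adaptive brain-stimulation therapies (e.g. phase-locked deep brain
stimulation for Essential Tremor or Parkinson's disease) must pick the
stimulation setting that best suppresses a pathological synchrony
biomarker. That optimal setting is not fixed: disease progression shifts
it gradually and biological rhythms (circadian cycle, medication) shift it
periodically. Standard Bayesian optimization assumes a stationary
objective and degrades under such drift.

This package implements a **time-varying Bayesian optimization
(TV-BayesOpt)** controller whose Gaussian-process surrogate uses a
spatio-temporal covariance

K̃((x,t), (x′,t′)) = K_s(x, x′) · K_t(t, t′),

the product of a periodic spatial kernel over stimulation phases
(exponential-sine-squared, period 2π) and a temporal kernel over
optimization-step indices that down-weights stale samples:

* forgetting: K_t = (1 − ε)^(|t − t′|/2), forgetting factor ε ∈ [0, 1);
* periodic: K_t = exp(−2 sin²(π|t − t′|/T_t) / l²_{t,p});
* forgetting-periodic: their product.

Samples are chosen by minimizing the GP lower confidence bound
α(x) = μ\*(x) − κ σ\*(x).

The testbed is a population of N = 50 coupled Kuramoto oscillators
(8 Hz, coupling γ = 0.8) with a type-II phase response curve
Z(θ) = −sin(θ + Δθ); phase-locked pulses (intensity I = 30) are delivered
at a target mean phase, and the objective is the normalized change in mean
phase-coherence Δρ per stimulation trial (negative = desynchronization =
symptom suppression). Drift scenarios translate the optimal phase by
moving the PRC offset Δθ over time; regret against the (measured) true
optimum quantifies tracking.

## Worked example

The empirical amplitude response curve (ARC) — the objective the
controller optimizes — from a 12-phase scan of the oscillator model:

```r
library(tvbayesopt)
arc <- arc_scan(seed = 1)     # 200 s burn-in + 12 phase-locked trials
round(arc$delta_rho, 3)
#>  [1] -0.682 -0.612 -0.234 -0.008  0.096  0.127  0.135  0.123  0.078 -0.008
#> [11] -0.202 -0.593
arc$psi_target[which.min(arc$delta_rho)]
#> [1] -3.141593
```

Stimulation on the outer half of the phase circle desynchronizes the
population (Δρ < 0), the inner half increases synchrony, and the strongest
suppression is at the mean-phase antipode ψ\* = −π.

Tracking a gradual drift of the optimum with the forgetting kernel versus
time-invariant BayesOpt (fast analytic objective, 200 steps, same seed):

```r
drift <- make_drift("gradual", n_steps = 200)
tv <- run_bayesopt(toy_objective(drift, noise_std_y = 0.05, seed = 1), drift,
                   hp = gp_hyperparams(kernel_kind = "forgetting",
                                       epsilon = 0.22),
                   n_steps = 200, f_true = -1, seed = 1)
st <- run_bayesopt(toy_objective(drift, noise_std_y = 0.05, seed = 1), drift,
                   hp = gp_hyperparams(kernel_kind = "static"),
                   n_steps = 200, f_true = -1, seed = 1)
summary(tv)
#> tv controller, 200 steps, gradual drift
#>   mean |tracking error|: 0.653 rad (last quarter: 0.630 rad)
#>   final cumulative regret: -0.2420, AUC: -67.2532
summary(st)
#> static controller, 200 steps, gradual drift
#>   mean |tracking error|: 1.505 rad (last quarter: 2.483 rad)
#>   final cumulative regret: -0.9488, AUC: -111.5987
```

The time-varying controller stays near the moving optimum while the static
controller ends up ~2.5 rad off and accumulates about 1.7× the regret
magnitude. Regret is the optimum's objective value minus the achieved one
(non-positive up to noise; nearer zero is better), cumulative regret its
running mean, and `AUC` the area under that curve — magnitudes are the
comparison scale. Oscillator-backed runs use the same interface through
`kuramoto_objective()` or `run_from_config()`; `plot(tv)` shows the
tracking and regret curves.

A thin command-line driver wraps the same functions
(`inst/cli/tvbo.R`: `simulate`, `optimize`, `sweep-epsilon`,
`sweep-period`), reading a JSON run configuration (`parse_config()`) and
writing CSV traces with a replay sidecar (`write_trace()`).

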