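# trackinfo

Feedback and feedforward information rates in visuomotor tracking.

When a person tracks a moving target with a cursor, the information shared
between target `X` and cursor `Y` mixes two things: real-time transfer
through the visuomotor channel, delayed by the visuomotor delay (VMD), and
prediction from the target's learned dynamics, which costs no real-time
processing at all. `trackinfo` separates them. The feedback component is a
transfer-entropy-style conditional mutual information evaluated at the VMD,

    IFB = I(Y_t ; {X_{t-VMD}, X_{t-VMD-1}} | {Y_{t-VMD}, Y_{t-VMD-1}, Y_{t-1}})

(history depths 2 because the targets are order-2 processes; the extra
conditioning on `Y_{t-1}` makes it a per-sample rate, so `IFB x frame rate`
is a bits/s real-time processing rate). The total shared information is

    Itotal = I(Y_t ; {X_t, X_{t-1}, X_{t-VMD}, X_{t-VMD-1}})

and the predictive, feedforward component is `IFF = Itotal - IFB`. The VMD
is estimated from data as the peak latency of the transfer-entropy curve
over candidate delays. All information terms use the Gaussian-copula
estimator (rank -> uniform -> normal-quantile transform, covariance
determinants) with analytic Wishart/digamma bias correction of each sample
log-determinant — exactly invariant to monotone marginal transforms, and a
lower bound on the true mutual information.

The package also ships the instruments around the measures:

* an AR(2) resonator target generator with a single predictability knob
  (`signal_config()`, `generate_target()`);
* a delay-augmented LQG simulator of the tracking task (Kalman filter +
  receding-horizon quadratic control) that exposes exact model-internal
  feedback/feedforward information (`build_plant()`,
  `simulate_tracking()`, `ground_truth_tfb()`, `ground_truth_tff()`);
* a validation pipeline correlating estimates with ground truth across
  predictability levels, recovering implanted delays, and fitting the
  exponential relation between lag ratio and feedback rate
  (`run_predictability_sweep()`, `run_vmd_sweep()`, `fit_exponential()`,
  `full_report()`).

## Worked example

Simulate tracking of a mid-complexity target, estimate the VMD from the
transfer-entropy peak, and decompose the information:

```r
library(trackinfo)

cfg    <- signal_config(a1 = 2, n_frames = 10700, seed = 11)
target <- generate_target(cfg)
plant  <- build_plant(cfg)              # visual 12 + motor 3 frames
run    <- simulate_tracking(plant, target, seed = 99)
run
#> LQG tracking simulation run
#>   10000 frames kept, true VMD 16 frames, seed 99
#>   ground truth: TFB = 0.4736, TFF = 10.0847 bits/sample

curve <- te_latency_curve(run$pair, 2, 30)
curve
#> Transfer-entropy latency curve over d = 2..30 frames
#>   peak at d = 16 (0.2453 bits/sample)

decompose_tracking(run$pair, vmd = curve$peak_delay)
#> Tracking information decomposition (VMD = 16 frames)
#>   feedback    IFB    =   0.2453 bits/sample  (14.72 bits/s at 60 Hz)
#>   feedforward IFF    =   1.6356 bits/sample
#>   total       Itotal =   1.8809 bits/sample   [n = 10000 frames]

performance_lag(run$pair)
#> [1] 11
```

The transfer-entropy peak recovers the implanted 16-frame delay exactly.
The estimated feedback rate (0.245 bits/sample) stays below the
model-internal ground truth (0.474 bits/sample), as it must — the ground
truth is an upper bound at the state-estimate level. The performance lag
(11 frames) is *below* the 16-frame VMD because the controller's prediction
of the partly predictable target compensates part of the delay.

Experimental data can enter through the same interface: a CSV with columns
`frame,target_x,cursor_x` (optional `trial`) read by
`read_trajectory_csv()`, then `estimate_vmd()` and `decompose_tracking()`.
A thin command-line front end is installed at `inst/cli/visuotrack.R`
(subcommands `simulate-signal`, `decompose`, `estimate-vmd`, `simulate`,
`validate`).

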