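# motileCTRW

Single-cell tracking and continuous-time random walk (CTRW) modelling of
bacterial ensemble transport.

Run-and-tumble bacteria — including metal-reducing organisms relevant to
bioremediation — alternate straight runs ("jumps") with waiting periods,
and both jump lengths and waiting times can be heavy-tailed, spanning
orders of magnitude. Models of their ensemble spreading based on the
advection–diffusion equation (ADE) assume Gaussian increments and
variance growing linearly in time; whether that is adequate for a given
organism is an empirical question. `motileCTRW` is for microbiologists
and transport modellers who want to answer it from video-microscopy
data: it extracts single-cell trajectories from grayscale frame stacks,
segments them into jumps and waits, and predicts ensemble breakthrough
(first-passage) curves at radial control planes with three models —
coupled CTRW, uncoupled CTRW, and an erfc-form ADE with time-varying
diffusion coefficient — compared against the "real path" breakthroughs
computed directly from the trajectories.

## The model in brief

A trajectory is a walk
**r**<sub>n+1</sub> = **r**<sub>n</sub> + **ε**<sub>n</sub>,
t<sub>n+1</sub> = t<sub>n</sub> + τ<sub>n</sub>, with the increments
drawn from the *master table* of all observed steps. The coupled CTRW
bootstrap-resamples whole rows (ε and τ stay paired); the uncoupled CTRW
draws ε and τ from independent rows. The ADE benchmark is

C/C₀ = ½ erfc((L − V·t) / (2·√(D·t))),

with V the slope of the ensemble mean displacement over time and
D(t) = ½ ∂σ²/∂t from the ensemble variance (held constant beyond the
observation window). Breakthrough curves at control radius L are
first-arrival-time densities normalized by the ensemble size, so their
area equals the recovery — the fraction of cells that reach L.

Because no raw videos ship with the package, a first-class synthetic
module generates ground-truth run-and-tumble trajectories (heavy-tailed
jumps with mode ≈ 5.5 µm and hard 100 µm maximum; heavy-tailed waits up
to 250 s; optional drift and lag-1 step correlations via a calibrated
Gaussian copula) and renders them as microscopy-like TIFF stacks
(1024 × 1024 px, dark cells on bright noisy background), so the whole
chain is testable end to end.

## Worked example

Generate a synthetic ensemble, build its master step table, and compare
the coupled-CTRW breakthrough prediction against the real-path curves:

```r
library(motileCTRW)

params <- motility_params(n_cells = 400, t_max = 125, seed = 1,
                          body_length = 2)
truth  <- generate_trajectories(params)

master <- build_master(segment_steps(truth$paths, body_length = 2))
ctrw   <- simulate_ctrw(master, ctrw_config(coupled = TRUE,
                                            n_particles = 1000,
                                            t_max = 125, seed = 2))
bt_ctrw <- first_passage(ctrw, radii = c(10, 20, 30, 40))
bt_real <- real_breakthrough(truth$paths, radii = c(10, 20, 30, 40))

bt_real[["20"]]
#> <breakthrough_curve> L = 20 um: recovery 100%, mean 5.926 s, std 8.186 s

compare_report(bt_real, ctrw_coupled = bt_ctrw)
#>   L_um       source recovery mean_arrival_s std_arrival_s n_arrived excluded
#> 1   10 ctrw_coupled        1           2.55          4.41      1000    FALSE
#> 2   10         real        1           2.72          6.44       400    FALSE
#> 3   20 ctrw_coupled        1           6.03          7.98      1000    FALSE
#> 4   20         real        1           5.93          8.19       400    FALSE
#> 5   30 ctrw_coupled        1          10.05         10.43      1000    FALSE
#> 6   30         real        1           9.38          9.92       400    FALSE
#> 7   40 ctrw_coupled        1          14.94         14.04      1000    FALSE
#> 8   40         real        1          14.24         13.84       400    FALSE
```

With independent steps (the default), the coupled CTRW tracks the
real-path mean arrival within a few percent at every control plane: the
walk model is self-consistent. Per-radius recovery is the fraction of the
ensemble reaching that radius within the 125 s horizon; means and
standard deviations are over arrivers. Injecting lag-1 jump correlation
into the generator (`jump_corr = 0.7`) degrades the CTRW match with
growing control-plane distance — the signature that successive steps of
real cells are not independent. `plot_breakthrough_comparison()` overlays
the density curves per radius.

The tracking half of the pipeline works the same way from images:
`render_frames()` → `detect_cells()` → `link_detections()` →
`filter_trajectories()` → `convert_units()` recovers the injected
trajectories from a rendered stack to sub-pixel accuracy (RMSE ≈ 0.15 px
on a noiseless 20-cell, 200-frame stack).

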