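---
title: "Modelling bacterial ensemble transport with CTRW and ADE breakthroughs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bacterial ensemble transport with CTRW and ADE breakthroughs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motileCTRW)
```

## The problem

Many motile bacteria — among them metal-reducing organisms whose transport
matters for bioremediation — move in a run-and-tumble pattern: straight
displacements ("jumps" or runs) separated by waiting periods, with both jump
lengths and waiting times spanning several orders of magnitude. Classical
transport models based on the advection–diffusion equation (ADE) assume
Gaussian increments and variance growing linearly in time, assumptions such
heavy-tailed motion can violate badly. `motileCTRW` implements the full
analysis chain for testing this on single-cell video data:

1. **synthesize** ground-truth run-and-tumble trajectories and render them
   as microscopy-like image stacks (`generate_trajectories()`,
   `render_frames()`);
2. **track** cells in an intensity stack (`detect_cells()`,
   `link_detections()`, `filter_trajectories()`);
3. **quantify motility**: unit conversion, segmentation into jumps and
   waits, empirical distributions, ensemble moments, drift, lag-1 step
   correlations (`convert_units()`, `segment_steps()`, `build_master()`,
   `empirical_pdf()`, `ensemble_moments()`, `drift_speed()`,
   `step_correlation()`);
4. **model ensemble transport** with a continuous-time random walk in
   coupled and uncoupled variants (`simulate_ctrw()`, `first_passage()`)
   and with an erfc-form ADE solution driven by a time-varying diffusion
   coefficient (`diffusion_coefficient()`, `ade_breakthrough()`);
5. **compare** modelled breakthrough (first-passage) curves at radial
   control planes against the "real path" breakthroughs computed directly
   from trajectories (`real_breakthrough()`, `compare_report()`).

## The walk model

A trajectory is a sequence of steps. Step $n$ displaces the cell by an
increment $\varepsilon_n$ (length `eps`, direction arbitrary) and advances
its clock by $\tau_n$,

$$\mathbf r_{n+1} = \mathbf r_n + \boldsymbol\varepsilon_n,
\qquad t_{n+1} = t_n + \tau_n.$$

The package stores with each step both components of its time increment:
the stationary waiting period `tau_wait` that precedes the run and the run
traversal time `tau_run`, with `tau = tau_wait + tau_run`. This convention
makes the step times of a trajectory sum to its recorded duration, and it
lets either reading of "waiting (residence) time" — dwell only, or time to
complete a run — be reproduced from the same master table. The CTRW
simulator uses `tau`.

**Coupled versus uncoupled sampling.** The empirical master table (all
steps of all trajectories of a dataset) is the walk's distribution. In the
*coupled* variant whole rows `(dx, dy, tau)` are bootstrap-resampled, so a
waiting time stays attached to the jump length it was observed with — the
empirical joint distribution, with no parametric copula. In the
*uncoupled* variant the displacement and the waiting time come from two
independently drawn rows: every waiting time is equally likely regardless
of jump length.

**Finite-speed jumps.** Jumps traverse their chord at constant speed over
`tau_run` rather than teleporting. With jumps as long as 100 µm,
instantaneous displacement would let a single event cross every control
plane closer than 100 µm at its start time and badly distort early-time
breakthrough. For first passage, the distance from the origin along a
straight chord is convex, so a segment produces a crossing exactly when it
ends at or beyond the control radius having started inside it; the
crossing time solves a quadratic along the chord.

**No drift in the CTRW.** The observed slow ensemble drift enters only the
ADE model's velocity term; the CTRW resamples observed increments as-is
(an isotropizing `resample_direction` option exists but is off by
default, preserving any anisotropy in the master table).

## The ADE model

From the ensemble variance $\sigma^2(t)$ of cell locations the
time-varying diffusion coefficient is $D(t) = \tfrac12\,
\partial\sigma^2/\partial t$ (central finite differences, optional
moving-average smoothing, negative estimates floored at zero). Beyond the
last observed time $D$ is held at its final value — the value computed
for the longest recorded trajectories. Breakthrough at control radius $L$
uses the one-dimensional semi-infinite solution

$$\frac{C}{C_0} = \frac12\,\mathrm{erfc}
\left(\frac{L - V t}{2\sqrt{D t}}\right),$$

with $V$ the slope of the mean displacement over time. Two deliberate
approximations are preserved because they are part of the method being
evaluated: the planar solution is applied radially, and the expression is
a resident concentration rather than a strict first-passage probability
(the test suite documents this by matching it against the resident
fraction of a matched 1-D drift–diffusion walk). The arrival-time density
is the numerical derivative of $C/C_0$, floored at zero (a time-varying
$D$ can make the raw derivative locally negative) and rescaled to
integrate to the window recovery; arrival moments are density-weighted
over a configurable horizon `T_model`, since the model curves extend
beyond the observation window.

Note a convention trap the package handles explicitly: with the *radial*
(2-D) variance, a Brownian ensemble with per-axis diffusion $D_0$ has
$\sigma^2 = 4 D_0 t$, so the estimator returns $2 D_0$. Both the radial
and per-axis conventions are exposed in `ensemble_moments()`; radial is
the default.

## Segmentation rules

A cell is *waiting* in a frame interval when it moved less than its body
length; consecutive waiting intervals accumulate. A *run* opens with a
supra-body-length displacement and extends while each per-frame direction
stays within 5° of the run's current mean direction (the direction of its
net displacement so far — the cumulative baseline matches the "about 1
pixel change in perpendicular direction over 10 pixels of displacement"
reading, and is robust to pixel-level jitter in a way a frame-to-frame
baseline is not). A new jump is registered when the cell leaves a waiting
state or turns by more than 5°. A trajectory that ends waiting emits a
terminal pure-wait record with `eps = 0`, preserving the time budget;
such records are excluded from jump statistics by default.

Segmentation uses displacements only, hence is exactly invariant to
translating or rotating a trajectory — a property test in the suite.

## The synthetic-data generator as study conditions

No raw videos accompany the analysis this package operationalizes, so the
generator defines the study conditions, chosen once to match the reported
motility statistics:

* **Jump lengths**: truncated Pareto, `xmin = 5.5` µm, `alpha = 1.6`,
  `max = 100` µm. The mode of a truncated Pareto is exactly `xmin`,
  matching the reported 5–6 µm peak; the hard 100 µm maximum and heavy
  tail match the reported range. A lognormal with the same mode was
  rejected as default because it places ~6 % of its mass below a 3 µm
  body length, and any jump below the body length is *by construction* of
  the waiting-state rule unrecoverable — the segmented marginal would
  differ from the generating one for reasons inherent to the rule, not to
  the data. Lognormal and exponential families remain available.
* **Waiting times**: truncated Pareto, `xmin = 0.25` s, `alpha = 1.2`,
  `max = 250` s — heavy-tailed, support reaching the longest recording.
  The 0.25 s minimum also guarantees that at 8 Hz every wait covers at
  least two frame intervals, so sampled runs are always separated by at
  least one genuinely stationary interval.
* **Body length**: 3 µm default (a flagellated swimmer);
  2 µm used in several tests (a small twitcher). Reported jumps of 100 µm
  are "20 to 50 times" a body length, bounding plausible values to 2–5 µm.
* **Run speed**: 30 µm/s, so per-frame displacements during runs
  (3.75 µm at 8 Hz) comfortably exceed the body length.
* **Drift**: optional uniform drift of ~0.15–0.22 µm/s emulating the
  residual ensemble motion observed in sealed chambers.
* **Correlations**: lag-1 dependence between successive jump lengths (and
  waits) through a stationary AR(1) Gaussian copula on the sampling
  uniforms, *calibrated by quadrature so the Pearson lag-1 correlation of
  the generated series equals the requested value*. Not every value is
  attainable: a strongly skewed heavy-tailed marginal bounds the Pearson
  correlation away from ±1 (the default waiting-time marginal cannot go
  below about −0.03), and `calibrate_copula_rho()` reports the attainable
  interval when asked for more.
* **Rendering**: dark disks (radius ≥ 1 px, so ≥ 2 px diameter) on a
  bright background with i.i.d. Gaussian noise, 13 µm sensor pixels,
  configurable magnification and frame rate; cells outside the window are
  simply absent, emulating entry and exit.

What the generator does **not** emulate: hydrodynamic wall effects,
chemotaxis, cell shape and orientation, out-of-focus blur, pixel
saturation, illumination gradients, or obstacle geometry. Passing tests
therefore certify the *pipeline* — detection, linking, segmentation,
sampling, first-passage bookkeeping — not the biology of any particular
organism.

## Numerical and design choices

* **Detection backgrounds.** The temporal background is the per-pixel
  median over frames with scale `1.4826 × MAD`; a per-frame *spatial*
  median criterion is OR-ed in so that cells which never move are still
  detected (they must be, because idleness is diagnosed downstream from
  trajectories, not assumed at detection). Foreground components use
  8-connectivity; components below 2 px are dropped.
* **Linking.** Greedy nearest-neighbour within a search radius, closest
  pairs first, ties broken by detection index; unmatched detections start
  new tracks only beyond `new_path_radius`; tracks survive up to
  `max_missed = 2` consecutive dropouts. Identity is not guaranteed
  through close encounters (documented contract). Global-likelihood
  linking is out of scope by design.
* **Frame discretization bias.** When a continuous path is sampled at
  frame rate, the boundary intervals of a run carry only part of its
  displacement; a partial displacement below the body length is classed
  as waiting, truncating the measured jump by up to one body length per
  run end (expected loss ≈ `body_length²/(2 · run_speed · Δt)` per end).
  This is a property of the frame-based rule itself, present in any
  real-video analysis at finite frame rate. Distribution-recovery tests
  therefore segment the generator's native piecewise-linear paths (where
  recovery is exact), while the render → track → segment round trip is
  checked for shrinking KS distance with growing sample size.
* **Moment series.** Trajectories are translated to a common origin and
  clock; moments are reported on the native frame grid only while at
  least 50 unique trajectories remain, mirroring how sparse long
  recordings become. Mean displacement defaults to the mean of
  magnitudes; the magnitude-of-the-mean-vector convention (the right one
  for estimating a slow uniform drift, since the magnitude of a noisy
  mean is biased upward) is available and used by the drift tests.
* **Breakthrough curves.** Densities are normalized by the total ensemble
  size `C0`, so curve areas equal recovery; arrival moments use the
  population (divide-by-n) convention over arrivers only, matching how
  finite moments can coexist with recoveries well below one. Curves with
  recovery below 2 % are flagged unreliable and dropped from comparison
  plots.
* **Problem sizes.** The test suite uses ensembles of 20–2 500 cells and
  CTRW ensembles of up to 5 000 particles, 125–250 s horizons, and one
  1024² × 200-frame rendered stack; these sizes give every statistical
  assertion a comfortable noise margin while keeping a full run of the
  suite in the minutes range on a single core.

## Known limitations

* Mean arrival times under the default heavy-tailed waiting marginal
  (`alpha = 1.2`) converge slowly; comparisons based on them need
  thousands of trajectories per ensemble (the self-consistency tests are
  sized accordingly).
* The ADE model is evaluated exactly as formulated — planar solution on
  radial control planes, resident-concentration form — because the point
  of the comparison is to quantify that model's adequacy, not to fix it.
* The tracker is not a cell-identity tracker: cells that leave the field
  of view longer than `max_missed` frames return as new trajectories, and
  crossing cells may swap identities. The downstream statistics are
  invariant to both, because trajectories are treated as exchangeable
  samples of the motion process.

## A minimal end-to-end run

```{r pipeline, eval = FALSE}
params <- motility_params(n_cells = 500, t_max = 125, seed = 1,
                          body_length = 2)
truth <- generate_trajectories(params)

master <- build_master(segment_steps(truth$paths, body_length = 2))
ctrw <- simulate_ctrw(master, ctrw_config(coupled = TRUE, n_particles = 2000,
                                          t_max = 125, seed = 2))
bt_ctrw <- first_passage(ctrw, radii = c(10, 20, 30, 40))

bt_real <- real_breakthrough(truth$paths, radii = c(10, 20, 30, 40))

mom <- ensemble_moments(sample_trajectories(truth, frequency = 8))
bt_ade <- ade_breakthrough(
  ade_params(V = max(0, drift_speed(mom)),
             D = diffusion_coefficient(mom, smooth_window = 9),
             radii = c(10, 20, 30, 40)),
  seq(0.25, 125, 0.25))

compare_report(bt_real, ade = bt_ade, ctrw_coupled = bt_ctrw)
plot_breakthrough_comparison(bt_real, ade = bt_ade, ctrw_coupled = bt_ctrw)
```
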