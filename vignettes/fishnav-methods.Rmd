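---
title: "Methods: fish-inspired spiking neural network navigation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fish-inspired spiking neural network navigation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishnav)
```

## The scientific problem

Teleost fish navigate cluttered three-dimensional environments without a
mammal-style hippocampal place-cell map. Recordings from the goldfish
telencephalon instead show **boundary vector cells (BVCs)** — neurons whose
firing increases as the animal approaches a boundary within a receptive
field of up to 1.4 m — and **hydrostatic pressure (HP) cells** tuned to
depth, a one-dimensional ecological cue that is free to read anywhere in
the water column. `fishnav` asks whether these two cell classes, wired
into a biologically plausible spiking controller, are *sufficient* for
goal-directed navigation, and how such an agent compares with a classical
A\* planner given the same sensing limits.

## The model

### Arena

Trials run in a square vertical slice of the water column (default
4 m × 4 m on $[-2, 2]^2$; x is horizontal, z is depth) populated with
circular "coral" obstacles of 0.15 m radius. Start and target are sampled
in opposite quadrants. Walls are visible to the boundary sense and
physically clamp motion. Collisions are **counted, never blocked**: the
collision metric is the fraction of trajectory samples whose distance to
any coral center is below the radius, matching the source's sample-counting
definition.

### Sensing

Distances to the nearest boundary are ray-cast in 24 angular bins of 15°
around the current heading, up to 1.4 m (`visual_scene()`). Each bin feeds
one BVC channel through a rectified-linear distance tuning curve that peaks
at contact and vanishes at the receptive-field edge
(`bvc_tuning_curve()`). The BVC array is an array of *identical* ensembles,
so every channel shares the population-mean tuning. The target itself is
only visible within $r_\mathrm{vis} = 0.3$ m, where a goal attractor
$g - p$ engages.

### Control law

Every millisecond:

1. **Steering.** If the path ahead is blocked ($d_0 < D = 0.4$ m), a
   winner-take-all over the 13 frontal channels picks the clearest
   direction; the steering angle blends 90% of the new winner with 10% of
   the previous one (`steer()`), and ties break toward the smallest
   deviation from the current heading.
2. **Speed.** Blocked: the potential speed is scaled by the relative
   distance $\hat d = (d_0 - \varepsilon)/(D - \varepsilon)$ with a small
   boost $v_\varepsilon$ so a stopped agent can recover. Clear: it
   accelerates by $d_c \tau_2$ per step. Speed folds into $[0, v_{\max}]$,
   $v_{\max} = 0.5$ m/s.
3. **Tracking.** Actual speed and heading relax toward their commands with
   time constant $\tau_2 = 0.1$ s (`error_update()`, heading error wrapped
   to the shortest arc).
4. **Kinematics.** The speed/heading conjunction is filtered with
   $\tau_1 = 0.02$ s and integrated through a $\tau_2$ synapse
   (`integrator_step()`); positional noise of scale $\sigma\sqrt{dt}$ is
   added when $\sigma > 0$.

Strategies differ only in the information available: `null` starts within
±45° of the true bearing and then only avoids obstacles; `azimuth` knows
the initial bearing; `hp` knows the target *depth* plus a fixed binary
horizontal prior $\theta_{HP} \in \{0, \pi\}$ — it climbs or dives at
$\pm\pi/2$ until within 0.2 m of the target depth, then follows the prior.
`hp_max` (LIF, 400 spikes/s, 10× neurons) and `hp_default` (generic
simulator tuning) are controls for the electrophysiological realism.

### Neural substrate

A minimal Neural Engineering Framework implementation
(`nef_ensemble()`, `compute_decoders()`): populations encode variables in
heterogeneous tuning curves and decode functions with regularized
least squares. Rate mode is the deterministic limit; spiking mode carries
the velocity signal in a LIF ensemble whose filtered spike train is
decoded online. Peak rates and receptive fields are drawn from
right-skewed skew-normal fits clipped to the recorded 0.1–4 spikes/s and
(0, 1.4] m ranges; a 10,000-neuron budget is split using the recorded
35/196 BVC fraction (`allocate_populations()`).

## Numerical choices

* `dt` = 1 ms; synaptic filters use the exact discrete update
  $s \leftarrow s + (1 - e^{-dt/\tau})(u - s)$.
* **LIF currents live in drive space** ($J - 1$). At peak rates of
  4 spikes/s, $J_{\max} - 1 \approx 5\times10^{-15}$, far below the
  relative resolution of $1 + x$ in doubles; forming $J$ directly silences
  most of the population. Gains, rates, and the membrane equation are all
  expressed in the suprathreshold drive.
* **The membrane is integrated exactly** in threshold-distance form
  $w = 1 - v$: $w(t) = -j + (j + w_0)e^{-t/\tau_{rc}}$, and the
  threshold-crossing time is interpolated within the step so the
  refractory starts at the crossing. A full-`dt` reset would lengthen
  every interspike interval by up to `dt` — an 18% rate deficit at
  400 spikes/s.
* **Spiking state starts at the stationary phase distribution** (uniform
  in time along each neuron's firing cycle at the known initial value).
  Rest-synchronized neurons at ~1.5 spikes/s would stay collectively
  silent for ~0.5 s, an onset artifact with no biological counterpart.
* The velocity ensemble's representational radius equals $v_{\max}$: the
  folding law bounds the commanded speed and the synaptic low-passes are
  convex, so the signal never leaves that ball.
* Positional noise is interpreted as meters per $\sqrt{s}$ and scaled by
  $\sqrt{dt}$ per step, so per-second variance matches $\sigma^2$.

## Interpretation decisions (gaps in the source description)

* $v_\varepsilon$ is used but never defined; default 0.05 m/s.
* Target capture radius 0.05 m ("reaching the target area" is not
  quantified).
* The printed blocked-speed update has an outer `min` that makes speed
  monotonically non-increasing while blocked, contradicting the stated
  purpose of $v_\varepsilon$ ("so the scaled speed can recover"). The
  exported unit operation `axis_speed_update()` keeps the printed form;
  the trial loop uses the recovering form $(s + v_\varepsilon)\hat d$.
* The slow-down/steering reflex only engages when the agent is *not*
  currently inside a coral. Because collisions are counted rather than
  blocked, an interpenetrating agent sees the exit surface ahead; braking
  on it would park the agent just inside the boundary forever.
* HP bias mapping: the discrete sets $\{0, \pi\}$ and vertical seeking at
  $\pm\pi/2$ are mapped to heading commands; the prior is fixed at trial
  start.
* The A\* local mode accretes sensed corals into memory (forgetting makes
  20 Hz "replanning" ill-defined), and replans take effect at the next
  cell center, so the executed path is always a valid grid path — this
  makes the local-cost ≥ global-cost optimality oracle exact.

## Scope and limitations

* The paper's full scale (50 environments × 10 repeats per condition,
  full spiking populations) is reproduced *scaled down* by default
  (`population_scale = 0.2`, 5–20 environments); plan files under
  `inst/plans/` document each experiment.
* Scene computation (ray casting) is external to the neural substrate, as
  in the source, which black-boxes sensory transduction. The velocity
  pathway is the spiking-mode bottleneck that is actually simulated with
  spikes.
* At the recorded ≤ 4 spikes/s rates, the analytic decoder noise floor
  $\sigma^2 = \sum_i d_i^2 r_i(x) / (2(\tau_1 + \tau_2))$ for 1500 LIF
  neurons is ~9–11% of signal RMS, so spiking-vs-rate velocity agreement
  hovers at the 10% level by physics, not by implementation error.
* The deterministic A\* local agent is *better* than the published one
  (mean normalized time ~0.008 vs ~0.03) and ties the global mode's
  collision rate exactly; both modes traverse the same marginal-clearance
  corridors of the optimal grid path.

## Reproducing the headline numbers

```r
# strategy ordering at desk scale (about 3 minutes)
cs <- fishnav:::child_seed
score <- function(kind, i) {
  env <- generate_environment(arena_config(), seed = cs(42L, 4L, i))
  st <- make_strategy(kind, population_scale = 0.2)
  run_trial(env, st, seed = cs(42L, 4L, i, match(kind, c("hp", "azimuth",
            "null"))), log = FALSE)$result
}
# HP reaches 20/20, azimuth 19/20, null 7/20; Cohen's d (HP vs null) = 1.77

# A* acceptance targets
res <- compare_astar(n_envs = 20, seed = 42L)
```

The acceptance targets themselves are recomputed from scratch by
`scripts/acceptance.R` (see the README).
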