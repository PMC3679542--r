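---
title: "Models and methods behind iftmotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind iftmotion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iftmotion)
```

## The biological problem

*Chlamydomonas* cells glide over surfaces using their flagella. The working
model implemented here is that intraflagellar transport (IFT) trains —
protein complexes hauled along the axoneme by kinesin-2 (anterograde,
base to tip) and dynein-1b (retrograde, tip to base) — carry the flagellar
membrane glycoprotein FMG1-B as cargo. When the glycoprotein's extracellular
domain adheres to the substrate, the train pauses; the dynein motors still
engaged with the paused retrograde train then pull the whole cell toward the
anchor. iftmotion provides the quantitative chain for testing this model:
kymograph construction, velocity decomposition, pause/gliding/lag
statistics, bead-train colocalization, and optical-trap force and drag
analysis — together with a synthetic-data generator that simulates the
underlying biophysics so every stage can be validated against known ground
truth.

## The synthetic-data generator

`simulate_ift()` injects anterograde trains at the base and retrograde
trains at the tip as independent Poisson processes and moves each train at a
per-train speed drawn around the configured means (defaults 2.0 and
2.96 µm/s, the retrograde value with 0.14 µm/s jitter). Trains vanish when
they reach the far end; tip/base remodeling is not simulated because the
analyses concern transit, not turnaround.

**Pausing.** Pausing events form a Poisson process whose rate depends on
free calcium through a saturating Hill map with coefficient 1 and
half-saturation 1 µM:
$$\lambda(c) = \lambda_{\mathrm{res}} + (\lambda_{\max} -
\lambda_{\mathrm{res}})\,\frac{c}{c + K}.$$
So $\lambda(0)$ is the residual rate (default one tenth of the maximum,
matching the roughly tenfold drop seen in calcium-deprived cells) and
$\lambda$ at 0.34 mM (standard TAP media) is within 0.3% of
$\lambda_{\max}$ (default 0.125 s⁻¹). Each event anchors a uniformly chosen
currently-moving train; pause durations are exponential (mean 2 s — the
literature gives no distribution, and an exponential is the natural
memoryless choice consistent with single-adhesion release kinetics; the
mean is set so typical gliding runs span a few micrometres at 0.86 µm/s).
The configured rate is interpreted as the *per-cell aggregate* rate, which
is the observable reported from kymographs (events per acquisition time);
the equivalent per-train hazard would vary with the number of trains in
transit.

**Bead dynamics.** A membrane-bound bead alternates between reflected 1D
diffusion (default 0.1 µm²/s) and coupled segments in which it rides a
train. Attachment events fire as a Poisson process scaled by the same
calcium map (calcium-deprived beads only diffuse) and only take effect when
a train passes within a capture radius (0.25 µm) of the bead — a bead can
only bind cargo it can physically reach. Coupled beads move at
`bead_speed_factor` times the train's velocity (default 0.7: bead-carrying
trains move about 30% slower). For the small-bead colocalization regime the
factor is 1 — small beads move at the same speed as the trains carrying
them; the 30% slowdown applies to the large (~1 µm) beads used in trapping.

**Gliding.** While at least one retrograde-origin pause is anchored and the
two flagella's anchors are unbalanced, the cell body moves at `glide_speed`
(default 0.86 µm/s) toward the majority flagellum, and never beyond the
nearest anchored train; anterograde-origin pauses never initiate motion and
equal anchor counts cancel. Integration is event-driven, so the caps are
exact rather than step-quantized. Train tracks are kept in the body frame
(the frame in which kymographs of the flagellum are drawn); the body track
is lab-frame.

**Rendering.** `render_movie()` draws every train and bead as a symmetric
2D Gaussian (σ = 0.13 µm on a 0.106 µm pixel grid) at its subpixel position
along a straight or per-frame evolving path, integrating four sub-frame
positions per frame — a camera exposure integrates the full frame interval,
and at 5 fps a train moves 4–6 pixels per frame, so instantaneous sampling
would be temporally aliased rather than motion-blurred. Shot noise
(Poisson of signal plus background) and Gaussian read noise are then
applied. Trains are rendered point-like: real trains span 0.2–1 µm, but the
analyses here operate on ridge positions and slopes, which a point emitter
represents faithfully.

**Trap traces.** `simulate_trap_trace()` integrates the overdamped Langevin
equation
$$x_{t+\Delta} = x_t + \Delta\,\frac{F_{\mathrm{motor}} - \kappa x_t}{\gamma}
+ \sqrt{2 k_B T \Delta/\gamma}\,\xi$$
by Euler–Maruyama at the 2 kHz detector rate, with a stability guard
$\Delta\kappa/\gamma < 1$. Motor runs ramp the force at
$\kappa v_{\mathrm{motor}}$ until a drawn stall force (default
N(25.2, 5) pN), hold through an exponential dwell, then release
(exponential recoil with time constant $\gamma/\kappa$) or, for an escape
run, keep pulling past the detector's ±200 nm linear range. Ground-truth
labels record each run with its true peak force; runs with dwell under
100 ms are labelled releases, matching the operational stall definition.

All randomness flows through one seeded generator with per-entity
sub-streams, so identical config and seed give byte-identical ground truth,
movies and traces.

## Kymographs along evolving paths

`sample_kymograph()` resamples the flagellar polyline at 1 px arc-length
steps, reads the movie by bilinear interpolation (edge padding outside the
frame), and averages 3 samples perpendicular to the local tangent (the
flagellum is about 2 px across at 106 nm/px). For cells that reorient their
flagella, `flagellar_path()` takes keyframed curves that share a common
anchor point (validated within 2 px); `interpolate_paths()` resamples each
keyframe at equal arc-length spacing *relative to the anchor* and blends
vertex-wise linearly, so the anchor maps to the same arc-length coordinate
— the same kymograph column — in every frame. Vertex-wise linear blending
is this package's choice of interpolant; for the modest per-keyframe
rotations seen in gliding reversals it deviates from a true rotation by
less than a pixel.

## Fourier-space direction analysis (FSDA)

A trajectory at velocity $v$ in a kymograph concentrates its 2D spectral
energy on the line $f_t = -v f_s$. `build_masks()` partitions frequency
space into velocity wedges — retrograde $(-\infty, -v_{\min})$, paused
$[-v_{\min}, v_{\min}]$, anterograde $(v_{\min}, \infty)$ by default, with
$v_{\min} = 0.2$ µm/s, an order of magnitude below train speeds — with
raised-cosine transitions over 10% of the adjacent wedge angle (hard edges
available for oracle tests). Masks are Hermitian-symmetric and sum exactly
to 1 at every non-DC frequency, so the inverse transforms are real and the
components plus background reconstruct the windowed input to machine
precision. The DC term goes to a background component; the $f_t = 0$ axis
(static structure) falls in the paused wedge; the $f_s = 0$ axis is shared
between the anterograde and retrograde wedges by the softness rule.

`fsda_decompose()` applies a 2D Tukey window (α = 0.25) before the FFT to
suppress border leakage; components can optionally be divided by the window
where it exceeds 0.05 to restore input scale away from the borders. Energy
fractions apply each mask to the power spectrum, so they sum to exactly 1
even with soft edges. One sampling subtlety matters for fast trains at slow
frame rates: a 3 µm/s ridge at 5 fps has spectral content beyond the
temporal Nyquist frequency wherever its spatial frequency exceeds
~0.8 cycles/µm, and that content wraps into the opposite-direction wedge.
The optional `pre_smooth_px` argument applies a ~1 px Gaussian anti-alias
filter along the arc-length axis before the transform, suppressing the
wrapped energy at negligible cost to the ridge geometry.

`velocity_colormap()` labels each pixel by the largest locally smoothed
component magnitude, and `extract_tracks()` turns a directional component
into tracks by per-row local maxima (subpixel via parabolic interpolation),
linking with constant-velocity prediction — a fast ridge advances several
pixels per frame, and gating around the last position rather than the
extrapolated one systematically links to lagging noise peaks and biases
fitted speeds low — and least-squares line fits whose slopes are the train
velocities.

The direction-recovery validation scores a simulated train as correctly
assigned when its own direction component dominates along its ridge, using
the *median* component magnitude over the ridge pixels: a sum is corrupted
by crossings with brighter ridges of the opposite direction. Trains whose
mean Tukey-window weight is below 0.5 are outside the analysis window — a
windowed FFT method cannot measure signal it has apodized away — and are
excluded from the score on both sides.

## Event statistics

**Pauses.** A pause is a maximal run of speed below 0.2 µm/s lasting at
least 0.4 s (2 frames at 5 fps) inside a track that moves before or after;
tracks immotile for the entire acquisition are excluded. Pause *boundaries*
are taken from single-frame displacements: a frame-to-frame gap is
sub-threshold exactly when it lies inside the pause, so the duration
estimate has a symmetric phase error and the censoring threshold is sharp
at the nominal minimum duration. (A central-difference velocity, used here
only for the prior-direction call because it is smoother, needs *both*
neighbours inside the pause, which would shift the effective censoring
threshold a full frame upward and bias the frequency low.) Because pauses
shorter than the minimum duration are censored, the raw count/time
frequency is biased low; `detect_pauses()` also reports a corrected
frequency using the exponential-duration model (detected durations of an
exponential with mean $m$ truncated at $d_{\min}$ average $m + d_{\min}$,
and a fraction $e^{-d_{\min}/m}$ of all pauses is detected). The recovery
suites use the corrected estimator, on noise-free ground-truth tracks: they
isolate the estimator's bias, not localization noise.

**Lag times.** For each gliding onset, the lag to the most recent
retrograde pause start is measured (pause start, not surface-anchoring
time, which is not separately observable); the exponential fit is by
maximum likelihood on the lags themselves, for which the fitted mean equals
the sample mean — bin-free, so there is no histogram-width sensitivity.
Onsets with no preceding retrograde pause are flagged and excluded.

**Independence test.** Under the null that gliding onsets are independent
of pausing, a lag behaves like the waiting time since the last pause:
exponential with the mean inter-pause interval (8.25 s). The mean of $n$
such lags is Gamma distributed, which the test exploits by drawing the
Monte-Carlo sample means directly as Gamma variates; the one-sided p-value
uses the plus-one correction. With the observed mean lag of 0.48 s at
$n = 36$ the p-value is at the Monte-Carlo floor, far below $10^{-4}$.

**Colocalization.** The observed statistic per bead sample is the distance
to the nearest train moving in the same direction. The null preserves each
train's geometry and speed but circularly shifts its start time uniformly
on the frame grid. Two features matter for calibration: consecutive frames
give strongly autocorrelated distances, so bead samples are decimated to
~1 s spacing (the timescale on which a 2.5 µm/s train rearranges the
nearest-distance field); and the pooled null mixes over train arrangements,
making the asymptotic two-sample Kolmogorov–Smirnov p anti- or
over-conservative. The reported p-value is therefore the Monte-Carlo rank
of the observed KS statistic among the same statistic computed for each
null replicate against the pool of the others — exchangeable under the
null, hence calibrated by construction (uniform over replicate simulations,
verified in the test suite). The smallest attainable p is
$1/(n_{\mathrm{null}}+1)$, so detecting coupling at $p < 0.01$ needs at
least 100 randomizations.

## Optical-trap analysis

Stiffness is calibrated by equipartition, $\kappa = k_B T/\mathrm{var}(x)$,
guarded by a split-half variance-ratio stationarity check (ratio within
[0.5, 2]). Event classification segments excursions from the baseline (the
density mode of the trace core) with hysteresis at 5 and 2.5 thermal
standard deviations, then finds the zero-velocity plateau at the excursion
peak with a ~20 ms sliding mean velocity, a threshold of twice the thermal
velocity floor of that estimator, and gap-merging at a quarter of the
100 ms dwell criterion (an Ornstein–Uhlenbeck trace crosses any velocity
threshold transiently, so unmerged runs would fragment every plateau).
Plateaus of at least 100 ms are stalls; shorter returns are releases;
excursions beyond the ±200 nm linear range (equivalently 80 pN at
0.4 pN/nm) are escapes. Stall peak force is the trap force at the plateau
level (the mean over the plateau), which is unbiased under thermal noise,
rather than the running maximum, which is biased upward by extreme-value
noise.

Drag constants come from two routes that must agree: exponential fits to
recoils after detachment ($x(t) = x_0 e^{-t/\tau}$, $\gamma = \kappa\tau$,
reported in pN·s/µm via the factor 1000 from pN/nm·s), with fits rejected
below $R^2 = 0.8$ or when the fitted $\tau$ exceeds the observed decay
(non-identifiable); and per-step relaxation fits to a ±500 nm, 0.2 Hz
square-wave trap oscillation at 0.07 pN/nm, pooled as mean ± SD. Derived
quantities are `motor_count()` = ⌈F/f₁⌉ (at 6–7 pN per motor, a 25.2 pN
peak implies at least 4 motors) and `drag_force()` = γv (16–24 pN at
2–3 µm/s with γ = 8 pN·s/µm) — large enough to explain why bead-carrying
trains and gliding cells move slower than unloaded IFT.

## Problem sizes, tolerances and limitations

The validation suites run at deliberately modest problem sizes chosen to
make their statistical tolerances meaningful: 100 simulated cells of 200 s
for pause-frequency recovery (3 standard errors of the pooled Poisson
count), 200/40 replicates for colocalization calibration/power, 8 cells for
FSDA direction recovery (several hundred trains), 100 recoils and ~350 s of
trace for the trap suites, 150 replicates per τ for lag recovery. FSDA
reconstruction is exact to machine precision by construction; the 10⁻⁶
criterion guards against regressions, not numerical luck.

What the generator does not emulate: photobleaching, multicolor crosstalk,
2D membrane diffusion, axoneme mechanics, bead-size-dependent
hydrodynamics, or the train-length intensity structure. Passing recovery
tests therefore demonstrates that the estimators are unbiased and
well-calibrated under the stated model — not that the model captures every
feature of real TIRF movies. The pause-detection thresholds (0.2 µm/s,
0.4 s) are package defaults an analyst should revisit for data at other
frame rates; the pausing-duration distribution and the per-cell reading of
the pausing rate are modelling choices documented above.
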