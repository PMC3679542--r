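# iftmotion

Quantitative analysis of intraflagellar transport (IFT) and flagellar
surface motility, for researchers studying how IFT trains couple to the
flagellar membrane and drive whole-cell gliding in *Chlamydomonas* and
related flagellates.

IFT trains are hauled along the axoneme by kinesin-2 (anterograde, base →
tip, ~2 µm/s) and dynein-1b (retrograde, tip → base, ~3 µm/s). The model
this package quantifies: trains carry the membrane glycoprotein FMG1-B;
when that cargo adheres to a surface the train pauses, and the dynein
motors still engaged with a paused *retrograde* train pull the cell body
toward the anchor — gliding motility. The package implements the full
evidence chain:

- **Kymographs** from TIFF movies along straight or per-frame evolving
  flagellar paths (`sample_kymograph()`, `flagellar_path()`,
  `interpolate_paths()`), with fixed-anchor stacking for reorienting cells.
- **Fourier-space direction analysis (FSDA)**: a ridge at velocity *v*
  concentrates spectral energy on the line *f_t = −v·f_s*, so wedge masks in
  frequency space split a kymograph into anterograde, retrograde and paused
  components (`fsda_decompose()`, `velocity_colormap()`,
  `extract_tracks()`).
- **Event statistics**: subpixel 2D Gaussian localization
  (`localize_gaussian()`), bead–train colocalization against a
  time-randomized null with a Kolmogorov–Smirnov statistic
  (`colocalization_test()`), pause detection and pausing frequency
  (`detect_pauses()`), gliding onsets (`detect_gliding_onset()`),
  pause-to-gliding lag times with exponential fits (`lag_time_analysis()`),
  and a Monte-Carlo independence test (`independence_test()`).
- **Optical-trap analysis**: equipartition stiffness calibration
  (κ = k_BT / var(x), `calibrate_stiffness()`), stall / release / escape
  classification with the ≥100 ms zero-velocity stall criterion
  (`classify_events()`), peak-force statistics (`peak_force_stats()`), drag
  constants from exponential recoils (γ = κτ, `fit_recoil()`) and from
  square-wave trap oscillation (`oscillation_drag()`), and the derived
  quantities `motor_count()` (⌈F/f₁⌉) and `drag_force()` (γ·v).
- **A synthetic-data generator** (`simulate_ift()`, `simulate_bead()`,
  `simulate_gliding()`, `render_movie()`, `simulate_trap_trace()`) that
  simulates the underlying biophysics — Poisson train injection,
  calcium-dependent pausing, bead coupling, anchor-capped gliding,
  overdamped Langevin bead-in-trap dynamics — so every analysis stage is
  testable against known ground truth without any experimental data.

Everything tabular flows through tibbles and pipes; result objects have
`tidy()` / `glance()` methods and `autoplot()` ggplot2 graphics.

## Worked example

```r
library(iftmotion)

cfg <- sim_config(duration = 60, seed = 3)       # one cell, 60 s at 5 fps
truth <- simulate_ift(cfg) |>
  simulate_bead(config = cfg) |>
  simulate_gliding(config = cfg)
truth
#> <ift_truth>
#>   120 trains (13 pauses, 0 dropped), 60 s, 1 flagella
#>   bead track: 301 samples
#>   cell-body track: 301 samples

movie <- render_movie(truth, cfg)                # noisy TIRF-like stack
movie
#> <ift_movie> 301 frames, 16 x 111 px, 0.106 um/px, 0.2 s/frame

kymo <- sample_kymograph(movie,
                         iftmotion:::straight_path(cfg$flagellum_length,
                                                   cfg$pixel_size, 8, 8))
fsda_decompose(kymo)
#> <fsda_result>
#>   retrograde   energy fraction 0.2051
#>   paused       energy fraction 0.0908
#>   anterograde  energy fraction 0.2575
#>   background   energy fraction 0.4467
```

The energy fractions say how the kymograph's (non-windowed-out) signal
splits across transport directions: here comparable anterograde and
retrograde traffic over a diffuse background, with a small paused fraction —
as expected at this pausing rate. Pause statistics and the independence
test:

```r
detect_pauses(truth$track, acquisition_time = cfg$duration)
#> <pause_set> 12 pauses in 60.0 s: 0.2000 s^-1 raw, 0.2731 corrected (0 immotile tracks excluded)

independence_test(mean_lag = 0.48, n = 36, mean_interpause = 8.25,
                  n_mc = 1e6, seed = 1)
#> # A tibble: 1 × 6
#>      p_value mean_lag mean_interpause     n    n_mc  seed
#>        <dbl>    <dbl>           <dbl> <int>   <int> <int>
#> 1 0.00000100     0.48            8.25    36 1000000     1
```

(The configured pausing rate is 0.125 s⁻¹; this particular 60 s draw
happened to land on the upper tail of the Poisson count — over many seeds
the corrected estimate averages the configured rate, which is what the
recovery suite checks.)

With a mean lag of 0.48 s between the last retrograde pause and gliding
onset, against pausing events every 8.25 s, the null that pausing and
gliding are independent is rejected at the Monte-Carlo floor (p ≈ 10⁻⁶,
i.e. p < 0.0001): gliding onsets follow retrograde pauses far too quickly
to be coincidence.

Trap-side, in one chain:

```r
trace <- simulate_trap_trace(trap_sim_config(run_rate = 1, seed = 11),
                             duration = 120)
events <- classify_events(trace)
peak_force_stats(events)$summary |> dplyr::filter(type == "stall")
#> # A tibble: 2 × 5
#>   direction   type      n  mean   sem
#>   <chr>       <chr> <int> <dbl> <dbl>
#> 1 anterograde stall    26  25.4 1.20
#> 2 retrograde  stall    31  26.4 0.913
motor_count(25.2, 7)     # >= 4 motors behind a 25.2 pN stall
#> [1] 4
drag_force(8.0, 2:3)     # 16-24 pN viscous load at transport speeds
#> [1] 16 24
```

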