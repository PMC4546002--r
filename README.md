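# okndrive

Optokinetic nystagmus (OKN) analysis of driver gaze strategies in bends.

Where do drivers look when steering through a curve — at the **tangent
point** (TP), the spot where the line of sight grazes the inside lane edge,
or at **waypoints on the future path**? The two targets sit so close in the
visual field that gaze position cannot tell them apart. Gaze *velocity*
can: on a constant-radius path the TP is stationary in the visual field
(its direction from the heading is `90° − asin(R/d)`, constant), while the
line of sight to any world-fixed point on the path rotates at exactly
**minus half the vehicle yaw rate** — so waypoint tracking produces an OKN
pattern of slow pursuit phases at `−ω/2` with small resetting saccades.
The package's central statistic, per detected slow phase during cornering,
is

    Δ = ½·|mean yaw rate| − v_against      (deg/s)

where `v_against` is the horizontal slow-phase velocity against the bend.
Waypoint tracking predicts Δ ≈ 0; TP fixation predicts Δ ≈ +½|yaw|.

The package provides, as testable R functions:

* closed-form cornering geometry (`bend_geometry()`, `vehicle_state_at()`,
  `tangent_point_direction()`, `waypoint_direction()`, `gaze_angle_rate()`);
* a seeded simulator of multirate gaze/vehicle sensor records (60 Hz gaze,
  100 Hz CAN, 1 Hz GPS) under waypoint, TP, and TP-plus-reflex strategies,
  with exact ground-truth event logs (`simulate_trial()`,
  `simulate_cohort()`);
* preprocessing: quality filtering, multirate resampling, GPS alignment to
  a prototype lap, bend-phase labelling (`align_trial()`);
* exact dynamic-programming segmentation of noisy 2-D gaze traces into
  linear slow phases and saccades (`partition_signal()`,
  `detect_segments()`);
* the Δ statistic with per-subject aggregation, 95% confidence intervals
  and condition contrasts (`velocity_statistic()`, `group_inference()`).

## Worked example

The geometry behind the predictions, at the study's scale (48 m radius,
42 km/h):

```r
library(okndrive)
b  <- bend_geometry()                      # 46 m inner edge + 4 m lane
st <- vehicle_state_at(b, path_radius = 48, speed = 42 / 3.6, t = 0)
st$yaw_rate
#> [1] 13.92606                             # deg/s, = (v/r)·180/π
tangent_point_direction(st, b)$horizontal
#> [1] 16.59784                             # deg, constant while cornering
wp <- path_point(b, 48, arc_position = 40) # a waypoint 40 m ahead
gaze_angle_rate(st, wp) / st$yaw_rate
#> [1] -0.5                                 # the half-yaw-rate law
```

A full synthetic experiment — 7 subjects, 16 laps each in alternating
normal/tp blocks — simulated, segmented and analysed (about 20 s):

```r
cfg      <- run_config()
trials   <- simulate_cohort(cfg$sim)
segments <- detect_cohort(trials, cfg)
analyze_segments(segments, cfg)
#> <okn_report>
#> <group_result>
#>   normal   mean Delta =   0.58 deg/s, 95% CI [0.40, 0.76], n = 7
#>   tp       mean Delta =   7.19 deg/s, 95% CI [6.46, 7.92], n = 7
#>   paired tp - normal: t(6) = 21.64, p = 6.36e-07
#>   pooled normal+control CI [0.40, 0.76], n = 7
#>   trial strategy classification accuracy: 100.0%
```

Reading the numbers: under free ("normal") driving the per-subject mean Δ
sits near zero — horizontal slow-phase velocity matches half the yaw rate,
as waypoint tracking predicts — while under the tangent-point instruction Δ
rises to about ½·|yaw| (here ≈ 7.2 deg/s at ≈ 14.4 deg/s mean yaw),
because the eye stops moving horizontally. The paired contrast separates
the conditions decisively and every lap is classified to the correct
strategy. The small positive offset in the normal condition is a known
detection-stage bias at the default noise level, quantified and discussed
in the methods vignette (`vignettes/okn-curve-driving.Rmd`).

File-based runs (`run_all(cfg, "out/")`) write trial CSVs with ground-truth
sidecars, a segments TSV, and a JSON report; formats are documented in
`FORMATS.md`, and `inst/cli/okndrive-cli.R` wraps the same functions for
shell use.

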