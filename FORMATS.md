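# File formats

All files are UTF-8 text with `.` as the decimal separator. Angles are in
degrees, angular rates in deg/s, distances in metres, speeds in m/s, times
in seconds. A header row is mandatory in every tabular file.

## Trial CSV (`trial_<subject>_<nn>_<condition>.csv`)

One row per 60 Hz gaze sample, comma-separated:

| column      | meaning                                                      |
|-------------|--------------------------------------------------------------|
| `t`         | time from trial start (s)                                    |
| `gh_deg`    | horizontal gaze angle (deg, positive right of heading)       |
| `gv_deg`    | vertical gaze angle (deg, positive below the horizon)        |
| `quality`   | tracker quality in [0, 1]; samples < 0.2 are excluded        |
| `speed_mps` | vehicle speed, CAN channel held at the preceding 100 Hz value|
| `yaw_dps`   | yaw rate, allocentric heading rate (CCW positive)            |
| `x_m`, `y_m`| planar position, 1 Hz GPS linearly interpolated              |
| `subject`, `trial`, `condition` | labels (`condition` in normal/tp/control)|

A sidecar JSON with the same basename carries the ground-truth event log
(`t_start`, `t_end`, `type` slow_phase/saccade, `target_id`) and the trial
metadata including the bend geometry.

## Bend geometry JSON

Keys mirror `bend_geometry()` fields: `center` (m), `inner_edge_radius`
(m), `lane_width` (m), `arc_span` (deg), `handedness` (right/left),
`entry_length` (m), `exit_cutoff` (m), `id`.

## Segments TSV (`segments.tsv`)

Tab-separated, one row per detected segment: `subject`, `trial`,
`condition`, `bend`, `handedness`, `phase`, `t_start`, `t_end`,
`duration`, `n`, `slope_h`, `slope_v`, `amp_h`, `amp_v`, `speed`,
`direction` (deg, 0 = vehicle-frame upward, positive clockwise), `class`
(slow_phase/saccade/discarded), `yaw_mean`.

## Analysis report (`analysis/report.json`)

`parameters` echoes every threshold and sign convention (including the
Delta orientation: tangent-point fixation positive) plus the configuration
MD5 and package version; `groups` holds per-condition means and 95%
confidence intervals of per-subject mean Delta; `paired_normal_tp` and
`independent_normal_control` the condition contrasts;
`classification_accuracy` the per-trial strategy classification rate.
Companion TSVs: `per_subject.tsv`, `histogram.tsv`, `delta_stats.tsv`.
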