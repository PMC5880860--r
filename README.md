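# gazeparse

Adaptive parsing of raw eye-tracking data into fixations and saccades, with
per-trial data-driven velocity thresholds, robustness-aware post-processing,
data-quality metrics, and a ground-truth gaze simulator for validation.

## The problem

Eye-tracking studies need raw gaze samples segmented into **fixations**
(gaze nearly stationary; visual encoding happens) and **saccades** (rapid
jumps between fixations). Manufacturer defaults use one fixed threshold for
everyone — a velocity cut (EyeLink: 35 deg/s) or a dispersion cut (Tobii
Clearview: 0.9°). When data quality varies across participants and trials —
the rule in infant, clinical and developmental work — fixed thresholds shred
noisy fixations into spurious short ones and end fixations at every signal
dropout, correlating data quality with the very outcome measures under study.

`gazeparse` instead estimates a velocity threshold for every trial from that
trial's own data. Per-sample speed is the central difference

v(i) = ‖p(i+1) − p(i−1)‖ / (t(i+1) − t(i−1))   [deg/s],

and samples whose speed strictly exceeds both neighbours are *local speed
maxima*. Their exceedance distribution S_obs(v) = #{m > v} is compared to a
uniform null S_null(v) = n·(max−v)/(max−min) through a gap statistic

gap(v) = (S_null(v) − S_obs(v)) / n,

which is smoothed by locally weighted quadratic regression (loess) at
increasing bandwidths until unimodal; the speed at the unique mode is the
trial's threshold. Around that core sit: binocular (cyclopean) merging,
velocity-guarded interpolation of missing runs < 250 ms, convex-hull overlap
merging of successive fixations, and a 100-ms duration threshold. Baseline
parsers (`mould`, `mouldDur`, fixed `velocity`, `dispersion`), per-trial
quality metrics (robustness = mean valid-segment length; precision = mean
deviation from a 100-ms windowed mean), a cross-method fixation split/
not-classified comparison, and a ground-truth scanpath simulator are
included. See the vignette in `vignettes/adaptive-gaze-parsing.Rmd` for the
full method description and design rationale.

## Worked example

Simulate a noisy, flickery binocular recording with known ground truth and
parse it adaptively:

```r
library(gazeparse)

sim <- simulate_gaze(simulation_spec(
  n_trials = 2, noise_sd_deg = 0.3, seed = 42,
  flicker = list(mean_valid_ms = 300, mean_missing_ms = 100)))

ev <- parse_recording(sim$recording, parser_config("gazepath"))
head(ev, 7)
#>   Participant Value Duration Start  End mean_x mean_y sdPOGsacAMP    RMS Order Trial
#> 1         sim     f     1124     2 1126 1176.6  959.3      14.051 0.4953     1     1
#> 2         sim     s        2  1126 1128 1184.5  958.1          NA     NA     2     1
#> 3         sim     s        2  1130 1132 1175.6  980.9          NA     NA     3     1
#> 4         sim     s       34  1140 1174  797.5  911.2      17.088     NA     4     1
#> 5         sim     s        2  1176 1178  412.3  855.4          NA     NA     5     1
#> 6         sim     f     1700  1178 2878  372.4  848.2      28.039 0.4981     6     1
#> 7         sim     s        8  2878 2886  606.7  697.2       3.537     NA     7     1
```

Each row is one event: `Value` marks fixation (`f`) or saccade (`s`);
`Duration`, `Start`, `End` are in ms from trial start; `mean_x`/`mean_y` the
pixel centroid; `sdPOGsacAMP` holds the standard deviation of point of gaze
in px for fixations and the saccade amplitude in degrees for saccades; `RMS`
the within-fixation sample-to-sample root-mean-square in degrees. The first
fixation lasts 1124 ms around (1177, 959) with a 14-px spread; the 2-ms `s`
rows are single-sample bursts above threshold around flicker gaps — material
the 100-ms duration rule keeps out of the fixation set.

Per-trial threshold diagnostics and quality metrics:

```r
attr(ev, "diagnostics")
#>   trial threshold n_local_maxima bandwidth valid n_events
#> 1     1     266.9           1347       0.1  TRUE       27
#> 2     2     256.1           1302       0.1  TRUE       21

trial_quality(sim$recording)
#>   participant trial robustness_ms precision_px n_valid n_total
#> 1         sim     1         974.5        35.15    3898    4000
#> 2         sim     2         832.9        26.28    3748    4000
```

The estimated thresholds (~260 deg/s) track this recording's heavy noise
(0.3° per axis at 500 Hz); robustness below 1 s reflects the injected
flicker. Both trials recover exactly the 10 true fixations:

```r
sum(ev$Value == "f")           # 20 parsed fixations
sum(sim$truth$events$kind == "f")  # 20 true fixations
```

Real recordings enter through `read_recording()` with a `column_map()`
describing the export's columns, and results leave through `write_events()`
in four forms (`all`, `fixations_only`, `complete_all`,
`complete_fixations`). A command-line front end (`inst/exec/gazeparse`)
wraps the batch workflow: `parse`, `simulate`, `compare`, `quality`.

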