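# fepoch

Floating-epoch analysis of raw hip-worn accelerometry for predicting
oxygen consumption (VO2) during walking.

Conventional raw-accelerometry intensity metrics summarise the signal over
fixed windows — typically the mean amplitude deviation (MAD) of the
resultant acceleration over 6 s epochs. Fixed windows smooth over the
braking, re-acceleration and turning events that make irregular walking
energetically expensive, which is exactly where fixed-epoch VO2 prediction
equations fail. `fepoch` implements a stride-adaptive alternative: the
analysis epoch *floats* with the gait, spanning two adjacent steps and
advancing one step at a time.

For step *k* with *N<sub>k</sub>* samples starting at sample *j*:

* per-step MAD: `MAD_k = (1/N_k) Σ |r[i] − R_LF[i]|`, where `r` is the
  resultant acceleration and `R_LF` its 0.12 Hz low-pass baseline;
* floating-epoch MAD (two adjacent steps, one-step overlap):
  `MAD_f,k = (MAD_{k−1} N_{k−1} + MAD_k N_k) / (N_{k−1} + N_k)`;
* epoch-to-epoch change: `dMAD_f,k = MAD_f,k − MAD_f,k−1`;
* step frequency: `f_s,k = 2·sr / (N_{k−1} + N_k)` at sampling rate `sr`.

Steps are segmented on the 1–3 Hz band-passed resultant by positive zero
crossing through +0.05 g with ±0.05 g hysteresis; all filters are the
fixed-point recursive forms used on-device (see
`vignette("floating-epochs")`). VO2 is predicted by linear equations
`VO2 = b0 + b1·MAD + b2·|dMAD| + b3·exp(f_s)` (mL/kg/min); four published
coefficient sets are bundled, and models can be refitted by ordinary least
squares and compared with bias, SEE, R², MAPE and Bland–Altman limits of
agreement. A synthetic gait generator emulates the two source protocols
(staged constant-speed walking; fast 15 m shuttle walking with turns) so
the whole pipeline is testable without human data.

## Worked example

Simulate two minutes of walking (60 s at 1.0 m/s, then 60 s at 1.8 m/s),
extract features, and predict VO2 for the faster minute:

```r
library(fepoch)

prof <- gait_profile(stages = data.frame(duration_s = c(60, 60),
                                         speed_ms = c(1.0, 1.8)), seed = 42)
sim   <- simulate_recording(prof)       # recording + generator ground truth
feats <- epoch_features(sim$recording)  # floating and fixed 6 s epochs

summ <- summarize_features(feats, "floating", window = c(60, 120))
summ
#> <feature_summary> floating, 126 epochs, window [60.0, 120.0] s
#>   mean MAD     292.580 mg
#>   mean |dMAD|    2.342 mg
#>   mean f_s      2.1200 Hz

m <- bundled_model("acdc_float")
predict(m, summ)
#> [1] 15.50626
```

The summary says: across the 126 stride-cycle epochs in the second minute,
the movement intensity averaged 293 mg of MAD, the stride-to-stride change
was small (2.3 mg — steady gait), and the cadence was 2.12 Hz. The bundled
shuttle-test floating-epoch equation maps those features to an oxygen cost
of 15.5 mL/kg/min, a brisk walk. The fixed 6 s epochs over the same window
give a near-identical mean MAD (292.674 mg), as they should on steady
gait — the two epoch kinds diverge only when intensity changes within a
window.

A command-line interface wrapping the same functions is installed at
`exec/fepoch` (subcommands `features`, `predict`, `fit`, `validate`,
`simulate`; run it with `Rscript`).

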