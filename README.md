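# swinescore

Pig-specific sepsis severity scoring for conscious swine trauma models.

Clinical sepsis scores are defined for humans; using them in a porcine
trauma model requires species-specific thresholds that respect the
animal facility's 12-h light cycle. `swinescore` implements the complete
analysis chain for a 72-hour conscious Yorkshire-pig model of penetrating
abdominal trauma (PAT) with fecal peritonitis:

* **Threshold derivation** — pig-specific SIRS criteria and NEWS2 bands
  from healthy-baseline telemetry, per diurnal phase: SIRS bounds at
  `mean ± 2 SD`, NEWS2 band edges at `mean ± {1,2,3,4} SD`, rounded to
  display precision, with an audit report comparing every derived cell
  against the published tables.
* **Scoring engines** — SIRS (≥2 of 4 criteria strictly outside the
  phase bounds), an adapted six-system porcine SOFA (0–24, sepsis at an
  increase of ≥2 over the animal's pre-injury baseline) whose
  neurological component is the SNORT observer rubric (2–11), and NEWS2
  (positive at a total ≥5 or any single 3-point "extreme" parameter).
* **Cohort pipeline** — trailing 8-h telemetry window averaging at each
  blood draw, per-timepoint prevalence tables with death censoring,
  exact Mann-Whitney group comparison (full rank enumeration, mid-rank
  ties) with Holm-Sidak step-down correction, survival summaries, and a
  deterministic rule-based classifier emulating blinded group review.
* **Synthetic cohort generator** — a first-class, tested simulator of
  control and PAT animal courses (diurnal AR(1) telemetry, 8-hourly
  blood panels, SNORT walks, a calibrated mortality process) so the
  entire pipeline is reproducible without animal data.

## Worked example

```r
library(swinescore)

cfg    <- simulation_config(telemetry_step_min = 30, seed = 2026)
cohort <- simulate_cohort(cfg)

stats <- compute_diurnal_stats(cohort)     # 48-h healthy baseline window
sirs  <- derive_sirs_table(stats)
news2 <- derive_news2_table(stats)
sirs
#>   parameter  phase     mean         sd lower upper
#> 1        hr    day 99.53088 15.0995232  69.0 130.0
#> 2        hr  night 90.32050 12.1507928  66.0 115.0
#> 3        rr    day 22.09536  3.6317139  15.0  29.0
#> 4        rr  night 16.16976  3.2154422  10.0  23.0
#> 5      temp    day 38.56418  0.6742864  37.2  39.9
#> 6      temp  night 38.83163  0.4457288  37.9  39.7
#> 7       wbc pooled 19.21551  3.5323112  12.2  26.3

tc <- score_cohort(cohort, sirs, news2)    # snapshots at 0, 8, ..., 72 h
pv <- prevalence_table(tc)
head(pv[pv$group == "pat", ], 5)
#>    time_h group n_alive sirs_pct sofa_pct news2_pct
#> 2       0   pat       8        0        0         0
#> 4       8   pat       8      100      100       100
#> 6      16   pat       7       86      100       100
#> 8      24   pat       6       33      100       100
#> 10     32   pat       6        0      100       100

survival_summary(cohort)
#> $survival_rate_pct
#> [1] 75
#> $mean_survival_h
#> [1] 58.11909

head(compare_groups(tc, score = "news2_total"), 4)
#>   time_h n_control n_pat statistic       p_raw      p_adj
#> 1      0         4     8        10 0.490909091 0.49090909
#> 2      8         4     8         0 0.002020202 0.02001935
#> 3     16         4     7         0 0.003030303 0.02694448
#> 4     24         4     6         0 0.004761905 0.03746633

attr(classify_cohort(tc), "accuracy")
#> [1] 1
```

Reading the output: the derived SIRS bounds recover the configured
healthy-baseline physiology (daytime heart rate 100 ± 15.1 bpm gives
bounds near 70/130 bpm); after injury every surviving PAT animal is
NEWS2-positive and SOFA-flagged from 8 h onward while controls stay
silent; one quarter of the PAT group dies (here at 75% survival, mean
survival ~58 h); the exact Mann-Whitney p values separate the groups at
every post-injury timepoint after Holm-Sidak correction; and the
rule-based classifier recovers every group label.

Individual snapshots can be scored directly:

```r
tab  <- printed_sirs_table()
snap <- vitals_snapshot(phase = "day", hr = 201, rr = 20,
                        temp = 39.2, wbc = 3.9)
evaluate_sirs(snap, tab)
#> <sirs_result> 2/4 criteria met -> SIRS state: TRUE
#>    hr:MET  rr:-  temp:-  wbc:MET
```

## Package layout

| Area | Functions |
| --- | --- |
| Simulation | `channel_spec`, `default_channels`, `injury_response`, `simulation_config`, `simulate_cohort`, `simulate_survival`, `sample_death_times` |
| Thresholds | `diurnal_phase`, `partition_diurnal`, `compute_diurnal_stats`, `derive_sirs_table`, `derive_news2_table`, `printed_*`, `audit_*`, `write/read_thresholds_yaml` |
| Scoring | `vitals_snapshot`, `evaluate_sirs`, `sofa_component`, `sofa_total`, `news2_points`, `news2_total`, `snort_rubric`, `snort_score` |
| Pipeline | `window_average`, `diurnal_average`, `score_cohort`, `prevalence_table`, `survival_summary`, `exact_mann_whitney`, `holm_sidak_adjust`, `compare_groups`, `classify_animal`, `classify_cohort`, `robust_outlier_flag`, `write/read_cohort` |

See `vignettes/severity-scoring-methods.Rmd` for the full account of the
models, band conventions, generator calibration and known limitations.
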