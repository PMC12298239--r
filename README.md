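# tremorband

Band-limited spectral analysis of physiological tremor from single-axis
accelerometry, with the cohort statistics used in neuromuscular fatigue
studies.

## What it does, and for whom

Physiological tremor — the involuntary low-amplitude oscillation of a limb
in healthy people — changes measurably after intense exercise, which makes
it a non-invasive marker of neuromuscular fatigue in sports science and
rehabilitation. The standard protocol records the vertical acceleration of
a supported lower limb at 200 Hz for ~30 s per trial and reduces each
recording to two indices per frequency band:

* **L(f₁,f₂)** — the band log-amplitude,
  `L = (1/(f₂−f₁)) ∫ ln PSD(f) df`, discretized as the mean of `ln PSD`
  over FFT bins inside the closed band;
* **F(f₁,f₂)** — the band mean frequency (spectral centroid),
  `F = ∫ f·PSD df / ∫ PSD df`, in Hz;

over the lower-limb bands **2–5 Hz** (postural control, slow-twitch drive)
and **9–14 Hz** (central drive, fast-twitch activation). The PSD is a
6-segment averaged, Hann-windowed, density-scaled FFT periodogram of
1024-sample blocks (Δf = 0.1953125 Hz).

On top of the indices sits the cohort layer for the fully within-subject
design condition (rest / after endurance / after sprint) × side
(left / right): Shapiro–Wilk and Levene assumption checks, two-within-factor
repeated-measures ANOVA with partial η², Tukey post hoc contrasts on the
matching repeated-measures error term, and pooled-variance t / Cohen's d
computed directly from printed group summaries.

Because raw tremor recordings are rarely deposited, the package includes a
seeded synthetic generator at two levels — band-shaped signals with a
closed-form true spectrum, and index-level cohorts with known condition
effects, subject random effects and interlimb correlation — so the whole
pipeline is testable end to end.

## Worked example

```r
library(tremorband)

# one synthetic recording with known spectral ground truth
rec <- simulate_tremor_signal(signal_params(seed = 7))
rec
#> <accel_recording> subject SIM01, left limb, rest
#>   6144 samples @ 200 Hz (30.72 s), units: m/s^2

compute_indices(rec)
#> # A tibble: 2 × 6
#>   subject_id condition limb  band      L     F
#> 1 SIM01      rest      left  2_5    7.69  3.12
#> 2 SIM01      rest      left  9_14   4.41 11.5
```

`L = 7.69` is the mean log PSD density over the 15 bins of the 2–5 Hz band
(sensor-unit dependent up to an additive constant); `F = 3.12 Hz` is the
in-band centroid, close to the generator's 3.2 Hz bump.

```r
# a 19-subject cohort with calibrated post-training shifts
tab <- simulate_cohort(cohort_design(seed = 42))
fit <- rm_anova(tab, dv = "L", band = "2_5")
fit
#> Repeated-measures ANOVA: L, band 2_5 (n = 19 subjects)
#>          effect ss_effect ss_error df1 df2 statistic partial_eta_sq   p_value effect_label
#>       condition  19.18754   18.028   2  36  19.15763        0.51558 2.158e-06        large
#>            side   0.07412    2.570   1  18   0.51919        0.02804 4.804e-01        small
#>  condition:side   0.01813    3.468   2  36   0.09409        0.00520 9.104e-01   negligible

tukey_posthoc(tab, dv = "L", band = "2_5")
#> # A tibble: 3 × 4
#>   contrast           estimate    p_unadj      p_adj
#> 1 endurance - rest     0.837  0.00000927 0.0000272
#> 2 sprint - rest        0.900  0.00000284 0.00000835
#> 3 sprint - endurance   0.0625 0.702      0.922
```

Training condition has a large effect on low-band tremor amplitude
(η²ₚ = 0.52): both post-training conditions differ from rest, while sprint
and endurance do not differ from each other — the qualitative pattern the
generator's calibration encodes. `tidy(fit)` and `glance(fit)` return the
same results as tibbles; `autoplot(estimate_psd(rec))` and
`plot_indices(tab)` draw the spectrum and the cohort distributions.

Group comparisons from printed summaries alone:

```r
demographic_tests(speed_skater_demographics())
#> # A tibble: 3 × 6
#>   variable  statistic    df p_value cohen_d effect_label
#> 1 age          -1.13     36  0.266    0.366 small
#> 2 body_mass    -2.07     36  0.0453   0.673 medium
#> 3 height       -0.920    36  0.364    0.299 small
```

`run_pipeline(pipeline_config(...))` chains every stage (read or simulate →
PSD → indices → assumption checks → ANOVA → post hoc) into one seeded,
reproducible run that writes TSV reports; a thin command-line wrapper lives
at `inst/scripts/tremorband.R`.

## Method vignette

`vignettes/tremorband-methods.Rmd` documents the estimation conventions
(windowing, normalization, band rules, the log-periodogram bias), the
statistical model and its assumptions, the generator's calibration and its
limits, and the numerical edge-case policy.
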