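---
title: "Band-limited spectral analysis of physiological tremor: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-limited spectral analysis of physiological tremor: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tremorband)
library(dplyr)
```

## The measurement problem

Physiological tremor is the involuntary, low-amplitude oscillation of a limb
in healthy individuals, arising from the interplay of mechanical resonance
and neural drive. After strenuous exercise its amplitude and spectral
content shift, which makes it a convenient non-invasive window on
neuromuscular fatigue. The measurement setup this package targets is a
single-axis accelerometer on a supported lower limb, recording the vertical
acceleration component at 200 Hz while the subject holds the limb still;
each trial contributes 6144 analyzed samples (30.72 s).

Two summary indices are extracted from each recording's power spectral
density (PSD), per frequency band $[f_1, f_2]$:

* the **log-amplitude** $L(f_1,f_2) = \frac{1}{f_2-f_1}\int_{f_1}^{f_2}
  \ln \mathrm{PSD}(f)\, df$, discretized as the unweighted mean of
  $\ln \mathrm{PSD}$ over the FFT bins whose centers fall in the closed
  band interval;
* the **mean frequency** $F(f_1,f_2) = \int f\,\mathrm{PSD}\,df \big/
  \int \mathrm{PSD}\,df$, the in-band spectral centroid, in Hz.

The canonical lower-limb bands are 2–5 Hz (postural control, slow-twitch
drive) and 9–14 Hz (central drive, fast-twitch activation). These replace
the 8–12 Hz convention familiar from upper-limb work: the larger muscle
mass of the leg shifts and widens the informative ranges.

## PSD estimation

`estimate_psd()` implements a segment-averaged periodogram:

1. take exactly `n_segments` (default 6) contiguous, non-overlapping blocks
   of `segment_length` (default 1024) samples from the start of the
   recording — 6 × 1024 = 6144 uses the full analyzed trace with zero
   overlap;
2. subtract each block's mean (`detrend = "mean"`), since the gravity /
   posture DC offset would otherwise dominate bin 0;
3. taper with a periodic raised-cosine (Hann) window — the standard reading
   of a "cosine window" in PSD estimation; the rectangular window is kept as
   an option because its Parseval identity is exact, which the test oracles
   exploit;
4. FFT and form the one-sided density periodogram
   $P_k = 2\lvert X_k \rvert^2 / (f_s U N)$ with no doubling at DC and
   Nyquist, where $U = \overline{w^2}$ compensates the window's power loss;
5. average the six periodograms arithmetically.

With these conventions $\sum_k P_k \,\Delta f$ equals the mean per-segment
variance of the detrended signal — exactly for the rectangular window, in
expectation (a fraction of a percent in practice) for Hann, where windowing
redistributes but does not create or destroy power on white noise. The
frequency grid is $k \Delta f$ with $\Delta f = f_s/N = 0.1953125$ Hz at
the defaults.

No digital anti-alias filter is applied: analog Nyquist filtering belongs
in the acquisition hardware before sampling, and re-filtering already
sampled data at Nyquist is a no-op. The synthetic generator therefore
produces band-limited signals by construction.

```{r psd-example}
rec <- simulate_tremor_signal(signal_params(seed = 7))
psd <- estimate_psd(rec)
sum(psd$psd) * psd_resolution(psd)   # ~ signal variance
```

## Index conventions and their consequences

* **Band rule.** A bin belongs to the band when its center frequency lies
  in the closed interval $[f_1, f_2]$; the DC bin is always excluded and
  edges are never interpolated. At the defaults, the 2–5 Hz band covers 15
  bins (2.148–4.883 Hz) and a flat spectrum has
  $F(2,5) = 3.515625$ Hz, the mean in-band bin frequency.
* **Normalization of L.** $L$ averages over included bins rather than
  dividing the integral by $f_2 - f_1$, which avoids bias when band edges
  fall between bins. The difference from the continuous definition is
  $O(\Delta f)$ and vanishes as `segment_length` grows (checked at 1024 vs
  8192 in the test suite).
* **Units.** $L$ is only defined up to the additive constant $2 \ln c$
  fixed by the sensor's unit convention ($c$ a rescaling of the signal),
  while $F$ is scale-free. Published absolute levels of $L$ (≈ 8.9 at rest
  in the low band) are in unstated sensor units, so the package never
  targets absolute $L$ levels analytically — only differences, contrasts
  and analytic references are meaningful, and all tests respect that.
* **Estimator bias of L.** Each bin of an $m$-segment averaged periodogram
  of Gaussian noise is $\mathrm{PSD} \cdot \chi^2_{2m}/2m$ distributed, so
  $\mathbb{E}[\ln \widehat{\mathrm{PSD}}] = \ln \mathrm{PSD} + \psi(m) -
  \ln m$ — about −0.085 at $m = 6$. `log_psd_bias()` exposes this offset;
  analytic references in the tests include it.
* **Degenerate spectra.** Zero in-band power makes $L$ undefined and $F$
  degenerate; both fail loudly. A positive log-floor can be supplied
  explicitly (`floor =`), never silently.

## The statistical layer

The cohort design is fully within-subject: condition (rest, after
endurance, after sprint) × side (left, right), measured on the same
subjects. `rm_anova()` performs the univariate repeated-measures
decomposition per dependent variable and band: effect sums of squares from
marginal cell means, error sums of squares from the effect × subject
interaction, $F = \mathrm{MS}_\mathrm{effect}/\mathrm{MS}_\mathrm{error}$
with the standard balanced dfs — (2, 36) for condition, (1, 18) for side at
$n = 19$ — and partial
$\eta_p^2 = SS_\mathrm{effect}/(SS_\mathrm{effect}+SS_\mathrm{error})$.

No sphericity correction is applied by default. Greenhouse–Geisser is
available behind `correction = "greenhouse-geisser"`; it rescales only the
reference distribution's dfs, never the reported table dfs, with
$\varepsilon$ computed per effect from orthonormal contrasts of the cell
covariance. The two-level side factor has a single contrast, so its
$\varepsilon$ is exactly 1.

`tukey_posthoc()` compares condition marginal means using the
condition × subject error term of the same decomposition — the error
matching the repeated design, not a between-groups MSE — with
studentized-range p values (`ptukey`). Because `ptukey`'s far tail is less
accurate than the t tail, the adjusted p is floored at the unadjusted
pairwise p, which is the mathematically guaranteed relation.

`t_from_summary()` / `cohen_d_from_summary()` operate on printed group
summaries (mean, SD, n): the pooled-variance t with $n_1+n_2-2$ dfs and the
balanced pooled-SD $d = |m_1-m_2| / \sqrt{(s_1^2+s_2^2)/2}$. These
reproduce published demographic comparisons exactly from the printed
numbers:

```{r demo}
demographic_tests(speed_skater_demographics())
```

(The recomputed body-mass p is 0.0453; some published reports round the t
statistic before computing p, which can move the third decimal.)

Assumption checks use Shapiro–Wilk (pass at $p > 0.05$) and Levene with
deviations about group means. Effect-size labels follow the conventional
thresholds ($\eta_p^2$: 0.01 / 0.06 / 0.14; $d$: 0.2 / 0.5 / 0.8), exposed
as `interpret_eta_squared()` / `interpret_cohen_d()`. Statistics are run
per band and per index with no cross-band multiplicity correction, matching
field practice for these two pre-specified bands.

## The synthetic generator

Raw tremor recordings are rarely deposited, so the package ships a
generator with exported ground truth at two distinct levels.

**Signal level** (`simulate_tremor_signal()`): the target PSD is a white
floor plus Gaussian bumps (center, FWHM bandwidth, peak ln-gain per band).
Synthesis happens in the frequency domain — complex Gaussian coefficients
with magnitudes matching the target spectrum, inverse FFT — so the true
PSD is known in closed form, which is far easier to verify than a
time-domain filter design. Defaults emulate a resting lower-limb spectrum:
bumps at 3.2 Hz and 11.3 Hz over a broadband floor.

**Index level** (`simulate_cohort()`): for cohort statistics, condition
effects are injected directly on the indices:
value = rest mean + condition shift + subject effect + limb-correlated
residual. The two paths are deliberately separate — mapping index-level
effects exactly onto signal-level gains is nonlinear, and conflating them
would make neither verifiable.

The default cohort calibration uses published limb-averaged cell means for
elite speed skaters (low-band $L$ 8.745 at rest, +0.735 after endurance,
+0.815 after sprint; high-band $L$ 4.63, +0.99, +1.02; centroids 3.19 Hz
and 11.365 Hz with shifts of ±0.1–0.2 Hz), with marginal SDs near the
published ≈0.9 split as 0.70 between subjects and 0.55 residual for
low-band $L$. That split, and the interlimb residual correlation of 0.6,
are modeling choices: published tables conflate between-subject and
residual variance and report no interlimb correlation, so the split was
fixed once at values typical for within-subject physiological indices and
all downstream properties are stated at those defaults.

What the generator does **not** emulate: mechanistic tremor physiology
(stretch-reflex loops, motor-unit firing), the 1 kg inertial load's
dynamics, non-Gaussian residuals, drift or movement artifacts. Passing
tests therefore demonstrate correctness of the estimators and statistics
under the stated stochastic model, not robustness to real-world artifacts.

All randomness flows from explicit integer seeds; both generators save and
restore the global RNG state so library code leaves no hidden trace.

## Numerical choices and degenerate inputs

* Band-edge membership uses a $10^{-9}$ Hz tolerance so exact bin-center
  edges are included regardless of floating-point representation.
* Recordings serialize samples with 17 significant digits, making the
  write/read round trip bit-exact.
* Zero or constant inputs fail with named errors everywhere (degenerate
  spectra, constant Shapiro–Wilk input, zero pooled SDs, incomplete ANOVA
  crossings listing the missing cells).
* When an effect's SS and its error SS both vanish (a dv constant within
  subjects), $F$ and $\eta_p^2$ are defined as 0 rather than NaN.

## Problem sizes in the test suite

The suite verifies stochastic properties at sizes chosen to keep
Monte-Carlo error well inside the asserted bands: variance conservation
over 100 seeds; the white-noise log-amplitude reference over 200 seeds
($\pm 0.05$ band vs a ≈0.01 standard error of the mean); centroid recovery
over 50 seeds; the type-I error rate of the condition test over 1000 null
cohorts at $n = 19$ (nominal 0.05, asserted within ±0.02); detection power
over 500 calibrated cohorts; and cell-mean recovery averaged over three
replicate cohorts of $n = 2000$ subjects, where a single replicate would
leave the check's own false-alarm rate near 5% against its ±0.05 band.

## Known limitations

* The univariate RM-ANOVA assumes sphericity unless Greenhouse–Geisser is
  requested; no multivariate or mixed-model alternative is offered.
* Only single-axis recordings are supported; no vendor binary formats.
* Welch-style overlapping segments, multitaper and parametric spectral
  estimators are out of scope — the six contiguous segments are the
  protocol being implemented, not a tunable.
* Absolute $L$ levels depend on sensor units and calibration; cross-study
  comparisons require identical conventions.
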