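---
title: "Arrayed pulse-wave analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arrayed pulse-wave analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arraypulse)
```

## The measurement problem

A single pressure sensor on the radial artery records one pulse
waveform. A 3 x 4 tactile array records twelve of them at once: three
transverse rows of sensors — the radial (RP), intermediate (IP) and
ulnar (UP) passages — each with four elements along the artery's axis.
At every sample time the twelve amplitudes form a small spatial field,
and the quantity of interest is the **array pulse volume (APV)**: the
volume under the surface obtained by bilinear interpolation of that
field over the array footprint. Read over a beat, the APV traces a
volume waveform whose landmark values (main wave, tidal wave, dicrotic
notch, dicrotic wave) summarise the spatiotemporal pulse in a handful of
numbers that can be compared between clinical groups.

`arraypulse` implements that chain end to end: denoising, beat
segmentation, ensemble templating, fiducial detection, surface
interpolation, the volume statistic, feature extraction and the
two-group comparison, plus a synthetic-signal generator that stands in
for the sensor hardware and a clinical cohort.

## Processing chain

### Denoising

Raw recordings carry baseline drift (wrist motion), powerline pickup
and broadband sensor noise. With beat rates of 60–100 bpm the pulse
fundamental lies at 1–1.7 Hz, so the denoiser is a band-pass of
**1–4 Hz**: a Chebyshev type-I design of realised order 6 (third-order
low-pass prototype) with 0.5 dB passband ripple, applied
forward–backward so that fiducial timing is not phase-distorted.
Zero-phase application squares the magnitude response; mirror padding
of one impulse-settling length suppresses end transients.

Two consequences matter downstream. First, the DC gain is zero, so all
amplitudes are *relative*: every feature is measured against the beat
onset, never as an absolute contact pressure. Second, a 4 Hz cutoff
keeps only about three harmonics of a resting pulse, so the filtered
waveform is much smoother than the raw one — the dicrotic notch becomes
a shallow dip, and the tidal wave usually survives as an inflection
shoulder rather than a distinct peak. The fiducial detector and the
synthetic presets are built around this fact.

### Beats, APW and MRPW

Beat feet are local minima immediately preceding upstrokes whose slope
exceeds an adaptive threshold (half the 95th percentile of positive
first differences), with a refractory gap of one fastest-admissible
beat (default bounds 40–180 bpm). Complete beats are resampled linearly
to the **median** beat length and averaged pointwise into the average
pulse wave (APW); resampling to the median, rather than a fixed grid,
preserves the subject's own period. Each beat's Pearson correlation
with the APW selects the most representative pulse wave (MRPW) — the
single real beat most like the ensemble — whose window defines where
features are read. Ties go to the earliest beat; zero-variance beats
are excluded.

### Fiducial points

On one beat (onset at the first sample) the detector locates:

* **h1**, the main (percussion) wave: the global maximum;
* **h4**, the dicrotic notch: the lowest local minimum within 0.6 of
  the period after the main peak, a physiological bound on systole;
* **h3**, the tidal (predicrotic) wave: the largest local maximum
  between peak and notch; when the tidal wave has merged into the
  descending limb, the strongest negative-to-positive zero crossing of
  the second derivative is used instead, and the mode is recorded.
  The inflection fallback is applied only when a distinct notch
  exists — the descending limb of any smooth lobe carries an
  inflection, so without dicrotic structure a "shoulder" reading would
  be spurious and h3 is flagged absent;
* **h5**, the dicrotic wave: the largest local maximum after the
  notch, *measured from the notch level*, so an absent rebound gives
  exactly 0 and noise can push it slightly negative. This convention
  is the only one compatible with near-zero and negative dicrotic
  feature values seen in clinical tables.

Amplitudes other than h5 are relative to the onset amplitude. The
main-wave width `w` is measured at two-thirds of h1 ("one third below
the peak") with sub-sample linear interpolation at the crossings; the
complementary reading (one third *of* h1) is available through
`width_at_fraction()`. An optional Savitzky–Golay smoothing (pipeline
default 50 ms, cubic) stabilises extremum localisation on noisy beats;
with smoothing off the detector is exact: `h1 = max(beat) - beat[1]`.

### Surface interpolation and the volume statistic

The twelve amplitudes at one time form a 3 x 4 frame `F` whose nodes
span the footprint (rows across the width, columns along the length;
default a unit square, since the element pitch of array hardware is not
standardised — physical dimensions rescale volumes linearly and leave
ratios untouched). `F` is interpolated bilinearly onto an N x N grid
(instrument convention N = 1000) and the volume is the Riemann sum

$$ V = S \sum_{i=1}^{N}\sum_{j=1}^{N} M_{ij}, \qquad S = \frac{A_{\text{total}}}{N^2}. $$

`S` must be the *per-cell* area: with the total footprint area in its
place the "volume" would grow as N², whereas the Riemann-sum reading
makes V independent of N (tests verify < 1% drift between N = 200 and
N = 1000, and exact invariance for constant frames). For a constant
frame of height c the volume is exactly `c * A_total`.

Per-passage volumes restrict the surface to the transverse third of
grid rows nearest that passage's sensor row (with N not divisible by 3,
RP takes rows `[0, N/3)`, IP `[N/3, 2N/3)`, UP the rest) and are
normalised as (regional mean height) x A_total so that all four groups
— RP, IP, UP and the 12-channel mean — share one scale and the mean is,
up to band rounding, the average of the three passages. Because
bilinear interpolation is linear in the frame, every regional volume is
a fixed weighted sum of the twelve channel amplitudes; the weights
(regional means of the twelve interpolated unit basis frames) are
computed once per grid size and cached, which reduces the per-sample
cost from an N x N interpolation to a dot product. The tests compare
this weighted path against explicit surface integration.

### APV features

Within the MRPW beat window, each group's waveform is the mean of its
channels; fiducials are detected *per group*, so each passage keeps its
own timing (passage waveforms genuinely differ), and the group's volume
series is read at those times:

* `APV_h1 = V(t_h1) - V(t_onset)`, likewise `APV_h3`, `APV_h4`;
* `APV_h5 = V(t_h5) - V(t_h4)` (notch-relative; 0 when absent);
* ratio features divide by `APV_h1`.

That yields 4 groups x 7 parameters = 28 values per subject. For a
*separable* recording — every channel equal to a spatial gain times one
common waveform — V(t) is proportional to that waveform, so every
group's ratio features equal the waveform's own amplitude ratios; this
parameter-recovery property is tested to 1e-6 on noiseless input. A
time-constant window has identically zero volume differences, so
amplitudes are 0 by convention and ratios undefined.

### Statistics

Per (passage, parameter), subjects' values are compared between groups:
Student's pooled-variance t when *both* samples pass the Shapiro–Wilk
gate at alpha 0.05, otherwise the Mann–Whitney U test (exact by
enumeration for tie-free samples with `n_x + n_y <= 12`, else the
normal approximation with tie and continuity corrections). P values are
two-sided; tiers are starred at 0.05 / 0.01 / 0.001. No
multiple-testing correction is applied by default, matching the
per-parameter reporting convention of clinical pulse studies;
`adjust = "BH"` adds a Benjamini–Hochberg column for reuse.

## The synthetic generator

No public recordings from array hardware exist, so the generator is a
first-class module with known ground truth rather than a test fixture.

**Beat model.** One beat is the sum of three asymmetric Gaussian bumps
— percussion (amplitude fixed at 1, centre 0.13 of the period), tidal
(0.30) and dicrotic (0.58) — ramp-corrected to start and end at zero
and rescaled to unit peak. A Gaussian-bump model was chosen over
physiological transmission-line models because the pipeline needs
morphology, not physiology, and ground-truth component times stay
analytic. The percussion bump's slow right-hand decay doubles as the
systolic envelope on which the tidal shoulder and dicrotic rebound
ride.

**Presets.** The two cohort presets are specified by the tidal ratio
h3/h1 that the *pipeline measures after the standard 1–4 Hz filter* on
clean input: 0.823 for the healthy preset and 0.874 for the
hypertensive one — values representative of normotensive versus
hypertensive radial-pulse morphology at the 12-channel mean. The knob
is the percussion decay width, solved by bisection (with a final
refinement over the sample-quantised steps of the measured ratio, which
is why targets are met to ~0.005 rather than exactly). Calibrating the
*measured* ratio, not the raw bump amplitude, is deliberate: the 4 Hz
cutoff reshapes the waveform, so raw-waveform ratios would not survive
the filter. The same knob raises the dicrotic-notch ratio h4/h1
(measured ~0.56 healthy vs ~0.72 hypertensive), consistent with the
elevated peripheral resistance of hypertension — so a single
physiologically meaningful parameter carries the group difference. The
dicrotic bump amplitude (0.6) is set so the post-filter rebound stays
above the in-band noise floor and the notch remains detectable across
the simulated heart-rate range; the resulting dicrotic-wave ratio
(~0.03–0.08) is larger than the clinical average, a known idealisation.

**Recording.** Per-beat periods are drawn from a truncated normal heart
rate (default mean 75 bpm, beat-to-beat SD 2 bpm); channel c is its
spatial gain (a 2-D Gaussian over the grid, emulating the artery's
position) times the beat train, plus a common drift sinusoid (default
0.3 amplitude at 0.2 Hz), 50 Hz powerline pickup at 5% of the beat
amplitude, and independent white noise per channel (default SD 0.06,
about 20 dB SNR for a unit-gain channel). The default resting rate of
75 bpm sits mid-band of the 60–100 bpm design range of the 1–4 Hz
filter; above ~90 bpm too few harmonics pass for a dicrotic notch to
survive at all, which the detector then reports via its fallback —
physiologically not unreasonable, but worth knowing when simulating
tachycardic subjects.

**Cohort.** Between-subject variation: log-normal jitter (log-SD 0.1)
on the tidal and dicrotic amplitudes, per-subject resting heart rate
N(mean, 5 bpm) truncated to 40–180, and a jittered artery position.
Per-subject seeds derive deterministically from the master seed.

**What passing tests do and do not show.** The generator produces
quasi-periodic, band-limited, spatially smooth signals with stationary
noise. It does not model arrhythmia, probe-pressure drift, sensor
cross-talk, motion artefacts with in-band energy, or the full
between-subject diversity of clinical waveforms — simulated cohorts
have tighter feature SDs (~0.02 for ratio features) than clinical
tables report (~0.09). Recovery of a group difference here therefore
demonstrates correctness of the computation chain, not clinical
sensitivity.

## Numerical choices and edge cases

* Filter: poles are checked against the unit circle at design time;
  records shorter than three settling lengths are refused rather than
  silently transient-dominated.
* Segmentation: constant or monotone signals return an *empty*
  segmentation with a warning, not an error; downstream steps demand
  at least two complete beats.
* Resampling uses linear interpolation throughout (`stats::approx`),
  matching the linear-interpolation character of the method.
* Fiducials: the notch search is capped at 0.6 of the period after the
  peak; `which.max` tie-breaks to the earliest sample; widths
  interpolate crossings sub-sample.
* Volumes: band rounding gives RP/IP/UP row counts differing by at
  most 2 rows out of N, bounding the passage-average versus mean
  discrepancy at well under 1%.
* Tests run the interpolation grid at N = 200 (validated against
  N = 1000 by the convergence property) and the full problem sizes the
  study design prescribes elsewhere: 30 s at 100 Hz, 26 subjects per
  group, 50 cohort replicates for the directional-recovery property,
  500 replicates for test size.

## Known limitations

* Absolute APV units are arbitrary: the hardware's element pitch and
  contact area are unpublished, and the band-pass removes DC, so only
  ratios and within-study contrasts are meaningful.
* The per-passage volume definition (restricted surface, regional mean
  x total area) is one of several defensible readings of "the average
  of the four channels"; it was chosen because it keeps all four groups
  on a single scale while letting passages keep their own fiducial
  timing.
* The t statistics printed by clinical tables of this design cannot
  generally be reproduced from printed summary rows (test labels are
  omitted there); this package always records which test produced each
  statistic.
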