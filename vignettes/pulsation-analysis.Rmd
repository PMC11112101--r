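---
title: "Spectral analysis of physiological brain pulsations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral analysis of physiological brain pulsations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfpulse)
```

## The problem

Cerebrospinal fluid (CSF) pulses with the cardiac and respiratory cycles, and
this motion modulates the signal intensity of ultrafast echo-planar imaging
(EPI) time series. With repetition times of 51-155 ms, a 600-volume scan
resolves frequencies up to 3.2-9.8 Hz at ~0.011 Hz resolution -- enough to
separate respiratory (~0.3 Hz), cardiac (~1.2 Hz) and first-harmonic
(~2.4 Hz) components and to localize them in the brain. csfpulse implements
the complete analysis: per-voxel and per-region magnitude spectra, an
envelope-normalized peak-identification procedure, per-band biomarkers, band
localization masks, and comparison against simultaneously recorded ECG and
respiration-belt traces. A seeded synthetic phantom makes every stage
testable without scan data.

## Spectral model

Each voxel time series (length $T$, sampling interval $TR$) is demeaned and
transformed with the FFT. We store the one-sided *amplitude* spectrum,

$$M(k) = \frac{2}{T}\,\bigl|X(k)\bigr|, \qquad 0 < k < T/2,$$

with $1/T$ scaling at DC and (even $T$) Nyquist, so an on-grid sinusoid of
amplitude $A$ appears with magnitude exactly $A$ at its bin. Magnitudes are
in arbitrary units throughout; any fixed convention is equally valid, and
the amplitude convention makes the "3 dB drop" factor $\sqrt{2}/2$ read
directly on the curve. Region-of-interest spectra average the per-voxel
*magnitudes* per frequency (never the complex values), so voxels pulsing
out of phase still contribute -- appropriate for pulsatile flow whose phase
varies spatially.

Design choices a reader should know:

* **Demeaning only.** The temporal mean is removed before the FFT so the DC
  bin is exactly zero; no detrending or windowing is applied by default. A
  rectangular window keeps on-grid amplitudes exact.
* **No slice-timing or slab-phase correction.** Multi-slab acquisitions are
  concatenated as-is ([merge_slabs()]); magnitude spectra are invariant to
  the per-slab acquisition-time offsets, which is precisely why the
  analysis lives in the frequency domain.

## Peak identification

Peaks are identified on each ROI spectrum by a six-stage procedure:

1. **Savitzky-Golay smoothing**, order 2, window 0.133 Hz. The window width
   is the span of the normal adult respiratory range (12-20 breaths/min =
   8/60 Hz), so structure narrower than a plausible physiological band is
   treated as noise. The window is converted to samples via the spectrum's
   own $\Delta f$, forced odd with a 5-sample minimum; for very short TR
   (<= 75 ms) the sample count is doubled, compensating the denser
   frequency grid of those acquisitions.
2. **Lower envelope.** The spectral floor is a characteristic of the
   acquisition: it decreases with frequency and carries no physiological
   information. We model it as a piecewise-linear curve through the local
   minima of the smoothed spectrum, *pruned to the lower convex hull*:
   a minimum that lies above the straight line joining its neighbouring
   minima sits on the shoulder of a peak, not on the floor, and keeping it
   would let the envelope climb onto the peaks it is meant to bridge
   under. The envelope is clipped to never exceed the curve and floored at
   a tiny positive value. Because demeaning forces the DC bin to zero, DC
   is excluded from envelope construction and inherits its neighbour's
   value; DC can never be a peak.
3. **Adjustment.** The smoothed spectrum is divided by the envelope and one
   is subtracted: the *adjusted spectrum* measures relative elevation above
   the acquisition floor and is zero wherever the curve touches it. The
   smoothed curve is clamped at zero first (magnitudes are non-negative;
   smoothing undershoot is non-physical).
4. **Primary peaks.** Local maxima whose height reaches the mean plus one
   sample standard deviation of the adjusted spectrum (DC excluded from
   both statistics and candidacy). Flat-topped runs count once, at their
   centre bin, ties toward the lower frequency.
5. **Baseline.** An exclusion zone of total width 0.667 Hz -- the span of
   the normal adult cardiac range (60-100 beats/min = 40/60 Hz) -- is
   placed around each primary peak; the mean and sample standard deviation
   of the remaining bins form the baseline. We read "a zone around each
   peak" as a *total* width; a flag (`exclusion_half_width`) switches to
   the +/-0.667 Hz reading for sensitivity analyses. If the zones blanket
   the whole grid the procedure stops with an informative error.
6. **Final peaks.** Local maxima at or above baseline mean + sd whose
   topographic prominence on the decibel ratio curve
   $R_{dB} = 20\log_{10}(1 + \text{adjusted})$ reaches 1.5 dB. The
   20-log convention matches the amplitude reading of the 3 dB bandwidth
   ($\sqrt{2}/2$ of peak height); 1.5 dB corresponds to a linear factor of
   about 1.19.

All thresholds use the sample (n-1) standard deviation. That convention is
pinned down empirically: in the published per-volunteer band table, the
two-subject band with centre frequencies 0.516/0.484 Hz prints a standard
deviation of 0.023, which equals $|0.516-0.484|/\sqrt{2}$ (the n-1 value),
not the n value.

## Band biomarkers

For each final peak the band is the interval where the adjusted spectrum
stays above $\sqrt{2}/2$ of the peak height (a 3 dB amplitude drop; we read
the occasionally-typeset "2/2" factor as $\sqrt{2}/2$). Edges are located
by linear interpolation at the first crossing; if the curve reaches the
grid edge, or rises into a taller neighbouring peak, before crossing, the
edge (or intervening valley) is used and the band is flagged `truncated`
rather than dropped. Bandwidth is `f_hi - f_lo`; the area is the
trapezoidal integral of the adjusted curve over the band (units Hz, the
adjusted curve being dimensionless). Metrics are computed on the adjusted
curve -- the curve on which peaks were identified -- with a config flag
(`metric_curve = "smoothed"`) for the smoothed raw spectrum instead.

Bands from multiple subjects are grouped by single-linkage clustering of
centre frequency with a 0.2 Hz gap tolerance, chosen so the typical
cross-subject spread of the cardiac band (~1.13-1.31 Hz) stays in one group
while remaining separate from sub-cardiac bands below ~0.92 Hz. Group
summaries report mean and sample standard deviation per metric, with the
standard deviation omitted for single-subject groups.

## Spatial localization

A band's power map is the per-voxel mean of magnitude-spectrum values over
the band's bins (a `--power` style flag squares them first; with the
amplitude convention the default map is an amplitude map, which preserves
the thresholding logic). The map is binarized at 75% of its maximum -- the
threshold must live in map units, so "peak amplitude of the band" is read
as the map maximum, with a quantile alternative for robustness -- then
smoothed with an isotropic Gaussian of sigma 1.6 *voxels* and re-binarized
at 0.5. The 0.5 cut is the symmetric choice: a grid-spanning half-space is
preserved exactly, isolated single-voxel speckles vanish (the 3D kernel's
centre weight at sigma 1.6 is below 0.5), and boundaries round smoothly.
Smoothing is volumetric by default with a slice-wise (2D) option, since
either reading of a bare "sigma of 1.6" is defensible.

## Physiological comparison

ECG and respiration-belt traces enter as CSV with a metadata header
(sampling rate, channel, scanner-trigger timestamp). Traces are cropped to
the scan window using the trigger, their spectra computed with the same
convention as image spectra on their own frequency grid
($\Delta f = 1/\text{duration}$), and peak-identified with the *same*
six-stage procedure -- one code path for all spectra. Image and physio
bands are then compared in interval space: each cross pair's intersection
and Jaccard fraction is reported, with empty intersections omitted. No
resampling of physio data onto the image grid takes place, avoiding
interpolation artifacts; no R-peak detection or heart-rate-variability
analysis is attempted.

## The synthetic phantom

`phantom_spec()` describes a 64 x 64 x 20 x 600 dataset at TR 0.155 s
(the whole-brain slab-acquisition geometry): a CSF ellipsoid inside a
white-matter interior inside a cortical grey-matter shell, semi-axes given
as grid fractions so specs scale down for fast tests. Each region pulses
with three shared components (respiratory 0.3 Hz, cardiac 1.2 Hz, harmonic
2.4 Hz, snapped to the frequency grid) whose amplitude fractions fall from
CSF to cGM to cWM (cardiac 3%/1%/0.4% of baseline; respiratory
1.5%/0.8%/0.4%; harmonic one third of cardiac), over baselines of
500/450/400 a.u. and a slow 0.02 a.u./s drift.

Three further ingredients make the phantom behave like data rather than
like a textbook sinusoid:

* **Rate drift.** Heart and breathing rates are not constant over a
  90-second scan. Each component's instantaneous frequency sweeps smoothly
  and monotonically across $f \pm 2\gamma$ with a truncated-Lorentzian
  dwell-time density ($\gamma$ = 0.025 Hz by default), spreading each
  spectral line over a smooth bell a few bins wide. `line_width_hz = 0`
  recovers exactly monochromatic components for analytic tests. Without
  this, single-bin lines of realistic intensity ring under the
  Savitzky-Golay smoother and no parameter setting reproduces the smooth
  single-peak structure seen in real spectra.
* **Coloured floor.** A $1/f$ (power) noise term with amplitude
  proportional to the regional baseline (0.15% at 1 Hz by default)
  produces the decreasing lower envelope characteristic of the
  acquisition; it is synthesized in the frequency domain with
  deterministic per-bin amplitude and random phase, so the envelope shape
  is stable while the time series stays random. Background voxels carry no
  coloured floor.
* **Rician observation.** The observed value is
  $\sqrt{(S+\epsilon_1)^2 + \epsilon_2^2}$ with independent Gaussian
  channel noise (sigma 2 a.u.), the distribution of MRI magnitude data;
  where signal vanishes this reduces to Rayleigh noise with mean
  $\sigma\sqrt{\pi/2}$, which the tests verify.

Matched physiological traces are generated from the same specification:
a respiration sinusoid and an ECG-like train of narrow Gaussian pulses at
the phantom's (grid-snapped) rates, digitized at 250 Hz with the scan
starting 10 s into the recording.

What the phantom does *not* emulate: k-space acquisition, coil
sensitivities, B0 distortion, motion, partial-volume mixtures at region
boundaries, or spatially varying phase of the pulsation. Passing the
recovery studies therefore demonstrates that the algorithm chain is
correct and robust to the modelled noise structure -- not that it is
validated on real scanner data.

## Validation studies and problem sizes

Two seeded studies are exported so users can reproduce the package's own
validation:

* `evaluate_phantom_recovery()` runs the full pipeline on 20 independently
  seeded default phantoms (64 x 64 x 20 x 600) and scores per seed whether
  all three component frequencies are matched by final CSF peaks within
  one frequency bin, whether the cardiac-band magnitude orders
  CSF > cGM > cWM, and the Dice overlap of the cardiac band mask against
  the true CSF ellipsoid.
* `evaluate_physio_coupling()` uses a reduced 16 x 16 x 8 x 600 phantom
  (the geometry scales with the grid) plus matched traces, and checks that
  band overlap finds a cardiac pair on the ECG channel and a respiratory
  pair on the respiration channel.

The reduced grid in the coupling study keeps it light; the spectra it
feeds the detector are ROI averages, whose quality depends on voxel count
far less than the mask study does.

## Numerical choices and degenerate inputs

* Constant series produce all-zero spectra, which flow through every stage
  and yield zero peaks (no errors).
* The envelope is floored at $10^{-12} \times \max(\text{smoothed})$;
  all-zero spectra keep a zero envelope and a zero adjusted curve.
* Flat-topped extrema count once at the centre bin, ties to the lower
  frequency; plateau bins are never envelope knots.
* Band-edge interpolation is exact on linear segments; truncated bands are
  flagged, never silently dropped.
* Odd-length series have no Nyquist bin; the grid tops out at
  $\lfloor T/2 \rfloor \Delta f$.
* All seeds flow through a single integer in each generator; identical
  seeds give bit-identical phantoms and traces.

## Known limitations

* The envelope model assumes a floor that is convex-decreasing at the
  scale of the spectrum; a strongly non-convex floor (e.g. a broad
  hardware resonance hump) would be bridged under rather than followed.
* Peak centres are reported on the frequency grid (no sub-bin
  interpolation of the maximum); band edges are interpolated.
* Physio spectra of strongly non-sinusoidal signals (pulse trains) contain
  many harmonics; all of them are legitimate peaks to the detector, so
  band-overlap reports should be filtered by the band of interest.
* EPI-to-structural registration, segmentation and denoising are outside
  the package: it consumes preprocessed images and label maps.
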