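---
title: "Segmenting phonocardiograms into S1-S4: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting phonocardiograms into S1-S4: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcgseg)
```

A phonocardiogram (PCG) records the sounds of the beating heart. A normal
beat has two transient components — the first heart sound S1 (closure of the
mitral/tricuspid valves, bounding the start of systole) and the second heart
sound S2 (aortic/pulmonary closure, start of diastole). Pathological or
borderline recordings may add the low-frequency diastolic gallop sounds S3
(shortly after S2) and S4 (just before the next S1), and murmurs: sustained,
noise-like sounds from turbulent flow occupying systolic and/or diastolic
intervals. Segmentation — locating each component's onset and offset and
naming it — is the prerequisite for most downstream PCG analysis.

`pcgseg` implements a fully automatic segmentation pipeline:

1. **Preprocessing** — down-sample to 2 kHz, wavelet-denoise, normalize to
   unit peak.
2. **Murmur elimination** — an automatic-cutoff low-pass filter (ALPF) whose
   cutoff is read from the smoothed FFT-magnitude envelope.
3. **Boundary detection** — a mathematical-morphology envelope with adaptive
   amplitude and energy thresholds yields candidate onset/offset pairs.
4. **Cardiac-cycle estimation** — unbiased autocorrelation of the envelope
   with side-peak suppression.
5. **Component identification** — Stockwell-transform instantaneous
   frequency plus inter-component timing rules label each detected
   component S1/S2/S3/S4.

A seeded synthetic-PCG generator with exact ground truth makes every stage
testable without clinical recordings.

## Preprocessing

Heart-sound energy lies below 1 kHz, so recordings are resampled to 2 kHz
(zero-phase Butterworth anti-aliasing — two cascaded 4th-order
forward-backward passes at 0.9 x the target Nyquist — followed by cubic
spline evaluation on the target grid; zero phase matters because later
stages read event times off the waveform). Denoising uses a db4 discrete
wavelet transform at depth 7 with soft thresholding. The threshold magnitude
is not part of the original design and is the standard universal choice
`sigma * sqrt(2 log N)`, with `sigma` estimated from the median absolute
deviation of the finest-scale detail coefficients; only detail coefficients
are thresholded. Boundary handling uses symmetric extension, which minimizes
edge artifacts on transient signals. Finally the signal is divided by its
maximum absolute value (`normalize_unit_peak()`), making all later
thresholds scale-free.

## Murmur elimination (ALPF)

Murmurs are broadband and sit mostly above the component band, so a low-pass
filter removes them — the question is the cutoff. The classic fixed 200 Hz
cutoff leaves any murmur energy below 200 Hz untouched. The ALPF instead
reads the cutoff from the data: the one-sided FFT modulus is smoothed by a
moving average of radius `l_f = 5` bins (larger radii merge adjacent
spectral peaks), normalized to unit peak, and searched for the first valley
(local minimum) after the primary peak — the global envelope maximum, where
component energy concentrates — whose height is below 0.2, within
20–200 Hz. If no such valley exists the cutoff falls back to 200 Hz, which
reduces the ALPF to the fixed filter. The filter itself is an order-6
Butterworth applied forward-backward: flat passband, zero phase, so
component onsets stay aligned.

Numerical notes, decided here because the original description leaves them
open:

* Local extrema use the simplest deterministic definition — a bin strictly
  above/below both neighbors, plateaus collapsing to their first bin. On
  short (three-cycle) inputs, the smoothed envelope of the decaying
  component tail carries low-amplitude ripple, so the selected valley in
  practice sits essentially where the envelope first drops below 0.2. That
  point can clip the upper band edge of a narrowband S2: on the murmur-free
  synthetic preset the cutoff lands near 136 Hz and the 120 Hz S2 keeps its
  shape to about 14% relative error (S1 about 2%). Detection and labelling
  are unaffected; the trade-off is intrinsic to a threshold-based cutoff.
* The right-edge moving-average windows are truncated to valid bins, with
  the divisor equal to the number of terms actually summed.
* The spectral arithmetic operates on the one-sided spectrum only; the modulus
  of a real signal is symmetric and the search band is 20–200 Hz, so this
  halves the work without changing any value.

## Boundary detection

The envelope is the morphological closing (dilation then erosion with a
flat, zero-valued structuring element) of the *rectified* murmur-reduced
signal — rectification makes the envelope bound both polarities of the
oscillatory waveform. Element lengths are physiological: the closing length
`Q = 30` samples (15 ms at 2 kHz) is far below the shortest inter-component
gap (at least 100 ms), so separate components are never merged; the opening
length `Q' = 50` samples (25 ms) is below the shortest component duration
(S3/S4, about 50 ms), so true components survive while narrow residues and
clicks are erased. Windows are centered with radius `floor(Q/2)` and shrink
at the edges, keeping the envelope aligned and equal-length with the
signal.

Between closing and opening, the envelope is thresholded at
`theta = min(0.8 * sd(env), 0.025)` (population standard deviation,
divisor N). The adaptive term tracks the signal; the 0.025 cap keeps the
threshold small so boundary positions move as little as possible — its job
is only to detach low-amplitude murmur residues from component edges.

The opened envelope is exactly zero between components, so onsets/offsets
fall out of a zero-crossing rule: an onset is a zero sample immediately
followed by a nonzero one; an offset a zero immediately preceded by a
nonzero one (0-based indices; a run touching the array edge takes the edge
index). Runs separated by a single zero sample would make one sample both
an offset and the next onset, violating the strict interleaving invariant,
so such runs are merged. Finally each pair's energy
`E_k = sum(env^2)` over the pair is computed and pairs with `E_k < 0.25`
are removed and zeroed — ties are kept (the removal test is strict).

## Cardiac cycle

Heart sounds are quasi-periodic; the average cycle length anchors beat
grouping. The biased (divisor `N`) autocorrelation of the envelope has
primary peaks that shrink linearly with lag, so the unbiased form (divisor
`N - m`) is used: it averages only the terms actually summed and keeps the
primary peaks at full height. The sequence is squared (widening the
primary/side peak gap), thresholded at 0.4 x its maximum, and the *last*
surviving peak — typically an S1xS2 cross-product side peak amplified by the
small unbiased divisor — is forcibly removed, whatever it is. A second
unbiased autocorrelation of the result (`R_Final`) is thresholded at 0.5 x
its maximum; the lags between adjacent surviving peaks (each peak is a
maximal nonzero run represented by its argmax; the run containing lag 0 is
excluded) are averaged into the cycle estimate. With a single surviving
non-origin peak, its lag is the estimate; with none, a typed condition
(`pcg_cycle_error`) is raised and the pipeline labels all components
`unknown` rather than guessing.

Two design limits worth knowing:

* The estimator is built for inputs of roughly **three cycles** — the same
  windowing under which the approach was originally evaluated. On much
  longer inputs the unbiased divisor amplifies *several* late-lag peaks and
  removing one "last peak" no longer cancels the artifact. For long
  recordings use `run_windowed()`, which sizes three-cycle windows (one
  cycle of overlap) from a 4 s leading chunk and reconciles overlapping
  labels by majority, real labels outvoting `unknown`.
* Under beat-to-beat timing jitter the period peak smears. With independent
  +/-5% cycle-length jitter on three-cycle segments, adjacent inter-beat
  lags can differ by about one envelope-hump width, and the smeared peak
  can fall just below the fixed 0.5 threshold: cycle estimation then fails
  for a substantial fraction of random draws (in a 12-seed sweep, about 20%
  of preset-draws), taking label accuracy down with it while boundary
  detection is unaffected. This is the arrhythmia sensitivity the method is
  known for, not an implementation artifact; the thresholds (0.4, 0.5) are
  part of the design.

## Component identification

Identification runs on the *original* preprocessed signal (not the
murmur-filtered one) so the time-frequency picture is complete. The
Stockwell transform (row `n` is the inverse DFT of the spectrum shifted by
`n` and weighted by the Gaussian `exp(-2 pi^2 m^2 / n^2)`; the
zero-frequency row is the signal mean) gives a modulus matrix whose amplitude-weighted
column mean is the instantaneous frequency; averaging it over each detected
component span yields one number per component. The gallop sounds S3/S4
(20-70 Hz) score clearly below S1/S2 (80-150 Hz) on this measure.

Three implementation decisions:

* **Row range and snippets.** The full transform is O(N^2). Rows are
  computed only up to 300 Hz (on the reported axis — all component energy
  is far below), and per component only a snippet of the signal (the span
  padded by 100 ms) enters the transform. The padding covers the Gaussian
  window support of every retained row over the span, so the averaged
  columns match the full transform up to window leakage at the snippet
  edges; the classifier consumes only the *ordering* of the per-component
  averages, which is also invariant to the conventional halving of the
  frequency axis (`F(m) = m fs / 2N`) retained here.
* **Beat grouping.** Beats are found from the cycle estimate by
  *re-anchoring*: the first beat starts at the first detected component,
  and each next beat at the component nearest the previous anchor plus one
  cycle (searched within a quarter cycle of the prediction). On a regular
  rhythm this is identical to slicing a fixed grid of cycle-length windows,
  but unlike the grid it does not accumulate drift when the rhythm wanders.
  A trailing single-component "beat" whose average frequency is below every
  component of the preceding beat is merged back into it — that is a gallop
  sound whose following S1 lies beyond the end of the recording.
* **S3 vs S4.** For three-component beats the lowest-frequency component is
  the gallop; its immediate neighbors are S2 (before) and S1 (after). The
  gallop resolves to S3 when the gap from the preceding S2 is shorter than
  the gap to the following S1, else S4 — the physiological timing priors
  (S2-S3 short, S4-S1 short). The original description also contains a
  sentence stating the opposite mapping; it contradicts those priors, so
  the priors are the default and `s3s4_rule = "verbatim"` switches to the
  literal sentence for comparison.

Two-component beats compare the intra-beat gap with the gap to the next
beat's first component: the shorter gap is systole, so the first component
of the beat is S1 exactly when the intra-beat gap is shorter. A final beat
without a successor reuses the majority orientation of earlier beats.
Four-component beats take the earlier of the two lowest-frequency
components as S3 and the later as S4, with S2 before S3 and S1 opening the
beat. Any per-beat label collision degrades that beat to `unknown`.

## Synthetic phonocardiograms

`preset_catalog()` covers the evaluated categories: normal (S1+S2), S3 and
S4 gallops, each with and without murmurs, the full four-component beat,
systolic and diastolic murmurs, and a click artifact. Components are
Gaussian-windowed sinusoids — S1 at 100 Hz/100 ms/amplitude 1.0, S2 at
120 Hz/90 ms/0.8, S3 45 Hz and S4 35 Hz at 50 ms/0.4 — with the window
standard deviation set to duration/6 so the -40 dB points defining the
ground-truth boundaries coincide with the nominal span. Timing follows the
physiological interval ordering: S1 at the cycle start, S2 at 0.30 s of a
0.8 s cycle, S3 0.12 s after S2's offset, S4 ending 0.07 s before the next
S1; all inter-component gaps are at least 0.1 s. Murmurs are band-passed
(150-400 Hz) white noise, Tukey-tapered inside their systolic or diastolic
window, at peak amplitude 0.25 — a clearly audible but not dominant murmur.
Clicks are 10 ms, 180 Hz, amplitude 0.3 transients. A single seed drives
all randomness (murmur noise, additive noise, jitter), making every fixture
bit-reproducible; `noise_snr_db` sets white noise relative to the clean
signal RMS and `timing_jitter_frac` draws each cycle length uniformly
within the given fraction, independently per beat.

What the generator does *not* model — and what passing tests therefore do
not show about clinical data: split S1/S2 morphology, respiratory
modulation, valve-mechanics waveforms, broadband component spectra,
friction-rub and sensor artifacts, and murmurs overlapping component
spans. The synthetic suite demonstrates that the implementation realizes
the method's mechanics exactly, not that the method attains any particular
clinical accuracy.

## Evaluation machinery

The signal-murmur ratio `SMR = 10 log10(E_U / E_V)` compares energy in
annotated component regions (U) with murmur regions (V); both masks come
from the generator (on clinical data they would be annotated by hand) and
are held fixed when comparing filtered and unfiltered versions of the same
sound, so SMR gains measure the filter alone. Detection quality uses
tolerance-based greedy one-to-one onset matching (default tolerance 50 ms;
the synthetic acceptance checks use a stricter 20 ms) feeding sensitivity,
positive predictive value and accuracy; for pure event detection there is
no true-negative class, so TN = 0 and accuracy reduces to
TP/(TP+FN+FP). The paired two-sample t statistic and its critical value
(from the t quantile function, not a table) support significance statements
about per-recording SMR gains.

## Problem sizes and runtime

Unit and acceptance tests run the full pipeline on three-cycle, 2 kHz
synthetics (about 4900 samples), 200-case morphology oracle sweeps, and
S-transform oracle checks up to N = 64 — the whole suite completes in well
under two minutes on one core, and `scripts/acceptance.R` in a few
seconds. These sizes exercise every code path at full fidelity; nothing in
the method scales worse than the per-window O(N log N) transforms at
deployment sizes, except the exact S-transform, which is why it is
restricted to component snippets.

## Known limitations

* Severe arrhythmia defeats the cycle estimator (see above); components are
  then reported with `unknown` labels rather than guessed.
* The ALPF assumes murmurs sit mostly above the component band; a murmur
  concentrated below ~100 Hz would survive.
* Split S1/S2 are treated as single components.
* The S3/S4 timing priors assume at most one gallop sound per beat unless
  all four components are present.
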