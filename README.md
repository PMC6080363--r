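# pcgseg — automatic segmentation of heart sounds

`pcgseg` segments single-channel phonocardiogram (PCG) recordings into the
heart-sound components S1–S4 and the named intervals between them. It is
aimed at biomedical-signal researchers who need sample-accurate component
boundaries and labels for normal heart sounds *and* for sounds with the
diastolic gallops S3/S4 and with murmurs — the cases where most classical
segmenters (Shannon-energy, envelope-peak or HSMM-based) stop working or
were never defined.

## The method

Given a recording $x(n)$, the pipeline is:

1. **Preprocessing.** Down-sample to 2 kHz (heart-sound energy lies below
   1 kHz), db4 wavelet denoising (level 7, soft universal threshold), and
   unit-peak normalization $HS_N(n) = HS(n) / \max|HS(n)|$.
2. **Murmur elimination (ALPF).** Smooth the one-sided FFT modulus with a
   moving average (radius $L_F = 5$ bins), normalize, find the first valley
   after the primary (global-maximum) peak with envelope value < 0.2 within
   20–200 Hz, and low-pass filter at that frequency (order-6 Butterworth,
   forward–backward, zero phase); fall back to 200 Hz when no valley
   qualifies.
3. **Boundary detection.** Envelope = morphological closing (flat element,
   length $Q = 30$) of the rectified signal, normalized; threshold at
   $\theta = \min(0.8\,\mathrm{sd}, 0.025)$; morphological opening (length
   $Q' = 50$); onsets/offsets from the zero/nonzero transitions; remove
   pairs whose envelope energy $E_k = \sum \tilde E_{NO}^2$ falls below
   $\eta = 0.25$.
4. **Cardiac cycle.** Unbiased autocorrelation
   $R'(m) = \frac{1}{N-m}\sum_n e(n)\,e(n{+}m)$ of the envelope (its primary
   peaks do not attenuate with lag, unlike the biased form), squared,
   thresholded at $0.4\max$, last peak forcibly removed, autocorrelated
   again ($R_{Final}$), thresholded at $0.5\max$; the average lag between
   adjacent surviving peaks is the cycle.
5. **Identification.** Per detected component, the average Stockwell-
   transform instantaneous frequency
   $f_H(n) = \sum_m F(m)\,|S|_{m,n} / \sum_m |S|_{m,n}$; gallop sounds
   (S3/S4, 20–70 Hz) score far below S1/S2 (80–150 Hz). Beats of 2–4
   components are then labelled by the physiological timing rules
   (S1S2 < S2S1; S2S3 < S3S1; S2S4 > S4S1).

Evaluation tools include the signal–murmur ratio
$SMR = 10\log_{10}(E_U/E_V)$ over component/murmur region masks,
tolerance-based detection matching with Se/PPV/Acc, and the paired t test.
A seeded synthetic-PCG generator (`preset_catalog()`, `generate_pcg()`)
produces ground-truthed recordings for every evaluated category, so the
whole pipeline is testable offline. See the vignette
(`vignettes/heart-sound-segmentation.Rmd`) for the full methods account.

## Worked example

Generate a three-cycle recording with S4 gallops and a mid-systolic murmur,
segment it, and compare with the generator's ground truth:

```r
library(pcgseg)

cfg <- preset_catalog(seed = 7)[["s4-murmur"]]
g   <- generate_pcg(cfg)
seg <- segment_recording(g$signal)
seg
#> <pcg_segmentation> 9 component(s): S1=3, S2=3, S4=3
#>   cycle: 0.793 s

head(seg$components[, c("beat", "label", "onset_s", "offset_s", "avg_freq_hz")], 3)
#>   beat label onset_s offset_s avg_freq_hz
#> 1    1    S1  0.0000   0.0940    58.82338
#> 2    1    S2  0.3040   0.3855    65.26622
#> 3    1    S4  0.6840   0.7255    30.40451

head(seg$intervals, 3)
#>   name from to duration_s
#> 1 S1S2    1  2     0.2100
#> 2 S2S4    2  3     0.2985
#> 3 S4S1    3  4     0.0800
```

All nine components are found and labelled; the S4s are flagged by their
low instantaneous frequency (~30 Hz vs ~60 Hz for S1/S2), the estimated
cycle (0.793 s) is within 1% of the true 0.8 s, and the interval table
shows the expected geometry (short S4→S1 gap of 0.08 s). Scoring against
the generator's truth at a 20 ms tolerance:

```r
evaluate_segmentation(seg, g$truth$annotations, tol_s = 0.02,
                      fs = seg$diagnostics$fs)[c("se", "ppv", "label_acc")]
#> $se        [1] 100
#> $ppv       [1] 100
#> $label_acc [1] 100
```

and the murmur-removal effect, measured as SMR over the generator's
component/murmur masks:

```r
hs <- preprocess(g$signal)
smr(hs, g$truth$region_mask)                             # 13.76 dB
smr(eliminate_murmurs(hs)$signal, g$truth$region_mask)   # 39.74 dB
```

The adaptive filter (cutoff picked at 136 Hz here) raises the SMR by
~26 dB, i.e. the murmur all but disappears while the components survive.

A command-line interface with the same functionality ships in
`exec/pcgseg` (`segment`, `synth`, `eval`, `smr` subcommands).

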