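---
title: "Measuring beat-to-beat variability of repolarization with stvqt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring beat-to-beat variability of repolarization with stvqt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stvqt)
```

## The statistic and the measurement problem

Short-term variability of the QT interval (STVQT), often called
beat-to-beat variability of repolarization (BVR), quantifies how much
ventricular repolarization duration fluctuates from one beat to the
next:

$$\mathrm{BVR} = \frac{\sum_n |QT_{n+1} - QT_n|}{n_\text{beats}\,\sqrt{2}},$$

the mean absolute successive difference of per-beat QT, scaled by
$\sqrt 2$. During acute myocardial ischemia this lability rises in the
leads facing the injured territory and surges in the minute before
ventricular fibrillation, which makes it a candidate marker for
imminent-arrhythmia monitoring. The statistic itself is trivial; the
scientific difficulty is upstream: QT must be measured per beat, per
lead, at sub-millisecond effective resolution, in the presence of
ectopy, baseline drift and noise — and the measurement error of a
successive-difference statistic does not average out; it adds in
quadrature to the quantity being estimated. Most of this package is
therefore about the measurement chain, and about a synthetic generator
whose ground truth is known analytically so that the chain can be
audited end to end.

Two conventions matter throughout:

* **Denominator.** The formula above divides by the number of QT
  intervals analyzed (beats), not the number of successive differences;
  `stv(..., denominator = "differences")` provides the alternative
  reading for sensitivity analyses. Differences are only taken between
  *consecutive* valid beats — a pair that bridges an excluded beat is
  not beat-to-beat and is dropped, never bridged.
* **T-wave end.** QT runs from QRS onset to the tangent-method T end:
  the intersection of the tangent at the steepest post-peak T downslope
  with the baseline level. The generator defines its ground truth by
  the same convention, so "truth" and "measurement" answer the same
  question.

## The synthetic generator

`synthesizeRecord()` builds multi-lead records from a sum-of-Gaussians
beat model (P, Q, R, S waves plus a single-Gaussian T). A
single-Gaussian T is a deliberate restriction: its tangent T-end has
the closed form $t_\text{peak} + 2\sigma_T$ (the steepest downslope is
the inflection point at $t_\text{peak}+\sigma_T$, and the tangent there
reaches baseline one further $\sigma_T$ later), which gives every beat
an analytic QT truth.

Per-beat QT is prescribed as `qtBase` plus stationary AR(1) noise. For
Gaussian increments the successive difference has
$\mathrm{sd}(\Delta) = \sigma_w\sqrt{2/(1+\phi)}$ and
$E|\Delta| = \mathrm{sd}(\Delta)\sqrt{2/\pi}$, so the expectation of
the *sample* STV of a record with $N$ analyzed beats and $N_d$
admissible successive pairs is

$$E[\mathrm{STV}] = \frac{N_d}{N}\cdot\frac{E|\Delta|}{\sqrt 2}.$$

When `stvTarget` is given, the innovation SD $\sigma_w$ is obtained by
inverting this expression for the record actually generated (its $N$
and $N_d$ are known once the beat train and any scheduled ectopy are
fixed), so `stvTrue(truth)` is exact rather than asymptotic. A
piecewise profile (`stvSegments`) supports pre-VF-style ramps; there
the large-$N$ calibration is used and `stvTrue` is `NA`.

To realize a prescribed QT, the whole T wave is *translated* in time by
$\delta_i = QT_i - QT_\text{nominal}$ with its shape fixed. An
alternative — stretching the T about its peak — was rejected after
analysis: under a stretch, samples of the T-end neighborhood move by
$x\,\Delta\sigma$ where $x$ is the standardized distance from the peak,
so segment re-alignment recovers a slope-weighted average
($\approx 0.7\,\Delta QT$) rather than $\Delta QT$ — a multiplicative
bias between truth and any correlation-based measurement. Translation
makes the truth and the measurement model coincide. The cost is a
limitation worth stating: real repolarization change alters T-wave
*shape* as well as timing, and this generator does not emulate that.

Other generator conditions and their defaults:

* `rrMean` 1000 ms, `rrSd` 25 ms (anesthetized large-animal sinus
  rhythm, truncated at `rrMean/2` to prevent beat overlap),
  `qtBase` 400 ms, default `stvTarget` 0.4 ms — a quiet baseline
  matching the magnitude reported for pre-occlusion recordings.
* Scheduled PVCs are early, wide, inverted complexes with a discordant
  T, a prescribed coupling interval and a full compensatory pause
  ($2\,\overline{RR} - \text{coupling}$). Their QT truth is `NA`.
* Ischemia (`applyIschemia`) adds a per-lead raised-cosine ST pedestal
  between the QRS offset and T onset and rescales the T amplitude from
  a given onset; samples before the onset are bit-identical to the
  input, and amplitude scaling provably does not move a Gaussian's
  tangent intersection, so QT truth is unchanged.
* Noise: baseline wander 0.05 mV at 0.3 Hz, broadband 3 µV RMS, mains
  0.005 mV at 50 Hz. The broadband level is deliberately low and is
  anchored to the study conditions this generator emulates: a reported
  1-kHz baseline BVR of ~0.3 ms is only observable if per-beat
  measurement error — and hence in-band noise — is at the few-µV level.
  Holter-grade recordings are substantially noisier; conclusions from
  these defaults transfer to clean clinical systems, not to ambulatory
  hardware.
* The seed feeds two separate streams (beat-level truth; sample noise),
  so one seed yields the same beat train and QT series at any sampling
  rate — the sampling-rate experiment compares rates on identical
  truth.

What the generator does not emulate: T-wave shape change and alternans,
respiration-linked QT/RR coupling, rate adaptation of QT (the study
design compares windows with unchanged heart rate), conduction
abnormalities, VF waveforms (VF onset is an event time, not a
waveform), and any species-specific morphology. Passing tests
demonstrate that the *measurement chain* is calibrated and that its
failure modes (exclusion handling, rate effects) behave as described —
not that real ischemic ECG is this simple.

## The measurement chain

Per lead and segment, `analyzeSegment()` runs:

1. **Conditioning.** Zero-phase 2nd-order 0.5-Hz high-pass (baseline
   wander), 50-Hz notch (mains), and the 50-Hz 4th-order low-pass that
   mirrors the recording systems emulated here. All corners are config
   keys (`highpassHz`, `notchHz`, `lowpass50`).
2. **R detection.** A Pan–Tompkins-class detector (5–15 Hz band-pass,
   derivative, squaring, 150-ms integration, adaptive threshold, 200-ms
   refractory). Squaring makes it polarity-insensitive, so wide
   inverted ectopic beats are found.
3. **Template.** Sinus beats are aligned about R by cross-correlation
   (±20 ms) with fractional-shift extraction and averaged; beats
   correlating below 0.9 with the running average are excluded, and
   fewer than 8 usable beats is an error. Fractional alignment matters:
   integer alignment smears the average by up to half a sample, which
   widens the T and biases the tangent.
4. **Template annotation.** QRS onset/offset by a sustained 2%
   threshold on |dV/dt| (an 8-ms run requirement steps over the
   derivative zero-crossings inside the QRS), T peak as the largest
   baseline-referenced excursion after the QRS, T end by the tangent
   method with sub-sample interpolation.
5. **Beat classification.** A beat is a PVC iff it is premature (RR
   < 0.80 × trailing 8-beat sinus RR mean) *and* morphologically
   dissimilar (template correlation < 0.8 about R). The two-gate rule
   keeps sinus arrhythmia from being mislabeled. Both thresholds are
   config keys; the emulated study ascertained ectopy visually, so no
   printed values exist for them.
6. **Per-beat QT** (fiducial segment averaging). The template's
   QRS-onset neighborhood (60 ms) and T neighborhood (120 ms, anchored
   a quarter-window before the T peak) are re-aligned to each beat:
   integer-lag normalized cross-correlation within ±20 ms, then an
   iterated matched refinement (a Newton step on the squared-difference
   objective using the template derivative, with linearly interpolated
   fractional extraction). Per-beat QT = (T end + T shift) − (QRS onset
   + onset shift). Beats whose alignment correlation falls below 0.8
   are flagged invalid, never silently dropped.
7. **Exclusion.** Every PVC, its successor, and — when the PVC falls
   before the preceding beat's T end — its predecessor are removed from
   the QT series before `stv()`.

Two estimator details were forced by analysis rather than taste. The
T-segment window is anchored on the T *peak* because the late T tail is
nearly shift/scale-degenerate for normalized correlation: a time shift
of an exponential-like decay is indistinguishable from an amplitude
change, so a window centered on the T end ill-conditions the alignment.
And the sub-sample step uses the matched (derivative-projection)
estimator rather than parabolic interpolation of the correlation peak,
whose location is noise-fragile on broad smooth peaks. The window
lengths (60/120 ms) are package decisions — the emulated toolchain does
not publish its values — sized so that the QRS onset complex and the T
peak-to-downslope region fall inside the respective windows. Widening
them further does sharpen 1-kHz precision slightly, but it also lets
the sub-sample refinement compensate most of the coarse-grid error at
200 Hz, erasing the rate effect the pipeline is meant to expose; the
chosen lengths keep the estimator honest at both rates.

## Segment metrics and the study design

`segmentMetrics()` bundles, per 60-s window (the study's segment
length): per-lead BVR, mean QT, heart rate from sinus beats
(60000/mean RR), ST deviation (median amplitude over J+60–80 ms
referenced to the same beat's PR segment, minus the baseline window's
level; the measurement points are config keys since the study does not
print its own), QT dispersion (inter-lead range of segment-mean QT),
cumulative BVR and cumulative |ST| across leads, maximal BVR, and PVC
counts. Failed leads carry a reason string instead of silent `NA`s.

`makeTimepoints()` encodes the design windows: baseline ends 15 min
before occlusion; early ischemia starts occlusion + 5 min; `pre1` ends
exactly at VF onset; `pre5` is the 60-s window ending at VF − 4 min
(reading "5 min pre-VF" as the minute centered on that mark;
`pre5Mode = "ending"` gives the alternative ending at VF − 5 min).
Animals without VF reuse the same arithmetic at a supplied matched time
point. The analysis lead follows "lead II or V4 as appropriate",
realized as the candidate lead with the largest absolute
baseline-to-early-ischemia ST deviation — the study does not state its
selection criterion, so this is a documented interpretation.

`surgeDetect()` flags an imminent-arrhythmia surge when
BVR(pre1) − BVR(pre5) exceeds a threshold, default 1.4 ms — a working
point between the reported group-mean changes of animals with
(+2.23 ms) and without (+0.66 ms) VF. It is a configurable default
with no claim of clinical validity.

`inducibilityIndex()` maps a programmed-stimulation outcome onto a
percentage scale: induction at the first step (S1 600 ms, one
extrastimulus S2 400 ms) is 100%; completing the most aggressive step
(S1 350 ms, S2/S3/S4 200/180/150 ms) without induction is 0%;
intermediate steps map linearly, $100\,(S-k+1)/S$ for induction at
step $k$ of $S$. Only the endpoints are protocol facts; the default
9-step ladder (drive cycles 600/400/350 ms × 1–3 extrastimuli) and the
linearity are package decisions, and the index is defined over
whatever ladder the user supplies. `erpFromDrivetrain()` returns the
shortest non-capturing S2 at the 400-ms drive train, flagging
non-monotone capture sequences and out-of-range boundaries.

## The sampling-rate experiment

`samplingStudy()` re-runs the full chain on the same underlying signal
at 200 Hz (obtained by anti-aliased downsampling), 1 kHz, and — only
when a genuinely 4-kHz recording is supplied — 4 kHz. Upsampling is
never accepted as a stand-in, and inputs below 500 Hz are refused
(QT-variability measurement is unreliable there) unless forced.
Downsampling uses a zero-phase 8th-order Butterworth anti-alias filter
at 80% of the new Nyquist frequency before polyphase decimation;
`signal::resample`'s default decimation filter showed ~14% passband
ripple and is used only for the upsampling stage.

Coarse sampling inflates measured BVR: at 5-ms resolution the
alignment estimator's residual error grows, and those per-beat errors
add in quadrature to the successive differences. The package's
verification exercises this where the effect is cleanest — quiet
baseline records (true STV 0.2 ms) of 5 min, the recording length the
emulated sampling comparison used — and separately checks that 1-kHz
and 4-kHz measurements of the same truth agree to well under 0.1 ms.
With sub-sample refinement the 200-Hz inflation is far milder than a
grid-marking toolchain would produce (tens of percent rather than
several-fold); the direction, not the magnitude, is the reproducible
claim.

## Numerical choices and degenerate inputs

* Tangent search window: T peak to T peak + 200 ms; no downslope or no
  baseline crossing in that window is an explicit error, as are flat
  signals for the R detector ("no beats") and templates without a T
  wave.
* RR truncation at `rrMean/2` uses `pmax` (mass at the bound) rather
  than rejection sampling; at the default 25-ms SD the bound is 20
  standard deviations away and unreachable.
* Records are written as CSV (1e-6 mV precision) with a JSON sidecar
  (`fs`, `leads`, `t0`) and a truth table
  (`beat_time_ms,label,qt_true_ms`); a sidecar missing a field names
  that field in its error.
* Run logs hash the configuration (`tools::md5sum` of its canonical
  YAML) so cohort reports are reproducible byte for byte.

## Problem sizes used in the shipped verification

Unit and acceptance tests run single-lead records: 60-s windows
(~59 beats) for calibration and recovery (100 seeds per target),
5-min records for the 200-Hz comparison (100 seeds), 15 paired
1-kHz/4-kHz records, and 2 × 20 two-window cohorts for the surge
detector. These sizes keep the full suite in the tens of minutes on a
single core while leaving Monte-Carlo standard errors well below the
tolerances being asserted.

## Known limitations

* Truth and measurement share the tangent convention and the
  translated-T generator; agreement does not validate tangent QT
  against other T-end conventions on real data.
* Per-lead analysis only; no multi-lead fiducial fusion, P-wave
  analysis, QT rate correction, T-wave alternans, or QT variability
  index.
* The PVC detector emulates visual ascertainment with two fixed
  thresholds; couplet/run handling labels runs of ≥3 PVCs as nsVT and
  excludes them wholesale, but no VT/VF waveform detection is
  attempted.
* The surge threshold and the PES ladder interpolation are pragmatic
  defaults for synthetic experiments, not clinically validated values.
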