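# stvqt

Beat-to-beat variability of repolarization (BVR, also written STVQT)
on the multi-lead ECG: the mean absolute successive difference of the
per-beat QT interval,

    BVR = sum(|QT[n+1] - QT[n]|) / (n_beats * sqrt(2))   [ms],

a marker of repolarization lability that rises during acute myocardial
ischemia and surges in the minute before ventricular fibrillation.
`stvqt` is for electrophysiology researchers who need that statistic
computed reproducibly from raw multi-lead waveforms — and who need to
know how much of a measured BVR is physiology versus measurement
artifact.

The package provides:

* a synthetic 12-lead ECG generator (`synthesizeRecord`) with
  analytically known per-beat QT ground truth, prescribed short-term
  variability (closed-form AR(1) calibration), scheduled premature
  ventricular complexes, ischemic ST/T changes (`applyIschemia`), and
  anti-aliased resampling (`resampleRecord`);
* the measurement chain (`analyzeSegment`): Pan–Tompkins-class R
  detection, fiducial-segment-averaging templates, tangent-method
  T-wave end, PVC classification and the standard exclusion rule
  (PVC + successor + predecessor when the PVC lands before the prior
  T end);
* repolarization metrics per 60-s segment (`segmentMetrics`, `stv`,
  `poincarePairs`, `qtDispersion`, ST deviation);
* study orchestration: occlusion/pre-VF time-point windows
  (`makeTimepoints`, `analyzeTimepoints`), pre-VF surge detection
  (`surgeDetect`), the sampling-rate experiment (`samplingStudy`), and
  a programmed-electrical-stimulation inducibility index
  (`inducibilityIndex`, `erpFromDrivetrain`).

## Worked example

Generate a quiet baseline record with a prescribed short-term QT
variability of 1.5 ms, one scheduled PVC, and measure it back:

```r
library(stvqt)

cfg <- synthConfig(duration = 60, leads = "II", stvTarget = 1.5,
                   pvcSchedule = data.frame(beat = 20, coupling = 300,
                                            scale = 1),
                   seed = 7)
out <- synthesizeRecord(cfg)
out$truth
#> GroundTruth: 59 beats ( 1 PVC ); analytic STV = 1.5 ms

a <- analyzeSegment(out$record, "II")
a
#> SegmentAnalysis [ II ]: 59 beats, 56 valid; BVR 1.404 ms; mean QT 401.4 ms; HR 59.7 bpm; 1 PVC
```

The generator's truth says the expected sample STV of this record is
exactly 1.5 ms; the pipeline detected all 59 beats, recognized the
scheduled PVC, excluded it together with its flagged neighbors (56
beats analyzed), and measured a BVR of 1.40 ms for this seed — one
draw of a statistic whose mean across seeds is calibrated to the
target. The measured mean QT matches the prescribed 400 ms and the
heart rate the prescribed 1000-ms RR.

Downsampling the same signal to a Holter-like 200 Hz inflates the
measured BVR — the sampling-rate artifact the pipeline is built to
expose. On a quiet 5-min baseline record (true STV 0.4 ms):

```r
base <- synthesizeRecord(synthConfig(duration = 300, leads = "II",
                                     seed = 11))
samplingStudy(base$record, lead = "II")
#>     fs       bvr  mean_qt n_valid ratio_vs_1k
#> 1  200 0.4034830 400.8275     299    1.027459
#> 2 1000 0.3926999 400.7853     299    1.000000
```

The inflation is modest for this sub-sample-interpolating instrument
and grows as true lability falls; a grid-marking toolchain shows a
several-fold version of the same effect. The acceptance tests
characterize the direction of the effect over 100 seeds.

Study-design analysis of a long record uses an event log:

```r
ev  <- eventLog(occlusionTime = 1000, vfTime = 2050)
tps <- makeTimepoints(ev, recordSpan = c(0, 2100))
tps[, c("window", "start_s", "end_s")]
#>     window start_s end_s
#> 1 baseline      40   100
#> 2     ami5    1300  1360
#> 3     pre5    1750  1810
#> 4     pre1    1990  2050

surgeDetect(bvrPre5 = 1.67, bvrPre1 = 3.78)
#> SurgeResult: dBVR = 2.110 ms; SURGE (threshold 1.4 ms)
```

And the inducibility scale from programmed stimulation:

```r
inducibilityIndex(pesOutcome(inducedAtStep = 1))  # first step
#> [1] 100
inducibilityIndex(pesOutcome())                   # noninducible
#> [1] 0
```

## Documentation

The methods vignette (`vignettes/stvqt-methods.Rmd`) describes the
statistic, the generator's ground-truth construction, every tunable
threshold with its default and rationale, and the package's known
limitations.
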