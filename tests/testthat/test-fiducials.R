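# R-peak detection, template annotation, tangent T-end, QT measurement.

test_that("R peaks of a clean record match generator truth", {
  out <- synthesizeRecord(quietConfig(duration = 60, seed = 31))
  x <- leadSignal(out$record, "II")
  rIdx <- detectRPeaks(x, 1000)
  tR <- rTimes(out$truth)
  expect_equal(length(rIdx), length(tR))
  expect_lt(max(abs((rIdx - 1) - tR)), 10)          # within 10 ms
  expect_true(all(diff(rIdx) > 0))
  expect_true(all(diff(rIdx) >= 0.2 * 1000))        # refractory
})

test_that("degenerate signals raise a no-beats error", {
  expect_error(detectRPeaks(rep(0, 5000), 1000), "no beats")
  expect_error(detectRPeaks(rep(NaN, 5000), 1000), "no beats")
  expect_error(detectRPeaks(rnorm(500), 1000), "2 s")
})

test_that("detection recall stays high under broadband noise", {
  hits <- 0; total <- 0
  for (s in 1:5) {
    out <- synthesizeRecord(quietConfig(
      duration = 60, seed = 100 + s,
      noise = list(wanderAmp = 0, broadbandSd = 0.05, powerlineAmp = 0)))
    x <- leadSignal(out$record, "II")
    rIdx <- detectRPeaks(x, 1000)
    tR <- rTimes(out$truth)
    total <- total + length(tR)
    hits <- hits + sum(vapply(tR, function(t0)
      any(abs((rIdx - 1) - t0) < 50), logical(1)))
  }
  expect_gte(hits / total, 0.98)
})

test_that("template of identical beats equals the single beat", {
  # repeat one noise-free beat exactly; the mean must reproduce it
  beat <- makeBeatTemplate(fs = 1000, rrMean = 1000, qt = 400,
                           leads = "II")$waveform[, 1]
  x <- rep(beat, 20)
  rIdx <- detectRPeaks(x, 1000)
  tpl <- buildTemplate(x, 1000, rIdx)
  ref <- makeBeatTemplate(fs = 1000, rrMean = 3000, qt = 400,
                          leads = "II")$waveform[, 1]
  # align both on their own amplitude peak (the detector's R anchor can
  # sit one sample off the analytic center)
  r0 <- which.max(tpl@waveform)
  refR <- which.max(ref)
  seg <- function(w, c0, half) w[(c0 - half):(c0 + half)]
  expect_lt(max(abs(seg(tpl@waveform, r0, 250) -
                    seg(ref, refR, 250))), 1e-6)
  expect_gte(tpl@nBeats, 8)
})

test_that("template averaging suppresses additive noise ~ sqrt(n)", {
  beat <- makeBeatTemplate(fs = 1000, rrMean = 1000, qt = 400,
                           leads = "II")$waveform[, 1]
  set.seed(5)
  sdN <- 0.02
  x <- rep(beat, 64) + rnorm(64000, 0, sdN)
  rIdx <- detectRPeaks(x, 1000)
  tpl <- buildTemplate(x, 1000, rIdx)
  # judge noise suppression on the flat pre-P stretch, where residual
  # sub-sample alignment cannot leak waveform slope into the residual
  flat <- tpl@waveform[1:80]
  expect_lt(sd(flat - mean(flat)), 3 * sdN / sqrt(tpl@nBeats))
})

test_that("insufficient usable beats is an explicit error", {
  out <- synthesizeRecord(quietConfig(duration = 8, seed = 3))
  x <- leadSignal(out$record, "II")
  rIdx <- detectRPeaks(x, 1000)
  expect_error(buildTemplate(x, 1000, rIdx), "insufficient beats")
})

test_that("tangent T-end matches the Gaussian closed form", {
  fs <- 1000
  t <- seq(0, 799)
  for (sig in c(20, 30, 40, 50, 60)) {
    w <- 0.4 * exp(-(t - 300)^2 / (2 * sig^2))
    te <- tangentTEnd(w, fs, tPeakHint = 300)
    expect_lt(abs(te - (300 + 2 * sig)), 1)         # one sample at 1 kHz
  }
  # inverted T wave
  w <- -0.4 * exp(-(t - 300)^2 / (2 * 40^2))
  expect_lt(abs(tangentTEnd(w, fs, 300) - 380), 1)
  # baseline-shift invariance
  w2 <- 0.4 * exp(-(t - 300)^2 / (2 * 40^2)) + 0.1
  expect_lt(abs(tangentTEnd(w2, fs, 300, baselineLevel = 0.1) - 380), 1)
})

test_that("tangent of a descending ramp is the ramp itself", {
  t <- seq(0, 599)
  w <- pmax(0, pmin(1, (420 - t) / 120))   # hits baseline at exactly 420
  expect_equal(tangentTEnd(w, 1000, tPeakHint = 300), 420,
               tolerance = 1e-9)
})

test_that("tangent errors on flat or non-crossing waveforms", {
  t <- seq(0, 599)
  expect_error(tangentTEnd(rep(0, 600), 1000, 300), "flat")
  ramp <- 1 + t * 1e-6                      # no downslope after the peak
  expect_error(tangentTEnd(ramp, 1000, 590), "peak|downslope|crossing")
})

test_that("annotated template fiducials match generator truth", {
  out <- synthesizeRecord(quietConfig(duration = 60, seed = 32,
                                      stvTarget = 0))
  x <- leadSignal(out$record, "II")
  rIdx <- detectRPeaks(x, 1000)
  tpl <- annotateTemplate(buildTemplate(x, 1000, rIdx))
  f <- fiducials(tpl)
  expect_true(f["qrsOn"] < f["rPeak"] && f["rPeak"] < f["tPeak"] &&
              f["tPeak"] < f["tEnd"])
  # template QT against the prescribed constant 400 ms
  expect_lt(abs((f["tEnd"] - f["qrsOn"]) - 400), 4)
})

test_that("template without a T wave raises a not-found error", {
  m <- defaultMorphology("II")
  m$t$amp <- 0
  beat <- makeBeatTemplate(m, fs = 1000, rrMean = 1000, leads = "II")
  x <- rep(beat$waveform[, 1], 20)
  rIdx <- detectRPeaks(x, 1000)
  tpl <- buildTemplate(x, 1000, rIdx)
  expect_error(annotateTemplate(tpl), "T wave")
})

test_that("fiducials agree across 1 kHz and 4 kHz within 1.5 ms", {
  qts <- list()
  for (fs in c(1000, 4000)) {
    out <- synthesizeRecord(quietConfig(duration = 60, seed = 33,
                                        fs = fs, stvTarget = 0.4))
    a <- analyzeSegment(out$record, "II")
    f <- fiducials(a$template)
    qts[[as.character(fs)]] <- c(f["tEnd"] - f["qrsOn"], a$meanQt)
  }
  expect_lt(max(abs(qts[["1000"]] - qts[["4000"]])), 1.5)
})

test_that("per-beat QT recovers a constant prescribed QT", {
  out <- synthesizeRecord(quietConfig(duration = 60, seed = 34,
                                      stvTarget = 0))
  a <- analyzeSegment(out$record, "II")
  qm <- qtValues(a$qts)[validMask(a$qts)]
  expect_gte(length(qm), 50)
  expect_lt(max(abs(qm - 400)), 2)
})

test_that("measured per-beat QT tracks a prescribed AR(1) series", {
  out <- synthesizeRecord(quietConfig(
    duration = 60, seed = 35, stvTarget = 2, qtArCoef = 0.5,
    noise = list(wanderAmp = 0, broadbandSd = 0.02, powerlineAmp = 0)))
  a <- analyzeSegment(out$record, "II")
  tr <- out$truth
  n <- min(length(rTimes(tr)), length(qtValues(a$qts)))
  ok <- validMask(a$qts)[1:n]
  expect_gte(cor(qtValues(a$qts)[1:n][ok], qtValues(tr)[1:n][ok]), 0.9)
})

test_that("QT bookkeeping: one value per beat, order preserved", {
  out <- synthesizeRecord(quietConfig(
    duration = 60, seed = 36,
    pvcSchedule = data.frame(beat = c(10, 30), coupling = c(300, 320),
                             scale = 1)))
  x <- leadSignal(out$record, "II")
  rIdx <- detectRPeaks(x, 1000)
  tpl <- annotateTemplate(buildTemplate(x, 1000, rIdx))
  bs <- measureQT(x, 1000, rIdx, tpl)
  expect_identical(nrow(bs@beats), length(rIdx))
  expect_true(all(diff(bs@beats$r_time_ms) > 0))
  expect_error(measureQT(x, 500, rIdx, tpl), "sampling rates differ")
})

test_that("fiducial times are invariant to amplitude scaling", {
  out <- synthesizeRecord(quietConfig(duration = 60, seed = 37,
                                      stvTarget = 1))
  a1 <- analyzeSegment(out$record, "II")
  rec2 <- out$record
  rec2@signal <- rec2@signal * 2.5
  a2 <- analyzeSegment(rec2, "II")
  expect_equal(qtValues(a1$qts), qtValues(a2$qts), tolerance = 1e-6)
  expect_equal(a1$bvr, a2$bvr, tolerance = 1e-6)
})

test_that("fiducial times shift with the record clock (t0)", {
  out <- synthesizeRecord(quietConfig(duration = 60, seed = 38))
  rec2 <- out$record
  rec2@t0 <- 120
  a1 <- analyzeSegment(out$record, "II")
  a2 <- analyzeSegment(rec2, "II")
  expect_equal(rTimes(a2$qts), rTimes(a1$qts) + 120 * 1000)
  expect_equal(qtValues(a2$qts), qtValues(a1$qts))
})
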