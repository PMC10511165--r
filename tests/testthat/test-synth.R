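# Synthetic ECG generator: determinism, calibration, schedules, I/O.

test_that("identical configs give bit-identical records and truth", {
  cfg <- quietConfig(duration = 20, stvTarget = 1.0, seed = 11,
                     noise = list())
  a <- synthesizeRecord(cfg)
  b <- synthesizeRecord(cfg)
  expect_identical(a$record@signal, b$record@signal)
  expect_identical(rTimes(a$truth), rTimes(b$truth))
  expect_identical(qtValues(a$truth), qtValues(b$truth))
})

test_that("beat-level truth is independent of the sampling rate", {
  a <- synthesizeRecord(quietConfig(duration = 20, seed = 5, fs = 1000))
  b <- synthesizeRecord(quietConfig(duration = 20, seed = 5, fs = 4000))
  expect_identical(rTimes(a$truth), rTimes(b$truth))
  expect_identical(qtValues(a$truth), qtValues(b$truth))
})

test_that("zero QT noise gives a constant QT series and zero STV", {
  out <- synthesizeRecord(quietConfig(duration = 20, stvTarget = NULL,
                                      qtWhiteSd = 0))
  expect_equal(stvTrue(out$truth), 0)
  expect_true(all(abs(qtValues(out$truth) - 400) < 1e-12))
})

test_that("STV calibration: mean sample STV matches stv_true over seeds", {
  # truth-level Monte-Carlo check of the closed-form calibration
  # (fs = 200 keeps waveform assembly cheap; the truth is fs-independent)
  vals <- vapply(1:200, function(s) {
    out <- synthesizeRecord(quietConfig(duration = 60, fs = 200,
                                        stvTarget = 1.5, seed = s))
    stv(qtValues(out$truth))
  }, numeric(1))
  expect_equal(mean(vals), 1.5, tolerance = 0.02)   # within 2 %
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 1.5), 3 * se)
})

test_that("AR(1) QT noise honors the requested lag-1 autocorrelation", {
  out <- synthesizeRecord(quietConfig(duration = 300, fs = 200,
                                      stvTarget = 2, qtArCoef = 0.6,
                                      seed = 4))
  x <- qtValues(out$truth) - 400
  r1 <- cor(x[-1], x[-length(x)])
  expect_equal(r1, 0.6, tolerance = 0.15)
})

test_that("PVC schedule bookkeeping: coupling and compensatory pause", {
  out <- synthesizeRecord(quietConfig(
    duration = 40, stvTarget = 0,
    pvcSchedule = data.frame(beat = 20, coupling = 250, scale = 1)))
  tr <- out$truth
  expect_identical(sum(beatLabels(tr) == "pvc"), 1L)
  expect_identical(which(beatLabels(tr) == "pvc"), 20L)
  r <- rTimes(tr)
  expect_equal(r[20] - r[19], 250)
  expect_equal(r[21] - r[20], 2 * 1000 - 250)
  expect_true(is.na(qtValues(tr)[20]))
})

test_that("invalid configurations are rejected", {
  expect_error(synthConfig(fs = -1), "fs")
  expect_error(synthConfig(qtBase = 1200, rrMean = 1000), "rrMean > qtBase")
  expect_error(synthConfig(qtArCoef = 1), "qtArCoef")
  expect_error(synthConfig(pvcSchedule = data.frame(beat = 5,
                                                    coupling = 1500)),
               "coupling")
  expect_error(makeBeatTemplate(fs = 0), "fs")
})

test_that("single-beat template reports analytic fiducials", {
  b <- makeBeatTemplate(fs = 1000, rrMean = 1000, qt = 400)
  expect_equal(nrow(b$waveform), 1000)     # rrMean * fs / 1000 samples
  expect_equal(unname(b$fiducials["tEnd"] - b$fiducials["qrsOn"]), 400)
  # flat morphology: zero waveform, QT undefined
  m <- defaultMorphology()
  m$waves$amp[] <- 0; m$t$amp <- 0
  fb <- makeBeatTemplate(m, fs = 1000)
  expect_true(all(fb$waveform == 0))
  expect_true(is.na(fb$qt))
})

test_that("ischemia is local: no sample changes before onset", {
  out <- synthesizeRecord(quietConfig(duration = 30, seed = 2,
                                      noise = list()))
  isc <- applyIschemia(out$record, out$truth,
                       stOffsets = c(II = 0.2), tScale = 0.7,
                       onsetS = 15)
  i0 <- floor(15 * 1000)
  expect_identical(out$record@signal[1:i0, ], isc$record@signal[1:i0, ])
  expect_false(identical(out$record@signal, isc$record@signal))
  expect_equal(unname(isc$truth@stOffset["II"]), 0.2)
  # identity case
  same <- applyIschemia(out$record, out$truth, stOffsets = c(II = 0),
                        tScale = 1, onsetS = 15)
  expect_identical(out$record@signal, same$record@signal)
  expect_error(applyIschemia(out$record, out$truth, c(II = 0.1),
                             onsetS = 99), "onset")
})

test_that("resampling preserves length, duration and tone amplitude", {
  out <- synthesizeRecord(quietConfig(duration = 60, seed = 3))
  expect_identical(resampleRecord(out$record, 1000), out$record)
  r200 <- resampleRecord(out$record, 200)
  expect_lte(abs(nSamples(r200) - 12000), 1)
  expect_lt(abs(recordDuration(r200) - recordDuration(out$record)),
            1 / 200)
  expect_identical(leadNames(r200), leadNames(out$record))
  # spectral invariance: 5-Hz tone amplitude preserved within 1 %
  t <- seq(0, 10, by = 1 / 1000)
  tone <- ecgRecord(cbind(II = sin(2 * pi * 5 * t)), fs = 1000)
  tone200 <- resampleRecord(tone, 200)
  mid <- leadSignal(tone200, "II")[200:1800]
  expect_equal(max(abs(mid)), 1, tolerance = 0.01)
  expect_error(resampleRecord(out$record, -5), "positive")
})

test_that("record round trip preserves signal, metadata and truth", {
  dir <- withr::local_tempdir()
  out <- synthesizeRecord(quietConfig(duration = 10, seed = 8,
    pvcSchedule = data.frame(beat = 5, coupling = 300, scale = 1)))
  writeRecord(out$record, dir, "r1", truth = out$truth)
  back <- readRecord(dir, "r1")
  expect_equal(back$record@fs, 1000)
  expect_identical(leadNames(back$record), "II")
  expect_lt(max(abs(back$record@signal - out$record@signal)), 1e-6)
  expect_equal(rTimes(back$truth), rTimes(out$truth))
  expect_identical(beatLabels(back$truth), beatLabels(out$truth))
  expect_equal(qtValues(back$truth), qtValues(out$truth))
  # missing fs in the sidecar is a named parse error
  side <- file.path(dir, "r1.json")
  j <- jsonlite::read_json(side)
  j$fs <- NULL
  jsonlite::write_json(j, side, auto_unbox = TRUE)
  expect_error(readRecord(dir, "r1"), "fs")
})

test_that("YAML SynthConfig round trip", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(list(duration = 15, leads = "II", stvTarget = 0.8,
                        seed = 12,
                        pvcSchedule = list(list(beat = 4, coupling = 300,
                                                scale = 1))), p)
  cfg <- readSynthConfig(p)
  expect_s3_class(cfg, "SynthConfig")
  expect_equal(cfg$stvTarget, 0.8)
  expect_equal(cfg$pvcSchedule$coupling, 300)
  out <- synthesizeRecord(cfg)
  expect_identical(sum(beatLabels(out$truth) == "pvc"), 1L)
})
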