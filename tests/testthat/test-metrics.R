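# The STV statistic and companion segment metrics.

test_that("stv matches the printed-formula hand evaluations", {
  expect_equal(stv(c(400, 400, 400, 400)), 0)
  # sum|diff| = 30 over 4 analyzed beats: 30 / (4 * sqrt(2))
  expect_equal(stv(c(400, 410, 400, 410)), 30 / (4 * sqrt(2)),
               tolerance = 1e-12)
  expect_equal(stv(c(400, 410, 400, 410), denominator = "differences"),
               30 / (3 * sqrt(2)), tolerance = 1e-12)
})

test_that("stv equals the brute-force oracle on random masked series", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(5:60, 1)
    qt <- 400 + rnorm(n, 0, 5)
    valid <- runif(n) > 0.2
    if (sum(valid) < 2) valid[1:2] <- TRUE
    expect_equal(stv(qt, valid), bruteStv(qt, valid),
                 tolerance = 1e-12)
    expect_equal(stv(qt, valid, denominator = "differences"),
                 bruteStv(qt, valid, "differences"), tolerance = 1e-12)
  }
})

test_that("stv is translation invariant and positively homogeneous", {
  set.seed(7)
  qt <- 400 + rnorm(30, 0, 3)
  expect_equal(stv(qt + 55), stv(qt), tolerance = 1e-12)
  expect_equal(stv(2.5 * qt), 2.5 * stv(qt), tolerance = 1e-12)
})

test_that("exclusion gaps are dropped, never bridged", {
  # constant QT with one PVC and its exclusions still gives exactly 0
  qt <- rep(400, 12); qt[6] <- 350              # the PVC's own (bogus) QT
  valid <- rep(TRUE, 12); valid[5:7] <- FALSE   # preceding, PVC, succeeding
  expect_identical(stv(qt, valid), 0)
  # a bridged pair would see |400-400| = 0 too; prove pairs are dropped
  qt2 <- c(400, 410, 500, 410, 400)
  valid2 <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  expect_equal(stv(qt2, valid2), (10 + 10) / (4 * sqrt(2)))
  expect_error(stv(c(400), valid = TRUE), "2 valid")
})

test_that("poincare pairs enumerate admissible successive pairs", {
  p <- poincarePairs(c(400, 410, 400))
  expect_equal(p$qt, c(400, 410))
  expect_equal(p$qtNext, c(410, 400))
  cst <- poincarePairs(rep(400, 5))
  expect_true(all(cst$qt == cst$qtNext))
  # pair count always equals the number of differences used by stv
  set.seed(9)
  for (rep in 1:20) {
    qt <- 400 + rnorm(25, 0, 4)
    valid <- runif(25) > 0.3
    if (sum(valid) < 2) valid[1:2] <- TRUE
    np <- nrow(poincarePairs(qt, valid))
    nd <- sum(valid[-25] & valid[-1])
    expect_identical(np, nd)
  }
})

test_that("qt dispersion is the inter-lead range", {
  expect_equal(qtDispersion(rep(400, 12)), 0)
  expect_equal(qtDispersion(seq(380, 420, length.out = 12)), 40)
  set.seed(3)
  v <- 400 + rnorm(12, 0, 10)
  expect_identical(qtDispersion(v), max(v) - min(v))
  expect_error(qtDispersion(c(400)), "2 leads")
})

test_that("ST deviation round-trips an injected plateau offset", {
  cfg <- quietConfig(duration = 80, leads = c("II", "V4"),
                     stvTarget = 0.4, seed = 21, noise = list())
  out <- synthesizeRecord(cfg)
  isc <- applyIschemia(out$record, out$truth, stOffsets = c(V4 = 0.2),
                       onsetS = 15)
  sm <- segmentMetrics(isc$record, window = c(20, 80),
                       baselineWindow = c(0, 15) + c(0, 0),
                       leads = c("II", "V4"))
  pl <- sm$perLead
  expect_equal(pl$st_dev[pl$lead == "V4"], 0.2, tolerance = 0.02)
  expect_lt(abs(pl$st_dev[pl$lead == "II"]), 0.02)
  # sign flip of the offset flips the deviation
  neg <- applyIschemia(out$record, out$truth, stOffsets = c(V4 = -0.2),
                       onsetS = 15)
  smn <- segmentMetrics(neg$record, window = c(20, 80),
                        baselineWindow = c(0, 15), leads = "V4")
  expect_equal(smn$perLead$st_dev[1], -0.2, tolerance = 0.02)
})

test_that("segment metrics aggregate across leads", {
  # identical leads: cumulative BVR = n * per-lead, max = per-lead
  out <- synthesizeRecord(quietConfig(duration = 60, stvTarget = 1,
                                      seed = 13, rrSd = 0))
  x <- leadSignal(out$record, "II")
  rec3 <- ecgRecord(cbind(II = x, V4 = x, V5 = x), fs = 1000)
  sm <- segmentMetrics(rec3)
  bvrs <- sm$perLead$bvr
  expect_equal(bvrs[1], bvrs[2], tolerance = 1e-12)
  expect_equal(sm$cumulativeBvr, 3 * bvrs[1])
  expect_equal(sm$maxBvr, bvrs[1])
  expect_equal(sm$qtDispersion, 0, tolerance = 1e-9)
  # constant RR 1000 ms: heart rate 60 beats/min
  expect_equal(sm$hr, 60, tolerance = 0.5)
})

test_that("failing leads are recorded as absent with a reason", {
  out <- synthesizeRecord(quietConfig(duration = 60, seed = 14))
  flat <- cbind(leadSignal(out$record, "II"), 0)
  colnames(flat) <- c("II", "V4")
  sm <- segmentMetrics(ecgRecord(flat, fs = 1000))
  expect_identical(sm$perLead$status[1], "ok")
  expect_false(sm$perLead$status[2] == "ok")
  expect_true(is.na(sm$perLead$bvr[2]))
  expect_equal(sm$cumulativeBvr, sm$perLead$bvr[1])
})
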