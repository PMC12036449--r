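test_that("log frequency grid has the documented geometry", {
  g <- logFreqGrid(4, 150, 50)
  expect_length(g, 50L)
  expect_equal(g[1], 4)
  expect_equal(g[50], 150)
  ratios <- g[-1] / g[-50]
  expect_equal(ratios, rep(ratios[1], 49), tolerance = 1e-12)
  expect_error(logFreqGrid(0, 150), "fMin")
})

test_that("Morlet cycle counts interpolate geometrically from 4 to 9", {
  g <- logFreqGrid()
  cy <- morletCycles(g)
  expect_equal(cy[1], 4)
  expect_equal(cy[length(cy)], 9)
  expect_equal(diff(log(cy)), rep(diff(log(cy))[1], length(cy) - 1),
               tolerance = 1e-9)
})

test_that("Gabor filters have unit energy and sit at the Gabor limit", {
  for (v0 in c(5, 8, 40, 110)) {
    g <- gaborFilter(v0, fs = 500)
    expect_equal(sum(Mod(g$h)^2) / 500, 1, tolerance = 1e-6)
    expect_equal(g$sigmaT * g$sigmaF, 1 / (4 * pi), tolerance = 1e-12)
    # FWHM of the amplitude response equals the fractional bandwidth
    expect_equal(2 * sqrt(2 * log(2)) * sqrt(2) * g$sigmaF, 0.25 * v0,
                 tolerance = 1e-9)
  }
  expect_error(gaborFilter(300, fs = 500), "v0")
})

test_that("Gabor analytic amplitude matches the analytic tone response", {
  fs <- 500
  f0 <- 7
  amp <- 1.8
  tt <- seq_len(8 * fs) / fs
  x <- amp * cos(2 * pi * f0 * tt)
  env <- gaborHAA(x, fs, band = c(4, 9))
  centers <- attr(env, "centers")
  expected <- mean(vapply(centers, function(v0) {
    g <- gaborFilter(v0, fs)
    (amp / 2) * g$A * sqrt(pi / g$s0) * exp(-pi^2 * (f0 - v0)^2 / g$s0)
  }, 0))
  mid <- seq(2 * fs, 6 * fs)
  expect_equal(mean(env[mid]), expected, tolerance = 0.01)
  expect_lt(sd(env[mid]) / mean(env[mid]), 0.05)
})

test_that("Morlet power localizes tones and scales with amplitude squared", {
  fs <- 500
  tt <- seq_len(6 * fs) / fs
  freqs <- logFreqGrid(4, 40, 20)
  x1 <- cos(2 * pi * 10 * tt)
  x2 <- 2 * cos(2 * pi * 10 * tt)
  p1 <- morletTFR(x1, fs, freqs, keepPhase = FALSE)$power
  p2 <- morletTFR(x2, fs, freqs, keepPhase = FALSE)$power
  mid <- seq(2 * fs, 4 * fs)
  prof <- colMeans(p1[mid, ])
  expect_equal(freqs[which.max(prof)], freqs[which.min(abs(freqs - 10))])
  # doubling the amplitude quadruples the power
  expect_equal(mean(p2[mid, which.max(prof)]) / mean(p1[mid, which.max(prof)]),
               4, tolerance = 1e-3)
  # out-of-band response is down by more than 20 dB
  far <- which.min(abs(freqs - 40))
  expect_gt(10 * log10(prof[which.max(prof)] / prof[far]), 20)
})

test_that("epoching produces exact half-open windows", {
  fs <- 500
  x <- seq_len(30 * fs)                  # sample index as signal value
  ep <- epochSignal(x, c(5, 12), c(-0.5, 2), fs)
  expect_identical(dim(ep), c(1250L, 2L))
  # window [t - 0.5, t + 2): first sample is the one at t - 0.5
  expect_equal(ep[1, 1], 5 * fs - 0.5 * fs + 1)
  expect_equal(ep[1250, 1], 5 * fs + 2 * fs)
  ep2 <- epochSignal(x, c(5, 12), c(-1, 1), fs)
  expect_identical(dim(ep2), c(1000L, 2L))
  # events whose window leaves the recording are dropped and reported
  ep3 <- epochSignal(x, c(0.2, 5, 29.9), c(-1, 1), fs)
  expect_identical(attr(ep3, "kept"), 2L)
  expect_error(epochSignal(x, 100, c(-1, 1), fs), "no epoch")
})

test_that("epoching a recording stacks trials across channels", {
  beh <- fixture("beh1x30", makeBehavior(1, 30, seed = 301))
  ds <- fixture("ds1x30", {
    generateDataset(beh, recordingSpec(channels = c(dmPFC = 2L, dlPFC = 1L),
                                       seed = 302))
  })
  rec <- patientRecording(ds, 1)
  env <- epochRecording(rec, "dmPFC", "band", window = c(0, 2),
                        align = "feedback", band = c(4, 9), decimate = 5L)
  expect_s4_class(env, "BandEnvelope")
  expect_identical(ncol(env@amplitude), 60L)        # 30 trials x 2 channels
  expect_identical(nrow(env@amplitude), 200L)       # 1000 samples / 5
  expect_identical(sort(unique(env@events$channel)),
                   c("dmPFCch1", "dmPFCch2"))
})
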