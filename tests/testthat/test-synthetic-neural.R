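test_that("background noise has the requested scale and spectral slope", {
  fs <- 500
  x <- genBackground(2^16, fs, alpha = 1, amplitude = 1.5, seed = 41)
  expect_length(x, 2^16)
  expect_equal(sd(x), 1.5, tolerance = 1e-9)
  # PSD slope on the log-log periodogram, band-limited and bin-averaged
  sp <- Mod(fft(x)[2:(2^15)])^2
  f <- (1:(2^15 - 1)) * fs / 2^16
  keep <- f > 2 & f < 80
  lf <- log10(f[keep]); lp <- log10(sp[keep])
  bins <- cut(lf, 24)
  slope <- coef(lm(tapply(lp, bins, mean) ~ tapply(lf, bins, mean)))[2]
  expect_equal(unname(slope), -1, tolerance = 0.15)
  # alpha = 0 gives a flat spectrum
  w <- genBackground(2^14, fs, alpha = 0, amplitude = 1, seed = 42)
  expect_equal(sd(w), 1, tolerance = 1e-9)
})

test_that("behavior events carry the study codings", {
  sess <- banditSession(choices = c(1, 1, 2, 2), outcomes = c(1, 0, 0, 1))
  tr <- sessionTrajectory(sess, vkfSpec(), vkfParams())
  ev <- behaviorEvents(sess, tr, patient = "P07")
  expect_identical(ev$patient, rep("P07", 4))
  # decision: stay = 1 / switch = 0 relative to the NEXT trial, NA at the end
  expect_identical(ev$decision, c(1L, 0L, 1L, NA_integer_))
  expect_identical(ev$prev_feedback, c(NA_integer_, 1L, 0L, 0L))
  expect_identical(ev$reward, c(1L, 0L, 0L, 1L))
  expect_equal(ev$feedback_time - ev$selection_time, rep(0.5, 4))
  expect_equal(ev$pe, tr@pe)
})

test_that("regressor-modulated power scales with the regressor", {
  fs <- 500
  ev <- data.frame(selection_time = c(4, 12), feedback_time = c(4.5, 12.5),
                   reward = c(0L, 1L))
  sig <- injectRegressorPower(numeric(20 * fs), fs, ev, band = c(4, 9),
                              regressor = "reward", slope = 0.8,
                              stage = "post_feedback", amp = 1)
  expect_identical(attr(sig, "skipped"), 0L)
  rms <- function(t0) sqrt(mean(sig[(t0 * fs + 1):(t0 * fs + 2 * fs)]^2))
  # sample-sd z-scoring of reward 0/1 gives z = -1/sqrt(2), +1/sqrt(2)
  expect_equal(rms(12.5) / rms(4.5),
               (1 + 0.8 / sqrt(2)) / (1 - 0.8 / sqrt(2)), tolerance = 0.05)
  # a window outside the recording is skipped, not an error
  ev2 <- rbind(ev, data.frame(selection_time = 19.8, feedback_time = 20.3,
                              reward = 1L))
  sig2 <- injectRegressorPower(numeric(20 * fs), fs, ev2, c(4, 9), "reward",
                               0.8)
  expect_identical(attr(sig2, "skipped"), 1L)
})

test_that("PAC injection places components in the configured regions", {
  fs <- 500
  ev <- data.frame(selection_time = c(4, 10), feedback_time = c(4.5, 10.5))
  set.seed(51)
  inj <- injectPac(numeric(15 * fs), fs, ev, phaseFreq = 8, ampFreq = 110,
                   depth = 1, stage = "pre_selection",
                   phaseSignal = numeric(15 * fs))
  win <- (3 * fs + 1):(4 * fs)
  out <- (6 * fs + 1):(8 * fs)
  expect_gt(sd(inj$signal[win]), 0)
  expect_gt(sd(inj$phaseSignal[win]), 0)
  expect_equal(sd(inj$signal[out]), 0)
  # fast energy sits near 110 Hz in the amplitude channel only
  spec <- function(x) {
    f <- seq(0, fs, length.out = length(x) + 1)[seq_along(x)]
    s <- Mod(fft(x))^2
    sum(s[f > 90 & f < 130]) / sum(s[f > 0 & f < 250])
  }
  expect_gt(spec(inj$signal[win]), 0.8)
  expect_lt(spec(inj$phaseSignal[win]), 0.1)
  # NA depth means no injection on that trial
  set.seed(52)
  injNA <- injectPac(numeric(15 * fs), fs, ev, 8, 110,
                     depth = c(NA_real_, 1), stage = "pre_selection")
  expect_equal(sd(injNA[win]), 0)
  expect_error(injectPac(numeric(15 * fs), fs, ev, 8, 110, depth = 2),
               "depth")
})

test_that("shared-envelope injection tracks the target correlation", {
  fs <- 500
  nTr <- 25
  fb <- 4 + 6 * (seq_len(nTr) - 1)
  ev <- data.frame(selection_time = fb - 0.5, feedback_time = fb)
  measure <- function(targetR, seed) {
    set.seed(seed)
    n <- (max(fb) + 4) * fs
    inj <- injectSharedEnvelope(numeric(n), numeric(n), fs, ev,
                                band = c(4, 9), targetR = targetR,
                                stage = "post_feedback", amp = 1)
    # interior of the injection window: the shared edge taper would
    # otherwise add a deterministic common shape to both envelopes
    eA <- epochSignal(as.numeric(gaborHAA(inj$a, fs, c(4, 9))), fb,
                      c(0.25, 1.75), fs)
    eB <- epochSignal(as.numeric(gaborHAA(inj$b, fs, c(4, 9))), fb,
                      c(0.25, 1.75), fs)
    mean(aac(eA, eB))
  }
  rHigh <- measure(0.9, 61)
  rZero <- measure(0, 62)
  rNeg <- measure(-0.9, 63)
  expect_gt(rHigh, 0.5)
  expect_lt(abs(rZero), 0.3)
  expect_lt(rNeg, -0.3)
})

test_that("dataset generation is deterministic and shape-consistent", {
  beh <- fixture("beh1x30", makeBehavior(1, 30, seed = 301))
  spec <- recordingSpec(channels = c(dmPFC = 2L, dlPFC = 1L), seed = 302)
  ds1 <- fixture("ds1x30", generateDataset(beh, spec))
  ds2 <- generateDataset(beh, spec)
  expect_equal(ds1$signals$dmPFC[[1]], ds2$signals$dmPFC[[1]])
  expect_identical(nrow(ds1$events), 30L)
  expect_identical(nrow(ds1$signals$dmPFC[[1]]), 2L)
  rec <- patientRecording(ds1, 1)
  expect_s4_class(rec, "SyntheticRecording")
  expect_identical(names(rec@signals), c("dmPFC", "dlPFC"))
  expect_identical(rec@fs, 500)
})

test_that("recording specs reject inconsistent configurations", {
  expect_error(recordingSpec(fs = 100,
                             pac = list(phaseRegion = "a", ampRegion = "b",
                                        phaseFreq = 8, ampFreq = 110,
                                        depth = 0.5)), "Nyquist|fs must")
  expect_error(recordingSpec(pac = list(phaseFreq = 8, ampFreq = 110,
                                        depth = 1.4)), "depth")
  expect_error(recordingSpec(aac = list(band = c(4, 9), targetR = 1.2)),
               "targetR")
  expect_error(recordingSpec(noiseAlpha = -1), "noiseAlpha")
})
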