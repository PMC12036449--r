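test_that("modulation index is exact for an analytically coupled pair", {
  # a = 1 + cos(phi) over whole cycles: mi = |mean((1 + cos) e^{i phi})| = 1/2
  phi <- 2 * pi * seq(0, 20, length.out = 4001)[-1]
  a <- 1 + cos(phi)
  expect_equal(pacMI(a, phi), 0.5, tolerance = 1e-10)
  # phase-independent amplitude gives (near) zero
  expect_lt(pacMI(rep(1, length(phi)), phi), 1e-10)
  expect_error(pacMI(a, phi[-1]), "length mismatch")
})

test_that("FFT all-lags modulation index matches the direct loop", {
  set.seed(71)
  n <- 256
  a <- abs(rnorm(n)) + 0.2
  phi <- cumsum(rnorm(n, 0.3, 0.1))
  fast <- neurobandit:::.miAllLags(a, phi)
  direct <- vapply(0:(n - 1), function(s) {
    idx <- ((seq_len(n) - 1 + s) %% n) + 1
    pacMI(a[idx], phi)
  }, 0)
  expect_equal(as.numeric(fast), direct, tolerance = 1e-10)
})

test_that("permutation z separates coupled from independent series", {
  fs <- 500
  n <- 8 * fs
  set.seed(72)
  # phase from narrowband-filtered noise, as in real use: a pure periodic
  # phase would make the circular-shift null degenerate (the MI is
  # lag-invariant against a single complex exponential)
  x <- genBackground(n, fs, alpha = 1)
  phi <- Arg(neurobandit:::.gaussFilterBank(x, fs, 8, 2)[, 1])
  aCoupled <- (1 + 0.8 * cos(phi)) * (1 + 0.1 * rnorm(n))
  zc <- pacPermutationZ(aCoupled, phi %% (2 * pi), nPerm = 300, seed = 2)
  expect_s3_class(zc, "pacResult")
  expect_gt(zc$z, 5)
  aInd <- 1 + 0.5 * abs(rnorm(n))
  zi <- pacPermutationZ(aInd, phi %% (2 * pi), nPerm = 300, seed = 2)
  expect_lt(abs(zi$z), 4)
  expect_output(print(zc), "PAC")
})

test_that("the PAC grid has the 18 x 22 shape and localizes an injection", {
  fs <- 500
  nTr <- 15
  fb <- 4 + 5 * (seq_len(nTr) - 1)
  ev <- data.frame(selection_time = fb - 0.5, feedback_time = fb)
  set.seed(73)
  n <- (max(fb) + 4) * fs
  sig <- genBackground(n, fs, alpha = 1, amplitude = 0.3)
  sig <- injectPac(sig, fs, ev, phaseFreq = 8, ampFreq = 110, depth = 0.9,
                   stage = "post_feedback", amp0 = 0.8, slowAmp = 1)
  grid <- pacGridSearch(sig, sig, fs, ev, stage = "post_feedback",
                        nPerm = 100, seed = 3)
  expect_identical(dim(grid$z), c(18L, 22L))
  expect_equal(unname(grid$peak["phase"]), 8, tolerance = 0.25)
  expect_equal(unname(grid$peak["amp"]), 110, tolerance = 0.15)
})

test_that("amplitude-amplitude coupling behaves like a per-trial Pearson", {
  set.seed(74)
  A <- matrix(rnorm(200), 50, 4)
  expect_equal(aac(A, A), rep(1, 4))
  expect_equal(aac(A, -A), rep(-1, 4))
  B <- matrix(rnorm(200), 50, 4)
  expect_equal(aac(A, B),
               vapply(1:4, function(i) cor(A[, i], B[, i]), 0))
  # zero-variance trials yield NA rather than an error
  A2 <- A; A2[, 2] <- 1
  expect_true(is.na(aac(A2, B)[2]))
  expect_error(aac(A, B[, 1:2]), "matching dimensions")
})

test_that("the per-patient coupling table joins measures to regressors", {
  beh <- fixture("beh1x30", makeBehavior(1, 30, seed = 301))
  ds <- fixture("ds1x30", {
    generateDataset(beh, recordingSpec(channels = c(dmPFC = 2L, dlPFC = 1L),
                                       seed = 302))
  })
  tab <- couplingTable(patientRecording(ds, 1), nPerm = 60, seed = 5)
  expect_s3_class(tab, "couplingTable")
  expect_setequal(unique(tab$measure),
                  c("aac_theta_theta", "aac_xfreq", "pac_z"))
  expect_setequal(unique(tab$stage), c("post_feedback", "pre_selection"))
  expect_identical(unique(tab$stage_code[tab$stage == "pre_selection"]), 1L)
  expect_identical(nrow(tab), 30L * 2L * 3L)
  expect_true(all(c("pe", "rv", "ru", "reward", "decision") %in% names(tab)))
  aacVals <- tab$value[grepl("^aac", tab$measure)]
  expect_true(all(abs(aacVals) <= 1 | is.na(aacVals)))
})
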