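makeCouplingFrame <- function(nPatients = 4, nTrials = 50, seed = 81,
                              stageShift = -0.3, decisionSlope = 0.6,
                              peSlope = 0.5) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nPatients), function(p) {
    ic <- rnorm(1, 0, 0.2)
    do.call(rbind, lapply(c("post_feedback", "pre_selection"), function(st) {
      sc <- as.integer(st == "pre_selection")
      pe <- runif(nTrials, -1, 1)
      dec <- rbinom(nTrials, 1, 0.6)
      val <- ic + stageShift * sc + peSlope * pe * (1 - sc) +
        decisionSlope * (dec - 0.5) * sc + rnorm(nTrials, 0, 0.3)
      data.frame(patient = sprintf("P%02d", p), trial = seq_len(nTrials),
                 stage = st, stage_code = sc, measure = "aac_theta_theta",
                 value = val, reward = rbinom(nTrials, 1, 0.5),
                 decision = dec, pe = pe, rv = runif(nTrials),
                 ru = runif(nTrials))
    }))
  }))
}

test_that("mixed-model fits honor the binary codings", {
  set.seed(82)
  n <- 80
  dat <- data.frame(
    patient = rep(c("P01", "P02", "P03"), length.out = n),
    reward = rbinom(n, 1, 0.5))
  dat$y <- 0.8 * dat$reward + rnorm(n, 0, 0.4)
  fit <- fitLME(dat, "y", "reward", channelNested = FALSE)
  expect_identical(fit$term, "reward")
  expect_gt(fit$t, 3)
  # flipping the coding flips the sign but not the magnitude
  dat$rewardFlip <- 1L - dat$reward
  fit2 <- fitLME(dat, "y", "rewardFlip", channelNested = FALSE)
  expect_equal(fit2$t, -fit$t, tolerance = 1e-6)
  # a single-patient table falls back to ordinary least squares
  one <- dat[dat$patient == "P01", ]
  expect_identical(attr(fitLME(one, "y", "reward"), "engine"), "lm")
})

test_that("the vectorized stratified solver agrees with lm per pixel", {
  set.seed(83)
  n <- 90
  strata <- factor(rep(c("a", "b", "c"), each = 30))
  X <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  Y <- matrix(rnorm(n * 5), n, 5)
  Y[, 3] <- Y[, 3] + 0.9 * X[, 1]
  fit <- neurobandit:::.fastTMap(Y, X, strata)
  for (px in c(1, 3, 5)) {
    ref <- summary(lm(Y[, px] ~ X + strata))$coefficients
    expect_equal(unname(fit$t[, px]),
                 unname(ref[c("Xx1", "Xx2"), "t value"]), tolerance = 1e-8)
  }
  expect_equal(fit$df, n - 2 - 3)
})

test_that("pixel areas follow the geometric bin-width rule", {
  times <- seq(0, 1, by = 0.02)
  freqs <- logFreqGrid(4, 150, 50)
  A <- pixelAreas(times, freqs)
  r <- freqs[2] / freqs[1]
  expect_equal(A[1, 1], 20 * 4 * (sqrt(r) - 1 / sqrt(r)))
  expect_equal(A[5, 50], 20 * 150 * (sqrt(r) - 1 / sqrt(r)))
  # areas grow with frequency on a log grid
  expect_true(all(diff(A[1, ]) > 0))
})

test_that("clusters below the minimum area are filtered out", {
  tmat <- matrix(0, 10, 10)
  tmat[2:5, 2:5] <- 5                    # 16-pixel cluster
  tmat[8, 8] <- 5                        # single pixel
  areas <- matrix(30, 10, 10)            # Hz*ms per pixel
  cs <- neurobandit:::.clusterStats(tmat, thr = 3, areas, minArea = 320)
  expect_identical(nrow(cs), 1L)
  expect_equal(cs$area, 16 * 30)
  expect_equal(cs$stat, 16 * 25)
  # with a permissive threshold both clusters survive
  cs2 <- neurobandit:::.clusterStats(tmat, 3, areas, minArea = 25)
  expect_identical(nrow(cs2), 2L)
})

test_that("cluster permutation detects an injected reward effect", {
  tf <- nullTFMap(nTimes = 18, nFreqs = 12, nPatients = 2, nChannels = 2,
                  trialsPer = 40, seed = 84)
  hit <- tf@events$reward == 1
  tf@power[4:9, 4:8, hit] <- tf@power[4:9, 4:8, hit] + 1.5
  cl <- clusterPermutation2d(tf, c("reward", "prev_feedback"),
                             term = "reward", nPerm = 300, seed = 85)
  expect_s3_class(cl, "clusterResult")
  expect_gte(sum(cl$clusters$significant), 1L)
  top <- cl$clusters[which.max(cl$clusters$stat), ]
  inside <- cl$labels[4:9, 4:8] == top$id
  expect_gt(mean(inside), 0.8)
  expect_output(print(cl), "cluster")
})

test_that("regression and cluster maps agree between engines on the truth", {
  tf <- nullTFMap(nTimes = 10, nFreqs = 8, nPatients = 3, nChannels = 1,
                  trialsPer = 30, seed = 86)
  hit <- tf@events$reward == 1
  tf@power[3:6, 3:6, hit] <- tf@power[3:6, 3:6, hit] + 1.2
  ols <- tfRegressionMap(tf, "reward", engine = "ols")
  lmm <- tfRegressionMap(tf, "reward", engine = "lmm")
  expect_identical(dim(ols$t$reward), c(10L, 8L))
  # both engines put their strongest response inside the injected block
  expect_true(which.max(ols$t$reward) %in%
                as.vector(outer(3:6, (3:6 - 1) * 10, "+")))
  expect_gt(cor(as.vector(ols$t$reward), as.vector(lmm$t$reward)), 0.95)
})

test_that("FDR-corrected timecourses isolate the effect window", {
  set.seed(87)
  nT <- 60; nTr <- 240
  amp <- matrix(abs(rnorm(nT * nTr, 1, 0.2)), nT, nTr)
  ev <- data.frame(patient = rep(c("P01", "P02"), each = nTr / 2),
                   reward = rbinom(nTr, 1, 0.5))
  amp[21:35, ev$reward == 1] <- amp[21:35, ev$reward == 1] + 0.6
  env <- new("BandEnvelope", amplitude = amp,
             times = seq(0, 2, length.out = nT), band = c(4, 9), events = ev)
  tc <- timecourseRegressionFDR(env, "reward", q = 0.001)
  expect_s3_class(tc, "tcResult")
  expect_true(all(tc$mask["reward", 21:35]))
  expect_false(any(tc$mask["reward", c(1:15, 45:60)]))
})

test_that("coupling statistics recover constructed effects with signs", {
  tab <- makeCouplingFrame()
  sc <- couplingStageContrast(tab, "aac_theta_theta")
  expect_lt(sc$t, -3)                    # weaker coupling pre-selection
  dp <- couplingDecisionPrediction(tab, "aac_theta_theta", "pre_selection")
  expect_gt(dp$t, 3)                     # higher coupling precedes stays
  dpl <- couplingDecisionPrediction(tab, "aac_theta_theta", "pre_selection",
                                    logistic = TRUE)
  expect_gt(dpl$t, 2)
  cv <- couplingVariableCorrelation(tab, "aac_theta_theta", "post_feedback",
                                    regressors = "pe")
  expect_gt(cv$effects$t[1], 3)          # coupling rises with the PE
  expect_identical(as.integer(sort(unique(cv$bins$bin))), 1:25)
  cvStay <- couplingVariableCorrelation(tab, "aac_theta_theta",
                                        "pre_selection", regressors = "pe",
                                        subset = "stay")
  expect_true(all(cvStay$bins$n >= 1))
})
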