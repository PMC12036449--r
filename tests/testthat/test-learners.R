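test_that("Rescorla-Wagner update matches the closed form", {
  expect_equal(rwUpdate(0.5, 1, 0.3), 0.65)
  expect_equal(rwUpdate(0.5, 0, 0.3, aNeg = 0.1), 0.45)
  expect_equal(rwUpdate(0.2, 0, 0.5), 0.1)
  expect_error(rwUpdate(0.5, 1, 1.2), "learning rates")
})

test_that("Kalman-filter update matches hand-derived values", {
  # m = 0.5, w = 0.1, O = 1, v = 0.01, sigma2 = 0.2:
  # k = 0.11 / 0.31, m' = 0.5 + k * 0.5, w' = (1 - k) * 0.11
  up <- kfUpdate(0.5, 0.1, 1, 0.01, 0.2)
  expect_equal(up$k, 0.11 / 0.31, tolerance = 1e-12)
  expect_equal(up$m, 0.5 + (0.11 / 0.31) * 0.5, tolerance = 1e-12)
  expect_equal(up$w, (1 - 0.11 / 0.31) * 0.11, tolerance = 1e-12)
  expect_equal(up$pe, 0.5)
  expect_error(kfUpdate(0.5, 0.1, 1, 0.01, 0), "sigma2")
})

test_that("volatile-Kalman-filter update matches hand-derived values", {
  # m = 0, w = v = omega = 0.5, O = 1, lambda = 0.1:
  # k = 1/1.5 = 2/3, m' = 2/3, w' = 1/3, wCov = 1/6,
  # v' = 0.5 + 0.1 * ((2/3)^2 + 0.5 + 1/3 - 1/3 - 0.5) = 0.5 + 0.1 * 4/9
  up <- vkfUpdate(0, 0.5, 0.5, 1, 0.1, 0.5)
  expect_equal(up$k, 2 / 3, tolerance = 1e-12)
  expect_equal(up$m, 2 / 3, tolerance = 1e-12)
  expect_equal(up$w, 1 / 3, tolerance = 1e-12)
  expect_equal(up$wCov, 1 / 6, tolerance = 1e-12)
  expect_equal(up$v, 0.5 + 0.1 * 4 / 9, tolerance = 1e-12)
  # the volatility never collapses below the floor
  low <- vkfUpdate(0.5, 1e-9, 1e-9, 0, 1, 10, vFloor = 1e-8)
  expect_gte(low$v, 1e-8)
})

test_that("softmax probabilities match an independent computation", {
  sp <- modelSpec("KF", "value_and_uncertainty", TRUE)
  pr <- choiceProbabilities(c(0.6, 0.3, 0.1), c(0.5, 0.3, 0.2), sp,
                            modelParams(sp, list(v = 0.1, sigma2 = 0.2,
                                                 betaV = 3, betaU = 1)))
  expect_equal(pr, c(0.6674810, 0.2221851, 0.1103339), tolerance = 1e-6)
  expect_equal(sum(pr), 1)
  # max-subtraction keeps extreme temperatures finite
  big <- choiceProbabilities(c(0.9, 0.05, 0.05), c(1, 1, 1), sp,
                             modelParams(sp, list(v = 0.1, sigma2 = 0.2,
                                                  betaV = 5000, betaU = 0)))
  expect_true(all(is.finite(big)))
  expect_equal(big[1], 1, tolerance = 1e-6)
})

test_that("RW1 session trajectory equals a plain R reference loop", {
  sess <- banditSession(choices = c(1, 1, 2, 1, 3, 2),
                        outcomes = c(1, 0, 1, 1, 0, 0))
  sp <- modelSpec("RW1", "value_only", FALSE)
  a <- 0.35
  tr <- sessionTrajectory(sess, sp, list(a = a, betaV = 2))
  m <- rep(0.5, 3)
  nll <- 0
  for (t in 1:6) {
    e <- exp(2 * m - max(2 * m))
    pr <- e / sum(e)
    nll <- nll - log(pr[sess@choices[t]])
    m[sess@choices[t]] <- m[sess@choices[t]] +
      a * (sess@outcomes[t] - m[sess@choices[t]])
    expect_equal(tr@m[t, ], m, tolerance = 1e-12)
  }
  expect_equal(tr@nll, nll, tolerance = 1e-10)
})

test_that("a zero-temperature policy has uniform likelihood", {
  sess <- fixture("sess40", {
    simulateAgent(banditConfig(nTrials = 40, seed = 21), vkfSpec(),
                  vkfParams(), seed = 22)
  })
  nll <- sessionNLL(sess, vkfSpec(),
                    list(lambda = 0.2, v0 = 0.5, omega = 0.5,
                         betaV = 0, betaU = 0))
  expect_equal(nll, 40 * log(3), tolerance = 1e-10)
})

test_that("unchosen arms keep their means and inflate their variances", {
  sess <- banditSession(choices = c(1, 1), outcomes = c(1, 1), nArms = 3)
  sp <- modelSpec("KF", "value_only", TRUE)
  tr <- sessionTrajectory(sess, sp, list(v = 0.05, sigma2 = 0.3, betaV = 1))
  expect_equal(tr@m[1, 2:3], c(0.5, 0.5))
  expect_equal(tr@w[1, 2:3], c(1.05, 1.05))
  expect_equal(tr@w[2, 2:3], c(1.10, 1.10))
  expect_lt(tr@w[1, 1], 1)
})

test_that("trajectory invariants hold on simulated sessions", {
  sess <- fixture("sess40", {
    simulateAgent(banditConfig(nTrials = 40, seed = 21), vkfSpec(),
                  vkfParams(), seed = 22)
  })
  tr <- sessionTrajectory(sess, vkfSpec(), vkfParams())
  expect_equal(rowSums(tr@choiceProbs), rep(1, 40), tolerance = 1e-9)
  expect_true(all(tr@k >= 0 & tr@k <= 1))
  expect_true(all(tr@rv >= 0 & tr@rv <= 1))
  expect_true(all(tr@ru >= 0 & tr@ru <= 1))
  expect_true(all(tr@v > 0))
  expect_equal(sessionNLL(sess, vkfSpec(), vkfParams()), tr@nll)
  tab <- trajectoryTable(tr, sess)
  expect_identical(nrow(tab), 40L)
  expect_true(all(c("m1", "w3", "v2", "pe", "p1", "choice") %in% names(tab)))
})

test_that("modelParams validates bounds and fills fixed initial conditions", {
  sp <- vkfSpec()
  full <- modelParams(sp, vkfParams())
  expect_equal(full$m0, 0.5)
  expect_equal(full$w0, 1)
  expect_error(modelParams(sp, list(lambda = 1.5, v0 = 0.5, omega = 0.5,
                                    betaV = 1, betaU = 1)), "lambda")
  expect_error(modelParams(sp, list(lambda = 0.2, v0 = -1, omega = 0.5,
                                    betaV = 1, betaU = 1)), "v0")
  expect_error(modelParams(sp, list(lambda = 0.2, v0 = 0.5, betaV = 1,
                                    betaU = 1)), "missing parameters")
})
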