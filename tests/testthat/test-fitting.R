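test_that("parameter links round-trip exactly", {
  sp <- vkfSpec()
  p <- vkfParams()
  th <- toTransformed(p, sp)
  back <- toNative(th, sp)
  expect_equal(back[freeParamNames(sp)], p[freeParamNames(sp)],
               tolerance = 1e-10)
  # unit-range parameters stay in (0, 1), positive ones stay positive
  wild <- toNative(setNames(c(-30, 4, 4, 3, 3), names(th)), sp)
  expect_true(wild$lambda > 0 && wild$lambda < 1)
  expect_true(wild$v0 > 0 && wild$omega > 0)
})

test_that("MAP fit beats the generating parameters and reports BIC", {
  sess <- fixture("fitSess", {
    simulateAgent(banditConfig(nTrials = 150, seed = 31), vkfSpec(),
                  vkfParams(), seed = 32)
  })
  fit <- mapFit(sess, vkfSpec(), nStarts = 3, seed = 5)
  expect_false(isTRUE(fit$failed))
  # the penalized optimum should (nearly) dominate the generating point
  truth <- sessionNLL(sess, vkfSpec(), vkfParams()) +
    sum(toTransformed(vkfParams(), vkfSpec())^2 / (2 * 6.25))
  expect_lte(fit$penalized, truth + 0.1)
  d <- length(freeParamNames(vkfSpec()))
  expect_equal(fit$bic, 2 * fit$nll + d * log(nTrials(sess)))
  expect_true(all(is.finite(unlist(fit$paramsNative))))
  expect_true(fit$paramsNative$lambda >= 0 && fit$paramsNative$lambda <= 1)
  expect_true(is.finite(fit$logEvidence))
})

test_that("exceedance probabilities respect symmetry and ordering", {
  L <- matrix(rnorm(10, sd = 0.01), 5, 2)
  L[, 2] <- L[, 1]                       # identical evidence
  bms <- exceedanceProbability(L, nSamples = 2e4, seed = 3)
  expect_equal(unname(bms$xp), c(0.5, 0.5), tolerance = 0.05)
  expect_equal(sum(bms$xp), 1)
  L2 <- cbind(rnorm(5), rnorm(5) + 5, rnorm(5))
  bms2 <- exceedanceProbability(L2, nSamples = 2e4, seed = 3)
  expect_identical(unname(which.max(bms2$xp)), 2L)
})

test_that("hierarchical fitting returns coherent group structures", {
  beh <- fixture("beh2x60", makeBehavior(2, 60, seed = 201))
  sessions <- lapply(beh, `[[`, "session")
  specs <- list(modelSpec("RW1", "value_only", FALSE),
                modelSpec("VKF", "value_and_uncertainty", TRUE))
  gf <- hierarchicalFit(sessions, specs, maxIter = 2, nStarts = 2, seed = 4)
  expect_s3_class(gf, "groupFit")
  expect_identical(dim(gf$logEvidence), c(2L, 2L))
  expect_equal(rowSums(gf$responsibilities), rep(1, 2), tolerance = 1e-6)
  expect_equal(sum(gf$xp), 1, tolerance = 1e-9)
  expect_length(gf$fits, 2L)
  expect_output(print(gf), "groupFit")
})

test_that("parameter recovery reports per-parameter correlations", {
  sp <- modelSpec("RW1", "value_only", FALSE)
  grid <- data.frame(a = c(0.2, 0.5, 0.8), betaV = c(6, 3, 9))
  rep <- parameterRecovery(sp, grid, nTrials = 80, seed = 11, nStarts = 2)
  expect_s3_class(rep, "recoveryReport")
  expect_named(rep$r, c("a", "betaV"))
  expect_identical(nrow(rep$table), 6L)
  expect_true(all(is.finite(rep$table$recovered)))
  expect_error(parameterRecovery(sp, data.frame(a = 0.5), nTrials = 80),
               "betaV")
})

test_that("the default model grid spans the intended eight models", {
  grid <- defaultModelGrid()
  expect_length(grid, 8L)
  labs <- vapply(grid, function(s) paste0(s@learner, "/", s@choiceRule), "")
  expect_identical(sum(grepl("^RW", labs)), 2L)
  expect_identical(sum(grepl("^KF", labs)), 3L)
  expect_identical(sum(grepl("^VKF", labs)), 3L)
  expect_false(anyDuplicated(labs) > 0)
})
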