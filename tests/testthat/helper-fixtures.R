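# Shared fixtures, built lazily and cached for the whole test run.

nbFixtures <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = nbFixtures, inherits = FALSE))
    assign(key, force(expr), envir = nbFixtures)
  get(key, envir = nbFixtures, inherits = FALSE)
}

vkfSpec <- function() modelSpec("VKF", "value_and_uncertainty", TRUE)

vkfParams <- function() list(lambda = 0.2, v0 = 0.5, omega = 0.5,
                             betaV = 8, betaU = 2)

# simulated multi-patient behavior under the default generating agent
makeBehavior <- function(nPatients = 2, nTrials = 60, seed = 101) {
  lapply(seq_len(nPatients), function(i) {
    cfg <- banditConfig(nTrials = nTrials, seed = seed + 10L * i)
    sess <- simulateAgent(cfg, vkfSpec(), vkfParams(), seed = seed + 10L * i + 1L)
    list(session = sess, trajectory = sessionTrajectory(sess, vkfSpec(), vkfParams()))
  })
}

# a pure-noise (null) time-frequency map with stacked patient/channel strata
nullTFMap <- function(nTimes = 18, nFreqs = 12, nPatients = 2,
                      nChannels = 2, trialsPer = 40, seed = 1) {
  set.seed(seed)
  n <- nPatients * nChannels * trialsPer
  power <- array(exp(rnorm(nTimes * nFreqs * n, sd = 0.5)),
                 c(nTimes, nFreqs, n))
  events <- data.frame(
    patient = rep(sprintf("P%02d", seq_len(nPatients)),
                  each = nChannels * trialsPer),
    channel = rep(rep(paste0("ch", seq_len(nChannels)), each = trialsPer),
                  nPatients),
    reward = rbinom(n, 1, 0.5),
    prev_feedback = rbinom(n, 1, 0.5))
  new("TFMap", power = power, phase = array(0, c(0, 0, 0)),
      times = seq(0, 2, length.out = nTimes),
      freqs = logFreqGrid(4, 150, nFreqs), events = events)
}
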