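#' Construct a restless-bandit environment configuration
#'
#' Defaults reproduce the task environment: three arms whose hidden reward
#' probabilities each have a 10\% chance per trial of moving by 0.2
#' (direction uniform among moves that keep the value inside
#' \code{[0.1, 0.9]}), starting from random lattice values.
#'
#' @param nArms number of arms.
#' @param pChange per-trial per-arm change probability.
#' @param step change magnitude.
#' @param bounds closed probability interval.
#' @param nTrials session length.
#' @param seed integer seed for the environment.
#' @return a \linkS4class{BanditConfig}
#' @export
banditConfig <- function(nArms = 3L, pChange = 0.1, step = 0.2,
                         bounds = c(0.1, 0.9), nTrials = 300L, seed = 1L) {
  new("BanditConfig", nArms = as.integer(nArms), pChange = pChange,
      step = step, bounds = as.numeric(bounds), nTrials = as.integer(nTrials),
      seed = as.integer(seed))
}

#' Simulate the drifting reward-probability walk
#'
#' Each arm starts at a seeded value on the lattice
#' \code{seq(bounds[1], bounds[2], by = step)}. On every trial, independently
#' per arm, the probability changes with probability \code{pChange}; the
#' direction is drawn uniformly among directions that stay within bounds (at
#' a boundary the single legal direction is taken), so the change rate is
#' \code{pChange} everywhere.
#'
#' @param config a \linkS4class{BanditConfig}
#' @return nTrials x nArms matrix of reward probabilities
#' @export
simulateProbabilityWalk <- function(config) {
  stopifnot(is(config, "BanditConfig"))
  validObject(config)
  lo <- config@bounds[1]; hi <- config@bounds[2]; st <- config@step
  lattice <- seq(lo, hi, by = st)
  set.seed(config@seed)
  p <- matrix(NA_real_, config@nTrials, config@nArms)
  cur <- sample(lattice, config@nArms, replace = TRUE)
  for (t in seq_len(config@nTrials)) {
    p[t, ] <- cur
    change <- runif(config@nArms) < config@pChange
    if (any(change)) {
      up <- cur + st <= hi + 1e-12
      dn <- cur - st >= lo - 1e-12
      # uniform among legal directions; both legal -> fair coin
      dir <- ifelse(up & dn, sign(runif(config@nArms) - 0.5),
                    ifelse(up, 1, -1))
      cur <- ifelse(change, pmin(hi, pmax(lo, cur + dir * st)), cur)
    }
  }
  p
}

#' Simulate an agent playing the restless bandit
#'
#' Choices are sampled from the agent's own softmax probabilities given its
#' running latent state; outcomes are Bernoulli draws from the hidden reward
#' probability of the chosen arm. Event timestamps follow the task timeline:
#' feedback appears \code{selToFb} seconds after selection, feedback display
#' plus inter-trial interval (Gaussian, truncated positive) separate trials.
#'
#' @param config a \linkS4class{BanditConfig}
#' @param spec a \linkS4class{ModelSpec}
#' @param params named list of learner/choice parameters
#'   (see \code{\link{modelParams}})
#' @param seed integer seed for agent and outcome randomness
#' @param selToFb selection-to-feedback delay (s)
#' @param postFb feedback display plus fixation duration before the next
#'   selection becomes available (s)
#' @param itiMean,itiSd inter-trial interval distribution (s)
#' @param leadIn recording time before the first selection (s)
#' @return a \linkS4class{BanditSession}
#' @export
simulateAgent <- function(config, spec, params, seed = 1L,
                          selToFb = 0.5, postFb = 2.5,
                          itiMean = 0.626, itiSd = 0.072, leadIn = 2) {
  stopifnot(is(config, "BanditConfig"), is(spec, "ModelSpec"))
  params <- modelParams(spec, params)
  probs <- simulateProbabilityWalk(config)
  set.seed(seed)
  n <- config@nTrials; A <- config@nArms
  m <- rep(params$m0, A); w <- rep(params$w0, A)
  v <- rep(if (spec@learner == "VKF") params$v0 else params$v %||% 0, A)
  choicesv <- integer(n); outc <- integer(n)
  selT <- numeric(n); fbT <- numeric(n)
  tcur <- leadIn
  for (t in seq_len(n)) {
    pr <- choiceProbabilities(m, w, spec = spec, params = params)
    c_t <- sample.int(A, 1L, prob = pr)
    o_t <- rbinom(1L, 1L, probs[t, c_t])
    choicesv[t] <- c_t; outc[t] <- o_t
    selT[t] <- tcur; fbT[t] <- tcur + selToFb
    iti <- max(0.05, rnorm(1, itiMean, itiSd))
    tcur <- fbT[t] + postFb + iti
    st <- .updateState(m, w, v, c_t, o_t, spec, params)
    m <- st$m; w <- st$w; v <- st$v
  }
  new("BanditSession", choices = choicesv, outcomes = outc, trueProbs = probs,
      selectionTimes = selT, feedbackTimes = fbT)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one learner update step in R (reference path; the session-level forward
# pass uses the compiled implementation)
.updateState <- function(m, w, v, chosen, outcome, spec, params) {
  A <- length(m)
  other <- setdiff(seq_len(A), chosen)
  switch(spec@learner,
    RW1 = { m[chosen] <- rwUpdate(m[chosen], outcome, params$a) },
    RW2 = { m[chosen] <- rwUpdate(m[chosen], outcome, params$aPos, params$aNeg) },
    KF = {
      up <- kfUpdate(m[chosen], w[chosen], outcome, params$v, params$sigma2)
      m[chosen] <- up$m; w[chosen] <- up$w
      w[other] <- w[other] + params$v
    },
    VKF = {
      up <- vkfUpdate(m[chosen], w[chosen], v[chosen], outcome,
                      params$lambda, params$omega)
      m[chosen] <- up$m; w[chosen] <- up$w; v[chosen] <- up$v
      w[other] <- w[other] + v[other]
    })
  list(m = m, w = w, v = v)
}

#' Win-stay proportion
#'
#' Among trials whose previous trial was rewarded, the fraction on which the
#' previous choice was repeated.
#'
#' @param session a \linkS4class{BanditSession} with at least 2 trials
#' @return proportion in \code{[0, 1]}, or \code{NA} when no trial follows a
#'   reward
#' @export
winStay <- function(session) {
  n <- nTrials(session)
  if (n < 2L) stop("win-stay needs at least 2 trials")
  prevWin <- session@outcomes[-n] == 1L
  if (!any(prevWin)) return(NA_real_)
  stayed <- session@choices[-1L] == session@choices[-n]
  mean(stayed[prevWin])
}

#' Lose-shift proportion
#'
#' Among trials whose previous trial was unrewarded, the fraction on which
#' the choice changed.
#'
#' @inheritParams winStay
#' @return proportion in \code{[0, 1]}, or \code{NA} when no trial follows a
#'   non-reward
#' @export
loseShift <- function(session) {
  n <- nTrials(session)
  if (n < 2L) stop("lose-shift needs at least 2 trials")
  prevLoss <- session@outcomes[-n] == 0L
  if (!any(prevLoss)) return(NA_real_)
  shifted <- session@choices[-1L] != session@choices[-n]
  mean(shifted[prevLoss])
}

#' Build a session from explicit components
#'
#' Convenience constructor for tests and externally supplied behavior; event
#' times default to a regular 4-second trial grid.
#'
#' @param choices integer arm indices
#' @param outcomes binary rewards
#' @param trueProbs optional matrix of hidden probabilities
#' @param selectionTimes,feedbackTimes optional event times (s)
#' @param nArms arm count when \code{trueProbs} is missing
#' @return a \linkS4class{BanditSession}
#' @export
banditSession <- function(choices, outcomes, trueProbs = NULL,
                          selectionTimes = NULL, feedbackTimes = NULL,
                          nArms = max(choices)) {
  n <- length(choices)
  if (is.null(trueProbs)) trueProbs <- matrix(0.5, n, nArms)
  if (is.null(selectionTimes)) selectionTimes <- 2 + 4 * (seq_len(n) - 1)
  if (is.null(feedbackTimes)) feedbackTimes <- selectionTimes + 0.5
  new("BanditSession", choices = as.integer(choices),
      outcomes = as.integer(outcomes), trueProbs = trueProbs,
      selectionTimes = selectionTimes, feedbackTimes = feedbackTimes)
}

#' Write / read sessions as CSV
#'
#' One row per trial: trial, choice, outcome, per-arm hidden probabilities,
#' selection and feedback onsets.
#' @param session a \linkS4class{BanditSession}
#' @param path CSV file path
#' @return \code{readSessionCsv} returns a \linkS4class{BanditSession}
#' @export
writeSessionCsv <- function(session, path) {
  p <- session@trueProbs
  colnames(p) <- paste0("p_arm", seq_len(ncol(p)))
  df <- data.frame(trial = seq_len(nTrials(session)),
                   choice = session@choices, outcome = session@outcomes, p,
                   selection_time_s = session@selectionTimes,
                   feedback_time_s = session@feedbackTimes)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSessionCsv
#' @export
readSessionCsv <- function(path) {
  df <- read.csv(path)
  pcols <- grep("^p_arm", names(df))
  banditSession(df$choice, df$outcome,
                trueProbs = as.matrix(df[, pcols, drop = FALSE]),
                selectionTimes = df$selection_time_s,
                feedbackTimes = df$feedback_time_s)
}
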