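#' @import methods
#' @importFrom stats rnorm runif rbinom sd cor var optim qt pt quantile
#'   median rgamma setNames complete.cases p.adjust mad fft
#' @importFrom utils head tail write.csv read.csv
#' @useDynLib neurobandit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Configuration of the restless three-armed bandit environment
#'
#' Holds the parameters of the drifting reward-probability process: on each
#' trial every arm's hidden reward probability has probability \code{pChange}
#' of moving by \code{step} (direction uniform among in-bounds directions),
#' and stays within the closed interval \code{bounds}.
#'
#' @slot nArms number of arms (default 3).
#' @slot pChange per-trial, per-arm probability of a probability change.
#' @slot step magnitude of a probability change.
#' @slot bounds length-2 numeric, closed interval containing all reward
#'   probabilities.
#' @slot nTrials number of trials in a session.
#' @slot seed integer seed for the environment random walk.
#' @export
setClass("BanditConfig",
  representation(nArms = "integer", pChange = "numeric", step = "numeric",
                 bounds = "numeric", nTrials = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nArms < 2L) msg <- c(msg, "nArms must be >= 2")
    if (object@pChange < 0 || object@pChange > 1)
      msg <- c(msg, "pChange must be in [0, 1]")
    if (object@step <= 0) msg <- c(msg, "step must be > 0")
    if (length(object@bounds) != 2L || any(object@bounds < 0) ||
        any(object@bounds > 1) || diff(object@bounds) <= 0)
      msg <- c(msg, "bounds must be an increasing interval within [0, 1]")
    if (object@nTrials < 1L) msg <- c(msg, "nTrials must be >= 1")
    # the walk lives on the lattice bounds[1] + k*step; step must fit
    span <- diff(object@bounds)
    k <- span / object@step
    if (abs(k - round(k)) > 1e-8)
      msg <- c(msg, "step incompatible with bounds: (bounds[2]-bounds[1])/step must be integer")
    if (length(msg)) msg else TRUE
  })

#' One session of restless-bandit play
#'
#' Per-trial choices, binary outcomes, the hidden per-arm reward
#' probabilities, and event timestamps (selection onset and feedback onset,
#' seconds from recording start).
#'
#' @slot choices integer vector of chosen arm indices (1-based).
#' @slot outcomes integer vector of rewards in \{0, 1\}.
#' @slot trueProbs nTrials x nArms matrix of hidden reward probabilities.
#' @slot selectionTimes,feedbackTimes numeric vectors of event onsets (s).
#' @export
setClass("BanditSession",
  representation(choices = "integer", outcomes = "integer",
                 trueProbs = "matrix",
                 selectionTimes = "numeric", feedbackTimes = "numeric"),
  validity = function(object) {
    n <- length(object@choices)
    msg <- character()
    if (length(object@outcomes) != n || nrow(object@trueProbs) != n ||
        length(object@selectionTimes) != n || length(object@feedbackTimes) != n)
      msg <- c(msg, "all per-trial slots must have the same length")
    if (!all(object@outcomes %in% c(0L, 1L)))
      msg <- c(msg, "outcomes must be binary")
    if (any(object@choices < 1L) || any(object@choices > ncol(object@trueProbs)))
      msg <- c(msg, "choices out of arm range")
    ev <- as.vector(rbind(object@selectionTimes, object@feedbackTimes))
    if (n > 0 && any(diff(ev) <= 0))
      msg <- c(msg, "event times must be strictly increasing within the session")
    if (length(msg)) msg else TRUE
  })

#' Learner/choice-rule specification
#'
#' @slot learner one of \code{"RW1"}, \code{"RW2"}, \code{"KF"}, \code{"VKF"}.
#' @slot choiceRule one of \code{"value_only"}, \code{"uncertainty_only"},
#'   \code{"value_and_uncertainty"}.
#' @slot useRelative logical; if \code{TRUE} the softmax operates on the
#'   relative value/uncertainty vectors (each arm's quantity divided by the
#'   sum over arms).
#' @export
setClass("ModelSpec",
  representation(learner = "character", choiceRule = "character",
                 useRelative = "logical"),
  validity = function(object) {
    msg <- character()
    if (!object@learner %in% c("RW1", "RW2", "KF", "VKF"))
      msg <- c(msg, "unknown learner")
    if (!object@choiceRule %in%
        c("value_only", "uncertainty_only", "value_and_uncertainty"))
      msg <- c(msg, "unknown choice rule")
    if (object@learner %in% c("RW1", "RW2") &&
        object@choiceRule != "value_only")
      msg <- c(msg, "uncertainty-based choice rules require a learner that tracks uncertainty (KF or VKF)")
    if (length(msg)) msg else TRUE
  })

#' Per-trial latent trajectory of a learner run over a session
#'
#' Rows index trials. \code{m}, \code{w}, \code{v} hold the post-update
#' per-arm value means, posterior variances and (VKF) volatilities;
#' \code{choiceProbs} holds the pre-outcome softmax probabilities used for
#' the likelihood. \code{pe}, \code{rv}, \code{ru} are the chosen-arm
#' prediction error and post-update relative value/uncertainty, which stay
#' constant until the next selection.
#'
#' @slot m,w,v nTrials x nArms numeric matrices (v has zero columns for
#'   learners that do not track volatility).
#' @slot k Kalman gain (or learning rate actually applied) per trial.
#' @slot pe,rv,ru per-trial chosen-arm scalars.
#' @slot choiceProbs nTrials x nArms matrix, rows sum to 1.
#' @slot nll negative log-likelihood of the observed choices.
#' @slot spec the generating \linkS4class{ModelSpec}.
#' @export
setClass("LearnerTrajectory",
  representation(m = "matrix", w = "matrix", v = "matrix", k = "numeric",
                 pe = "numeric", rv = "numeric", ru = "numeric",
                 choiceProbs = "matrix", nll = "numeric", spec = "ModelSpec"),
  validity = function(object) {
    msg <- character()
    n <- nrow(object@m)
    if (nrow(object@choiceProbs) != n) msg <- c(msg, "shape mismatch")
    if (n > 0) {
      s <- rowSums(object@choiceProbs)
      if (max(abs(s - 1)) > 1e-8) msg <- c(msg, "choiceProbs rows must sum to 1")
      if (any(object@k < -1e-12 | object@k > 1 + 1e-12))
        msg <- c(msg, "Kalman gain outside [0, 1]")
      if (any(object@w < -1e-12)) msg <- c(msg, "negative posterior variance")
    }
    if (length(msg)) msg else TRUE
  })

#' Synthetic two-region multichannel recording
#'
#' @slot signals named list, region -> channels x samples numeric matrix.
#' @slot fs sampling rate (Hz).
#' @slot events per-trial data.frame (selection/feedback times, reward,
#'   decision, regressors, patient/session labels).
#' @slot truth list echoing the generating ground-truth parameters.
#' @export
setClass("SyntheticRecording",
  representation(signals = "list", fs = "numeric", events = "data.frame",
                 truth = "list"),
  validity = function(object) {
    msg <- character()
    if (object@fs <= 0) msg <- c(msg, "fs must be positive")
    dur <- vapply(object@signals, function(s) ncol(s) / object@fs, 0)
    tmax <- suppressWarnings(max(object@events$feedback_time,
                                 object@events$selection_time, -Inf))
    if (length(dur) && is.finite(tmax) && tmax > min(dur))
      msg <- c(msg, "event times exceed signal duration")
    if (length(msg)) msg else TRUE
  })

#' Epoched time-frequency power (and optionally phase)
#'
#' @slot power time x frequency x trial array, non-negative.
#' @slot phase same shape as power, or a zero-length array when phase was
#'   not retained.
#' @slot times time axis in seconds relative to the locking event.
#' @slot freqs frequency axis in Hz.
#' @slot events per-trial metadata (one row per slice of the 3rd dimension).
#' @export
setClass("TFMap",
  representation(power = "array", phase = "array", times = "numeric",
                 freqs = "numeric", events = "data.frame"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@power)
    if (length(d) != 3L) msg <- c(msg, "power must be a 3D array")
    else {
      if (d[1] != length(object@times)) msg <- c(msg, "time axis mismatch")
      if (d[2] != length(object@freqs)) msg <- c(msg, "frequency axis mismatch")
      if (nrow(object@events) && d[3] != nrow(object@events))
        msg <- c(msg, "events rows must match trial dimension")
      if (any(object@power < 0)) msg <- c(msg, "power must be non-negative")
    }
    if (length(msg)) msg else TRUE
  })

#' Epoched band-limited analytic amplitude
#'
#' @slot amplitude time x trial matrix of non-negative analytic amplitudes.
#' @slot times time axis in seconds relative to the locking event.
#' @slot band length-2 numeric band edges in Hz.
#' @slot events per-trial metadata.
#' @export
setClass("BandEnvelope",
  representation(amplitude = "matrix", times = "numeric", band = "numeric",
                 events = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@amplitude) != length(object@times))
      msg <- c(msg, "time axis mismatch")
    if (nrow(object@events) && ncol(object@amplitude) != nrow(object@events))
      msg <- c(msg, "events rows must match trial dimension")
    if (any(object@amplitude < 0)) msg <- c(msg, "amplitude must be non-negative")
    if (length(object@band) != 2L || diff(object@band) <= 0)
      msg <- c(msg, "band must be an increasing interval")
    if (length(msg)) msg else TRUE
  })
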