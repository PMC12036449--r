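#' Number of trials
#' @param x a session, trajectory or epoched object
#' @return integer trial count
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' Per-trial stay flags
#'
#' \code{stayFlags(x)[t]} is 1 when the choice on trial \code{t} repeats the
#' choice on trial \code{t-1} (stay), 0 when it changes (switch), and
#' \code{NA} for the first trial.
#' @param x a \linkS4class{BanditSession}
#' @return integer vector with \code{NA} in position 1
#' @export
setGeneric("stayFlags", function(x) standardGeneric("stayFlags"))

#' Event metadata table
#' @param x an object carrying per-trial events
#' @return data.frame
#' @export
setGeneric("trialEvents", function(x) standardGeneric("trialEvents"))

#' @rdname nTrials
#' @export
setMethod("nTrials", "BanditSession", function(x) length(x@choices))
#' @rdname nTrials
#' @export
setMethod("nTrials", "LearnerTrajectory", function(x) nrow(x@m))
#' @rdname nTrials
#' @export
setMethod("nTrials", "TFMap", function(x) dim(x@power)[3])
#' @rdname nTrials
#' @export
setMethod("nTrials", "BandEnvelope", function(x) ncol(x@amplitude))

#' @rdname stayFlags
#' @export
setMethod("stayFlags", "BanditSession", function(x) {
  n <- length(x@choices)
  if (n < 2L) return(rep(NA_integer_, n))
  c(NA_integer_, as.integer(x@choices[-1L] == x@choices[-n]))
})

#' @rdname trialEvents
#' @export
setMethod("trialEvents", "TFMap", function(x) x@events)
#' @rdname trialEvents
#' @export
setMethod("trialEvents", "BandEnvelope", function(x) x@events)
#' @rdname trialEvents
#' @export
setMethod("trialEvents", "SyntheticRecording", function(x) x@events)

#' Choices, outcomes and hidden probabilities of a session
#' @param x a \linkS4class{BanditSession}
#' @return integer vector / matrix
#' @export
choices <- function(x) x@choices
#' @rdname choices
#' @export
outcomes <- function(x) x@outcomes
#' @rdname choices
#' @export
trueProbs <- function(x) x@trueProbs

#' Latent-state accessors for learner trajectories
#' @param x a \linkS4class{LearnerTrajectory}
#' @return matrix or numeric vector of per-trial quantities
#' @export
valueMeans <- function(x) x@m
#' @rdname valueMeans
#' @export
posteriorVars <- function(x) x@w
#' @rdname valueMeans
#' @export
volatilities <- function(x) x@v
#' @rdname valueMeans
#' @export
kalmanGains <- function(x) x@k
#' @rdname valueMeans
#' @export
predictionErrors <- function(x) x@pe
#' @rdname valueMeans
#' @export
relativeValues <- function(x) x@rv
#' @rdname valueMeans
#' @export
relativeUncertainties <- function(x) x@ru
#' @rdname valueMeans
#' @export
choiceProbs <- function(x) x@choiceProbs

setMethod("show", "BanditConfig", function(object) {
  cat("BanditConfig:", object@nArms, "arms,", object@nTrials, "trials; ",
      "P(change)=", object@pChange, ", step=", object@step,
      ", bounds=[", object@bounds[1], ",", object@bounds[2], "]\n", sep = " ")
})

setMethod("show", "BanditSession", function(object) {
  n <- nTrials(object)
  cat("BanditSession:", n, "trials,", ncol(object@trueProbs), "arms\n")
  if (n) cat("  reward rate:", round(mean(object@outcomes), 3),
             " stay rate:", round(mean(stayFlags(object), na.rm = TRUE), 3), "\n")
})

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec:", object@learner, "+", object@choiceRule,
      if (object@useRelative) "(relative inputs)" else "(raw inputs)", "\n")
})

setMethod("show", "LearnerTrajectory", function(object) {
  cat("LearnerTrajectory (", object@spec@learner, "): ", nrow(object@m),
      " trials x ", ncol(object@m), " arms; NLL = ",
      round(object@nll, 2), "\n", sep = "")
})

setMethod("show", "SyntheticRecording", function(object) {
  cat("SyntheticRecording @", object@fs, "Hz\n")
  for (r in names(object@signals))
    cat("  ", r, ": ", nrow(object@signals[[r]]), " channels x ",
        ncol(object@signals[[r]]), " samples\n", sep = "")
  cat("  ", nrow(object@events), " trial events\n", sep = "")
})

setMethod("show", "TFMap", function(object) {
  d <- dim(object@power)
  cat("TFMap:", d[1], "time points x", d[2], "frequency bins x",
      d[3], "trials\n")
  cat("  time:", round(min(object@times), 3), "..", round(max(object@times), 3),
      "s; freq:", round(min(object@freqs), 2), "..",
      round(max(object@freqs), 2), "Hz\n")
})

setMethod("show", "BandEnvelope", function(object) {
  cat("BandEnvelope [", object@band[1], "-", object@band[2], " Hz]: ",
      nrow(object@amplitude), " time points x ", ncol(object@amplitude),
      " trials\n", sep = "")
})
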