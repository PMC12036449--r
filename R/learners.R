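#' Construct a learner/choice-rule specification
#'
#' @param learner \code{"RW1"}, \code{"RW2"}, \code{"KF"} or \code{"VKF"}.
#' @param choiceRule \code{"value_only"}, \code{"uncertainty_only"} or
#'   \code{"value_and_uncertainty"}.
#' @param useRelative feed the softmax the relative (sum-normalized) value
#'   and uncertainty vectors rather than the raw ones.
#' @return a \linkS4class{ModelSpec}
#' @export
modelSpec <- function(learner = "VKF", choiceRule = "value_and_uncertainty",
                      useRelative = TRUE) {
  new("ModelSpec", learner = learner, choiceRule = choiceRule,
      useRelative = useRelative)
}

#' Free parameters of a model specification
#'
#' @param spec a \linkS4class{ModelSpec}
#' @return character vector of free parameter names in canonical order
#' @export
freeParamNames <- function(spec) {
  lp <- switch(spec@learner,
               RW1 = "a", RW2 = c("aPos", "aNeg"),
               KF = c("v", "sigma2"), VKF = c("lambda", "v0", "omega"))
  bp <- switch(spec@choiceRule,
               value_only = "betaV", uncertainty_only = "betaU",
               value_and_uncertainty = c("betaV", "betaU"))
  c(lp, bp)
}

#' Validate and complete a parameter list
#'
#' Checks bounds (learning rates in \code{[0, 1]}, variances and inverse
#' temperatures positive), fills the fixed initial conditions
#' (\code{m0 = 0.5}, \code{w0 = 1}) and, for unspecified inverse
#' temperatures, zero.
#'
#' @param spec a \linkS4class{ModelSpec}
#' @param params named list of parameter values
#' @return completed named list
#' @export
modelParams <- function(spec, params) {
  need <- freeParamNames(spec)
  miss <- setdiff(need, names(params))
  if (length(miss))
    stop("missing parameters for ", spec@learner, "/", spec@choiceRule, ": ",
         paste(miss, collapse = ", "))
  unit <- intersect(c("a", "aPos", "aNeg", "lambda"), need)
  for (p in unit)
    if (params[[p]] < 0 || params[[p]] > 1)
      stop(p, " must be in [0, 1]")
  pos <- intersect(c("sigma2", "omega", "v0"), need)
  for (p in pos)
    if (params[[p]] <= 0) stop(p, " must be > 0")
  if ("v" %in% need && params$v < 0) stop("v must be >= 0")
  for (p in intersect(c("betaV", "betaU"), names(params)))
    if (params[[p]] < 0) stop(p, " must be >= 0")
  params$m0 <- params$m0 %||% 0.5
  params$w0 <- params$w0 %||% 1
  params$betaV <- params$betaV %||% 0
  params$betaU <- params$betaU %||% 0
  params
}

#' Rescorla-Wagner value update
#'
#' \code{m' = m + a (O - m)}; with separate learning rates, \code{aPos} is
#' applied after reward and \code{aNeg} after non-reward.
#'
#' @param m current value of the chosen arm
#' @param outcome binary reward
#' @param a learning rate (positive-feedback rate when \code{aNeg} differs)
#' @param aNeg negative-feedback learning rate (defaults to \code{a})
#' @return updated value
#' @export
rwUpdate <- function(m, outcome, a, aNeg = a) {
  if (a < 0 || a > 1 || aNeg < 0 || aNeg > 1)
    stop("learning rates must be in [0, 1]")
  rate <- if (outcome == 1) a else aNeg
  m + rate * (outcome - m)
}

#' Kalman-filter update for the chosen arm
#'
#' Gain \code{k = (w + v) / (w + v + sigma2)}, mean
#' \code{m' = m + k (O - m)}, posterior variance
#' \code{w' = (1 - k)(w + v)}; the prediction error is \code{O - m}.
#'
#' @param m,w prior mean and posterior variance of the chosen arm
#' @param outcome binary reward
#' @param v process-noise variance (volatility)
#' @param sigma2 observation-noise variance (stochasticity), > 0
#' @return list with elements \code{m}, \code{w}, \code{k}, \code{pe}
#' @export
kfUpdate <- function(m, w, outcome, v, sigma2) {
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  if (w < 0 || v < 0) stop("variances must be non-negative")
  k <- (w + v) / (w + v + sigma2)
  pe <- outcome - m
  list(m = m + k * pe, w = (1 - k) * (w + v), k = k, pe = pe)
}

#' Volatile-Kalman-filter update for the chosen arm
#'
#' As \code{\link{kfUpdate}} with the binary-observation noise \code{omega}
#' in place of \code{sigma2}, plus the volatility recursion
#' \code{v' = v + lambda ((m' - m)^2 + w + w' - 2 wCov - v)} with the
#' lag-one posterior covariance \code{wCov = (1 - k) w}. The volatility is
#' floored at a small positive epsilon.
#'
#' @param m,w,v prior mean, posterior variance and volatility of the chosen
#'   arm
#' @param outcome binary reward
#' @param lambda volatility learning rate in \code{[0, 1]}
#' @param omega observation-noise parameter for binary outcomes, > 0
#' @param vFloor lower bound kept on the volatility
#' @return list with \code{m}, \code{w}, \code{v}, \code{k}, \code{wCov},
#'   \code{pe}
#' @export
vkfUpdate <- function(m, w, v, outcome, lambda, omega, vFloor = 1e-8) {
  if (!all(is.finite(c(m, w, v, outcome, lambda, omega))))
    stop("non-finite input to vkfUpdate")
  if (omega <= 0) stop("omega must be > 0")
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  k <- (w + v) / (w + v + omega)
  pe <- outcome - m
  mNew <- m + k * pe
  wNew <- (1 - k) * (w + v)
  wCov <- (1 - k) * w
  vNew <- v + lambda * ((mNew - m)^2 + w + wNew - 2 * wCov - v)
  list(m = mNew, w = wNew, v = max(vNew, vFloor), k = k, wCov = wCov, pe = pe)
}

#' Relative value and relative uncertainty
#'
#' \code{RV_i = m_i / sum(m)} and \code{RU_i = w_i / sum(w)}; returns the
#' chosen arm's values together with the full vectors.
#'
#' @param m per-arm value means
#' @param w per-arm posterior variances
#' @param chosen chosen arm index
#' @return list with \code{rv}, \code{ru}, \code{rvVec}, \code{ruVec}
#' @export
relativeQuantities <- function(m, w, chosen) {
  if (sum(m) <= 0 || sum(w) <= 0)
    stop("degenerate state: per-arm sums must be positive")
  rvVec <- m / sum(m); ruVec <- w / sum(w)
  list(rv = rvVec[chosen], ru = ruVec[chosen], rvVec = rvVec, ruVec = ruVec)
}

#' Softmax choice probabilities
#'
#' \code{P_i} is proportional to \code{exp(betaV V_i + betaU U_i)} with the
#' inputs determined by the choice rule; with relative inputs, \code{V} and
#' \code{U} are the sum-normalized vectors. Computed with max-subtraction
#' for overflow safety.
#'
#' @param values per-arm value means
#' @param uncertainties per-arm posterior variances (ignored under
#'   \code{value_only})
#' @param spec a \linkS4class{ModelSpec}
#' @param params parameter list carrying \code{betaV} / \code{betaU}
#' @return per-arm probability vector summing to 1
#' @export
choiceProbabilities <- function(values, uncertainties = NULL, spec, params) {
  stopifnot(all(is.finite(values)))
  V <- values
  U <- uncertainties
  if (spec@useRelative) {
    if (sum(V) <= 0) stop("degenerate state: value sum must be positive")
    V <- V / sum(V)
    if (!is.null(U)) {
      if (sum(U) <= 0) stop("degenerate state: uncertainty sum must be positive")
      U <- U / sum(U)
    }
  }
  eta <- switch(spec@choiceRule,
                value_only = params$betaV * V,
                uncertainty_only = params$betaU * U,
                value_and_uncertainty = params$betaV * V + params$betaU * U)
  e <- exp(eta - max(eta))
  e / sum(e)
}

.learnerCode <- c(RW1 = 0L, RW2 = 1L, KF = 2L, VKF = 3L)
.ruleCode <- c(value_only = 0L, uncertainty_only = 1L,
               value_and_uncertainty = 2L)

.runForward <- function(session, spec, params) {
  params <- modelParams(spec, params)
  cpp_trajectory(session@choices - 1L, session@outcomes,
                 .learnerCode[[spec@learner]], .ruleCode[[spec@choiceRule]],
                 spec@useRelative, ncol(session@trueProbs),
                 params$m0, params$w0,
                 params$a %||% 0, params$aPos %||% 0, params$aNeg %||% 0,
                 params$v %||% 0, params$sigma2 %||% 1,
                 params$lambda %||% 0, params$v0 %||% 0,
                 params$omega %||% 1, params$betaV, params$betaU)
}

#' Run a learner over a session
#'
#' Forward pass applying the update equations trial by trial. The choice
#' probabilities recorded for trial \code{t} use the state before trial
#' \code{t}'s outcome (they define the likelihood); the prediction error and
#' relative value/uncertainty recorded for trial \code{t} are those holding
#' after the outcome update, which remain constant until the next selection.
#'
#' @param session a \linkS4class{BanditSession}
#' @param spec a \linkS4class{ModelSpec}
#' @param params named parameter list
#' @return a \linkS4class{LearnerTrajectory}
#' @export
sessionTrajectory <- function(session, spec, params) {
  out <- .runForward(session, spec, params)
  if (any(!is.finite(out$m)))
    stop("non-finite learner state at trial ",
         which(!is.finite(rowSums(out$m)))[1])
  new("LearnerTrajectory", m = out$m, w = out$w, v = out$v, k = out$k,
      pe = out$pe, rv = out$rv, ru = out$ru, choiceProbs = out$probs,
      nll = out$nll, spec = spec)
}

#' Session negative log-likelihood
#'
#' \code{-sum(log P(choice_t))} with probabilities taken before each trial's
#' outcome update; probabilities are floored at a machine-safe epsilon.
#'
#' @inheritParams sessionTrajectory
#' @return non-negative scalar
#' @export
sessionNLL <- function(session, spec, params) {
  .runForward(session, spec, params)$nll
}

#' Export a learner trajectory as a per-trial data.frame
#'
#' @param trajectory a \linkS4class{LearnerTrajectory}
#' @param session optional \linkS4class{BanditSession} to attach choices and
#'   outcomes
#' @return data.frame, one row per trial
#' @export
trajectoryTable <- function(trajectory, session = NULL) {
  A <- ncol(trajectory@m)
  df <- data.frame(trial = seq_len(nrow(trajectory@m)))
  for (j in seq_len(A)) df[[paste0("m", j)]] <- trajectory@m[, j]
  for (j in seq_len(A)) df[[paste0("w", j)]] <- trajectory@w[, j]
  if (ncol(trajectory@v))
    for (j in seq_len(A)) df[[paste0("v", j)]] <- trajectory@v[, j]
  df$k <- trajectory@k; df$pe <- trajectory@pe
  df$rv <- trajectory@rv; df$ru <- trajectory@ru
  for (j in seq_len(A)) df[[paste0("p", j)]] <- trajectory@choiceProbs[, j]
  if (!is.null(session)) {
    df$choice <- session@choices; df$outcome <- session@outcomes
  }
  df
}
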