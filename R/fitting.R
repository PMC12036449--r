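#' Parameter transforms for unconstrained optimization
#'
#' Unit-range parameters (learning rates, the volatility learning rate) use
#' a sigmoid link; positive parameters (variances, volatilities, inverse
#' temperatures) use an exponential link. The Gaussian prior (mean 0,
#' variance 6.25 by default) applies in the transformed space.
#'
#' @param spec a \linkS4class{ModelSpec}
#' @return named character vector, \code{"sigmoid"} or \code{"exp"} per free
#'   parameter
#' @export
paramLinks <- function(spec) {
  nm <- freeParamNames(spec)
  l <- ifelse(nm %in% c("a", "aPos", "aNeg", "lambda"), "sigmoid", "exp")
  names(l) <- nm
  l
}

#' @rdname paramLinks
#' @param theta unconstrained parameter vector (transformed space)
#' @export
toNative <- function(theta, spec) {
  links <- paramLinks(spec)
  out <- ifelse(links == "sigmoid", 1 / (1 + exp(-theta)), exp(theta))
  # numerical guards at the link boundaries
  out <- ifelse(links == "sigmoid", pmin(pmax(out, 1e-8), 1 - 1e-8),
                pmax(out, 1e-12))
  as.list(setNames(out, names(links)))
}

#' @rdname paramLinks
#' @param params native-space named list
#' @export
toTransformed <- function(params, spec) {
  links <- paramLinks(spec)
  x <- unlist(params[names(links)])
  out <- numeric(length(x))
  sg <- links == "sigmoid"
  out[sg] <- log(x[sg] / (1 - x[sg]))
  out[!sg] <- log(x[!sg])
  setNames(out, names(links))
}

.penalizedObjective <- function(session, spec, priorMean, priorVar) {
  force(session); force(spec)
  function(theta) {
    nll <- tryCatch(sessionNLL(session, spec, toNative(theta, spec)),
                    error = function(e) 1e10)
    if (!is.finite(nll)) nll <- 1e10
    nll + sum((theta - priorMean)^2 / (2 * priorVar))
  }
}

.hessDiag <- function(f, theta, h = 1e-3) {
  d <- length(theta)
  f0 <- f(theta)
  vapply(seq_len(d), function(j) {
    e <- rep(0, d); e[j] <- h
    (f(theta + e) - 2 * f0 + f(theta - e)) / h^2
  }, 0)
}

#' MAP fit of one model to one session
#'
#' Minimizes the penalized negative log-likelihood (Gaussian prior in
#' transformed space, default mean 0 and variance 6.25) from multiple seeded
#' restarts, and returns the best optimum together with a Laplace
#' approximation of the log model evidence (diagonal Hessian by finite
#' differences) and the BIC.
#'
#' @param session a \linkS4class{BanditSession}
#' @param spec a \linkS4class{ModelSpec}
#' @param priorMean,priorVar prior moments in transformed space (scalars or
#'   per-parameter vectors)
#' @param nStarts number of optimizer restarts
#' @param seed seed for restart locations
#' @param maxit per-restart optimizer budget
#' @return object of class \code{"subjectFit"}: native and transformed
#'   parameters, \code{nll}, \code{logEvidence}, \code{hessianDiag},
#'   posterior variances, \code{bic}
#' @export
mapFit <- function(session, spec, priorMean = 0, priorVar = 6.25,
                   nStarts = 8, seed = 1, maxit = 500) {
  d <- length(freeParamNames(spec))
  priorMean <- rep_len(priorMean, d)
  priorVar <- rep_len(priorVar, d)
  obj <- .penalizedObjective(session, spec, priorMean, priorVar)
  set.seed(seed)
  starts <- lapply(seq_len(nStarts), function(i) {
    if (i == 1) priorMean else priorMean + rnorm(d, 0, sqrt(priorVar) / 2)
  })
  best <- NULL
  ok <- FALSE
  for (s in starts) {
    res <- tryCatch(optim(s, obj, method = "Nelder-Mead",
                          control = list(maxit = maxit)),
                    error = function(e) NULL)
    if (is.null(res)) next
    ok <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (!ok) {
    return(structure(list(spec = spec, failed = TRUE), class = "subjectFit"))
  }
  theta <- best$par
  params <- toNative(theta, spec)
  nll <- sessionNLL(session, spec, params)
  h <- pmax(.hessDiag(obj, theta), 1e-6)
  logEv <- -best$value + 0.5 * d * log(2 * pi) - 0.5 * sum(log(h))
  structure(list(
    spec = spec, failed = FALSE,
    paramsNative = params, paramsTransformed = theta,
    nll = nll, penalized = best$value,
    hessianDiag = h, posteriorVar = 1 / h,
    logEvidence = logEv,
    bic = 2 * nll + d * log(nTrials(session)),
    nFree = d, nTrials = nTrials(session)
  ), class = "subjectFit")
}

#' @export
print.subjectFit <- function(x, ...) {
  if (isTRUE(x$failed)) { cat("subjectFit: FAILED\n"); return(invisible(x)) }
  cat("subjectFit:", x$spec@learner, "/", x$spec@choiceRule, "\n")
  cat("  params:", paste(names(x$paramsNative[seq_len(x$nFree)]),
                         signif(unlist(x$paramsNative[seq_len(x$nFree)]), 3),
                         sep = "=", collapse = ", "), "\n")
  cat("  NLL =", round(x$nll, 2), " BIC =", round(x$bic, 2),
      " logEv =", round(x$logEvidence, 2), "\n")
  invisible(x)
}

.dirichletWeights <- function(logEv, alpha0 = 1, maxIter = 200, tol = 1e-6) {
  K <- ncol(logEv)
  L <- logEv - apply(logEv, 1, max)
  alpha <- rep(alpha0, K)
  for (it in seq_len(maxIter)) {
    lw <- sweep(L, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    u <- exp(lw - apply(lw, 1, max))
    u <- u / rowSums(u)
    alphaNew <- alpha0 + colSums(u)
    if (max(abs(alphaNew - alpha)) < tol) { alpha <- alphaNew; break }
    alpha <- alphaNew
  }
  list(alpha = alpha, u = u)
}

#' Exceedance probability from per-subject model evidences
#'
#' Random-effects Bayesian model selection: per-subject model
#' responsibilities and Dirichlet parameters over model frequencies are
#' estimated by the standard variational scheme, then the exceedance
#' probability of each model (the posterior probability that its frequency
#' exceeds all others) is estimated from Monte-Carlo Dirichlet draws.
#'
#' @param logEv subjects x models matrix of log model evidences
#' @param nSamples number of Dirichlet draws
#' @param seed Monte-Carlo seed
#' @param alpha0 symmetric Dirichlet prior count
#' @return list with \code{xp}, Dirichlet \code{alpha}, and per-subject
#'   responsibilities \code{u}
#' @export
exceedanceProbability <- function(logEv, nSamples = 1e5, seed = 1,
                                  alpha0 = 1) {
  logEv <- as.matrix(logEv)
  stopifnot(all(is.finite(logEv)))
  K <- ncol(logEv)
  if (K == 1L)
    return(list(xp = 1, alpha = alpha0 + nrow(logEv),
                u = matrix(1, nrow(logEv), 1)))
  fit <- .dirichletWeights(logEv, alpha0)
  set.seed(seed)
  g <- matrix(rgamma(nSamples * K, shape = rep(fit$alpha, each = nSamples)),
              nSamples, K)
  win <- max.col(g, ties.method = "random")
  xp <- tabulate(win, K) / nSamples
  names(xp) <- colnames(logEv)
  list(xp = xp, alpha = fit$alpha, u = fit$u)
}

#' Empirical-Bayes hierarchical fit across subjects
#'
#' Iterates (1) per-subject, per-model MAP fits under the current group
#' priors, (2) responsibility updates from the per-model evidences, and
#' (3) re-estimation of group prior means/variances from
#' responsibility-weighted Laplace posteriors. Starts from the prior
#' (0, 6.25) in transformed space and stops when the prior means move less
#' than \code{tol} or after \code{maxIter} sweeps.
#'
#' @param sessions list of \linkS4class{BanditSession}, one per subject
#' @param specs list of \linkS4class{ModelSpec} to compare
#' @param maxIter,tol outer-loop controls
#' @param nStarts,seed forwarded to \code{\link{mapFit}}
#' @param updatePriors set \code{FALSE} to keep the initial priors fixed
#'   (one sweep of independent MAP fits)
#' @param minVar floor on group prior variances
#' @return object of class \code{"groupFit"}: per-model priors, per-subject
#'   fits, evidence matrix, responsibilities, Dirichlet \code{alpha} and
#'   exceedance probabilities \code{xp}
#' @export
hierarchicalFit <- function(sessions, specs, maxIter = 10, tol = 1e-2,
                            nStarts = 4, seed = 1, updatePriors = TRUE,
                            minVar = 0.01) {
  stopifnot(length(sessions) >= 2)
  if (is(specs, "ModelSpec")) specs <- list(specs)
  nS <- length(sessions); K <- length(specs)
  priors <- lapply(specs, function(sp) {
    d <- length(freeParamNames(sp))
    list(mean = rep(0, d), var = rep(6.25, d))
  })
  fits <- NULL; L <- NULL
  converged <- FALSE
  nIter <- if (updatePriors) maxIter else 1L
  for (it in seq_len(nIter)) {
    fits <- lapply(seq_len(nS), function(i)
      lapply(seq_len(K), function(k)
        mapFit(sessions[[i]], specs[[k]],
               priorMean = priors[[k]]$mean, priorVar = priors[[k]]$var,
               nStarts = nStarts, seed = seed + 1000L * i + k)))
    L <- matrix(vapply(seq_len(nS), function(i) vapply(seq_len(K), function(k) {
      f <- fits[[i]][[k]]
      if (isTRUE(f$failed)) -1e10 else f$logEvidence
    }, 0), numeric(K)), nS, K, byrow = TRUE)
    bw <- .dirichletWeights(L)
    r <- bw$u
    if (!updatePriors) break
    maxShift <- 0
    for (k in seq_len(K)) {
      th <- t(vapply(seq_len(nS), function(i)
        fits[[i]][[k]]$paramsTransformed, priors[[k]]$mean))
      pv <- t(vapply(seq_len(nS), function(i)
        fits[[i]][[k]]$posteriorVar, priors[[k]]$mean))
      wts <- r[, k] / max(sum(r[, k]), 1e-12)
      muNew <- colSums(th * wts)
      varNew <- pmax(colSums(((th - rep(muNew, each = nS))^2 + pv) * wts),
                     minVar)
      maxShift <- max(maxShift, max(abs(muNew - priors[[k]]$mean)))
      priors[[k]] <- list(mean = muNew, var = varNew)
    }
    if (maxShift < tol) { converged <- TRUE; break }
  }
  bms <- exceedanceProbability(L, seed = seed)
  structure(list(specs = specs, priors = priors, fits = fits,
                 logEvidence = L, responsibilities = bms$u,
                 alpha = bms$alpha, xp = bms$xp,
                 converged = converged || !updatePriors),
            class = "groupFit")
}

#' @export
print.groupFit <- function(x, ...) {
  K <- length(x$specs)
  cat("groupFit:", nrow(x$logEvidence), "subjects x", K, "models",
      if (!x$converged) "(not converged)" else "", "\n")
  lab <- vapply(x$specs, function(s)
    paste0(s@learner, "/", s@choiceRule,
           if (s@useRelative) "/rel" else ""), "")
  for (k in seq_len(K))
    cat(sprintf("  %-32s xp = %.3f  sum logEv = %.1f\n", lab[k], x$xp[k],
                sum(x$logEvidence[, k])))
  invisible(x)
}

#' Default model-comparison grid
#'
#' RW1 and RW2 with the value-only rule, and KF and VKF crossed with the
#' three choice rules using relative inputs: eight models.
#' @return list of \linkS4class{ModelSpec}
#' @export
defaultModelGrid <- function() {
  c(list(modelSpec("RW1", "value_only", FALSE),
         modelSpec("RW2", "value_only", FALSE)),
    unlist(lapply(c("KF", "VKF"), function(l)
      lapply(c("value_only", "uncertainty_only", "value_and_uncertainty"),
             function(r) modelSpec(l, r, TRUE))), recursive = FALSE))
}

#' Simulate-and-refit parameter recovery
#'
#' For each row of \code{trueGrid}, simulates an agent with those parameters
#' on a fresh environment, refits it by MAP, and tabulates true versus
#' recovered values with per-parameter Pearson correlations.
#'
#' @param spec a \linkS4class{ModelSpec}
#' @param trueGrid data.frame, one row per simulated subject, columns the
#'   free parameters
#' @param nTrials session length (> 0)
#' @param seed base seed
#' @param nStarts optimizer restarts per fit
#' @return object of class \code{"recoveryReport"}: long table of true and
#'   recovered values and named correlation vector \code{r}
#' @export
parameterRecovery <- function(spec, trueGrid, nTrials = 300, seed = 1,
                              nStarts = 4) {
  if (nTrials < 1) stop("insufficient data: nTrials must be >= 1")
  need <- freeParamNames(spec)
  if (!all(need %in% names(trueGrid)))
    stop("trueGrid must contain columns: ", paste(need, collapse = ", "))
  nSub <- nrow(trueGrid)
  rec <- matrix(NA_real_, nSub, length(need), dimnames = list(NULL, need))
  for (i in seq_len(nSub)) {
    cfg <- banditConfig(nTrials = nTrials, seed = seed + 7919L * i)
    sess <- simulateAgent(cfg, spec, as.list(trueGrid[i, , drop = FALSE]),
                          seed = seed + i)
    fit <- mapFit(sess, spec, nStarts = nStarts, seed = seed + i)
    if (!isTRUE(fit$failed))
      rec[i, ] <- unlist(fit$paramsNative[need])
  }
  r <- vapply(need, function(p) {
    tv <- trueGrid[[p]]
    if (sd(tv) == 0 || all(is.na(rec[, p]))) return(NA_real_)
    cor(tv, rec[, p], use = "complete.obs")
  }, 0)
  tab <- do.call(rbind, lapply(need, function(p)
    data.frame(subject = seq_len(nSub), param = p,
               true = trueGrid[[p]], recovered = rec[, p])))
  structure(list(table = tab, r = r, spec = spec, nTrials = nTrials),
            class = "recoveryReport")
}

#' @export
print.recoveryReport <- function(x, ...) {
  cat("parameter recovery (", x$spec@learner, ", ",
      length(unique(x$table$subject)), " subjects x ", x$nTrials,
      " trials)\n", sep = "")
  for (p in names(x$r))
    cat(sprintf("  %-8s r = %.3f\n", p, x$r[p]))
  invisible(x)
}
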