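#' Mixed-effects fit with the study's random-effect structure
#'
#' Fits \code{response ~ fixed terms + (1 | patient)} plus, when
#' \code{channelNested} and a \code{channel} column is present,
#' \code{(1 | patient:channel)}. Binary codings are used as supplied
#' (decision stay = 1 / switch = 0, feedback reward = 1 / non-reward = 0,
#' stage pre-selection = 1 / post-feedback = 0). A singular nested fit is
#' downgraded to the patient-only random intercept (flagged via the
#' \code{"downgraded"} attribute); a single-patient table falls back to
#' ordinary least squares.
#'
#' @param data data.frame containing the response, the fixed terms and
#'   \code{patient} (and optionally \code{channel})
#' @param response response column name
#' @param fixed character vector of fixed-effect column names
#' @param channelNested include the channel-in-patient random intercept
#' @return data.frame with one row per fixed term: \code{term},
#'   \code{beta}, \code{se}, \code{df}, \code{t}, \code{p}
#' @export
fitLME <- function(data, response, fixed, channelNested = TRUE) {
  keep <- complete.cases(data[, c(response, fixed, "patient"), drop = FALSE])
  data <- data[keep, , drop = FALSE]
  if (length(unique(data$patient)) < 2) {
    f <- stats::as.formula(paste(response, "~", paste(fixed, collapse = "+")))
    sm <- summary(stats::lm(f, data))$coefficients
    rows <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
    out <- data.frame(term = rownames(rows), beta = rows[, 1],
                      se = rows[, 2], df = NA_real_, t = rows[, 3],
                      p = rows[, 4], row.names = NULL)
    attr(out, "engine") <- "lm"
    return(out)
  }
  useChan <- channelNested && "channel" %in% names(data) &&
    length(unique(data$channel)) > 1
  rhs <- paste(c(fixed, "(1 | patient)",
                 if (useChan) "(1 | patient:channel)"), collapse = " + ")
  f <- stats::as.formula(paste(response, "~", rhs))
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(f, data = data,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))))
  downgraded <- FALSE
  if (useChan && lme4::isSingular(fit, tol = 1e-5)) {
    rhs2 <- paste(c(fixed, "(1 | patient)"), collapse = " + ")
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(stats::as.formula(paste(response, "~", rhs2)),
                     data = data,
                     control = lme4::lmerControl(check.conv.singular = "ignore"))))
    downgraded <- TRUE
  }
  sm <- summary(fit)$coefficients
  rows <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
  out <- data.frame(term = rownames(rows), beta = rows[, "Estimate"],
                    se = rows[, "Std. Error"], df = rows[, "df"],
                    t = rows[, "t value"], p = rows[, "Pr(>|t|)"],
                    row.names = NULL)
  attr(out, "engine") <- "lmer"
  attr(out, "downgraded") <- downgraded
  out
}

# vectorized fixed-effects regression absorbing patient x channel random
# intercepts by within-stratum centering; Y is trials x pixels
.fastTMap <- function(Y, X, strata) {
  n <- nrow(Y)
  g <- as.factor(strata)
  Xc <- X - rowsum(X, g)[g, , drop = FALSE] / as.vector(table(g))[g]
  Yc <- Y - rowsum(Y, g)[g, , drop = FALSE] / as.vector(table(g))[g]
  XtX <- crossprod(Xc)
  Ainv <- solve(XtX)
  XtY <- crossprod(Xc, Yc)
  B <- Ainv %*% XtY
  Syy <- colSums(Yc^2)
  quad <- colSums(B * XtY)
  df <- n - ncol(X) - nlevels(g)
  sigma2 <- pmax(Syy - quad, 0) / df
  se <- sqrt(outer(diag(Ainv), sigma2))
  list(t = B / se, beta = B, df = df, Xc = Xc, Yc = Yc, Ainv = Ainv,
       Syy = Syy, strata = g)
}

.designMatrix <- function(events, fixed) {
  X <- as.matrix(events[, fixed, drop = FALSE])
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("fixed-effect columns contain NA; subset trials first")
  X
}

.pixelStrata <- function(events) {
  if ("channel" %in% names(events))
    interaction(events$patient, events$channel, drop = TRUE)
  else as.factor(events$patient)
}

#' Regression t-map over time-frequency pixels
#'
#' Fits the mixed model at every (time, frequency) pixel of a
#' \linkS4class{TFMap}. \code{engine = "lmm"} refits
#' \code{\link{fitLME}} per pixel (faithful, slow); \code{engine = "ols"}
#' absorbs the patient-by-channel random intercepts by within-stratum
#' centering and solves all pixels in one vectorized pass (the
#' approximation used inside the permutation machinery).
#'
#' @param tfmap a \linkS4class{TFMap} whose events carry the fixed terms
#' @param fixed character vector of fixed-effect columns
#' @param engine \code{"ols"} or \code{"lmm"}
#' @return list of class \code{"tfTMap"}: per-term \code{t} and \code{p}
#'   matrices (time x frequency), axes, residual \code{df}, engine
#' @export
tfRegressionMap <- function(tfmap, fixed, engine = c("ols", "lmm")) {
  engine <- match.arg(engine)
  ev <- tfmap@events
  keep <- complete.cases(ev[, fixed, drop = FALSE])
  pw <- tfmap@power[, , keep, drop = FALSE]
  ev <- ev[keep, , drop = FALSE]
  d <- dim(pw)
  Y <- t(matrix(pw, d[1] * d[2], d[3]))
  tm <- list(); pm <- list()
  if (engine == "ols") {
    X <- .designMatrix(ev, fixed)
    fit <- .fastTMap(Y, X, .pixelStrata(ev))
    for (j in seq_along(fixed)) {
      tmat <- matrix(fit$t[j, ], d[1], d[2])
      tm[[fixed[j]]] <- tmat
      pm[[fixed[j]]] <- 2 * pt(abs(tmat), fit$df, lower.tail = FALSE)
    }
    df <- fit$df
  } else {
    df <- NA_real_
    for (j in seq_along(fixed)) {
      tm[[fixed[j]]] <- matrix(NA_real_, d[1], d[2])
      pm[[fixed[j]]] <- matrix(NA_real_, d[1], d[2])
    }
    for (px in seq_len(ncol(Y))) {
      dat <- cbind(ev, .y = Y[, px])
      res <- tryCatch(fitLME(dat, ".y", fixed),
                      error = function(e) NULL)
      if (is.null(res)) next
      it <- (px - 1) %% d[1] + 1; jf <- (px - 1) %/% d[1] + 1
      for (j in seq_along(fixed)) {
        tm[[fixed[j]]][it, jf] <- res$t[j]
        pm[[fixed[j]]][it, jf] <- res$p[j]
      }
    }
  }
  structure(list(t = tm, p = pm, times = tfmap@times, freqs = tfmap@freqs,
                 df = df, terms = fixed, engine = engine),
            class = "tfTMap")
}

#' Geometric pixel areas on a log frequency grid
#'
#' Local bin width \code{df_i = f_i (sqrt(r) - 1/sqrt(r))} for the constant
#' grid ratio \code{r}, times the time step in milliseconds.
#'
#' @param times,freqs axes of a t-map
#' @return time x frequency matrix of pixel areas in Hz times ms
#' @export
pixelAreas <- function(times, freqs) {
  dtMs <- 1000 * (if (length(times) > 1) times[2] - times[1] else 1)
  r <- if (length(freqs) > 1) freqs[2] / freqs[1] else 2
  dfHz <- freqs * (sqrt(r) - 1 / sqrt(r))
  outer(rep(dtMs, length(times)), dfHz)
}

.clusterStats <- function(tmat, thr, areas, minArea) {
  mask <- is.finite(tmat) & abs(tmat) > thr
  lab <- cpp_label4(mask)
  nl <- attr(lab, "nLabels")
  if (nl == 0)
    return(data.frame(id = integer(), area = numeric(), stat = numeric()))
  area <- vapply(seq_len(nl), function(k) sum(areas[lab == k]), 0)
  stat <- vapply(seq_len(nl), function(k) sum(tmat[lab == k]^2), 0)
  keep <- area >= minArea
  data.frame(id = which(keep), area = area[keep], stat = stat[keep])
}

#' 2D cluster-based permutation test on a time-frequency t-map
#'
#' Pixels with \code{p < alpha} (default 0.05 divided by the number of
#' fixed effects) are grouped into 4-connected clusters; clusters smaller
#' than \code{minArea} (default 4 Hz x 80 ms = 320 Hz ms, measured with
#' geometric bin widths on the log grid) are dropped; each cluster's
#' statistic is the sum of squared t-values. The null distribution holds
#' the per-permutation maximum cluster statistic with trial labels shuffled
#' within each patient-by-channel stratum; a cluster is significant when
#' its statistic exceeds the 95th percentile of that null.
#'
#' @param tfmap a \linkS4class{TFMap}
#' @param fixed fixed-effect columns (all enter the model)
#' @param term the fixed effect whose map is cluster-tested
#' @param nPerm number of permutations
#' @param alpha pixel threshold (defaults to 0.05 / length(fixed))
#' @param minArea minimum cluster area (Hz ms)
#' @param seed permutation seed
#' @param engine map engine; permutation refits always use the vectorized
#'   within-stratum solver
#' @return list of class \code{"clusterResult"}: cluster table with areas,
#'   statistics, p-values and significance flags, the suprathreshold label
#'   matrix, the observed t-map and the null maxima
#' @export
clusterPermutation2d <- function(tfmap, fixed, term = fixed[1],
                                 nPerm = 1000, alpha = 0.05 / length(fixed),
                                 minArea = 320, seed = 1,
                                 engine = c("ols", "lmm")) {
  engine <- match.arg(engine)
  ev <- tfmap@events
  keep <- complete.cases(ev[, fixed, drop = FALSE])
  pw <- tfmap@power[, , keep, drop = FALSE]
  ev <- ev[keep, , drop = FALSE]
  d <- dim(pw)
  Y <- t(matrix(pw, d[1] * d[2], d[3]))
  X <- .designMatrix(ev, fixed)
  strata <- .pixelStrata(ev)
  jTerm <- match(term, fixed)
  fit <- .fastTMap(Y, X, strata)
  areas <- pixelAreas(tfmap@times, tfmap@freqs)
  if (engine == "lmm") {
    obs <- tfRegressionMap(tfmap, fixed, engine = "lmm")
    tObs <- obs$t[[term]]
    pObs <- obs$p[[term]]
    mask <- is.finite(pObs) & pObs < alpha
    lab <- cpp_label4(mask)
    nl <- attr(lab, "nLabels")
    clus <- if (nl == 0)
      data.frame(id = integer(), area = numeric(), stat = numeric())
    else {
      area <- vapply(seq_len(nl), function(k) sum(areas[lab == k]), 0)
      stat <- vapply(seq_len(nl), function(k) sum(tObs[lab == k]^2), 0)
      kp <- area >= minArea
      data.frame(id = which(kp), area = area[kp], stat = stat[kp])
    }
  } else {
    tObs <- matrix(fit$t[jTerm, ], d[1], d[2])
    thr <- qt(1 - alpha / 2, fit$df)
    mask <- abs(tObs) > thr
    clus <- .clusterStats(tObs, thr, areas, minArea)
  }
  # permutation null: shuffle fixed-effect rows within strata, refit with
  # the vectorized solver (X'X is invariant under within-stratum shuffles)
  thrPerm <- qt(1 - alpha / 2, fit$df)
  idxByStr <- split(seq_len(d[3]), strata)
  set.seed(seed)
  nullMax <- numeric(nPerm)
  Xc <- fit$Xc
  for (b in seq_len(nPerm)) {
    prm <- seq_len(d[3])
    for (ii in idxByStr) prm[ii] <- ii[sample.int(length(ii))]
    Xp <- Xc[prm, , drop = FALSE]
    XtY <- crossprod(Xp, fit$Yc)
    B <- fit$Ainv %*% XtY
    quad <- colSums(B * XtY)
    sigma2 <- pmax(fit$Syy - quad, 0) / fit$df
    se <- sqrt(outer(diag(fit$Ainv), sigma2))
    tP <- matrix((B / se)[jTerm, ], d[1], d[2])
    cs <- .clusterStats(tP, thrPerm, areas, minArea)
    nullMax[b] <- if (nrow(cs)) max(cs$stat) else 0
  }
  crit <- quantile(nullMax, 0.95, names = FALSE)
  if (nrow(clus)) {
    clus$p <- vapply(clus$stat, function(s) mean(nullMax >= s), 0)
    clus$significant <- clus$stat > crit
  } else {
    clus$p <- numeric(); clus$significant <- logical()
  }
  lab <- cpp_label4(mask)
  structure(list(clusters = clus, labels = lab, tMap = tObs,
                 nullMax = nullMax, critical = crit, alpha = alpha,
                 minArea = minArea, term = term, nPerm = nPerm),
            class = "clusterResult")
}

#' @export
print.clusterResult <- function(x, ...) {
  cat("2D cluster permutation (", x$term, "): ", nrow(x$clusters),
      " cluster(s) >= ", x$minArea, " Hz*ms, ",
      sum(x$clusters$significant), " significant (crit = ",
      round(x$critical, 1), ", ", x$nPerm, " perms)\n", sep = "")
  invisible(x)
}

#' Per-timepoint band regression with FDR control
#'
#' Fits the mixed model at every timepoint of an epoched band envelope and
#' applies Benjamini-Hochberg correction across timepoints within the
#' trace at level \code{q}.
#'
#' @param env a \linkS4class{BandEnvelope}
#' @param fixed fixed-effect columns
#' @param q FDR level
#' @param engine \code{"lmm"} (per-timepoint \code{\link{fitLME}}) or
#'   \code{"ols"} (vectorized within-stratum solver)
#' @param decimate fit every \code{decimate}-th timepoint
#' @return list of class \code{"tcResult"}: \code{times}, per-term
#'   \code{t}, \code{p} and corrected \code{mask} matrices
#' @export
timecourseRegressionFDR <- function(env, fixed, q = 0.001,
                                    engine = c("ols", "lmm"),
                                    decimate = 1L) {
  engine <- match.arg(engine)
  ev <- env@events
  keep <- complete.cases(ev[, fixed, drop = FALSE])
  A <- env@amplitude[, keep, drop = FALSE]
  ev <- ev[keep, , drop = FALSE]
  sel <- seq(1L, nrow(A), by = decimate)
  times <- env@times[sel]
  nT <- length(sel)
  tmat <- matrix(NA_real_, length(fixed), nT,
                 dimnames = list(fixed, NULL))
  pmat <- tmat
  if (engine == "ols") {
    X <- .designMatrix(ev, fixed)
    fit <- .fastTMap(t(A[sel, , drop = FALSE]), X, .pixelStrata(ev))
    tmat[, ] <- fit$t
    pmat[, ] <- 2 * pt(abs(fit$t), fit$df, lower.tail = FALSE)
  } else {
    for (i in seq_len(nT)) {
      dat <- cbind(ev, .y = A[sel[i], ])
      res <- tryCatch(fitLME(dat, ".y", fixed), error = function(e) NULL)
      if (is.null(res)) next
      tmat[, i] <- res$t
      pmat[, i] <- res$p
    }
  }
  mask <- t(apply(pmat, 1, function(p) {
    adj <- p.adjust(p, method = "BH")
    !is.na(adj) & adj < q
  }))
  structure(list(times = times, t = tmat, p = pmat, mask = mask, q = q,
                 terms = fixed, engine = engine), class = "tcResult")
}

.couplingSubset <- function(table, measure, stage = NULL) {
  x <- table[table$measure == measure, , drop = FALSE]
  if (!is.null(stage)) x <- x[x$stage == stage, , drop = FALSE]
  x
}

#' Stage contrast of a coupling measure
#'
#' \code{value ~ stage + (1 | patient)} with stage coded pre-selection = 1,
#' post-feedback = 0; a negative t means stronger coupling after feedback.
#'
#' @param table a \code{\link{couplingTable}}
#' @param measure one of \code{"aac_theta_theta"}, \code{"aac_xfreq"},
#'   \code{"pac_z"}
#' @return one-row data.frame (beta, t, p for the stage term)
#' @export
couplingStageContrast <- function(table, measure) {
  x <- .couplingSubset(table, measure)
  if (length(unique(x$stage)) < 2) stop("both stages must be present")
  fitLME(x, "value", "stage_code", channelNested = FALSE)
}

#' Does a coupling measure predict the upcoming stay/switch decision?
#'
#' \code{decision ~ value + (1 | patient)} on one stage, decision coded
#' stay = 1 / switch = 0 (so a negative t means higher coupling precedes
#' switches). A logistic variant is available.
#'
#' @param table a \code{\link{couplingTable}}
#' @param measure coupling measure name
#' @param stage \code{"post_feedback"} or \code{"pre_selection"}
#' @param logistic use a binomial mixed model instead of the linear one
#' @return one-row data.frame for the coupling term
#' @export
couplingDecisionPrediction <- function(table, measure, stage,
                                       logistic = FALSE) {
  x <- .couplingSubset(table, measure, stage)
  x <- x[!is.na(x$decision) & !is.na(x$value), , drop = FALSE]
  if (length(unique(x$decision)) < 2)
    stop("decision is constant in this subset")
  if (!logistic) return(fitLME(x, "decision", "value", channelNested = FALSE))
  fit <- suppressMessages(suppressWarnings(
    lme4::glmer(decision ~ value + (1 | patient), data = x,
                family = stats::binomial())))
  sm <- summary(fit)$coefficients
  data.frame(term = "value", beta = sm["value", 1], se = sm["value", 2],
             df = NA_real_, t = sm["value", 3], p = sm["value", 4])
}

#' Coupling versus model-derived variables
#'
#' \code{value ~ regressors + (1 | patient)} on one stage and decision
#' subset (all trials, stay trials or switch trials), plus a 25-bin
#' percentile summary of the measure against each regressor for plotting.
#'
#' @param table a \code{\link{couplingTable}}
#' @param measure coupling measure name
#' @param stage analysis stage
#' @param regressors subset of \code{c("pe", "rv", "ru")}
#' @param subset \code{"all"}, \code{"stay"} or \code{"switch"}
#' @param bins number of percentile bins
#' @return list with \code{effects} (per-regressor beta/t/p) and
#'   \code{bins} (regressor, bin, bin mean, measure mean, SEM, n)
#' @export
couplingVariableCorrelation <- function(table, measure, stage,
                                        regressors = c("pe", "rv", "ru"),
                                        subset = c("all", "stay", "switch"),
                                        bins = 25) {
  subset <- match.arg(subset)
  x <- .couplingSubset(table, measure, stage)
  if (subset != "all") {
    wanted <- if (subset == "stay") 1L else 0L
    x <- x[!is.na(x$decision) & x$decision == wanted, , drop = FALSE]
  }
  x <- x[complete.cases(x[, c("value", regressors)]), , drop = FALSE]
  if (!nrow(x)) stop("empty trial subset")
  effects <- fitLME(x, "value", regressors, channelNested = FALSE)
  binTab <- do.call(rbind, lapply(regressors, function(rg) {
    rk <- rank(x[[rg]], ties.method = "first")
    b <- ceiling(rk / length(rk) * bins)
    agg <- lapply(split(seq_len(nrow(x)), b), function(ii)
      data.frame(regressor = rg, bin = b[ii[1]],
                 regMean = mean(x[[rg]][ii]),
                 measureMean = mean(x$value[ii]),
                 sem = sd(x$value[ii]) / sqrt(length(ii)),
                 n = length(ii)))
    do.call(rbind, agg)
  }))
  rownames(binTab) <- NULL
  list(effects = effects, bins = binTab, subset = subset, stage = stage)
}
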