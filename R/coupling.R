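#' Phase-amplitude modulation index
#'
#' \code{mi = | n^-1 sum_t a_t exp(i phi_t) |}: the modulus of the
#' time-averaged amplitude-weighted unit phasor. Zero when amplitude is
#' unrelated to phase; bounded above by \code{mean(a)}.
#'
#' @param a non-negative amplitude series
#' @param phi phase series in radians
#' @return non-negative scalar
#' @export
pacMI <- function(a, phi) {
  if (length(a) != length(phi)) stop("length mismatch between a and phi")
  if (length(a) < 2) stop("need at least 2 samples")
  Mod(mean(a * exp(1i * phi)))
}

# modulation index at every circular lag of a against exp(i phi), via FFT
# cross-correlation; lag s gives | n^-1 sum_t a_{t+s} exp(i phi_t) |
.miAllLags <- function(a, phi) {
  n <- length(a)
  u <- exp(1i * phi)
  r <- fft(fft(a) * Conj(fft(Conj(u))), inverse = TRUE) / n
  Mod(r) / n
}

#' Permutation-standardized phase-amplitude coupling
#'
#' Builds a null by circularly shifting the amplitude series (random
#' offsets of at least \code{minShiftFrac * n} samples) while the phase
#' series stays fixed, recomputing the modulation index per shift, and
#' returns \code{z = (mi - mean(null)) / sd(null)}.
#'
#' @param a,phi amplitude and phase series
#' @param nPerm number of permutations
#' @param minShiftFrac minimum shift as a fraction of the series length
#' @param seed permutation seed
#' @return list of class \code{"pacResult"}: \code{mi}, \code{z},
#'   \code{nullMean}, \code{nullSd}, \code{nPerm}
#' @export
pacPermutationZ <- function(a, phi, nPerm = 5000, minShiftFrac = 0.1,
                            seed = 1) {
  n <- length(a)
  if (n != length(phi)) stop("length mismatch between a and phi")
  lagMI <- .miAllLags(a, phi)
  mi <- lagMI[1]
  minLag <- max(1L, floor(minShiftFrac * n))
  allowed <- seq.int(minLag, n - minLag)
  set.seed(seed)
  shifts <- sample(allowed, nPerm, replace = TRUE)
  nullVals <- lagMI[shifts + 1L]
  ns <- sd(nullVals)
  if (ns == 0) stop("degenerate permutation null (zero variance)")
  structure(list(mi = mi, z = (mi - mean(nullVals)) / ns,
                 nullMean = mean(nullVals), nullSd = ns, nPerm = nPerm),
            class = "pacResult")
}

#' @export
print.pacResult <- function(x, ...) {
  cat(sprintf("PAC: mi = %.4g, z = %.2f (null %.4g +/- %.4g, %d perms)\n",
              x$mi, x$z, x$nullMean, x$nullSd, x$nPerm))
  invisible(x)
}

#' Exploratory PAC grid search
#'
#' Computes the permutation-standardized modulation index for every pair of
#' a phase frequency below \code{phaseMax} and an amplitude frequency above
#' \code{ampMin} on the standard log grid: the 50-bin 4-150 Hz grid yields
#' an 18 x 22 matrix. Phase comes from \code{phaseSignal} (e.g., dlPFC) and
#' amplitude from \code{ampSignal} (e.g., dmPFC); both are restricted to
#' the per-trial stage windows and concatenated before the modulation index
#' is computed.
#'
#' @param phaseSignal,ampSignal single-channel signals
#' @param fs sampling rate (Hz)
#' @param events per-trial event table
#' @param stage \code{"post_feedback"} or \code{"pre_selection"}
#' @param freqs frequency grid
#' @param phaseMax,ampMin grid split points (Hz)
#' @param nPerm permutations per pair
#' @param seed permutation seed
#' @return list of class \code{"pacGrid"}: \code{z} matrix (phase x amp
#'   frequencies), axes, and the argmax \code{peak}
#' @export
pacGridSearch <- function(phaseSignal, ampSignal, fs, events,
                          stage = "post_feedback", freqs = logFreqGrid(),
                          phaseMax = 15, ampMin = 30, nPerm = 200,
                          seed = 1) {
  phaseFreqs <- freqs[freqs < phaseMax]
  ampFreqs <- freqs[freqs > ampMin]
  st <- .stageTimes(events, stage)
  tfrP <- morletTFR(phaseSignal, fs, phaseFreqs)
  tfrA <- morletTFR(ampSignal, fs, ampFreqs, keepPhase = FALSE)
  phE <- epochSignal(tfrP$phase, st$times, st$window, fs)
  amE <- epochSignal(sqrt(tfrA$power), st$times, st$window, fs)
  z <- matrix(NA_real_, length(phaseFreqs), length(ampFreqs),
              dimnames = list(signif(phaseFreqs, 4), signif(ampFreqs, 4)))
  for (i in seq_along(phaseFreqs)) {
    phi <- as.numeric(phE[, i, ])
    for (j in seq_along(ampFreqs)) {
      a <- as.numeric(amE[, j, ])
      z[i, j] <- pacPermutationZ(a, phi, nPerm = nPerm,
                                 seed = seed + 131L * i + j)$z
    }
  }
  pk <- which(z == max(z), arr.ind = TRUE)[1, ]
  structure(list(z = z, phaseFreqs = phaseFreqs, ampFreqs = ampFreqs,
                 peak = c(phase = phaseFreqs[pk[1]], amp = ampFreqs[pk[2]])),
            class = "pacGrid")
}

#' @export
print.pacGrid <- function(x, ...) {
  cat("PAC grid:", nrow(x$z), "phase x", ncol(x$z), "amplitude bins; ",
      sprintf("peak z = %.2f at (%.3g Hz, %.3g Hz)\n", max(x$z),
              x$peak["phase"], x$peak["amp"]))
  invisible(x)
}

#' Amplitude-amplitude coupling
#'
#' Per-trial Pearson correlation between two epoched analytic-amplitude
#' series over their common window (e.g., theta-theta between regions, or
#' dmPFC high-gamma against dlPFC theta). Zero-variance trials yield
#' \code{NA}.
#'
#' @param envA,envB \linkS4class{BandEnvelope} objects (or plain
#'   time x trial matrices) with matching trial counts and sample counts
#' @return numeric vector of per-trial correlations
#' @export
aac <- function(envA, envB) {
  A <- if (is(envA, "BandEnvelope")) envA@amplitude else envA
  B <- if (is(envB, "BandEnvelope")) envB@amplitude else envB
  if (!all(dim(A) == dim(B)))
    stop("envelope windows must have matching dimensions")
  vapply(seq_len(ncol(A)), function(i) {
    x <- A[, i]; y <- B[, i]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }, 0)
}

#' Per-trial coupling table for one patient
#'
#' Computes stage-windowed coupling measures from one phase/amplitude
#' channel pair of a recording and joins them to the behavioral regressors:
#' theta-theta AAC, cross-frequency AAC (dmPFC high-gamma vs dlPFC theta)
#' and the per-trial PAC z-score at a fixed frequency pair, for both task
#' stages.
#'
#' @param rec a \linkS4class{SyntheticRecording}
#' @param phaseRegion,ampRegion region names providing theta phase (and
#'   theta envelope) and high-gamma amplitude
#' @param channelPhase,channelAmp channel indices
#' @param thetaBand,gammaBand band edges (Hz)
#' @param pacPair length-2 numeric \code{c(phaseFreq, ampFreq)} for the
#'   per-trial PAC measure
#' @param nPerm permutations for per-trial PAC z
#' @param seed permutation seed
#' @return data.frame of class \code{"couplingTable"}: patient, trial,
#'   stage, measure, value plus joined regressors
#' @export
couplingTable <- function(rec, phaseRegion = "dlPFC", ampRegion = "dmPFC",
                          channelPhase = 1L, channelAmp = 1L,
                          thetaBand = c(4, 9), gammaBand = c(70, 150),
                          pacPair = c(8, 110), nPerm = 200, seed = 1) {
  ev <- rec@events
  fs <- rec@fs
  xPhase <- rec@signals[[phaseRegion]][channelPhase, ]
  xAmp <- rec@signals[[ampRegion]][channelAmp, ]
  thetaP <- gaborHAA(xPhase, fs, thetaBand)
  thetaA <- gaborHAA(xAmp, fs, thetaBand)
  gammaA <- gaborHAA(xAmp, fs, gammaBand)
  # narrowband phase / amplitude for the fixed PAC pair
  phPAC <- Arg(.gaussFilterBank(xPhase, fs, pacPair[1],
                                pacPair[1] / 6)[, 1])
  amPAC <- Mod(.gaussFilterBank(xAmp, fs, pacPair[2], pacPair[2] / 6)[, 1])
  rows <- list()
  for (stage in c("post_feedback", "pre_selection")) {
    st <- .stageTimes(ev, stage)
    al <- if (stage == "post_feedback") "feedback" else "selection"
    eTheta1 <- epochSignal(as.numeric(thetaP), st$times, st$window, fs)
    eTheta2 <- epochSignal(as.numeric(thetaA), st$times, st$window, fs)
    eGamma <- epochSignal(as.numeric(gammaA), st$times, st$window, fs)
    ePhi <- epochSignal(as.numeric(phPAC), st$times, st$window, fs)
    eAmp <- epochSignal(as.numeric(amPAC), st$times, st$window, fs)
    kept <- attr(eTheta1, "kept")
    evk <- ev[kept, , drop = FALSE]
    aacTT <- aac(eTheta2, eTheta1)
    aacX <- aac(eGamma, eTheta1)
    pacZ <- vapply(seq_len(ncol(ePhi)), function(i)
      pacPermutationZ(eAmp[, i], ePhi[, i], nPerm = nPerm,
                      seed = seed + i)$z, 0)
    for (ms in c("aac_theta_theta", "aac_xfreq", "pac_z")) {
      val <- switch(ms, aac_theta_theta = aacTT, aac_xfreq = aacX,
                    pac_z = pacZ)
      rows[[length(rows) + 1L]] <-
        data.frame(patient = evk$patient, trial = evk$trial,
                   stage = stage,
                   stage_code = as.integer(stage == "pre_selection"),
                   measure = ms, value = val,
                   reward = evk$reward, decision = evk$decision,
                   pe = evk$pe, rv = evk$rv, ru = evk$ru)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("couplingTable", "data.frame")
  out
}
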