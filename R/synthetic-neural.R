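#' Specification of a synthetic two-region recording
#'
#' Describes the generative model for ground-truth local field potentials:
#' 1/f background noise, base oscillators, trial-locked band oscillations
#' whose amplitudes carry linear effects of behavioral regressors,
#' theta-phase to gamma-amplitude coupling of configurable depth, and
#' inter-regional envelope correlation. Stage windows follow the analysis
#' epochs: post-feedback = [0, 2] s from feedback onset, pre-selection =
#' [-1, 0] s from selection onset.
#'
#' @param fs sampling rate (Hz)
#' @param channels named integer vector, channels per region
#' @param noiseAlpha 1/f exponent of the background
#' @param noiseAmp background standard deviation
#' @param oscillators list of \code{list(band = c(lo, hi), amp = a)} base
#'   oscillations present in all channels
#' @param effects list of \code{list(region, band, regressor, slope, stage,
#'   amp)} regressor-modulated oscillations
#' @param pac \code{NULL} or \code{list(phaseRegion, ampRegion, phaseFreq,
#'   ampFreq, depth, stage, amp0, slowAmp)}; \code{depth} may be a scalar or
#'   the name of a per-trial events column
#' @param aac \code{NULL} or \code{list(regionA, regionB, band, targetR,
#'   stage, amp)}; \code{targetR} may be a scalar or an events column name
#' @param seed integer generation seed
#' @return list of class \code{"RecordingSpec"}
#' @export
recordingSpec <- function(fs = 500,
                          channels = c(dmPFC = 4L, dlPFC = 8L),
                          noiseAlpha = 1, noiseAmp = 1,
                          oscillators = list(),
                          effects = list(), pac = NULL, aac = NULL,
                          seed = 1L) {
  spec <- list(fs = fs, channels = channels, noiseAlpha = noiseAlpha,
               noiseAmp = noiseAmp, oscillators = oscillators,
               effects = effects, pac = pac, aac = aac,
               seed = as.integer(seed))
  fmax <- 0
  for (o in oscillators) fmax <- max(fmax, o$band)
  for (e in effects) fmax <- max(fmax, e$band)
  if (!is.null(pac)) fmax <- max(fmax, pac$ampFreq)
  if (fs <= 2 * fmax) stop("fs must exceed twice the highest oscillator frequency")
  if (!is.null(pac) && is.numeric(pac$depth) &&
      (pac$depth < 0 || pac$depth > 1))
    stop("pac depth must be in [0, 1]")
  if (!is.null(aac) && is.numeric(aac$targetR) && abs(aac$targetR) > 1)
    stop("aac targetR must be in [-1, 1]")
  if (noiseAlpha < 0) stop("noiseAlpha must be >= 0")
  class(spec) <- "RecordingSpec"
  spec
}

#' Gaussian 1/f^alpha background noise
#'
#' White Gaussian noise spectrally shaped so that the power spectral density
#' falls off as \code{f^-alpha}, then rescaled to the requested standard
#' deviation. Deterministic given the RNG state (seed it with
#' \code{set.seed} or pass \code{seed}).
#'
#' @param nSamples signal length
#' @param fs sampling rate (Hz)
#' @param alpha spectral exponent (0 = white)
#' @param amplitude output standard deviation
#' @param seed optional seed
#' @return numeric vector
#' @export
genBackground <- function(nSamples, fs, alpha = 1, amplitude = 1,
                          seed = NULL) {
  if (nSamples <= 0) stop("nSamples must be > 0")
  if (alpha < 0) stop("alpha must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  x <- rnorm(nSamples)
  if (alpha > 0) {
    z <- fft(x)
    f <- seq(0, fs, length.out = nSamples + 1)[seq_len(nSamples)]
    f <- pmin(f, fs - f)            # two-sided frequency magnitude
    g <- ifelse(f > 0, f^(-alpha / 2), 0)
    x <- Re(fft(z * g, inverse = TRUE)) / nSamples
  }
  amplitude * x / sd(x)
}

# cosine taper (Tukey) over a window of n samples
.taper <- function(n, frac = 0.2) {
  k <- max(1L, round(frac * n))
  ramp <- 0.5 * (1 - cos(pi * seq_len(k) / k))
  c(ramp, rep(1, max(0L, n - 2L * k)), rev(ramp))[seq_len(n)]
}

.windowIndex <- function(eventTimes, window, fs, nSamples) {
  n <- round((window[2] - window[1]) * fs)
  start <- round(eventTimes * fs) + round(window[1] * fs) + 1L
  ok <- start >= 1L & (start + n - 1L) <= nSamples
  list(start = start, n = n, ok = ok)
}

.stageTimes <- function(events, stage) {
  switch(stage,
         post_feedback = list(times = events$feedback_time, window = c(0, 2)),
         pre_selection = list(times = events$selection_time, window = c(-1, 0)),
         stop("unknown stage: ", stage))
}

#' Inject a regressor-modulated band oscillation
#'
#' Adds, within a peri-event window on each trial, an oscillation at the
#' band's geometric center frequency whose amplitude equals
#' \code{amp * max(0, 1 + slope * z)} with \code{z} the z-scored regressor
#' (clipping keeps the amplitude non-negative). Window edges are
#' cosine-tapered. Trials whose window falls outside the signal are skipped
#' and counted in the \code{"skipped"} attribute.
#'
#' @param signal numeric vector (one channel)
#' @param fs sampling rate (Hz)
#' @param events per-trial event table with \code{feedback_time} /
#'   \code{selection_time} columns
#' @param band length-2 band edges (Hz); the carrier sits at their geometric
#'   mean
#' @param regressor events column name
#' @param slope linear effect size on the z-scored regressor
#' @param stage \code{"post_feedback"} or \code{"pre_selection"}
#' @param amp base amplitude
#' @param randomPhase draw a random carrier phase per trial
#' @return modified signal
#' @export
injectRegressorPower <- function(signal, fs, events, band, regressor,
                                 slope, stage = "post_feedback", amp = 1,
                                 randomPhase = TRUE) {
  if (!regressor %in% names(events))
    stop("regressor not present in events: ", regressor)
  st <- .stageTimes(events, stage)
  x <- events[[regressor]]
  z <- if (sd(x, na.rm = TRUE) > 0) (x - mean(x, na.rm = TRUE)) / sd(x, na.rm = TRUE) else x * 0
  z[is.na(z)] <- 0
  gain <- pmax(1 + slope * z, 0)
  f0 <- sqrt(band[1] * band[2])
  idx <- .windowIndex(st$times, st$window, fs, length(signal))
  tap <- .taper(idx$n)
  tt <- seq_len(idx$n) / fs
  skipped <- 0L
  for (i in seq_along(idx$start)) {
    if (!idx$ok[i]) { skipped <- skipped + 1L; next }
    ph <- if (randomPhase) runif(1, 0, 2 * pi) else 0
    sel <- idx$start[i]:(idx$start[i] + idx$n - 1L)
    signal[sel] <- signal[sel] + amp * gain[i] * tap * cos(2 * pi * f0 * tt + ph)
  }
  attr(signal, "skipped") <- skipped
  signal
}

# slow-phase and modulated-fast components for one trial window
.pacComponents <- function(n, fs, phaseFreq, ampFreq, depth, amp0, slowAmp,
                           phi0, psi0) {
  tt <- seq_len(n) / fs
  phi <- 2 * pi * phaseFreq * tt + phi0
  slow <- slowAmp * cos(phi)
  fast <- amp0 * (1 + depth * cos(phi)) * cos(2 * pi * ampFreq * tt + psi0)
  tap <- .taper(n)
  list(slow = tap * slow, fast = tap * fast)
}

#' Inject phase-amplitude coupling
#'
#' Within each trial window adds a slow oscillation at \code{phaseFreq} and
#' a fast oscillation at \code{ampFreq} whose amplitude is
#' \code{amp0 (1 + d cos(phi_slow))}. When \code{phaseSignal} is supplied
#' the slow component goes into it (the phase-providing region) and the
#' modulated fast component into \code{signal} (the amplitude region);
#' otherwise both are added to \code{signal}.
#'
#' @param signal channel receiving the fast (amplitude) component
#' @param fs sampling rate (Hz)
#' @param events per-trial event table
#' @param phaseFreq,ampFreq slow and fast frequencies (Hz),
#'   \code{ampFreq > phaseFreq}
#' @param depth coupling depth in \code{[0, 1]}; scalar or per-trial vector
#' @param stage analysis stage defining the injection window
#' @param amp0 fast-carrier base amplitude
#' @param slowAmp slow-carrier amplitude
#' @param phaseSignal optional second channel receiving the slow component
#' @return modified signal, or \code{list(signal, phaseSignal)} when a phase
#'   channel was given
#' @export
injectPac <- function(signal, fs, events, phaseFreq, ampFreq, depth,
                      stage = "pre_selection", amp0 = 1, slowAmp = 1,
                      phaseSignal = NULL) {
  if (ampFreq <= phaseFreq) stop("ampFreq must exceed phaseFreq")
  d <- rep_len(depth, nrow(events))
  if (any(d < 0 | d > 1, na.rm = TRUE)) stop("depth must be in [0, 1]")
  st <- .stageTimes(events, stage)
  idx <- .windowIndex(st$times, st$window, fs, length(signal))
  for (i in seq_along(idx$start)) {
    if (!idx$ok[i] || is.na(d[i])) next  # unlabeled trials get no injection
    comp <- .pacComponents(idx$n, fs, phaseFreq, ampFreq, d[i], amp0,
                           slowAmp, runif(1, 0, 2 * pi), runif(1, 0, 2 * pi))
    sel <- idx$start[i]:(idx$start[i] + idx$n - 1L)
    if (is.null(phaseSignal)) {
      signal[sel] <- signal[sel] + comp$slow + comp$fast
    } else {
      signal[sel] <- signal[sel] + comp$fast
      phaseSignal[sel] <- phaseSignal[sel] + comp$slow
    }
  }
  if (is.null(phaseSignal)) signal else list(signal = signal,
                                             phaseSignal = phaseSignal)
}

# standardized low-pass noise for envelope construction
.slowNoise <- function(n, fs, cutoff) {
  x <- rnorm(n)
  z <- fft(x)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, fs - f)
  z[f > cutoff] <- 0
  y <- Re(fft(z, inverse = TRUE)) / n
  (y - mean(y)) / max(sd(y), 1e-12)
}

#' Inject a shared band-limited envelope into two channels
#'
#' Both channels receive an oscillation at the band's geometric center whose
#' slow envelopes share a common component mixed so that the envelope
#' Pearson correlation approximates \code{targetR} on clean signals:
#' \code{env = 1 + envSd (sqrt(|r|) c + sqrt(1-|r|) e)} with shared
#' \code{c} and independent \code{e} per channel (sign of \code{r} flips the
#' shared component for the second channel). Envelopes are clipped positive.
#'
#' @param sigA,sigB the two channels
#' @param fs sampling rate (Hz)
#' @param events per-trial event table
#' @param band length-2 band edges (Hz)
#' @param targetR target envelope correlation; scalar or per-trial vector
#' @param stage analysis stage defining the injection window
#' @param amp carrier amplitude
#' @param envSd envelope fluctuation scale
#' @param envCutoff envelope low-pass cutoff (Hz)
#' @return \code{list(a, b)} of modified channels
#' @export
injectSharedEnvelope <- function(sigA, sigB, fs, events, band, targetR,
                                 stage = "post_feedback", amp = 1,
                                 envSd = 0.3, envCutoff = 2.5) {
  r <- rep_len(targetR, nrow(events))
  r[is.na(r)] <- 0                       # unlabeled trials: independent envelopes
  if (any(abs(r) > 1)) stop("targetR must be in [-1, 1]")
  st <- .stageTimes(events, stage)
  idx <- .windowIndex(st$times, st$window, fs, length(sigA))
  f0 <- sqrt(band[1] * band[2])
  tt <- seq_len(idx$n) / fs
  tap <- .taper(idx$n)
  for (i in seq_along(idx$start)) {
    if (!idx$ok[i]) next
    cm <- .slowNoise(idx$n, fs, envCutoff)
    eA <- .slowNoise(idx$n, fs, envCutoff)
    eB <- .slowNoise(idx$n, fs, envCutoff)
    ra <- abs(r[i]); sgn <- sign(r[i] + 1e-300)
    envA <- pmax(1 + envSd * (sqrt(ra) * cm + sqrt(1 - ra) * eA), 0.05)
    envB <- pmax(1 + envSd * (sgn * sqrt(ra) * cm + sqrt(1 - ra) * eB), 0.05)
    sel <- idx$start[i]:(idx$start[i] + idx$n - 1L)
    phA <- runif(1, 0, 2 * pi); phB <- runif(1, 0, 2 * pi)
    sigA[sel] <- sigA[sel] + amp * tap * envA * cos(2 * pi * f0 * tt + phA)
    sigB[sel] <- sigB[sel] + amp * tap * envB * cos(2 * pi * f0 * tt + phB)
  }
  list(a = sigA, b = sigB)
}

#' Build the per-trial events table from behavior
#'
#' Joins session events with model-derived regressors. Codings:
#' \code{reward} 1/0 for the current trial's feedback, \code{prev_feedback}
#' the previous trial's reward, \code{decision} stay = 1 / switch = 0 for
#' the NEXT trial relative to the current choice (NA on the last trial).
#'
#' @param session a \linkS4class{BanditSession}
#' @param trajectory a \linkS4class{LearnerTrajectory} run on that session
#' @param patient patient label
#' @return data.frame, one row per trial
#' @export
behaviorEvents <- function(session, trajectory, patient = "P01") {
  n <- nTrials(session)
  ch <- session@choices
  nextStay <- c(as.integer(ch[-1L] == ch[-n]), NA_integer_)
  mch <- trajectory@m[cbind(seq_len(n), ch)]
  wch <- trajectory@w[cbind(seq_len(n), ch)]
  data.frame(patient = patient, trial = seq_len(n),
             selection_time = session@selectionTimes,
             feedback_time = session@feedbackTimes,
             choice = ch, reward = session@outcomes,
             prev_feedback = c(NA_integer_, session@outcomes[-n]),
             decision = nextStay,
             pe = trajectory@pe, rv = trajectory@rv, ru = trajectory@ru,
             value = mch, uncertainty = wch)
}

#' Generate a full synthetic recording
#'
#' Composes, per patient and channel, 1/f background, base oscillators and
#' every configured ground-truth effect (regressor-modulated power,
#' phase-amplitude coupling between the configured regions, shared envelope
#' correlation), time-locked to the behavioral events. Injected components
#' are coherent across channels within a region. The generating parameters
#' are echoed in the \code{truth} slot.
#'
#' @param behavior list, one element per patient, each
#'   \code{list(session =, trajectory =)}
#' @param spec a \code{\link{recordingSpec}}
#' @return a \linkS4class{SyntheticRecording}
#' @export
generateDataset <- function(behavior, spec) {
  stopifnot(inherits(spec, "RecordingSpec"))
  fs <- spec$fs
  set.seed(spec$seed)
  allEvents <- list()
  sigList <- setNames(vector("list", length(spec$channels)),
                      names(spec$channels))
  for (p in seq_along(behavior)) {
    beh <- behavior[[p]]
    ev <- behaviorEvents(beh$session, beh$trajectory,
                         patient = sprintf("P%02d", p))
    if (nrow(ev) != nTrials(beh$session))
      stop("inconsistent trial counts")
    dur <- max(ev$feedback_time) + 3
    nSamp <- ceiling(dur * fs)
    regs <- lapply(names(spec$channels), function(region) {
      nCh <- spec$channels[[region]]
      base <- matrix(0, nCh, nSamp)
      for (ci in seq_len(nCh))
        base[ci, ] <- genBackground(nSamp, fs, spec$noiseAlpha, spec$noiseAmp)
      base
    })
    names(regs) <- names(spec$channels)
    tt <- seq_len(nSamp) / fs
    for (o in spec$oscillators) {
      f0 <- sqrt(o$band[1] * o$band[2])
      for (region in names(regs)) {
        ph <- runif(1, 0, 2 * pi)
        osc <- o$amp * cos(2 * pi * f0 * tt + ph)
        regs[[region]] <- sweep(regs[[region]], 2, osc, "+")
      }
    }
    # regressor effects: one coherent component per region, added to all
    # channels of that region
    for (e in spec$effects) {
      comp <- injectRegressorPower(numeric(nSamp), fs, ev, e$band,
                                   e$regressor, e$slope,
                                   stage = e$stage %||% "post_feedback",
                                   amp = e$amp %||% 1)
      regs[[e$region]] <- sweep(regs[[e$region]], 2, as.numeric(comp), "+")
    }
    if (!is.null(spec$pac)) {
      pc <- spec$pac
      d <- if (is.character(pc$depth)) ev[[pc$depth]] else pc$depth
      inj <- injectPac(numeric(nSamp), fs, ev, pc$phaseFreq, pc$ampFreq, d,
                       stage = pc$stage %||% "pre_selection",
                       amp0 = pc$amp0 %||% 1, slowAmp = pc$slowAmp %||% 1,
                       phaseSignal = numeric(nSamp))
      regs[[pc$ampRegion]] <- sweep(regs[[pc$ampRegion]], 2,
                                    inj$signal, "+")
      regs[[pc$phaseRegion]] <- sweep(regs[[pc$phaseRegion]], 2,
                                      inj$phaseSignal, "+")
    }
    if (!is.null(spec$aac)) {
      ac <- spec$aac
      r <- if (is.character(ac$targetR)) ev[[ac$targetR]] else ac$targetR
      inj <- injectSharedEnvelope(numeric(nSamp), numeric(nSamp), fs, ev,
                                  ac$band, r,
                                  stage = ac$stage %||% "post_feedback",
                                  amp = ac$amp %||% 1)
      regs[[ac$regionA]] <- sweep(regs[[ac$regionA]], 2, inj$a, "+")
      regs[[ac$regionB]] <- sweep(regs[[ac$regionB]], 2, inj$b, "+")
    }
    for (region in names(regs)) sigList[[region]][[p]] <- regs[[region]]
    allEvents[[p]] <- ev
  }
  events <- do.call(rbind, allEvents)
  truth <- list(spec = unclass(spec))
  out <- list(signals = sigList, fs = fs, events = events, truth = truth)
  class(out) <- "SyntheticDataset"
  out
}

#' Extract one patient's recording as a SyntheticRecording object
#'
#' @param dataset result of \code{\link{generateDataset}}
#' @param patient patient index
#' @return a \linkS4class{SyntheticRecording}
#' @export
patientRecording <- function(dataset, patient) {
  pid <- sprintf("P%02d", patient)
  ev <- dataset$events[dataset$events$patient == pid, , drop = FALSE]
  sig <- lapply(dataset$signals, function(lst) lst[[patient]])
  new("SyntheticRecording", signals = sig, fs = dataset$fs,
      events = ev, truth = dataset$truth)
}
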