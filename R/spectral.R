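#' Logarithmically spaced frequency grid
#'
#' \code{f_i = fMin (fMax/fMin)^(i/(n-1))}; the default grid is 50 bins
#' from 4 to 150 Hz, which puts 18 bins below 15 Hz and 22 bins above
#' 30 Hz.
#'
#' @param fMin,fMax grid endpoints (Hz)
#' @param nBins number of bins (>= 2)
#' @return strictly increasing numeric vector
#' @export
logFreqGrid <- function(fMin = 4, fMax = 150, nBins = 50) {
  if (fMin <= 0 || fMax <= fMin || nBins < 2)
    stop("need 0 < fMin < fMax and nBins >= 2")
  fMin * (fMax / fMin)^(seq(0, 1, length.out = nBins))
}

#' Frequency-dependent Morlet cycle counts
#'
#' Geometric interpolation from \code{cMin} cycles at the lowest frequency
#' to \code{cMax} at the highest (defaults 4 and 9).
#'
#' @param freqs frequency grid
#' @param cMin,cMax endpoint cycle counts
#' @return numeric vector aligned with \code{freqs}
#' @export
morletCycles <- function(freqs, cMin = 4, cMax = 9) {
  n <- length(freqs)
  cMin * (cMax / cMin)^(seq(0, 1, length.out = n))
}

.reflectPad <- function(x, p) {
  n <- length(x)
  p <- min(p, n - 1L)
  c(x[(p + 1L):2L], x, x[(n - 1L):(n - p)])
}

# one-sided Gaussian filters in the frequency domain applied by FFT with
# reflection padding; returns complex matrix (samples x filters)
.gaussFilterBank <- function(x, fs, f0, sigmaF, gain = 2) {
  n <- length(x)
  sigT <- 1 / (2 * pi * sigmaF)
  pad <- min(n - 1L, ceiling(5 * max(sigT) * fs))
  xp <- .reflectPad(x, pad)
  # round up to a 2-3-5-smooth length: R's mixed-radix FFT is quadratic for
  # lengths with large prime factors
  N <- stats::nextn(length(xp), factors = c(2, 3, 5))
  xp <- c(xp, numeric(N - length(xp)))
  X <- fft(xp)
  f <- (seq_len(N) - 1) * fs / N
  out <- matrix(0i, n, length(f0))
  for (j in seq_along(f0)) {
    H <- gain * exp(-0.5 * ((f - f0[j]) / sigmaF[j])^2)
    H[f > fs / 2] <- 0            # one-sided: analytic output
    z <- fft(X * H, inverse = TRUE) / N
    out[, j] <- z[(pad + 1L):(pad + n)]
  }
  out
}

#' Complex Morlet time-frequency decomposition
#'
#' Convolves the signal with complex Morlet wavelets (complex sine tapered
#' by a Gaussian) at each grid frequency, with cycle counts geometrically
#' increasing across the grid. Implemented as frequency-domain Gaussian
#' filtering with reflection padding; wavelet peak gain is 1 so power scales
#' with the square of signal amplitude.
#'
#' @param x numeric signal (one channel)
#' @param fs sampling rate (Hz)
#' @param freqs frequency grid (default \code{\link{logFreqGrid}()})
#' @param cycles per-frequency cycle counts (default
#'   \code{\link{morletCycles}(freqs)})
#' @param keepPhase retain the phase matrix
#' @return list of class \code{"ContinuousTFR"} with \code{power}
#'   (samples x frequencies), optional \code{phase}, \code{freqs}, \code{fs}
#' @export
morletTFR <- function(x, fs, freqs = logFreqGrid(),
                      cycles = morletCycles(freqs), keepPhase = TRUE) {
  if (max(freqs) >= fs / 2)
    stop("fs below Nyquist for the highest frequency")
  sigmaF <- freqs / cycles
  z <- .gaussFilterBank(x, fs, freqs, sigmaF, gain = 1)
  out <- list(power = Mod(z)^2,
              phase = if (keepPhase) Arg(z) else NULL,
              freqs = freqs, cycles = cycles, fs = fs)
  class(out) <- "ContinuousTFR"
  out
}

#' Gabor filter impulse response
#'
#' Complex Gabor atom \code{g(t) = A exp(-s0 t^2) exp(2 pi i v0 t)} with the
#' duration parameter set so that the amplitude frequency response has full
#' width at half maximum \code{fbw * v0}, and \code{A} chosen for unit
#' energy. The energy-density standard deviations satisfy
#' \code{sigmaT * sigmaF = 1/(4 pi)} (the Gabor limit).
#'
#' @param v0 center frequency (Hz)
#' @param fs sampling rate (Hz)
#' @param fbw fractional bandwidth
#' @param nSigma half-support of the returned response in envelope SDs
#' @return list with complex \code{h}, \code{t}, \code{s0}, \code{A},
#'   \code{sigmaT}, \code{sigmaF}
#' @export
gaborFilter <- function(v0, fs, fbw = 0.25, nSigma = 5) {
  if (v0 <= 0 || v0 >= fs / 2) stop("v0 must lie in (0, fs/2)")
  s0 <- pi^2 * (fbw * v0)^2 / (4 * log(2))
  A <- (2 * s0 / pi)^0.25
  sigEnv <- 1 / sqrt(2 * s0)           # amplitude-envelope SD
  half <- ceiling(nSigma * sigEnv * fs)
  t <- (-half:half) / fs
  h <- A * exp(-s0 * t^2) * exp(2i * pi * v0 * t)
  list(h = h, t = t, s0 = s0, A = A,
       sigmaT = 1 / (2 * sqrt(s0)),    # energy-density SDs
       sigmaF = sqrt(s0) / (2 * pi))
}

#' Band-limited Hilbert analytic amplitude via a Gabor filter bank
#'
#' The band is divided into eight logarithmically spaced sub-bands; each is
#' filtered with a unit-energy complex Gabor filter (fractional bandwidth
#' 0.25), the analytic-signal magnitude is taken, and the eight magnitudes
#' are averaged into a single envelope.
#'
#' @param x numeric signal (one channel)
#' @param fs sampling rate (Hz)
#' @param band length-2 band edges (Hz)
#' @param nSubbands number of sub-bands
#' @param fbw fractional bandwidth of each Gabor filter
#' @return numeric envelope with attributes \code{band} and
#'   \code{centers}
#' @export
gaborHAA <- function(x, fs, band, nSubbands = 8, fbw = 0.25) {
  if (band[1] <= 0 || band[2] >= fs / 2 || band[2] <= band[1])
    stop("band must lie within (0, fs/2)")
  edges <- exp(seq(log(band[1]), log(band[2]), length.out = nSubbands + 1))
  centers <- sqrt(edges[-1] * edges[-(nSubbands + 1)])
  if (any(diff(centers) < 1 / (length(x) / fs)))
    stop("band too narrow for ", nSubbands, " distinct sub-bands")
  n <- length(x)
  env <- numeric(n)
  for (f0 in centers) {
    g <- gaborFilter(f0, fs, fbw)
    pad <- (length(g$h) - 1L) / 2L
    if (pad > n - 1L)
      stop("signal too short for the Gabor filter at ", signif(f0, 4), " Hz")
    xp <- .reflectPad(x, pad)
    # smooth FFT length (see .gaussFilterBank); extra zeros lie beyond the
    # reflection padding and cannot reach the de-padded output region
    N <- stats::nextn(length(xp), factors = c(2, 3, 5))
    xp <- c(xp, numeric(N - length(xp)))
    H <- fft(c(g$h / fs, rep(0, N - length(g$h))))
    X <- fft(xp)
    z <- fft(X * H, inverse = TRUE) / N
    # compensate the filter's group delay (centered kernel)
    z <- z[(2L * pad + 1L):(2L * pad + n)]
    env <- env + Mod(z)
  }
  env <- env / length(centers)
  attr(env, "band") <- band
  attr(env, "centers") <- centers
  env
}

.epochIndex <- function(eventTimes, window, fs) {
  nSamp <- round((window[2] - window[1]) * fs)
  if (nSamp <= 0) stop("zero-length epoch window")
  start <- round(eventTimes * fs) + round(window[1] * fs) + 1L
  list(start = start, n = nSamp,
       times = window[1] + (seq_len(nSamp) - 1L) / fs)
}

#' Epoch a continuous signal around events
#'
#' Extracts half-open windows \code{[tPre, tPost)} around each event:
#' exactly \code{fs * (tPost - tPre)} samples per trial, the event sample at
#' index \code{fs * |tPre| + 1} for negative \code{tPre}. Trials whose
#' window leaves the recording are dropped (reported via the \code{"kept"}
#' attribute).
#'
#' @param x numeric vector, or samples x frequency matrix (e.g., one plane
#'   of a \code{\link{morletTFR}} result)
#' @param eventTimes event onsets in seconds
#' @param window length-2 numeric \code{c(tPre, tPost)} relative to the
#'   event
#' @param fs sampling rate (Hz)
#' @return time x trial matrix, or time x frequency x trial array; the
#'   \code{"kept"} attribute indexes the surviving events, \code{"times"}
#'   gives the relative time axis
#' @export
epochSignal <- function(x, eventTimes, window, fs) {
  if (length(eventTimes) == 0) stop("empty event table")
  ix <- .epochIndex(eventTimes, window, fs)
  nTotal <- if (is.matrix(x)) nrow(x) else length(x)
  ok <- ix$start >= 1L & (ix$start + ix$n - 1L) <= nTotal
  if (!any(ok)) stop("no epoch fits inside the recording")
  starts <- ix$start[ok]
  if (is.matrix(x)) {
    out <- array(NA_real_, c(ix$n, ncol(x), length(starts)))
    for (i in seq_along(starts))
      out[, , i] <- x[starts[i]:(starts[i] + ix$n - 1L), , drop = FALSE]
  } else {
    out <- vapply(starts, function(s) x[s:(s + ix$n - 1L)], numeric(ix$n))
  }
  attr(out, "kept") <- which(ok)
  attr(out, "times") <- ix$times
  out
}

#' Epoch a continuous time-frequency decomposition into a TFMap
#'
#' @param tfr a \code{"ContinuousTFR"} from \code{\link{morletTFR}}
#' @param events per-trial event table carrying \code{feedback_time} and
#'   \code{selection_time}
#' @param window epoch window \code{c(tPre, tPost)} in seconds
#' @param align \code{"feedback"} or \code{"selection"}
#' @return a \linkS4class{TFMap}
#' @export
epochTFR <- function(tfr, events, window = c(-0.5, 2),
                     align = c("feedback", "selection")) {
  align <- match.arg(align)
  times <- events[[paste0(align, "_time")]]
  pw <- epochSignal(tfr$power, times, window, tfr$fs)
  ph <- if (!is.null(tfr$phase))
    epochSignal(tfr$phase, times, window, tfr$fs)
  else array(0, c(0, 0, 0))
  kept <- attr(pw, "kept")
  new("TFMap", power = unclass(pw)[, , , drop = FALSE],
      phase = if (length(ph)) unclass(ph)[, , , drop = FALSE] else array(0, c(0, 0, 0)),
      times = attr(pw, "times"), freqs = tfr$freqs,
      events = events[kept, , drop = FALSE])
}

#' Epoch a band envelope into a BandEnvelope
#'
#' @param env continuous envelope from \code{\link{gaborHAA}}
#' @param events per-trial event table
#' @param window epoch window in seconds
#' @param align \code{"feedback"} or \code{"selection"}
#' @param fs sampling rate (Hz)
#' @param band band edges (defaults to the envelope's \code{"band"}
#'   attribute)
#' @return a \linkS4class{BandEnvelope}
#' @export
epochEnvelope <- function(env, events, window = c(0, 2),
                          align = c("feedback", "selection"), fs,
                          band = attr(env, "band")) {
  align <- match.arg(align)
  times <- events[[paste0(align, "_time")]]
  am <- epochSignal(as.numeric(env), times, window, fs)
  kept <- attr(am, "kept")
  new("BandEnvelope", amplitude = unclass(am[, , drop = FALSE]),
      times = attr(am, "times"), band = as.numeric(band),
      events = events[kept, , drop = FALSE])
}

#' Epoch every channel of a recording region and stack trials x channels
#'
#' Produces the stacked trial dimension used by the group models (each
#' channel contributes its trials; the events table gains a \code{channel}
#' column).
#'
#' @param rec a \linkS4class{SyntheticRecording}
#' @param region region name
#' @param type \code{"tfr"} (Morlet power) or \code{"band"} (Gabor analytic
#'   amplitude)
#' @param window,align epoch definition
#' @param freqs,band spectral parameters for the chosen type
#' @param channels channel subset (default all)
#' @param decimate keep every \code{decimate}-th time sample (and, for
#'   \code{"tfr"}, every frequency bin of a decimated grid if
#'   \code{freqs} is supplied decimated)
#' @return \linkS4class{TFMap} or \linkS4class{BandEnvelope}
#' @export
epochRecording <- function(rec, region, type = c("tfr", "band"),
                           window = c(-0.5, 2), align = "feedback",
                           freqs = logFreqGrid(), band = c(4, 9),
                           channels = NULL, decimate = 1L) {
  type <- match.arg(type)
  sig <- rec@signals[[region]]
  if (is.null(sig)) stop("unknown region: ", region)
  if (is.null(channels)) channels <- seq_len(nrow(sig))
  pieces <- lapply(channels, function(ch) {
    x <- sig[ch, ]
    if (type == "tfr") {
      tfr <- morletTFR(x, rec@fs, freqs, keepPhase = FALSE)
      m <- epochTFR(tfr, rec@events, window, align)
      m@events$channel <- paste0(region, "ch", ch)
      m
    } else {
      env <- gaborHAA(x, rec@fs, band)
      m <- epochEnvelope(env, rec@events, window, align, rec@fs, band)
      m@events$channel <- paste0(region, "ch", ch)
      m
    }
  })
  if (type == "tfr") {
    pw <- array(unlist(lapply(pieces, function(p) p@power)),
                c(dim(pieces[[1]]@power)[1:2],
                  sum(vapply(pieces, nTrials, 0L))))
    ev <- do.call(rbind, lapply(pieces, function(p) p@events))
    out <- new("TFMap", power = pw, phase = array(0, c(0, 0, 0)),
               times = pieces[[1]]@times, freqs = pieces[[1]]@freqs,
               events = ev)
    if (decimate > 1L) {
      keep <- seq(1L, length(out@times), by = decimate)
      out <- new("TFMap", power = out@power[keep, , , drop = FALSE],
                 phase = array(0, c(0, 0, 0)), times = out@times[keep],
                 freqs = out@freqs, events = out@events)
    }
    out
  } else {
    am <- do.call(cbind, lapply(pieces, function(p) p@amplitude))
    ev <- do.call(rbind, lapply(pieces, function(p) p@events))
    out <- new("BandEnvelope", amplitude = am, times = pieces[[1]]@times,
               band = as.numeric(band), events = ev)
    if (decimate > 1L) {
      keep <- seq(1L, length(out@times), by = decimate)
      out <- new("BandEnvelope",
                 amplitude = out@amplitude[keep, , drop = FALSE],
                 times = out@times[keep], band = out@band,
                 events = out@events)
    }
    out
  }
}
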