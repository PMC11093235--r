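# Scalogram construction: Morlet continuous wavelet power at 16 band
# centers, time-binned to 2000 bins, assembled with the resampled stage
# vector into the fixed 2000 x 16 x 7 model-input tensor.

#' Default scalogram band centers
#'
#' 16 log-spaced centers from 0.5 to 48 Hz. The ladder is configurable
#' everywhere it is consumed; this is the package default.
#'
#' @return numeric vector of 16 ascending frequencies (Hz).
#' @export
defaultBandCenters <- function() {
  exp(seq(log(0.5), log(48), length.out = 16))
}

#' Morlet continuous wavelet power
#'
#' Analytic Morlet CWT (`omega0 = 6`) evaluated by FFT at the requested band
#' centers; returns power (squared modulus), which scales quadratically with
#' signal amplitude. Scales follow the standard center-frequency relation
#' `scale = omega0 / (2 * pi * f)`. Wavelets are amplitude-normalized (unit
#' peak frequency response), so a pure tone produces the same power in its
#' nearest band regardless of frequency, while broadband-noise band power
#' grows with the band's absolute bandwidth.
#'
#' @param channel numeric vector (length > `fs`).
#' @param fs sampling rate, Hz.
#' @param bandCenters band center frequencies, Hz (ascending).
#' @param omega0 Morlet non-dimensional center frequency.
#' @return `length(bandCenters)` x T matrix of strictly positive power.
#' @export
cwtPower <- function(channel, fs = 200, bandCenters = defaultBandCenters(),
                     omega0 = 6) {
  n <- length(channel)
  stopifnot(n > fs)
  if (is.unsorted(bandCenters, strictly = TRUE)) {
    stop("bandCenters must be strictly ascending")
  }
  nf <- stats::nextn(n, c(2, 3, 5))
  x <- c(channel, rep(0, nf - n))
  X <- fft(x)
  omega <- 2 * pi * fs * (0:(nf - 1)) / nf
  pos <- seq_len(floor(nf / 2) + 1)  # non-negative frequencies (analytic wavelet)
  out <- matrix(0, length(bandCenters), n)
  for (b in seq_along(bandCenters)) {
    s <- omega0 / (2 * pi * bandCenters[b])
    psi <- numeric(nf)
    psi[pos] <- exp(-(s * omega[pos] - omega0)^2 / 2)
    w <- fft(X * psi, inverse = TRUE) / nf
    out[b, ] <- Mod(w[seq_len(n)])^2
  }
  pmax(out, .Machine$double.xmin)
}

#' Bin a power matrix into equal-width time bins
#'
#' Mean log10 power within each of `nBins` equal-width bins; when T is not a
#' multiple of `nBins` the last bin absorbs the remainder.
#'
#' @param power bands x T positive power matrix.
#' @param nBins number of time bins (2000 by convention).
#' @return `nBins` x bands matrix of mean log10 power.
#' @export
binTime <- function(power, nBins = 2000) {
  tlen <- ncol(power)
  if (tlen < nBins) stop(sprintf("need at least %d time samples, got %d", nBins, tlen))
  width <- floor(tlen / nBins)
  lp <- log10(power)
  edges <- c((0:(nBins - 1)) * width, tlen)
  out <- matrix(0, nBins, nrow(power))
  for (i in seq_len(nBins)) {
    out[i, ] <- rowMeans(lp[, (edges[i] + 1):edges[i + 1], drop = FALSE])
  }
  out
}

#' Resample a hypnogram to time bins
#'
#' Nearest-epoch assignment by bin-center time, mapped to the `[0, 1]` stage
#' grid (`W=0, N1=0.25, N2=0.5, N3=0.75, REM=1`).
#'
#' @param hypnogram a [Hypnogram-class].
#' @param nBins number of time bins.
#' @return numeric vector of length `nBins`.
#' @export
resampleStages <- function(hypnogram, nBins = 2000) {
  stopifnot(is(hypnogram, "Hypnogram"), nBins >= 1)
  dur <- recordingDuration(hypnogram)
  centers <- (seq_len(nBins) - 0.5) / nBins * dur
  idx <- pmin(floor(centers / hypnogram@epochLenS) + 1, nEpochs(hypnogram))
  unname(STAGE_CODES[stages(hypnogram)[idx]])
}

#' Assemble the model-input tensor
#'
#' Concatenates the six channel scalograms with the stage vector broadcast
#' across the 16-band axis, yielding the fixed 2000 x 16 x 7 input.
#' Channels 1-6 of the result equal the input scalograms exactly.
#'
#' @param scalograms 2000 x 16 x 6 array of binned log10 power.
#' @param stageVec length-2000 stage-code vector from [resampleStages()].
#' @param bandCenters the 16 band centers (Hz).
#' @param meta optional metadata list to attach.
#' @return a [ModelInput-class].
#' @export
assembleInput <- function(scalograms, stageVec,
                          bandCenters = defaultBandCenters(), meta = list()) {
  d <- dim(scalograms)
  if (length(d) != 3 || !identical(d[1:2], c(2000L, 16L)) || d[3] != 6) {
    stop(sprintf("scalograms must be 2000 x 16 x 6 (got %s)", paste(d, collapse = " x ")))
  }
  if (length(stageVec) != 2000) stop("stage vector must have length 2000")
  tensor <- array(0, dim = c(2000, 16, 7))
  tensor[, , 1:6] <- scalograms
  tensor[, , 7] <- matrix(stageVec, 2000, 16)
  new("ModelInput", tensor = tensor, bandCentersHz = bandCenters, meta = meta)
}

#' Build the model input from clean EEG and a hypnogram
#'
#' Convenience composition: per-channel Morlet power, time binning to 2000
#' bins, stage resampling, tensor assembly.
#'
#' @param eeg 6 x N matrix of preprocessed (z-scored) EEG.
#' @param hypnogram the trimmed [Hypnogram-class] matching `eeg`.
#' @param fs sampling rate, Hz.
#' @param bandCenters band centers (Hz).
#' @param meta metadata list to attach (e.g. chronological age).
#' @return a [ModelInput-class].
#' @export
buildModelInput <- function(eeg, hypnogram, fs = 200,
                            bandCenters = defaultBandCenters(), meta = list()) {
  stopifnot(nrow(eeg) == 6)
  scal <- array(0, dim = c(2000, 16, 6))
  for (ch in seq_len(6)) {
    scal[, , ch] <- binTime(cwtPower(eeg[ch, ], fs = fs, bandCenters = bandCenters))
  }
  assembleInput(scal, resampleStages(hypnogram), bandCenters = bandCenters,
                meta = meta)
}
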