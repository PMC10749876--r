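#' Synthesize a stand-in sound spectrogram
#'
#' Generates a reproducible log-compressed, log-spaced-channel spectrogram
#' for one sound identity.  These are synthetic stand-ins for recorded
#' natural-sound spectrograms: each sound id gets a distinct spectral
#' envelope and temporal modulation pattern, silence maps to the constant
#' floor.  Default geometry is 18 channels (about 1/3 octave each) at 100 Hz
#' over 1 s, the representation used by the encoding models.
#'
#' @param soundId integer id; 0 is silence.
#' @param duration duration in seconds (default 1).
#' @param dt bin width in seconds (default 0.01).
#' @param nChannels number of spectral channels (default 18).
#' @param freqRange range of channel center frequencies in Hz.
#' @param family spectral profile family: \code{"natural"} (modulated
#'   broadband, default), \code{"tone"} (single active channel) or
#'   \code{"noise"} (unmodulated band noise).
#' @param floor log-power floor for silence / out-of-band channels.
#' @param seed integer seed; combined with \code{soundId} so that every sound
#'   has a stable signature under one seed.
#' @return a \linkS4class{Spectrogram}.
#' @export
synthesizeSoundSpectrogram <- function(soundId, duration = 1, dt = 0.01,
                                       nChannels = 18L,
                                       freqRange = c(200, 20000),
                                       family = c("natural", "tone", "noise"),
                                       floor = 0, seed = 1L) {
  family <- match.arg(family)
  if (duration <= 0 || dt <= 0 || duration < dt)
    stop("invalid duration/dt")
  nChannels <- as.integer(nChannels)
  if (nChannels < 2L) stop("need at least 2 channels")
  nt <- as.integer(round(duration / dt))
  freqs <- exp(seq(log(freqRange[1]), log(freqRange[2]), length.out = nChannels))
  vals <- matrix(floor, nChannels, nt)
  if (soundId != 0L) {
    ## per-sound deterministic stream, independent of caller's RNG state
    vals <- withLocalSeed(seed * 1000L + as.integer(soundId), {
      tt <- seq_len(nt) * dt
      if (family == "tone") {
        ch <- sample.int(nChannels, 1L)
        vals[ch, ] <- floor + 4
        vals
      } else {
        center <- stats::runif(1, 1, nChannels)
        width <- stats::runif(1, 1.5, 6)
        envelope <- exp(-((seq_len(nChannels) - center)^2) / (2 * width^2))
        if (family == "noise") {
          vals + 4 * envelope %o% rep(1, nt)
        } else {
          ## slow amplitude modulation shared across channels plus per-channel
          ## jitter: gives non-trivial stationarity and spectral correlation
          f1 <- stats::runif(1, 1, 6); f2 <- stats::runif(1, 6, 14)
          common <- 1 + 0.6 * sin(2 * pi * f1 * tt + stats::runif(1, 0, 2 * pi)) +
                        0.3 * sin(2 * pi * f2 * tt + stats::runif(1, 0, 2 * pi))
          jitter <- matrix(stats::rnorm(nChannels * nt, sd = 0.15), nChannels, nt)
          phase <- stats::runif(nChannels, 0, 2 * pi)
          chmod <- 1 + 0.25 * sin(outer(phase, 2 * pi * f1 * tt, FUN = "+"))
          pmax(vals + 4 * (envelope %o% common) * pmax(chmod, 0) + jitter, floor)
        }
      }
    })
  }
  new("Spectrogram", values = vals, channelFreqs = freqs, dt = dt)
}

#' Descriptive sound metrics from a spectrogram
#'
#' Computes the three spectro-temporal descriptors used to characterize the
#' sound library: bandwidth (octave span of the frequencies holding the
#' central 70\% of total spectral power, 15th to 85th percentiles),
#' temporal stationarity (standard deviation over time of each spectral
#' channel within the 70\%-bandwidth regime, averaged over those channels)
#' and spectral correlation (mean pairwise Pearson correlation over time
#' among the in-band channels).
#'
#' Channels are treated as abutting bins on the log2-frequency axis (bin
#' width = channel spacing); the cumulative power distribution is linearly
#' interpolated within bins, so a flat spectrum spanning 6 octaves of bin
#' extent has bandwidth 0.7 * 6 = 4.2 octaves.
#'
#' @param spec a \linkS4class{Spectrogram} with >= 2 time bins.
#' @return list with \code{bandwidth} (octaves), \code{temporalStationarity}
#'   (std units), \code{spectralCorrelation} (Pearson r, NA if fewer than two
#'   in-band channels vary over time), and \code{inBand} (logical per channel).
#' @export
computeSoundMetrics <- function(spec) {
  stopifnot(is(spec, "Spectrogram"))
  v <- spec@values
  if (ncol(v) < 2L) stop("need at least 2 time bins")
  chPower <- rowSums(v)
  total <- sum(chPower)
  if (total <= 0) stop("undefined-metric: zero total power")
  lf <- log2(spec@channelFreqs)
  d <- diff(lf)
  ## bin edges on the log2-frequency axis (end bins extended half a spacing)
  edges <- c(lf[1] - d[1] / 2, lf[-length(lf)] + d / 2,
             lf[length(lf)] + d[length(d)] / 2)
  cum <- c(0, cumsum(chPower)) / total
  pct <- function(q) stats::approx(cum, edges, xout = q, ties = "ordered")$y
  lo <- pct(0.15); hi <- pct(0.85)
  bandwidth <- hi - lo
  inBand <- lf >= lo & lf <= hi
  if (!any(inBand)) inBand <- seq_along(lf) == which.max(chPower)
  bandVals <- v[inBand, , drop = FALSE]
  stationarity <- mean(apply(bandVals, 1L, stats::sd))
  varying <- apply(bandVals, 1L, stats::sd) > 0
  spectralCorrelation <- if (sum(varying) >= 2L) {
    cm <- stats::cor(t(bandVals[varying, , drop = FALSE]))
    mean(cm[upper.tri(cm)])
  } else NA_real_
  list(bandwidth = bandwidth, temporalStationarity = stationarity,
       spectralCorrelation = spectralCorrelation, inBand = inBand)
}
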