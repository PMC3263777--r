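#' Welch power spectral density
#'
#' Hann-tapered segment-averaged periodogram (one-sided density). The default
#' analysis settings of the sweep protocol are 2 s segments with 50% overlap.
#'
#' @param x numeric series.
#' @param sample_rate sampling rate (Hz).
#' @param segment_s segment length (s).
#' @param overlap_fraction overlap between consecutive segments, in \[0, 1).
#' @param demean subtract the mean of each segment?
#' @param db return power in dB relative to the largest value?
#' @return data.frame with `frequency` (Hz) and `power` (units^2/Hz, or dB).
#' @export
psd_welch <- function(x, sample_rate, segment_s = 2, overlap_fraction = 0.5,
                      demean = TRUE, db = FALSE) {
  nseg <- floor(segment_s * sample_rate)
  if (nseg < 8) stop("segment too short")
  if (length(x) < nseg) stop("series shorter than one segment")
  step <- max(1L, floor(nseg * (1 - overlap_fraction)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / nseg)   # Hann taper
  U <- sum(w^2)
  nf <- nseg %/% 2
  acc <- numeric(nf + 1L)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1L)]
    if (demean) seg <- seg - mean(seg)
    X <- stats::fft(seg * w)
    P <- Mod(X[1:(nf + 1L)])^2 / (U * sample_rate)
    P[2:nf] <- 2 * P[2:nf]                              # one-sided
    acc <- acc + P
  }
  pow <- acc / length(starts)
  freq <- (0:nf) * sample_rate / nseg
  if (db) pow <- 10 * log10(pow / max(pow))
  data.frame(frequency = freq, power = pow)
}

#' -3 dB frequency of a low-pass power spectrum
#'
#' Estimates the frequency at which the spectrum falls to half of its
#' low-frequency plateau level: the plateau is the mean power below
#' `plateau_to * f_guess`, the spectrum is smoothed with a running mean, and
#' the half-power crossing is located by linear interpolation.
#'
#' @param psd data.frame from [psd_welch()] (linear power).
#' @param f_guess rough scale of the expected cut-off (Hz) used to set the
#'   plateau band.
#' @param plateau_to upper edge of the plateau band as a fraction of `f_guess`.
#' @param smooth half-width (bins) of the running-mean smoother.
#' @return estimated -3 dB frequency (Hz).
#' @export
psd_minus3db <- function(psd, f_guess, plateau_to = 0.4, smooth = 5) {
  p <- psd$power
  if (smooth > 0) {
    k <- 2 * smooth + 1
    p <- stats::filter(p, rep(1 / k, k), sides = 2)
  }
  ok <- !is.na(p)
  f <- psd$frequency[ok]; p <- p[ok]
  plateau <- mean(p[f > 0 & f <= plateau_to * f_guess])
  target <- plateau / 2
  above <- p >= target
  cross <- which(above[-length(above)] & !above[-1] & f[-1] > plateau_to * f_guess)
  if (!length(cross)) stop("no -3 dB crossing found")
  i <- cross[1]
  f[i] + (target - p[i]) * (f[i + 1] - f[i]) / (p[i + 1] - p[i])
}
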