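#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (\code{signal::filtfilt}), so the net filter has zero group delay and a
#' symmetric impulse response.
#'
#' @param x numeric vector
#' @param lo,hi band edges in Hz; \code{0 < lo < hi < fs/2}
#' @param fs sampling rate (Hz)
#' @param order polynomial order of the band-pass (even; default 4)
#' @return filtered signal, same length as \code{x}
#' @export
bandpass <- function(x, lo, hi, fs, order = 4L) {
  if (!(lo > 0 && lo < hi && hi < fs / 2)) stop("invalid band")
  if (order %% 2L != 0L) stop("order must be even for a band-pass")
  bf <- signal::butter(order / 2L, c(lo, hi) * 2 / fs, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Analytic signal via the Hilbert transform
#'
#' FFT construction: positive frequencies doubled, negative zeroed. The
#' magnitude is the instantaneous amplitude envelope and the argument the
#' instantaneous phase of \code{x}.
#'
#' @param x real numeric vector
#' @return complex vector of the same length
#' @export
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Unit-sum Gaussian smoothing kernel
#'
#' Discrete Gaussian taper of length \code{len_s} seconds with width factor
#' \code{alpha}: the taper's standard deviation is \code{(L-1)/(2*alpha)}
#' samples, the convention used by window-design routines. Normalized to unit
#' sum so convolution preserves the mean level.
#'
#' @param alpha width factor (larger = narrower Gaussian)
#' @param len_s kernel length in seconds
#' @param fs sampling rate (Hz)
#' @return numeric vector of weights summing to 1
#' @export
gauss_kernel <- function(alpha = 2.0, len_s = 0.2, fs = 1000) {
  L <- max(3L, round(len_s * fs))
  if (L %% 2L == 0L) L <- L + 1L  # odd length keeps the smoother centered
  n <- seq(-(L - 1) / 2, (L - 1) / 2)
  sd <- (L - 1) / (2 * alpha)
  k <- exp(-0.5 * (n / sd)^2)
  k / sum(k)
}

# centered moving-average style convolution (same length as input)
.conv_same <- function(x, k) {
  L <- length(k); half <- (L - 1L) %/% 2L
  # pad by edge replication to avoid spurious edge dips
  xp <- c(rep(x[1], half), x, rep(x[length(x)], L - 1L - half))
  as.numeric(stats::filter(xp, rev(k), sides = 1))[L:(length(xp))][
    seq_along(x)]
}

#' Welch power spectral density
#'
#' Averaged periodogram with Hann-tapered segments and 50\% overlap; the
#' staging module's band powers are means of this PSD over a band.
#'
#' @param x numeric vector
#' @param fs sampling rate (Hz)
#' @param seg_s segment length in seconds (default 1)
#' @return list with \code{freq} (Hz) and \code{psd} (power per Hz)
#' @export
pwelch <- function(x, fs, seg_s = 1) {
  L <- round(seg_s * fs)
  if (length(x) < L) stop("signal shorter than one segment")
  step <- max(1L, L %/% 2L)
  starts <- seq(1L, length(x) - L + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, L - 1) / (L - 1)))  # Hann
  U <- sum(w^2)
  nf <- L %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- abs(stats::fft(seg))^2 / (U * fs)
    acc <- acc + P[1:nf]
  }
  psd <- acc / length(starts)
  # fold negative frequencies into the one-sided spectrum
  if (nf > 2L) psd[2:(nf - 1L)] <- 2 * psd[2:(nf - 1L)]
  list(freq = seq(0, nf - 1L) * fs / L, psd = psd)
}

#' Mean PSD over a frequency band
#' @param x numeric vector
#' @param fs sampling rate (Hz)
#' @param band length-2 numeric, band edges in Hz (inclusive)
#' @param seg_s Welch segment length (s)
#' @return mean power density over the band
#' @export
band_power <- function(x, fs, band, seg_s = 1) {
  p <- pwelch(x, fs, seg_s)
  sel <- p$freq >= band[1] & p$freq <= band[2]
  mean(p$psd[sel])
}
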