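#' Construct a spectral estimate
#'
#' @param frequencies strictly increasing Hz grid.
#' @param power non-negative spectral density per bin (uV^2/Hz).
#' @param band `(f_low, f_high)` Hz the estimate is restricted to.
#' @return a `spectral_estimate` object.
#' @export
spectral_estimate <- function(frequencies, power, band = range(frequencies)) {
  if (any(diff(frequencies) <= 0)) stop("frequencies must be strictly increasing")
  if (any(power < 0)) stop("power must be non-negative")
  structure(list(frequencies = frequencies, power = power, band = band),
            class = "spectral_estimate")
}

#' Welch power spectral density of an epoch
#'
#' Averaged modified periodogram (Hann window, 50% overlap), one-sided and
#' scaled as a density so that `sum(power) * df` equals the signal variance
#' (Parseval, within windowing tolerance). Bins outside `band` are dropped.
#'
#' @param epoch an [epoched_signal()] or numeric vector.
#' @param band `(f_low, f_high)` in Hz.
#' @param nfft segment length in samples.
#' @param sampling_rate required when `epoch` is a bare vector.
#' @return a [spectral_estimate()].
#' @export
estimate_spectrum <- function(epoch, band = NULL, nfft = 1024, sampling_rate = NULL) {
  if (inherits(epoch, "epoched_signal")) {
    x <- epoch$samples; fs <- epoch$sampling_rate
  } else {
    x <- as.numeric(epoch); fs <- sampling_rate
  }
  if (is.null(fs)) stop("sampling rate required")
  if (is.null(band)) band <- c(0, fs / 2)
  if (band[2] > fs / 2 + 1e-9) stop("band outside Nyquist range")
  n <- length(x)
  nfft <- min(nfft, n)
  step <- max(1, floor(nfft / 2))
  starts <- seq(1, n - nfft + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nfft - 1) / (nfft - 1))   # Hann
  u <- sum(w^2)
  nf <- floor(nfft / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1)] * w
    P <- abs(stats::fft(seg))^2 / (fs * u)
    p1 <- P[seq_len(nf)]
    # one-sided: double everything except DC (and Nyquist when nfft even)
    dbl <- rep(2, nf); dbl[1] <- 1
    if (nfft %% 2 == 0) dbl[nf] <- 1
    acc <- acc + p1 * dbl
  }
  pow <- acc / length(starts)
  freq <- seq(0, nf - 1) * fs / nfft
  keep <- freq >= band[1] & freq <= band[2]
  if (!any(keep)) stop("band contains no frequency bins")
  spectral_estimate(freq[keep], pow[keep], band)
}

#' Weighted spectral median frequency (WSMF)
#'
#' Smallest frequency at which the cumulative (optionally weighted) power
#' reaches 50% of the total, with linear interpolation between bins. With
#' uniform weights this is the plain spectral median frequency.
#'
#' @param spectrum a [spectral_estimate()].
#' @param weighting optional per-bin weight vector (recycled), default uniform.
#' @return median frequency in Hz.
#' @export
wsmf <- function(spectrum, weighting = NULL) {
  stopifnot(inherits(spectrum, "spectral_estimate"))
  p <- spectrum$power
  if (!is.null(weighting)) p <- p * rep_len(weighting, length(p))
  tot <- sum(p)
  if (tot <= 0) stop("zero total weighted power: WSMF undefined")
  cum <- cumsum(p)
  half <- tot / 2
  k <- which(cum >= half)[1]
  f <- spectrum$frequencies
  if (k == 1) return(f[1])
  # interpolate inside the bin that crosses 50%
  f[k - 1] + (half - cum[k - 1]) / (cum[k] - cum[k - 1]) * (f[k] - f[k - 1])
}

#' Quotient of spectral median frequencies (qWSMF)
#'
#' WSMF over `band_a` divided by WSMF over `band_b`, both computed from the
#' same epoch. Default bands: beta band 8-30 Hz over the full analysis band.
#'
#' @param epoch an [epoched_signal()].
#' @param band_a,band_b Hz bands for numerator and denominator.
#' @param weighting optional weights passed to [wsmf()].
#' @return dimensionless ratio.
#' @export
qwsmf <- function(epoch, band_a = c(8, 30), band_b = c(0.5, 49), weighting = NULL) {
  wa <- wsmf(estimate_spectrum(epoch, band_a), weighting)
  wb <- wsmf(estimate_spectrum(epoch, band_b), weighting)
  wa / wb
}

#' Normalized spectral entropy
#'
#' Shannon entropy of the bin-normalized power distribution over the band,
#' divided by `log(number of bins)` so the value lies in `[0, 1]`: 0 for a
#' single-bin (pure oscillation) spectrum, 1 for a flat one.
#'
#' @param spectrum a [spectral_estimate()].
#' @return value in `[0, 1]`.
#' @export
spectral_entropy <- function(spectrum) {
  stopifnot(inherits(spectrum, "spectral_estimate"))
  p <- spectrum$power
  tot <- sum(p)
  if (tot <= 0) stop("zero total power: spectral entropy undefined")
  if (length(p) == 1) return(0)
  q <- p / tot
  q <- q[q > 0]
  -sum(q * log(q)) / log(length(p))
}
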