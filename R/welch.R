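#' Canonical EEG frequency bands
#'
#' @return Data frame with columns `name`, `low`, `high` (Hz): delta
#'   0.5-4, theta 4-8, alpha 8-12, beta 12-30, gamma 30-70.
#' @export
band_definitions <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             low = c(0.5, 4, 8, 12, 30),
             high = c(4, 8, 12, 30, 70),
             stringsAsFactors = FALSE)
}

#' Welch power spectral density
#'
#' Welch's method with a Hann window, 50% overlap and per-segment constant
#' detrending, one-sided density scaling (units x^2/Hz).
#'
#' @param x Numeric time series.
#' @param fs Sampling frequency (Hz).
#' @param nperseg Segment length in samples (default 1000).
#' @return List with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, nperseg = 1000) {
  n <- length(x)
  if (n < 2 * nperseg)
    stop("time series must be at least two segments long")
  step <- nperseg %/% 2
  nseg <- (n - nperseg) %/% step + 1
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nperseg) / nperseg))
  scale <- 1 / (fs * sum(w^2))
  nf <- nperseg %/% 2 + 1
  acc <- numeric(nf)
  for (k in seq_len(nseg)) {
    seg <- x[((k - 1) * step + 1):((k - 1) * step + nperseg)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)[seq_len(nf)]
    p <- scale * Mod(X)^2
    p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]
    acc <- acc + p
  }
  list(freq = (seq_len(nf) - 1) * fs / nperseg, psd = acc / nseg)
}

#' Mean band power from a Welch spectrum
#'
#' Arithmetic mean of the Welch PSD bins with frequency in
#' `[band$low, band$high)`.
#'
#' @param x Numeric time series.
#' @param fs Sampling frequency (Hz).
#' @param segment Welch segment length in samples.
#' @param band Either one row of [band_definitions()] (or any list with
#'   `low`, `high`) or a numeric vector `c(low, high)`.
#' @return Mean PSD in the band (x^2/Hz), nonnegative.
#' @export
welch_band_power <- function(x, fs, segment = 1000, band) {
  if (is.numeric(band) && length(band) == 2)
    band <- list(low = band[1], high = band[2])
  if (!(band$low > 0 && band$high > band$low))
    stop("band edges must satisfy 0 < low < high")
  if (band$high > fs / 2)
    stop("band extends above the Nyquist frequency")
  ps <- welch_psd(x, fs, segment)
  idx <- ps$freq >= band$low & ps$freq < band$high
  mean(ps$psd[idx])
}

# Internal: mean PSD of a series in each canonical band, plus the peak
# frequency in a search range.
.band_profile <- function(x, fs, segment, bands = band_definitions()) {
  ps <- welch_psd(x, fs, segment)
  vapply(seq_len(nrow(bands)), function(i) {
    idx <- ps$freq >= bands$low[i] & ps$freq < bands$high[i]
    mean(ps$psd[idx])
  }, numeric(1))
}

#' Dominant spectral peak frequency
#'
#' Frequency of the maximum Welch PSD bin within a search range.
#'
#' @param x Numeric time series.
#' @param fs Sampling frequency (Hz).
#' @param range Numeric `c(low, high)` search range in Hz.
#' @param segment Welch segment length in samples.
#' @return Peak frequency in Hz (resolution `fs/segment`).
#' @export
spectral_peak <- function(x, fs, range = c(1, 30), segment = 1000) {
  ps <- welch_psd(x, fs, segment)
  idx <- which(ps$freq >= range[1] & ps$freq <= range[2])
  ps$freq[idx][which.max(ps$psd[idx])]
}
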