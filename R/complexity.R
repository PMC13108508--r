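#' Median binarization of a time series
#'
#' Values strictly below the epoch median become `0`; values at or above
#' it become `1` (so a constant series maps to all ones).
#'
#' @param x Non-empty numeric vector.
#' @return Integer vector of 0/1 symbols.
#' @export
binarize_median <- function(x) {
  if (!length(x)) stop("empty series")
  as.integer(x >= median(x))
}

# Internal: accept a 0/1 integer vector or a "0101" character string.
.as_bits <- function(bits) {
  if (is.character(bits) && length(bits) == 1)
    bits <- as.integer(strsplit(bits, "")[[1]])
  bits <- as.integer(bits)
  if (any(is.na(bits)) || any(!bits %in% c(0L, 1L)))
    stop("input must be a binary (0/1) sequence")
  bits
}

#' Normalized Lempel-Ziv-Welch complexity
#'
#' Compresses the binary sequence with the LZW algorithm (dictionary
#' initialized with the two symbols) and returns the description length per
#' input character, `rho0 = l_LZW / n` with
#' `l_LZW = codes * ceil(log2(dictionary size))` (fixed-width coding with
#' the final dictionary).
#'
#' @param bits Binary sequence: 0/1 vector or a character string of 0s
#'   and 1s, length >= 2.
#' @return `rho0` in bits per character.
#' @export
lzw_rho0 <- function(bits) {
  bits <- .as_bits(bits)
  n <- length(bits)
  if (n < 2) stop("sequence must have length >= 2")
  st <- lzw_encode_stats(bits)
  codes <- st[1]; dict <- st[2]
  (codes * ceiling(log2(dict))) / n
}

#' Entropy rate of a binary sequence at a Markov order
#'
#' Plug-in (maximum-likelihood) estimate of the conditional entropy
#' `H(X_t | X_{t-1}, ..., X_{t-n})` from empirical (n+1)-gram frequencies;
#' order 0 is the marginal symbol entropy.  Base-2 logarithm (bits).
#'
#' @param bits Binary sequence (0/1 vector or character string).
#' @param order Markov order `n` in 0..5 (or higher if the sequence allows).
#' @return Entropy rate in bits.
#' @export
entropy_rate <- function(bits, order = 0) {
  bits <- .as_bits(bits)
  n <- length(bits)
  if (order < 0) stop("order must be >= 0")
  if (n < 100 * 2^order)
    stop(sprintf("sequence of length %d too short for order %d (need >= %d)",
                 n, order, 100 * 2^order))
  m <- order + 1
  # encode each m-gram as an integer
  ng <- integer(n - m + 1)
  for (k in seq_len(m)) ng <- ng * 2L + bits[k:(n - m + k)]
  joint <- tabulate(ng + 1L, nbins = 2^m) / length(ng)
  H <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  if (order == 0) return(H(joint))
  ctx <- integer(n - order + 1)
  for (k in seq_len(order)) ctx <- ctx * 2L + bits[k:(n - order + k)]
  ctx <- ctx[seq_len(length(ng))]  # contexts aligned with the m-grams
  cond <- tabulate(ctx + 1L, nbins = 2^order) / length(ctx)
  H(joint) - H(cond)
}

#' Shannon spectral entropy
#'
#' Normalizes a PSD vector to unit sum and computes
#' `H = -sum(p * log(p))` with the stated logarithm base (default 2).
#'
#' @param psd Nonnegative PSD vector, not all zero.
#' @param base Logarithm base (default 2, bits).
#' @return Spectral entropy; lies in `[0, log(length(psd), base)]`.
#' @export
spectral_entropy <- function(psd, base = 2) {
  if (any(!is.finite(psd)) || any(psd < 0))
    stop("PSD bins must be finite and nonnegative")
  s <- sum(psd)
  if (s <= 0) stop("PSD must contain power")
  p <- psd / s
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Zero-phase band-pass filter
#'
#' Fourth-order Butterworth band-pass applied forward and backward
#' (zero phase).
#'
#' @param x Numeric series.
#' @param fs Sampling frequency (Hz).
#' @param low,high Band edges (Hz); `high` must be below Nyquist.
#' @return Filtered series.
#' @export
bandpass_filter <- function(x, fs, low = 0.5, high = 100) {
  if (high >= fs / 2) stop("high edge must be below the Nyquist frequency")
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Complexity and entropy metrics of simulated EEG
#'
#' Reproduces the broadband-epoch complexity analysis: a single epoch of
#' EEG is band-passed to 0.5-100 Hz, each channel is binarized at its
#' median, the channel strings are concatenated, and the LZW complexity
#' `rho0` plus entropy rates for Markov orders 0..5 are computed on the
#' concatenated string.  Spectral entropy is computed from the
#' channel-averaged Welch PSD of the epoch.
#'
#' @param eeg A [project_eeg()] result.
#' @param epoch Epoch length in seconds (default 5); taken from the start
#'   of the record.
#' @param band Broadband range (Hz), default `c(0.5, 100)`.
#' @param orders Markov orders for the entropy rate (default 0:5).
#' @param segment Welch segment length for the spectral entropy.
#' @return An object of class `complexity_metrics`: `rho0`,
#'   `entropy_rate` (named vector `h0`, `h1`, ...), `spectral_entropy`.
#' @export
eeg_complexity_suite <- function(eeg, epoch = 5, band = c(0.5, 100),
                                 orders = 0:5, segment = 1000) {
  if (length(eeg$channels) < 1) stop("EEG record has no channels")
  n_ep <- as.integer(round(epoch * eeg$fs))
  if (nrow(eeg$signals) < n_ep) stop("EEG record shorter than the epoch")
  seg <- eeg$signals[seq_len(n_ep), , drop = FALSE]
  filt <- apply(seg, 2, bandpass_filter, fs = eeg$fs,
                low = band[1], high = band[2])
  bits <- as.integer(unlist(apply(filt, 2, binarize_median,
                                  simplify = FALSE), use.names = FALSE))
  h <- vapply(orders, function(o) entropy_rate(bits, o), numeric(1))
  names(h) <- paste0("h", orders)
  psd_mat <- vapply(seq_len(ncol(filt)), function(i) {
    welch_psd(filt[, i], eeg$fs, min(segment, n_ep %/% 2))$psd
  }, numeric(min(segment, n_ep %/% 2) %/% 2 + 1))
  se <- spectral_entropy(rowMeans(psd_mat))
  structure(list(rho0 = lzw_rho0(bits), entropy_rate = h,
                 spectral_entropy = se),
            class = "complexity_metrics")
}

#' @export
print.complexity_metrics <- function(x, ...) {
  cat(sprintf("rho0 = %.3f bits/char; spectral entropy = %.3f bits\n",
              x$rho0, x$spectral_entropy))
  cat("entropy rate:", paste(sprintf("%s=%.3f", names(x$entropy_rate),
                                     x$entropy_rate), collapse = " "), "\n")
  invisible(x)
}
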