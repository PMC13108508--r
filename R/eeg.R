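#' Equivalent dipole strength from pyramidal activity
#'
#' Linear combination of the mean-centered P1 and P2 membrane potentials of
#' each parcel, a declared stand-in for detailed multicompartment current
#' source density modeling.  Default weights strongly emphasize the deep
#' pyramidal population (`w_P1 = 1`, `w_P2 = 0.25`) so the simulated EEG
#' spectrum is alpha-dominated, as empirical scalp EEG is (see vignette).
#'
#' @param nts A [simulate_network()] result storing `vP1` and `vP2`.
#' @param w_P1,w_P2 Layer weights.
#' @return An object of class `lanmm_dipoles`: `strength` (samples x
#'   parcels), `fs`, `labels`, `psi`.
#' @export
dipole_strength <- function(nts, w_P1 = 1, w_P2 = 0.25) {
  if (is.null(nts$vP1) || is.null(nts$vP2))
    stop("run must store vP1 and vP2 to compute dipoles")
  keep <- seq.int(floor(nts$discard * nts$fs) + 1, nrow(nts$vP1))
  center <- function(m) sweep(m, 2, colMeans(m))
  d <- w_P1 * center(nts$vP1[keep, , drop = FALSE]) +
       w_P2 * center(nts$vP2[keep, , drop = FALSE])
  structure(list(strength = d, fs = nts$fs, labels = nts$labels,
                 psi = nts$psi),
            class = "lanmm_dipoles")
}

#' Project dipoles to scalp EEG through a leadfield
#'
#' Multiplies the parcel dipole strengths by the channels x parcels gain
#' matrix and applies an average reference (each sample re-referenced to
#' the channel mean).
#'
#' @param dipoles A [dipole_strength()] result.
#' @param leadfield Channels x parcels numeric matrix; row names are
#'   channel labels.
#' @return An object of class `lanmm_eeg`: `signals` (samples x channels),
#'   `fs`, `channels`, `psi`, `reference = "average"`.
#' @export
project_eeg <- function(dipoles, leadfield) {
  lf <- as.matrix(leadfield)
  if (any(!is.finite(lf))) stop("leadfield must be finite")
  if (ncol(lf) != ncol(dipoles$strength))
    stop(sprintf("leadfield has %d parcels but dipoles have %d",
                 ncol(lf), ncol(dipoles$strength)))
  eeg <- dipoles$strength %*% t(lf)
  eeg <- eeg - rowMeans(eeg)
  channels <- rownames(lf)
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(lf)))
  colnames(eeg) <- channels
  structure(list(signals = eeg, fs = dipoles$fs, channels = channels,
                 psi = dipoles$psi, reference = "average"),
            class = "lanmm_eeg")
}

#' @export
print.lanmm_eeg <- function(x, ...) {
  cat(sprintf("Simulated EEG: %d channels, %.1f s at %g Hz (psi = %g)\n",
              length(x$channels), nrow(x$signals) / x$fs, x$fs, x$psi))
  invisible(x)
}

#' Per-channel band-power table of an EEG record
#'
#' Mean Welch PSD of every channel in each canonical band.
#'
#' @param eeg A [project_eeg()] result.
#' @param bands Band table as in [band_definitions()].
#' @param segment Welch segment length (samples).
#' @return Tidy data frame (channel, band, mean_psd).
#' @export
channel_band_table <- function(eeg, bands = band_definitions(),
                               segment = 1000) {
  if (any(bands$high > eeg$fs / 2))
    stop("band extends above the Nyquist frequency")
  out <- do.call(rbind, lapply(seq_along(eeg$channels), function(i) {
    data.frame(channel = eeg$channels[i], band = bands$name,
               mean_psd = .band_profile(eeg$signals[, i], eeg$fs, segment,
                                        bands),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write a leadfield as delimited text
#'
#' @param leadfield Channels x parcels matrix with channel row names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_leadfield <- function(leadfield, path) write_matrix_tsv(leadfield, path)

#' Read a leadfield from delimited text
#'
#' @param path File written by [write_leadfield()].
#' @return Channels x parcels matrix.
#' @export
read_leadfield <- function(path) read_matrix_tsv(path)
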