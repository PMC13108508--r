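#' Balloon-Windkessel hemodynamic parameters
#'
#' Standard published constants of the hemodynamic model: signal decay
#' `kappa`, autoregulation `gamma`, transit time `tau`, vessel stiffness
#' exponent `alpha`, resting oxygen extraction `E0` and resting venous
#' volume fraction `V0`.
#'
#' @param kappa Signal decay rate (1/s).
#' @param gamma Autoregulatory feedback rate (1/s).
#' @param tau Hemodynamic transit time (s).
#' @param alpha Grubb stiffness exponent in `(0, 1]`.
#' @param E0 Resting oxygen extraction fraction.
#' @param V0 Resting venous blood volume fraction.
#' @return An object of class `hemodynamic_parameters`.
#' @export
hemodynamic_parameters <- function(kappa = 0.65, gamma = 0.41, tau = 0.98,
                                   alpha = 0.32, E0 = 0.34, V0 = 0.02) {
  vals <- c(kappa, gamma, tau, alpha, E0, V0)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all hemodynamic parameters must be positive")
  if (alpha > 1) stop("alpha must lie in (0, 1]")
  structure(list(kappa = kappa, gamma = gamma, tau = tau, alpha = alpha,
                 E0 = E0, V0 = V0),
            class = "hemodynamic_parameters")
}

#' BOLD signal from neural drive
#'
#' Integrates the four-state Balloon-Windkessel ODE (vasodilatory signal,
#' inflow, venous volume, deoxyhemoglobin) per parcel with RK4 at the
#' drive's sampling rate and emits the nonlinear BOLD observation
#' downsampled to the output repetition time.  Deterministic.
#'
#' @param drive Samples x parcels matrix of neural drive (typically the
#'   z-scored P1 firing rate, see [neural_drive()]).
#' @param fs Sampling frequency of `drive` (Hz).
#' @param h [hemodynamic_parameters()].
#' @param tr_out Output repetition time (s); must be >= `1/fs`.
#' @return List with `bold` (volumes x parcels), `tr` and parcel labels.
#' @export
bold_from_activity <- function(drive, fs, h = hemodynamic_parameters(),
                               tr_out = 2) {
  drive <- as.matrix(drive)
  if (any(!is.finite(drive))) stop("drive must be finite")
  if (tr_out < 1 / fs) stop("tr_out must be >= 1/fs")
  bold <- balloon_bold(drive, 1 / fs, h$kappa, h$gamma, h$tau, h$alpha,
                       h$E0, h$V0)
  if (any(!is.finite(bold))) stop("hemodynamic states became non-finite")
  step <- as.integer(round(tr_out * fs))
  idx <- seq.int(step, nrow(bold), by = step)
  out <- bold[idx, , drop = FALSE]
  colnames(out) <- colnames(drive)
  list(bold = out, tr = tr_out, labels = colnames(drive))
}

#' Neural drive for the hemodynamic model
#'
#' Extracts the per-parcel z-scored P1 firing rate from a network run,
#' the package's default coupling between neural and hemodynamic activity.
#'
#' @param nts A [simulate_network()] result storing `phiP1`.
#' @return Samples x parcels matrix with zero mean and unit variance per
#'   parcel.
#' @export
neural_drive <- function(nts) {
  x <- nts$phiP1
  if (is.null(x)) stop("run was simulated without storing phiP1")
  scale(x)[, , drop = FALSE]
}

#' Functional connectivity from BOLD series
#'
#' Pearson correlation matrix across parcels after discarding an initial
#' transient.
#'
#' @param bold A [bold_from_activity()] result, or a volumes x parcels
#'   matrix (then `tr` must be given).
#' @param discard Seconds dropped from the start (default 5).
#' @param tr Repetition time, required when `bold` is a bare matrix.
#' @return An `fc_matrix`: correlation matrix with parcel labels.
#' @export
compute_fc <- function(bold, discard = 5, tr = NULL) {
  if (is.list(bold)) {
    tr <- bold$tr
    m <- bold$bold
  } else m <- as.matrix(bold)
  if (is.null(tr)) stop("tr must be supplied for a bare matrix")
  drop_n <- floor(discard / tr)
  if (nrow(m) - drop_n < 2)
    stop("fewer than 2 volumes remain after discarding the transient")
  m <- m[seq.int(drop_n + 1, nrow(m)), , drop = FALSE]
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    labs <- colnames(m)
    if (is.null(labs)) labs <- as.character(which(sds == 0))
    stop("constant BOLD series; correlation undefined for parcel(s): ",
         paste(labs[sds == 0], collapse = ", "))
  }
  fc <- cor(m)
  diag(fc) <- 1
  structure(fc, class = c("fc_matrix", "matrix", "array"))
}

#' Compare two functional-connectivity matrices
#'
#' Root mean squared error and Pearson correlation computed on the upper
#' off-diagonal triangle only.
#'
#' @param a,b FC matrices with identical parcel labels.
#' @return Named numeric vector `c(rmse, pcc)`.
#' @export
fc_similarity <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  if (!identical(dim(a), dim(b))) stop("FC matrices differ in size")
  la <- rownames(a); lb <- rownames(b)
  if (!is.null(la) && !is.null(lb) && !identical(la, lb))
    stop("FC matrices have different parcel labels")
  ut <- upper.tri(a)
  va <- a[ut]; vb <- b[ut]
  c(rmse = sqrt(mean((va - vb)^2)), pcc = cor(va, vb))
}
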