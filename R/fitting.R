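#' Personalize coupling and noise by grid search
#'
#' For every `(G, sigma_c/sigma_i)` grid point and noise realization,
#' simulates the whole-brain model at baseline, generates BOLD, computes
#' functional connectivity, and scores it against the empirical FC.  The
#' returned optimum minimizes the RMSE among grid points satisfying the
#' structural constraint `PCC(simFC, empFC) > PCC(empFC, SC)`; when no
#' point satisfies it, the overall RMSE minimum is returned with
#' `constraint_satisfied = FALSE`.  The best value across noise
#' realizations is selected.
#'
#' @param con A [connectome()].
#' @param empirical_fc Target FC matrix (labels matching the connectome).
#' @param g_grid Numeric vector of candidate `G` values (default 25 points
#'   in `[0, 3]`).
#' @param ratio_grid Candidate `sigma_c/sigma_i` ratios (default 9 points
#'   in `[0, 2]`).
#' @param params Column parameters.
#' @param n_realizations Noise realizations per grid point (default 5).
#' @param duration Simulated seconds per realization (default 300).
#' @param fs Neural sampling rate (Hz).
#' @param tr BOLD repetition time (s).
#' @param sd_total Total e1 noise SD split between common and homotopic
#'   streams (see [noise_sigmas_from_ratio()]).
#' @param decimate Decimation of the stored firing rate before the
#'   hemodynamic step (default 10, i.e. 100 Hz).
#' @param fc_discard Seconds of BOLD discarded before FC (default 5).
#' @param seed Base seed.
#' @return An object of class `lanmm_fit`: optimal `G`, `ratio`, `rmse`,
#'   `pcc`, `constraint_satisfied`, `sc_pcc`, the full `scores` table and
#'   the grids.
#' @export
grid_search_fit <- function(con, empirical_fc,
                            g_grid = seq(0, 3, length.out = 25),
                            ratio_grid = seq(0, 2, length.out = 9),
                            params = lanmm_parameters(),
                            n_realizations = 5, duration = 300, fs = 1000,
                            tr = 2, sd_total = 54, decimate = 10L,
                            fc_discard = 5, seed = 1) {
  if (!length(g_grid) || !length(ratio_grid)) stop("grids must be non-empty")
  sc_pcc <- fc_similarity(empirical_fc, .sc_as_fc(con))[["pcc"]]
  scores <- expand.grid(G = g_grid, ratio = ratio_grid,
                        realization = seq_len(n_realizations))
  scores$rmse <- NA_real_
  scores$pcc <- NA_real_
  scores$constraint <- NA
  for (k in seq_len(nrow(scores))) {
    sig <- noise_sigmas_from_ratio(scores$ratio[k], sd_total)
    net <- network_parameters(G = scores$G[k], sigma_c = sig[["sigma_c"]],
                              sigma_i = sig[["sigma_i"]], psi = 0)
    model <- build_network(con, params, net)
    nts <- tryCatch(
      simulate_network(model, duration = duration, fs = fs,
                       seed = seed + 1000L * scores$realization[k],
                       store = "phiP1", decimate = decimate),
      error = function(e) NULL)
    if (is.null(nts)) next
    bold <- bold_from_activity(neural_drive(nts), fs / decimate, tr_out = tr)
    fc <- compute_fc(bold, discard = fc_discard)
    s <- fc_similarity(fc, empirical_fc)
    scores$rmse[k] <- s[["rmse"]]
    scores$pcc[k] <- s[["pcc"]]
    scores$constraint[k] <- s[["pcc"]] > sc_pcc
  }
  if (all(is.na(scores$rmse))) stop("all grid-point simulations diverged")
  ok <- which(!is.na(scores$rmse) & scores$constraint)
  pool <- if (length(ok)) ok else which(!is.na(scores$rmse))
  best <- pool[which.min(scores$rmse[pool])]
  structure(list(G = scores$G[best], ratio = scores$ratio[best],
                 rmse = scores$rmse[best], pcc = scores$pcc[best],
                 constraint_satisfied = isTRUE(scores$constraint[best]) &&
                   length(ok) > 0,
                 sc_pcc = sc_pcc, scores = scores,
                 g_grid = g_grid, ratio_grid = ratio_grid,
                 n_realizations = n_realizations),
            class = "lanmm_fit")
}

# Internal: structural connectome recast as a correlation-like matrix for
# the constraint comparison (unit diagonal, same labels).
.sc_as_fc <- function(con) {
  m <- con$weights
  diag(m) <- 1
  m
}

#' @export
print.lanmm_fit <- function(x, ...) {
  cat(sprintf(
    "Whole-brain fit: G* = %.3g, (sigma_c/sigma_i)* = %.3g\n", x$G, x$ratio))
  cat(sprintf("RMSE = %.3f, PCC = %.3f (SC-FC PCC = %.3f), constraint %s\n",
              x$rmse, x$pcc, x$sc_pcc,
              if (x$constraint_satisfied) "satisfied" else "NOT satisfied"))
  invisible(x)
}

#' Dynamic-FC variance against phase-randomized surrogates
#'
#' Computes sliding-window FC, summarizes its temporal fluctuation as the
#' mean (over parcel pairs) variance of FC across windows, and compares the
#' observed statistic with surrogate BOLD obtained by independent phase
#' randomization of each parcel series (power spectra preserved).
#'
#' @param bold A [bold_from_activity()] result or volumes x parcels matrix.
#' @param tr Repetition time (required for a bare matrix).
#' @param window Window length (s).
#' @param step Window step (s).
#' @param n_surrogates Number of surrogate datasets (default 100).
#' @param seed Integer seed for the surrogate phases.
#' @return List with `observed`, `surrogate` (vector), and `exceeds`
#'   (observed above the surrogate 95th percentile).
#' @export
dfc_variance_test <- function(bold, tr = NULL, window = 30, step = 5,
                              n_surrogates = 100, seed = 1) {
  if (is.list(bold)) { tr <- bold$tr; m <- bold$bold } else m <- as.matrix(bold)
  if (is.null(tr)) stop("tr must be supplied for a bare matrix")
  wlen <- floor(window / tr)
  wstep <- max(1L, floor(step / tr))
  if (wlen > nrow(m)) stop("window longer than the series")
  starts <- seq.int(1L, nrow(m) - wlen + 1L, by = wstep)
  if (length(starts) < 5) stop("series too short for 5 sliding windows")
  stat <- function(mm) {
    ut <- upper.tri(diag(ncol(mm)))
    vals <- vapply(starts, function(s0) {
      cor(mm[s0:(s0 + wlen - 1L), , drop = FALSE])[ut]
    }, numeric(sum(ut)))
    mean(apply(vals, 1, var))
  }
  observed <- stat(m)
  set.seed(seed)
  surrogate <- vapply(seq_len(n_surrogates), function(b) {
    stat(apply(m, 2, .phase_randomize))
  }, numeric(1))
  list(observed = observed, surrogate = surrogate,
       exceeds = observed > quantile(surrogate, 0.95))
}

# Internal: phase randomization preserving the amplitude spectrum (and
# conjugate symmetry, so the surrogate is real).
.phase_randomize <- function(x) {
  n <- length(x)
  X <- fft(x)
  half <- if (n %% 2 == 0) seq.int(2, n / 2) else seq.int(2, (n + 1) / 2)
  ph <- runif(length(half), 0, 2 * pi)
  X[half] <- Mod(X[half]) * exp(1i * ph)
  if (n %% 2 == 0) X[n / 2 + 1] <- Mod(X[n / 2 + 1])
  X[n + 2 - half] <- Conj(X[half])
  Re(fft(X, inverse = TRUE)) / n
}
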