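#' Whole-brain network coupling parameters
#'
#' Global coupling gain `G`, the relative weights of the three long-range
#' projection types (`P1 -> P1` lateral 0.5, `P1 -> P2` feedback 0.5,
#' `P2 -> P2` feedforward 1), the common/homotopic noise standard
#' deviations driving the pyramidal `e1` inputs, and the psychedelic dose.
#'
#' @param G Global coupling gain (dimensionless, >= 0).
#' @param w_lateral,w_feedback,w_feedforward Relative projection weights.
#' @param sigma_c Standard deviation of the noise stream common to all
#'   parcels (1/s).
#' @param sigma_i Standard deviation of the noise stream shared within each
#'   homotopic pair (1/s).
#' @param psi Psychedelic dose in `[0, 1]`.
#' @return An object of class `network_parameters`.
#' @export
network_parameters <- function(G = 1, w_lateral = 0.5, w_feedback = 0.5,
                               w_feedforward = 1, sigma_c = 38,
                               sigma_i = 38, psi = 0) {
  if (!is.finite(G) || G < 0) stop("G must be >= 0")
  if (sigma_c < 0 || sigma_i < 0) stop("noise SDs must be >= 0")
  if (psi < 0 || psi > 1) stop("psi must lie in [0, 1]")
  structure(list(G = G, w_lateral = w_lateral, w_feedback = w_feedback,
                 w_feedforward = w_feedforward, sigma_c = sigma_c,
                 sigma_i = sigma_i, psi = psi),
            class = "network_parameters")
}

#' Noise SDs from a common-to-homotopic ratio
#'
#' The personalization fits the ratio `sigma_c / sigma_i` with the total
#' noise variance held fixed; this helper converts a ratio into the two
#' standard deviations such that `sigma_c^2 + sigma_i^2 = sd_total^2`.
#'
#' @param ratio Desired `sigma_c / sigma_i` (>= 0; `Inf` gives all-common).
#' @param sd_total Total input-noise SD (1/s); defaults to the column's
#'   baseline `e1` noise SD.
#' @return Named numeric vector with `sigma_c` and `sigma_i`.
#' @export
noise_sigmas_from_ratio <- function(ratio, sd_total = 54) {
  if (!is.finite(ratio)) return(c(sigma_c = sd_total, sigma_i = 0))
  if (ratio < 0) stop("ratio must be >= 0")
  sigma_i <- sd_total / sqrt(1 + ratio^2)
  c(sigma_c = ratio * sigma_i, sigma_i = sigma_i)
}

#' Couple LaNMM columns through a connectome
#'
#' Builds a whole-brain model of identical columns coupled by the
#' connectome: the firing rate of `P1` (resp. `P2`) of parcel `j` drives
#' parcel `i` through `G * w * W[j, i]`, entering a dedicated excitatory
#' long-range synapse on the target population (`P1 -> P1` lateral,
#' `P1 -> P2` feedback, `P2 -> P2` feedforward).  Per parcel, the
#' receptor-weighted dose relation sets the gain of the modulated local
#' synapses and of the long-range input onto `P1`.
#'
#' @param con A [connectome()].
#' @param params Column parameters ([lanmm_parameters()]).
#' @param net [network_parameters()].
#' @param receptors A [receptor_map()] sharing the connectome's labels, or
#'   `NULL` for a uniform zero map (no regional modulation).
#' @param mod A [modulation_spec()] providing the gain endpoints; its dose
#'   is overridden by `net$psi`.
#' @return An object of class `lanmm_network`.
#' @export
build_network <- function(con, params = lanmm_parameters(),
                          net = network_parameters(), receptors = NULL,
                          mod = modulation_spec()) {
  if (!inherits(con, "connectome")) stop("con must be a connectome")
  validate_lanmm_parameters(params)
  n <- length(con$labels)
  if (is.null(receptors)) {
    R <- rep(0, n)
  } else {
    if (!setequal(receptors$labels, con$labels))
      stop("receptor map and connectome labels differ: ",
           paste(c(setdiff(con$labels, receptors$labels),
                   setdiff(receptors$labels, con$labels)), collapse = ", "))
    R <- unname(receptors$values[con$labels])
  }
  mod$psi <- net$psi
  gains <- modulated_gain(mod, R)
  tabs <- .integrator_tables(params)
  n_slots <- length(tabs$A)
  Amat <- matrix(tabs$A, n_slots, n)
  Amat[tabs$modulated, ] <- rep(gains, each = sum(tabs$modulated))
  # rescale the coupling matrix to unit mean column sum so the global gain
  # G is comparable across connectome sizes and normalizations (recorded)
  cs <- mean(colSums(con$weights))
  wscale <- if (cs > 0) 1 / cs else 1
  structure(list(connectome = con, params = params, net = net,
                 receptors = R, gains = gains, tabs = tabs, Amat = Amat,
                 weight_scale = wscale),
            class = "lanmm_network")
}

#' Structured external input rates for a network run
#'
#' Builds the per-parcel `e1` firing-rate input as
#' `mean + sigma_c * eta_common(t) + sigma_i * eta_pair(i)(t)`, where
#' `eta_common` is shared by all parcels and `eta_pair` is shared within
#' each homotopic pair (unpaired parcels get their own stream).  All
#' streams are i.i.d. standard Gaussian per integration step.
#'
#' @param n_parcels Number of parcels.
#' @param duration Length of the series (s).
#' @param fs Sampling frequency (Hz).
#' @param sigma_c,sigma_i Common and homotopic noise SDs (1/s).
#' @param pairing Homotopic pairing (integer vector or `NULL`).
#' @param seed Integer seed.
#' @param mean Mean input rate (1/s), default the column's baseline.
#' @return Matrix of size `duration*fs` x `n_parcels`.
#' @export
generate_network_inputs <- function(n_parcels, duration, fs, sigma_c,
                                    sigma_i, pairing = NULL, seed = 1,
                                    mean = 316) {
  set.seed(seed)
  n <- as.integer(round(duration * fs))
  .generate_inputs(n, n_parcels, mean, sigma_c, sigma_i, pairing, 0, 0)$e1
}

#' Simulate a coupled whole-brain LaNMM model
#'
#' RK4 integration of all columns with instantaneous connectome coupling.
#' The transient window is flagged (`discard`), not removed.
#'
#' @param model A [build_network()] model.
#' @param duration Simulated time (s), default 40.
#' @param fs Sampling frequency (Hz), default 1000.
#' @param seed Integer seed (determinism: same seed, same output).
#' @param discard Transient flag (s), default 10.
#' @param store Which series to keep: any of `"vP1"`, `"vP2"`, `"phiP1"`,
#'   `"phiP2"`.
#' @param decimate Keep every `decimate`-th sample (default 1).
#' @param divergence_bound Abort threshold on |membrane potential| (mV).
#' @return An object of class `lanmm_network_ts`: requested series as
#'   samples x parcels matrices, plus `fs`, `duration`, `discard`, `seed`,
#'   `psi`, `labels`.
#' @export
simulate_network <- function(model, duration = 40, fs = 1000, seed = 1,
                             discard = 10,
                             store = c("vP1", "vP2", "phiP1", "phiP2"),
                             decimate = 1L, divergence_bound = 1e6) {
  if (!inherits(model, "lanmm_network")) stop("model must be a lanmm_network")
  n_steps <- as.integer(round(duration * fs))
  n <- length(model$connectome$labels)
  inp <- model$params$inputs
  m1 <- inp$mean[inp$target == "P1"]
  m2 <- inp$mean[inp$target == "P2"]; s2 <- inp$sd[inp$target == "P2"]
  set.seed(seed)
  noise <- .generate_inputs(n_steps, n, m1, model$net$sigma_c,
                            model$net$sigma_i, model$connectome$pairing,
                            m2, s2)
  store_v <- c("vP1", "vSS", "vSST", "vP2", "vPV") %in% store
  store_phi <- c("phiP1", "phiSS", "phiSST", "phiP2", "phiPV") %in% store
  res <- lanmm_integrate(model$tabs$src, model$tabs$tgt, model$Amat,
                         model$tabs$a, model$tabs$C, model$tabs$sgn,
                         model$tabs$sig,
                         model$connectome$weights * model$weight_scale,
                         model$net$G, model$net$w_lateral,
                         model$net$w_feedback, model$net$w_feedforward,
                         noise$e1, noise$e2, 1 / fs, n_steps,
                         divergence_bound, store_v, store_phi,
                         as.integer(decimate))
  if (!isTRUE(res$ok))
    stop(sprintf(
      "network simulation diverged at t = %.3f s in parcel %s",
      res$t, model$connectome$labels[res$parcel]))
  out <- list(fs = fs / decimate, duration = duration, discard = discard,
              seed = seed, psi = model$net$psi,
              labels = model$connectome$labels)
  vn <- c("vP1", "vSS", "vSST", "vP2", "vPV")
  pn <- c("phiP1", "phiSS", "phiSST", "phiP2", "phiPV")
  for (p in 1:5) {
    if (store_v[p]) {
      m <- res$v[[p]]; colnames(m) <- out$labels; out[[vn[p]]] <- m
    }
    if (store_phi[p]) {
      m <- res$phi[[p]]; colnames(m) <- out$labels; out[[pn[p]]] <- m
    }
  }
  class(out) <- "lanmm_network_ts"
  out
}

#' @export
print.lanmm_network_ts <- function(x, ...) {
  cat(sprintf(
    "LaNMM network run: %d parcels, %g s at %g Hz (discard %g s), psi = %g\n",
    length(x$labels), x$duration, x$fs, x$discard, x$psi))
  invisible(x)
}

#' Per-parcel band power of a network run
#'
#' Mean Welch PSD per parcel and canonical band for a stored population
#' series, computed on the post-transient window.
#'
#' @param nts A [simulate_network()] result.
#' @param series Which stored series to analyze (default `"vP1"`).
#' @param segment Welch segment length (samples).
#' @return Tidy data frame (parcel, band, mean_psd).
#' @export
parcel_band_table <- function(nts, series = "vP1", segment = 1000) {
  x <- nts[[series]]
  if (is.null(x)) stop("series ", series, " was not stored in this run")
  keep <- seq.int(floor(nts$discard * nts$fs) + 1, nrow(x))
  bands <- band_definitions()
  out <- do.call(rbind, lapply(seq_along(nts$labels), function(i) {
    data.frame(parcel = nts$labels[i], band = bands$name,
               mean_psd = .band_profile(x[keep, i], nts$fs, segment, bands),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
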