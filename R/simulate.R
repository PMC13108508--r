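# Internal: build the integrator arguments shared by node and network runs.
# Long-range slots are appended after the 13 local synapses; for an
# uncoupled run they receive zero input (G = 0).
.integrator_tables <- function(params) {
  syn <- params$synapses
  src <- .pop_codes[syn$source]
  tgt <- .pop_codes[syn$target]
  lr_src <- unname(.lr_codes)
  lr_tgt <- .pop_codes[c("P1", "P2", "P2")]
  exc <- syn$sign == "excitatory"
  # long-range inputs use the local excitatory kernel of the target circuit
  a_exc <- syn$a[syn$source == "SS" & syn$target == "P1"]
  list(
    src = as.integer(c(src, lr_src)),
    tgt = as.integer(c(tgt, lr_tgt)),
    A   = c(syn$A, rep(syn$A[exc][1], 3)),
    a   = c(syn$a, rep(a_exc, 3)),
    # long-range connectivity constant; the connectome is rescaled to unit
    # mean column sum in build_network(), so G ~ O(1) is a meaningful range
    C   = c(syn$C, 60, 15, 15),
    sgn = c(ifelse(exc, 1, -1), rep(1, 3)),
    modulated = c(syn$modulated, TRUE, FALSE, FALSE),
    sig = {
      g <- params$sigmoid[match(.populations, params$sigmoid$population), ]
      as.matrix(g[, c("phi0", "nu0", "r")])
    })
}

# Internal: external input rate series. Draw order (fixed for
# reproducibility): the shared noise stream, then one stream per homotopic
# pair group in parcel order, then the per-parcel e2 streams.
.generate_inputs <- function(n_steps, n_parcels, mean1, sigma_c, sigma_i,
                             pairing, mean2, sd2) {
  eta_c <- rnorm(n_steps)
  group <- .pair_groups(pairing, n_parcels)
  e1 <- matrix(0, n_steps, n_parcels)
  etas <- matrix(0, n_steps, max(group))
  for (g in seq_len(max(group))) etas[, g] <- rnorm(n_steps)
  for (i in seq_len(n_parcels))
    e1[, i] <- mean1 + sigma_c * eta_c + sigma_i * etas[, group[i]]
  e2 <- matrix(rnorm(n_steps * n_parcels, mean2, sd2), n_steps, n_parcels)
  list(e1 = e1, e2 = e2)
}

# Internal: map a homotopic pairing (integer vector, pairing[i] = partner
# index or NA) to group ids 1..n_groups in order of first appearance.
.pair_groups <- function(pairing, n_parcels) {
  if (is.null(pairing)) pairing <- rep(NA_integer_, n_parcels)
  group <- integer(n_parcels)
  g <- 0L
  for (i in seq_len(n_parcels)) {
    if (group[i] > 0L) next
    g <- g + 1L
    group[i] <- g
    j <- pairing[i]
    if (!is.na(j) && j >= 1 && j <= n_parcels) group[j] <- g
  }
  group
}

#' Simulate one uncoupled LaNMM column
#'
#' Integrates the 13-synapse column with a fourth-order Runge-Kutta scheme
#' at `dt = 1/fs`.  External firing-rate noise is sampled once per step and
#' held constant within the step.  All state starts at rest (zero); the
#' `discard` attribute flags the transient window but no samples are
#' removed, so downstream analyses choose their own window.
#'
#' @param params A [lanmm_parameters()] object.
#' @param duration Simulated time in seconds (default 40).
#' @param fs Sampling frequency in Hz (default 1000).
#' @param seed Integer seed; identical seed and parameters give
#'   bit-identical output.
#' @param gain_override If non-`NULL`, sets the gain of all modulated
#'   synapses simultaneously and equally to this value (mV).
#' @param discard Transient window flagged for downstream exclusion (s).
#' @param divergence_bound Absolute membrane potential (mV) beyond which
#'   the simulation aborts with an error naming the first offending time.
#' @return An object of class `lanmm_node_ts`: list with `potentials`
#'   (matrix, samples x populations, mV), `rates` (firing rates of P1 and
#'   P2, 1/s), `fs`, `duration`, `discard`, `seed`.
#' @examples
#' ts <- simulate_node(duration = 2, seed = 1)
#' colnames(ts$potentials)
#' @export
simulate_node <- function(params = lanmm_parameters(), duration = 40,
                          fs = 1000, seed = 1, gain_override = NULL,
                          discard = 10, divergence_bound = 1e6) {
  validate_lanmm_parameters(params)
  n_steps <- duration * fs
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stop("duration * fs must be an integer number of steps")
  n_steps <- as.integer(round(n_steps))
  tabs <- .integrator_tables(params)
  A <- tabs$A
  if (!is.null(gain_override)) {
    if (!is.finite(gain_override) || gain_override <= 0)
      stop("gain_override must be a positive gain in mV")
    A[tabs$modulated] <- gain_override
  }
  inp <- params$inputs
  m1 <- inp$mean[inp$target == "P1"]; s1 <- inp$sd[inp$target == "P1"]
  m2 <- inp$mean[inp$target == "P2"]; s2 <- inp$sd[inp$target == "P2"]
  set.seed(seed)
  noise <- .generate_inputs(n_steps, 1L, m1, s1, 0, NULL, m2, s2)
  res <- lanmm_integrate(tabs$src, tabs$tgt, matrix(A, ncol = 1),
                         tabs$a, tabs$C, tabs$sgn, tabs$sig,
                         matrix(0, 1, 1), 0, 0.5, 0.5, 1,
                         noise$e1, noise$e2, 1 / fs, n_steps,
                         divergence_bound,
                         rep(TRUE, 5), c(TRUE, FALSE, FALSE, TRUE, FALSE), 1L)
  if (!isTRUE(res$ok))
    stop(sprintf("simulation diverged at t = %.3f s (|v| > %g mV)",
                 res$t, divergence_bound))
  pot <- do.call(cbind, lapply(res$v, function(m) m[, 1]))
  colnames(pot) <- .populations
  rates <- cbind(P1 = res$phi[[1]][, 1], P2 = res$phi[[4]][, 1])
  structure(list(potentials = pot, rates = rates, fs = fs,
                 duration = duration, discard = discard, seed = seed),
            class = "lanmm_node_ts")
}

#' @export
print.lanmm_node_ts <- function(x, ...) {
  cat(sprintf("LaNMM column run: %g s at %g Hz (discard %g s), seed %d\n",
              x$duration, x$fs, x$discard, x$seed))
  invisible(x)
}
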