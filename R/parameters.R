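#' Sigmoid (firing-rate) parameters
#'
#' Parameters of the population firing-rate sigmoid
#' \eqn{\varphi(\nu) = 2\varphi_0 / (1 + e^{r(\nu_0 - \nu)})}.
#'
#' @param phi0 Half of the maximum firing rate (1/s). Must be positive.
#' @param nu0 Membrane potential at which the rate equals `phi0` (mV).
#' @param r Slope parameter at the symmetry point (1/mV). Must be positive.
#' @return An object of class `sigmoid_parameters`.
#' @examples
#' p <- sigmoid_parameters()
#' sigmoid_rate(p$nu0, p)  # equals phi0
#' @export
sigmoid_parameters <- function(phi0 = 2.5, nu0 = 6, r = 0.56) {
  stopifnot(is.numeric(phi0), is.numeric(nu0), is.numeric(r),
            length(phi0) == 1, length(nu0) == 1, length(r) == 1)
  if (!is.finite(phi0) || phi0 <= 0) stop("phi0 must be positive and finite")
  if (!is.finite(r) || r <= 0) stop("r must be positive and finite")
  structure(list(phi0 = phi0, nu0 = nu0, r = r),
            class = "sigmoid_parameters")
}

#' Population firing-rate sigmoid
#'
#' Converts a membrane potential into an average population firing rate.
#' The output lies in `(0, 2 * phi0)`, is strictly increasing in `v` and
#' equals `phi0` at `v = nu0`.
#'
#' @param v Membrane potential (mV); vectorized.
#' @param p A [sigmoid_parameters()] object.
#' @return Firing rate(s) in 1/s.
#' @export
sigmoid_rate <- function(v, p = sigmoid_parameters()) {
  if (!inherits(p, "sigmoid_parameters")) stop("p must be sigmoid_parameters")
  if (any(!is.finite(v))) stop("non-finite membrane potential")
  2 * p$phi0 / (1 + exp(p$r * (p$nu0 - v)))
}

#' Default LaNMM parameter set
#'
#' Builds the full parameterization of one uncoupled laminar neural mass
#' column: a Jansen-Rit subcircuit (populations `P1` layer-5 pyramidal,
#' `SS` spiny stellate, `SST` slow inhibitory) generating alpha activity,
#' coupled to a PING subcircuit (`P2` layer-2/3 pyramidal, `PV` fast
#' inhibitory) generating gamma activity.  The 13 synapses are described by
#' connectivity constant `C` (mean contacts), synaptic gain `A` (mV), rate
#' constant `a` (1/s, the reciprocal synaptic time constant) and sign.
#'
#' The Jansen-Rit subcircuit carries the classic values (`C` based on 135,
#' excitatory `A` = 3.25 mV with `a` = 100/s, slow inhibition 22 mV); the
#' slow-inhibitory rate constant (46/s) and the PING constants were
#' calibrated once so that at the nominal gain the column oscillates at
#' 10 Hz in `P1` and 40 Hz in `P2` (see the package vignette).  The
#' `modulated` flag marks the three glutamatergic synapses onto `P1`
#' (`SS->P1`, `P2->P1`, `e1->P1`) that carry the serotonin-2A-dependent
#' gain; the bookkeeping 13th connection (`P1->PV`) completes the
#' cross-coupling between the two subcircuits.
#'
#' External inputs `e1` (to `P1`) and `e2` (to `P2`) are Gaussian
#' firing-rate perturbations with the given mean and standard deviation.
#'
#' @return An object of class `lanmm_params` with elements `synapses`
#'   (data frame: index, source, target, C, A, a, sign, modulated),
#'   `sigmoid` (data frame of per-population sigmoid parameters) and
#'   `inputs` (data frame: target, mean, sd).
#' @examples
#' p <- lanmm_parameters()
#' p$synapses
#' @export
lanmm_parameters <- function() {
  synapses <- data.frame(
    index  = 1:13,
    source = c("SS", "SST", "e1", "P2", "PV",
               "P1", "P1", "P1", "e2", "PV", "P2", "P1", "PV"),
    target = c("P1", "P1", "P1", "P1", "P1",
               "SS", "SST", "P2", "P2", "P2", "PV", "PV", "PV"),
    C    = c(108, 33.75, 1, 10, 2, 135, 33.75, 220, 1, 140, 135, 20, 10),
    A    = c(3.25, 22, 3.25, 3.25, 30, 3.25, 3.25, 3.25, 3.25, 30,
             3.25, 3.25, 30),
    a    = c(100, 46, 100, 100, 240, 100, 100, 100, 100, 240,
             200, 200, 240),
    sign = c("excitatory", "inhibitory", "excitatory", "excitatory",
             "inhibitory", "excitatory", "excitatory", "excitatory",
             "excitatory", "inhibitory", "excitatory", "excitatory",
             "inhibitory"),
    modulated = c(TRUE, FALSE, TRUE, TRUE, rep(FALSE, 9)),
    stringsAsFactors = FALSE)

  sig <- sigmoid_parameters()
  sigmoid <- data.frame(
    population = .populations,
    phi0 = sig$phi0, nu0 = sig$nu0, r = sig$r,
    stringsAsFactors = FALSE)

  inputs <- data.frame(
    target = c("P1", "P2"),
    mean = c(316, 0),
    sd = c(54, 25),
    stringsAsFactors = FALSE)

  out <- structure(list(synapses = synapses, sigmoid = sigmoid,
                        inputs = inputs),
                   class = "lanmm_params")
  validate_lanmm_parameters(out)
  out
}

#' Validate a LaNMM parameter set
#'
#' Checks the structural invariants of a parameter set: positive gains and
#' rate constants, nonnegative connectivity, unique (source, target) pairs,
#' valid population names, and that exactly the excitatory synapses
#' targeting `P1` from `SS`, `P2` and `e1` are flagged as modulated.
#'
#' @param params An object of class `lanmm_params`.
#' @return `params`, invisibly; errors describe the first violated invariant.
#' @export
validate_lanmm_parameters <- function(params) {
  if (!inherits(params, "lanmm_params")) stop("not a lanmm_params object")
  syn <- params$synapses
  need <- c("index", "source", "target", "C", "A", "a", "sign", "modulated")
  if (!all(need %in% names(syn))) stop("synapse table lacks columns: ",
                                       paste(setdiff(need, names(syn)),
                                             collapse = ", "))
  if (!all(syn$source %in% c(.populations, .ext_sources)))
    stop("unknown synapse source population")
  if (!all(syn$target %in% .populations))
    stop("unknown synapse target population")
  key <- paste(syn$source, syn$target)
  if (anyDuplicated(key)) stop("duplicated (source, target) pair: ",
                               key[duplicated(key)][1])
  if (any(syn$C < 0)) stop("connectivity constants C must be >= 0")
  if (any(syn$A <= 0)) stop("synaptic gains A must be > 0")
  if (any(syn$a <= 0)) stop("rate constants a must be > 0")
  if (!all(syn$sign %in% c("excitatory", "inhibitory")))
    stop("sign must be 'excitatory' or 'inhibitory'")
  expect_mod <- syn$target == "P1" & syn$sign == "excitatory" &
    syn$source %in% c("SS", "P2", "e1")
  if (!identical(expect_mod, syn$modulated))
    stop("modulated flags must mark exactly the excitatory synapses onto P1 ",
         "from SS, P2 and e1")
  sg <- params$sigmoid
  if (any(sg$phi0 <= 0) || any(sg$r <= 0))
    stop("sigmoid parameters phi0 and r must be positive")
  if (!setequal(sg$population, .populations))
    stop("sigmoid table must cover populations ",
         paste(.populations, collapse = ", "))
  inp <- params$inputs
  if (any(inp$sd < 0)) stop("input noise sd must be >= 0")
  if (!all(inp$target %in% c("P1", "P2")))
    stop("external inputs must target P1 or P2")
  invisible(params)
}

#' Serotonergic gain-modulation specification
#'
#' Holds the dose and the gain endpoints of the linear neuromodulation
#' relation \eqn{A(\psi, R) = A_0 + \psi R (A_{max} - A_0)}: at zero dose
#' the modulated synapses keep the nominal gain `A0`; at full dose a parcel
#' with maximal normalized receptor density reaches `Amax`.
#'
#' @param psi Psychedelic dose in `[0, 1]` (0 baseline, 1 full effect).
#' @param A0 Nominal synaptic gain (mV), default 3.25.
#' @param Amax Maximum synaptic gain (mV), default 3.75.
#' @return An object of class `modulation_spec`.
#' @export
modulation_spec <- function(psi = 0, A0 = 3.25, Amax = 3.75) {
  if (!is.finite(psi) || psi < 0 || psi > 1)
    stop("psi must lie in [0, 1]")
  if (!is.finite(A0) || A0 <= 0) stop("A0 must be positive")
  if (!is.finite(Amax) || Amax < A0) stop("Amax must be >= A0")
  structure(list(psi = psi, A0 = A0, Amax = Amax), class = "modulation_spec")
}

#' Receptor-weighted modulated gain
#'
#' Evaluates the neuromodulation relation
#' \eqn{A = A_0 + \psi R (A_{max} - A_0)} for a normalized receptor
#' density `R`.
#'
#' @param mod A [modulation_spec()].
#' @param R Normalized serotonin-2A receptor density in `[0, 1]`; vectorized.
#' @return Modulated gain(s) in mV.
#' @export
modulated_gain <- function(mod, R) {
  if (!inherits(mod, "modulation_spec")) stop("mod must be a modulation_spec")
  if (any(!is.finite(R)) || any(R < 0) || any(R > 1))
    stop("receptor density R must lie in [0, 1]")
  mod$A0 + mod$psi * R * (mod$Amax - mod$A0)
}

#' Apply serotonergic gain modulation to a column
#'
#' Returns a copy of the parameter set in which every modulated synapse
#' (the glutamatergic inputs to the layer-5 pyramidal population) has its
#' gain set to `A0 + psi * R * (Amax - A0)`; all other synapses are
#' unchanged.
#'
#' @param params A [lanmm_parameters()] object.
#' @param mod A [modulation_spec()].
#' @param R Normalized receptor density of the parcel, in `[0, 1]`.
#' @return A modified `lanmm_params` object.
#' @examples
#' p <- apply_psychedelic_gain(lanmm_parameters(),
#'                             modulation_spec(psi = 1), R = 1)
#' unique(p$synapses$A[p$synapses$modulated])  # 3.75
#' @export
apply_psychedelic_gain <- function(params, mod, R) {
  validate_lanmm_parameters(params)
  if (length(R) != 1) stop("R must be a single receptor density")
  g <- modulated_gain(mod, R)
  params$synapses$A[params$synapses$modulated] <- g
  params
}

#' Signed membrane potential from a node state
#'
#' Sums the postsynaptic potential perturbations `u_s` of all synapses
#' incoming to a population, with inhibitory synapses entering negatively.
#'
#' @param state A list with element `u`, a numeric vector of per-synapse
#'   potentials aligned with `params$synapses`.
#' @param population One of `"P1"`, `"SS"`, `"SST"`, `"P2"`, `"PV"`.
#' @param params The parameter set defining the synapse table.
#' @return Membrane potential in mV.
#' @export
membrane_potential <- function(state, population, params = lanmm_parameters()) {
  if (!population %in% .populations)
    stop("unknown population: ", population)
  syn <- params$synapses
  if (length(state$u) != nrow(syn))
    stop("state$u must have one entry per synapse")
  idx <- syn$target == population
  s <- ifelse(syn$sign == "inhibitory", -1, 1)
  sum(s[idx] * state$u[idx])
}

#' Second-order synaptic dynamics
#'
#' First-order form of the synaptic operator
#' \eqn{(1/A)[(1/a) u'' + 2 u' + a u] = C \varphi}: given the current
#' state and presynaptic rate, returns the derivatives
#' `(u', u'') = (udot, A a C phi - 2 a udot - a^2 u)`.
#'
#' @param u Postsynaptic potential perturbation (mV).
#' @param udot Its time derivative (mV/s).
#' @param phi_in Presynaptic firing rate (1/s).
#' @param syn One row of the synapse table (with columns `A`, `a`, `C`).
#' @return Numeric vector `c(udot, uddot)`.
#' @export
synapse_derivatives <- function(u, udot, phi_in, syn) {
  if (syn$a <= 0) stop("rate constant a must be positive")
  if (any(!is.finite(c(u, udot, phi_in)))) stop("non-finite synapse state")
  c(udot, syn$A * syn$a * syn$C * phi_in - 2 * syn$a * udot - syn$a^2 * u)
}

#' @export
print.lanmm_params <- function(x, ...) {
  cat("LaNMM parameter set:", nrow(x$synapses), "synapses,",
      nrow(x$sigmoid), "populations\n")
  cat("Modulated synapses:",
      paste(sprintf("%s->%s", x$synapses$source[x$synapses$modulated],
                    x$synapses$target[x$synapses$modulated]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write a LaNMM parameter set to a text config
#'
#' Serializes the synapse table, sigmoid block and input block to a plain
#' text file that [read_lanmm_config()] restores exactly (numbers are
#' written with 17 significant digits).
#'
#' @param params A `lanmm_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lanmm_config <- function(params, path) {
  validate_lanmm_parameters(params)
  fmt <- function(x) vapply(x, function(v) format(v, digits = 17), "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# LaNMM column configuration", con)
  writeLines("[synapses]", con)
  writeLines("index\tsource\ttarget\tC\tA\ta\tsign\tmodulated", con)
  s <- params$synapses
  writeLines(paste(s$index, s$source, s$target, fmt(s$C), fmt(s$A),
                   fmt(s$a), s$sign, s$modulated, sep = "\t"), con)
  writeLines("[sigmoid]", con)
  writeLines("population\tphi0\tnu0\tr", con)
  g <- params$sigmoid
  writeLines(paste(g$population, fmt(g$phi0), fmt(g$nu0), fmt(g$r),
                   sep = "\t"), con)
  writeLines("[inputs]", con)
  writeLines("target\tmean\tsd", con)
  i <- params$inputs
  writeLines(paste(i$target, fmt(i$mean), fmt(i$sd), sep = "\t"), con)
  invisible(path)
}

#' Read a LaNMM parameter set from a text config
#'
#' @param path File written by [write_lanmm_config()] (or hand-edited in the
#'   same format).
#' @return A validated `lanmm_params` object.
#' @export
read_lanmm_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  sect <- which(grepl("^\\[", lines))
  names(sect) <- gsub("\\[|\\]", "", lines[sect])
  get_block <- function(name) {
    if (!name %in% names(sect)) stop("config lacks section [", name, "]")
    i0 <- sect[[name]] + 1
    nxt <- sect[sect > sect[[name]]]
    i1 <- if (length(nxt)) min(nxt) - 1 else length(lines)
    read.table(text = paste(lines[i0:i1], collapse = "\n"), header = TRUE,
               sep = "\t", stringsAsFactors = FALSE)
  }
  out <- structure(list(synapses = get_block("synapses"),
                        sigmoid = get_block("sigmoid"),
                        inputs = get_block("inputs")),
                   class = "lanmm_params")
  validate_lanmm_parameters(out)
  out
}
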