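#' Configuration of a synaptic-gain sweep
#'
#' @param g_lo,g_hi Gain range (mV).
#' @param step Grid step (mV), default 0.05.
#' @param duration Per-point simulated time (s), default 40.
#' @param discard Transient excluded from spectra (s), default 10.
#' @param fs Sampling frequency (Hz), default 1000.
#' @param segment Welch segment length (samples), default 1000.
#' @param alpha_floor Alpha-presence threshold on P1 mean PSD (mV^2/Hz),
#'   default 0.1.
#' @param gamma_floor Gamma-presence threshold on P2 mean PSD (mV^2/Hz);
#'   defaults to `alpha_floor`.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(g_lo = 2.5, g_hi = 4.5, step = 0.05, duration = 40,
                         discard = 10, fs = 1000, segment = 1000,
                         alpha_floor = 0.1, gamma_floor = alpha_floor) {
  if (step <= 0) stop("step must be positive")
  if (discard >= duration) stop("discard must be shorter than duration")
  structure(list(g_lo = g_lo, g_hi = g_hi, step = step, duration = duration,
                 discard = discard, fs = fs, segment = segment,
                 alpha_floor = alpha_floor, gamma_floor = gamma_floor),
            class = "sweep_config")
}

#' Sweep the modulated synaptic gain of an uncoupled column
#'
#' Simulates the column once per grid gain (seed `seed + index - 1`),
#' applying the gain simultaneously and equally to all modulated synapses,
#' and tabulates the mean Welch PSD of the P1 and P2 membrane potentials in
#' each canonical band over the post-transient window.  A diverging grid
#' point is recorded (`diverged = TRUE`, `NA` power) and the sweep
#' continues.
#'
#' @param params A [lanmm_parameters()] object.
#' @param cfg A [sweep_config()].
#' @param seed Base seed.
#' @return An object of class `lanmm_sweep`: data frame `table` with
#'   columns (gain, population, band, mean_psd, diverged) plus the
#'   configuration as attributes.
#' @export
run_sweep <- function(params = lanmm_parameters(), cfg = sweep_config(),
                      seed = 1) {
  gains <- seq(cfg$g_lo, cfg$g_hi, by = cfg$step)
  bands <- band_definitions()
  rows <- vector("list", length(gains))
  keep <- seq.int(cfg$discard * cfg$fs + 1, cfg$duration * cfg$fs)
  for (i in seq_along(gains)) {
    ts <- tryCatch(
      simulate_node(params, duration = cfg$duration, fs = cfg$fs,
                    seed = seed + i - 1L, gain_override = gains[i]),
      error = function(e) NULL)
    if (is.null(ts)) {
      rows[[i]] <- data.frame(gain = gains[i],
                              population = rep(c("P1", "P2"),
                                               each = nrow(bands)),
                              band = rep(bands$name, 2),
                              mean_psd = NA_real_, diverged = TRUE,
                              stringsAsFactors = FALSE)
      next
    }
    p1 <- .band_profile(ts$potentials[keep, "P1"], cfg$fs, cfg$segment, bands)
    p2 <- .band_profile(ts$potentials[keep, "P2"], cfg$fs, cfg$segment, bands)
    rows[[i]] <- data.frame(gain = gains[i],
                            population = rep(c("P1", "P2"),
                                             each = nrow(bands)),
                            band = rep(bands$name, 2),
                            mean_psd = c(p1, p2), diverged = FALSE,
                            stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, rows), gains = gains, cfg = cfg,
                 seed = seed),
            class = "lanmm_sweep")
}

# Internal: extract one (population, band) power profile over the gain grid.
.sweep_profile <- function(sweep, population, band) {
  t <- sweep$table
  sel <- t$population == population & t$band == band
  p <- t$mean_psd[sel][match(sweep$gains, t$gain[sel])]
  p
}

#' Alpha/gamma coexistence window of a gain sweep
#'
#' Finds the smallest and largest grid gains at which the P1 alpha-band and
#' P2 gamma-band mean PSD simultaneously reach their presence thresholds.
#'
#' @param sweep A [run_sweep()] result.
#' @param alpha_floor,gamma_floor Presence thresholds (mV^2/Hz); default to
#'   the sweep configuration values.
#' @return List with `g_low`, `g_high` (mV) and `empty` (logical).  When no
#'   gain qualifies, `empty = TRUE` and the bounds are `NA` (no error is
#'   thrown).
#' @export
detect_coexistence_window <- function(sweep,
                                      alpha_floor = sweep$cfg$alpha_floor,
                                      gamma_floor = sweep$cfg$gamma_floor) {
  a <- .sweep_profile(sweep, "P1", "alpha")
  g <- .sweep_profile(sweep, "P2", "gamma")
  ok <- !is.na(a) & !is.na(g) & a >= alpha_floor & g >= gamma_floor
  if (!any(ok))
    return(list(g_low = NA_real_, g_high = NA_real_, empty = TRUE))
  list(g_low = min(sweep$gains[ok]), g_high = max(sweep$gains[ok]),
       empty = FALSE)
}

#' First gain at which alpha power falls below a floor
#'
#' Scans grid gains at or above `from` (the nominal gain by default) and
#' returns the smallest at which the P1 alpha-band mean PSD is below
#' `floor`.
#'
#' @param sweep A [run_sweep()] result.
#' @param floor Alpha threshold (mV^2/Hz), default from the sweep config.
#' @param from Lowest gain considered (mV), default 3.25.
#' @return The crossing gain (mV), or `NA_real_` when alpha never drops
#'   below the floor in the sweep range.
#' @export
find_alpha_floor_gain <- function(sweep, floor = sweep$cfg$alpha_floor,
                                  from = 3.25) {
  a <- .sweep_profile(sweep, "P1", "alpha")
  sel <- sweep$gains >= from & !is.na(a)
  hit <- which(sel & a < floor)
  if (!length(hit)) return(NA_real_)
  sweep$gains[min(hit)]
}

#' @export
print.lanmm_sweep <- function(x, ...) {
  cat(sprintf("LaNMM gain sweep: %d points in [%g, %g] mV (step %g)\n",
              length(x$gains), x$cfg$g_lo, x$cfg$g_hi, x$cfg$step))
  w <- detect_coexistence_window(x)
  if (!w$empty)
    cat(sprintf("Alpha/gamma coexistence window: [%g, %g] mV\n",
                w$g_low, w$g_high))
  invisible(x)
}
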