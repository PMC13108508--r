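#' Stage I: personalize whole-brain models against empirical FC
#'
#' Runs the grid search of [grid_search_fit()] for every cohort subject
#' against their target FC.  Subjects whose best fit violates the
#' SC-correlation constraint are flagged, not dropped.
#'
#' @param cohort A [synth_cohort()] bundle (or a list with the same shape).
#' @param g_grid,ratio_grid Search grids.
#' @param n_realizations Noise realizations per grid point.
#' @param duration Seconds simulated per realization.
#' @param seed Base seed.
#' @param ... Further arguments to [grid_search_fit()].
#' @return List of `lanmm_fit` objects (one per subject, named by subject
#'   id) with a `manifest` attribute recording configuration, seeds and
#'   per-subject constraint flags.
#' @export
run_stage1_personalize <- function(cohort,
                                   g_grid = seq(0.5, 3, by = 0.5),
                                   ratio_grid = c(0.5, 1, 2),
                                   n_realizations = 3, duration = 120,
                                   seed = 1, ...) {
  fits <- vector("list", length(cohort$subjects))
  names(fits) <- vapply(cohort$subjects, `[[`, "", "id")
  for (s in seq_along(cohort$subjects)) {
    sub <- cohort$subjects[[s]]
    fits[[s]] <- grid_search_fit(sub$connectome, sub$empirical_fc,
                                 g_grid = g_grid, ratio_grid = ratio_grid,
                                 n_realizations = n_realizations,
                                 duration = duration,
                                 seed = seed + 100L * s, ...)
  }
  attr(fits, "manifest") <- list(
    stage = "personalize", time = format(Sys.time()),
    g_grid = g_grid, ratio_grid = ratio_grid, seed = seed,
    n_realizations = n_realizations, duration = duration,
    constraint_flags = vapply(fits, `[[`, TRUE, "constraint_satisfied"))
  fits
}

#' Stage II: paired baseline/psychedelic simulation and band statistics
#'
#' For every subject, simulates the personalized model at `psi = 0` and at
#' `psi` with the same noise seed (a paired contrast), tabulates per-parcel
#' band powers of the P1 and P2 membrane potentials, runs the paired
#' Wilcoxon tests per band and population, and computes the correlation of
#' receptor density with the subject-averaged PSD change in the alpha and
#' gamma bands.
#'
#' @param cohort A [synth_cohort()] bundle.
#' @param fits Output of [run_stage1_personalize()].
#' @param psi Psychedelic dose of the treated arm (default 1).
#' @param duration,fs Simulation settings (40 s at 1000 Hz by default).
#' @param seed Base seed (one seed per subject, shared by both arms).
#' @param sd_total Total e1 noise SD.
#' @param keep_runs Keep the membrane-potential series for Stage III.
#' @return An object of class `lanmm_stage2`: per-subject band tables,
#'   Wilcoxon tables per population, receptor correlations, and (when
#'   `keep_runs`) the paired network runs.
#' @export
run_stage2_psychedelic <- function(cohort, fits, psi = 1, duration = 40,
                                   fs = 1000, seed = 1, sd_total = 54,
                                   keep_runs = TRUE) {
  if (!length(fits)) stop("no personalization results supplied")
  subjects <- cohort$subjects
  if (length(fits) != length(subjects))
    stop("fits and cohort subject counts differ")
  band_rows <- list(); runs <- list()
  for (s in seq_along(subjects)) {
    sub <- subjects[[s]]
    fit <- fits[[s]]
    sig <- noise_sigmas_from_ratio(fit$ratio, sd_total)
    run_arm <- function(dose) {
      net <- network_parameters(G = fit$G, sigma_c = sig[["sigma_c"]],
                                sigma_i = sig[["sigma_i"]], psi = dose)
      model <- build_network(sub$connectome, net = net,
                             receptors = cohort$receptors)
      simulate_network(model, duration = duration, fs = fs,
                       seed = seed + s, store = c("vP1", "vP2"))
    }
    pre <- run_arm(0); post <- run_arm(psi)
    for (cond in c("baseline", "psychedelic")) {
      nts <- if (cond == "baseline") pre else post
      for (pop in c("P1", "P2")) {
        bt <- parcel_band_table(nts, paste0("v", pop))
        bt$subject <- sub$id; bt$condition <- cond; bt$population <- pop
        band_rows[[length(band_rows) + 1L]] <- bt
      }
    }
    if (keep_runs) runs[[sub$id]] <- list(baseline = pre, psychedelic = post)
  }
  bands_tbl <- do.call(rbind, band_rows)
  tests <- lapply(c(P1 = "P1", P2 = "P2"), function(pop) {
    pre <- bands_tbl[bands_tbl$condition == "baseline" &
                       bands_tbl$population == pop, ]
    post <- bands_tbl[bands_tbl$condition == "psychedelic" &
                        bands_tbl$population == pop, ]
    if (length(unique(pre$subject)) >= 5)
      paired_band_test(pre, post, n_tests = 10) else NULL
  })
  correlations <- .stage2_receptor_correlations(bands_tbl, cohort$receptors)
  structure(list(band_table = bands_tbl, tests = tests,
                 receptor_correlations = correlations,
                 runs = if (keep_runs) runs, psi = psi, seed = seed),
            class = "lanmm_stage2")
}

# Internal: receptor correlations on subject-averaged parcel PSD changes.
.stage2_receptor_correlations <- function(bands_tbl, receptors) {
  out <- list()
  for (pop in c("P1", "P2")) {
    sub <- bands_tbl[bands_tbl$population == pop, ]
    avg <- stats::aggregate(mean_psd ~ parcel + band + condition, sub, mean)
    pre <- avg[avg$condition == "baseline", ]
    post <- avg[avg$condition == "psychedelic", ]
    al <- pre[pre$band == "alpha", ]
    base_alpha <- stats::setNames(al$mean_psd, al$parcel)
    for (bd in c("alpha", "gamma")) {
      key <- paste(pop, bd, sep = "_")
      out[[key]] <- tryCatch(
        receptor_psd_correlation(pre, post, receptors, bd,
                                 baseline_alpha = base_alpha),
        error = function(e) list(pcc = NA_real_, p = NA_real_,
                                 n_included = 0L, error = conditionMessage(e)))
    }
  }
  out
}

#' Stage III: EEG projection, channel statistics and complexity
#'
#' Projects every Stage-II run through the cohort leadfield, tabulates
#' per-channel band power, tests the paired alpha/gamma channel contrast
#' across subjects, and computes the broadband complexity metrics
#' (LZW rho0, entropy rates, spectral entropy) per subject and condition.
#'
#' @param cohort A [synth_cohort()] bundle (provides the leadfield).
#' @param stage2 Output of [run_stage2_psychedelic()] with `keep_runs`.
#' @param w_P1,w_P2 Dipole layer weights.
#' @param epoch Complexity epoch length (s).
#' @return An object of class `lanmm_stage3`: `channel_table`,
#'   `channel_tests` (alpha/gamma Wilcoxon across subjects),
#'   `complexity` (tidy per subject and condition), `eeg` records.
#' @export
run_stage3_eeg_metrics <- function(cohort, stage2, w_P1 = 1, w_P2 = 0.25,
                                   epoch = 5) {
  if (is.null(stage2$runs))
    stop("stage 2 was run with keep_runs = FALSE; no time series available")
  rows <- list(); cx <- list(); eegs <- list()
  for (id in names(stage2$runs)) {
    for (cond in c("baseline", "psychedelic")) {
      nts <- stage2$runs[[id]][[cond]]
      dip <- dipole_strength(nts, w_P1, w_P2)
      eeg <- project_eeg(dip, cohort$leadfield)
      eegs[[paste(id, cond, sep = ".")]] <- eeg
      ct <- channel_band_table(eeg)
      ct$subject <- id; ct$condition <- cond
      rows[[length(rows) + 1L]] <- ct
      m <- eeg_complexity_suite(eeg, epoch = epoch)
      cx[[length(cx) + 1L]] <- data.frame(
        subject = id, condition = cond, rho0 = m$rho0,
        t(m$entropy_rate), spectral_entropy = m$spectral_entropy,
        stringsAsFactors = FALSE)
    }
  }
  channel_table <- do.call(rbind, rows)
  complexity <- do.call(rbind, cx)
  channel_tests <- NULL
  if (length(unique(channel_table$subject)) >= 5) {
    pre <- channel_table[channel_table$condition == "baseline", ]
    post <- channel_table[channel_table$condition == "psychedelic", ]
    names(pre)[names(pre) == "channel"] <- "entity"
    names(post)[names(post) == "channel"] <- "entity"
    channel_tests <- paired_band_test(pre, post, n_tests = 2)
    channel_tests <- channel_tests[channel_tests$band %in%
                                     c("alpha", "gamma"), ]
  }
  structure(list(channel_table = channel_table,
                 channel_tests = channel_tests, complexity = complexity,
                 eeg = eegs),
            class = "lanmm_stage3")
}
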