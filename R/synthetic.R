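#' Synthetic parcel geometry on two mirrored hemispheres
#'
#' Samples parcel centroids on two mirrored unit hemispheres (left/right),
#' defining the homotopic pairing and the spatial embedding reused by the
#' synthetic connectome, receptor map and leadfield generators.
#'
#' @param n_parcels Even number of parcels.
#' @param seed Integer seed.
#' @return List with `coords` (N x 3), `labels` (`lh_*`, `rh_*`) and
#'   `pairing` (integer involution).
#' @export
synth_parcel_geometry <- function(n_parcels, seed = 1) {
  if (n_parcels %% 2 != 0) stop("n_parcels must be even")
  nh <- n_parcels / 2
  set.seed(seed)
  # right hemisphere: x > 0 half of the unit sphere
  u <- runif(nh, -1, 1); th <- runif(nh, 0, pi)
  r <- sqrt(1 - u^2)
  right <- cbind(x = abs(r * cos(th)) + 0.05, y = r * sin(th) * sample(c(-1, 1), nh, TRUE), z = u)
  right <- right / sqrt(rowSums(right^2))
  left <- right; left[, 1] <- -left[, 1]
  coords <- rbind(left, right)
  labels <- c(paste0("lh_", seq_len(nh)), paste0("rh_", seq_len(nh)))
  pairing <- c(seq_len(nh) + nh, seq_len(nh))
  rownames(coords) <- labels
  list(coords = coords, labels = labels, pairing = as.integer(pairing))
}

#' Synthetic structural connectome
#'
#' Random geometric graph over the parcel geometry (edges between the
#' closest `density` fraction of parcel pairs) with log-normal streamline
#' counts; homotopic pairs are always connected and their counts multiplied
#' by `homotopic_boost`.  The count matrix is symmetric with zero diagonal
#' and is normalized with [normalize_connectome()].
#'
#' @param n_parcels Even number of parcels.
#' @param density Fraction of connected pairs, in `(0, 1]`.
#' @param homotopic_boost Multiplier on homotopic streamline counts.
#' @param seed Integer seed.
#' @param geometry Optional [synth_parcel_geometry()] result to reuse.
#' @return A [connectome()] with pairing and normalization record.
#' @export
synth_connectome <- function(n_parcels, density = 0.35,
                             homotopic_boost = 3, seed = 1,
                             geometry = NULL) {
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  if (is.null(geometry)) geometry <- synth_parcel_geometry(n_parcels, seed)
  set.seed(seed + 1L)
  n <- n_parcels
  d <- as.matrix(dist(geometry$coords))
  ut <- upper.tri(d)
  thr <- quantile(d[ut], density)
  counts <- matrix(0, n, n)
  w <- exp(rnorm(sum(ut), mean = 3, sd = 0.6))
  counts[ut][d[ut] <= thr] <- w[d[ut] <= thr]
  counts <- round(counts + t(counts))
  for (i in seq_len(n)) {
    j <- geometry$pairing[i]
    if (!is.na(j) && i < j) {
      base <- max(counts[i, j], round(exp(3)))
      counts[i, j] <- counts[j, i] <- round(base * homotopic_boost)
    }
  }
  diag(counts) <- 0
  normalize_connectome(counts, n_parcels = n, labels = geometry$labels,
                       pairing = geometry$pairing)
}

#' Synthetic serotonin-2A receptor map
#'
#' Spatially smooth positive field over the parcel geometry (a Gaussian
#' random field built by kernel-smoothing i.i.d. normal deviates),
#' min-max normalized so the minimum is exactly 0 and the maximum
#' exactly 1.
#'
#' @param n_parcels Even number of parcels.
#' @param smoothness Kernel length scale (same units as the unit-sphere
#'   geometry); larger gives a smoother, flatter field.
#' @param seed Integer seed.
#' @param symmetric If `TRUE`, homotopic partners share the same density.
#' @param geometry Optional geometry to reuse.
#' @return A [receptor_map()].
#' @export
synth_receptor_map <- function(n_parcels, smoothness = 0.8, seed = 1,
                               symmetric = FALSE, geometry = NULL) {
  if (smoothness < 0) stop("smoothness must be >= 0")
  if (is.null(geometry)) geometry <- synth_parcel_geometry(n_parcels, seed)
  set.seed(seed + 2L)
  g <- rnorm(n_parcels)
  d <- as.matrix(dist(geometry$coords))
  K <- exp(-d^2 / (2 * max(smoothness, 1e-6)^2))
  vals <- as.numeric(K %*% g)
  if (symmetric) {
    for (i in seq_len(n_parcels)) {
      j <- geometry$pairing[i]
      if (!is.na(j) && i < j) {
        m <- (vals[i] + vals[j]) / 2
        vals[i] <- vals[j] <- m
      }
    }
  }
  normalize_receptor_map(vals, labels = geometry$labels)
}

#' Synthetic EEG leadfield
#'
#' Physically flavored stand-in for a template head model: 19 electrodes
#' of a 10-20-style montage on the unit sphere, parcels at 0.9 of the
#' sphere radius, channel gain proportional to a signed random orientation
#' factor (magnitude in `[0.5, 1]`, random polarity emulating gyral/sulcal
#' dipole orientations) with a steep `1/d^falloff` distance kernel so each
#' channel is dominated by nearby sources.
#'
#' @param n_parcels Even number of parcels.
#' @param seed Integer seed.
#' @param geometry Optional geometry to reuse.
#' @param falloff Distance exponent of the gain kernel (default 4).
#' @param src_radius Radial position of the parcel sources (default 0.9).
#' @return Channels x parcels gain matrix with channel row names.
#' @export
synth_leadfield <- function(n_parcels, seed = 1, geometry = NULL,
                            falloff = 4, src_radius = 0.9) {
  if (is.null(geometry)) geometry <- synth_parcel_geometry(n_parcels, seed)
  set.seed(seed + 3L)
  elec <- .montage_1020()
  src <- geometry$coords * src_radius
  orient <- runif(n_parcels, 0.5, 1) * sample(c(-1, 1), n_parcels,
                                              replace = TRUE)
  lf <- matrix(0, nrow(elec), n_parcels,
               dimnames = list(rownames(elec), geometry$labels))
  for (ch in seq_len(nrow(elec))) {
    d2 <- colSums((t(src) - elec[ch, ])^2)
    lf[ch, ] <- orient / d2^(falloff / 2)
  }
  lf
}

# 19-channel 10-20-style electrode positions on the unit sphere:
# theta measured from the vertex, phi from the nasion (degrees).
.montage_1020 <- function() {
  ang <- rbind(
    Fp1 = c(92, -18), Fp2 = c(92, 18), F7 = c(92, -54), F3 = c(60, -39),
    Fz  = c(46, 0),   F4 = c(60, 39),  F8 = c(92, 54),  T3 = c(92, -90),
    C3  = c(46, -90), Cz = c(0, 0),    C4 = c(46, 90),  T4 = c(92, 90),
    T5  = c(92, -126), P3 = c(60, -141), Pz = c(46, 180),
    P4  = c(60, 141), T6 = c(92, 126), O1 = c(92, -162), O2 = c(92, 162))
  th <- ang[, 1] * pi / 180; ph <- ang[, 2] * pi / 180
  cbind(x = sin(th) * sin(ph), y = sin(th) * cos(ph), z = cos(th))
}

#' Synthetic "empirical" functional connectivity
#'
#' Generates a fitting target by running the forward model at known
#' `(G, ratio)`, computing FC from the resulting BOLD, and adding symmetric
#' zero-mean observation noise to the off-diagonal entries (clipped to
#' `[-1, 1]`, unit diagonal restored).
#'
#' @param con A [connectome()].
#' @param true_G,true_ratio Ground-truth coupling and noise ratio.
#' @param duration Simulated seconds (default 120).
#' @param noise_sd Observation noise SD on FC entries.
#' @param seed Integer seed.
#' @param params Column parameters.
#' @param sd_total,tr,fs,decimate As in [grid_search_fit()].
#' @return An `fc_matrix` with attribute `true_parameters`.
#' @export
synth_empirical_fc <- function(con, true_G, true_ratio, duration = 120,
                               noise_sd = 0.05, seed = 1,
                               params = lanmm_parameters(), sd_total = 54,
                               tr = 2, fs = 1000, decimate = 10L) {
  sig <- noise_sigmas_from_ratio(true_ratio, sd_total)
  net <- network_parameters(G = true_G, sigma_c = sig[["sigma_c"]],
                            sigma_i = sig[["sigma_i"]], psi = 0)
  model <- build_network(con, params, net)
  nts <- tryCatch(
    simulate_network(model, duration = duration, fs = fs, seed = seed,
                     store = "phiP1", decimate = decimate),
    error = function(e)
      stop("forward model diverged at true_G = ", true_G,
           "; use a smaller coupling"))
  bold <- bold_from_activity(neural_drive(nts), fs / decimate, tr_out = tr)
  fc <- compute_fc(bold)
  set.seed(seed + 7L)
  n <- nrow(fc)
  eps <- matrix(rnorm(n * n, 0, noise_sd), n, n)
  eps <- (eps + t(eps)) / 2
  out <- unclass(fc) + eps
  out[out > 1] <- 1; out[out < -1] <- -1
  diag(out) <- 1
  attr(out, "true_parameters") <- c(G = true_G, ratio = true_ratio)
  structure(out, class = c("fc_matrix", "matrix", "array"))
}

#' Specification of a synthetic cohort
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param n_parcels Even number of parcels (default 16).
#' @param g_range Range from which each subject's true coupling is drawn.
#'   The default spans the regime in which the models stay responsive to
#'   serotonergic stimulation (see the vignette), emulating the retained
#'   cohort after the study's exclusion of non-responsive extremes.
#' @param receptor_smoothness Receptor-field length scale.
#' @param fc_noise_sd Observation noise on the target FC.
#' @param master_seed Master seed; the whole bundle is a pure function of
#'   it and the other fields.
#' @param fc_duration Seconds simulated for each subject's target FC.
#' @param density,homotopic_boost Connectome generator settings.
#' @param jitter_sd SD of the log-normal multiplicative jitter giving each
#'   subject an individual connectome.
#' @param true_ratio Common-to-homotopic noise SD ratio used when
#'   generating the target FC (default 0.25).
#' @return An object of class `cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_subjects = 5, n_parcels = 16,
                                  g_range = c(0.8, 1.6),
                                  receptor_smoothness = 0.8,
                                  fc_noise_sd = 0.05, master_seed = 1,
                                  fc_duration = 120, density = 0.35,
                                  homotopic_boost = 3, jitter_sd = 0.1,
                                  true_ratio = 0.25) {
  if (n_subjects < 1) stop("need at least one subject")
  if (n_parcels %% 2 != 0) stop("n_parcels must be even")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic cohort bundle
#'
#' Emulates a multimodal study cohort: a base connectome with per-subject
#' multiplicative jitter, one shared receptor map (the same spatial
#' distribution applied to every subject), a shared leadfield, and a
#' per-subject "empirical" FC generated at a subject-specific true
#' coupling drawn from `g_range`.  Reproducible from the master seed.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @return An object of class `lanmm_cohort`: list with `subjects` (each
#'   with `connectome`, `empirical_fc`, `true_G`, `true_ratio`, `id`),
#'   `receptors`, `leadfield`, `geometry`, `spec`.
#' @export
synth_cohort <- function(spec = synthetic_cohort_spec()) {
  geometry <- synth_parcel_geometry(spec$n_parcels, spec$master_seed)
  base <- synth_connectome(spec$n_parcels, spec$density,
                           spec$homotopic_boost, spec$master_seed,
                           geometry = geometry)
  receptors <- synth_receptor_map(spec$n_parcels,
                                  spec$receptor_smoothness,
                                  spec$master_seed, geometry = geometry)
  leadfield <- synth_leadfield(spec$n_parcels, spec$master_seed,
                               geometry = geometry)
  raw <- denormalize_connectome(base)
  subjects <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    sseed <- spec$master_seed + 1000L + s
    set.seed(sseed)
    n <- spec$n_parcels
    j <- matrix(exp(rnorm(n * n, 0, spec$jitter_sd)), n, n)
    j <- (j + t(j)) / 2
    counts <- round(raw * j)
    con <- normalize_connectome(counts, n_parcels = n,
                                labels = geometry$labels,
                                pairing = geometry$pairing)
    true_G <- runif(1, spec$g_range[1], spec$g_range[2])
    true_ratio <- spec$true_ratio
    fc <- synth_empirical_fc(con, true_G, true_ratio,
                             duration = spec$fc_duration,
                             noise_sd = spec$fc_noise_sd, seed = sseed)
    subjects[[s]] <- list(id = sprintf("subject_%02d", s),
                          connectome = con, empirical_fc = fc,
                          true_G = true_G, true_ratio = true_ratio)
  }
  structure(list(subjects = subjects, receptors = receptors,
                 leadfield = leadfield, geometry = geometry, spec = spec),
            class = "lanmm_cohort")
}

#' @export
print.lanmm_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d parcels (seed %d)\n",
              length(x$subjects), x$spec$n_parcels, x$spec$master_seed))
  invisible(x)
}
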