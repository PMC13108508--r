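#' Paired band-power comparison across subjects
#'
#' Two-sided Wilcoxon signed-rank test per band on per-subject mean PSD
#' (averaged over entities), comparing baseline and psychedelic
#' conditions, with Bonferroni correction and a Kolmogorov-Smirnov
#' normality check of the paired differences.
#'
#' @param table_pre,table_post Tidy band-power tables with columns
#'   `subject`, `band`, `mean_psd` (and optionally `entity`), matched by
#'   subject.
#' @param n_tests Number of tests for the Bonferroni correction (defaults
#'   to the number of bands).
#' @return Data frame (band, statistic, p_raw, p_bonf, normality_p,
#'   direction) where `direction` is the sign of the median post - pre
#'   difference.
#' @export
paired_band_test <- function(table_pre, table_post, n_tests = NULL) {
  agg <- function(t) stats::aggregate(mean_psd ~ subject + band, t, mean)
  a <- agg(table_pre); b <- agg(table_post)
  bands <- unique(a$band)
  if (is.null(n_tests)) n_tests <- length(bands)
  out <- lapply(bands, function(bd) {
    pre <- a[a$band == bd, ]
    post <- b[b$band == bd, ]
    if (!setequal(pre$subject, post$subject))
      stop("subjects differ between conditions in band ", bd)
    post <- post[match(pre$subject, post$subject), ]
    if (nrow(pre) < 5)
      stop("fewer than 5 matched subjects; the paired test is underpowered")
    d <- post$mean_psd - pre$mean_psd
    if (sd(d) == 0) {
      w <- list(statistic = c(V = NA_real_),
                p.value = if (all(d == 0)) 1 else NA_real_)
      ks_p <- NA_real_
    } else {
      w <- suppressWarnings(wilcox.test(post$mean_psd, pre$mean_psd,
                                        paired = TRUE, exact = FALSE))
      ks_p <- suppressWarnings(ks.test(as.numeric(scale(d)), "pnorm"))$p.value
    }
    data.frame(band = bd, statistic = unname(w$statistic),
               p_raw = w$p.value, p_bonf = min(1, w$p.value * n_tests),
               normality_p = ks_p,
               direction = sign(median(d)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Correlation of receptor density with PSD change
#'
#' Pearson correlation across parcels between normalized serotonin-2A
#' receptor density and the band PSD difference (post - pre).  Parcels
#' whose baseline P1 alpha mean PSD is below `alpha_floor` are excluded
#' (for the alpha-band analysis and, by recorded policy, all bands).
#'
#' @param psd_pre,psd_post Tidy tables with columns `parcel`, `band`,
#'   `mean_psd` for the band/population under analysis (e.g. from
#'   [parcel_band_table()], averaged across subjects), in the baseline and
#'   psychedelic conditions respectively.
#' @param receptors A [receptor_map()] aligned by parcel label.
#' @param band Band name to analyze.
#' @param baseline_alpha Named per-parcel baseline P1 alpha mean PSD used
#'   for the inclusion rule; defaults to the alpha rows of `psd_pre`
#'   (appropriate when `psd_pre` describes P1).
#' @param alpha_floor Inclusion threshold (mV^2/Hz), default 0.1.
#' @return List with `pcc`, `p`, `n_included`, `included` labels.
#' @export
receptor_psd_correlation <- function(psd_pre, psd_post, receptors, band,
                                     baseline_alpha = NULL,
                                     alpha_floor = 0.1) {
  pre <- psd_pre[psd_pre$band == band, ]
  post <- psd_post[psd_post$band == band, ]
  post <- post[match(pre$parcel, post$parcel), ]
  if (any(is.na(post$mean_psd))) stop("parcels differ between conditions")
  if (is.null(baseline_alpha)) {
    al <- psd_pre[psd_pre$band == "alpha", ]
    baseline_alpha <- stats::setNames(al$mean_psd, al$parcel)
  }
  keep <- pre$parcel[baseline_alpha[pre$parcel] >= alpha_floor]
  if (length(keep) < 3)
    stop("fewer than 3 parcels pass the baseline alpha inclusion rule")
  sel <- pre$parcel %in% keep
  R <- receptors$values[pre$parcel[sel]]
  if (any(is.na(R))) stop("receptor map lacks parcels: ",
                          paste(pre$parcel[sel][is.na(R)], collapse = ", "))
  if (sd(R) == 0)
    stop("receptor densities are constant; correlation undefined")
  d <- post$mean_psd[sel] - pre$mean_psd[sel]
  if (sd(d) == 0)
    stop("PSD differences are constant; correlation undefined")
  ct <- stats::cor.test(R, d)
  list(pcc = unname(ct$estimate), p = ct$p.value,
       n_included = length(keep), included = keep)
}
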