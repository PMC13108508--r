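test_that("dipoles are the stated weighted sum of centered potentials", {
  set.seed(6)
  v1 <- matrix(rnorm(2000, mean = 5), 1000, 2)
  v2 <- matrix(rnorm(2000, mean = -3), 1000, 2)
  nts <- fake_network_ts(v1, v2)
  d <- dipole_strength(nts, w_P1 = 1, w_P2 = 0)
  expect_equal(d$strength, sweep(v1, 2, colMeans(v1)), ignore_attr = TRUE)
  d0 <- dipole_strength(nts, w_P1 = 0, w_P2 = 0)
  expect_true(all(d0$strength == 0))
})

test_that("a 10 + 40 Hz mixture shows the analytic 4:1 band-power ratio", {
  fs <- 1000
  t <- seq_len(20000) / fs
  v1 <- matrix(sin(2 * pi * 10 * t), ncol = 1)
  v2 <- matrix(sin(2 * pi * 40 * t), ncol = 1)
  nts <- fake_network_ts(v1, v2, fs = fs)
  d <- dipole_strength(nts, w_P1 = 1, w_P2 = 0.5)
  ps <- welch_psd(d$strength[, 1], fs, 1000)
  p10 <- ps$psd[ps$freq == 10]
  p40 <- ps$psd[ps$freq == 40]
  expect_equal(p10 / p40, 4, tolerance = 0.02)
})

test_that("leadfield projection equals the dense product, re-referenced", {
  set.seed(7)
  nts <- fake_network_ts(matrix(rnorm(3000), 1000, 3),
                         matrix(rnorm(3000), 1000, 3))
  d <- dipole_strength(nts)
  lf <- matrix(rnorm(12), 4, 3,
               dimnames = list(paste0("ch", 1:4), NULL))
  eeg <- project_eeg(d, lf)
  ref <- d$strength %*% t(lf)
  ref <- ref - rowMeans(ref)
  expect_lt(max(abs(eeg$signals - ref)), 1e-12)
  # identity leadfield returns the re-referenced dipoles themselves
  eeg_id <- project_eeg(d, diag(3))
  ref_id <- d$strength - rowMeans(d$strength)
  expect_lt(max(abs(eeg_id$signals - ref_id)), 1e-12)
  # a single active parcel projects proportionally to its column
  d1 <- d; d1$strength[, 2:3] <- 0
  eeg1 <- project_eeg(d1, lf)
  raw1 <- outer(d1$strength[, 1], lf[, 1])
  expect_lt(max(abs(eeg1$signals - (raw1 - rowMeans(raw1)))), 1e-12)
  expect_error(project_eeg(d, lf[, 1:2]), "parcels")
})

test_that("average-referenced EEG ignores common dipole offsets and is
           linear", {
  set.seed(10)
  v1 <- matrix(rnorm(1000), 500, 2)
  v2 <- matrix(rnorm(1000), 500, 2)
  lf <- matrix(runif(6, 0.5, 1), 3, 2)
  base <- project_eeg(dipole_strength(fake_network_ts(v1, v2)), lf)
  # a common offset on the pyramidal potentials is removed by the
  # mean-centering inside the dipole computation, so the EEG is unchanged
  lfe <- matrix(runif(6, 0.5, 2), 3, 2)
  d <- dipole_strength(fake_network_ts(v1, v2))
  d_shift <- dipole_strength(fake_network_ts(v1 + 7, v2 + 7))
  e1 <- project_eeg(d, lfe); e2 <- project_eeg(d_shift, lfe)
  expect_lt(max(abs(e1$signals - e2$signals)), 1e-10)
  # linearity: EEG of a sum of dipole fields is the sum of EEGs
  da <- d; db <- d
  db$strength <- matrix(rnorm(1000), 500, 2)
  dsum <- d; dsum$strength <- da$strength + db$strength
  expect_lt(max(abs(project_eeg(dsum, lf)$signals -
                      (project_eeg(da, lf)$signals +
                         project_eeg(db, lf)$signals))), 1e-10)
})

test_that("channel band tables recover known sinusoid mixtures", {
  fs <- 1000
  t <- seq_len(30000) / fs
  v1 <- matrix(2 * sin(2 * pi * 10 * t), ncol = 1)
  v2 <- matrix(sin(2 * pi * 40 * t), ncol = 1)
  eeg <- project_eeg(dipole_strength(fake_network_ts(v1, v2, fs)),
                     matrix(c(1, 1), 2, 1,
                            dimnames = list(c("A", "B"), NULL)))
  # average reference of two identical channels removes everything
  expect_lt(max(abs(eeg$signals)), 1e-12)
  # distinct gains keep the signal
  eeg2 <- project_eeg(dipole_strength(fake_network_ts(v1, v2, fs),
                                      w_P1 = 1, w_P2 = 0.5),
                      matrix(c(1, 3), 2, 1,
                             dimnames = list(c("A", "B"), NULL)))
  tab <- channel_band_table(eeg2)
  alpha <- tab$mean_psd[tab$band == "alpha"]
  gamma <- tab$mean_psd[tab$band == "gamma"]
  # amplitude ratio (2 w_P1) : (0.5) = 4 in amplitude, 16 in power; the
  # band means divide by different bin counts (4 vs 40 bins)
  expect_equal(alpha / gamma, rep(16 * 40 / 4, 2), tolerance = 0.05)
  expect_error(channel_band_table(eeg2, bands = data.frame(
    name = "x", low = 100, high = 900)), "Nyquist")
})
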