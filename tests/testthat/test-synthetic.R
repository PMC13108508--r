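test_that("synthetic connectomes satisfy the downstream invariants", {
  con <- synth_connectome(12, density = 0.4, seed = 3)
  W <- con$weights
  expect_true(isSymmetric(unname(W)))
  expect_true(all(W >= 0))
  expect_equal(unname(diag(W)), rep(0, 12))
  expect_equal(length(unique(con$labels)), 12)
  # pairing is an involution pairing lh_i with rh_i
  expect_equal(con$pairing[con$pairing], seq_len(12))
  # full density connects every off-diagonal pair
  full <- synth_connectome(8, density = 1, homotopic_boost = 1, seed = 1)
  expect_true(all(full$weights[upper.tri(full$weights)] > 0))
  # pure function of the seed
  expect_identical(synth_connectome(12, seed = 5)$weights,
                   synth_connectome(12, seed = 5)$weights)
  expect_false(identical(synth_connectome(12, seed = 5)$weights,
                         synth_connectome(12, seed = 6)$weights))
})

test_that("homotopic boost separates pair weights from the background", {
  ratios <- vapply(1:10, function(s) {
    con <- synth_connectome(16, density = 0.5, homotopic_boost = 10,
                            seed = 100 + s)
    W <- con$weights
    pair_idx <- cbind(seq_len(16), con$pairing)
    hom <- W[pair_idx]
    ut <- upper.tri(W)
    nonhom <- W[ut & !(row(W) == con$pairing[col(W)])]
    mean(hom) / mean(nonhom[nonhom > 0])
  }, numeric(1))
  expect_gt(mean(ratios), 5)
})

test_that("receptor maps are exactly normalized and optionally symmetric", {
  r <- synth_receptor_map(20, smoothness = 0.8, seed = 4)
  expect_equal(min(r$values), 0)
  expect_equal(max(r$values), 1)
  rs <- synth_receptor_map(20, seed = 4, symmetric = TRUE)
  geom <- synth_parcel_geometry(20, seed = 4)
  expect_equal(unname(rs$values), unname(rs$values[geom$pairing]))
})

test_that("the synthetic leadfield is finite with labelled channels", {
  lf <- synth_leadfield(10, seed = 2)
  expect_equal(dim(lf), c(19, 10))
  expect_true(all(is.finite(lf)) && all(lf != 0))
  # signed orientation factors: each parcel keeps one polarity across
  # channels, and both polarities occur over parcels
  pol <- sign(lf[1, ])
  expect_true(all(sign(lf) == rep(pol, each = 19)))
  expect_true(any(pol > 0) && any(pol < 0))
  expect_true(all(c("Cz", "O1", "Fp2") %in% rownames(lf)))
})

test_that("synthetic target FC is a valid, noise-degraded model FC", {
  con <- synth_connectome(8, seed = 7)
  clean <- synth_empirical_fc(con, true_G = 1, true_ratio = 1,
                              duration = 40, noise_sd = 0, seed = 9)
  expect_true(isSymmetric(unname(unclass(clean))))
  expect_equal(unname(diag(clean)), rep(1, 8))
  expect_true(all(abs(clean) <= 1))
  noisy <- synth_empirical_fc(con, true_G = 1, true_ratio = 1,
                              duration = 40, noise_sd = 0.5, seed = 9)
  expect_true(isSymmetric(unname(unclass(noisy))))
  expect_true(all(abs(noisy) <= 1))
  expect_lt(fc_similarity(clean, noisy)[["pcc"]], 0.8)
  expect_equal(attr(clean, "true_parameters")[["G"]], 1)
})

test_that("cohorts are reproducible pure functions of the master seed", {
  spec <- synthetic_cohort_spec(n_subjects = 1, n_parcels = 8,
                                fc_duration = 20, master_seed = 77)
  a <- synth_cohort(spec)
  b <- synth_cohort(spec)
  expect_identical(a$subjects[[1]]$empirical_fc,
                   b$subjects[[1]]$empirical_fc)
  expect_identical(a$receptors$values, b$receptors$values)
  spec2 <- spec; spec2$master_seed <- 78
  c <- synth_cohort(spec2)
  expect_false(identical(a$subjects[[1]]$empirical_fc,
                         c$subjects[[1]]$empirical_fc))
})

test_that("alpha-active parcel fraction declines with coupling strength", {
  con <- synth_connectome(16, seed = 42)
  rec <- synth_receptor_map(16, seed = 42)
  frac <- vapply(c(1, 2, 3), function(G) {
    net <- network_parameters(G = G, sigma_c = 38, sigma_i = 38, psi = 0)
    nts <- simulate_network(build_network(con, net = net, receptors = rec),
                            duration = 16, seed = 5, store = "vP1")
    bt <- parcel_band_table(nts, "vP1")
    mean(bt$mean_psd[bt$band == "alpha"] >= 0.1)
  }, numeric(1))
  expect_true(all(diff(frac) <= 0))
  expect_lt(frac[3], frac[1])
})
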