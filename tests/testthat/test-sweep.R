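test_that("window detection recovers constructed presence profiles", {
  gains <- seq(2.5, 4.5, by = 0.05)
  # gamma present only on [3.0, 3.5]
  sw <- fake_sweep(gains, p1_alpha = rep(1, length(gains)),
                   p2_gamma = ifelse(gains >= 3.0 & gains <= 3.5, 1, 0))
  w <- detect_coexistence_window(sw, alpha_floor = 0.1, gamma_floor = 0.1)
  expect_false(w$empty)
  expect_equal(w$g_low, 3.0)
  expect_equal(w$g_high, 3.5)
  # floors above the global maximum give an explicit empty window
  w2 <- detect_coexistence_window(sw, alpha_floor = 10, gamma_floor = 10)
  expect_true(w2$empty)
  expect_true(is.na(w2$g_low))
})

test_that("alpha-floor crossing is found on a monotone profile", {
  gains <- seq(2.5, 4.5, by = 0.1)
  sw <- fake_sweep(gains, p1_alpha = pmax(0, 4 - gains),
                   p2_gamma = rep(1, length(gains)))
  # alpha(g) = 4 - g crosses 1 at g = 3: first grid gain strictly below the
  # floor is one step later
  expect_equal(find_alpha_floor_gain(sw, floor = 1, from = 2.5), 3.1)
  # a floor of zero is never crossed
  expect_true(is.na(find_alpha_floor_gain(sw, floor = 0)))
})

test_that("raising either floor never widens the window", {
  set.seed(9)
  gains <- seq(2.5, 4.5, by = 0.05)
  for (rep in 1:5) {
    alpha <- abs(stats::filter(rnorm(length(gains)), rep(1, 5),
                               circular = TRUE))
    gamma <- abs(stats::filter(rnorm(length(gains)), rep(1, 5),
                               circular = TRUE))
    sw <- fake_sweep(gains, as.numeric(alpha), as.numeric(gamma))
    w0 <- detect_coexistence_window(sw, 0.5, 0.5)
    for (f in c(1, 2, 4)) {
      w1 <- detect_coexistence_window(sw, 0.5 * f, 0.5)
      w2 <- detect_coexistence_window(sw, 0.5, 0.5 * f)
      for (w in list(w1, w2)) {
        if (w0$empty) expect_true(w$empty)
        if (!w$empty) {
          expect_gte(w$g_low, w0$g_low)
          expect_lte(w$g_high, w0$g_high)
        }
      }
    }
  }
})

test_that("grid refinement moves fixture boundaries at most one coarse step", {
  profile <- function(g) ifelse(g >= 3.02 & g <= 3.97, 1, 0)
  coarse_g <- seq(2.5, 4.5, by = 0.1)
  fine_g <- seq(2.5, 4.5, by = 0.05)
  wc <- detect_coexistence_window(
    fake_sweep(coarse_g, profile(coarse_g), profile(coarse_g)), 0.5, 0.5)
  wf <- detect_coexistence_window(
    fake_sweep(fine_g, profile(fine_g), profile(fine_g)), 0.5, 0.5)
  expect_lte(abs(wc$g_low - wf$g_low), 0.1)
  expect_lte(abs(wc$g_high - wf$g_high), 0.1)
})

test_that("a single-point sweep agrees with a direct node simulation", {
  cfg <- sweep_config(g_lo = 3.25, g_hi = 3.25, duration = 14, discard = 10)
  sw <- run_sweep(cfg = cfg, seed = 5)
  expect_equal(nrow(sw$table), 10)  # 2 populations x 5 bands
  ts <- simulate_node(duration = 14, seed = 5, gain_override = 3.25)
  keep <- 10001:14000
  direct <- welch_band_power(ts$potentials[keep, "P1"], 1000, 1000, c(8, 12))
  got <- sw$table$mean_psd[sw$table$population == "P1" &
                             sw$table$band == "alpha"]
  expect_equal(got, direct, tolerance = 1e-12)
})
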