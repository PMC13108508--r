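test_that("median binarization applies the stated tie rule", {
  expect_equal(binarize_median(c(1, 2, 3, 4)), c(0L, 0L, 1L, 1L))
  expect_equal(binarize_median(rep(7, 5)), rep(1L, 5))  # ties map to 1
  alt <- rep(c(-1, 1), 10)
  b <- binarize_median(alt)
  expect_equal(mean(b), 0.5)
  expect_equal(b, rep(c(0L, 1L), 10))
  expect_error(binarize_median(numeric(0)), "empty")
})

test_that("LZW complexity matches a brute-force reference implementation", {
  set.seed(13)
  for (n in c(64, 256, 1024, 4096)) {
    for (p in c(0.5, 0.9)) {
      bits <- rbinom(n, 1, p)
      expect_equal(lzw_rho0(bits), ref_lzw_rho0(bits))
    }
  }
  # structured strings
  expect_equal(lzw_rho0(rep(0L, 16)), ref_lzw_rho0(rep(0L, 16)))
  expect_equal(lzw_rho0(rep(c(0L, 1L), 50)), ref_lzw_rho0(rep(c(0L, 1L), 50)))
  # string input form
  expect_equal(lzw_rho0("0011010110"), ref_lzw_rho0(c(0,0,1,1,0,1,0,1,1,0)))
  expect_error(lzw_rho0(c(0L, 2L)), "binary")
})

test_that("rho0 separates compressible from incompressible strings", {
  expect_lt(lzw_rho0(rep(0L, 1024)), 0.5)
  set.seed(17)
  for (s in 1:5) {
    # finite-length LZW with fixed-width final-dictionary codes parses
    # fair-coin bits at ~1.3 bits/char at this length (the asymptote of 1
    # is approached only logarithmically); structured strings sit far below
    coin <- rbinom(65536, 1, 0.5)
    r <- lzw_rho0(coin)
    expect_gt(r, 0.9); expect_lt(r, 1.5)
  }
  # relabeling symmetry: complement leaves rho0 unchanged
  set.seed(18)
  x <- rbinom(2048, 1, 0.3)
  expect_equal(lzw_rho0(x), lzw_rho0(1L - x))
  # dictionary reuse: two copies compress at most as badly as one
  y <- rbinom(1024, 1, 0.5)
  expect_lte(lzw_rho0(c(y, y)), lzw_rho0(y) + 1e-9)
})

test_that("entropy rates match exact values and the reference estimator", {
  set.seed(19)
  coin <- rbinom(1e5, 1, 0.5)
  expect_equal(entropy_rate(coin, 0), 1, tolerance = 0.01)
  alt <- rep(c(0L, 1L), 300)
  expect_equal(entropy_rate(alt, 0), 1, tolerance = 1e-3)
  expect_equal(entropy_rate(alt, 1), 0, tolerance = 1e-12)
  # agreement with the naive enumerator on assorted strings
  for (s in 1:4) {
    x <- rbinom(3000, 1, c(0.5, 0.7, 0.5, 0.9)[s])
    for (n in 0:3)
      expect_equal(entropy_rate(x, n), ref_entropy_rate(x, n),
                   tolerance = 1e-12)
  }
  # conditioning never increases entropy (up to plug-in estimation bias,
  # which is O(2^order / n) for the maximum-likelihood estimator)
  for (s in 1:5) {
    x <- rbinom(20000, 1, 0.6)
    h <- vapply(0:5, function(n) entropy_rate(x, n), numeric(1))
    expect_true(all(diff(h) <= 2e-3))
  }
  expect_error(entropy_rate(rbinom(50, 1, 0.5), 3), "too short")
})

test_that("spectral entropy has its closed-form extremes", {
  expect_equal(spectral_entropy(rep(2, 8)), 3)          # log2(8)
  expect_equal(spectral_entropy(c(0, 5, 0, 0)), 0)      # single bin
  expect_equal(spectral_entropy(c(1, 0, 0, 1)), 1)      # two equal bins
  expect_error(spectral_entropy(c(1, -1)), "nonnegative")
  expect_error(spectral_entropy(c(0, 0)), "power")
  # concentration never raises entropy: move mass into the largest bin
  set.seed(20)
  for (s in 1:5) {
    p <- runif(16)
    q <- p
    k <- which.max(q)
    j <- which.min(q)
    q[k] <- q[k] + q[j] / 2; q[j] <- q[j] / 2
    expect_lte(spectral_entropy(q), spectral_entropy(p) + 1e-9)
  }
})

test_that("removing the alpha component of a broadband mixture raises
           spectral entropy", {
  fs <- 1000
  t <- seq_len(10000) / fs
  set.seed(21)
  noise <- rnorm(10000, sd = 0.5)
  alpha_comp <- 3 * sin(2 * pi * 10 * t)
  with_alpha <- welch_psd(noise + alpha_comp, fs, 1000)$psd
  without <- welch_psd(noise, fs, 1000)$psd
  expect_gt(spectral_entropy(without), spectral_entropy(with_alpha))
})

test_that("the EEG complexity suite is deterministic and orders regularity", {
  fs <- 1000
  t <- seq_len(6000) / fs
  mk_eeg <- function(sig) {
    structure(list(signals = cbind(a = sig, b = rev(sig)), fs = fs,
                   channels = c("a", "b"), psi = 0, reference = "average"),
              class = "lanmm_eeg")
  }
  set.seed(22)
  noisy <- mk_eeg(rnorm(6000))
  tone <- mk_eeg(sin(2 * pi * 10 * t) + 0.01 * rnorm(6000))
  m1 <- eeg_complexity_suite(noisy)
  m2 <- eeg_complexity_suite(noisy)
  expect_identical(m1, m2)
  m3 <- eeg_complexity_suite(tone)
  expect_gt(m1$rho0, m3$rho0)
  expect_true(all(diff(m1$entropy_rate) <= 1e-12))
  expect_gt(m1$spectral_entropy, m3$spectral_entropy)
  expect_error(eeg_complexity_suite(mk_eeg(rnorm(1000)), epoch = 5),
               "shorter")
})
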