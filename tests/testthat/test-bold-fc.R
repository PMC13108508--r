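test_that("zero drive keeps BOLD at its baseline fixed point", {
  z <- matrix(0, 5000, 2)
  out <- bold_from_activity(z, fs = 100, tr_out = 1)
  expect_lt(max(abs(out$bold)), 1e-9)
})

test_that("the hemodynamic response matches an independent ODE solution", {
  skip_if_not_installed("deSolve")
  h <- hemodynamic_parameters()
  fs <- 100
  tt <- seq_len(20 * fs) / fs
  # constant drive avoids any forcing-discretization mismatch between the
  # two integrators, so agreement reflects the equations alone
  out <- bold_from_activity(matrix(0.4, 20 * fs, 1), fs = fs, h = h,
                            tr_out = 1 / fs)
  rhs <- function(t, y, p) {
    s <- y[1]; f <- max(y[2], 1e-6); v <- max(y[3], 1e-6); q <- y[4]
    fv <- v^(1 / p$alpha)
    Ef <- 1 - (1 - p$E0)^(1 / f)
    list(c(0.4 - p$kappa * s - p$gamma * (f - 1), s,
           (f - fv) / p$tau, (f * Ef / p$E0 - fv * q / v) / p$tau))
  }
  sol <- deSolve::ode(c(0, 1, 1, 1), c(0, tt), rhs, h, method = "rk4",
                      hini = 1 / fs)
  k1 <- 7 * h$E0; k2 <- 2; k3 <- 2 * h$E0 - 0.2
  ref <- h$V0 * (k1 * (1 - sol[-1, 5]) + k2 * (1 - sol[-1, 5] / sol[-1, 4]) +
                   k3 * (1 - sol[-1, 4]))
  expect_lt(max(abs(out$bold[, 1] - ref)), 1e-6)
})

test_that("a boxcar stimulus evokes the canonical hemodynamic shape", {
  fs <- 100
  tt <- seq_len(40 * fs) / fs
  z <- as.numeric(tt >= 2 & tt < 4)  # 2-s boxcar
  out <- bold_from_activity(matrix(z, ncol = 1), fs = fs, tr_out = 1 / fs)
  # peak several seconds after onset, then an undershoot
  peak_t <- tt[which.max(out$bold[, 1])]
  expect_gt(peak_t - 2, 3); expect_lt(peak_t - 2, 8)
  expect_lt(min(out$bold[tt > peak_t, 1]), 0)
})

test_that("parcels are hemodynamically independent", {
  set.seed(1)
  z <- matrix(rnorm(2000), 1000, 2)
  z[, 2] <- z[, 1]
  out <- bold_from_activity(z, fs = 100, tr_out = 0.5)
  expect_equal(out$bold[, 1], out$bold[, 2])
})

test_that("FC has the exact correlation structure of its inputs", {
  set.seed(8)
  x <- rnorm(1000)
  ident <- cbind(a = x, b = x + 0)
  fc <- compute_fc(ident, discard = 0, tr = 1)
  expect_equal(fc["a", "b"], 1)
  indep <- cbind(a = rnorm(1000), b = rnorm(1000))
  fc2 <- compute_fc(indep, discard = 0, tr = 1)
  expect_lt(abs(fc2["a", "b"]), 0.1)
  # three parcels sharing a common component of variance fraction rho:
  # x_i = sqrt(rho) g + sqrt(1-rho) e_i gives pairwise correlation rho
  rho <- 0.6
  g <- rnorm(20000)
  m <- vapply(1:3, function(i) sqrt(rho) * g + sqrt(1 - rho) * rnorm(20000),
              numeric(20000))
  fc3 <- compute_fc(m, discard = 0, tr = 1)
  off <- fc3[upper.tri(fc3)]
  expect_true(all(abs(off - rho) < 0.05))
  # constant series are reported by parcel
  bad <- cbind(ok = rnorm(100), flat = rep(1, 100))
  expect_error(compute_fc(bad, discard = 0, tr = 1), "flat")
})

test_that("FC similarity matches hand computation and edge cases", {
  a <- matrix(c(1, .2, .4, .2, 1, .6, .4, .6, 1), 3, 3)
  expect_equal(unname(fc_similarity(a, a)), c(0, 1))
  b <- a; b[upper.tri(b)] <- -a[upper.tri(a)]
  b[lower.tri(b)] <- t(b)[lower.tri(b)]
  expect_equal(fc_similarity(a, b)[["pcc"]], -1)
  # hand evaluation on the upper triangle (.2, .4, .6) vs (.3, .1, .5)
  c2 <- a; c2[upper.tri(c2)] <- c(0.3, 0.1, 0.5)
  expect_equal(fc_similarity(a, c2)[["rmse"]],
               sqrt(mean(c(.2 - .3, .4 - .1, .6 - .5)^2)))
  rownames(a) <- colnames(a) <- letters[1:3]
  d <- a; rownames(d) <- colnames(d) <- c("a", "b", "z")
  expect_error(fc_similarity(a, d), "labels")
})

test_that("FC is invariant to affine rescaling of BOLD", {
  set.seed(3)
  m <- matrix(rnorm(600), 200, 3)
  f1 <- compute_fc(m, discard = 0, tr = 1)
  f2 <- compute_fc(3.7 * m + 11, discard = 0, tr = 1)
  expect_equal(unclass(f1), unclass(f2), tolerance = 1e-12)
})
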