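test_that("sigmoid rate has the stated value, symmetry and saturation", {
  p <- sigmoid_parameters(phi0 = 2.5, nu0 = 6, r = 0.56)
  expect_equal(sigmoid_rate(p$nu0, p), 2.5)
  # direct evaluation at v = 0: 2*2.5 / (1 + exp(0.56 * 6))
  expect_equal(sigmoid_rate(0, p), 5 / (1 + exp(3.36)), tolerance = 1e-12)
  expect_equal(sigmoid_rate(p$nu0 + 50 / p$r, p), 2 * p$phi0,
               tolerance = 1e-12)
  v <- seq(-40, 40, by = 0.5)
  phi <- sigmoid_rate(v, p)
  expect_true(all(diff(phi) > 0))
  expect_true(all(phi > 0 & phi < 2 * p$phi0))
  expect_error(sigmoid_rate(NaN, p), "non-finite")
  expect_error(sigmoid_parameters(phi0 = -1), "positive")
})

test_that("synapse derivatives encode the second-order operator", {
  syn <- list(A = 3.25, a = 100, C = 108)
  # rest is a fixed point
  expect_equal(synapse_derivatives(0, 0, 0, syn), c(0, 0))
  # steady state under constant input: u* = (A/a) C phi
  phi_bar <- 2
  u_star <- syn$A / syn$a * syn$C * phi_bar
  expect_equal(synapse_derivatives(u_star, 0, phi_bar, syn), c(0, 0),
               tolerance = 1e-12)
  expect_error(synapse_derivatives(Inf, 0, 0, syn), "non-finite")
})

test_that("RK4 synapse response matches the closed-form impulse kernel", {
  # An impulse at t = 0 from rest sets udot = A a C; the subsequent free
  # response is u(t) = A a C t exp(-a t).
  rk4_kernel <- function(case, dt, t_end) {
    n <- round(t_end / dt)
    u <- 0; udot <- case$A * case$a * case$C
    traj <- numeric(n)
    f <- function(s) synapse_derivatives(s[1], s[2], 0, case)
    for (k in seq_len(n)) {
      y <- c(u, udot)
      k1 <- f(y); k2 <- f(y + dt / 2 * k1); k3 <- f(y + dt / 2 * k2)
      k4 <- f(y + dt * k3)
      y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      u <- y[1]; udot <- y[2]
      traj[k] <- u
    }
    traj
  }
  for (case in list(list(A = 3.25, a = 100, C = 1),
                    list(A = 22, a = 46, C = 33.75))) {
    for (dt in c(1e-3, 5e-4)) {
      traj <- rk4_kernel(case, dt, 0.025)
      tt <- dt * seq_along(traj)
      exact <- case$A * case$a * case$C * tt * exp(-case$a * tt)
      tol <- if (dt == 1e-3) 5e-6 else 1e-6
      for (ms in c(5, 10, 20)) {
        i <- which.min(abs(tt - ms / 1000))
        expect_lt(abs(traj[i] - exact[i]) / abs(exact[i]), tol)
      }
    }
  }
})

test_that("synaptic dynamics are linear in the input rate", {
  syn <- list(A = 3.25, a = 100, C = 135)
  u1 <- syn$A / syn$a * syn$C * 1.5
  u2 <- syn$A / syn$a * syn$C * 3.0
  expect_equal(u2, 2 * u1)
  # doubling the drive doubles the residual at any state
  d1 <- synapse_derivatives(0.3, 0.1, 1.5, syn)[2]
  d2 <- synapse_derivatives(0.6, 0.2, 3.0, syn)[2]
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
})

test_that("membrane potential is the signed sum of incoming perturbations", {
  p <- lanmm_parameters()
  st <- list(u = numeric(13))
  expect_equal(membrane_potential(st, "P1", p), 0)
  # P1 receives synapses 1 (exc), 2 (inh), 3 (exc), 4 (exc), 5 (inh)
  st$u[1] <- 2.0; st$u[4] <- 1.0; st$u[2] <- 0.5
  expect_equal(membrane_potential(st, "P1", p), 2.5)
  st2 <- list(u = numeric(13)); st2$u[6] <- 1.5
  expect_equal(membrane_potential(st2, "SS", p), 1.5)
  expect_error(membrane_potential(st, "L5", p), "unknown population")
})
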