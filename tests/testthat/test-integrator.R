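test_that("rk2_step matches the closed-form Heun update", {
  # f == 0: state unchanged
  s <- rk2_step(c(V = 1, x = 2), function(t, y) c(0, 0), 0, 0.1)
  expect_equal(unname(s), c(1, 2))
  # dV/dt = -V, V0 = 1, dt = 0.1: 1 - 0.1 + 0.005 = 0.905
  s <- rk2_step(c(V = 1), function(t, y) -y, 0, 0.1)
  expect_equal(unname(s), 0.905)
  expect_error(rk2_step(c(V = 1), function(t, y) NaN, 0, 0.1), "diverged")
})

test_that("the integrator is second order on a linear system", {
  # global error against exp(-t) shrinks ~4x when dt halves
  err <- sapply(c(0.2, 0.1, 0.05), function(dt) {
    y <- 1
    for (i in seq_len(round(10 / dt))) y <- rk2_step(y, function(t, v) -v, 0, dt)
    abs(y - exp(-10))
  })
  expect_equal(err[1] / err[2], 4, tolerance = 0.35)
  expect_equal(err[2] / err[3], 4, tolerance = 0.35)

  # dt halving on the passive membrane changes the final voltage < 1e-4 mV
  stim1 <- make_sinusoid(5, 0.1, 0, T = 1, dt = 0.1)
  stim2 <- make_sinusoid(5, 0.1, 0, T = 1, dt = 0.05)
  v1 <- simulate_cell(rc_cell(), stim1)$V
  v2 <- simulate_cell(rc_cell(), stim2)$V
  expect_lt(abs(tail(v1, 1) - tail(v2, 1)), 1e-4)
})

test_that("LIF relaxes to E_L + I/g_L and stays silent below threshold", {
  res <- simulate_cell(lif_cell(), make_constant(0.9, 2))
  expect_equal(tail(res$V, 1), -51, tolerance = 1e-3)
  expect_length(res$spikes$times, 0)
})

test_that("threshold crossing triggers the clamp-reset spike mechanism", {
  cell <- lif_cell(T_spike = 1)
  res <- simulate_cell(cell, make_constant(1.2, 1))  # V_inf = -48 > V_th
  expect_gt(length(res$spikes$times), 0)
  s1 <- res$spikes$times[1]
  i <- round(s1 / res$dt) + 1
  nclamp <- round(cell$T_spike / res$dt)
  expect_true(all(res$V[i:(i + nclamp - 1)] == cell$V_peak))
  expect_equal(res$V[i + nclamp], cell$V_reset)
  # no spike logged during the clamp: ISIs exceed T_spike
  expect_true(all(diff(res$spikes$times) > cell$T_spike))
})

test_that("subthreshold runs are bit-deterministic and trials reproducible", {
  stim <- make_sinusoid(8, 0.1, -1.85, 1)
  a <- simulate_cell(naph_cell(), stim, sigma = 0.3, seed = 5, trial = 2)
  b <- simulate_cell(naph_cell(), stim, sigma = 0.3, seed = 5, trial = 2)
  expect_identical(a$V, b$V)
  c <- simulate_cell(naph_cell(), stim, sigma = 0.3, seed = 5, trial = 3)
  expect_false(identical(a$V, c$V))

  # sigma = 0: all trials identical
  runs <- run_trials(lif_cell(), make_constant(0.9, 1), n_trials = 3,
                     master_seed = 1)
  expect_identical(runs[[1]]$V, runs[[3]]$V)
})

test_that("resonant conductance-based cell fires once per cycle at its band", {
  res <- simulate_cell(naph_cell(), make_sinusoid(8, 0.15, -1.85, 3),
                       arm_after = 1000, record = character(0))
  n_cycles <- 8 * 2  # analysis window 2 s
  expect_gte(sum(res$spikes$times > 1000), n_cycles)
})

test_that("divergence is reported as an error", {
  bad <- lif_cell(g_L = -2)  # unstable membrane
  # keep the threshold disarmed so the blow-up is not caught as a spike
  expect_error(simulate_cell(bad, make_constant(1, 1), arm_after = 1000),
               "diverged")
})

test_that("compiled trajectories agree with a reference ODE solver", {
  skip_if_not_installed("deSolve")
  stim <- make_sinusoid(7, 0.05, -1.85, 2)
  res <- simulate_cell(naph_cell(), stim, record = c("v", "aux"))
  cell <- naph_cell()
  rhs <- function(t, y, p) {
    I <- -1.85 + 0.05 * sin(2 * pi * 7 * t / 1000)
    list(unname(nap_h_deriv(y[1], y[2], I, cell)))
  }
  y0 <- c(neurores:::rest_V(cell, -1.85), 0)
  y0[2] <- naph_r_inf(y0[1])
  out <- deSolve::ode(y0, seq(0, 2000, by = 1), rhs, NULL, method = "ode45")
  idx <- round(out[, "time"] / 0.1) + 1
  expect_lt(max(abs(out[, 2] - res$V[idx])), 0.02)
})
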