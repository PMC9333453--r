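test_that("gating curves hit their midpoints and stay bounded and monotone", {
  expect_equal(naph_p_inf(-38), 0.5)
  expect_equal(naph_r_inf(-79.2), 0.5)
  expect_equal(pyr_gates(-82.9)$r_inf, 0.5)
  expect_equal(int_gates(-35)$q_inf, 0.5)
  expect_equal(H_syn(0), 0.5)
  expect_lt(abs(H_syn(50) - 1), 1e-10)

  V <- seq(-120, 60, by = 0.5)
  for (x in list(naph_p_inf(V), pyr_gates(V)$m_inf, pyr_gates(V)$h_inf,
                 pyr_gates(V)$n_inf, pyr_gates(V)$r_inf,
                 int_gates(V)$m_inf, int_gates(V)$h_inf,
                 int_gates(V)$n_inf, int_gates(V)$q_inf, naph_r_inf(V))) {
    expect_true(all(x >= 0 & x <= 1))
    d <- diff(x)
    expect_true(all(d >= -1e-12) || all(d <= 1e-12))  # monotone either way
  }
  for (tau in list(pyr_gates(V)$tau_h, pyr_gates(V)$tau_n, pyr_gates(V)$tau_r,
                   int_gates(V)$tau_h, int_gates(V)$tau_n, int_gates(V)$tau_q))
    expect_true(all(tau > 0))
})

test_that("derivative functions satisfy closed-form special cases", {
  expect_equal(lif_deriv(-60, 0)[["dV"]], 0)
  # steady state under bias: V_inf = E_L + I/g_L
  cell <- lif_cell()
  Vinf <- cell$E_L + 0.9 / cell$g_L
  expect_equal(lif_deriv(Vinf, 0.9)[["dV"]], 0)

  # calcium: N_C = 0 leaves pure decay of K
  d <- calcium_lif_deriv(-60, K = 0.4, N_C = 0, I_in = 0)
  expect_equal(d[["dK"]], -0.4 / 5)
  expect_equal(d[["dN_C"]], 0)
  # fixed N_C: K equilibrium where dK/dt = 0
  NC <- 0.1
  Keq <- uniroot(function(K) NC * (1 - K) / 50 - K / 5, c(0, 1))$root
  expect_equal(unname(calcium_lif_deriv(-60, Keq, NC, 0)[["dK"]]), 0,
               tolerance = 1e-9)
  expect_equal(Keq, (NC / 50) / (NC / 50 + 1 / 5), tolerance = 1e-6)

  # plasticity resting fixed points without presynaptic drive
  dp <- plasticity_deriv(D = 1, F = 0, V_pre = -60)
  expect_equal(unname(dp), c(0, 0), tolerance = 1e-6)
})

test_that("gating and plasticity variables stay in [0, 1] along trajectories", {
  set.seed(11)
  jitter <- function(x) x * runif(1, 0.8, 1.2)
  for (k in 1:4) {
    cell <- naph_cell(g_p = jitter(0.1), g_h = jitter(1), tau_r = jitter(100))
    res <- simulate_cell(cell, make_sinusoid(8, 0.1, -1.85, 1), sigma = 0.5,
                         seed = k, record = "aux")
    expect_true(all(res$aux[, "r"] >= 0 & res$aux[, "r"] <= 1))

    ccell <- calcium_lif_cell(g_C = jitter(0.08), tau_act = jitter(50),
                              tau_inact = jitter(5), tau_deact = jitter(70))
    res <- simulate_cell(ccell, make_sinusoid(8, 8, -3, 1), sigma = 0.3,
                         seed = k, record = "aux")
    expect_true(all(res$aux >= -1e-9 & res$aux <= 1 + 1e-9))

    pcell <- plastic_lif_cell(tau_dep = jitter(100), tau_fac = jitter(300))
    train <- make_periodic_spike_train(make_sinusoid(12, 1, 0, 1))
    vpre <- spikes_to_presynaptic_voltage(train, 0.1, 1)
    res <- simulate_cell(pcell, make_constant(1.2, 1), presyn = vpre,
                         sigma = 0.3, seed = k, record = "aux")
    expect_true(all(res$aux >= -1e-9 & res$aux <= 1 + 1e-9))
  }
  # biophysical cells through full spikes
  res <- simulate_cell(pyr_cell(), make_sinusoid(10, 0.3, -2.7, 1, dt = 0.025),
                       sigma = 0.2, seed = 1, record = "aux")
  expect_true(all(res$aux >= 0 & res$aux <= 1))
  res <- simulate_cell(int_cell(g_M = 0), make_constant(1, 1, dt = 0.025),
                       record = "aux")
  expect_true(all(res$aux >= 0 & res$aux <= 1))
})

test_that("ablations reduce the models to their passive references", {
  # persistent sodium and h-current removed: analytic RC impedance
  prof <- impedance_profile(rc_cell(), c(1, 5, 20), A_in = 0.05, I_bias = 0)
  ref <- rc_impedance(c(1, 5, 20))
  expect_true(all(abs(prof$mag / ref$mag - 1) < 0.01))

  # depression and facilitation disabled: conductance reduces to g_S * S
  train <- make_periodic_spike_train(make_sinusoid(10, 1, 0, 2))
  vpre <- spikes_to_presynaptic_voltage(train, 0.1, 2)
  plain <- plastic_lif_cell(depression = FALSE, facilitation = FALSE)
  plain$V_th <- 0
  simp <- simulate_cell(plain, make_constant(0, 2), presyn = vpre,
                        record = c("v", "aux"))
  expect_true(all(simp$aux[, "D"] == 1))
  expect_true(all(simp$aux[, "F"] == 1))
  # reference: integrate the same LIF + gate ODE with deSolve
  skip_if_not_installed("deSolve")
  cellp <- plain
  rhs <- function(t, y, parms) {
    i <- min(length(vpre$value), floor(t / 0.1) + 1)
    hv <- H_syn(vpre$value[i])
    dV <- (-cellp$g_L * (y[1] - cellp$E_L) -
             cellp$g_S * y[2] * (y[1] - cellp$E_S)) / cellp$C
    dS <- hv * (1 - y[2]) / cellp$tau_syn_r - y[2] / cellp$tau_syn_d
    list(c(dV, dS))
  }
  out <- deSolve::ode(c(V = -65, S = 0), seq(0, 2000, by = 0.5), rhs, NULL,
                      method = "ode45")
  idx <- round(out[, "time"] / 0.1) + 1
  # edge alignment of the 1 ms pulses differs between the fixed-step grid
  # and the adaptive reference; bounded by a fraction of the EPSP rise
  expect_lt(max(abs(out[, "V"] - simp$V[idx])), 0.6)
})
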