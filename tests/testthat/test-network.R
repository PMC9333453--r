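test_that("total synaptic current follows the class-conductance formalism", {
  expect_equal(total_synaptic_current(c(1, 1), c(0, 0), -60, c(0, -80)), 0)
  # one excitatory synapse at S = 1: -g (V - E) is depolarizing below E
  expect_equal(total_synaptic_current(1, 1, -60, 0), -60)
  # shunting: zero current at the reversal potential
  expect_equal(total_synaptic_current(0.4, 0.7, -80, -80), 0)
})

test_that("presets resolve and unknown names list the valid ones", {
  for (nm in c("subthreshold_EI", "rlif_EI", "psp_layers", "int_pyr",
               "gamma_int_pyr"))
    expect_s3_class(build_preset(nm), "nr_network")
  expect_error(build_preset("nonsense"), "valid presets")
  # the feedforward-inhibition preset carries its defining conductances
  net <- build_preset("int_pyr")
  expect_equal(net$syn$g_ei, 0.4)
  expect_equal(net$syn$g_ee + net$syn$g_ie + net$syn$g_ii, 0)
  expect_equal(net$drive$i$A_in, 0.5)
  expect_equal(net$drive$e$I_bias, -2.7)
})

test_that("decoupled network cells reproduce isolated trajectories", {
  net <- build_preset("rlif_EI")
  net$syn$g_ie <- 0; net$syn$g_ii <- 0
  net$sigma_e <- 0; net$sigma_i <- 0
  net$stim$T <- 2; net$settle <- 0.5
  run <- simulate_network(net, master_seed = 1, trial = 1, record_cells = 1L)
  # isolated E-cell with the same drive
  r <- run_chirp_trials(net$e_cell, f0 = 0, f1 = 40, T = 2,
                        A_in = 0.115, I_bias = 0.9, sigma = 0, settle = 0.5,
                        master_seed = 1, record = TRUE)
  expect_equal(run$V[["cell1"]], r$V, tolerance = 1e-12)
  expect_equal(run$spikes[[1]]$times, r$trains[[1]]$times)
})

test_that("feedforward structure: downstream changes cannot alter upstream", {
  net <- build_preset("psp_layers")
  net$stim$T <- 4
  a <- simulate_network(net, master_seed = 2, trial = 1, sigma2 = 0.3)
  net2 <- net
  net2$g23 <- 0  # cut layer-2 -> layer-3 synapses entirely
  b <- simulate_network(net2, master_seed = 2, trial = 1, sigma2 = 0.3)
  for (c in 1:net$N2)
    expect_identical(a$spikes[[c]]$times, b$spikes[[c]]$times)
  # and the layer-3 output did depend on it
  expect_false(identical(a$spikes[[net$N2 + 1]]$times,
                         b$spikes[[net$N2 + 1]]$times))
})

test_that("network runs are reproducible from (seed, trial)", {
  net <- build_preset("int_pyr")
  net$stim$T <- 2
  a <- simulate_network(net, master_seed = 9, trial = 4)
  b <- simulate_network(net, master_seed = 9, trial = 4)
  expect_identical(a$V$pyr, b$V$pyr)
  c <- simulate_network(net, master_seed = 9, trial = 5)
  expect_false(identical(a$V$pyr, c$V$pyr))
})

test_that("driven E/I network transmits spiking to the target population", {
  net <- build_preset("rlif_EI")
  net$stim$T <- 6
  run <- simulate_network(net, master_seed = 3, trial = 1)
  ne <- sum(lengths(lapply(run$spikes[1:16], `[[`, "times")) > 0)
  expect_gte(ne, 12)  # driven E-cells spike
  ni <- vapply(run$spikes[17:20], function(s) length(s$times), 0L)
  expect_true(all(ni > 0))  # noisy I-cells receive and fire
})

test_that("presets relax to bounded activity without drive or noise", {
  net <- build_preset("int_pyr")
  net$drive$i$A_in <- 0; net$sigma_i <- 0; net$sigma_e <- 0
  net$stim$T <- 5
  run <- simulate_network(net, master_seed = 1, trial = 1)
  expect_true(all(is.finite(run$V$pyr)))
  expect_true(all(abs(run$V$pyr) < 120))
})
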