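test_that("simulated RC impedance matches the closed form within 1%", {
  f <- seq(1, 40, by = 3)
  prof <- impedance_profile(rc_cell(), f, A_in = 0.05, I_bias = 0)
  ref <- rc_impedance(f)
  expect_true(all(abs(prof$mag / ref$mag - 1) < 0.01))
  # DC limit: |Z| -> 1/g_L = 10 mV per uA/cm2
  p0 <- impedance_profile(rc_cell(), 0.5, A_in = 0.05, I_bias = 0, T = 5,
                          settle = 1)
  expect_equal(p0$mag, 10, tolerance = 0.01)
  # phase -pi/4 at the corner frequency f = 1/(2 pi tau)
  fc <- 1000 / (2 * pi * 10)
  pc <- impedance_profile(rc_cell(), fc, A_in = 0.05, I_bias = 0)
  expect_equal(pc$phase, -pi / 4, tolerance = 0.01)
  expect_true(all(abs(prof$phase - rc_impedance(f)$phase) < 0.01))
})

test_that("impedance errors out when the cell spikes in the window", {
  expect_error(impedance_profile(naph_cell(), 8, A_in = 1), "subthreshold")
})

test_that("cycle-averaged rate assigns spikes to instantaneous frequency", {
  # one spike per cycle at every frequency: rate equals f
  stims <- lapply(c(4, 10, 20), function(f) make_sinusoid(f, 1, 0, 5))
  trains <- lapply(stims, make_periodic_spike_train)
  prof <- cycle_averaged_rate(trains, stims)
  expect_equal(prof$value, prof$f, tolerance = 0.05)
  # empty train: all-zero profile
  ch <- make_chirp(0, 40, 1, 0, 20)
  p0 <- cycle_averaged_rate(neurores:::new_spike_train(numeric(0), 20), ch)
  expect_true(all(p0$value == 0))
  # chirp-locked train: flat one-spike-per-cycle profile equals f
  tr <- make_periodic_spike_train(ch)
  p1 <- cycle_averaged_rate(tr, ch)
  mid <- p1$f > 5 & p1$f < 38
  expect_equal(p1$value[mid], p1$f[mid], tolerance = 0.15)
})

test_that("fingerprint conserves counts and marginalizes to the rate", {
  ch <- make_chirp(0, 40, 1, 0, 20)
  set.seed(4)
  trains <- lapply(1:3, function(k) random_train(300, 20, k))
  fp <- fingerprint(trains, ch)
  expect_equal(sum(fp$counts), 900)
  expect_equal(sum(fp$rate * fp$occupancy), 900, tolerance = 1e-6)
  marg <- fingerprint_rate_marginal(fp)
  rate <- cycle_averaged_rate(trains, ch)
  expect_equal(marg$value, rate$value, tolerance = 0.2)
  # homogeneous random spikes: approximately flat map (coarse bins so each
  # holds enough counts for the sampling error to stay small)
  fpc <- fingerprint(trains, ch, f_bin = 8, n_phase_bins = 9)
  occ_ok <- fpc$occupancy >= stats::median(fpc$occupancy)
  expect_lt(sd(fpc$rate[occ_ok]) / mean(fpc$rate[occ_ok]), 0.6)
  # expansion renders 1.5 cycles
  m <- expand_phase(fp)
  expect_equal(ncol(m), ceiling(length(fp$phase) * 1.5))
})

test_that("phase-band synthetic trains show a localized fingerprint patch", {
  synth <- make_synthetic_trains("phase_band", f_grid = 2:20, band = c(8, 12),
                                 kappa_in = 12, kappa_out = 0.3, T = 10,
                                 seed = 5)
  fp <- fingerprint(lapply(synth, `[[`, "train"), lapply(synth, `[[`, "stim"))
  peak <- which(fp$rate == max(fp$rate), arr.ind = TRUE)[1, ]
  expect_true(fp$f[peak[1]] >= 8 && fp$f[peak[1]] <= 12)
  expect_lt(abs(fp$phase[peak[2]]), 0.5)  # concentrated near phase 0
})

test_that("coherence is bounded, saturates under locking, decays to the floor", {
  # perfect locking to a 10 Hz sinusoid
  stim <- make_sinusoid(10, 1, 0, 30)
  tr <- make_periodic_spike_train(stim)
  co <- spike_input_coherence(tr, stim, f_max = 50)
  expect_true(all(co$coh >= 0 & co$coh <= 1))
  expect_gt(co$coh[co$f == 10], 0.99)
  # random spikes: coherence near the 1/n_segments bias floor at the drive f
  set.seed(6)
  cos_r <- replicate(8, {
    co_r <- spike_input_coherence(random_train(300, 30), stim, f_max = 50)
    co_r$coh[co_r$f == 10]
  })
  expect_lt(mean(cos_r), 3 / sqrt(co$n_segments))
  # property: bounded for arbitrary random trains against arbitrary inputs
  ch <- make_chirp(0, 40, 1, 0, 10)
  for (k in 1:5) {
    co_k <- spike_input_coherence(random_train(50 * k, 10), ch)
    expect_true(all(co_k$coh >= 0 & co_k$coh <= 1))
  }
  # zero spikes: defined, flagged
  co0 <- spike_input_coherence(neurores:::new_spike_train(numeric(0), 10), ch)
  expect_true(all(co0$coh == 0))
  expect_true(attr(co0, "zero_spikes"))
})

test_that("EPSP profiles express the depression/facilitation filters", {
  rates <- c(1, 4, 8, 14, 20, 30)
  dep <- epsp_profile(plastic_lif_cell(facilitation = FALSE), rates)
  expect_true(all(diff(dep$value) < 1e-9))  # LPF: non-increasing
  fac <- epsp_profile(plastic_lif_cell(depression = FALSE), rates)
  expect_true(all(diff(fac$value[1:5]) > -1e-9))  # HPF up to ~20 Hz
  both <- epsp_profile(plastic_lif_cell(), c(1, 2, 4, 6, 8, 10, 14, 20, 30, 40))
  pk <- find_resonant_peak(both, smooth = 1)
  expect_true(pk$resonant)
  expect_true(pk$f_peak >= 4 && pk$f_peak <= 12)
  # a single presynaptic spike yields the unitary EPSP amplitude
  cell <- plastic_lif_cell(depression = FALSE, facilitation = FALSE)
  cell$V_th <- 0
  tr1 <- neurores:::new_spike_train(500, 2)
  sim <- simulate_cell(cell, make_constant(0, 2),
                       presyn = spikes_to_presynaptic_voltage(tr1, 0.1, 2))
  expect_equal(epsp_magnitude(sim, tr1), max(sim$V) - (-65), tolerance = 1e-6)
})

test_that("peak extraction flags boundary peaks and breaks ties low", {
  mono <- neurores:::new_profile(1:10, 10:1, "rate")
  pk <- find_resonant_peak(mono, smooth = 1)
  expect_false(pk$resonant)
  bump <- neurores:::new_profile(1:19, dnorm(1:19, 10, 3), "rate")
  expect_equal(find_resonant_peak(bump)$f_peak, 10)
  tie <- neurores:::new_profile(1:5, c(1, 3, 3, 3, 1), "rate")
  expect_equal(find_resonant_peak(tie, smooth = 1)$f_peak, 2)
  expect_error(find_resonant_peak(neurores:::new_profile(numeric(0),
                                                         numeric(0), "rate")),
               "empty")
})

test_that("spiking bands are located with low-pass detection", {
  band <- spiking_band(neurores:::new_profile(1:20, c(rep(0, 5),
                                                      rep(8, 6), rep(0, 9)),
                                              "rate"))
  expect_equal(c(band$f_lo, band$f_hi), c(6, 11))
  expect_false(band$low_pass)
  lp <- spiking_band(neurores:::new_profile(1:20, c(rep(8, 6), rep(0, 14)),
                                            "rate"))
  expect_true(lp$low_pass)
})
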