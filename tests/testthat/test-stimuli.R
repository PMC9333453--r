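test_that("sinusoid stimulus follows I_bias + A sin(2 pi f t) on the grid", {
  s0 <- make_sinusoid(0, 0.15, -1.85, T = 1)
  expect_true(all(s0$value == -1.85))
  expect_equal(s0$kind, "constant")

  s <- make_sinusoid(10, 0.2, -1, T = 0.1, dt = 0.1)
  expect_equal(diff(s$t)[1], 0.1)
  expect_equal(length(s$value), round(0.1 * 1000 / 0.1) + 1)
  # quarter period of 10 Hz at t = 25 ms: value = bias + A
  expect_equal(s$value[s$t == 25], -1 + 0.2)

  s8 <- make_sinusoid(8, 0.15, -1.85, T = 3, dt = 0.1)
  expect_equal(min(s8$value), -2.0, tolerance = 1e-6)
  expect_equal(max(s8$value), -1.7, tolerance = 1e-6)
  expect_true(all(abs(s8$value - (-1.85)) <= 0.15 + 1e-12))

  expect_error(make_sinusoid(5, 1, 0, T = -1), "positive")
  expect_error(make_sinusoid(5, 1, 0, T = 1, dt = 0), "positive")
})

test_that("chirp phase starts at pi and sweeps frequency linearly", {
  ch <- make_chirp(0, 40, 0.3, -0.5, T = 20, dt = 0.1)
  expect_equal(ch$value[1], -0.5 + 0.3 * cos(pi))
  expect_equal(instantaneous_frequency(ch, 10 * 1000), 20)  # midpoint of ramp
  fi <- instantaneous_frequency(ch)
  expect_equal(fi[1], 0)
  expect_equal(fi[length(fi)], 40)
  expect_true(all(abs(diff(fi) - diff(fi)[1]) < 1e-9))  # linear in t
  # zero crossings of the AC part: about 2 * mean_f * T = 800
  ac <- ch$value + 0.5
  crossings <- sum(diff(sign(ac)) != 0)
  expect_true(abs(crossings - 800) <= 2)
  expect_error(make_chirp(10, 5, 1, 0, T = 1), "f1 >= f0")
})

test_that("periodic spike trains place one spike per waveform maximum", {
  tr <- make_periodic_spike_train(make_sinusoid(10, 1, 0, T = 1))
  expect_length(tr$times, 10)
  expect_equal(unique(round(diff(tr$times), 9)), 100)
  # first maximum of a 5 Hz sinusoid is at the quarter period, 50 ms
  tr5 <- make_periodic_spike_train(make_sinusoid(5, 1, 0, T = 1))
  expect_equal(tr5$times[1], 50)
  # chirp 0-40 over 20 s has ~400 maxima
  trc <- make_periodic_spike_train(make_chirp(0, 40, 1, 0, T = 20))
  expect_equal(length(trc$times), 400, tolerance = 0.005)
  # inter-spike intervals match the local instantaneous period within dt
  mid <- trc$times[100:300]
  isi <- diff(mid)
  f_loc <- instantaneous_frequency(make_chirp(0, 40, 1, 0, 20),
                                   (mid[-1] + mid[-length(mid)]) / 2)
  expect_true(all(abs(isi - 1000 / f_loc) < 0.35))
  # constant waveform: no maxima, empty train
  expect_length(make_periodic_spike_train(make_constant(1, 1))$times, 0)
})

test_that("presynaptic voltage encoding uses 1 ms two-level pulses", {
  empty <- neurores:::new_spike_train(numeric(0), 1)
  v0 <- spikes_to_presynaptic_voltage(empty, 0.1, 1)
  expect_true(all(v0$value == -60))

  one <- neurores:::new_spike_train(100, 1)
  v1 <- spikes_to_presynaptic_voltage(one, 0.1, 1)
  expect_true(all(v1$value %in% c(-60, 50)))
  hi <- v1$t[v1$value == 50]
  expect_equal(min(hi), 100)
  expect_equal(max(hi), 100.9)  # half-open [100, 101)

  # spikes 0.5 ms apart merge into one 1.5 ms pulse
  two <- neurores:::new_spike_train(c(100, 100.5), 1)
  v2 <- spikes_to_presynaptic_voltage(two, 0.1, 1)
  hi2 <- v2$t[v2$value == 50]
  expect_equal(range(hi2), c(100, 101.4))
  expect_equal(sum(diff(hi2) > 0.1 + 1e-9), 0)  # contiguous
})

test_that("per-step noise stream is calibrated and reproducible", {
  expect_true(all(make_noise_steps(0, 100) == 0))
  x <- make_noise_steps(1, 1e6, seed = 42)
  expect_equal(sd(x), 1, tolerance = 0.01)
  expect_equal(mean(x), 0, tolerance = 0.01)
  expect_identical(x, make_noise_steps(1, 1e6, seed = 42))
  y <- make_noise_steps(1, 1e6, seed = 43)
  expect_false(identical(x, y))
  expect_equal(sd(make_noise_steps(2, 1e5, g_N = 1, seed = 1)), 2,
               tolerance = 0.03)
})

test_that("synthetic rate-band trains double the in-band firing rate", {
  synth <- make_synthetic_trains("rate_band", f_grid = 2:20, band = c(8, 12),
                                 base_rate = 14, T = 20, seed = 3)
  f <- vapply(synth, function(s) s$f, 0)
  rate <- vapply(synth, function(s) length(s$train$times) / s$train$T, 0)
  in_band <- f >= 8 & f <= 12
  expect_equal(mean(rate[in_band]) / mean(rate[!in_band]), 2, tolerance = 0.12)
})

test_that("synthetic phase-band trains control spike-phase concentration", {
  # degenerate von Mises: all spikes at the same phase
  synth <- make_synthetic_trains("phase_band", f_grid = 8:12, band = c(8, 12),
                                 kappa_in = 1e7, T = 5, seed = 1)
  ph <- input_phase(synth[[1]]$stim, synth[[1]]$train$times)
  expect_lt(diff(range(ph)), 1e-3)
  # kappa equal in and out of band: coherence roughly flat across frequencies
  flat <- make_synthetic_trains("phase_band", f_grid = c(5, 10, 15),
                                band = c(8, 12), kappa_in = 2, kappa_out = 2,
                                T = 30, seed = 2)
  cohs <- vapply(flat, function(s) {
    co <- spike_input_coherence(s$train, s$stim, f_max = 20)
    co$coh[which.min(abs(co$f - s$f))]
  }, 0)
  expect_lt(max(cohs) - min(cohs), 0.25)
})
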