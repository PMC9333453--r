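# shared helpers for the test suite

# uniform random spike train on (0, T] seconds, times in ms
random_train <- function(n, T, trial = 1L) {
  neurores:::new_spike_train(sort(runif(n, 0, T * 1000)), T, trial)
}

# analytic RC impedance reference is rc_impedance(); cells used repeatedly:
rc_cell <- function() naph_cell(g_p = 0, g_h = 0, E_L = -65, I_bias = 0)
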