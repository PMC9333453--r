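# Network motifs: all-to-all E/I coupling, the 3-layer diverging/converging
# feedforward network, and the feedforward INT->PYR inhibition motif, plus
# the named parameter presets used by the scenario layer.

#' Total synaptic current onto a cell
#'
#' `I_syn = sum_j g_j S_j (V_post - E_j)`; the term is subtracted in the
#' voltage equation, so an excitatory synapse (`E = 0 mV`) with
#' `V_post < E` contributes a depolarizing current, and any synapse passes
#' zero current at its reversal potential.
#'
#' @param g Maximal conductances per presynaptic partner (mS/cm2).
#' @param S Synaptic activation variables in `[0, 1]`.
#' @param V_post Postsynaptic membrane potential (mV).
#' @param E_rev Reversal potentials per partner (mV).
#' @return Current in uA/cm2 (positive values hyperpolarize).
#' @export
total_synaptic_current <- function(g, S, V_post, E_rev) {
  sum(g * S * (V_post - E_rev))
}

default_syn <- function(g_ee = 0, g_ei = 0, g_ie = 0, g_ii = 0) {
  list(g_ee = g_ee, g_ei = g_ei, g_ie = g_ie, g_ii = g_ii,
       E_e = 0, E_i = -80,
       tau_r_e = 0.1, tau_d_e = 3,    # AMPA
       tau_r_i = 0.3, tau_d_i = 9)    # GABA_A
}

new_network <- function(class, fields) {
  structure(fields, class = c(class, "nr_network"))
}

#' Network and scenario presets
#'
#' Returns the parameter constellation of one of the studied network motifs,
#' including cell models, synaptic conductances, noise levels, drive
#' assignment, and the chirp stimulus specification.
#'
#' * `"subthreshold_EI"`: 16 subthreshold-resonant E-cells ([naph_cell()])
#'   with feedforward AMPA synapses onto 4 non-resonant LIF I-cells
#'   (`g_ie = 0.05`, `g_ii = 0.05`); chirp 0-40 Hz over 20 s to the E-cells
#'   (`A_in = 0.14125`, `sigma_e = 0.0125 mV`, `sigma_i = 3 mV`). Inherited
#'   network resonance from the membrane-potential level.
#' * `"rlif_EI"`: 16 resonant LIF E-cells onto 4 noisy LIF I-cells
#'   (`g_ie = 0.01`); spiking-level resonance inherited downstream.
#' * `"psp_layers"`: 3-layer diverging/converging feedforward network. A
#'   point-process layer-1 source fires one spike per chirp cycle; 50
#'   identical LIF cells with depressing+facilitating synapses
#'   (`g_S = 0.2`, `I_bias = 1.2`, independent noise) converge through
#'   plain AMPA synapses (`g_S = 0.12`) onto one noiseless LIF.
#' * `"depression_lif"`: single LIF with a depressing-only synapse, driven
#'   by periodic spike trains (intrinsic network resonance motif).
#' * `"int_pyr"`: Wang-Buzsaki interneuron (no M-current) with a GABA_A
#'   synapse (`g_ei = 0.4`) onto the 4D PYR; only the INT is driven
#'   (`A_in = 0.5`); inhibition-induced resonance. `dt = 0.025 ms`.
#' * `"gamma_int_pyr"`: same motif with the gamma-resonant interneuron
#'   (`g_M = 4`) and a stronger drive (`A_in = 2.1`, `I_bias = 3.7`).
#'
#' @param name Preset name.
#' @return An `nr_network` object; unknown names raise an error listing the
#'   valid presets.
#' @export
build_preset <- function(name = c("subthreshold_EI", "rlif_EI", "psp_layers",
                                  "depression_lif", "int_pyr",
                                  "gamma_int_pyr")) {
  valid <- eval(formals(build_preset)$name)
  if (!is.character(name) || !(name[1] %in% valid))
    stop("unknown preset; valid presets: ", paste(valid, collapse = ", "))
  name <- name[1]
  switch(name,
    subthreshold_EI = new_network("nr_ei_net", list(
      name = name,
      e_cell = naph_cell(),  # E_L = -65, V_reset = -70, T_spike = 1
      i_cell = lif_cell(E_L = -60, V_reset = -60, T_spike = 0.1, I_bias = -1),
      Ne = 16L, Ni = 4L,
      syn = default_syn(g_ie = 0.05, g_ii = 0.05),
      drive = list(e = list(I_bias = -1.85, A_in = 0.14125),
                   i = list(I_bias = -1, A_in = 0)),
      sigma_e = 0.0125, sigma_i = 3,
      stim = list(f0 = 0, f1 = 40, T = 20),
      dt = 0.1, settle = 1)),
    rlif_EI = new_network("nr_ei_net", list(
      name = name,
      e_cell = lif_cell(E_L = -60, V_reset = -60, T_spike = 1, I_bias = 0.9),
      i_cell = lif_cell(E_L = -60, V_reset = -60, T_spike = 1, I_bias = 0),
      Ne = 16L, Ni = 4L,
      syn = default_syn(g_ie = 0.01, g_ii = 0.05),
      drive = list(e = list(I_bias = 0.9, A_in = 0.115),
                   i = list(I_bias = 0, A_in = 0)),
      sigma_e = 0.02, sigma_i = 2,
      stim = list(f0 = 0, f1 = 40, T = 20),
      dt = 0.1, settle = 1)),
    psp_layers = new_network("nr_layers_net", list(
      name = name,
      l2_cell = plastic_lif_cell(g_S = 0.2, I_bias = 1.2),
      N2 = 50L,
      l3_cell = lif_cell(E_L = -65, V_reset = -70, T_spike = 0.1, I_bias = 0),
      g23 = 0.12, tau_r_e = 0.1, tau_d_e = 3, E_e = 0,
      sigma2 = 0.25, sigma3 = 0,
      I_bias2 = 1.2, I_bias3 = 0,
      stim = list(f0 = 0, f1 = 40, T = 20),
      dt = 0.1, settle = 1)),
    depression_lif = new_network("nr_plastic_cell", list(
      name = name,
      cell = plastic_lif_cell(g_S = 0.175, facilitation = FALSE,
                              I_bias = 1.2),
      sigma = 0.05,
      stim = list(f0 = 0, f1 = 40, T = 20),
      dt = 0.1, settle = 1)),
    int_pyr = new_network("nr_intpyr_net", list(
      name = name,
      i_cell = int_cell(g_M = 0),
      e_cell = pyr_cell(),
      syn = default_syn(g_ei = 0.4),
      drive = list(i = list(I_bias = -0.5, A_in = 0.5),
                   e = list(I_bias = -2.7, A_in = 0)),
      sigma_i = 0.1, sigma_e = 0.1,
      stim = list(f0 = 0, f1 = 40, T = 20),
      dt = 0.025, settle = 1)),
    gamma_int_pyr = new_network("nr_intpyr_net", list(
      name = name,
      i_cell = int_cell(g_M = 4),
      e_cell = pyr_cell(),
      syn = default_syn(g_ei = 0.4),
      drive = list(i = list(I_bias = 3.7, A_in = 2.1),
                   e = list(I_bias = -2.7, A_in = 0)),
      sigma_i = 0.1, sigma_e = 0.1,
      stim = list(f0 = 0, f1 = 40, T = 20),
      dt = 0.025, settle = 1)))
}

#' @export
print.nr_network <- function(x, ...) {
  cat(sprintf("<%s> preset '%s'\n", class(x)[1], x$name))
  invisible(x)
}

# Build the applied-current vector for one population: DC bias throughout
# (including the settle prefix) and the chirp AC only when that population
# is the stimulus target.
pop_current <- function(net, pop, n_settle, chirp_ac) {
  d <- net$drive[[pop]]
  ac <- if (d$A_in != 0) d$A_in * chirp_ac else numeric(length(chirp_ac))
  c(rep(d$I_bias, n_settle), d$I_bias + ac)
}

#' Simulate a network preset
#'
#' Integrates a network motif for one trial: a settling period at the DC
#' bias (length `net$settle` s) precedes the chirp; spike times are reported
#' relative to chirp onset and settle-period spikes are discarded. Every
#' cell receives an independent noise stream keyed by
#' `(master_seed, cell_id, trial)`.
#'
#' @param net An `nr_network` from [build_preset()].
#' @param master_seed,trial Noise stream keys.
#' @param record_cells Integer ids of cells whose voltage traces to keep
#'   (E/I nets: 1..Ne are E-cells, Ne+1..Ne+Ni are I-cells; layer net:
#'   1..N2 are layer-2 cells). For the INT->PYR motif both traces are
#'   always recorded.
#' @param sigma2 Optional override of the layer-2 noise SD (layer net).
#' @return An `nr_netsim` with `spikes` (list of `nr_spike_train`),
#'   population labels, the chirp `stimulus`, the layer-1 `input_train`
#'   where applicable, and any recorded voltages.
#' @export
simulate_network <- function(net, master_seed = 1, trial = 1,
                             record_cells = integer(0), sigma2 = NULL) {
  st <- net$stim
  chirp <- make_chirp(st$f0, st$f1, 1, 0, st$T, net$dt)
  n_settle <- round(net$settle * 1000 / net$dt)
  shift_train <- function(times) {
    new_spike_train(times[times > n_settle * net$dt] - n_settle * net$dt,
                    st$T, trial)
  }
  trim <- function(v) v[-seq_len(n_settle)]

  if (inherits(net, "nr_ei_net")) {
    Ie <- pop_current(net, "e", n_settle, chirp$value)
    Ii <- pop_current(net, "i", n_settle, chirp$value)
    out <- .sim_ei_cpp(model_id(net$e_cell), net$Ne, net$Ni,
                       cpp_par(net$e_cell), cpp_spike_par(net$e_cell),
                       cpp_par(net$i_cell), cpp_spike_par(net$i_cell),
                       with(net$syn, c(g_ee, g_ei, g_ie, g_ii, E_e, E_i,
                                       tau_r_e, tau_d_e, tau_r_i, tau_d_i)),
                       Ie, Ii, net$sigma_e, net$sigma_i, 1,
                       net$dt, master_seed, trial, as.integer(record_cells),
                       n_settle,
                       init_state(net$e_cell, net$drive$e$I_bias),
                       init_state(net$i_cell, net$drive$i$I_bias)[1])
    spikes <- lapply(out$spikes, shift_train)
    pops <- c(rep("E", net$Ne), rep("I", net$Ni))
    V <- if (!is.null(out$V)) lapply(out$V, trim) else NULL
    amp <- net$drive$e$A_in
    if (amp == 0) amp <- net$drive$i$A_in
    stim_out <- make_chirp(st$f0, st$f1, amp, 0, st$T, net$dt)
    structure(list(spikes = spikes, populations = pops, V = V,
                   stimulus = stim_out, net = net, trial = trial),
              class = "nr_netsim")
  } else if (inherits(net, "nr_layers_net")) {
    sig2 <- sigma2 %||% net$sigma2
    input_train <- make_periodic_spike_train(
      make_chirp(st$f0, st$f1, 1, 0, st$T, net$dt))
    vpre_chirp <- spikes_to_presynaptic_voltage(input_train, net$dt, st$T)
    Vpre <- c(rep(-60, n_settle), vpre_chirp$value)
    I2 <- c(rep(net$I_bias2, n_settle + length(vpre_chirp$value)))
    I3 <- c(rep(net$I_bias3, n_settle + length(vpre_chirp$value)))
    out <- .sim_layers_cpp(Vpre, cpp_par(net$l2_cell),
                           cpp_spike_par(net$l2_cell),
                           I2, sig2, net$N2,
                           cpp_par(net$l3_cell), cpp_spike_par(net$l3_cell),
                           I3, net$g23, net$tau_r_e, net$tau_d_e, net$E_e,
                           1, net$dt, master_seed, trial,
                           FALSE, as.integer(record_cells), n_settle,
                           init_state(net$l2_cell, net$I_bias2)[1],
                           init_state(net$l3_cell, net$I_bias3)[1])
    spikes <- lapply(out$spikes, shift_train)
    pops <- c(rep("layer2", net$N2), "layer3")
    V <- if (!is.null(out$V2)) lapply(out$V2, trim) else NULL
    structure(list(spikes = spikes, populations = pops, V = V,
                   input_train = input_train,
                   stimulus = make_chirp(st$f0, st$f1, 1, 0, st$T, net$dt),
                   net = net, trial = trial),
              class = "nr_netsim")
  } else if (inherits(net, "nr_intpyr_net")) {
    Ii <- pop_current(net, "i", n_settle, chirp$value)
    Ie <- pop_current(net, "e", n_settle, chirp$value)
    out <- .sim_intpyr_cpp(cpp_par(net$i_cell), cpp_par(net$e_cell),
                           with(net$syn, c(g_ee, g_ei, g_ie, g_ii, E_e, E_i,
                                           tau_r_e, tau_d_e, tau_r_i, tau_d_i)),
                           Ii, Ie, net$sigma_i, net$sigma_e, 1,
                           net$dt, master_seed, trial, TRUE,
                           init_state(net$i_cell, net$drive$i$I_bias),
                           init_state(net$e_cell, net$drive$e$I_bias))
    amp <- net$drive$i$A_in
    if (amp == 0) amp <- net$drive$e$A_in
    structure(list(spikes = list(int = shift_train(out$spikes_int),
                                 pyr = shift_train(out$spikes_pyr)),
                   populations = c("INT", "PYR"),
                   V = list(int = trim(out$V_int), pyr = trim(out$V_pyr)),
                   stimulus = make_chirp(st$f0, st$f1, amp, 0, st$T, net$dt),
                   net = net, trial = trial),
              class = "nr_netsim")
  } else {
    stop("unknown network class")
  }
}

#' @export
print.nr_netsim <- function(x, ...) {
  ns <- vapply(x$spikes, function(s) length(s$times), 0L)
  cat(sprintf("<nr_netsim> preset '%s', trial %d, %d cells, %d spikes total\n",
              x$net$name, x$trial, length(x$spikes), sum(ns)))
  invisible(x)
}
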