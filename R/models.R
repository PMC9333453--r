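# Cell models: parameter constructors, gating curves, and pure R derivative
# functions. The R derivatives mirror the compiled right-hand sides
# one-for-one and serve as the reference implementation for testing; the
# integrator itself runs the compiled versions.

# ------------------------------------------------------------- gating ------

#' Gating and synaptic activation curves
#'
#' Steady-state activation/inactivation curves and voltage-dependent time
#' constants for the cell models, plus the synaptic sigmoid
#' `H(V) = (1 + tanh(V/4)) / 2`. Terms of the form
#' `a (V + c) / (1 - exp(-(V + c)/b))` are evaluated as their limit `a b` at
#' `V = -c`.
#'
#' @param V Membrane potential in mV.
#' @return `naph_p_inf`, `naph_r_inf`, `H_syn`: numeric. `pyr_gates`,
#'   `int_gates`: a list with `m_inf`, `h_inf`, `tau_h`, `n_inf`, `tau_n`
#'   and the slow gate (`r_inf`/`tau_r` or `q_inf`/`tau_q`).
#' @export
naph_p_inf <- function(V) 1 / (1 + exp(-(V + 38) / 6.5))

#' @rdname naph_p_inf
#' @export
naph_r_inf <- function(V) 1 / (1 + exp((V + 79.2) / 9.78))

#' @rdname naph_p_inf
#' @export
H_syn <- function(V) (1 + tanh(V / 4)) / 2

vtrap_r <- function(a, V, c, b) {
  x <- V + c
  ifelse(abs(x) < 1e-7, a * b, a * x / (1 - exp(-x / b)))
}

#' @rdname naph_p_inf
#' @export
pyr_gates <- function(V) {
  ah <- 0.128 * exp(-(V + 50) / 18)
  bh <- 4 / (1 + exp(-(V + 27) / 5))
  am <- vtrap_r(0.32, V, 54, 4)
  bm <- {
    x <- V + 27
    ifelse(abs(x) < 1e-7, 0.28 * 5, 0.28 * x / (exp(x / 5) - 1))
  }
  an <- vtrap_r(0.032, V, 52, 5)
  bn <- 0.5 * exp(-(V + 57) / 40)
  list(m_inf = am / (am + bm),
       h_inf = ah / (ah + bh), tau_h = 1 / (ah + bh),
       n_inf = an / (an + bn), tau_n = 1 / (an + bn),
       r_inf = 1 / (1 + exp((V + 82.9) / 12.4)),
       tau_r = 136.36 * exp(0.033 * (V + 75)) / (1 + exp(0.083 * (V + 75))))
}

#' @rdname naph_p_inf
#' @export
int_gates <- function(V) {
  ah <- 0.07 * exp(-(V + 58) / 20)
  bh <- 1 / (1 + exp(-(V + 28) / 10))
  am <- vtrap_r(0.2, V, 35, 10)
  bm <- 4 * exp(-(V + 60) / 18)
  an <- vtrap_r(0.01, V, 34, 10)
  bn <- 0.125 * exp(-(V + 44) / 80)
  list(m_inf = am / (am + bm),
       h_inf = ah / (ah + bh), tau_h = 0.2 / (ah + bh),
       n_inf = an / (an + bn), tau_n = 0.2 / (an + bn),
       q_inf = 1 / (1 + exp(-(V + 35) / 10)),
       tau_q = 40 / (3.3 * exp((V + 35) / 20) + exp(-(V + 35) / 20)))
}

# ----------------------------------------------------- cell constructors ---

new_cell <- function(class, fields) {
  structure(fields, class = c(class, "nr_cell"))
}

#' Cell model constructors
#'
#' Each constructor returns a parameter object whose defaults are the
#' reference parameter sets used throughout the package. Conductances in
#' mS/cm2, capacitance in uF/cm2, potentials in mV, time constants in ms.
#'
#' * `naph_cell()`: 2D conductance-based neuron with leak, persistent sodium
#'   (instantaneous activation) and h-current, augmented with
#'   threshold-clamp-reset spiking. Subthreshold (theta-band) resonator.
#' * `lif_cell()`: leaky integrate-and-fire neuron.
#' * `calcium_lif_cell()`: LIF with a spike-triggered calcium current; the
#'   calcium gate `K` activates (time constant `tau_act / N_C`) while the
#'   spike-set variable `N_C` decays (`tau_deact`), producing a transient
#'   depolarization after each spike.
#' * `plastic_lif_cell()`: LIF driven through an AMPA-like synapse with
#'   short-term depression `D` and facilitation `F`; the effective synaptic
#'   conductance is `g_S * S * D * F`, `D F` being the release probability.
#'   Disabled factors are pinned to 1.
#' * `pyr_cell()`: 4D pyramidal cell (transient sodium with instantaneous
#'   activation, delayed-rectifier potassium, h-current).
#' * `int_cell()`: Wang-Buzsaki interneuron extended with a non-inactivating
#'   M-like potassium current (`g_M`); `g_M = 0` recovers the plain model.
#'
#' For the integrate-and-fire type cells a spike is logged when `V > V_th`
#' after a full integration step; `V` is then clamped at `V_peak` for
#' `T_spike` ms and reset to `V_reset`. The biophysical cells (`pyr_cell`,
#' `int_cell`) generate full spike waveforms; spike times are logged at
#' upward crossings of 0 mV.
#'
#' @param C Membrane capacitance.
#' @param g_L,E_L Leak conductance and reversal.
#' @param g_p,E_Na Persistent sodium conductance and reversal (`naph_cell`).
#' @param g_h,E_h h-current conductance and reversal.
#' @param tau_r h-current time constant (ms), voltage independent in
#'   `naph_cell`.
#' @param V_th,V_reset,V_peak,T_spike Spike mechanism.
#' @param g_C,E_Ca,tau_act,tau_inact,tau_deact,N_reset Calcium dynamics.
#' @param g_S,E_S Synaptic maximal conductance and reversal.
#' @param tau_syn_r,tau_syn_d Synaptic gate rise/decay time constants.
#' @param tau_reset_d,tau_dep,tau_reset_f,tau_fac Short-term plasticity time
#'   constants.
#' @param depression,facilitation Enable flags for `D` and `F`.
#' @param g_Na,E_Na_s,g_K,E_K Spiking sodium/potassium (biophysical cells).
#' @param g_M M-like current conductance (`int_cell`).
#' @param I_bias Default DC bias associated with the model's reference
#'   operating point (used by presets; simulations take the bias from the
#'   stimulus).
#' @return An object of class `c("<model>_cell", "nr_cell")`.
#' @examples
#' cell <- naph_cell()
#' naph_p_inf(-38)  # 0.5 at the activation midpoint
#' @export
naph_cell <- function(C = 1, g_L = 0.1, E_L = -65, g_p = 0.1, E_Na = 55,
                      g_h = 1, E_h = -20, tau_r = 100,
                      V_th = -50, V_reset = -70, V_peak = 50, T_spike = 1,
                      I_bias = -1.85) {
  new_cell("naph_cell", list(
    C = C, g_L = g_L, E_L = E_L, g_p = g_p, E_Na = E_Na, g_h = g_h,
    E_h = E_h, tau_r = tau_r, V_th = V_th, V_reset = V_reset,
    V_peak = V_peak, T_spike = T_spike, I_bias = I_bias))
}

#' @rdname naph_cell
#' @export
lif_cell <- function(C = 1, g_L = 0.1, E_L = -60,
                     V_th = -50, V_reset = -60, V_peak = 50, T_spike = 1,
                     I_bias = 0.9) {
  new_cell("lif_cell", list(
    C = C, g_L = g_L, E_L = E_L, V_th = V_th, V_reset = V_reset,
    V_peak = V_peak, T_spike = T_spike, I_bias = I_bias))
}

#' @rdname naph_cell
#' @export
calcium_lif_cell <- function(C = 1, g_L = 0.5, E_L = -60, g_C = 0.08,
                             E_Ca = 100, tau_act = 50, tau_inact = 5,
                             tau_deact = 70, V_th = -50, V_reset = -70,
                             V_peak = 50, T_spike = 1, N_reset = 0.1,
                             I_bias = -3) {
  new_cell("calcium_lif_cell", list(
    C = C, g_L = g_L, E_L = E_L, g_C = g_C, E_Ca = E_Ca,
    tau_act = tau_act, tau_inact = tau_inact, tau_deact = tau_deact,
    V_th = V_th, V_reset = V_reset, V_peak = V_peak, T_spike = T_spike,
    N_reset = N_reset, I_bias = I_bias))
}

#' @rdname naph_cell
#' @export
plastic_lif_cell <- function(C = 1, g_L = 0.1, E_L = -65, g_S = 0.175,
                             E_S = 0, tau_syn_r = 0.1, tau_syn_d = 3,
                             tau_reset_d = 0.1, tau_dep = 100,
                             tau_reset_f = 0.2, tau_fac = 300,
                             depression = TRUE, facilitation = TRUE,
                             V_th = -50, V_reset = -70, V_peak = 50,
                             T_spike = 0.1, I_bias = 1.3) {
  new_cell("plastic_lif_cell", list(
    C = C, g_L = g_L, E_L = E_L, g_S = g_S, E_S = E_S,
    tau_syn_r = tau_syn_r, tau_syn_d = tau_syn_d,
    tau_reset_d = tau_reset_d, tau_dep = tau_dep,
    tau_reset_f = tau_reset_f, tau_fac = tau_fac,
    depression = depression, facilitation = facilitation,
    V_th = V_th, V_reset = V_reset, V_peak = V_peak, T_spike = T_spike,
    I_bias = I_bias))
}

#' @rdname naph_cell
#' @export
pyr_cell <- function(C = 1, g_L = 0.1, E_L = -67, g_Na = 100, E_Na_s = 50,
                     g_K = 80, E_K = -100, g_h = 0.485, E_h = -33,
                     I_bias = -2.7) {
  new_cell("pyr_cell", list(
    C = C, g_L = g_L, E_L = E_L, g_Na = g_Na, E_Na_s = E_Na_s,
    g_K = g_K, E_K = E_K, g_h = g_h, E_h = E_h, I_bias = I_bias))
}

#' @rdname naph_cell
#' @export
int_cell <- function(C = 1, g_L = 0.1, E_L = -65, g_Na = 35, E_Na_s = 55,
                     g_K = 9, E_K = -90, g_M = 4, I_bias = -0.5) {
  new_cell("int_cell", list(
    C = C, g_L = g_L, E_L = E_L, g_Na = g_Na, E_Na_s = E_Na_s,
    g_K = g_K, E_K = E_K, g_M = g_M, I_bias = I_bias))
}

#' @export
print.nr_cell <- function(x, ...) {
  cat(sprintf("<%s>\n", class(x)[1]))
  flat <- unlist(x)
  cat(paste(sprintf("  %s = %g", names(flat), flat), collapse = "\n"), "\n")
  invisible(x)
}

# -------------------------------------------- compiled-core parameter maps -

model_id <- function(cell) {
  switch(class(cell)[1],
         lif_cell = 1L, naph_cell = 2L, calcium_lif_cell = 3L,
         plastic_lif_cell = 4L, pyr_cell = 5L, int_cell = 6L,
         stop("unknown cell class: ", class(cell)[1]))
}

cpp_par <- function(cell) {
  switch(class(cell)[1],
    lif_cell = c(cell$C, cell$g_L, cell$E_L),
    naph_cell = c(cell$C, cell$g_L, cell$E_L, cell$g_p, cell$E_Na,
                  cell$g_h, cell$E_h, cell$tau_r),
    calcium_lif_cell = c(cell$C, cell$g_L, cell$E_L, cell$g_C, cell$E_Ca,
                         cell$tau_act, cell$tau_inact, cell$tau_deact),
    plastic_lif_cell = c(cell$C, cell$g_L, cell$E_L, cell$g_S, cell$E_S,
                         cell$tau_syn_r, cell$tau_syn_d, cell$tau_reset_d,
                         cell$tau_dep, cell$tau_reset_f, cell$tau_fac,
                         as.numeric(cell$depression), as.numeric(cell$facilitation)),
    pyr_cell = c(cell$C, cell$g_L, cell$E_L, cell$g_Na, cell$E_Na_s,
                 cell$g_K, cell$E_K, cell$g_h, cell$E_h),
    int_cell = c(cell$C, cell$g_L, cell$E_L, cell$g_Na, cell$E_Na_s,
                 cell$g_K, cell$E_K, cell$g_M))
}

cpp_spike_par <- function(cell) {
  if (inherits(cell, "pyr_cell") || inherits(cell, "int_cell"))
    return(c(0, 0, 0, 0))
  sp <- c(cell$V_th, cell$V_reset, cell$V_peak, cell$T_spike)
  if (inherits(cell, "calcium_lif_cell")) sp <- c(sp, cell$N_reset)
  sp
}

# Resting membrane potential under a DC bias: the most hyperpolarized zero
# of the steady-state current-voltage relation (all gates at x_inf(V)).
# Falls back to E_L when no subthreshold root exists in [-120, -40] mV.
rest_V <- function(cell, I0) {
  iv <- function(V) {
    switch(class(cell)[1],
      lif_cell = ,
      calcium_lif_cell = ,
      plastic_lif_cell = I0 - cell$g_L * (V - cell$E_L),
      naph_cell = I0 - cell$g_L * (V - cell$E_L) -
        cell$g_p * naph_p_inf(V) * (V - cell$E_Na) -
        cell$g_h * naph_r_inf(V) * (V - cell$E_h),
      pyr_cell = {
        g <- pyr_gates(V)
        I0 - cell$g_L * (V - cell$E_L) -
          cell$g_Na * g$h_inf * g$m_inf^3 * (V - cell$E_Na_s) -
          cell$g_K * g$n_inf^4 * (V - cell$E_K) -
          cell$g_h * g$r_inf * (V - cell$E_h)
      },
      int_cell = {
        g <- int_gates(V)
        I0 - cell$g_L * (V - cell$E_L) -
          cell$g_Na * g$h_inf * g$m_inf^3 * (V - cell$E_Na_s) -
          cell$g_K * g$n_inf^4 * (V - cell$E_K) -
          cell$g_M * g$q_inf * (V - cell$E_K)
      })
  }
  grid <- seq(-120, -40, by = 0.05)
  vals <- vapply(grid, iv, 0)
  flip <- which(vals[-length(vals)] > 0 & vals[-1] <= 0)
  if (length(flip) == 0) return(cell$E_L)
  stats::uniroot(iv, c(grid[flip[1]], grid[flip[1] + 1]))$root
}

init_state <- function(cell, I0 = NULL) {
  V0 <- if (is.null(I0)) cell$E_L else rest_V(cell, I0)
  switch(class(cell)[1],
    lif_cell = V0,
    naph_cell = c(V0, naph_r_inf(V0)),
    calcium_lif_cell = c(V0, 0, 0),
    plastic_lif_cell = c(V0, 0,
                         1,
                         if (isTRUE(cell$facilitation)) 0 else 1),
    pyr_cell = {
      g <- pyr_gates(V0)
      c(V0, g$h_inf, g$n_inf, g$r_inf)
    },
    int_cell = {
      g <- int_gates(V0)
      c(V0, g$h_inf, g$n_inf, g$q_inf)
    })
}

aux_names <- function(cell) {
  switch(class(cell)[1],
    lif_cell = character(0),
    naph_cell = "r",
    calcium_lif_cell = c("K", "N_C"),
    plastic_lif_cell = c("S", "D", "F"),
    pyr_cell = c("h", "n", "r"),
    int_cell = c("h", "n", "q"))
}

# ------------------------------------------------------ R reference RHS ----

#' Model derivative functions (reference implementations)
#'
#' Pure R right-hand sides of the model ODEs, one call per state evaluation.
#' These mirror the compiled derivatives used by [simulate_cell()] and exist
#' so that trajectories can be cross-checked against a general-purpose ODE
#' solver. Derivatives are returned in mV/ms (voltages) or 1/ms (gates).
#'
#' @param V,r,K,N_C,S,D,F,h,n,q State variables.
#' @param I_in Applied current in uA/cm2 (stimulus + bias + noise).
#' @param V_pre Presynaptic membrane potential in mV.
#' @param I_syn Additional synaptic current in uA/cm2 (subtracted).
#' @param cell The matching parameter object.
#' @return Named numeric vector of derivatives.
#' @export
nap_h_deriv <- function(V, r, I_in, cell = naph_cell()) {
  dV <- (I_in - cell$g_L * (V - cell$E_L) -
           cell$g_p * naph_p_inf(V) * (V - cell$E_Na) -
           cell$g_h * r * (V - cell$E_h)) / cell$C
  c(dV = dV, dr = (naph_r_inf(V) - r) / cell$tau_r)
}

#' @rdname nap_h_deriv
#' @export
lif_deriv <- function(V, I_in, cell = lif_cell()) {
  c(dV = (I_in - cell$g_L * (V - cell$E_L)) / cell$C)
}

#' @rdname nap_h_deriv
#' @export
calcium_lif_deriv <- function(V, K, N_C, I_in, cell = calcium_lif_cell()) {
  dV <- (I_in - cell$g_L * (V - cell$E_L) -
           cell$g_C * K * (V - cell$E_Ca)) / cell$C
  c(dV = dV,
    dK = N_C * (1 - K) / cell$tau_act - K / cell$tau_inact,
    dN_C = -N_C / cell$tau_deact)
}

#' @rdname nap_h_deriv
#' @export
synapse_gate_deriv <- function(S, V_pre, tau_syn_r = 0.1, tau_syn_d = 3) {
  c(dS = H_syn(V_pre) * (1 - S) / tau_syn_r - S / tau_syn_d)
}

#' @rdname nap_h_deriv
#' @export
plasticity_deriv <- function(D, F, V_pre, cell = plastic_lif_cell()) {
  hv <- H_syn(V_pre)
  c(dD = -hv * D / cell$tau_reset_d + (1 - D) / cell$tau_dep,
    dF = hv * (1 - F) / cell$tau_reset_f - F / cell$tau_fac)
}

#' @rdname nap_h_deriv
#' @export
pyr_deriv <- function(V, h, n, r, I_in, I_syn = 0, cell = pyr_cell()) {
  g <- pyr_gates(V)
  dV <- (I_in - cell$g_L * (V - cell$E_L) -
           cell$g_Na * h * g$m_inf^3 * (V - cell$E_Na_s) -
           cell$g_K * n^4 * (V - cell$E_K) -
           cell$g_h * r * (V - cell$E_h) - I_syn) / cell$C
  c(dV = dV,
    dh = (g$h_inf - h) / g$tau_h,
    dn = (g$n_inf - n) / g$tau_n,
    dr = (g$r_inf - r) / g$tau_r)
}

#' @rdname nap_h_deriv
#' @export
int_deriv <- function(V, h, n, q, I_in, I_syn = 0, cell = int_cell()) {
  g <- int_gates(V)
  dV <- (I_in - cell$g_L * (V - cell$E_L) -
           cell$g_Na * h * g$m_inf^3 * (V - cell$E_Na_s) -
           cell$g_K * n^4 * (V - cell$E_K) -
           cell$g_M * q * (V - cell$E_K) - I_syn) / cell$C
  c(dV = dV,
    dh = (g$h_inf - h) / g$tau_h,
    dn = (g$n_inf - n) / g$tau_n,
    dq = (g$q_inf - q) / g$tau_q)
}
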