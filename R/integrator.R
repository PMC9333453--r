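# Fixed-step integration: R-level reference step, the simulate_cell()
# front-end to the compiled core, and multi-trial orchestration.

#' Simulation configuration
#'
#' @param dt Integration step in ms (0.1 for the integrate-and-fire level
#'   studies; 0.025 for the biophysical PYR/INT studies).
#' @param T Simulated duration in s.
#' @param n_trials Number of independent-noise trials.
#' @param settle Settling period in s discarded before metrics (for chirp
#'   drives the settle runs at the DC bias before the chirp starts).
#' @param master_seed Master seed; per-cell, per-trial noise streams are
#'   derived from it.
#' @export
sim_config <- function(dt = 0.1, T = 3, n_trials = 1, settle = 1,
                       master_seed = 1) {
  stopifnot(dt > 0, T > 0, n_trials >= 1, settle >= 0)
  structure(list(dt = dt, T = T, n_trials = n_trials, settle = settle,
                 master_seed = master_seed), class = "nr_config")
}

#' One explicit second-order Runge-Kutta (modified Euler) step
#'
#' Reference implementation of the endpoint RK2 update
#' `y' = y + dt/2 (k1 + k2)` with `k1 = f(t, y)` and
#' `k2 = f(t + dt, y + dt k1)`. The same additive noise increment enters the
#' first (voltage) component of the derivative in both stages.
#'
#' @param state Named numeric state vector (voltage first).
#' @param deriv_fn Function `(t, state) -> derivative vector`.
#' @param t Time in ms.
#' @param dt Step in ms.
#' @param noise_increment Additive voltage-derivative increment (mV/ms).
#' @return Updated state vector.
#' @export
rk2_step <- function(state, deriv_fn, t, dt, noise_increment = 0) {
  k1 <- deriv_fn(t, state)
  k1[1] <- k1[1] + noise_increment
  if (any(!is.finite(k1))) {
    bad <- names(state)[which(!is.finite(k1))[1]] %||% "state"
    stop("simulation diverged: non-finite derivative for ", bad)
  }
  k2 <- deriv_fn(t + dt, state + dt * k1)
  k2[1] <- k2[1] + noise_increment
  if (any(!is.finite(k2))) {
    bad <- names(state)[which(!is.finite(k2))[1]] %||% "state"
    stop("simulation diverged: non-finite derivative for ", bad)
  }
  state + dt / 2 * (k1 + k2)
}

new_sim_result <- function(t, V, aux, spikes, stimulus, cell, dt, trial) {
  structure(list(t = t, V = V, aux = aux, spikes = spikes,
                 stimulus = stimulus, cell = cell, dt = dt, trial = trial),
            class = "nr_sim")
}

#' Simulate a single cell
#'
#' Integrates one cell model with the compiled fixed-step RK2 core. For the
#' integrate-and-fire type models, threshold crossing triggers the
#' clamp-and-reset spike mechanism; the biophysical models log spikes at
#' upward zero crossings. One Gaussian noise draw per step enters the
#' voltage equation in both RK2 stages.
#'
#' @param cell A cell parameter object (see [naph_cell()]).
#' @param input Current stimulus trace (uA/cm2, bias included). For
#'   `plastic_lif_cell` this is the constant/oscillatory somatic current;
#'   the synaptic drive comes from `presyn`.
#' @param presyn Optional presynaptic voltage trace on the same grid
#'   (required for `plastic_lif_cell`).
#' @param sigma Noise SD in mV (per-step, see [make_noise_steps()]).
#' @param g_N Noise conductance in mS/cm2.
#' @param seed Master seed for the noise stream.
#' @param cell_id,trial Stream keys; trials with distinct ids receive
#'   independent noise.
#' @param record Character vector: any of `"v"`, `"aux"`.
#' @param arm_after Time (ms) before which the threshold-reset spike
#'   mechanism stays disarmed. Arming after the settling period lets the
#'   integrate-and-fire type models relax from the cold-start transient to
#'   their subthreshold operating point instead of latching onto a
#'   reset-driven firing loop the transient can trigger.
#' @return An `nr_sim` with `t` (ms), `V` (if recorded), `aux` (matrix of
#'   auxiliary states), and `spikes` (an `nr_spike_train`).
#' @examples
#' stim <- make_sinusoid(8, 0.05, -1.85, T = 2)
#' res <- simulate_cell(naph_cell(), stim)
#' range(res$V)
#' @export
simulate_cell <- function(cell, input, presyn = NULL, sigma = 0, g_N = 1,
                          seed = 1, cell_id = 1, trial = 1,
                          record = "v", arm_after = 0) {
  dt <- input$t[2] - input$t[1]
  vpre <- if (is.null(presyn)) numeric(0) else presyn$value
  if (inherits(cell, "plastic_lif_cell") && is.null(presyn))
    stop("plastic_lif_cell requires a presynaptic voltage trace (presyn)")
  if (!is.null(presyn) && length(presyn$value) != length(input$value))
    stop("input and presyn must share the same time grid")
  out <- .sim_cell_cpp(model_id(cell), cpp_par(cell), cpp_spike_par(cell),
                       input$value, vpre,
                       init_state(cell, input$meta$I_bias %||% input$value[1]),
                       dt, sigma, g_N,
                       seed, cell_id, trial,
                       "v" %in% record, "aux" %in% record,
                       as.integer(round(arm_after / dt)))
  aux <- NULL
  if (!is.null(out$aux)) {
    aux <- out$aux
    colnames(aux) <- aux_names(cell)
  }
  new_sim_result(t = input$t, V = out$V, aux = aux,
                 spikes = new_spike_train(out$spikes, input$meta$T, trial),
                 stimulus = input, cell = cell, dt = dt, trial = trial)
}

#' Repeat a simulation over independent-noise trials
#'
#' Runs `n_trials` simulations of a cell or network with the identical
#' stimulus; each trial's noise streams are derived from
#' `(master_seed, cell_id, trial)`, so any trial is reproducible in
#' isolation.
#'
#' @param object A cell (`nr_cell`) or network preset (`nr_network`).
#' @param input Stimulus trace (cells) or `NULL` (networks build their own).
#' @param n_trials Number of trials.
#' @param master_seed Master seed.
#' @param ... Passed to [simulate_cell()] or [simulate_network()].
#' @return List of per-trial results.
#' @export
run_trials <- function(object, input = NULL, n_trials = 1, master_seed = 1, ...) {
  if (inherits(object, "nr_cell")) {
    lapply(seq_len(n_trials), function(k)
      simulate_cell(object, input, seed = master_seed, trial = k, ...))
  } else if (inherits(object, "nr_network")) {
    lapply(seq_len(n_trials), function(k)
      simulate_network(object, master_seed = master_seed, trial = k, ...))
  } else {
    stop("object must be an nr_cell or nr_network")
  }
}

#' Minimal spiking amplitude over a frequency range
#'
#' Bisects on the stimulus amplitude `A_in` for the smallest value that
#' produces at least one spike at any frequency of `f_grid` (sinusoidal
#' drive at the cell's bias, no noise), mirroring how the minimal input
#' amplitude required to recruit spiking is determined.
#'
#' @param cell Cell parameter object.
#' @param f_grid Frequencies to test in Hz.
#' @param I_bias DC bias.
#' @param interval Numeric length-2 bracketing interval for `A_in`.
#' @param tol Bisection tolerance on `A_in`.
#' @param T,dt,settle Per-frequency simulation length (s), step (ms), and
#'   discarded settle (s).
#' @return List with `A_min` and `f_first` (frequency recruited at `A_min`).
#' @export
minimal_spiking_amplitude <- function(cell, f_grid = 1:40,
                                      I_bias = cell$I_bias,
                                      interval = c(0.01, 1), tol = 2e-3,
                                      T = 3, dt = 0.1, settle = 1) {
  spikes_at <- function(A) {
    for (f in f_grid) {
      res <- simulate_cell(cell, make_sinusoid(f, A, I_bias, T, dt),
                           record = character(0),
                           arm_after = settle * 1000)
      if (any(res$spikes$times > settle * 1000)) return(f)
    }
    NA_real_
  }
  lo <- interval[1]; hi <- interval[2]
  if (!is.na(spikes_at(lo))) stop("lower bracket already spikes")
  f_hi <- spikes_at(hi)
  if (is.na(f_hi)) stop("upper bracket does not spike")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    f_mid <- spikes_at(mid)
    if (is.na(f_mid)) lo <- mid else { hi <- mid; f_hi <- f_mid }
  }
  list(A_min = hi, f_first = f_hi)
}

#' @export
print.nr_sim <- function(x, ...) {
  cat(sprintf("<nr_sim> %s, %d samples, %d spikes (trial %d)\n",
              class(x$cell)[1], length(x$t), length(x$spikes$times), x$trial))
  invisible(x)
}
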