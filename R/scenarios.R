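# Declarative reproduction of the package's reference experiments: each
# scenario bundles a stimulus protocol, a model or network preset, a metric
# battery, and an optional parameter sweep, and returns a compact summary.

#' Simulate a cell driven by a chirp, over trials
#'
#' Prepends a bias-only settling period, runs the chirp, and returns the
#' post-settle spike trains (times relative to chirp onset) together with
#' the voltage trace of the last trial.
#'
#' @param cell Cell parameter object.
#' @param f0,f1,T Chirp range (Hz) and duration (s).
#' @param A_in,I_bias Drive amplitude and DC bias (uA/cm2).
#' @param dt Step (ms).
#' @param sigma Noise SD (mV).
#' @param settle Settling time (s) at the bias before the chirp.
#' @param n_trials,master_seed Trial count and seed.
#' @param record Keep the (post-settle) voltage trace of each trial?
#' @return List with `stimulus` (the chirp), `trains` (list of
#'   `nr_spike_train`), and `V` (last trial, if recorded).
#' @export
run_chirp_trials <- function(cell, f0 = 0, f1 = 40, T = 20, A_in = 0.1,
                             I_bias = cell$I_bias, dt = 0.1, sigma = 0,
                             settle = 1, n_trials = 1, master_seed = 1,
                             record = FALSE) {
  chirp <- make_chirp(f0, f1, A_in, I_bias, T, dt)
  n_settle <- round(settle * 1000 / dt)
  full <- new_stimulus(
    t = seq_len(n_settle + length(chirp$t)) * dt - dt,
    value = c(rep(I_bias, n_settle), chirp$value),
    kind = "chirp",
    meta = list(f0 = f0, f1 = f1, A_in = A_in, I_bias = I_bias,
                T = T + settle, dt = dt))
  trains <- vector("list", n_trials)
  V <- NULL
  for (k in seq_len(n_trials)) {
    res <- simulate_cell(cell, full, sigma = sigma, seed = master_seed,
                         trial = k,
                         record = if (record) "v" else character(0),
                         arm_after = n_settle * dt)
    tt <- res$spikes$times - n_settle * dt
    trains[[k]] <- new_spike_train(tt[tt > 0], T, k)
    if (record) V <- res$V[-seq_len(n_settle)]
  }
  list(stimulus = chirp, trains = trains, V = V)
}

scenario_registry <- function() list(
  subthreshold_impedance = function(seed, trials, ov) {
    fg <- ov$f_grid %||% seq(1, 40, by = 0.5)
    prof <- impedance_profile(naph_cell(), fg, A_in = ov$A_in %||% 0.05)
    pk <- find_resonant_peak(prof)
    list(summary = c(f_peak = pk$f_peak, peak_value = pk$magnitude,
                     resonant = as.numeric(pk$resonant)),
         profile = prof)
  },
  subthreshold_min_amplitude = function(seed, trials, ov) {
    r <- minimal_spiking_amplitude(naph_cell(),
                                   f_grid = ov$f_grid %||% 1:40,
                                   interval = ov$interval %||% c(0.05, 0.5),
                                   tol = ov$tol %||% 2e-3)
    list(summary = c(A_min = r$A_min, f_first = r$f_first))
  },
  calcium_band = function(seed, trials, ov) {
    cell <- calcium_lif_cell(g_C = ov$g_C %||% 0.08)
    fg <- ov$f_grid %||% 1:40
    sims <- lapply(fg, function(f) {
      stim <- make_sinusoid(f, ov$A_in %||% 8, cell$I_bias, ov$T %||% 3, 0.1)
      simulate_cell(cell, stim, sigma = ov$sigma %||% 0.001, seed = seed,
                    record = character(0), arm_after = 1000)$spikes
    })
    stims <- lapply(fg, function(f) make_sinusoid(f, 8, cell$I_bias, ov$T %||% 3, 0.1))
    prof <- cycle_averaged_rate(sims, stims, settle = 1)
    band <- spiking_band(prof, threshold = ov$threshold %||% 1)
    list(summary = c(band_center = band$center, f_lo = band$f_lo,
                     f_hi = band$f_hi, low_pass = as.numeric(band$low_pass)),
         profile = prof)
  },
  calcium_gc_sweep = function(seed, trials, ov) {
    gc_grid <- ov$g_C_grid %||% seq(0.04, 0.12, by = 0.02)
    rows <- lapply(gc_grid, function(gc) {
      s <- scenario_registry()$calcium_band(seed, trials, list(g_C = gc))$summary
      c(g_C = gc, s)
    })
    list(summary = c(n = length(gc_grid)),
         table = do.call(rbind, rows))
  },
  rlif_amplitude_sweep = function(seed, trials, ov) {
    amps <- ov$A_grid %||% seq(0.05, 0.3, by = 0.05)
    rows <- lapply(amps, function(a) {
      r <- run_chirp_trials(lif_cell(), A_in = a, I_bias = 0.9,
                            sigma = 0, n_trials = 1, master_seed = seed)
      coh <- spike_input_coherence(r$trains, r$stimulus, f_max = 40)
      pk <- find_resonant_peak(coh)
      c(A_in = a, f_peak = pk$f_peak, peak_coh = pk$magnitude,
        n_spikes = length(r$trains[[1]]$times))
    })
    list(summary = c(n = length(amps)), table = do.call(rbind, rows))
  },
  psp_layers_run = function(seed, trials, ov) {
    net <- build_preset("psp_layers")
    sig <- ov$sigma2 %||% 0.48
    runs <- lapply(seq_len(trials), function(k)
      simulate_network(net, master_seed = seed, trial = k, sigma2 = sig))
    input <- runs[[1]]$input_train
    N2 <- net$N2
    coh2 <- lapply(seq_len(N2), function(c)
      spike_input_coherence(lapply(runs, function(r) r$spikes[[c]]),
                            input, f_max = 40))
    coh2m <- mean_coherence(coh2)
    coh3 <- spike_input_coherence(lapply(runs, function(r) r$spikes[[N2 + 1]]),
                                  input, f_max = 40)
    pk2 <- find_resonant_peak(coh2m)
    pk3 <- find_resonant_peak(coh3)
    list(summary = c(layer2_peak = pk2$magnitude, layer2_f = pk2$f_peak,
                     layer3_peak = pk3$magnitude, layer3_f = pk3$f_peak),
         coherence_layer2 = coh2m, coherence_layer3 = coh3)
  },
  psp_layers_noise_sweep = function(seed, trials, ov) {
    sig_grid <- ov$sigma_grid %||% seq(0.2, 0.9, by = 0.1)
    rows <- lapply(sig_grid, function(s) {
      r <- scenario_registry()$psp_layers_run(seed, trials,
                                              list(sigma2 = s))$summary
      c(sigma = s, r)
    })
    tab <- do.call(rbind, rows)
    best <- which.max(tab[, "layer2_peak"])
    list(summary = c(sigma_best = unname(tab[best, "sigma"]),
                     layer2_peak_best = unname(tab[best, "layer2_peak"])),
         table = tab)
  },
  gamma_int_impedance = function(seed, trials, ov) {
    r <- run_chirp_trials(int_cell(), f0 = 0, f1 = 80, T = 10,
                          A_in = ov$A_in %||% 0.5,
                          I_bias = ov$I_bias %||% 3.8, dt = 0.025,
                          sigma = 0, master_seed = seed, record = TRUE)
    prof <- impedance_from_chirp(r$V, r$stimulus, smooth = ov$smooth %||% 4)
    pk <- find_resonant_peak(prof, smooth = 1)
    list(summary = c(f_peak = pk$f_peak, peak_value = pk$magnitude,
                     n_spikes = length(r$trains[[1]]$times)),
         profile = prof)
  },
  gamma_int_spiking = function(seed, trials, ov) {
    r <- run_chirp_trials(int_cell(), f0 = 0, f1 = 80, T = 10,
                          A_in = ov$A_in %||% 0.9,
                          I_bias = ov$I_bias %||% 3.7, dt = 0.025,
                          sigma = 0, master_seed = seed)
    band <- band_from_spikes(r$trains, r$stimulus)
    list(summary = c(band_center = band$center, f_lo = band$f_lo,
                     f_hi = band$f_hi, n_spikes = band$n_spikes))
  },
  pyr_direct = function(seed, trials, ov) {
    r <- run_chirp_trials(pyr_cell(), f0 = 0, f1 = 40, T = 20,
                          A_in = ov$A_in %||% 0.2, I_bias = -2.7,
                          dt = 0.025, sigma = ov$sigma %||% 0.1,
                          n_trials = trials, master_seed = seed)
    coh <- spike_input_coherence(r$trains, r$stimulus, f_max = 40)
    pk <- find_resonant_peak(coh)
    phs <- spike_phase_mean(r$trains, r$stimulus,
                            f_range = pk$f_peak + c(-2, 2))
    list(summary = c(f_peak = pk$f_peak, peak_coh = pk$magnitude,
                     phase = phs$phase, phase_R = phs$R),
         coherence = coh, trains = r$trains, stimulus = r$stimulus)
  },
  int_pyr_run = function(seed, trials, ov) {
    net <- build_preset(ov$preset %||% "int_pyr")
    runs <- lapply(seq_len(trials), function(k)
      simulate_network(net, master_seed = seed, trial = k))
    pyr_trains <- lapply(runs, function(r) r$spikes$pyr)
    coh <- spike_input_coherence(pyr_trains, runs[[1]]$stimulus, f_max = 40)
    pk <- find_resonant_peak(coh)
    phs <- spike_phase_mean(pyr_trains, runs[[1]]$stimulus,
                            f_range = pk$f_peak + c(-2, 2))
    list(summary = c(f_peak = pk$f_peak, peak_coh = pk$magnitude,
                     phase = phs$phase, phase_R = phs$R),
         coherence = coh, trains = pyr_trains, stimulus = runs[[1]]$stimulus)
  }
)

#' Run a named scenario
#'
#' Executes one of the package's reference experiments and returns its
#' metric summary; optionally writes the summary, profiles and resolved
#' parameters as delimited text under `out_dir`.
#'
#' @param name Scenario name; see `names(neurores:::scenario_registry())`.
#' @param seed Master seed for all randomness in the scenario.
#' @param trials Number of independent-noise trials (where applicable).
#' @param overrides Named list of scenario-specific overrides (e.g.
#'   `list(sigma2 = 0.3)`).
#' @param out_dir Optional output directory.
#' @return List with at least `summary` (named numeric vector); scenarios
#'   with profiles or sweep tables attach them.
#' @examples
#' \donttest{
#' run_scenario("subthreshold_impedance")$summary
#' }
#' @export
run_scenario <- function(name, seed = 1, trials = 10, overrides = list(),
                         out_dir = NULL) {
  reg <- scenario_registry()
  if (!name %in% names(reg))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  bad <- setdiff(names(overrides),
                 c("f_grid", "A_in", "I_bias", "sigma", "sigma2", "g_C",
                   "g_C_grid", "A_grid", "sigma_grid", "interval", "tol",
                   "T", "threshold", "smooth", "preset"))
  if (length(bad)) stop("unknown override key(s): ", paste(bad, collapse = ", "))
  res <- reg[[name]](seed, trials, overrides)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(data.frame(metric = names(res$summary),
                           value = as.numeric(res$summary)),
                file.path(out_dir, paste0(name, "_summary.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$table))
      write.table(as.data.frame(res$table),
                  file.path(out_dir, paste0(name, "_table.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$profile))
      write_profile(res$profile, file.path(out_dir, paste0(name, "_profile.tsv")))
    cfg <- c(scenario = name, seed = seed, trials = trials,
             unlist(overrides))
    writeLines(paste(names(cfg), cfg, sep = " = "),
               file.path(out_dir, paste0(name, "_config.txt")))
  }
  res
}

#' List available scenarios
#' @return Character vector of scenario names.
#' @export
list_scenarios <- function() names(scenario_registry())

#' Sweep one scenario parameter
#'
#' Re-runs a scenario across a grid of values for one override key and
#' binds the summaries into a table; all sweep points share the same seed.
#'
#' @param name Scenario name.
#' @param axis Override key to vary.
#' @param values Values for the axis.
#' @param seed,trials As in [run_scenario()].
#' @return A data.frame with one row per sweep value; empty for an empty
#'   value list.
#' @export
sweep_scenario <- function(name, axis, values, seed = 1, trials = 10) {
  rows <- lapply(values, function(v) {
    ov <- list(); ov[[axis]] <- v
    s <- run_scenario(name, seed = seed, trials = trials, overrides = ov)$summary
    c(stats::setNames(v, axis), s)
  })
  if (length(rows) == 0) return(data.frame())
  as.data.frame(do.call(rbind, rows))
}
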