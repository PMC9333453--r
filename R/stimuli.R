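# Stimulus generators: deterministic periodic currents, linear chirps,
# periodic spike trains and their presynaptic-voltage encoding, per-step
# Gaussian noise, and synthetic spike trains with controlled rate- or
# phase-band structure.
#
# Units: time grids in ms, durations T in s, frequencies in Hz, currents in
# uA/cm2, voltages in mV.

new_stimulus <- function(t, value, kind, meta) {
  structure(list(t = t, value = value, kind = kind, meta = meta),
            class = "nr_stimulus")
}

#' Sinusoidal current stimulus
#'
#' Builds `I(t) = I_bias + A_in * sin(2 pi f t)` on a uniform time grid.
#'
#' @param f Frequency in Hz (`f = 0` gives a constant trace at `I_bias`).
#' @param A_in AC amplitude in uA/cm2.
#' @param I_bias DC bias in uA/cm2.
#' @param T Duration in seconds.
#' @param dt Time step in ms.
#' @return A stimulus trace (class `nr_stimulus`) with fields `t` (ms),
#'   `value`, `kind`, and `meta`.
#' @examples
#' s <- make_sinusoid(f = 8, A_in = 0.15, I_bias = -1.85, T = 1)
#' range(s$value)
#' @export
make_sinusoid <- function(f, A_in, I_bias, T, dt = 0.1) {
  stopifnot(f >= 0)
  if (T <= 0 || dt <= 0) stop("T and dt must be positive")
  n <- round(T * 1000 / dt)
  t <- seq_len(n + 1L) * dt - dt
  value <- I_bias + A_in * sin(2 * pi * f * t / 1000)
  new_stimulus(t, value, if (f == 0 || A_in == 0) "constant" else "sinusoid",
               list(f = f, A_in = A_in, I_bias = I_bias, T = T, dt = dt))
}

#' Linear chirp current stimulus
#'
#' Builds `I(t) = I_bias + A_in * cos(pi + 2 pi f0 t + pi (f1 - f0) t^2 / T)`;
#' the instantaneous frequency rises linearly from `f0` to `f1` over `T`.
#'
#' @inheritParams make_sinusoid
#' @param f0,f1 Start and end frequency in Hz (`f1 >= f0 >= 0`).
#' @return A stimulus trace of kind `"chirp"`.
#' @export
make_chirp <- function(f0, f1, A_in, I_bias, T, dt = 0.1) {
  if (T <= 0 || dt <= 0) stop("T and dt must be positive")
  if (f1 < f0 || f0 < 0) stop("require f1 >= f0 >= 0")
  n <- round(T * 1000 / dt)
  t <- seq_len(n + 1L) * dt - dt
  ts <- t / 1000
  value <- I_bias + A_in * cos(pi + 2 * pi * f0 * ts + pi * (f1 - f0) * ts^2 / T)
  new_stimulus(t, value, "chirp",
               list(f0 = f0, f1 = f1, A_in = A_in, I_bias = I_bias, T = T, dt = dt))
}

#' Constant (bias-only) current stimulus
#'
#' @inheritParams make_sinusoid
#' @return A stimulus trace of kind `"constant"`.
#' @export
make_constant <- function(I_bias, T, dt = 0.1) {
  make_sinusoid(0, 0, I_bias, T, dt)
}

wrap_phase <- function(theta) ((theta + pi) %% (2 * pi)) - pi

#' Instantaneous frequency and phase of a stimulus
#'
#' The phase convention places phase 0 at the maxima of the input waveform,
#' so "spikes near zero phase" means spikes at the input peaks. Both are
#' computed analytically from the known phase function of the sinusoid or
#' chirp, not from the sampled waveform.
#'
#' @param stim A stimulus trace.
#' @param t Times in ms at which to evaluate (default: the stimulus grid).
#' @return For `instantaneous_frequency`, Hz; for `input_phase`, radians in
#'   `[-pi, pi)`.
#' @export
instantaneous_frequency <- function(stim, t = stim$t) {
  m <- stim$meta
  switch(stim$kind,
    sinusoid = rep(m$f, length(t)),
    constant = rep(0, length(t)),
    chirp = m$f0 + (m$f1 - m$f0) * (t / 1000) / m$T,
    spike_train_voltage = stop("no analytic frequency for a spike-train voltage trace"),
    stop("unknown stimulus kind"))
}

#' @rdname instantaneous_frequency
#' @export
input_phase <- function(stim, t = stim$t) {
  m <- stim$meta
  ts <- t / 1000
  theta <- switch(stim$kind,
    sinusoid = 2 * pi * m$f * ts - pi / 2,
    chirp = pi + 2 * pi * m$f0 * ts + pi * (m$f1 - m$f0) * ts^2 / m$T,
    stop("phase defined only for sinusoid and chirp stimuli"))
  wrap_phase(theta)
}

new_spike_train <- function(times, T, trial = 1L) {
  structure(list(times = as.numeric(times), T = T, trial = as.integer(trial)),
            class = "nr_spike_train")
}

#' Periodic spike train locked to a waveform
#'
#' Emits one spike at each local maximum of a sinusoid or chirp waveform.
#' Maxima are located analytically from the phase function. A constant
#' waveform yields an empty train.
#'
#' @param stim A stimulus trace of kind sinusoid, chirp or constant.
#' @return A spike train (class `nr_spike_train`) with `times` in ms.
#' @examples
#' tr <- make_periodic_spike_train(make_sinusoid(10, 1, 0, T = 1))
#' length(tr$times)  # 10 spikes, one per cycle
#' @export
make_periodic_spike_train <- function(stim) {
  m <- stim$meta
  T <- m$T
  if (stim$kind == "constant") return(new_spike_train(numeric(0), T))
  if (stim$kind == "sinusoid") {
    # maxima of sin(2 pi f t) at t = (k + 1/4) / f
    f <- m$f
    k <- 0:floor(f * T - 0.25)
    ts <- (k + 0.25) / f
  } else if (stim$kind == "chirp") {
    # maxima of cos(pi + 2 pi f0 t + pi (f1-f0) t^2 / T) where the phase
    # equals 2 pi k
    f0 <- m$f0; f1 <- m$f1
    kmax <- floor((T * (f0 + f1) + 1) / 2)
    k <- seq_len(max(kmax, 0))
    if (f1 > f0) {
      ts <- T * (-f0 + sqrt(f0^2 + (f1 - f0) * (2 * k - 1) / T)) / (f1 - f0)
    } else {
      if (f0 == 0) return(new_spike_train(numeric(0), T))
      ts <- (k - 0.5) / f0
    }
  } else {
    stop("periodic spike trains are defined for sinusoid or chirp waveforms")
  }
  ts <- ts[ts >= 0 & ts <= T]
  new_spike_train(ts * 1000, T)
}

#' Encode a spike train as a presynaptic voltage trace
#'
#' The presynaptic voltage is 50 mV at any time at which a spike occurred
#' within the last 1 ms and -60 mV otherwise; spikes closer than 1 ms merge
#' into a single prolonged pulse.
#'
#' @param train A spike train (times in ms).
#' @param dt Grid step in ms.
#' @param T Duration in s (default: the train's record duration).
#' @return A stimulus trace of kind `"spike_train_voltage"` (values in mV).
#' @export
spikes_to_presynaptic_voltage <- function(train, dt = 0.1, T = train$T) {
  n <- round(T * 1000 / dt)
  t <- seq_len(n + 1L) * dt - dt
  v <- rep(-60, n + 1L)
  for (s in train$times) {
    i0 <- ceiling(s / dt - 1e-9) + 1L
    i1 <- ceiling((s + 1) / dt - 1e-9)  # half-open: [s, s + 1)
    if (i0 <= n + 1L) v[i0:min(i1, n + 1L)] <- 50
  }
  new_stimulus(t, v, "spike_train_voltage",
               list(T = T, dt = dt, n_spikes = length(train$times)))
}

#' Per-step Gaussian current noise
#'
#' Draws i.i.d. increments `g_N * eta_k`, `eta_k ~ N(0, sigma)`, from the
#' same deterministic stream used inside the integrator, keyed by
#' `(seed, cell, trial)`. One draw is consumed per integration step and the
#' draw is *not* scaled by `sqrt(dt)`: `sigma` is the per-step noise
#' amplitude at the model's fixed `dt`.
#'
#' @param sigma Noise SD in mV.
#' @param n_steps Number of steps.
#' @param g_N Noise conductance in mS/cm2 (default 1).
#' @param seed,cell,trial Stream key.
#' @return Numeric vector of current increments in uA/cm2.
#' @export
make_noise_steps <- function(sigma, n_steps, g_N = 1, seed = 1, cell = 1, trial = 1) {
  stopifnot(sigma >= 0, n_steps > 0)
  .noise_steps_cpp(sigma, as.integer(n_steps), g_N, seed, cell, trial)
}

# Best & Fisher (1979) rejection sampler for the von Mises distribution.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  if (kappa > 5e5) return(rep(wrap_phase(mu), n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- wrap_phase(mu + sign(u3 - 0.5) * acos(f))
      i <- i + 1L
    }
  }
  out
}

#' Synthetic spike trains with a rate or phase band
#'
#' Generates, for each test frequency, a spike train locked to a sinusoid of
#' that frequency, with either (i) `mode = "rate_band"`: per-cycle spike
#' counts drawn from a Poisson distribution whose mean is doubled inside the
#' band, phases uniform; or (ii) `mode = "phase_band"`: a fixed count per
#' cycle with phases drawn from a von Mises distribution whose concentration
#' is elevated inside the band. These two constructions produce pure
#' cycle-averaged firing-rate resonance and pure spike-timing resonance,
#' respectively.
#'
#' @param mode `"rate_band"` or `"phase_band"`.
#' @param f_grid Test frequencies in Hz.
#' @param band Length-2 numeric, the resonant band in Hz (inclusive).
#' @param base_rate Out-of-band mean firing rate in spk/s (`rate_band`).
#' @param spikes_per_cycle Fixed per-cycle count (`phase_band`).
#' @param kappa_in,kappa_out von Mises concentrations inside/outside the band.
#' @param T Record duration per frequency in s.
#' @param seed RNG seed (R's RNG).
#' @return List with one element per frequency, each containing `f`, `train`
#'   (an `nr_spike_train`), and `stim` (the matching unit sinusoid).
#' @export
make_synthetic_trains <- function(mode = c("rate_band", "phase_band"),
                                  f_grid = 1:20, band = c(8, 12),
                                  base_rate = 14, spikes_per_cycle = 1,
                                  kappa_in = 8, kappa_out = 0.5,
                                  T = 10, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(band[1] >= min(f_grid), band[2] <= max(f_grid))
  set.seed(seed)
  lapply(f_grid, function(f) {
    in_band <- f >= band[1] & f <= band[2]
    n_cycles <- floor(f * T)
    if (mode == "rate_band") {
      lam <- base_rate / f * (if (in_band) 2 else 1)
      counts <- rpois(n_cycles, lam)
      phases <- runif(sum(counts), -pi, pi)
    } else {
      counts <- rep(spikes_per_cycle, n_cycles)
      kappa <- if (in_band) kappa_in else kappa_out
      phases <- rvonmises(sum(counts), 0, kappa)
    }
    cyc <- rep(seq_len(n_cycles) - 1L, counts)
    # invert the phase convention (0 = waveform maximum) to spike times
    ts <- (cyc + (phases + pi / 2) / (2 * pi)) / f
    ts <- sort(ts[ts >= 0 & ts <= T])
    list(f = f,
         train = new_spike_train(ts * 1000, T),
         stim = make_sinusoid(f, 1, 0, T))
  })
}

#' @export
print.nr_stimulus <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<nr_stimulus> kind=%s, T=%g s, dt=%g ms, %d samples\n",
              x$kind, m$T, m$dt %||% (x$t[2] - x$t[1]), length(x$t)))
  if (x$kind == "sinusoid") cat(sprintf("  f=%g Hz, A_in=%g, I_bias=%g\n", m$f, m$A_in, m$I_bias))
  if (x$kind == "chirp") cat(sprintf("  f0=%g -> f1=%g Hz, A_in=%g, I_bias=%g\n",
                                     m$f0, m$f1, m$A_in, m$I_bias))
  invisible(x)
}

#' @export
print.nr_spike_train <- function(x, ...) {
  cat(sprintf("<nr_spike_train> %d spikes over %g s (trial %d)\n",
              length(x$times), x$T, x$trial))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
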