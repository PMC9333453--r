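# Resonance metrics: impedance profiles, cycle-averaged rates,
# frequency-phase fingerprints, spike-input spectral coherence, EPSP
# magnitude profiles, and peak extraction.

new_profile <- function(f, value, kind) {
  structure(list(f = f, value = value, kind = kind), class = "nr_profile")
}

#' @export
print.nr_profile <- function(x, ...) {
  cat(sprintf("<nr_profile:%s> %d frequencies in [%g, %g] Hz\n",
              x$kind, length(x$f), min(x$f), max(x$f)))
  invisible(x)
}

profile_xy <- function(p) {
  if (inherits(p, "nr_impedance")) list(f = p$f, value = p$mag)
  else if (inherits(p, "nr_coherence")) list(f = p$f, value = p$coh)
  else if (inherits(p, "nr_profile")) list(f = p$f, value = p$value)
  else if (is.list(p) && !is.null(p$f)) list(f = p$f, value = p$value)
  else stop("not a profile object")
}

# ------------------------------------------------------------ impedance ----

#' Impedance profile from single-frequency sinusoidal drives
#'
#' For each frequency, drives the cell with
#' `I = I_bias + A_in sin(2 pi f t)` at zero noise, discards the settling
#' period, and computes the impedance magnitude
#' `|Z|(f) = (max V - min V) / (2 A_in)` (mV per uA/cm2) together with the
#' phase of the voltage fundamental relative to the input. Spikes inside
#' the analysis window raise an error: the impedance is a subthreshold
#' measure.
#'
#' @param cell Cell parameter object.
#' @param f_grid Frequencies in Hz.
#' @param A_in AC amplitude (uA/cm2), small enough to stay subthreshold.
#' @param I_bias DC bias.
#' @param T,dt,settle Per-frequency duration (s), step (ms), discarded
#'   settle (s).
#' @return An `nr_impedance` with `f`, `mag` and `phase` (radians, in
#'   `(-pi, pi]`).
#' @export
impedance_profile <- function(cell, f_grid, A_in = 0.05,
                              I_bias = cell$I_bias, T = 3, dt = 0.1,
                              settle = 1) {
  mag <- phase <- numeric(length(f_grid))
  for (i in seq_along(f_grid)) {
    f <- f_grid[i]
    stim <- make_sinusoid(f, A_in, I_bias, T, dt)
    res <- simulate_cell(cell, stim, arm_after = settle * 1000)
    idx <- stim$t >= settle * 1000
    if (any(res$spikes$times >= settle * 1000))
      stop("spikes detected in the analysis window at f = ", f,
           " Hz; use a subthreshold amplitude")
    v <- res$V[idx]
    mag[i] <- (max(v) - min(v)) / (2 * A_in)
    if (f > 0) {
      tw <- stim$t[idx]
      e <- exp(-2i * pi * f * tw / 1000)
      cV <- sum((v - mean(v)) * e)
      cI <- sum((stim$value[idx] - I_bias) * e)
      phase[i] <- Arg(cV / cI)
    }
  }
  structure(list(f = f_grid, mag = mag, phase = phase),
            class = c("nr_impedance", "nr_profile"))
}

#' Impedance profile from a chirp response
#'
#' Ratio of the Fourier transforms of the mean-subtracted voltage and input
#' current over the recorded window, magnitude-smoothed over `smooth` Hz.
#'
#' @param V Voltage trace (mV) on the stimulus grid.
#' @param stimulus The chirp stimulus that produced it.
#' @param smooth Moving-average bandwidth in Hz for the magnitude.
#' @return An `nr_impedance` restricted to the swept band.
#' @export
impedance_from_chirp <- function(V, stimulus, smooth = 2) {
  if (inherits(V, "nr_sim")) V <- V$V
  m <- stimulus$meta
  # truncate to the largest 5-smooth length <= n so the FFT stays fast;
  # at most a fraction of a percent of the sweep tail is dropped
  n <- smooth_length(length(V))
  V <- V[seq_len(n)]
  I <- stimulus$value[seq_len(n)]
  f1_eff <- m$f0 + (m$f1 - m$f0) * (n - 1) / (length(stimulus$value) - 1)
  fgrid <- (seq_len(n) - 1) / (n * (m$dt / 1000))  # Hz
  Z <- fft(V - mean(V)) / fft(I - mean(I))
  keep <- fgrid >= max(m$f0, fgrid[2]) & fgrid <= f1_eff
  mag <- Mod(Z)[keep]
  w <- max(1L, round(smooth / (fgrid[2] - fgrid[1])))
  structure(list(f = fgrid[keep], mag = running_mean(mag, w),
                 phase = Arg(Z)[keep]),
            class = c("nr_impedance", "nr_profile"))
}

# largest integer <= n whose prime factors are all in {2, 3, 5}
smooth_length <- function(n) {
  for (m in n:max(1, n - 5000)) {
    k <- m
    for (p in c(2L, 3L, 5L)) while (k %% p == 0L) k <- k %/% p
    if (k == 1L) return(m)
  }
  n
}

running_mean <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  h <- w %/% 2L
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Closed-form impedance of the passive RC membrane
#'
#' `|Z|(f) = (1/g_L) / sqrt(1 + (2 pi f C / g_L)^2)`, with phase
#' `-atan(2 pi f C / g_L)`; the analytic reference the simulated passive
#' membrane must reproduce.
#'
#' @param f Frequency in Hz.
#' @param C Capacitance (uF/cm2).
#' @param g_L Leak conductance (mS/cm2).
#' @return List with `mag` and `phase`.
#' @export
rc_impedance <- function(f, C = 1, g_L = 0.1) {
  wt <- 2 * pi * f / 1000 * C / g_L  # omega tau, f in Hz, tau in ms
  list(mag = (1 / g_L) / sqrt(1 + wt^2), phase = -atan(wt))
}

# ----------------------------------------------------- rates and phases ----

as_train_list <- function(spikes) {
  if (inherits(spikes, "nr_spike_train")) list(spikes) else spikes
}

#' Cycle-averaged firing rate versus input frequency
#'
#' Assigns every spike to the instantaneous frequency of the stimulus at
#' the spike time and normalizes counts by the time spent at each
#' frequency (pooled over trials), yielding spk/s per frequency bin. For a
#' single-frequency sinusoid the profile is a single bin.
#'
#' @param spikes An `nr_spike_train` or a list of them (trials).
#' @param stimulus The driving stimulus (chirp or sinusoid), or a list
#'   parallel to `spikes` for per-frequency runs.
#' @param f_bin Bin width in Hz (chirp).
#' @param settle Initial window to discard in s.
#' @return An `nr_profile` of kind `"rate"`.
#' @export
cycle_averaged_rate <- function(spikes, stimulus, f_bin = 1, settle = 0) {
  trains <- as_train_list(spikes)
  stims <- if (inherits(stimulus, "nr_stimulus"))
    rep(list(stimulus), length(trains)) else stimulus
  stopifnot(length(stims) == length(trains))
  kinds <- vapply(stims, function(s) s$kind, "")
  if (all(kinds %in% c("sinusoid", "constant")) &&
      length(unique(vapply(stims, function(s) s$meta$f, 0))) == length(stims) &&
      length(stims) > 1) {
    # per-frequency sinusoid runs: one rate value per stimulus
    f <- vapply(stims, function(s) s$meta$f, 0)
    rate <- mapply(function(tr, s) {
      sum(tr$times >= settle * 1000) / (s$meta$T - settle)
    }, trains, stims)
    o <- order(f)
    return(new_profile(f[o], rate[o], "rate"))
  }
  s1 <- stims[[1]]
  if (s1$kind == "chirp") {
    m <- s1$meta
    edges <- seq(m$f0, m$f1, by = f_bin)
    if (edges[length(edges)] < m$f1) edges <- c(edges, m$f1)
    nb <- length(edges) - 1
    counts <- numeric(nb)
    for (k in seq_along(trains)) {
      tt <- trains[[k]]$times
      tt <- tt[tt >= settle * 1000]
      fi <- instantaneous_frequency(stims[[k]], tt)
      counts <- counts + tabulate(findInterval(fi, edges,
                                               rightmost.closed = TRUE),
                                  nbins = nb)
    }
    # occupancy from the stimulus grid, pooled over trials
    gt <- s1$t[s1$t >= settle * 1000]
    gi <- findInterval(instantaneous_frequency(s1, gt), edges,
                       rightmost.closed = TRUE)
    occ <- tabulate(gi, nbins = nb) * (s1$t[2] - s1$t[1]) / 1000 *
      length(trains)
    rate <- ifelse(occ > 0, counts / occ, 0)
    new_profile((edges[-1] + edges[-(nb + 1)]) / 2, rate, "rate")
  } else {
    rate <- mean(vapply(trains, function(tr)
      sum(tr$times >= settle * 1000) / (s1$meta$T - settle), 0))
    new_profile(s1$meta$f, rate, "rate")
  }
}

#' Frequency-phase fingerprint
#'
#' Counts spikes in 2D (input frequency, input phase) bins, pooled over
#' trials, and divides by the time spent in each bin, yielding
#' instantaneous firing rates (spk/s). Phase 0 corresponds to the input
#' waveform maximum. Use [expand_phase()] to render the conventional
#' 1.5-cycle phase axis.
#'
#' @inheritParams cycle_averaged_rate
#' @param n_phase_bins Phase bins per cycle.
#' @return An `nr_fingerprint` with `f` (bin centers), `phase` (bin
#'   centers, radians), `rate`, `counts`, `occupancy` (s).
#' @export
fingerprint <- function(spikes, stimulus, f_bin = 1, n_phase_bins = 36,
                        settle = 0) {
  trains <- as_train_list(spikes)
  stims <- if (inherits(stimulus, "nr_stimulus"))
    rep(list(stimulus), length(trains)) else stimulus
  stopifnot(length(stims) == length(trains))
  fvals <- unlist(lapply(stims, function(s)
    range(instantaneous_frequency(s))))
  fmin <- floor(min(fvals) + 1e-9); fmax <- ceiling(max(fvals) - 1e-9)
  fedges <- seq(fmin, fmax, by = f_bin)
  if (fedges[length(fedges)] < fmax) fedges <- c(fedges, fmax)
  pedges <- seq(-pi, pi, length.out = n_phase_bins + 1)
  nf <- length(fedges) - 1
  counts <- occ <- matrix(0, nf, n_phase_bins)

  bin2 <- function(fi, ph) {
    i <- findInterval(fi, fedges, rightmost.closed = TRUE)
    j <- findInterval(ph, pedges, rightmost.closed = TRUE)
    ok <- i >= 1 & i <= nf & j >= 1 & j <= n_phase_bins
    cbind(i[ok], j[ok])
  }
  seen <- new.env()
  for (k in seq_along(trains)) {
    st <- stims[[k]]
    tt <- trains[[k]]$times
    tt <- tt[tt >= settle * 1000]
    if (length(tt)) {
      ij <- bin2(instantaneous_frequency(st, tt), input_phase(st, tt))
      for (r in seq_len(nrow(ij)))
        counts[ij[r, 1], ij[r, 2]] <- counts[ij[r, 1], ij[r, 2]] + 1
    }
    # occupancy from the stimulus grid (identical stimuli share it)
    key <- paste0(st$kind, st$meta$f %||% "", st$meta$f0 %||% "",
                  st$meta$T, st$meta$dt)
    if (is.null(seen[[key]])) {
      gt <- st$t[st$t >= settle * 1000]
      ij <- bin2(instantaneous_frequency(st, gt), input_phase(st, gt))
      o <- matrix(0, nf, n_phase_bins)
      tb <- table(factor(ij[, 1], levels = 1:nf),
                  factor(ij[, 2], levels = 1:n_phase_bins))
      o[] <- as.numeric(tb) * (st$t[2] - st$t[1]) / 1000
      seen[[key]] <- o
    }
    occ <- occ + seen[[key]]
  }
  rate <- ifelse(occ > 0, counts / occ, 0)
  structure(list(f = (fedges[-1] + fedges[-(nf + 1)]) / 2,
                 phase = (pedges[-1] + pedges[-(n_phase_bins + 1)]) / 2,
                 rate = rate, counts = counts, occupancy = occ),
            class = "nr_fingerprint")
}

#' @export
print.nr_fingerprint <- function(x, ...) {
  cat(sprintf("<nr_fingerprint> %d f-bins x %d phase-bins, %d spikes, peak %.1f spk/s\n",
              length(x$f), length(x$phase), sum(x$counts), max(x$rate)))
  invisible(x)
}

#' Expand a fingerprint to 1.5 phase cycles
#'
#' Returns the rate matrix with the phase axis wrapped to cover one and a
#' half cycles (the conventional rendering).
#'
#' @param fp An `nr_fingerprint`.
#' @return Matrix with `length(fp$phase) * 1.5` columns; column names give
#'   phases in radians.
#' @export
expand_phase <- function(fp) {
  np <- length(fp$phase)
  extra <- seq_len(ceiling(np / 2))
  m <- cbind(fp$rate, fp$rate[, extra, drop = FALSE])
  colnames(m) <- sprintf("%.3f", c(fp$phase, fp$phase[extra] + 2 * pi))
  rownames(m) <- sprintf("%g", fp$f)
  m
}

#' Phase-marginal of a fingerprint
#'
#' Marginalizing the fingerprint over phase (total counts over total
#' occupancy per frequency row) recovers the cycle-averaged rate profile.
#'
#' @param fp An `nr_fingerprint`.
#' @return An `nr_profile` of kind `"rate"`.
#' @export
fingerprint_rate_marginal <- function(fp) {
  occ <- rowSums(fp$occupancy)
  new_profile(fp$f, ifelse(occ > 0, rowSums(fp$counts) / occ, 0), "rate")
}

# ------------------------------------------------------------ coherence ----

#' Spike-input spectral coherence
#'
#' Magnitude of the complex coherence between the input (a current waveform
#' or a spike train) and output spike trains, estimated by Welch
#' segment-averaged cross-spectra pooled over segments and trials:
#' `coh = |sum S_xy| / sqrt(sum S_xx * sum S_yy)`. Spike trains enter as
#' binned indicator series on a `dt_bin` grid; segments are demeaned and
#' Hann-tapered. Coherence is 1 under perfect phase locking and decays to
#' the `1/n_segments` bias floor for unrelated trains.
#'
#' @param spikes An `nr_spike_train` or list of them (trials/cells pooled
#'   into one estimate).
#' @param input An `nr_stimulus` (waveform) or `nr_spike_train`.
#' @param dt_bin Spike binning step in ms.
#' @param seg_s Segment length in s (frequency resolution `1/seg_s`).
#' @param overlap Segment overlap fraction.
#' @param f_max Truncate the output above this frequency (Hz).
#' @return An `nr_coherence` with `f`, `coh` and `n_segments`; the
#'   `zero_spikes` attribute flags an all-empty input.
#' @export
spike_input_coherence <- function(spikes, input, dt_bin = 1, seg_s = 2,
                                  overlap = 0.5, f_max = NULL) {
  trains <- as_train_list(spikes)
  T <- if (inherits(input, "nr_stimulus")) input$meta$T else input$T
  nbin <- floor(T * 1000 / dt_bin)
  edges <- seq(0, nbin) * dt_bin

  bin_counts <- function(times) {
    times <- times[times > 0 & times <= nbin * dt_bin]
    tabulate(pmin(nbin, ceiling(times / dt_bin)), nbins = nbin)
  }
  x <- if (inherits(input, "nr_stimulus")) {
    dts <- input$t[2] - input$t[1]
    idx <- pmin(length(input$value),
                round((edges[-1] - dt_bin / 2) / dts) + 1)
    input$value[idx]
  } else {
    bin_counts(input$times)
  }

  nper <- round(seg_s * 1000 / dt_bin)
  step <- max(1, round(nper * (1 - overlap)))
  if (nper > nbin) stop("record shorter than one segment")
  starts <- seq(1, nbin - nper + 1, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(nper) / (nper + 1)))  # Hann

  xa <- vector("list", length(starts))
  for (s in seq_along(starts)) {
    xs <- x[starts[s]:(starts[s] + nper - 1)]
    xa[[s]] <- fft((xs - mean(xs)) * win)
  }
  nfreq <- nper %/% 2 + 1
  Sxx <- Syy <- numeric(nfreq)
  Sxy <- complex(nfreq)
  total <- 0L
  any_spike <- FALSE
  for (tr in trains) {
    y <- bin_counts(tr$times)
    any_spike <- any_spike || any(y > 0)
    for (s in seq_along(starts)) {
      ys <- y[starts[s]:(starts[s] + nper - 1)]
      Y <- fft((ys - mean(ys)) * win)[seq_len(nfreq)]
      X <- xa[[s]][seq_len(nfreq)]
      Sxx <- Sxx + Mod(X)^2
      Syy <- Syy + Mod(Y)^2
      Sxy <- Sxy + Conj(X) * Y
      total <- total + 1L
    }
  }
  coh <- ifelse(Sxx > 0 & Syy > 0, Mod(Sxy) / sqrt(Sxx * Syy), 0)
  f <- (seq_len(nfreq) - 1) / seg_s
  keep <- if (is.null(f_max)) rep(TRUE, nfreq) else f <= f_max
  structure(list(f = f[keep], coh = coh[keep], n_segments = total),
            class = c("nr_coherence", "nr_profile"),
            zero_spikes = !any_spike)
}

#' Average coherence spectra across cells
#'
#' @param cohs List of `nr_coherence` on identical frequency grids.
#' @return An `nr_coherence` with the mean magnitude.
#' @export
mean_coherence <- function(cohs) {
  co <- rowMeans(vapply(cohs, function(c) c$coh, numeric(length(cohs[[1]]$f))))
  structure(list(f = cohs[[1]]$f, coh = co,
                 n_segments = cohs[[1]]$n_segments),
            class = c("nr_coherence", "nr_profile"))
}

# ------------------------------------------------------------------ EPSP ---

#' Steady-state EPSP magnitude
#'
#' Peak-to-trough amplitude of the per-cycle postsynaptic potential after
#' the settling period, for a cell driven by a periodic presynaptic train
#' with spiking disabled. With a single presynaptic spike the magnitude is
#' the unitary EPSP amplitude.
#'
#' @param sim An `nr_sim` of a (non-spiking) synaptically driven cell.
#' @param presyn_train The presynaptic spike train.
#' @param settle Settling period in s.
#' @return Magnitude in mV (mean over the post-settle cycles).
#' @export
epsp_magnitude <- function(sim, presyn_train, settle = 1) {
  if (length(sim$spikes$times) > 0)
    stop("postsynaptic spikes present; EPSP magnitude requires a ",
         "non-spiking run (raise V_th)")
  ts <- presyn_train$times
  dt <- sim$dt
  if (length(ts) == 0) return(0)
  if (length(ts) == 1) {
    idx <- sim$t >= ts[1]
    return(max(sim$V[idx]) - min(sim$V[idx]))
  }
  ts <- ts[ts >= settle * 1000]
  if (length(ts) < 2) stop("too few presynaptic spikes after the settle period")
  amps <- vapply(seq_len(length(ts) - 1), function(k) {
    idx <- sim$t >= ts[k] & sim$t < ts[k + 1]
    max(sim$V[idx]) - min(sim$V[idx])
  }, 0)
  mean(tail(amps, max(3, ceiling(length(amps) * 0.3))))
}

#' EPSP magnitude profile over presynaptic rates
#'
#' Drives a synaptic cell with periodic presynaptic trains at each rate and
#' measures the steady-state EPSP magnitude; the spiking threshold is
#' raised to 0 mV so the membrane stays subthreshold.
#'
#' @param cell A `plastic_lif_cell`.
#' @param rates Presynaptic rates in Hz.
#' @param I_bias DC bias (defaults to 0: passive PSP measurement).
#' @param T,dt,settle Run length (s), step (ms), settle (s).
#' @return An `nr_profile` of kind `"epsp"` (mV vs Hz).
#' @export
epsp_profile <- function(cell, rates, I_bias = 0, T = 4, dt = 0.1,
                         settle = 1) {
  cell$V_th <- 0
  mag <- vapply(rates, function(f) {
    train <- make_periodic_spike_train(make_sinusoid(f, 1, 0, T, dt))
    vpre <- spikes_to_presynaptic_voltage(train, dt, T)
    sim <- simulate_cell(cell, make_constant(I_bias, T, dt), presyn = vpre)
    epsp_magnitude(sim, train, settle)
  }, 0)
  new_profile(rates, mag, "epsp")
}

# ------------------------------------------------------- peak extraction ---

#' Locate the resonant peak of a profile
#'
#' Argmax of the (optionally moving-average smoothed) profile; ties break
#' toward the lowest frequency. The profile is flagged resonant only when
#' the peak is interior to the frequency grid — a peak at either end is a
#' low- or high-pass response, not resonance.
#'
#' @param profile An `nr_profile`, `nr_impedance` (magnitude used) or
#'   `nr_coherence`.
#' @param smooth Moving-average width in bins (1 disables smoothing).
#' @return List with `f_peak`, `magnitude` (unsmoothed value at the peak),
#'   and `resonant`.
#' @export
find_resonant_peak <- function(profile, smooth = 3) {
  p <- profile_xy(profile)
  if (length(p$f) == 0) stop("empty profile")
  v <- running_mean(p$value, smooth)
  i <- which.max(v)  # which.max takes the first maximum: lowest f on ties
  list(f_peak = p$f[i], magnitude = p$value[i],
       resonant = i > 1 && i < length(p$f))
}

#' Contiguous spiking frequency band
#'
#' Finds the contiguous run of frequency bins with `value >= threshold`
#' that contains the profile maximum; used to summarize band-pass spiking
#' responses ("spikes confined to a band"). A band starting at the first
#' grid point is flagged low-pass.
#'
#' @param profile A rate (or coherence) profile on a monotone f grid.
#' @param threshold Minimum sustained value (default 1 spk/s).
#' @return List with `f_lo`, `f_hi`, `center`, and `low_pass`.
#' @export
spiking_band <- function(profile, threshold = 1) {
  p <- profile_xy(profile)
  on <- p$value >= threshold
  if (!any(on)) return(list(f_lo = NA, f_hi = NA, center = NA,
                            low_pass = FALSE))
  i <- which.max(p$value)
  lo <- i; while (lo > 1 && on[lo - 1]) lo <- lo - 1
  hi <- i; while (hi < length(on) && on[hi + 1]) hi <- hi + 1
  list(f_lo = p$f[lo], f_hi = p$f[hi], center = (p$f[lo] + p$f[hi]) / 2,
       low_pass = lo == 1L)
}

#' Circular mean spike phase within a frequency band
#'
#' Circular mean of the input phases at which spikes occur, restricted to
#' spikes whose instantaneous input frequency falls in `f_range`. Phase 0
#' is the input maximum, so phases near `+/- pi` indicate spiking at the
#' input trough.
#'
#' @param spikes Train or list of trains.
#' @param stimulus The driving sinusoid or chirp.
#' @param f_range Length-2 frequency window in Hz (default: all).
#' @return List with `phase` (radians), `R` (resultant length in `[0,1]`)
#'   and `n` spikes used.
#' @export
spike_phase_mean <- function(spikes, stimulus, f_range = NULL) {
  trains <- as_train_list(spikes)
  ph <- unlist(lapply(trains, function(tr) {
    tt <- tr$times
    if (!is.null(f_range)) {
      fi <- instantaneous_frequency(stimulus, tt)
      tt <- tt[fi >= f_range[1] & fi <= f_range[2]]
    }
    input_phase(stimulus, tt)
  }))
  if (length(ph) == 0) return(list(phase = NA, R = NA, n = 0L))
  z <- mean(exp(1i * ph))
  list(phase = Arg(z), R = Mod(z), n = length(ph))
}

#' Frequency band of spikes under a chirp
#'
#' Maps each spike to the chirp's instantaneous frequency and returns the
#' trimmed extent of the spike-carrying band.
#'
#' @param spikes Train or list of trains.
#' @param stimulus The chirp.
#' @param trim Quantile trimmed from each side.
#' @return List with `f_lo`, `f_hi`, `center`, `n_spikes`.
#' @export
band_from_spikes <- function(spikes, stimulus, trim = 0.025) {
  trains <- as_train_list(spikes)
  fi <- unlist(lapply(trains, function(tr)
    instantaneous_frequency(stimulus, tr$times)))
  if (length(fi) == 0)
    return(list(f_lo = NA, f_hi = NA, center = NA, n_spikes = 0L))
  q <- stats::quantile(fi, c(trim, 1 - trim), names = FALSE)
  list(f_lo = q[1], f_hi = q[2], center = mean(q), n_spikes = length(fi))
}
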