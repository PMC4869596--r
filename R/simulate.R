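# Synthetic coupled-oscillator EEG: band-limited oscillations with known
# pairwise phase coupling, a phase-locked evoked transient, broadband noise,
# and optional high-amplitude artifact epochs. Ground truth is returned so
# downstream recovery can be tested without real recordings.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify phase coupling among a channel set
#'
#' In the named condition and band, every listed channel mixes a fraction
#' `kappa` of a shared common-oscillator phase into its own independent
#' phase: phi = (1 - kappa) * phi_indep + kappa * phi_common. `kappa = 0`
#' leaves channels independent; `kappa = 1` makes their band-limited phases
#' identical, so the downstream phase-synchronization index between them
#' is 1.
#'
#' @param condition condition label the coupling applies to
#' @param band band name (must match a configured band)
#' @param channels channel labels to couple (length >= 2 when kappa > 0)
#' @param kappa coupling strength in \[0, 1\]
#' @return object of class `coupling_spec`
#' @export
coupling_spec <- function(condition, band, channels, kappa) {
  if (kappa < 0 || kappa > 1) stop("kappa must be in [0, 1]")
  if (kappa > 0 && length(channels) < 2) {
    stop("coupling with kappa > 0 needs at least 2 channels")
  }
  structure(list(condition = condition, band = band,
                 channels = as.character(channels), kappa = kappa),
            class = "coupling_spec")
}

#' Simulation configuration
#'
#' The stated world of the generator: 28 analysis channels sampled at
#' 1000 Hz, epochs spanning -200..800 ms around the event, three canonical
#' bands with fixed per-band amplitudes (theta/alpha/beta = 10/8/5 uV), a
#' Gaussian-windowed 5 Hz evoked transient peaking at 350 ms added
#' phase-locked to Go/NoGo epochs, and additive white noise (sd 5 uV).
#'
#' @param channels channel labels (default: the 28 analysis channels of
#'   [default_montage()])
#' @param srate sampling rate, Hz
#' @param window epoch window in ms, half-open `[start, end)`
#' @param n_epochs_per_condition epochs per condition (default 90, the
#'   approximate per-condition trial count of a six-block session)
#' @param conditions condition labels
#' @param bands named list of band edges, Hz
#' @param amplitudes named per-band oscillation amplitudes, uV
#' @param coupling list of [coupling_spec()] objects
#' @param evoked_amplitude peak amplitude of the evoked transient, uV
#' @param evoked_conditions conditions receiving the evoked transient
#' @param noise_sd white-noise standard deviation, uV
#' @param phase_jitter_sd per-sample Wiener phase-jitter sd, radians
#' @param artifact_fraction fraction of epochs given a high-amplitude spike
#' @param artifact_amplitude spike amplitude, uV
#' @return object of class `sim_config`
#' @export
sim_config <- function(channels = analysis_channels(default_montage()),
                       srate = 1000,
                       window = c(-200, 800),
                       n_epochs_per_condition = 90,
                       conditions = c("Baseline", "Go", "NoGo"),
                       bands = default_bands(),
                       amplitudes = c(theta = 10, alpha = 8, beta = 5),
                       coupling = list(),
                       evoked_amplitude = 10,
                       evoked_conditions = c("Go", "NoGo"),
                       noise_sd = 5,
                       phase_jitter_sd = 0.05,
                       artifact_fraction = 0,
                       artifact_amplitude = 200) {
  if (srate <= 0) stop("sampling rate must be positive")
  if (window[1] >= window[2]) stop("epoch window start must precede end")
  if (artifact_fraction < 0 || artifact_fraction > 1) {
    stop("artifact_fraction must be in [0, 1]")
  }
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  for (cs in coupling) {
    stopifnot(inherits(cs, "coupling_spec"))
    if (!cs$band %in% names(bands)) stop("coupling band not configured: ", cs$band)
    bad <- setdiff(cs$channels, channels)
    if (length(bad)) stop("coupling channels outside montage: ",
                          paste(bad, collapse = ", "))
  }
  missing_amp <- setdiff(names(bands), names(amplitudes))
  if (length(missing_amp)) stop("no amplitude for band(s): ",
                                paste(missing_amp, collapse = ", "))
  structure(list(channels = as.character(channels), srate = srate,
                 window = window,
                 n_epochs_per_condition = n_epochs_per_condition,
                 conditions = conditions, bands = bands,
                 amplitudes = amplitudes, coupling = coupling,
                 evoked_amplitude = evoked_amplitude,
                 evoked_conditions = evoked_conditions,
                 noise_sd = noise_sd, phase_jitter_sd = phase_jitter_sd,
                 artifact_fraction = artifact_fraction,
                 artifact_amplitude = artifact_amplitude),
            class = "sim_config")
}

#' The evoked transient waveform
#'
#' Gaussian-windowed 5 Hz cosine peaking at 350 ms (unit peak amplitude),
#' mimicking the latency range of inhibition-related event-related
#' components (~200-350 ms post-stimulus).
#'
#' @param times time axis in ms
#' @param peak_ms peak latency, ms
#' @param width_ms Gaussian sd, ms
#' @param freq carrier frequency, Hz
#' @return numeric vector, unit peak
#' @export
evoked_waveform <- function(times, peak_ms = 350, width_ms = 60, freq = 5) {
  exp(-(times - peak_ms)^2 / (2 * width_ms^2)) *
    cos(2 * pi * freq * (times - peak_ms) / 1000)
}

# cumulative sum along rows of a matrix
row_cumsum <- function(m) {
  if (ncol(m) > 1) t(apply(m, 1, cumsum)) else m
}

#' Generate synthetic epoched EEG with known coupling
#'
#' Each channel's signal is a sum over bands of A_b * cos(phi_bc(t)), where
#' phi_bc integrates a per-epoch instantaneous frequency drawn uniformly
#' inside the band plus a small Wiener phase jitter. Channels named in a
#' [coupling_spec()] mix the common oscillator's phase with weight kappa.
#' The evoked transient is added identically (phase-locked) to every epoch
#' of the configured conditions; white noise is added everywhere.
#'
#' @param config a [sim_config()]
#' @param seed integer seed; the same (config, seed) pair reproduces the
#'   output bit-for-bit
#' @param subject subject identifier stored in the output
#' @param group group label stored in the output
#' @return list with elements `epochs` (an [epochset()]) and `truth`
#'   (ground truth: the coupling design, the injected evoked waveform, and
#'   per-epoch artifact flags)
#' @export
generate_epochs <- function(config, seed = 1, subject = "S1",
                            group = NA_character_) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    dt_ms <- 1000 / config$srate
    times <- seq(config$window[1], config$window[2] - dt_ms, by = dt_ms)
    ns <- length(times)
    nc <- length(config$channels)
    ne <- config$n_epochs_per_condition * length(config$conditions)
    condition <- rep(config$conditions, each = config$n_epochs_per_condition)
    tsec <- (times - times[1]) / 1000
    evoked <- config$evoked_amplitude * evoked_waveform(times)
    vals <- array(0, c(nc, ns, ne))
    for (e in seq_len(ne)) {
      sig <- matrix(0, nc, ns)
      for (b in names(config$bands)) {
        edges <- config$bands[[b]]
        f_ind <- stats::runif(nc, edges[1], edges[2])
        phi0 <- stats::runif(nc, -pi, pi)
        jit <- row_cumsum(matrix(stats::rnorm(nc * ns, 0, config$phase_jitter_sd),
                                 nc, ns))
        phi <- 2 * pi * outer(f_ind, tsec) + phi0 + jit
        # common oscillator for this (condition, band); drawn even when
        # unused so the RNG stream does not depend on the coupling design
        f_com <- stats::runif(1, edges[1], edges[2])
        phi0_com <- stats::runif(1, -pi, pi)
        jit_com <- cumsum(stats::rnorm(ns, 0, config$phase_jitter_sd))
        phi_com <- 2 * pi * f_com * tsec + phi0_com + jit_com
        for (cs in config$coupling) {
          if (cs$band == b && cs$condition == condition[e] && cs$kappa > 0) {
            idx <- match(cs$channels, config$channels)
            phi[idx, ] <- (1 - cs$kappa) * phi[idx, ] +
              cs$kappa * matrix(phi_com, length(idx), ns, byrow = TRUE)
          }
        }
        sig <- sig + config$amplitudes[[b]] * cos(phi)
      }
      if (condition[e] %in% config$evoked_conditions) {
        sig <- sig + matrix(evoked, nc, ns, byrow = TRUE)
      }
      if (config$noise_sd > 0) {
        sig <- sig + matrix(stats::rnorm(nc * ns, 0, config$noise_sd), nc, ns)
      }
      vals[, , e] <- sig
    }
    es <- epochset(vals, config$channels, times, config$srate, condition,
                   subject = subject, group = group)
    flags <- rep(FALSE, ne)
    if (config$artifact_fraction > 0) {
      inj <- inject_artifacts(es, config$artifact_fraction,
                              config$artifact_amplitude,
                              seed = stats::runif(1, 1, 2^30))
      es <- inj$epochs
      flags <- inj$flags
    }
    list(epochs = es,
         truth = list(coupling = config$coupling, evoked = evoked,
                      artifact_flags = flags, times = times))
  })
}

#' Inject high-amplitude artifact transients into epochs
#'
#' Exactly `round(fraction * n_epochs)` randomly chosen epochs receive a
#' short spike of the given amplitude on one random channel, providing
#' fixtures for the amplitude-based rejection criteria.
#'
#' @param epochs an [epochset()]
#' @param fraction proportion of epochs to contaminate
#' @param amplitude spike amplitude in uV (choose above the rejection
#'   threshold to be exercised)
#' @param seed integer seed
#' @return list with `epochs` (modified copy) and `flags` (logical vector,
#'   TRUE for contaminated epochs)
#' @export
inject_artifacts <- function(epochs, fraction, amplitude, seed = 1) {
  stopifnot(inherits(epochs, "epochset"), fraction >= 0, fraction <= 1)
  ne <- n_epochs(epochs)
  n_bad <- round(fraction * ne)
  flags <- rep(FALSE, ne)
  if (n_bad == 0) return(list(epochs = epochs, flags = flags))
  with_seed(seed, {
    bad <- sample.int(ne, n_bad)
    flags[bad] <- TRUE
    ns <- dim(epochs$values)[2]
    nc <- dim(epochs$values)[1]
    spike_len <- max(1, round(epochs$srate * 0.01))  # 10 ms spike
    for (e in bad) {
      ch <- sample.int(nc, 1)
      at <- sample.int(ns - spike_len + 1, 1)
      epochs$values[ch, at:(at + spike_len - 1), e] <-
        epochs$values[ch, at:(at + spike_len - 1), e] + amplitude
    }
    list(epochs = epochs, flags = flags)
  })
}

#' Simulate a multi-subject study
#'
#' Convenience wrapper running [generate_epochs()] once per subject with
#' subject-specific seeds derived from `seed`.
#'
#' @param config a [sim_config()]
#' @param n_younger,n_older subjects per group
#' @param seed master seed
#' @return list of per-subject results as returned by [generate_epochs()]
#' @export
simulate_study <- function(config, n_younger = 4, n_older = 4, seed = 1) {
  n <- n_younger + n_older
  groups <- c(rep("younger", n_younger), rep("older", n_older))
  lapply(seq_len(n), function(i) {
    generate_epochs(config, seed = (as.numeric(seed) * 1000 + i) %% .Machine$integer.max,
                    subject = sprintf("S%02d", i), group = groups[i])
  })
}
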