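# Instantaneous phase via the analytic signal and the phase-synchronization
# index (mean phase coherence), assembled into per-condition association
# matrices.

#' Band-limited instantaneous phase of epochs
#'
#' Band-pass filters each epoch (zero-phase Butterworth, order 4 per pass),
#' computes the analytic signal over the full epoch, then crops to the
#' analysis window so Hilbert edge transients fall outside the retained
#' samples. The phase is the argument of the analytic signal, wrapped to
#' (-pi, pi].
#'
#' @param epochs an [epochset()] covering at least `window`
#' @param band `c(low, high)` in Hz, or a band name from [default_bands()]
#' @param window analysis window in ms (half-open); `NULL` keeps the full
#'   epoch
#' @param order Butterworth prototype order for the band filter
#' @return list of class `phase_series`: `phase` (channels x samples x
#'   epochs, radians), `degenerate` (logical channels x epochs matrix, TRUE
#'   where the band-limited signal is essentially zero and the phase is
#'   undefined), plus the band, times and annotations
#' @export
instantaneous_phase <- function(epochs, band, window = NULL, order = 4) {
  stopifnot(inherits(epochs, "epochset"))
  if (is.character(band)) band <- default_bands()[[band]]
  if (is.null(band)) stop("unknown band")
  f <- butter_sos(order, band[1], band[2], epochs$srate)
  filt <- filter_epochset(epochs, f)
  d <- dim(filt$values)
  x <- aperm(filt$values, c(2, 1, 3))
  dim(x) <- c(d[2], d[1] * d[3])
  z <- analytic_signal(x)
  dim(z) <- c(d[2], d[1], d[3])
  z <- aperm(z, c(2, 1, 3))
  keep <- if (is.null(window)) {
    seq_along(epochs$times)
  } else {
    which(epochs$times >= window[1] & epochs$times < window[2])
  }
  if (!length(keep)) stop("analysis window contains no samples")
  z <- z[, keep, , drop = FALSE]
  amp <- Mod(z)
  degenerate <- apply(amp, c(1, 3), max) < 1e-12
  structure(list(phase = Arg(z), degenerate = degenerate,
                 band = band, times = epochs$times[keep],
                 channels = epochs$channels, condition = epochs$condition,
                 subject = epochs$subject, group = epochs$group),
            class = "phase_series")
}

#' Phase-synchronization index (mean phase coherence) of two phase series
#'
#' `rho = sqrt(mean(cos(dphi))^2 + mean(sin(dphi))^2)` where
#' `dphi = phi1 - phi2`; the resultant length of the phase-difference
#' distribution. 1 for perfect 1:1 phase locking (any constant offset),
#' 0 in expectation for unrelated phases as the sample count grows.
#'
#' @param phi1,phi2 numeric vectors of instantaneous phase (radians),
#'   equal length >= 2
#' @return rho in \[0, 1\]
#' @export
psi <- function(phi1, phi2) {
  if (length(phi1) != length(phi2)) stop("phase series length mismatch")
  if (length(phi1) < 2) stop("need at least 2 samples")
  d <- phi1 - phi2
  sqrt(mean(cos(d))^2 + mean(sin(d))^2)
}

# per-epoch PSI matrix from a channels x samples phase matrix:
# rho_ij = |(1/T) sum_t e^{i phi_i} e^{-i phi_j}|
psi_matrix_one <- function(phase_ct) {
  E <- exp(1i * phase_ct)
  R <- Mod(E %*% Conj(t(E))) / ncol(phase_ct)
  diag(R) <- 0
  R
}

#' Condition-averaged PSI association matrix
#'
#' Computes the PSI between every unordered channel pair within each epoch
#' of the given condition, then averages the per-epoch matrices. Epochs
#' containing a degenerate (all-zero) channel are an error unless dropped
#' by the caller: phase is undefined there and would otherwise silently
#' contribute spurious synchrony.
#'
#' @param phases a `phase_series` from [instantaneous_phase()]
#' @param condition condition label to average over
#' @return symmetric channels x channels matrix in \[0, 1\], diagonal 0,
#'   with attributes `n_epochs`, `band`, `condition`, `subject`
#' @export
psi_matrix <- function(phases, condition) {
  stopifnot(inherits(phases, "phase_series"))
  idx <- which(phases$condition == condition)
  if (!length(idx)) stop("no epochs of condition '", condition, "'")
  if (any(phases$degenerate[, idx])) {
    stop("degenerate (all-zero) band-limited signal: phase undefined for ",
         "some channel/epoch of condition '", condition, "'")
  }
  n <- length(phases$channels)
  acc <- matrix(0, n, n)
  for (e in idx) acc <- acc + psi_matrix_one(phases$phase[, , e])
  m <- acc / length(idx)
  dimnames(m) <- list(phases$channels, phases$channels)
  attr(m, "n_epochs") <- length(idx)
  attr(m, "band") <- phases$band
  attr(m, "condition") <- condition
  attr(m, "subject") <- phases$subject
  m
}

#' Per-condition PSI matrices for one subject and band
#'
#' Convenience wrapper: phase extraction once, then one averaged matrix per
#' condition present.
#'
#' @param epochs an [epochset()]
#' @param band band edges or name
#' @param window analysis window in ms
#' @return named list of PSI matrices
#' @export
psi_by_condition <- function(epochs, band, window = NULL) {
  ph <- instantaneous_phase(epochs, band, window)
  conds <- unique(epochs$condition)
  stats::setNames(lapply(conds, function(cc) psi_matrix(ph, cc)), conds)
}
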