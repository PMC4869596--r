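# Frequency-domain band power: Hamming-tapered per-epoch periodograms
# averaged within condition, and task-related percentage change.

#' Hamming-tapered periodogram of one epoch window
#'
#' Power at the discrete Fourier frequencies (no zero-padding, so the
#' frequency resolution is srate / n_samples; 2 Hz for a 500 ms window).
#' Power is normalized so that the sum over all returned bins equals the
#' tapered-signal energy `sum((w * x)^2)` (a Parseval identity used by the
#' test-suite).
#'
#' @param x numeric vector (one channel, one epoch, analysis window)
#' @param srate sampling rate in Hz
#' @return list with `freq` (Hz, 0..Nyquist) and `power` (uV^2)
#' @keywords internal
periodogram_hamming <- function(x, srate) {
  n <- length(x)
  w <- hamming_window(n)
  X <- stats::fft(x * w)
  p_full <- Mod(X)^2 / n
  nh <- floor(n / 2) + 1
  p <- p_full[1:nh]
  # fold negative frequencies onto positive ones
  if (n %% 2 == 0) {
    if (nh > 2) p[2:(nh - 1)] <- p[2:(nh - 1)] + p_full[n:(nh + 1)]
  } else {
    if (nh > 1) p[2:nh] <- p[2:nh] + p_full[n:(nh + 1)]
  }
  list(freq = (0:(nh - 1)) * srate / n, power = p)
}

#' Band power per subject/condition/channel/band
#'
#' For each epoch and channel, computes the Hamming-tapered periodogram of
#' the analysis window, averages power across epochs of the same condition,
#' then averages over the frequency bins falling in each band (band edges
#' half-open: `low <= f < high`).
#'
#' @param epochs an [epochset()] (already cropped to the analysis window,
#'   or pass `window` to crop here)
#' @param bands named list of band edges in Hz (default [default_bands()])
#' @param window optional ms window passed to [extract_window()] first
#' @return data.table: subject, condition, channel, band, power
#' @export
band_power <- function(epochs, bands = default_bands(), window = NULL) {
  stopifnot(inherits(epochs, "epochset"))
  if (!is.null(window)) epochs <- extract_window(epochs, window)
  d <- dim(epochs$values)
  n <- d[2]
  freq <- (0:(floor(n / 2))) * epochs$srate / n
  bin_sets <- lapply(bands, function(e) which(freq >= e[1] & freq < e[2]))
  empty <- names(bands)[vapply(bin_sets, length, 1L) == 0]
  if (length(empty)) {
    stop("no frequency bins in band(s): ", paste(empty, collapse = ", "),
         " at resolution ", epochs$srate / n, " Hz")
  }
  out <- list()
  for (cond in unique(epochs$condition)) {
    idx <- which(epochs$condition == cond)
    # mean periodogram across epochs, per channel
    pmean <- matrix(0, d[1], length(freq))
    for (e in idx) {
      for (ch in seq_len(d[1])) {
        pmean[ch, ] <- pmean[ch, ] +
          periodogram_hamming(epochs$values[ch, , e], epochs$srate)$power
      }
    }
    pmean <- pmean / length(idx)
    for (b in names(bands)) {
      out[[length(out) + 1]] <- data.table::data.table(
        subject = epochs$subject, condition = cond,
        channel = epochs$channels, band = b,
        power = rowMeans(pmean[, bin_sets[[b]], drop = FALSE])
      )
    }
  }
  data.table::rbindlist(out)
}

#' Task-related percentage change of band power
#'
#' `100 * (task - reference) / reference` per (channel, band) cell, e.g.
#' Go or NoGo power relative to the pre-stimulus Baseline.
#'
#' @param power a [band_power()] table containing both conditions
#' @param task,reference condition labels
#' @return data.table: subject, channel, band, task, reference, pct_change
#' @export
percent_change <- function(power, task, reference) {
  ia <- which(power[["condition"]] == task)
  ib <- which(power[["condition"]] == reference)
  a <- power[ia, ]
  b <- power[ib, ]
  if (!nrow(a) || !nrow(b)) stop("condition not present in power table")
  m <- merge(a, b, by = c("subject", "channel", "band"),
             suffixes = c("_task", "_ref"))
  if (any(m$power_ref == 0)) stop("zero reference power")
  data.table::data.table(
    subject = m$subject, channel = m$channel, band = m$band,
    task = task, reference = reference,
    pct_change = 100 * (m$power_task - m$power_ref) / m$power_ref
  )
}
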