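# Preprocessing: zero-phase band-pass filtering, mastoid re-referencing,
# amplitude-based artifact rejection, per-condition ERP computation and
# subtraction (induced-activity isolation), analysis-window extraction.

# filter every channel x epoch series of an epochset with filtfilt;
# b may be an sos_filter
filter_epochset <- function(epochs, b, a = NULL) {
  d <- dim(epochs$values)
  x <- aperm(epochs$values, c(2, 1, 3))      # samples x channels x epochs
  dim(x) <- c(d[2], d[1] * d[3])
  y <- filtfilt(b, a, x)
  dim(y) <- c(d[2], d[1], d[3])
  epochs$values <- aperm(y, c(2, 1, 3))
  dimnames(epochs$values) <- list(epochs$channels, NULL, NULL)
  epochs
}

#' Zero-phase Butterworth band-pass filtering of epochs
#'
#' Applies a forward-backward (zero net phase shift) Butterworth band-pass
#' filter to every channel of every epoch. The default order-2 design gives
#' a 12 dB/oct roll-off per band edge per pass. An optional zero-phase
#' 50 Hz notch (no-op for band-limited synthetic data) can follow.
#'
#' @param epochs an [epochset()]
#' @param low,high passband edges in Hz
#' @param order Butterworth prototype order per pass (default 2)
#' @param notch optional notch center frequency in Hz (e.g. 50); `NULL`
#'   to skip
#' @param notch_bw notch -3 dB bandwidth in Hz (default 4, i.e. 50 +/- 2)
#' @return filtered [epochset()]
#' @export
bandpass_filter <- function(epochs, low = 0.1, high = 40, order = 2,
                            notch = NULL, notch_bw = 4) {
  stopifnot(inherits(epochs, "epochset"))
  if (high >= epochs$srate / 2) stop("passband exceeds Nyquist frequency")
  f <- butter_sos(order, low, high, epochs$srate)
  out <- filter_epochset(epochs, f)
  if (!is.null(notch)) {
    nf <- notch_biquad(notch, notch_bw, epochs$srate)
    out <- filter_epochset(out, nf$b, nf$a)
  }
  out
}

#' Re-reference epochs to the average of reference channels
#'
#' Subtracts the mean of the reference channels (e.g. bilateral mastoids
#' TP9/TP10) from every retained channel, then drops the reference
#' channels. EOG channels listed in `keep` are passed through unreferenced.
#'
#' @param epochs an [epochset()]
#' @param reference labels of the reference channels (must be present)
#' @param keep labels passed through without re-referencing (e.g. EOG)
#' @return re-referenced [epochset()] without the reference channels
#' @export
rereference <- function(epochs, reference, keep = character()) {
  stopifnot(inherits(epochs, "epochset"))
  miss <- setdiff(reference, epochs$channels)
  if (length(miss)) stop("missing reference channel(s): ",
                         paste(miss, collapse = ", "))
  ridx <- match(reference, epochs$channels)
  refmean <- colMeans(epochs$values[ridx, , , drop = FALSE])  # samples x epochs
  out_ch <- setdiff(epochs$channels, reference)
  eeg_ch <- setdiff(out_ch, keep)
  vals <- epochs$values[match(out_ch, epochs$channels), , , drop = FALSE]
  eidx <- match(eeg_ch, out_ch)
  for (i in eidx) vals[i, , ] <- vals[i, , ] - refmean
  epochset(vals, out_ch, epochs$times, epochs$srate, epochs$condition,
           epochs$subject, epochs$group)
}

#' Artifact-rejection criteria
#'
#' Thresholded amplitude criteria evaluated per epoch. EEG channels: (1)
#' peak-to-peak amplitude within a moving window (width 200 ms, step 50 ms)
#' exceeding 150 uV; (2) absolute voltage at any sample exceeding 100 uV.
#' EOG channels: (3) HEOG moving-window peak-to-peak (width 400 ms, step
#' 10 ms) exceeding 40 uV; (4) VEOG peak-to-peak within a fixed window
#' around the target (-200..200 ms) exceeding 50 uV. Moving windows advance
#' by the stated step and include a final partial window.
#'
#' @param eeg_ptp_uv,eeg_ptp_width_ms,eeg_ptp_step_ms EEG moving-window
#'   peak-to-peak criterion
#' @param eeg_abs_uv EEG absolute-voltage criterion
#' @param heog_ptp_uv,heog_ptp_width_ms,heog_ptp_step_ms HEOG criterion
#' @param veog_window_ms,veog_ptp_uv VEOG fixed-window criterion
#' @return object of class `artifact_criteria`
#' @export
artifact_criteria <- function(eeg_ptp_uv = 150, eeg_ptp_width_ms = 200,
                              eeg_ptp_step_ms = 50,
                              eeg_abs_uv = 100,
                              heog_ptp_uv = 40, heog_ptp_width_ms = 400,
                              heog_ptp_step_ms = 10,
                              veog_window_ms = c(-200, 200),
                              veog_ptp_uv = 50) {
  stopifnot(eeg_ptp_uv > 0, eeg_abs_uv > 0, heog_ptp_uv > 0, veog_ptp_uv > 0)
  structure(list(eeg_ptp_uv = eeg_ptp_uv,
                 eeg_ptp_width_ms = eeg_ptp_width_ms,
                 eeg_ptp_step_ms = eeg_ptp_step_ms,
                 eeg_abs_uv = eeg_abs_uv,
                 heog_ptp_uv = heog_ptp_uv,
                 heog_ptp_width_ms = heog_ptp_width_ms,
                 heog_ptp_step_ms = heog_ptp_step_ms,
                 veog_window_ms = veog_window_ms,
                 veog_ptp_uv = veog_ptp_uv),
            class = "artifact_criteria")
}

# max peak-to-peak over moving windows (final partial window included)
moving_ptp <- function(x, width, step) {
  n <- length(x)
  starts <- seq(1, n, by = step)
  starts <- starts[starts <= n]
  m <- 0
  for (s in starts) {
    w <- x[s:min(s + width - 1, n)]
    m <- max(m, max(w) - min(w))
    if (s + width - 1 >= n) break
  }
  m
}

#' Reject epochs exceeding amplitude criteria
#'
#' An epoch is removed iff any criterion fires on any applicable channel.
#' EEG criteria are evaluated on all channels except `eog`; EOG criteria
#' only on the named channels when present.
#'
#' @param epochs an [epochset()]
#' @param criteria an [artifact_criteria()]
#' @param eog character vector naming the HEOG/VEOG channels, in that
#'   order of roles; channels absent from the data are skipped
#' @return list with `epochs` (survivors), `report` (data.table: epoch,
#'   criterion, channel, value for each firing), and `kept` (logical)
#' @export
reject_artifacts <- function(epochs, criteria = artifact_criteria(),
                             eog = c("HEOG", "VEOG")) {
  stopifnot(inherits(epochs, "epochset"), inherits(criteria, "artifact_criteria"))
  d <- dim(epochs$values)
  spms <- epochs$srate / 1000               # samples per ms
  eeg_ch <- setdiff(epochs$channels, eog)
  heog <- if (length(eog) >= 1 && eog[1] %in% epochs$channels) eog[1] else NULL
  veog <- if (length(eog) >= 2 && eog[2] %in% epochs$channels) eog[2] else NULL
  w_eeg <- max(1L, round(criteria$eeg_ptp_width_ms * spms))
  s_eeg <- max(1L, round(criteria$eeg_ptp_step_ms * spms))
  rows <- list()
  kept <- rep(TRUE, d[3])
  vwin <- which(epochs$times >= criteria$veog_window_ms[1] &
                  epochs$times < criteria$veog_window_ms[2])
  for (e in seq_len(d[3])) {
    for (ch in eeg_ch) {
      x <- epochs$values[match(ch, epochs$channels), , e]
      v <- moving_ptp(x, w_eeg, s_eeg)
      if (v > criteria$eeg_ptp_uv) {
        rows[[length(rows) + 1]] <- list(e, "eeg_ptp", ch, v); kept[e] <- FALSE
      }
      v <- max(abs(x))
      if (v > criteria$eeg_abs_uv) {
        rows[[length(rows) + 1]] <- list(e, "eeg_abs", ch, v); kept[e] <- FALSE
      }
    }
    if (!is.null(heog)) {
      x <- epochs$values[match(heog, epochs$channels), , e]
      w <- max(1L, round(criteria$heog_ptp_width_ms * spms))
      s <- max(1L, round(criteria$heog_ptp_step_ms * spms))
      v <- moving_ptp(x, w, s)
      if (v > criteria$heog_ptp_uv) {
        rows[[length(rows) + 1]] <- list(e, "heog_ptp", heog, v); kept[e] <- FALSE
      }
    }
    if (!is.null(veog) && length(vwin)) {
      x <- epochs$values[match(veog, epochs$channels), vwin, e]
      v <- max(x) - min(x)
      if (v > criteria$veog_ptp_uv) {
        rows[[length(rows) + 1]] <- list(e, "veog_ptp", veog, v); kept[e] <- FALSE
      }
    }
  }
  report <- if (length(rows)) {
    data.table::rbindlist(lapply(rows, function(r) {
      data.table::data.table(epoch = r[[1]], criterion = r[[2]],
                             channel = r[[3]], value = r[[4]])
    }))
  } else {
    data.table::data.table(epoch = integer(), criterion = character(),
                           channel = character(), value = numeric())
  }
  list(epochs = subset_epochs(epochs, which(kept)), report = report,
       kept = kept)
}

#' Per-condition event-related potential (ERP)
#'
#' Arithmetic mean across all epochs of one condition, per channel and
#' sample — the evoked (time- and phase-locked) component of the signal.
#'
#' @param epochs an [epochset()]
#' @param condition the condition to average
#' @return object of class `erp_waveform` with fields `values`
#'   (channels x samples), `condition`, `n_epochs`, `channels`, `times`
#' @export
compute_erp <- function(epochs, condition) {
  idx <- which(epochs$condition == condition)
  if (!length(idx)) stop("no epochs of condition '", condition, "'")
  m <- apply(epochs$values[, , idx, drop = FALSE], c(1, 2), mean)
  structure(list(values = m, condition = condition, n_epochs = length(idx),
                 channels = epochs$channels, times = epochs$times),
            class = "erp_waveform")
}

#' Subtract a condition's ERP from that condition's epochs
#'
#' Removes the evoked component: after subtraction the per-condition mean
#' trace is exactly zero at every channel and sample, leaving the induced
#' (non-phase-locked) activity.
#'
#' @param epochs an [epochset()]
#' @param erp an `erp_waveform` from [compute_erp()] (same channels/samples)
#' @return an [epochset()] with the ERP removed from matching epochs
#' @export
subtract_erp <- function(epochs, erp) {
  stopifnot(inherits(erp, "erp_waveform"))
  if (!identical(erp$channels, epochs$channels) ||
      !identical(dim(erp$values), dim(epochs$values)[1:2])) {
    stop("ERP shape does not match epochs")
  }
  idx <- which(epochs$condition == erp$condition)
  for (e in idx) epochs$values[, , e] <- epochs$values[, , e] - erp$values
  epochs
}

#' Remove evoked activity from every condition
#'
#' Convenience wrapper: computes each condition's own ERP and subtracts it
#' from that condition's epochs (per subject, never a grand average).
#'
#' @param epochs an [epochset()]
#' @return list with `epochs` (induced activity) and `erps` (named list of
#'   the subtracted `erp_waveform`s)
#' @export
remove_evoked <- function(epochs) {
  erps <- list()
  for (cond in unique(epochs$condition)) {
    erp <- compute_erp(epochs, cond)
    epochs <- subtract_erp(epochs, erp)
    erps[[cond]] <- erp
  }
  list(epochs = epochs, erps = erps)
}

#' Extract a time window from epochs
#'
#' Retains samples with `window[1] <= t < window[2]` (half-open, ms); at
#' 1000 Hz the 200..700 ms analysis window yields exactly 500 samples.
#'
#' @param epochs an [epochset()]
#' @param window `c(start, end)` in ms relative to the event
#' @return an [epochset()] restricted to the window
#' @export
extract_window <- function(epochs, window) {
  idx <- which(epochs$times >= window[1] & epochs$times < window[2])
  if (!length(idx)) stop("window contains no samples")
  if (window[1] < min(epochs$times) ||
      window[2] > max(epochs$times) + 1000 / epochs$srate) {
    stop("window outside the epoch")
  }
  epochset(epochs$values[, idx, , drop = FALSE], epochs$channels,
           epochs$times[idx], epochs$srate, epochs$condition,
           epochs$subject, epochs$group)
}
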