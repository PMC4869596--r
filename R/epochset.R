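# EpochSet: the labeled epochs x channels x samples container, plus the
# delimited-text interchange format.

#' Construct an EpochSet
#'
#' The canonical container for epoched multichannel EEG: a 3-way numeric
#' array (channels x samples x epochs, microvolts), a uniform time axis in
#' milliseconds relative to the event, per-epoch condition labels, and
#' subject / group annotations.
#'
#' @param values numeric array, dim = c(n_channels, n_samples, n_epochs)
#' @param channels character vector of channel labels (length = dim 1)
#' @param times numeric vector of sample times in ms (length = dim 2),
#'   strictly increasing and uniformly spaced
#' @param srate sampling rate in Hz; must match the time-axis spacing
#' @param condition character vector of per-epoch condition labels
#' @param subject scalar subject identifier
#' @param group scalar group label (e.g. "younger"/"older")
#' @return object of class `epochset`
#' @export
epochset <- function(values, channels, times, srate,
                     condition, subject = "S1", group = NA_character_) {
  values <- unname(values)
  if (length(dim(values)) != 3) stop("values must be a 3-way array")
  d <- dim(values)
  if (length(channels) != d[1]) stop("channel labels do not match dim 1")
  if (anyDuplicated(channels)) stop("duplicate channel labels")
  if (length(times) != d[2]) stop("time axis does not match dim 2")
  dt <- diff(times)
  if (any(dt <= 0)) stop("time axis must be strictly increasing")
  if (diff(range(dt)) > 1e-6) stop("time axis must be uniform")
  if (abs(mean(dt) - 1000 / srate) > 1e-6) {
    stop("time-axis spacing inconsistent with sampling rate")
  }
  condition <- as.character(condition)
  if (length(condition) != d[3]) stop("condition labels do not match dim 3")
  dimnames(values) <- list(channels, NULL, NULL)
  structure(list(values = values, channels = as.character(channels),
                 times = as.numeric(times), srate = srate,
                 condition = condition, subject = subject, group = group),
            class = "epochset")
}

#' @export
print.epochset <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("epochset: %d epochs x %d channels x %d samples @ %g Hz\n",
              d[3], d[1], d[2], x$srate))
  cat(sprintf("  time %g..%g ms; subject %s; conditions: %s\n",
              min(x$times), max(x$times), x$subject,
              paste(sprintf("%s(%d)", names(table(x$condition)),
                            table(x$condition)), collapse = " ")))
  invisible(x)
}

n_epochs <- function(x) dim(x$values)[3]

# subset epochs by index, keeping annotations in step
subset_epochs <- function(x, idx) {
  epochset(x$values[, , idx, drop = FALSE], x$channels, x$times, x$srate,
           x$condition[idx], x$subject, x$group)
}

#' Select a subset of channels from an EpochSet
#' @param x an [epochset()]
#' @param channels labels to keep, in the order given
#' @return an [epochset()] with only those channels
#' @export
select_channels <- function(x, channels) {
  missing <- setdiff(channels, x$channels)
  if (length(missing)) {
    stop("channels not present: ", paste(missing, collapse = ", "))
  }
  idx <- match(channels, x$channels)
  epochset(x$values[idx, , , drop = FALSE], channels, x$times, x$srate,
           x$condition, x$subject, x$group)
}

#' Write an EpochSet to a delimited long-format table
#'
#' One row per (epoch, channel, sample): columns subject, group, condition,
#' epoch, channel, time_ms, value_uV. This plain-text format is the
#' language-neutral interchange/fixture format; [read_epochs_csv()] is its
#' exact inverse up to numeric printing precision.
#'
#' @param x an [epochset()]
#' @param path output file path (.csv)
#' @return `path`, invisibly
#' @export
write_epochs_csv <- function(x, path) {
  d <- dim(x$values)
  dt <- data.table::data.table(
    subject = x$subject,
    group = x$group,
    condition = rep(x$condition, each = d[1] * d[2]),
    epoch = rep(seq_len(d[3]), each = d[1] * d[2]),
    channel = rep(x$channels, times = d[2] * d[3]),
    time_ms = rep(rep(x$times, each = d[1]), times = d[3]),
    value_uV = as.vector(x$values)
  )
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read an EpochSet from the delimited long-format table
#'
#' @param path file written by [write_epochs_csv()] (or produced externally
#'   with the same columns)
#' @param montage optional [montage()]; if given, the file must contain all
#'   its recording channels (missing channels are an error) and channels are
#'   returned in montage order
#' @return an [epochset()]
#' @export
read_epochs_csv <- function(path, montage = NULL) {
  dt <- data.table::fread(path)
  need <- c("subject", "condition", "epoch", "channel", "time_ms", "value_uV")
  if (!all(need %in% names(dt))) {
    stop("missing columns: ", paste(setdiff(need, names(dt)), collapse = ", "))
  }
  channels <- unique(dt$channel)
  if (!is.null(montage)) {
    want <- c(montage$recording, intersect(montage$eog, channels))
    miss <- setdiff(montage$recording, channels)
    if (length(miss)) {
      stop("file is missing montage channels: ", paste(miss, collapse = ", "))
    }
    channels <- want
    dt <- dt[dt$channel %in% channels, ]
  }
  times <- sort(unique(dt$time_ms))
  epochs <- sort(unique(dt$epoch))
  srates <- 1000 / diff(times)
  if (diff(range(srates)) > 1e-6) stop("inconsistent sampling rate in file")
  srate <- srates[1]
  data.table::setorderv(dt, c("epoch", "time_ms"))
  dt[, `:=`(ci = match(channel, channels), ei = match(epoch, epochs),
            ti = match(time_ms, times))]
  vals <- array(NA_real_, c(length(channels), length(times), length(epochs)))
  vals[cbind(dt$ci, dt$ti, dt$ei)] <- dt$value_uV
  if (anyNA(vals)) stop("incomplete epoch grid in file")
  cond <- dt[, condition[1], by = "ei"][["V1"]]
  if (anyNA(cond)) stop("unlabeled epochs in file")
  epochset(vals, channels, times, srate, cond,
           subject = dt$subject[1],
           group = if ("group" %in% names(dt)) as.character(dt$group[1]) else NA_character_)
}

#' Write a square labeled matrix (e.g. a PSI matrix) to CSV
#' @param m square numeric matrix with dimnames
#' @param path output path
#' @return `path`, invisibly
#' @export
write_matrix_csv <- function(m, path) {
  dt <- data.table::as.data.table(m, keep.rownames = "channel")
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a square labeled matrix written by [write_matrix_csv()]
#' @param path input path
#' @return numeric matrix with dimnames
#' @export
read_matrix_csv <- function(path) {
  dt <- data.table::fread(path)
  labs <- dt$channel
  m <- as.matrix(dt[, -1])
  rownames(m) <- labs
  m
}
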