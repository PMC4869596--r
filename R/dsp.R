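# Digital signal processing primitives: IIR Butterworth design, zero-phase
# filtering, analytic signal. Self-contained (no external DSP dependency).

#' Polynomial coefficients from roots, in z^-1 convention
#'
#' Returns the coefficients of prod_k (1 - r_k z^-1), leading coefficient 1.
#' @param r complex vector of roots
#' @return numeric/complex coefficient vector, length `length(r) + 1`
#' @keywords internal
#' @noRd
poly_zm1 <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p) * ri
  p
}

#' Butterworth band-pass filter design
#'
#' Designs a digital Butterworth band-pass filter via the analog low-pass
#' prototype, low-pass-to-band-pass transformation and bilinear transform
#' with frequency pre-warping. An order-`n` design yields a digital filter
#' of order `2n` (roll-off 6n dB/oct per band edge).
#'
#' @param order prototype order (n poles in the analog low-pass)
#' @param low,high band edges in Hz, `0 < low < high < fs/2`
#' @param fs sampling rate in Hz
#' @return list with numerator `b` and denominator `a` (a\[1\] = 1)
#' @examples
#' f <- butter_bandpass(2, 8, 13, 1000)
#' abs(freq_response(f$b, f$a, 10.2, 1000))  # ~1 at band center
#' @export
butter_bandpass <- function(order, low, high, fs) {
  stopifnot(order >= 1, low > 0, low < high, high < fs / 2)
  n <- as.integer(order)
  # analog low-pass prototype poles on the unit circle, left half-plane
  k <- seq_len(n)
  p_proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  fs2 <- 2 * fs
  # pre-warped analog band edges
  w1 <- fs2 * tan(pi * low / fs)
  w2 <- fs2 * tan(pi * high / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  # low-pass -> band-pass: each pole splits into two
  phalf <- p_proto * bw / 2
  p_bp <- c(phalf + sqrt(phalf^2 - w0^2), phalf - sqrt(phalf^2 - w0^2))
  gain <- bw^n                      # n analog zeros at s = 0
  # bilinear transform
  p_d <- (fs2 + p_bp) / (fs2 - p_bp)
  z_d <- c(rep(1 + 0i, n), rep(-1 + 0i, n))  # s = 0 -> z = 1; s = Inf -> z = -1
  gain_d <- Re(gain * fs2^n / prod(fs2 - p_bp))
  b <- Re(poly_zm1(z_d)) * gain_d
  a <- Re(poly_zm1(p_d))
  list(b = b, a = a)
}

#' Butterworth band-pass design as second-order sections
#'
#' Same design as [butter_bandpass()] but factored into biquad sections
#' (one conjugate pole pair each, with one zero at z = 1 and one at
#' z = -1). Narrow bands relative to the sampling rate make the expanded
#' polynomial form numerically singular; the cascade form stays
#' well-conditioned and is what [filtfilt()] uses for band filters.
#'
#' @inheritParams butter_bandpass
#' @return list of class `sos_filter` with `sos` (n_sections x 6 matrix,
#'   columns b0 b1 b2 a0 a1 a2)
#' @export
butter_sos <- function(order, low, high, fs) {
  stopifnot(order >= 1, low > 0, low < high, high < fs / 2)
  n <- as.integer(order)
  k <- seq_len(n)
  p_proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low / fs)
  w2 <- fs2 * tan(pi * high / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  phalf <- p_proto * bw / 2
  p_bp <- c(phalf + sqrt(phalf^2 - w0^2), phalf - sqrt(phalf^2 - w0^2))
  gain_d <- Re(bw^n * fs2^n / prod(fs2 - p_bp))
  p_d <- (fs2 + p_bp) / (fs2 - p_bp)
  # group digital poles into conjugate (or real) pairs
  tol <- 1e-10
  cplx <- p_d[Im(p_d) > tol]
  real_p <- sort(Re(p_d[abs(Im(p_d)) <= tol]))
  pairs <- lapply(cplx, function(p) c(p, Conj(p)))
  if (length(real_p)) {
    if (length(real_p) %% 2 != 0) stop("internal error: unpaired real pole")
    for (i in seq(1, length(real_p), by = 2)) {
      pairs[[length(pairs) + 1]] <- real_p[c(i, i + 1)] + 0i
    }
  }
  sos <- t(vapply(seq_along(pairs), function(i) {
    pp <- pairs[[i]]
    a <- Re(poly_zm1(pp))                   # 1, a1, a2
    g <- if (i == 1) gain_d else 1
    c(g * c(1, 0, -1), a)                   # zeros at +1 and -1
  }, numeric(6)))
  structure(list(sos = sos), class = "sos_filter")
}

#' Second-order IIR notch filter
#'
#' Standard biquad notch at `f0` Hz with -3 dB bandwidth `bw` Hz.
#' @param f0 notch center frequency in Hz
#' @param bw -3 dB bandwidth in Hz
#' @param fs sampling rate in Hz
#' @return list with `b`, `a`
#' @export
notch_biquad <- function(f0, bw, fs) {
  stopifnot(f0 > 0, f0 < fs / 2, bw > 0)
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) * sinh(log(2) / 2 * (bw / f0) * w0 / sin(w0))
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Complex frequency response of a rational digital filter
#'
#' @param b numerator coefficients (z^-1 convention), or an `sos_filter`
#'   from [butter_sos()] (then `a` is ignored)
#' @param a denominator coefficients
#' @param f frequencies in Hz at which to evaluate
#' @param fs sampling rate in Hz
#' @return complex vector H(e^{i 2 pi f / fs})
#' @export
freq_response <- function(b, a = NULL, f, fs) {
  if (inherits(b, "sos_filter")) {
    H <- rep(1 + 0i, length(f))
    for (s in seq_len(nrow(b$sos))) {
      H <- H * freq_response(b$sos[s, 1:3], b$sos[s, 4:6], f, fs)
    }
    return(H)
  }
  vapply(f, function(fi) {
    zm <- exp(-1i * 2 * pi * fi / fs)
    sum(b * zm^(seq_along(b) - 1)) / sum(a * zm^(seq_along(a) - 1))
  }, complex(1))
}

# steady-state filter state for unit constant input (direct form II transposed),
# used to suppress the start-up transient in filtfilt
lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  a <- c(a, rep(0, nf - length(a)))
  b <- c(b, rep(0, nf - length(b)))
  b <- b / a[1]; a <- a / a[1]
  n <- nf - 1
  if (n == 0) return(numeric(0))
  A <- matrix(0, n, n)
  A[, 1] <- -a[-1]
  if (n > 1) A[seq_len(n - 1), 2:n] <- diag(n - 1)
  B <- b[-1] - b[1] * a[-1]
  solve(diag(n) - A, B)
}

# direct form II transposed filtering of each column of x; zi is the initial
# state per unit of initial input (already scaled by caller)
iir_filter <- function(b, a, x, zi = NULL) {
  x <- as.matrix(x)
  nf <- max(length(a), length(b))
  a <- c(a, rep(0, nf - length(a)))
  b <- c(b, rep(0, nf - length(b)))
  b <- b / a[1]; a <- a / a[1]
  n <- nf - 1
  nt <- nrow(x); nc <- ncol(x)
  y <- matrix(0, nt, nc)
  z <- if (is.null(zi)) matrix(0, max(n, 1), nc) else zi
  if (n == 0) return(b[1] * x)
  for (t in seq_len(nt)) {
    xt <- x[t, ]
    yt <- b[1] * xt + z[1, ]
    if (n > 1) {
      for (k in seq_len(n - 1)) {
        z[k, ] <- b[k + 1] * xt - a[k + 1] * yt + z[k + 1, ]
      }
    }
    z[n, ] <- b[n + 1] * xt - a[n + 1] * yt
    y[t, ] <- yt
  }
  y
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter forward and backward over each column of `x`, using
#' odd (anti-symmetric) end extension and steady-state initial conditions to
#' suppress edge transients. The magnitude response is squared and the net
#' phase shift is zero. `b` may be an `sos_filter` from [butter_sos()], in
#' which case the biquad cascade is applied section by section (the
#' numerically stable route for narrow bands).
#'
#' @param b numerator coefficients or an `sos_filter`
#' @param a denominator coefficients (ignored for `sos_filter`)
#' @param x numeric vector or matrix (time in rows, one series per column)
#' @return filtered object of the same shape as `x`
#' @export
filtfilt <- function(b, a = NULL, x) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  nt <- nrow(x)
  if (inherits(b, "sos_filter")) {
    sos <- b$sos
    ntaps <- 2L * nrow(sos) + 1L
    zis <- lapply(seq_len(nrow(sos)), function(s) {
      lfilter_zi(sos[s, 1:3], sos[s, 4:6])
    })
    run <- function(m) {
      for (s in seq_len(nrow(sos))) {
        z0 <- outer(zis[[s]], m[1, ])
        m <- iir_filter(sos[s, 1:3], sos[s, 4:6], m, zi = z0)
      }
      m
    }
  } else {
    ntaps <- max(length(a), length(b))
    zi <- lfilter_zi(b, a)
    run <- function(m) {
      z0 <- outer(zi, m[1, ])
      iir_filter(b, a, m, zi = z0)
    }
  }
  padlen <- min(3L * (ntaps - 1L), nt - 1L)
  if (padlen > 0) {
    # odd extension: 2*x[1] - x[(padlen+1):2], 2*x[nt] - x[(nt-1):(nt-padlen)]
    pre <- 2 * matrix(x[1, ], padlen, ncol(x), byrow = TRUE) -
      x[(padlen + 1):2, , drop = FALSE]
    post <- 2 * matrix(x[nt, ], padlen, ncol(x), byrow = TRUE) -
      x[(nt - 1):(nt - padlen), , drop = FALSE]
    ext <- rbind(pre, x, post)
  } else {
    ext <- x
  }
  y <- run(ext)
  y <- run(y[nrow(y):1, , drop = FALSE])
  y <- y[nrow(y):1, , drop = FALSE]
  if (padlen > 0) y <- y[(padlen + 1):(padlen + nt), , drop = FALSE]
  if (vec) drop(y) else y
}

#' Analytic signal via the FFT
#'
#' Computes the analytic signal x + i H\[x\] of each column, where H is the
#' Hilbert transform, by zeroing negative frequencies and doubling positive
#' ones.
#'
#' @param x numeric vector or matrix (time in rows)
#' @return complex object of the same shape
#' @export
analytic_signal <- function(x) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  n <- nrow(x)
  X <- stats::mvfft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::mvfft(X * h, inverse = TRUE) / n
  if (vec) drop(z) else z
}

#' Hamming window
#' @param n window length in samples
#' @return numeric vector of length `n`
#' @export
hamming_window <- function(n) {
  if (n == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}
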