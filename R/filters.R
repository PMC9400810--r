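#' Digital IIR filtering primitives
#'
#' Minimal Butterworth design (bilinear transform) plus zero-phase
#' forward-backward filtering. These exist because the analysis contract
#' requires specific, reproducible filters (band-pass, notch, low-pass) and no
#' DSP package is assumed at run time.
#'
#' @name filters
#' @keywords internal
NULL

# polynomial with given roots, leading coefficient 1 (complex-safe)
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

.butter_proto_poles <- function(n) {
  k <- seq_len(n)
  exp(1i * pi * (2 * k + n - 1) / (2 * n))
}

#' Butterworth filter coefficients
#'
#' Designs a digital Butterworth filter via analog prototype + bilinear
#' transform with frequency pre-warping. For `type = "pass"` the stated
#' `order` is the order of the final filter (must be even); the low-pass
#' prototype has order `order/2`.
#'
#' @param order filter order (final order; even for band-pass)
#' @param cutoff cutoff frequency in Hz (length 2 for band-pass)
#' @param fs sampling rate in Hz
#' @param type one of "low", "high", "pass"
#' @return list with numerator `b` and denominator `a`
#' @export
butter_filter <- function(order, cutoff, fs, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  stopifnot(order >= 1, fs > 0, all(cutoff > 0), all(cutoff < fs / 2))
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  if (type == "pass") {
    if (length(cutoff) != 2L || order %% 2L != 0L)
      stop("band-pass needs two cutoffs and an even order")
    n <- order %/% 2L
    p0 <- .butter_proto_poles(n)
    w1 <- warp(min(cutoff)); w2 <- warp(max(cutoff))
    bw <- w2 - w1; w0 <- sqrt(w1 * w2)
    q <- p0 * bw / 2
    p <- c(q + sqrt(q^2 - w0^2), q - sqrt(q^2 - w0^2))
    z <- rep(0 + 0i, n)
    k <- bw^n
  } else {
    if (length(cutoff) != 1L) stop("low/high-pass take a single cutoff")
    p0 <- .butter_proto_poles(order)
    wc <- warp(cutoff)
    if (type == "low") {
      p <- p0 * wc; z <- complex(0); k <- wc^order
    } else {
      p <- wc / p0; z <- rep(0 + 0i, order); k <- 1
    }
  }
  fs2 <- 2 * fs
  kd <- k * Re(prod(fs2 - z) / prod(fs2 - p))
  zd <- c((fs2 + z) / (fs2 - z), rep(-1 + 0i, length(p) - length(z)))
  pd <- (fs2 + p) / (fs2 - p)
  b <- Re(kd * poly_from_roots(zd))
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

#' Second-order IIR notch filter (constant-Q biquad)
#'
#' @param f0 notch centre frequency in Hz
#' @param fs sampling rate in Hz
#' @param Q quality factor (centre frequency / -3 dB bandwidth)
#' @return list with `b` and `a`
#' @export
notch_filter <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Apply an IIR filter (direct form, single pass)
#'
#' Uses `stats::filter` for C-speed convolution + recursion; zero initial
#' conditions. `x` may be a matrix, in which case each column is filtered.
#'
#' @param b,a filter coefficients
#' @param x numeric signal (vector, or matrix with one series per column)
#' @return filtered signal, same shape as `x`
#' @export
iir_filter <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b)
  mat <- is.matrix(x)
  n <- if (mat) nrow(x) else length(x)
  if (nb > 1) {
    pad <- if (mat) matrix(0, nb - 1, ncol(x)) else rep(0, nb - 1)
    xp <- if (mat) rbind(pad, x) else c(pad, x)
    v <- stats::filter(xp, b, method = "convolution", sides = 1)
    v <- if (mat) unclass(v)[(nb - 1) + seq_len(n), , drop = FALSE]
         else as.numeric(v)[(nb - 1) + seq_len(n)]
  } else {
    v <- b * x
  }
  if (length(a) > 1) {
    v <- stats::filter(v, -a[-1], method = "recursive")
    v <- if (mat) unclass(v) else as.numeric(v)
  }
  v
}

#' Zero-phase forward-backward filtering
#'
#' Odd-reflection padding at both ends suppresses start-up transients; the
#' default pad length is generous relative to the filter's impulse response so
#' zero initial conditions are adequate for the slow (0.5 Hz) high-pass edge.
#'
#' @param b,a filter coefficients
#' @param x numeric signal
#' @param padlen pad length in samples (default `min(n-1, 3 * fs_equiv)` via
#'   `10 * max(len(a), len(b))`, floor 256, capped at `length(x) - 1`)
#' @return zero-phase filtered signal
#' @export
filtfilt <- function(b, a, x, padlen = NULL) {
  mat <- is.matrix(x)
  n <- if (mat) nrow(x) else length(x)
  if (is.null(padlen)) padlen <- max(256L, 10L * max(length(a), length(b)))
  padlen <- min(padlen, n - 1L)
  if (mat) {
    front <- 2 * rep(x[1, ], each = padlen) - x[seq(padlen + 1, 2), , drop = FALSE]
    back <- 2 * rep(x[n, ], each = padlen) - x[seq(n - 1, n - padlen), , drop = FALSE]
    dim(front) <- c(padlen, ncol(x)); dim(back) <- c(padlen, ncol(x))
    xx <- rbind(front, x, back)
    y <- iir_filter(b, a, xx)
    y <- iir_filter(b, a, y[nrow(y):1, , drop = FALSE])
    y <- y[nrow(y):1, , drop = FALSE]
    y[padlen + seq_len(n), , drop = FALSE]
  } else {
    front <- 2 * x[1] - x[seq(padlen + 1, 2)]
    back <- 2 * x[n] - x[seq(n - 1, n - padlen)]
    xx <- c(front, x, back)
    y <- iir_filter(b, a, xx)
    y <- rev(iir_filter(b, a, rev(y)))
    y[padlen + seq_len(n)]
  }
}

#' Filter frequency response
#'
#' Evaluates H(e^{i 2 pi f / fs}) at the requested frequencies; used as the
#' independent oracle for attenuation/pass-band checks.
#'
#' @param b,a filter coefficients
#' @param f frequencies in Hz
#' @param fs sampling rate in Hz
#' @return complex response at each frequency
#' @export
freq_response <- function(b, a, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  pv <- function(coef) {
    out <- rep(0 + 0i, length(z))
    for (k in seq_along(coef)) out <- out + coef[k] * z^(k - 1)
    out
  }
  pv(b) / pv(a)
}
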