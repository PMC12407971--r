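# IIR filter design (Butterworth / Bessel) via the analog prototype ->
# band transform -> bilinear transform route, plus zero-phase filtering.
# Kept minimal: only what the observable stack needs (3rd-order designs),
# but written for general order. Coefficients match the scipy reference
# implementation (tested against frozen values).

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rk in r) p <- c(p, 0i) - c(0i, p * rk)
  p
}

butter_prototype <- function(n) {
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  list(z = complex(0), p = p, k = 1)
}

# Phase-normalised Bessel/Thomson prototype: poles are the roots of the
# reverse Bessel polynomial theta_n scaled by theta_n(0)^(-1/n), making the
# phase response reach its midpoint at angular frequency 1 (unit DC gain).
bessel_prototype <- function(n) {
  k <- 0:n
  coef <- factorial(2 * n - k) / (2^(n - k) * factorial(k) * factorial(n - k))
  # coef[i] multiplies s^(k = i-1); polyroot wants ascending order
  p <- polyroot(coef)
  scale <- coef[1]^(1 / n)   # theta_n(0)^(1/n)
  p <- p / scale
  list(z = complex(0), p = p, k = Re(prod(-p)))
}

zpk_lp2lp <- function(f, w0) {
  deg <- length(f$p) - length(f$z)
  list(z = f$z * w0, p = f$p * w0, k = f$k * w0^deg)
}

zpk_lp2hp <- function(f, w0) {
  deg <- length(f$p) - length(f$z)
  k <- f$k * Re(prod(-f$z) / prod(-f$p))
  list(z = c(w0 / f$z, rep(0 + 0i, deg)), p = w0 / f$p, k = k)
}

zpk_lp2bp <- function(f, w0, bw) {
  deg <- length(f$p) - length(f$z)
  zl <- f$z * bw / 2
  pl <- f$p * bw / 2
  z <- c(zl + sqrt(zl^2 - w0^2), zl - sqrt(zl^2 - w0^2), rep(0 + 0i, deg))
  p <- c(pl + sqrt(pl^2 - w0^2), pl - sqrt(pl^2 - w0^2))
  list(z = z, p = p, k = f$k * bw^deg)
}

zpk_bilinear <- function(f, fs) {
  fs2 <- 2 * fs
  deg <- length(f$p) - length(f$z)
  zd <- (fs2 + f$z) / (fs2 - f$z)
  pd <- (fs2 + f$p) / (fs2 - f$p)
  kd <- f$k * Re(prod(fs2 - f$z) / prod(fs2 - f$p))
  list(z = c(zd, rep(-1 + 0i, deg)), p = pd, k = kd)
}

zpk_to_ba <- function(f) {
  b <- Re(poly_from_roots(f$z)) * f$k
  a <- Re(poly_from_roots(f$p))
  list(b = b, a = a)
}

#' Design a digital IIR filter (Butterworth or Bessel)
#'
#' Analog prototype, frequency transform and bilinear transform with
#' prewarping, matching the conventional scipy/Matlab contract. The Bessel
#' design uses the phase-normalised prototype.
#'
#' @param n Filter order (of the analog prototype).
#' @param w Critical frequency in Hz (length 1 for low/high-pass, length 2
#'   for band-pass); must be below the Nyquist frequency `fs/2`.
#' @param fs Sampling rate (Hz).
#' @param type `"low"`, `"high"` or `"pass"`.
#' @param family `"butterworth"` or `"bessel"`.
#' @return List with numerator `b` and denominator `a` coefficients.
#' @export
iir_design <- function(n, w, fs, type = c("pass", "low", "high"),
                       family = c("bessel", "butterworth")) {
  type <- match.arg(type)
  family <- match.arg(family)
  if (any(w <= 0) || any(w >= fs / 2))
    stop("critical frequencies must lie strictly between 0 and fs/2")
  proto <- switch(family, bessel = bessel_prototype(n),
                  butterworth = butter_prototype(n))
  warped <- 2 * fs * tan(pi * w / fs)
  f <- switch(type,
    low  = zpk_lp2lp(proto, warped[1]),
    high = zpk_lp2hp(proto, warped[1]),
    pass = {
      if (length(w) != 2) stop("band-pass design needs two critical frequencies")
      zpk_lp2bp(proto, sqrt(warped[1] * warped[2]), warped[2] - warped[1])
    })
  zpk_to_ba(zpk_bilinear(f, fs))
}

#' Steady-state initial conditions for [lfilter()]
#'
#' Solves for the internal state of the direct-form II transposed filter
#' that makes the step response start at its asymptotic value, so that
#' `lfilter(b, a, x, zi * x[1])` has no leading transient for constant
#' input.
#'
#' @param b,a Filter coefficients.
#' @return Numeric state vector of length `max(length(a), length(b)) - 1`.
#' @export
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1]
  a <- c(a, rep(0, n - length(a))) / a[1]
  comp <- matrix(0, n - 1, n - 1)
  comp[1, ] <- -a[-1]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  IminusA <- diag(n - 1) - t(comp)
  B <- b[-1] - a[-1] * b[1]
  solve(IminusA, B)
}

#' Apply an IIR filter (single pass)
#'
#' Direct-form II transposed implementation of the standard linear filter
#' `a[1] y[k] = sum b x - sum a y`, with optional initial state.
#'
#' @param b,a Coefficients.
#' @param x Signal.
#' @param zi Initial state (length `max(length(a), length(b)) - 1`) or NULL.
#' @return Filtered signal, same length as `x`.
#' @export
lfilter <- function(b, a, x, zi = NULL) {
  lfilter_cpp(as.numeric(b), as.numeric(a), as.numeric(x),
              if (is.null(zi)) numeric(0) else as.numeric(zi))
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter forwards and backwards with odd extension of the
#' signal at both ends (`padlen = 3 * max(length(a), length(b))` by
#' default) and steady-state initial conditions, cancelling the filter's
#' phase response.
#'
#' @param b,a Coefficients.
#' @param x Signal (length must exceed `padlen`).
#' @param padlen Number of padded samples at each end.
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt <- function(b, a, x, padlen = 3 * max(length(a), length(b))) {
  n <- length(x)
  if (padlen >= n) stop("signal too short for the requested pad length")
  zi <- lfilter_zi(b, a)
  ext <- c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[n] - x[(n - 1):(n - padlen)])
  y <- lfilter(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- lfilter(b, a, y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1):(padlen + n)]
}

#' Analytic-signal amplitude via the Hilbert transform
#'
#' FFT implementation of the analytic signal; returns its magnitude (the
#' instantaneous amplitude envelope).
#'
#' @param x Real signal.
#' @return Envelope, same length as `x`.
#' @export
hilbert_envelope <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(fft(x) * h, inverse = TRUE) / n)
}
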