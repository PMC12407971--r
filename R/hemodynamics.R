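#' Hemodynamic (generalized Balloon-Windkessel) parameters
#'
#' Time constants and kinetic constants of the neurovascular cascade mapping
#' a neural activity input to a BOLD-like signal.
#'
#' @param tau_s Vasodilatory signal decay (s). Default 0.65.
#' @param tau_f Blood inflow time constant (s). Default 0.41.
#' @param tau_v Blood volume time constant (s). Default 0.98.
#' @param tau_q Deoxyhemoglobin time constant (s). Default 0.98.
#' @param kappa Vein stiffness exponent (unitless). Default 0.32.
#' @param E0 Resting oxygen extraction fraction. Default 0.4.
#' @param V0 Resting venous blood volume fraction. Default 0.04.
#' @param k1,k2,k3 BOLD kinetic constants. Defaults 2.77, 0.2, 0.5.
#' @return An object of class `hemodynamic_params`.
#' @export
hemodynamic_params <- function(tau_s = 0.65, tau_f = 0.41, tau_v = 0.98,
                               tau_q = 0.98, kappa = 0.32, E0 = 0.4,
                               V0 = 0.04, k1 = 2.77, k2 = 0.2, k3 = 0.5) {
  stopifnot(tau_s > 0, tau_f > 0, tau_v > 0, tau_q > 0, E0 > 0, E0 < 1, V0 > 0)
  structure(list(tau_s = tau_s, tau_f = tau_f, tau_v = tau_v, tau_q = tau_q,
                 kappa = kappa, E0 = E0, V0 = V0, k1 = k1, k2 = k2, k3 = k3),
            class = "hemodynamic_params")
}

#' Hemodynamic state derivatives
#'
#' Vector field of the Balloon-Windkessel cascade:
#' \preformatted{
#' ds = z - s/tau_s - (f - 1)/tau_f
#' df = s
#' dv = (f - v^(1/kappa)) / tau_v
#' dq = (f (1 - (1 - E0)^(1/f))/E0 - q v^(1/kappa)/v) / tau_q
#' }
#' The rest state `(s, f, v, q) = (0, 1, 1, 1)` is a fixed point for z = 0.
#'
#' @param state Named numeric vector (or list) with `s`, `f`, `v`, `q`;
#'   entries may be vectors (one per region).
#' @param z Neural input (same length as the state entries).
#' @param hp [hemodynamic_params()].
#' @return Named list of derivatives `s`, `f`, `v`, `q`.
#' @export
hemo_derivatives <- function(state, z, hp = hemodynamic_params()) {
  s <- state$s; f <- state$f; v <- state$v; q <- state$q
  if (any(f <= 0) || any(v <= 0))
    stop("blood inflow and volume must stay positive (fractional powers)")
  vk <- v^(1 / hp$kappa)
  list(
    s = z - s / hp$tau_s - (f - 1) / hp$tau_f,
    f = s,
    v = (f - vk) / hp$tau_v,
    q = (f * (1 - (1 - hp$E0)^(1 / f)) / hp$E0 - q * vk / v) / hp$tau_q)
}

#' BOLD readout
#'
#' Nonlinear observation of the hemodynamic state:
#' `B = V0 (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v))`; zero at rest.
#'
#' @inheritParams hemo_derivatives
#' @return BOLD amplitude (same shape as the state entries).
#' @export
bold_readout <- function(state, hp = hemodynamic_params()) {
  if (any(state$v <= 0)) stop("blood volume must be positive")
  hp$V0 * (hp$k1 * (1 - state$q) + hp$k2 * (1 - state$q / state$v) +
             hp$k3 * (1 - state$v))
}

#' Simulate BOLD-like signals from firing rates
#'
#' Integrates the Balloon-Windkessel cascade per region with the explicit
#' Euler method (default 10 ms step) driven by the pyramidal firing rate
#' series, then decimates the BOLD readout to the repetition time `tr`. The
#' neural series is resampled to the hemodynamic grid by averaging within
#' each integration-step bin (anti-aliasing by averaging); rates are passed
#' in Hz without normalisation, scaled by `gain`.
#'
#' @param rate Time-by-regions firing-rate matrix (Hz) or a vector for one
#'   region.
#' @param in_fs Sampling rate of `rate` (Hz).
#' @param hp [hemodynamic_params()].
#' @param dt Euler step (s). Default 0.01.
#' @param tr Output repetition time (s). Default 2.08.
#' @param gain Multiplicative input gain. Default 1.
#' @param t_discard Seconds of BOLD output discarded from the start
#'   (hemodynamic transient). Default 0.
#' @return List with `bold` (time-by-regions matrix at `tr`), `tr` and
#'   `time` (s, relative to the start of `rate`).
#' @export
simulate_bold <- function(rate, in_fs, hp = hemodynamic_params(), dt = 0.01,
                          tr = 2.08, gain = 1, t_discard = 0) {
  if (is.vector(rate)) rate <- matrix(rate, ncol = 1)
  if (!all(is.finite(rate))) stop("non-finite neural input")
  nreg <- ncol(rate)
  # bin-average the neural series onto the hemodynamic grid
  k <- in_fs * dt
  if (abs(k - round(k)) > 1e-8)
    stop("in_fs must be an integer multiple of 1/dt")
  k <- round(k)
  nbin <- nrow(rate) %/% k
  if (nbin < 1) stop("neural series shorter than one hemodynamic step")
  z <- sapply(seq_len(nreg), function(j) {
    colMeans(matrix(rate[seq_len(nbin * k), j], nrow = k))
  })
  if (is.vector(z)) z <- matrix(z, ncol = nreg)
  z <- z * gain

  s <- numeric(nreg); f <- rep(1, nreg); v <- rep(1, nreg); q <- rep(1, nreg)
  every <- tr / dt
  if (abs(every - round(every)) > 1e-8)
    stop("tr must be an integer multiple of dt")
  every <- round(every)
  n_out <- nbin %/% every
  bold <- matrix(0, n_out, nreg)
  out_i <- 0L
  for (i in seq_len(nbin)) {
    st <- list(s = s, f = f, v = v, q = q)
    d <- hemo_derivatives(st, z[i, ], hp)
    s <- s + dt * d$s; f <- f + dt * d$f; v <- v + dt * d$v; q <- q + dt * d$q
    if (i %% every == 0) {
      out_i <- out_i + 1L
      bold[out_i, ] <- bold_readout(list(s = s, f = f, v = v, q = q), hp)
    }
  }
  colnames(bold) <- colnames(rate)
  keep <- which((seq_len(n_out) * tr) > t_discard)
  list(bold = bold[keep, , drop = FALSE], tr = tr, time = seq_len(n_out)[keep] * tr)
}
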