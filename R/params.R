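#' Sigmoid (wave-to-pulse) parameters
#'
#' Parameters of the logistic function that converts a membrane postsynaptic
#' potential (PSP, mV) into a population firing rate (Hz).
#'
#' @param zeta_max Maximal firing rate (Hz). Default 5.
#' @param r Slope of the sigmoid (1/mV). Default 0.56.
#' @param v_th PSP at which the output is half-maximal (mV). Default 6.
#' @return An object of class `sigmoid_params`.
#' @export
sigmoid_params <- function(zeta_max = 5, r = 0.56, v_th = 6) {
  stopifnot(zeta_max > 0, r > 0)
  structure(list(zeta_max = zeta_max, r = r, v_th = v_th),
            class = "sigmoid_params")
}

#' Kinetic constants of one neural-mass subpopulation
#'
#' Each subpopulation is characterised by the maximal amplitudes of its
#' excitatory/inhibitory postsynaptic potentials and the inverse
#' characteristic time constants of the corresponding synaptic kernels.
#'
#' @param A Excitatory PSP amplitude (mV).
#' @param a Inverse excitatory time constant (1/s).
#' @param B Inhibitory PSP amplitude (mV).
#' @param b Inverse inhibitory time constant (1/s).
#' @return An object of class `subpop_params`.
#' @export
subpop_params <- function(A, a, B, b) {
  stopifnot(A > 0, a > 0, B > 0, b > 0)
  structure(list(A = A, a = a, B = B, b = b), class = "subpop_params")
}

#' Gamma-subpopulation gains from its time constants
#'
#' The fast (gamma) subpopulation keeps the same gain-to-rate-constant ratio
#' as the slow (alpha) one: `A = 32.5 a / 1000` and `B = 440 b / 1000`.
#' Evaluating the formulas at the alpha time constants (a = 120, b = 60 1/s)
#' recovers the alpha gains (3.9 and 26.4 mV).
#'
#' @param a_gamma Inverse excitatory time constant (1/s).
#' @param b_gamma Inverse inhibitory time constant (1/s).
#' @return Named numeric vector with elements `A` and `B` (mV).
#' @export
resolve_gamma_gains <- function(a_gamma, b_gamma) {
  stopifnot(a_gamma > 0, b_gamma > 0)
  c(A = 32.5 * a_gamma / 1000, B = 440 * b_gamma / 1000)
}

#' Local circuit connectivity parameters
#'
#' The four intra-columnar connection gains are expressed as fractions of a
#' single local connectivity scale `C`: `C1 = c1*C` (pyramidal to excitatory
#' interneurons), `C2 = c2*C` (excitatory interneurons back to pyramidal),
#' `C3 = c3*C` (pyramidal to inhibitory interneurons) and `C4` (inhibitory
#' interneurons back to pyramidal), the last being the quantity the
#' homeostatic plasticity adjusts at run time from `c4_init*C`.
#'
#' @param C Local connectivity scale (unitless). Default 135.
#' @param c1,c2,c3 Fractions of `C` for the static gains. Defaults 1, 0.8,
#'   0.25.
#' @param c4_init Initial fraction of `C` for the plastic inhibitory gain.
#'   Default 0.25.
#' @param r_alpha Proportion of the alpha subpopulation in the combined
#'   pyramidal output, in `[0, 1]`. Default 0.5.
#' @return An object of class `circuit_params`.
#' @export
local_circuit_params <- function(C = 135, c1 = 1, c2 = 0.8, c3 = 0.25,
                                 c4_init = 0.25, r_alpha = 0.5) {
  stopifnot(C > 0, c4_init >= 0, r_alpha >= 0, r_alpha <= 1)
  structure(list(C = C, c1 = c1, c2 = c2, c3 = c3, c4_init = c4_init,
                 r_alpha = r_alpha), class = "circuit_params")
}

#' Inhibitory synaptic plasticity (ISP) parameters
#'
#' Homeostatic rule adjusting the inhibitory-to-pyramidal gain C4 so that the
#' pyramidal firing rate tracks the target `rho`:
#' `tau * dC4/dt = zeta_inh * (zeta_pyr - rho) * ((C4 - c4_min)/C)^beta`.
#'
#' @param enabled Logical; ISP on/off.
#' @param rho Target pyramidal firing rate (Hz). Default 2.5.
#' @param tau Inverse learning rate (s). Default 2.
#' @param beta Soft-bound exponent (unitless). Default 1.
#' @param c4_min Lower bound on C4 (unitless, absolute). Default 0.
#' @return An object of class `plasticity_params`.
#' @export
plasticity_params <- function(enabled = TRUE, rho = 2.5, tau = 2, beta = 1,
                              c4_min = 0) {
  stopifnot(rho > 0, tau > 0, beta >= 0, c4_min >= 0)
  structure(list(enabled = isTRUE(enabled), rho = rho, tau = tau, beta = beta,
                 c4_min = c4_min), class = "plasticity_params")
}

#' Background drive parameters
#'
#' Each subpopulation of each region receives an excitatory background input
#' `p(t)` (Hz). Under `noise_mode = "iid"` (default) `p` is redrawn from
#' `N(p_mean, p_sd)` at every integration step, the literal reading of input
#' values "randomly sampled from a normal distribution". Under
#' `noise_mode = "diffusion"` the mean enters the drift and the fluctuation
#' is injected as a Wiener increment `A*a*p_sd*sqrt(dt)*N(0,1)` in the y1
#' update, which keeps the input statistics step-size invariant.
#'
#' @param p_mean Mean input (Hz). Default 220.
#' @param p_sd Input standard deviation (Hz). Default 31.
#' @param noise_mode `"iid"` or `"diffusion"`.
#' @return An object of class `drive_params`.
#' @export
drive_params <- function(p_mean = 220, p_sd = 31, noise_mode = c("iid", "diffusion")) {
  stopifnot(p_sd >= 0)
  noise_mode <- match.arg(noise_mode)
  structure(list(p_mean = p_mean, p_sd = p_sd, noise_mode = noise_mode),
            class = "drive_params")
}

#' Full model parameter set
#'
#' Bundles the subpopulation, circuit, sigmoid, plasticity and drive
#' parameters together with the global coupling `K`. Defaults reproduce the
#' reference multi-frequency configuration: a slow subpopulation tuned near
#' the EEG alpha band (A = 3.9 mV, a = 120 1/s, B = 26.4 mV, b = 60 1/s) and
#' a fast one near the gamma band (a = 660, b = 330 1/s, gains from
#' [resolve_gamma_gains()]).
#'
#' @param r_alpha Proportion of the alpha subpopulation, in `[0, 1]`.
#' @param K Global coupling (unitless).
#' @param alpha,gamma [subpop_params()] for the two subpopulations.
#' @param circuit [local_circuit_params()]; its `r_alpha` is overridden by
#'   the `r_alpha` argument.
#' @param sigmoid [sigmoid_params()].
#' @param plasticity [plasticity_params()].
#' @param drive [drive_params()].
#' @return An object of class `jr_params`.
#' @examples
#' p <- jr_params(r_alpha = 1, K = 0, plasticity = plasticity_params(enabled = FALSE))
#' @export
jr_params <- function(r_alpha = 0.5, K = 0,
                      alpha = subpop_params(A = 3.9, a = 120, B = 26.4, b = 60),
                      gamma = NULL,
                      circuit = local_circuit_params(),
                      sigmoid = sigmoid_params(),
                      plasticity = plasticity_params(),
                      drive = drive_params()) {
  stopifnot(r_alpha >= 0, r_alpha <= 1, K >= 0)
  if (is.null(gamma)) {
    g <- resolve_gamma_gains(660, 330)
    gamma <- subpop_params(A = g[["A"]], a = 660, B = g[["B"]], b = 330)
  }
  circuit$r_alpha <- r_alpha
  structure(list(r_alpha = r_alpha, K = K, alpha = alpha, gamma = gamma,
                 circuit = circuit, sigmoid = sigmoid, plasticity = plasticity,
                 drive = drive), class = "jr_params")
}

#' Simulation protocol
#'
#' @param dt Integration step (s). Default 0.001.
#' @param t_sim Total simulated time (s). Default 180.
#' @param t_discard Initial transient discarded from the outputs (s).
#'   Default 60.
#' @param out_fs Output sampling rate after decimation (Hz); must divide
#'   `1/dt`. Default 200.
#' @param seed RNG seed used by [simulate_jr()].
#' @param n_seeds Number of realisations for seed-averaged protocols.
#' @return An object of class `jr_protocol`.
#' @export
jr_protocol <- function(dt = 1e-3, t_sim = 180, t_discard = 60, out_fs = 200,
                        seed = 1L, n_seeds = 1L) {
  stopifnot(dt > 0, t_discard < t_sim, out_fs <= 1 / dt + 1e-9)
  decim <- round(1 / (dt * out_fs))
  if (abs(decim * dt * out_fs - 1) > 1e-8)
    stop("out_fs must be an integer divisor of 1/dt")
  structure(list(dt = dt, t_sim = t_sim, t_discard = t_discard,
                 out_fs = out_fs, seed = as.integer(seed),
                 n_seeds = as.integer(n_seeds), decim = as.integer(decim)),
            class = "jr_protocol")
}
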