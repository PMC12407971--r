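#' Simulate the coupled multi-frequency Jansen-Rit network
#'
#' Integrates the two-subpopulation Jansen-Rit model with optional
#' inhibitory synaptic plasticity on an arbitrary connectome using the
#' Euler-Maruyama scheme (compiled core). Outputs are recorded after the
#' protocol's transient `t_discard` and decimated to `out_fs` by
#' block-averaging (boxcar anti-aliasing) over `1/(dt*out_fs)` steps.
#'
#' @param connectome A [connectome()] object, a square numeric matrix, or
#'   `NULL` for a single isolated node.
#' @param params [jr_params()].
#' @param protocol [jr_protocol()]; `protocol$seed` seeds the RNG so that
#'   identical seeds give bit-identical results.
#' @return An object of class `jr_sim` with elements `eeg` (time x regions,
#'   combined pyramidal PSP, mV), `rate_pyr` (Hz, in `[0, zeta_max]`), `x0`
#'   (combined excitatory-loop PSP, mV), `c4` (3-d array time x regions x
#'   subpopulation), `fs`, `time`, `params`, `protocol`, `seed` and region
#'   `labels`.
#' @examples
#' \donttest{
#' p <- jr_params(r_alpha = 1, K = 0, plasticity = plasticity_params(enabled = FALSE),
#'                drive = drive_params(p_sd = 0))
#' sim <- simulate_jr(NULL, p, jr_protocol(t_sim = 30, t_discard = 10))
#' }
#' @export
simulate_jr <- function(connectome = NULL, params = jr_params(),
                        protocol = jr_protocol()) {
  M <- if (is.null(connectome)) matrix(0, 1, 1)
       else if (inherits(connectome, "connectome")) connectome$mat
       else as.matrix(connectome)
  labels <- if (inherits(connectome, "connectome")) connectome$labels
            else colnames(M)
  ci <- params$circuit
  n_steps <- round(protocol$t_sim / protocol$dt)
  discard <- round(protocol$t_discard / protocol$dt)
  nm <- match(params$drive$noise_mode, c("iid", "diffusion")) - 1L
  set.seed(protocol$seed)
  res <- jr_simulate_cpp(
    M, params$r_alpha, params$K,
    ci$c1 * ci$C, ci$c2 * ci$C, ci$c3 * ci$C, ci$c4_init * ci$C,
    params$alpha$A, params$alpha$a, params$alpha$B, params$alpha$b,
    params$gamma$A, params$gamma$a, params$gamma$B, params$gamma$b,
    params$sigmoid$zeta_max, params$sigmoid$r, params$sigmoid$v_th,
    params$drive$p_mean, params$drive$p_sd, nm,
    params$plasticity$enabled, params$plasticity$rho, params$plasticity$tau,
    params$plasticity$beta, params$plasticity$c4_min, ci$C,
    protocol$dt, n_steps, discard, protocol$decim)
  n_out <- nrow(res$eeg)
  c4 <- array(c(res$c4_alpha, res$c4_gamma),
              dim = c(n_out, ncol(M), 2),
              dimnames = list(NULL, labels, c("alpha", "gamma")))
  colnames(res$eeg) <- colnames(res$rate_pyr) <- colnames(res$x0) <- labels
  structure(list(
    eeg = res$eeg, rate_pyr = res$rate_pyr, x0 = res$x0, c4 = c4,
    fs = protocol$out_fs,
    time = protocol$t_discard + (seq_len(n_out)) / protocol$out_fs,
    params = params, protocol = protocol, seed = protocol$seed,
    labels = labels), class = "jr_sim")
}

#' @export
print.jr_sim <- function(x, ...) {
  cat("Jansen-Rit simulation:", ncol(x$eeg), "region(s),",
      nrow(x$eeg), "samples at", x$fs, "Hz\n")
  cat("  r_alpha =", x$params$r_alpha, " K =", x$params$K,
      " ISP =", x$params$plasticity$enabled,
      if (x$params$plasticity$enabled) paste0("(rho = ", x$params$plasticity$rho, ")"),
      "\n")
  cat("  seed =", x$seed, "\n")
  invisible(x)
}

#' Numerical attractor scan over the background input
#'
#' Replaces formal continuation: for each value of the constant background
#' input `p` a noise-free simulation is run and the retained combined PSP is
#' classified as oscillatory when its peak-to-peak amplitude exceeds
#' `amp_threshold` (default 0.1 mV, orders of magnitude above a settled
#' fixed point). Extrema of the excitatory-loop PSP `x0` and the Welch peak
#' frequency are reported per `p`.
#'
#' @param p_values Sorted numeric vector of input values (Hz).
#' @param params [jr_params()]; its drive SD is forced to zero.
#' @param protocol [jr_protocol()].
#' @param amp_threshold Peak-to-peak oscillation threshold (mV).
#' @return A data.frame with columns `p`, `x0_min`, `x0_max`, `amplitude`,
#'   `dominant_freq` (NA when not oscillating) and `oscillating`.
#' @export
attractor_scan <- function(p_values, params = jr_params(),
                           protocol = jr_protocol(t_sim = 60, t_discard = 30),
                           amp_threshold = 0.1) {
  stopifnot(!is.unsorted(p_values))
  rows <- lapply(p_values, function(p) {
    pars <- params
    pars$drive <- drive_params(p_mean = p, p_sd = 0,
                               noise_mode = params$drive$noise_mode)
    sim <- simulate_jr(NULL, pars, protocol)
    eeg <- sim$eeg[, 1]
    amp <- diff(range(eeg))
    osc <- is.finite(amp) && amp > amp_threshold
    df <- if (osc) {
      psd <- welch_psd(eeg, sim$fs)
      dominant_frequency(psd)
    } else NA_real_
    data.frame(p = p, x0_min = min(sim$x0), x0_max = max(sim$x0),
               amplitude = amp, dominant_freq = df, oscillating = osc)
  })
  do.call(rbind, rows)
}
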