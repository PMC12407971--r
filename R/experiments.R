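#' Read / write a model configuration (JSON)
#'
#' A flat configuration document mirrors the model parameter names
#' (`A_alpha`, `a_gamma`, `r_alpha`, `rho`, `tau`, `beta`, `K`, `p_mean`,
#' `p_sd`, `dt`, `t_sim`, `t_discard`, `out_fs`, `seed`, ...). Unknown keys
#' are rejected.
#'
#' @param path JSON file path.
#' @return `read_config` returns a named list; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), names(default_config()))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  modifyList(default_config(), cfg)
}

#' @rdname read_config
#' @param config Named list of configuration values.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

default_config <- function() {
  list(A_alpha = 3.9, a_alpha = 120, B_alpha = 26.4, b_alpha = 60,
       a_gamma = 660, b_gamma = 330,
       zeta_max = 5, r = 0.56, v_th = 6,
       C = 135, c1 = 1, c2 = 0.8, c3 = 0.25, c4_init = 0.25,
       r_alpha = 0.5, K = 0,
       isp = TRUE, rho = 2.5, tau = 2, beta = 1, c4_min = 0,
       p_mean = 220, p_sd = 31, noise_mode = "iid",
       dt = 0.001, t_sim = 180, t_discard = 60, out_fs = 200,
       seed = 1, n_seeds = 1)
}

#' Build parameter and protocol objects from a flat configuration
#'
#' @param config Named list as returned by [read_config()]; missing keys
#'   take their defaults.
#' @return List with `params` ([jr_params()]) and `protocol`
#'   ([jr_protocol()]).
#' @export
config_to_model <- function(config = list()) {
  cfg <- modifyList(default_config(), config)
  g <- resolve_gamma_gains(cfg$a_gamma, cfg$b_gamma)
  params <- jr_params(
    r_alpha = cfg$r_alpha, K = cfg$K,
    alpha = subpop_params(cfg$A_alpha, cfg$a_alpha, cfg$B_alpha, cfg$b_alpha),
    gamma = subpop_params(g[["A"]], cfg$a_gamma, g[["B"]], cfg$b_gamma),
    circuit = local_circuit_params(cfg$C, cfg$c1, cfg$c2, cfg$c3, cfg$c4_init,
                                   cfg$r_alpha),
    sigmoid = sigmoid_params(cfg$zeta_max, cfg$r, cfg$v_th),
    plasticity = plasticity_params(cfg$isp, cfg$rho, cfg$tau, cfg$beta,
                                   cfg$c4_min),
    drive = drive_params(cfg$p_mean, cfg$p_sd, cfg$noise_mode))
  protocol <- jr_protocol(cfg$dt, cfg$t_sim, cfg$t_discard, cfg$out_fs,
                          cfg$seed, cfg$n_seeds)
  list(params = params, protocol = protocol)
}

#' Registered desk-scale experiments
#'
#' @return Character vector of experiment ids accepted by
#'   [run_experiment()].
#' @export
list_experiments <- function() {
  c("single_node_ralpha_map", "isp_clamping", "tau_sweep", "attractor_scan",
    "dual_fit_demo")
}

#' Run a registered experiment
#'
#' Config-driven reproductions of the model's desk-scale characterisation
#' runs, at reduced grid resolution and seed counts by default (full-scale
#' settings are one override away):
#' \describe{
#'   \item{single_node_ralpha_map}{dominant frequency and normalised
#'     spectrum of an isolated node against the alpha-proportion
#'     `r_alpha` (no ISP).}
#'   \item{isp_clamping}{noise-free single-node runs over a grid of target
#'     rates `rho`; reports time-averaged combined firing rate and C4.}
#'   \item{tau_sweep}{dominant frequency of a small coupled network against
#'     the plasticity time constant `tau`.}
#'   \item{attractor_scan}{oscillatory input ranges with and without ISP
#'     (numerical stand-in for a bifurcation diagram).}
#'   \item{dual_fit_demo}{parameter recovery on synthetic targets: data are
#'     generated at known `(K*, rho*)` on a synthetic connectome with a
#'     held-out seed, then recovered by [grid_sweep()] +
#'     [dual_fit_select()].}
#' }
#'
#' @param id Experiment id, see [list_experiments()].
#' @param overrides Named list overriding experiment defaults (axis grids,
#'   seed counts, protocol fields; see each experiment's defaults in the
#'   source).
#' @param out_dir Optional output directory; tables are written as CSV and
#'   a JSON summary with the full configuration echo is produced.
#' @param seed Base seed.
#' @return Experiment-specific result list (also written to `out_dir` when
#'   given); all experiments are deterministic given `seed`.
#' @export
run_experiment <- function(id, overrides = list(), out_dir = NULL, seed = 1) {
  id <- match.arg(id, list_experiments())
  res <- switch(id,
    single_node_ralpha_map = exp_ralpha_map(overrides, seed),
    isp_clamping = exp_isp_clamping(overrides, seed),
    tau_sweep = exp_tau_sweep(overrides, seed),
    attractor_scan = exp_attractor_scan(overrides, seed),
    dual_fit_demo = exp_dual_fit_demo(overrides, seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(res$tables))
      write.csv(res$tables[[nm]], file.path(out_dir, paste0(id, "_", nm, ".csv")),
                row.names = FALSE)
    jsonlite::write_json(res$summary, file.path(out_dir, paste0(id, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(res)
}

exp_defaults <- function(overrides, defaults) {
  modifyList(defaults, overrides)
}

exp_ralpha_map <- function(overrides, seed) {
  cfg <- exp_defaults(overrides, list(
    r_alpha = seq(0, 1, length.out = 9), n_seeds = 3,
    t_sim = 120, t_discard = 60))
  rows <- lapply(cfg$r_alpha, function(ra) {
    freqs <- vapply(seq_len(cfg$n_seeds), function(s) {
      pars <- jr_params(r_alpha = ra, K = 0,
                        plasticity = plasticity_params(enabled = FALSE))
      prot <- jr_protocol(t_sim = cfg$t_sim, t_discard = cfg$t_discard,
                          seed = seed + 1000 * s + round(1000 * ra))
      sim <- simulate_jr(NULL, pars, prot)
      dominant_frequency(welch_psd(sim$eeg[, 1], sim$fs))
    }, numeric(1))
    data.frame(r_alpha = ra, dominant_freq = median(freqs))
  })
  tab <- do.call(rbind, rows)
  list(tables = list(map = tab),
       summary = list(experiment = "single_node_ralpha_map", seed = seed,
                      config = cfg))
}

exp_isp_clamping <- function(overrides, seed) {
  cfg <- exp_defaults(overrides, list(
    rho = c(2.0, 2.5, 3.0), r_alpha = 0.5, t_sim = 180, t_discard = 120))
  rows <- lapply(cfg$rho, function(rho) {
    pars <- jr_params(r_alpha = cfg$r_alpha, K = 0,
                      plasticity = plasticity_params(rho = rho),
                      drive = drive_params(p_sd = 0))
    sim <- simulate_jr(NULL, pars,
                       jr_protocol(t_sim = cfg$t_sim,
                                   t_discard = cfg$t_discard, seed = seed))
    data.frame(rho = rho,
               mean_rate = mean(sim$rate_pyr),
               mean_c4_alpha = mean(sim$c4[, , "alpha"]),
               mean_c4_gamma = mean(sim$c4[, , "gamma"]))
  })
  tab <- do.call(rbind, rows)
  tab$rel_error <- abs(tab$mean_rate - tab$rho) / tab$rho
  list(tables = list(clamping = tab),
       summary = list(experiment = "isp_clamping", seed = seed, config = cfg))
}

exp_tau_sweep <- function(overrides, seed) {
  cfg <- exp_defaults(overrides, list(
    tau = c(0.1, 2, 50), K = 0.5, rho = 2.5, r_alpha = 0.5,
    n_nodes = 8, t_sim = 660, t_discard = 60))
  conn <- add_homotopic(synthetic_connectome(cfg$n_nodes, seed = seed))
  rows <- lapply(cfg$tau, function(tau) {
    pars <- jr_params(r_alpha = cfg$r_alpha, K = cfg$K,
                      plasticity = plasticity_params(rho = cfg$rho, tau = tau))
    sim <- simulate_jr(conn, pars,
                       jr_protocol(t_sim = cfg$t_sim,
                                   t_discard = cfg$t_discard, seed = seed))
    psd <- welch_psd(rowMeans(sim$eeg), sim$fs)
    data.frame(tau = tau, dominant_freq = dominant_frequency(psd))
  })
  list(tables = list(sweep = do.call(rbind, rows)),
       summary = list(experiment = "tau_sweep", seed = seed, config = cfg))
}

exp_attractor_scan <- function(overrides, seed) {
  cfg <- exp_defaults(overrides, list(
    p_values = seq(0, 560, length.out = 15), rho = 2.5, r_alpha = 1,
    t_sim = 60, t_discard = 30, amp_threshold = 0.1))
  prot <- jr_protocol(t_sim = cfg$t_sim, t_discard = cfg$t_discard,
                      seed = seed)
  base <- jr_params(r_alpha = cfg$r_alpha, K = 0,
                    drive = drive_params(p_sd = 0))
  without <- base
  without$plasticity <- plasticity_params(enabled = FALSE)
  with_isp <- base
  with_isp$plasticity <- plasticity_params(rho = cfg$rho)
  scan_no <- attractor_scan(cfg$p_values, without, prot, cfg$amp_threshold)
  scan_isp <- attractor_scan(cfg$p_values, with_isp, prot, cfg$amp_threshold)
  list(tables = list(no_isp = scan_no, isp = scan_isp),
       summary = list(experiment = "attractor_scan", seed = seed, config = cfg,
                      n_oscillating_no_isp = sum(scan_no$oscillating),
                      n_oscillating_isp = sum(scan_isp$oscillating)))
}

#' Synthetic dual-fit targets
#'
#' Generates the "empirical" observables for the dual-fit demonstration by
#' simulating the model at a known parameter pair with a held-out seed: the
#' relative theta/alpha/beta power of the region-mean EEG and the BOLD FC
#' matrix.
#'
#' @param conn [connectome()].
#' @param K_star,rho_star Generating parameters.
#' @param seed Held-out seed (not reused by the recovery sweep).
#' @param protocol [jr_protocol()].
#' @param tr BOLD repetition time (s).
#' @param bold_discard BOLD transient discard (s).
#' @return List with `spectral` (length-3 vector) and `fc_bold` (matrix),
#'   plus the generating configuration.
#' @export
make_dualfit_targets <- function(conn, K_star, rho_star, seed = 999,
                                 protocol = jr_protocol(t_sim = 320),
                                 tr = 2.08, bold_discard = 20) {
  pars <- jr_params(r_alpha = 0.5, K = K_star,
                    plasticity = plasticity_params(rho = rho_star))
  prot <- protocol
  prot$seed <- seed
  sim <- simulate_jr(conn, pars, prot)
  psd <- welch_psd(rowMeans(sim$eeg), sim$fs)
  spectral <- relative_band_power(psd, eeg_bands(c("theta", "alpha", "beta")))
  bb <- simulate_bold(sim$rate_pyr, sim$fs, tr = tr, t_discard = bold_discard)
  list(spectral = spectral, fc_bold = unclass(bold_fc(bb$bold, tr)),
       K_star = K_star, rho_star = rho_star, seed = seed)
}

exp_dual_fit_demo <- function(overrides, seed) {
  cfg <- exp_defaults(overrides, list(
    n_nodes = 8, K_grid = seq(0, 3, length.out = 5),
    rho_grid = seq(2, 3, length.out = 5), K_star = 1.5, rho_star = 2.5,
    n_seeds = 3, t_sim = 320, t_discard = 60, threshold = 0.85))
  conn <- add_homotopic(synthetic_connectome(cfg$n_nodes, seed = seed))
  targets <- make_dualfit_targets(conn, cfg$K_star, cfg$rho_star,
                                  seed = seed + 900000,
                                  protocol = jr_protocol(t_sim = cfg$t_sim,
                                                         t_discard = cfg$t_discard))
  prot <- jr_protocol(t_sim = cfg$t_sim, t_discard = cfg$t_discard,
                      seed = seed, n_seeds = cfg$n_seeds)
  surfaces <- grid_sweep(conn, axes = list(K = cfg$K_grid, rho = cfg$rho_grid),
                         params = jr_params(r_alpha = 0.5),
                         protocol = prot,
                         targets = list(spectral = targets$spectral,
                                        fc_bold = targets$fc_bold))
  fit <- dual_fit_select(surfaces$spectral, surfaces$fc_bold,
                         threshold = cfg$threshold)
  grid_tab <- write_surface_df(surfaces)
  list(tables = list(surfaces = grid_tab),
       summary = list(experiment = "dual_fit_demo", seed = seed, config = cfg,
                      generating = c(K = cfg$K_star, rho = cfg$rho_star),
                      recovered = if (fit$ok) as.list(fit$selected) else NULL,
                      fmri_ssim = if (fit$ok) fit$ssim else NA),
       fit = fit, surfaces = surfaces, targets = targets)
}

write_surface_df <- function(surfaces) {
  ax <- surfaces[[1]]$axes
  df <- expand.grid(ax[[1]], ax[[2]])
  names(df) <- names(ax)
  for (nm in names(surfaces)) df[[nm]] <- as.vector(surfaces[[nm]]$values)
  df
}
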