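# Shared fixtures and independent reference implementations used across the
# test files. Everything is generated in code; no binary fixtures.

# short protocols for fast unit runs
quick_protocol <- function(t_sim = 30, t_discard = 10, seed = 1, ...) {
  jr_protocol(t_sim = t_sim, t_discard = t_discard, seed = seed, ...)
}

noise_free <- function(p_mean = 220) drive_params(p_mean = p_mean, p_sd = 0)

alpha_only_params <- function(isp = FALSE, rho = 2.5, p_sd = 0) {
  jr_params(r_alpha = 1, K = 0,
            plasticity = if (isp) plasticity_params(rho = rho)
                         else plasticity_params(enabled = FALSE),
            drive = drive_params(p_sd = p_sd))
}

# independently coded classical Jansen-Rit integrator (single population,
# explicit Euler, written directly from the textbook second-order form) used
# as a regression oracle for the compiled core at r_alpha = 1, ISP off.
classical_jr <- function(A = 3.9, a = 120, B = 26.4, b = 60, C = 135,
                         p = 220, dt = 1e-3, n_steps, zmax = 5, r = 0.56,
                         v0 = 6) {
  C1 <- C; C2 <- 0.8 * C; C3 <- 0.25 * C; C4 <- 0.25 * C
  S <- function(v) zmax / (1 + exp(r * (v0 - v)))
  st <- rep(0, 6)  # x0 x1 x2 y0 y1 y2
  out <- numeric(n_steps)
  for (k in seq_len(n_steps)) {
    x0 <- st[1]; x1 <- st[2]; x2 <- st[3]; y0 <- st[4]; y1 <- st[5]; y2 <- st[6]
    d <- c(y0, y1, y2,
           A * a * S(x1 - x2) - 2 * a * y0 - a^2 * x0,
           A * a * (p + C2 * S(C1 * x0)) - 2 * a * y1 - a^2 * x1,
           B * b * C4 * S(C3 * x0) - 2 * b * y2 - b^2 * x2)
    st <- st + dt * d
    out[k] <- st[2] - st[3]
  }
  out
}

# tiny deterministic connectome used by several network tests
test_connectome <- function(n = 8, seed = 42) {
  add_homotopic(synthetic_connectome(n, seed = seed))
}

# symmetric correlation-like fixture pair for the SSIM oracle test
ssim_fixture <- function() {
  set.seed(11)
  A <- matrix(runif(400, -1, 1), 20)
  A <- (A + t(A)) / 2; diag(A) <- 1
  N <- matrix(rnorm(400, 0, 0.2), 20)
  list(A = A, B = A + (N + t(N)) / 2)
}
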