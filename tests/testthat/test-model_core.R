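test_that("sigmoid has the correct midpoint, saturation and monotonicity", {
  sp <- sigmoid_params()
  expect_equal(sigmoid(6, sp), 2.5)
  expect_equal(sigmoid(60, sp), 5, tolerance = 1e-6 / 5)
  expect_equal(sigmoid(0, sp), 5 / (1 + exp(0.56 * 6)))
  v <- seq(-50, 50, by = 0.5)
  s <- sigmoid(v, sp)
  expect_true(all(diff(s) > 0))
  expect_true(all(s > 0 & s < sp$zeta_max))
})

test_that("PSP impulse response peaks at 1/a with value A/e and vanishes at the ends", {
  expect_equal(psp_impulse_response(1 / 120, A = 3.9, a = 120), 3.9 / exp(1))
  expect_equal(psp_impulse_response(0, A = 3.9, a = 120), 0)
  expect_equal(psp_impulse_response(-0.5, A = 3.9, a = 120), 0)
  expect_lt(psp_impulse_response(1, A = 3.9, a = 120), 1e-40)
  # the analytic maximum is a true maximum on a grid
  t <- seq(0, 0.1, by = 1e-5)
  h <- psp_impulse_response(t, A = 3.9, a = 120)
  expect_equal(t[which.max(h)], 1 / 120, tolerance = 1e-3)
})

test_that("gamma gains follow the stated linear formulas and recover the alpha gains", {
  g <- resolve_gamma_gains(660, 330)
  expect_equal(g[["A"]], 21.45)
  expect_equal(g[["B"]], 145.2)
  g_alpha <- resolve_gamma_gains(120, 60)
  expect_equal(g_alpha[["A"]], 3.9)
  expect_equal(g_alpha[["B"]], 26.4)
  expect_error(resolve_gamma_gains(-1, 330))
})

test_that("combined output and rate interpolate between the subpopulations", {
  st <- jr_node_state(alpha = c(x1 = 2, x2 = 0), gamma = c(x1 = 4, x2 = 0))
  expect_equal(combined_output(st, 1), 2)
  expect_equal(combined_output(st, 0), 4)
  expect_equal(combined_output(st, 0.5), 3)
  sp <- sigmoid_params()
  st2 <- jr_node_state(alpha = c(x1 = 6), gamma = c(x1 = 0))
  expect_equal(combined_pyramidal_rate(st2, 1, sp), 2.5)
  # equal PSPs collapse to a single sigmoid
  st3 <- jr_node_state(alpha = c(x1 = 3), gamma = c(x1 = 3))
  expect_equal(combined_pyramidal_rate(st3, 0.5, sp), sigmoid(3, sp))
  st4 <- jr_node_state(alpha = c(x1 = 0), gamma = c(x1 = 60))
  expect_equal(combined_pyramidal_rate(st4, 0.3, sp),
               0.3 * sigmoid(0, sp) + 0.7 * sigmoid(60, sp))
})

test_that("node derivatives match hand evaluation at the origin and react linearly to p", {
  pars <- jr_params(r_alpha = 1, K = 0)
  st <- jr_node_state(c4 = rep(0.25 * 135, 2))
  sp <- pars$sigmoid
  d0 <- node_derivatives(st, p_drive = 0, net_drive = 0, pars)
  # at the origin only the sigmoid drive terms survive
  s0 <- sigmoid(0, sp)
  expect_equal(d0$alpha[["y0"]], 3.9 * 120 * s0)
  expect_equal(d0$alpha[["y1"]], 3.9 * 120 * (0.8 * 135 * s0))
  expect_equal(d0$alpha[["y2"]], 26.4 * 60 * 33.75 * s0)
  expect_equal(d0$alpha[["x0"]], 0)
  # p enters only dy1, linearly with slope A*a
  d1 <- node_derivatives(st, p_drive = 100, net_drive = 0, pars)
  d2 <- node_derivatives(st, p_drive = 200, net_drive = 0, pars)
  expect_equal(d2$alpha[["y1"]] - d1$alpha[["y1"]], 3.9 * 120 * 100)
  same <- setdiff(names(d1$alpha), "y1")
  expect_equal(d1$alpha[same], d2$alpha[same])
})

test_that("a numerically located fixed point annihilates the drift", {
  # damped fixed-point iteration on the deterministic alpha system, an
  # oracle independent of node_derivatives' algebra
  pars <- jr_params(r_alpha = 1, K = 0, drive = noise_free(p_mean = 50),
                    plasticity = plasticity_params(enabled = FALSE))
  S <- function(v) sigmoid(v, pars$sigmoid)
  A <- 3.9; a <- 120; B <- 26.4; b <- 60
  C1 <- 135; C2 <- 108; C3 <- 33.75; C4 <- 33.75; p <- 50
  x <- c(0, 0, 0)
  for (i in 1:5000) {
    new <- c(A / a * S(x[2] - x[3]),
             A / a * (p + C2 * S(C1 * x[1])),
             B / b * C4 * S(C3 * x[1]))
    x <- x + 0.2 * (new - x)
  }
  st <- jr_node_state(alpha = c(x0 = x[1], x1 = x[2], x2 = x[3]),
                      gamma = c(x0 = x[1], x1 = x[2], x2 = x[3]),
                      c4 = rep(33.75, 2))
  d <- node_derivatives(st, p_drive = 50, net_drive = 0, pars)
  expect_lt(max(abs(unlist(d[c("alpha", "gamma")]))), 1e-6)
})

test_that("ISP derivative has the homeostatic fixed point, absorbing bound and stated value", {
  pp <- plasticity_params(rho = 2.5, tau = 2, beta = 1, c4_min = 0)
  expect_equal(isp_derivative(33.75, zeta_inh = 1, zeta_pyr = 2.5, pp, C = 135), 0)
  expect_equal(isp_derivative(0, zeta_inh = 1, zeta_pyr = 4, pp, C = 135), 0)
  expect_equal(isp_derivative(0.25 * 135, zeta_inh = 1, zeta_pyr = 3.5, pp, C = 135),
               0.5 * 1 * 1 * 0.25)
  # sign follows zeta_pyr - rho
  expect_lt(isp_derivative(30, 1, 2.0, pp, C = 135), 0)
  expect_gt(isp_derivative(30, 1, 3.0, pp, C = 135), 0)
})

test_that("coupling drive vanishes at K = 0 and matches a brute-force double loop", {
  sp <- sigmoid_params()
  mk <- function(v_a, v_g) jr_node_state(alpha = c(x1 = v_a), gamma = c(x1 = v_g))
  states <- list(mk(1, 2), mk(6, 0))
  M <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(coupling_drive(states, M, K = 0, C = 135, r_alpha = 1, sp),
               c(0, 0))
  # node 2 at threshold drives node 1 with K*C*zeta_max/2
  expect_equal(coupling_drive(list(mk(0, 0), mk(6, 6)), M, K = 0.5, C = 135,
                              r_alpha = 0.7, sp)[1], 0.5 * 135 * 2.5)
  # random 5-node instance against naive summation
  set.seed(3)
  states5 <- replicate(5, mk(runif(1, -5, 10), runif(1, -5, 10)),
                       simplify = FALSE)
  M5 <- matrix(runif(25), 5); M5 <- (M5 + t(M5)) / 2; diag(M5) <- 0
  got <- coupling_drive(states5, M5, K = 1.2, C = 135, r_alpha = 0.4, sp)
  want <- numeric(5)
  for (i in 1:5) for (j in 1:5) if (i != j)
    want[i] <- want[i] + 1.2 * 135 * M5[i, j] *
      sigmoid(combined_output(states5[[j]], 0.4), sp)
  expect_equal(got, want)
  expect_error(coupling_drive(states5, M, K = 1, C = 135, r_alpha = 1, sp),
               "dimensions")
})

test_that("em_step reduces to explicit Euler without noise", {
  pars <- jr_params(r_alpha = 0.5, K = 0, drive = noise_free())
  states <- list(jr_node_state(c4 = rep(33.75, 2)))
  dt <- 1e-3
  stepped <- em_step(states, pars, dt)[[1]]
  d <- node_derivatives(states[[1]], 220, 0, pars)
  for (s in c("alpha", "gamma"))
    expect_equal(stepped[[s]], states[[1]][[s]] + dt * d[[s]])
  expect_equal(stepped$c4, states[[1]]$c4 + dt * d$c4)
})

test_that("the diffusion-mode noise increment has the stated variance scaling", {
  # Monte-Carlo estimate of Var over repeated single steps from rest
  pars <- jr_params(r_alpha = 1, K = 0,
                    plasticity = plasticity_params(enabled = FALSE),
                    drive = drive_params(p_sd = 31, noise_mode = "diffusion"))
  dt <- 1e-3
  states <- list(jr_node_state(c4 = rep(33.75, 2)))
  base <- em_step(list(jr_node_state(c4 = rep(33.75, 2))),
                  jr_params(r_alpha = 1, K = 0,
                            plasticity = plasticity_params(enabled = FALSE),
                            drive = noise_free()), dt)[[1]]$alpha[["y1"]]
  set.seed(99)
  n <- 20000
  incr <- replicate(n, em_step(states, pars, dt)[[1]]$alpha[["y1"]] - base)
  want_var <- (3.9 * 120 * 31)^2 * dt
  expect_equal(var(incr), want_var, tolerance = 0.05)
})
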