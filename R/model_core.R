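#' Wave-to-pulse sigmoid
#'
#' Converts a membrane PSP (mV) into a population firing rate (Hz):
#' `S(v) = zeta_max / (1 + exp(r * (v_th - v)))`.
#'
#' @param v PSP (mV); vectorised.
#' @param sp [sigmoid_params()].
#' @return Firing rate (Hz), strictly in `(0, zeta_max)`.
#' @export
sigmoid <- function(v, sp = sigmoid_params()) {
  sp$zeta_max / (1 + exp(sp$r * (sp$v_th - v)))
}

#' Synaptic impulse response
#'
#' Alpha-function kernel `h(t) = A * a * t * exp(-a t)` for `t >= 0` and 0
#' otherwise; it peaks at `t = 1/a` with value `A/e`.
#'
#' @param t Time (s); vectorised, negative values yield 0.
#' @param A Kernel amplitude (mV).
#' @param a Inverse time constant (1/s).
#' @return Kernel value (mV).
#' @export
psp_impulse_response <- function(t, A, a) {
  ifelse(t >= 0, A * a * t * exp(-a * t), 0)
}

#' Combined pyramidal PSP of a node
#'
#' The EEG-like output of one region: the alpha and gamma pyramidal PSPs
#' (`x1 - x2` of each subpopulation) weighted by the subpopulation proportion.
#'
#' @param state Node state as returned by [jr_node_state()].
#' @param r_alpha Alpha-subpopulation proportion.
#' @return Combined PSP (mV).
#' @export
combined_output <- function(state, r_alpha) {
  r_alpha * (state$alpha[["x1"]] - state$alpha[["x2"]]) +
    (1 - r_alpha) * (state$gamma[["x1"]] - state$gamma[["x2"]])
}

#' Combined pyramidal firing rate of a node
#'
#' Weighted sum of the sigmoids of the two subpopulations' pyramidal PSPs;
#' bounded in `[0, zeta_max]`.
#'
#' @inheritParams combined_output
#' @param sp [sigmoid_params()].
#' @return Firing rate (Hz).
#' @export
combined_pyramidal_rate <- function(state, r_alpha, sp = sigmoid_params()) {
  r_alpha * sigmoid(state$alpha[["x1"]] - state$alpha[["x2"]], sp) +
    (1 - r_alpha) * sigmoid(state$gamma[["x1"]] - state$gamma[["x2"]], sp)
}

#' Node state constructor
#'
#' Twelve dynamical variables (six per subpopulation) plus one plastic
#' inhibitory gain per subpopulation. The zero state with `C4 = c4_init * C`
#' is the default initial condition.
#'
#' @param alpha,gamma Named numeric vectors with elements x0, x1, x2, y0,
#'   y1, y2 (defaults all zero).
#' @param c4 Numeric length-2 vector, plastic gains of the alpha and gamma
#'   subpopulation.
#' @return An object of class `jr_node_state`.
#' @export
jr_node_state <- function(alpha = NULL, gamma = NULL, c4 = c(33.75, 33.75)) {
  zero <- c(x0 = 0, x1 = 0, x2 = 0, y0 = 0, y1 = 0, y2 = 0)
  fill <- function(x) { if (is.null(x)) return(zero); zero[names(x)] <- x; zero }
  structure(list(alpha = fill(alpha), gamma = fill(gamma),
                 c4 = c(alpha = c4[[1]], gamma = c4[[2]])),
            class = "jr_node_state")
}

#' Deterministic drift of one node
#'
#' Evaluates the Jansen-Rit vector field of both subpopulations of one
#' region. Per subpopulation `s`:
#' \preformatted{
#' dx0 = y0
#' dy0 = A_s a_s S(x1 - x2)                       - 2 a_s y0 - a_s^2 x0
#' dx1 = y1
#' dy1 = A_s a_s (p + C2 S(C1 x0) + net)          - 2 a_s y1 - a_s^2 x1
#' dx2 = y2
#' dy2 = B_s b_s C4_s S(C3 x0)                    - 2 b_s y2 - b_s^2 x2
#' }
#' When ISP is enabled the drift of the plastic gain is given by
#' [isp_derivative()] with `zeta_pyr = S(x1 - x2)` and
#' `zeta_inh = S(C3 x0)` of the same subpopulation.
#'
#' @param state [jr_node_state()].
#' @param p_drive Background input (Hz).
#' @param net_drive Network input (Hz), see [coupling_drive()].
#' @param params [jr_params()].
#' @return A `jr_node_state`-shaped list of derivatives.
#' @export
node_derivatives <- function(state, p_drive, net_drive, params) {
  ci <- params$circuit
  C1 <- ci$c1 * ci$C; C2 <- ci$c2 * ci$C; C3 <- ci$c3 * ci$C
  sp <- params$sigmoid
  d <- list()
  for (s in c("alpha", "gamma")) {
    pp <- params[[s]]
    st <- state[[s]]
    spyr <- sigmoid(st[["x1"]] - st[["x2"]], sp)
    sinh <- sigmoid(C3 * st[["x0"]], sp)
    d[[s]] <- c(
      x0 = st[["y0"]],
      x1 = st[["y1"]],
      x2 = st[["y2"]],
      y0 = pp$A * pp$a * spyr - 2 * pp$a * st[["y0"]] - pp$a^2 * st[["x0"]],
      y1 = pp$A * pp$a * (p_drive + C2 * sigmoid(C1 * st[["x0"]], sp) + net_drive) -
        2 * pp$a * st[["y1"]] - pp$a^2 * st[["x1"]],
      y2 = pp$B * pp$b * state$c4[[s]] * sinh - 2 * pp$b * st[["y2"]] -
        pp$b^2 * st[["x2"]]
    )[c("x0", "x1", "x2", "y0", "y1", "y2")]
  }
  dc4 <- c(alpha = 0, gamma = 0)
  if (params$plasticity$enabled) {
    for (s in c("alpha", "gamma")) {
      st <- state[[s]]
      dc4[[s]] <- isp_derivative(
        state$c4[[s]],
        zeta_inh = sigmoid(C3 * st[["x0"]], sp),
        zeta_pyr = sigmoid(st[["x1"]] - st[["x2"]], sp),
        pp = params$plasticity, C = ci$C)
    }
  }
  structure(list(alpha = d$alpha, gamma = d$gamma, c4 = dc4),
            class = "jr_node_state")
}

#' ISP drift of the plastic inhibitory gain
#'
#' Homeostatic (Vogels-type, soft-bounded) rule:
#' `dC4/dt = (1/tau) * zeta_inh * (zeta_pyr - rho) * ((C4 - c4_min)/C)^beta`.
#' Its sign equals the sign of `zeta_pyr - rho` whenever `zeta_inh > 0` and
#' `C4 > c4_min`; the bound `C4 = c4_min` is absorbing for `beta > 0`.
#'
#' @param c4 Current gain (unitless).
#' @param zeta_inh Inhibitory interneuron firing rate (Hz).
#' @param zeta_pyr Pyramidal firing rate (Hz).
#' @param pp [plasticity_params()].
#' @param C Local connectivity scale.
#' @return dC4/dt (1/s).
#' @export
isp_derivative <- function(c4, zeta_inh, zeta_pyr, pp, C) {
  g <- pmax((c4 - pp$c4_min) / C, 0)
  (1 / pp$tau) * zeta_inh * (zeta_pyr - pp$rho) * g^pp$beta
}

#' Network coupling drive
#'
#' Node `i` receives `K * C * sum_{j != i} M[i, j] * S(v_j)` (Hz), where
#' `v_j` is node `j`'s combined pyramidal PSP; inter-regional projections
#' involve pyramidal populations only, so a single combined output per
#' source region enters the sum.
#'
#' @param states List of [jr_node_state()], one per node.
#' @param M Connectivity matrix (square, matching `length(states)`).
#' @param K Global coupling.
#' @param C Local connectivity scale.
#' @param r_alpha Alpha proportion.
#' @param sp [sigmoid_params()].
#' @return Numeric vector of per-node drives (Hz); identically zero for
#'   `K = 0`.
#' @export
coupling_drive <- function(states, M, K, C, r_alpha, sp = sigmoid_params()) {
  n <- length(states)
  if (nrow(M) != n || ncol(M) != n)
    stop("connectivity matrix dimensions do not match the number of nodes")
  rates <- vapply(states, function(s) sigmoid(combined_output(s, r_alpha), sp),
                  numeric(1))
  M0 <- M
  diag(M0) <- 0
  as.numeric(K * C * (M0 %*% rates))
}

#' One Euler-Maruyama step of the coupled network (reference implementation)
#'
#' Pure-R single step used as an independent check of the compiled
#' integrator: all derivatives are evaluated on the pre-step state, the ISP
#' gain is advanced and clamped, then positions and velocities are updated.
#' Under `"iid"` noise the background input is redrawn per node and
#' subpopulation; under `"diffusion"` a Wiener increment
#' `A_s a_s p_sd sqrt(dt) N(0,1)` enters the y1 update. With `p_sd = 0` the
#' step reduces to explicit Euler.
#'
#' @param states List of [jr_node_state()].
#' @param params [jr_params()].
#' @param dt Step (s).
#' @return Updated list of states.
#' @export
em_step <- function(states, params, dt) {
  M <- attr(states, "M")
  if (is.null(M)) M <- matrix(0, length(states), length(states))
  net <- coupling_drive(states, M, params$K, params$circuit$C, params$r_alpha,
                        params$sigmoid)
  dr <- params$drive
  new <- states
  for (i in seq_along(states)) {
    st <- states[[i]]
    p_a <- if (dr$noise_mode == "iid" && dr$p_sd > 0)
      rnorm(2, dr$p_mean, dr$p_sd) else rep(dr$p_mean, 2)
    # evaluate subpopulation drifts with their own input draw
    der <- list()
    for (k in 1:2) {
      s <- c("alpha", "gamma")[k]
      one <- st
      dfull <- node_derivatives(one, p_a[k], net[i], params)
      der[[s]] <- dfull[[s]]
      if (k == 1) dc4 <- dfull$c4
    }
    c4new <- st$c4
    if (params$plasticity$enabled) {
      c4new <- pmax(st$c4 + dt * dc4, params$plasticity$c4_min)
    }
    for (s in c("alpha", "gamma")) {
      pp <- params[[s]]
      dn <- if (dr$noise_mode == "diffusion" && dr$p_sd > 0)
        pp$A * pp$a * dr$p_sd * sqrt(dt) * rnorm(1) else 0
      st[[s]] <- st[[s]] + dt * der[[s]]
      st[[s]][["y1"]] <- st[[s]][["y1"]] + dn
    }
    st$c4 <- c4new
    new[[i]] <- st
  }
  attr(new, "M") <- M
  new
}
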