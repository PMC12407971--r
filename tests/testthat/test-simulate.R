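test_that("simulation output dimensions, bounds and metadata are consistent", {
  pars <- jr_params(r_alpha = 0.5, K = 0)
  prot <- quick_protocol(t_sim = 25, t_discard = 5, seed = 3)
  sim <- simulate_jr(NULL, pars, prot)
  expect_equal(nrow(sim$eeg), (25 - 5) * 200)
  expect_equal(sim$fs, 200)
  # firing rates bounded by the sigmoid ceiling
  expect_true(all(sim$rate_pyr >= 0 & sim$rate_pyr <= 5))
  # C4 stays above the bound with ISP on
  expect_true(all(sim$c4 >= pars$plasticity$c4_min))
  expect_equal(sim$seed, 3)
})

test_that("identical seeds give bit-identical trajectories, different seeds differ", {
  pars <- jr_params(r_alpha = 0.5, K = 0.3)
  conn <- test_connectome(4)
  s1 <- simulate_jr(conn, pars, quick_protocol(seed = 11))
  s2 <- simulate_jr(conn, pars, quick_protocol(seed = 11))
  expect_identical(s1$eeg, s2$eeg)
  expect_identical(s1$rate_pyr, s2$rate_pyr)
  s3 <- simulate_jr(conn, pars, quick_protocol(seed = 12))
  expect_false(identical(s1$eeg, s3$eeg))
})

test_that("noise-free compiled trajectories match the independent classical implementation", {
  # with r_alpha = 1 and ISP off the node is the classical single-population
  # system; compare against the separately coded reference at full rate
  pars <- alpha_only_params()
  prot <- jr_protocol(t_sim = 2, t_discard = 0, out_fs = 1000, seed = 1)
  sim <- simulate_jr(NULL, pars, prot)
  ref <- classical_jr(n_steps = 2000)
  expect_equal(sim$eeg[, 1], ref, tolerance = 1e-10)
})

test_that("the em_step reference and the compiled core agree on a noise-free network", {
  conn <- test_connectome(4)
  pars <- jr_params(r_alpha = 0.5, K = 0.4, drive = noise_free())
  prot <- jr_protocol(t_sim = 0.5, t_discard = 0, out_fs = 1000, seed = 1)
  sim <- simulate_jr(conn, pars, prot)
  states <- replicate(4, jr_node_state(c4 = rep(0.25 * 135, 2)),
                      simplify = FALSE)
  attr(states, "M") <- conn$mat
  eeg_r <- matrix(0, 500, 4)
  for (k in 1:500) {
    states <- em_step(states, pars, 1e-3)
    eeg_r[k, ] <- vapply(states, combined_output, numeric(1), r_alpha = 0.5)
  }
  expect_equal(unname(sim$eeg), eeg_r, tolerance = 1e-9)
})

test_that("single-node spectral phenomenology: alpha ~10-12 Hz, gamma fast, ISP keeps alpha", {
  domf <- function(pars, seed = 1) {
    sim <- simulate_jr(NULL, pars, jr_protocol(t_sim = 90, t_discard = 30,
                                               seed = seed))
    dominant_frequency(welch_psd(sim$eeg[, 1], sim$fs))
  }
  expect_equal(domf(alpha_only_params()), 11.5, tolerance = 0.2)
  f_gamma <- domf(jr_params(r_alpha = 0, K = 0,
                            plasticity = plasticity_params(enabled = FALSE),
                            drive = noise_free()))
  expect_gt(f_gamma, 30)
  f_isp <- domf(jr_params(r_alpha = 1, K = 0,
                          plasticity = plasticity_params(rho = 3.5),
                          drive = noise_free()))
  expect_gt(f_isp, 8); expect_lt(f_isp, 13)
})

test_that("dominant frequency shifts down with coupling K and up with target rate rho", {
  conn <- test_connectome(6, seed = 4)
  domf <- function(K, rho) {
    pars <- jr_params(r_alpha = 0.5, K = K,
                      plasticity = plasticity_params(rho = rho))
    sim <- simulate_jr(conn, pars, jr_protocol(t_sim = 120, t_discard = 40,
                                               seed = 2))
    dominant_frequency(welch_psd(rowMeans(sim$eeg), sim$fs))
  }
  # non-increasing in K at fixed rho (K = 0 sits in the gamma regime)
  fK <- c(domf(0, 2.5), domf(0.5, 2.5), domf(1, 2.5))
  expect_true(all(diff(fK) <= 0))
  expect_gt(fK[1], 30)
  # non-decreasing in rho at fixed K
  fr <- c(domf(0.5, 2.0), domf(0.5, 2.5), domf(0.5, 3.0))
  expect_true(all(diff(fr) >= 0))
})

test_that("ISP reduces to the classical system when disabled and clamps C4 when enabled", {
  # disabled ISP leaves C4 constant at its initial value
  pars <- jr_params(r_alpha = 0.5, K = 0,
                    plasticity = plasticity_params(enabled = FALSE))
  sim <- simulate_jr(NULL, pars, quick_protocol())
  expect_true(all(sim$c4 == 0.25 * 135))
  # enabled ISP moves C4 and respects the lower bound
  pars2 <- jr_params(r_alpha = 0.5, K = 0,
                     plasticity = plasticity_params(rho = 2.5, c4_min = 20))
  sim2 <- simulate_jr(NULL, pars2, quick_protocol(t_sim = 60, t_discard = 5))
  expect_gt(max(abs(sim2$c4 - 0.25 * 135)), 1)
  expect_true(all(sim2$c4 >= 20))
})

test_that("attractor scan classifies fixed points vs limit cycles and handles a degenerate threshold", {
  pars <- alpha_only_params()
  prot <- jr_protocol(t_sim = 40, t_discard = 20, seed = 1)
  scan <- attractor_scan(c(40, 220), pars, prot)
  expect_false(scan$oscillating[1])   # far below the oscillatory input range
  expect_true(scan$oscillating[2])
  expect_equal(scan$dominant_freq[2], 11.5, tolerance = 0.2)
  scan_inf <- attractor_scan(c(40, 220), pars, prot, amp_threshold = Inf)
  expect_false(any(scan_inf$oscillating))
  expect_error(attractor_scan(c(220, 40), pars, prot))
})
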