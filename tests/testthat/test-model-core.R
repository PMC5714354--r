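test_that("activation function is calibrated, monotone, and bounded", {
  p <- model_params()
  expect_equal(sigmoid_rate(p$v0, p), p$e0)          # half-maximum at v0
  expect_equal(sigmoid_rate(4, p), 1.230, tolerance = 1e-3)
  expect_equal(sigmoid_rate(1e6, p), 2 * p$e0)       # saturation
  V <- seq(-40, 40, by = 0.5)
  s <- sigmoid_rate(V, p)
  expect_true(all(diff(s) > 0))
  expect_true(all(s > 0 & s < 2 * p$e0))
  expect_true(all(sigmoid_rate(c(-1e6, 1e6), p) >= 0))
  expect_true(all(sigmoid_rate(c(-1e6, 1e6), p) <= 2 * p$e0))
  # slope matches numerical derivative of the rate
  num <- (sigmoid_rate(V + 1e-6, p) - sigmoid_rate(V - 1e-6, p)) / 2e-6
  expect_equal(sigmoid_slope(V, p), num, tolerance = 1e-6)
  expect_equal(sigmoid_inverse(sigmoid_rate(3.7, p), p), 3.7)
})

test_that("parameter validation rejects invalid values and unknown keys", {
  expect_error(model_params(tau_e = -0.01), "tau_e")
  expect_error(model_params(b1 = 1.5), "b1")
  expect_error(model_params(N_PP = -1), "N_PP")
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(He = 4, bogus_key = 1), f)
  expect_error(read_params(f), "bogus_key")
})

test_that("rhs implements the alpha-kernel channels", {
  p <- model_params()
  # the origin is not an equilibrium: S(0) > 0 feeds connected channels
  d0 <- circuit_rhs(rep(0, 10), 0, p)
  expect_true(any(abs(d0) > 1e-6))
  # decoupled single channel relaxes to H*tau*u: closed form
  pz <- model_params(N_EP = 0, N_PE = 0, N_IP = 0, N_PI = 0, N_PP = 0,
                     N_II = 0, b1 = 1)
  tr <- integrate_heun(pz, stimulus_protocol(100, 4.8, onset = 0,
                                             total_time = 4.8))
  expect_equal(tr$states[nrow(tr$states), 1], pz$He * pz$tau_e * 100,
               tolerance = 1e-6)
  expect_error(circuit_rhs(c(rep(0, 9), NaN), 0, p), "finite")
})

test_that("steady-state map fixed points are exactly the rhs equilibria", {
  for (p in list(model_params(), two_population(),
                 two_population_disinhibited())) {
    eq <- find_equilibria(0, p)
    for (i in seq_len(nrow(eq))) {
      V <- as.numeric(eq[i, paste0("V", 1:5)])
      expect_equal(steady_state_map(V, 0, p), V, tolerance = 1e-8)
      expect_lt(max(abs(circuit_rhs(c(V, rep(0, 5)), 0, p))), 1e-6)
    }
  }
  # iterating the map (damped) from the origin reaches the resting state
  p <- model_params()
  V <- rep(0, 5)
  for (k in 1:2000) V <- 0.9 * V + 0.1 * steady_state_map(V, 0, p)
  expect_equal(V[2] - V[3], -1.9038, tolerance = 1e-3)
})

test_that("analytic Jacobian agrees with central finite differences", {
  set.seed(7)
  pars <- list(model_params(), two_population(),
               two_population_disinhibited(), model_params(b1 = 0.4))
  for (p in pars) {
    for (k in 1:5) {
      x <- runif(10, -8, 12)
      J <- circuit_jacobian(x, p)
      Jfd <- fd_jacobian(x, 0, p)
      expect_equal(J, Jfd, tolerance = 1e-6)
    }
  }
})

test_that("zero-gain Jacobian is the critically damped kernel block", {
  pz <- model_params(N_EP = 0, N_PE = 0, N_IP = 0, N_PI = 0, N_PP = 0,
                     N_II = 0)
  ev <- eigen(circuit_jacobian(rep(0, 10), pz), only.values = TRUE)$values
  expect_equal(sort(unique(round(Re(ev), 6))),
               sort(-1 / c(pz$tau_i, pz$tau_e)))
  expect_true(all(abs(Im(ev)) < 1e-6))
})

test_that("resting equilibrium has a damped-oscillation eigenpair", {
  p <- model_params()
  eq <- find_equilibria(0, p)
  low <- eq[which.min(eq$V_Py), ]
  ev <- eigen(circuit_jacobian(c(as.numeric(low[paste0("V", 1:5)]),
                                 rep(0, 5)), p),
              only.values = TRUE)$values
  lead <- ev[order(-Re(ev))][1:2]
  expect_true(all(Re(lead) < 0))
  expect_true(all(abs(Im(lead)) > 1))   # complex pair, not overdamped
  expect_equal(lead[1], Conj(lead[2]))
})

test_that("architectural switches act as documented", {
  # b2 = 1: channel 5 has no input; started at V5 = W5 = 0 it stays there
  p <- model_params()
  tr <- run_protocol(120, 1, p)
  expect_true(all(tr$states[, 5] == 0))
  expect_true(all(tr$states[, 10] == 0))
  # continuity of the resting potential in b1 over [0, 1]
  b1s <- seq(0, 1, by = 0.05)
  vr <- vapply(b1s, function(b) {
    eq <- find_equilibria(0, model_params(b1 = b))
    min(eq$V_Py[eq$stable])
  }, numeric(1))
  expect_lt(max(abs(diff(vr))), 0.2)
  expect_equal(vr[1], -2.394, tolerance = 1e-3)
  expect_equal(vr[length(vr)], -1.9038, tolerance = 1e-3)
})
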