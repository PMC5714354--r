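test_that("equilibrium counts and locations match the dense-scan oracle", {
  # three-population defaults: S-shaped curve with 3 equilibria at rest,
  # a single upper-branch equilibrium under strong drive
  p <- model_params()
  eq0 <- find_equilibria(0, p)
  expect_equal(nrow(eq0), 3)
  expect_equal(sort(eq0$V_Py), sort(oracle_equilibria(0, p)),
               tolerance = 1e-6)
  expect_equal(min(eq0$V_Py[eq0$stable]), -1.9038, tolerance = 1e-3)
  eq200 <- find_equilibria(200, p)
  expect_equal(nrow(eq200), 1)
  expect_equal(eq200$V_Py, oracle_equilibria(200, p), tolerance = 1e-6)
  expect_true(eq200$stable)
  # degenerate decoupled case
  pz <- model_params(N_EP = 0, N_PE = 0, N_IP = 0, N_PI = 0, N_PP = 0,
                     N_II = 0)
  eqz <- find_equilibria(0, pz)
  expect_equal(nrow(eqz), 1)
  expect_equal(as.numeric(eqz[1, paste0("V", 1:5)]), rep(0, 5))
})

test_that("oracle equivalence holds across random parameterizations", {
  for (p in random_params(25)) {
    got <- find_equilibria(0, p)$V_Py
    want <- oracle_equilibria(0, p)
    expect_equal(length(got), length(want),
                 label = sprintf("count at He=%.2f Hi=%.2f b1=%g b2=%g",
                                 p$He, p$Hi, p$b1, p$b2))
    expect_equal(sort(got), sort(want), tolerance = 1e-5)
  }
})

test_that("default branch carries the documented bifurcation structure", {
  br <- continue_branch(model_params(), classify_hopf = TRUE)
  ev <- br$events
  expect_equal(sort(ev$type[grepl("FOLD", ev$type)]),
               c("FOLD_SN", "FOLD_SS"))
  expect_equal(ev$p_ext[ev$type == "FOLD_SN"], 78.25, tolerance = 0.01)
  expect_equal(ev$p_ext[ev$type == "FOLD_SS"], -29.91, tolerance = 0.01)
  hopf <- ev[grepl("HOPF", ev$type), ]
  expect_equal(nrow(hopf), 1)
  expect_equal(hopf$type, "HOPF_SUB")
  expect_equal(hopf$p_ext, -5.307, tolerance = 0.01)
  # consistency: stability labels match eigenvalues, folds sit at turning
  # points between them
  expect_true(all((br$points$max_re < 0) == br$points$stable))
})

test_that("Hopf points carry a pure-imaginary conjugate pair", {
  p <- model_params()
  br <- continue_branch(p)
  yh <- br$events$V_Py[grepl("HOPF", br$events$type)]
  b <- cmcircuit:::branch_states(yh, p)
  ev <- eigen(circuit_jacobian(c(b$V[1, ], rep(0, 5)), p),
              only.values = TRUE)$values
  pair <- ev[order(abs(Re(ev)))][1:2]
  expect_lt(max(abs(Re(pair))), 1e-4)
  expect_gt(min(abs(Im(pair))), 1)
  expect_equal(sort(Im(pair)), sort(-Im(pair)))
})

test_that("simulation confirms stability labels of equilibria", {
  p <- model_params()
  eq <- find_equilibria(0, p)
  for (i in seq_len(nrow(eq))) {
    x0 <- c(as.numeric(eq[i, paste0("V", 1:5)]), rep(0, 5))
    x0[2] <- x0[2] + 0.01
    tr <- integrate_heun(p, stimulus_protocol(0, 0, total_time = 4),
                         x0 = x0)
    dev <- abs(tr$v_py[length(tr$v_py)] - eq$V_Py[i])
    if (eq$stable[i]) expect_lt(dev, 1e-3) else expect_gt(dev, 0.1)
  }
})

test_that("bistability regimes separate the architectures", {
  expect_equal(bistability_check(model_params(), 0)$regime,
               "bistable_nodes")
  expect_equal(bistability_check(two_population(), 0)$regime, "monostable")
  pz <- model_params(N_EP = 0, N_PE = 0, N_IP = 0, N_PI = 0, N_PP = 0,
                     N_II = 0)
  expect_equal(bistability_check(pz, 0)$regime, "monostable")
})

test_that("memory labels imply coexisting attractors at rest", {
  # cross-module consistency on a small He-Hi subgrid
  He_grid <- seq(2.5, 4.5, length.out = 5)
  Hi_grid <- seq(14, 30, length.out = 5)
  m <- dynamic_function_map(He_grid, Hi_grid, model_params(),
                            intensities = seq(80, 250, length.out = 5),
                            durations = seq(0.5, 1.5, length.out = 5))
  for (i in seq_along(He_grid)) for (j in seq_along(Hi_grid)) {
    if (!grepl("MEMORY", m$labels[i, j])) next
    bc <- bistability_check(cmcircuit:::with_gains(model_params(),
                                                   He_grid[i], Hi_grid[j]))
    expect_true(bc$regime != "monostable",
                label = sprintf("He=%.2f Hi=%.2f labelled %s but %s",
                                He_grid[i], Hi_grid[j], m$labels[i, j],
                                bc$regime))
  }
})

test_that("the two-population fold locus splits from saddle-node to saddle-saddle", {
  loc <- trace_codim2(two_population(), "upper", Hi_values = seq(3, 8, 0.5))
  expect_true(all(loc$fold_type[loc$Hi <= 4] == "FOLD_SN"))
  expect_true(all(loc$fold_type[loc$Hi >= 4.5] == "FOLD_SS"))
  sp <- attr(loc, "splits")
  expect_equal(nrow(sp), 1)
  expect_equal(sp$Hi, 4.40, tolerance = 0.05)
  # locus points satisfy the defining conditions: fold at p_ext = 0
  for (k in c(1, nrow(loc))) {
    p <- cmcircuit:::with_gains(two_population(), loc$He[k], loc$Hi[k])
    f <- cmcircuit:::named_fold(p, "upper")
    expect_lt(abs(f$p_ext), 1e-5)
    ev <- eigen(circuit_jacobian(
      c(cmcircuit:::branch_states(f$y, p)$V[1, ], rep(0, 5)), p),
      only.values = TRUE)$values
    expect_lt(min(abs(Re(ev))), 1e-3)    # singular direction at the fold
  }
})

test_that("disinhibition sweep reduces to the plain two-population model at N_II = 0", {
  sw <- nii_sweep(c(0, 33.25), p_ext_range = c(-100, 400))
  ref <- continue_branch(two_population(), p_ext_range = c(-100, 400))
  expect_equal(sw[["0"]]$p_ext, ref$events$p_ext, tolerance = 1e-8)
  expect_equal(sw[["0"]]$type, ref$events$type)
  # at the default self-feedback level the fold pair persists and the upper
  # branch beyond the fold is stable
  ev <- sw[["33.25"]]
  expect_equal(sum(grepl("FOLD", ev$type)), 2)
  expect_true("FOLD_SN" %in% ev$type[ev$V_Py > 4])
  expect_error(nii_sweep(10, params = two_population()), "b1 = 0, b2 = 0")
})

test_that("bifurcation locations vary continuously along the N_II sweep", {
  # the fold pair is born at intermediate self-feedback (absent in the plain
  # two-population limit) and then drifts smoothly with N_II
  sw0 <- nii_sweep(0, p_ext_range = c(-200, 500))
  expect_false(any(grepl("FOLD", sw0[["0"]]$type)))
  nii <- seq(15, 33.25, length.out = 12)
  sw <- nii_sweep(nii, p_ext_range = c(-200, 500))
  lower <- vapply(sw, function(ev) max(ev$p_ext[grepl("FOLD", ev$type)]),
                  numeric(1))
  upper <- vapply(sw, function(ev) min(ev$p_ext[grepl("FOLD", ev$type)]),
                  numeric(1))
  expect_true(all(is.finite(lower)) && all(is.finite(upper)))
  expect_lt(max(abs(diff(lower))), 10)
  expect_lt(max(abs(diff(upper))), 20)
})
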