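two_node_spec <- function(gain = 20, sign = "excitatory") {
  network_spec(
    data.frame(name = c("A", "B"), module = c("S", "V")),
    data.frame(from = "A", to = "B", sign = sign, gain = gain))
}

test_that("a decoupled node reproduces the single-circuit integrator bit-exactly", {
  spec <- network_spec(data.frame(name = "solo", module = "S"))
  sched <- word_schedule("solo", onset = 1, duration = 1, intensity = 120)
  net <- simulate_network(spec, sched, total_time = 5)
  tr <- run_protocol(120, 1, model_params())
  expect_identical(as.numeric(net$vpy[, "solo"]), as.numeric(tr$v_py))
})

test_that("network specs are validated", {
  nodes <- data.frame(name = c("A", "B"), module = c("S", "V"))
  expect_error(network_spec(nodes,
                            data.frame(from = "A", to = "C",
                                       sign = "excitatory", gain = 1)),
               "unknown node")
  expect_error(network_spec(nodes,
                            data.frame(from = "A", to = "B", sign = "weird",
                                       gain = 1)), "sign")
  expect_error(network_spec(rbind(nodes, nodes)), "unique")
})

test_that("isolated pulses drive only the stimulated node into memory", {
  spec <- network_spec(data.frame(name = c("A", "B"), module = c("S", "V")))
  sched <- word_schedule("A", onset = 1, duration = 1.2, intensity = 120)
  net <- simulate_network(spec, sched, total_time = 6)
  expect_true(net$final_active[["A"]])
  expect_false(net$final_active[["B"]])
})

test_that("pre-activation shifts the downstream baseline without activating it", {
  sched <- word_schedule("A", onset = 1, duration = 1.2, intensity = 120)
  base <- simulate_network(two_node_spec(0), sched, total_time = 6)
  expect_equal(preactivation_level("B", base, c(5, 6)), 0, tolerance = 1e-3)
  shifts <- vapply(c(2, 5, 10, 18, 26), function(g) {
    net <- simulate_network(two_node_spec(g), sched, total_time = 6)
    preactivation_level("B", net, c(5, 6))
  }, numeric(1))
  expect_true(all(diff(shifts) > 0))          # monotone in the edge gain
  expect_true(all(shifts > 0 & shifts < 4 + 1.9038))  # below threshold
  # active node: measurement undefined
  netA <- simulate_network(two_node_spec(20), sched, total_time = 6)
  expect_error(preactivation_level("A", netA, c(5, 6)), "active")
})

test_that("gating: a subthreshold word activates only when pre-activated", {
  sched_both <- word_schedule(c("A", "B"), onset = c(1, 3),
                              duration = 1.2, intensity = c(120, 60))
  alone <- simulate_network(two_node_spec(0),
                            word_schedule("B", 3, 1.2, 60), total_time = 7)
  expect_false(alone$final_active[["B"]])
  primed <- simulate_network(two_node_spec(20), sched_both, total_time = 7)
  expect_true(primed$final_active[["B"]])
})

test_that("the sentence demo resolves the ambiguity by context", {
  hi <- sentence_demo("high")
  lo <- sentence_demo("low")
  ph <- simulate_network(hi$spec, hi$schedule, seed = 1)
  pl <- simulate_network(lo$spec, lo$schedule, seed = 1)
  expect_equal(ph$outcome, "interpretation_A")
  expect_equal(pl$outcome, "interpretation_B")
  core <- c("I", "hit", "the_thief", "the_club")
  expect_true(all(ph$final_active[core]))
  expect_true(all(pl$final_active[core]))
  # winner-take-all: exactly one modifier survives at every context level
  for (off in c(0, 15, 30, 45, 60)) {
    d <- sentence_demo("high")
    d$spec$context$offset <- off
    d$spec$context$sd <- 0.1 * off
    res <- simulate_network(d$spec, d$schedule, seed = 3)
    expect_equal(sum(res$final_active[c("with_vmod", "with_omod")]), 1,
                 label = sprintf("context offset %g", off))
  }
})

test_that("network runs are reproducible given the seed", {
  d <- sentence_demo("high")
  a <- simulate_network(d$spec, d$schedule, seed = 9)
  b <- simulate_network(d$spec, d$schedule, seed = 9)
  expect_identical(a$vpy, b$vpy)
})

test_that("an inhibitory bias of the balance breaks the parse", {
  d <- sentence_demo("high")
  res <- balance_perturbation(d$spec, d$schedule, c(22, 23, 24), seed = 1)
  expect_equal(res[["22"]]$outcome, "interpretation_A")
  expect_true(res[["23"]]$outcome %in% c("defective", "memory_loss"))
  expect_true(res[["24"]]$outcome %in% c("defective", "memory_loss"))
})

test_that("parse outcomes are a pure function of the activation bits", {
  d <- sentence_demo("high")
  spec <- d$spec
  bits <- setNames(rep(TRUE, 6), spec$nodes$name)
  b1 <- bits; b1[c("with_vmod")] <- FALSE
  expect_equal(parse_outcome(b1, spec), "interpretation_A")
  b2 <- bits; b2[c("with_omod")] <- FALSE
  expect_equal(parse_outcome(b2, spec), "interpretation_B")
  expect_equal(parse_outcome(bits, spec), "defective")       # both modifiers
  expect_equal(parse_outcome(!bits, spec), "memory_loss")
  b3 <- b1; b3["hit"] <- FALSE
  expect_equal(parse_outcome(b3, spec), "defective")
})
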