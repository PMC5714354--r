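# Independent oracles, coded directly from the model algebra (no package
# continuation/Newton internals).

# dense 1-D scan for equilibria at fixed drive: reduce the 5-D steady state
# to a scalar residual in y = V_Py and count sign changes
oracle_equilibria <- function(p_ext, p, y_grid = seq(-60, 40, by = 0.02)) {
  sig <- function(V) 2 * p$e0 / (1 + exp(p$r * (p$v0 - V)))
  resid <- function(y) {
    phiP <- sig(y)
    V4 <- p$He * p$tau_e * (p$N_IP * phiP)
    V5 <- if (p$b2 == 1) 0 else
      uniroot(function(v) v - (1 - p$b2) * p$Hi * p$tau_i * p$N_II *
                sig(V4 - v),
              c(0, (1 - p$b2) * p$Hi * p$tau_i * p$N_II * 2 * p$e0 + 1),
              tol = 1e-12)$root
    phiI <- sig(V4 - V5)
    V3 <- p$Hi * p$tau_i * p$N_PI * phiI
    V2 <- y + V3
    V1 <- p$He * p$tau_e * (p$N_EP * phiP + p$b1 * p_ext)
    V2 - p$He * p$tau_e * (p$b1 * p$N_PE * sig(V1) +
                             (1 - p$b1) * p$N_PP * phiP +
                             (1 - p$b1) * p_ext)
  }
  g <- vapply(y_grid, resid, numeric(1))
  idx <- which(diff(sign(g)) != 0)
  vapply(idx, function(i)
    uniroot(resid, c(y_grid[i], y_grid[i + 1]), tol = 1e-11)$root,
    numeric(1))
}

# central finite differences of circuit_rhs
fd_jacobian <- function(state, p_ext, p, h = 1e-6) {
  J <- matrix(0, 10, 10)
  for (j in 1:10) {
    e <- numeric(10); e[j] <- h
    J[, j] <- (circuit_rhs(state + e, p_ext, p) -
                 circuit_rhs(state - e, p_ext, p)) / (2 * h)
  }
  J
}

# random but reproducible parameter draws spanning the studied architectures
random_params <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    model_params(He = runif(1, 1.5, 7), Hi = runif(1, 3, 40),
                 b1 = sample(c(0, 1), 1), b2 = sample(c(0, 1), 1)))
}
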