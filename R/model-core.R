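#' Logistic activation function and its derivatives
#'
#' Converts a mean membrane potential (mV) into a mean firing rate (s^-1)
#' through the logistic sigmoid `2 e0 / (1 + exp(r (v0 - V)))`.  The output
#' lies strictly in `(0, 2 e0)`; the exponent is clamped to +/-500 so the
#' function is total over all finite doubles (the clamp is unreachable for
#' any membrane potential of physiological magnitude).
#'
#' @param V membrane potential (mV); vectorized.
#' @param params a [model_params()] object (only `e0`, `r`, `v0` are used).
#' @return Firing rate(s) in s^-1.
#' @examples
#' p <- model_params()
#' sigmoid_rate(p$v0, p)       # half-maximum: e0 = 2.5 /s
#' sigmoid_rate(4, p) / (2 * p$e0)  # ~24.6% of maximum at the 4 mV threshold
#' @export
sigmoid_rate <- function(V, params) {
  z <- params$r * (params$v0 - V)
  2 * params$e0 / (1 + exp(pmin(pmax(z, -500), 500)))
}

#' @rdname sigmoid_rate
#' @export
sigmoid_slope <- function(V, params) {
  s <- sigmoid_rate(V, params)
  params$r * s * (1 - s / (2 * params$e0))
}

#' @rdname sigmoid_rate
#' @param phi firing rate(s) in `(0, 2 e0)` to invert.
#' @export
sigmoid_inverse <- function(phi, params) {
  if (any(phi <= 0 | phi >= 2 * params$e0))
    stop("firing rate outside the open range (0, 2*e0)")
  params$v0 - log(2 * params$e0 / phi - 1) / params$r
}

# per-channel kernel constants: H, tau for channels 1..5
channel_kernels <- function(params) {
  list(H = c(params$He, params$He, params$Hi, params$He, params$Hi),
       tau = c(params$tau_e, params$tau_e, params$tau_i, params$tau_e,
               params$tau_i))
}

# total synaptic input u_c to each of the five channels
channel_inputs <- function(V, p_ext, p_iin, params) {
  phiP <- sigmoid_rate(V[2] - V[3], params)
  phiE <- sigmoid_rate(V[1], params)
  phiI <- sigmoid_rate(V[4] - V[5], params)
  b1 <- params$b1
  c(params$N_EP * phiP + b1 * p_ext,
    b1 * params$N_PE * phiE + (1 - b1) * params$N_PP * phiP +
      (1 - b1) * p_ext,
    params$N_PI * phiI,
    params$N_IP * phiP + p_iin,
    (1 - params$b2) * params$N_II * phiI)
}

#' Right-hand side of the microcircuit ODE system
#'
#' The five second-order synaptic channels, each governed by the critically
#' damped alpha-kernel operator, are written as ten first-order equations in
#' the state `(V1..V5, W1..W5)` with `W = dV/dt`.  For a channel with kernel
#' gain `H`, time constant `tau`, and total input `u`:
#' `dV/dt = W`, `dW/dt = (H/tau) u - (2/tau) W - V/tau^2`.
#'
#' The pyramidal output potential is `V_Py = V2 - V3`; the EIN potential is
#' `V1` and the IIN potential `V4 - V5`.
#'
#' @param state numeric length-10 state vector `(V1..V5, W1..W5)`.
#' @param p_ext external firing-rate drive (s^-1), routed by `b1` between the
#'   EIN channel and the Py channel.
#' @param p_iin optional external drive to the IIN (s^-1), used by
#'   reset/deactivation experiments.
#' @param params a [model_params()] object.
#' @return The length-10 time derivative of `state`.
#' @export
circuit_rhs <- function(state, p_ext, params, p_iin = 0) {
  if (length(state) != 10L) stop("state must have 10 components")
  if (!all(is.finite(state))) stop("non-finite state (numerical blow-up?)")
  V <- state[1:5]; W <- state[6:10]
  u <- channel_inputs(V, p_ext, p_iin, params)
  k <- channel_kernels(params)
  c(W, (k$H / k$tau) * u - (2 / k$tau) * W - V / k$tau^2)
}

#' Steady-state map of the five membrane potentials
#'
#' At equilibrium each channel's operator reduces to multiplication by
#' `1/(H tau)`, so the potentials satisfy the algebraic fixed-point map
#' `V* = H tau u(V*)`.  Fixed points of this map are exactly the equilibria
#' of [circuit_rhs()] (with all derivatives `W = 0`).
#'
#' @param V numeric length-5 vector of channel potentials `(V1..V5)`.
#' @inheritParams circuit_rhs
#' @return The mapped length-5 potential vector.
#' @export
steady_state_map <- function(V, p_ext, params, p_iin = 0) {
  if (length(V) != 5L) stop("V must have 5 components")
  u <- channel_inputs(V, p_ext, p_iin, params)
  k <- channel_kernels(params)
  k$H * k$tau * u
}

#' Analytic Jacobian of the microcircuit
#'
#' Returns the 10x10 derivative matrix of [circuit_rhs()] with respect to the
#' state, evaluated at `state`.  Sigmoid terms use
#' `S'(V) = r S(V) (1 - S(V)/(2 e0))`.  Used for linear stability analysis
#' of equilibria (eigenvalues) and for bifurcation test functions.
#'
#' @inheritParams circuit_rhs
#' @return A 10x10 numeric matrix, rows/cols ordered `(V1..V5, W1..W5)`.
#' @export
circuit_jacobian <- function(state, params) {
  if (length(state) != 10L) stop("state must have 10 components")
  V <- state[1:5]
  spP <- sigmoid_slope(V[2] - V[3], params)
  spE <- sigmoid_slope(V[1], params)
  spI <- sigmoid_slope(V[4] - V[5], params)
  b1 <- params$b1; b2 <- params$b2
  dU <- matrix(0, 5, 5)   # dU[c, j] = du_c / dV_j
  dU[1, 2] <- params$N_EP * spP;              dU[1, 3] <- -dU[1, 2]
  dU[2, 1] <- b1 * params$N_PE * spE
  dU[2, 2] <- (1 - b1) * params$N_PP * spP;   dU[2, 3] <- -dU[2, 2]
  dU[3, 4] <- params$N_PI * spI;              dU[3, 5] <- -dU[3, 4]
  dU[4, 2] <- params$N_IP * spP;              dU[4, 3] <- -dU[4, 2]
  dU[5, 4] <- (1 - b2) * params$N_II * spI;   dU[5, 5] <- -dU[5, 4]
  k <- channel_kernels(params)
  A <- (k$H / k$tau) * dU - diag(1 / k$tau^2)
  rbind(cbind(matrix(0, 5, 5), diag(5)),
        cbind(A, diag(-2 / k$tau)))
}

#' Pyramidal output potential of a state or state matrix
#'
#' @param state length-10 state vector or an n x 10 state matrix.
#' @return `V2 - V3`, a scalar or vector of pyramidal membrane potentials (mV).
#' @export
v_py <- function(state) {
  if (is.matrix(state)) state[, 2] - state[, 3] else state[2] - state[3]
}
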