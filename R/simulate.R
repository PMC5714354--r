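#' Stimulus protocols
#'
#' A protocol is a set of piecewise-constant rectangular drive segments, each
#' targeting either the circuit's afferent route (`"p_ext"`, routed by `b1`
#' between EIN and Py) or the inhibitory interneurons (`"p_iin"`).  Segment
#' boundaries follow the half-open convention `[onset, onset + duration)` on
#' the discrete time grid.  The default single-pulse protocol applies one
#' rectangular `p_ext` pulse after a 1 s settling period within a 5 s run.
#'
#' @param intensity pulse intensity (s^-1).
#' @param duration pulse duration (s).
#' @param onset pulse onset (s).
#' @param total_time total simulated time (s).
#' @param segments optional data frame with columns `target`, `onset`,
#'   `duration`, `intensity` overriding the single-pulse arguments.
#' @return An object of class `cm_protocol`.
#' @export
stimulus_protocol <- function(intensity = 0, duration = 0, onset = 1,
                              total_time = 5, segments = NULL) {
  if (is.null(segments)) {
    segments <- data.frame(target = "p_ext", onset = onset,
                           duration = duration, intensity = intensity,
                           stringsAsFactors = FALSE)
  }
  stopifnot(all(c("target", "onset", "duration", "intensity") %in%
                  names(segments)))
  if (!all(segments$target %in% c("p_ext", "p_iin")))
    stop("segment target must be 'p_ext' or 'p_iin'")
  if (any(segments$onset < 0) || any(segments$duration < 0))
    stop("onsets and durations must be non-negative")
  if (any(segments$intensity < 0))
    stop("simulation protocols use non-negative intensities")
  structure(list(segments = segments, total_time = total_time),
            class = "cm_protocol")
}

# per-step drive vectors on a grid of n points spaced dt
drive_vectors <- function(proto, dt, n) {
  t <- (seq_len(n) - 1L) * dt
  p_ext <- numeric(n); p_iin <- numeric(n)
  for (i in seq_len(nrow(proto$segments))) {
    s <- proto$segments[i, ]
    on <- t >= s$onset & t < s$onset + s$duration
    if (s$target == "p_ext") p_ext[on] <- p_ext[on] + s$intensity
    else p_iin[on] <- p_iin[on] + s$intensity
  }
  list(t = t, p_ext = p_ext, p_iin = p_iin)
}

#' Integrate one microcircuit with Heun's method
#'
#' Explicit two-stage Heun scheme (Euler predictor, trapezoidal corrector)
#' with a fixed step, the integration scheme under which this model family
#' is routinely studied.  Drives are evaluated as piecewise-constant per step
#' and held frozen through both stages.  Optional Gaussian noise on the
#' afferent drive is sampled once per step (frozen-noise stochastic Heun),
#' floored so the total drive stays non-negative, and is reproducible given
#' `seed`.
#'
#' @param params a [model_params()] object.
#' @param protocol a [stimulus_protocol()].
#' @param x0 initial length-10 state; defaults to the zero vector.
#' @param dt integration step (s); default 1 ms.
#' @param noise optional `list(mean =, sd =)` Gaussian perturbation of the
#'   afferent drive, resampled each step.
#' @param seed optional integer seed used when `noise` is given.
#' @return A `cm_trajectory`: list with the time grid `t`, the n x 10 state
#'   matrix `states`, the pyramidal potential `v_py`, the applied drives, and
#'   metadata.
#' @export
integrate_heun <- function(params, protocol = stimulus_protocol(),
                           x0 = rep(0, 10), dt = 1e-3, noise = NULL,
                           seed = NULL) {
  stopifnot(inherits(params, "cm_params"))
  if (dt <= 0) stop("dt must be positive")
  if (length(x0) != 10L || !all(is.finite(x0)))
    stop("x0 must be a finite length-10 state")
  n <- as.integer(round(protocol$total_time / dt)) + 1L
  d <- drive_vectors(protocol, dt, n)
  if (!is.null(noise)) {
    if (!is.null(seed)) set.seed(seed)
    d$p_ext <- pmax(0, d$p_ext + stats::rnorm(n, noise$mean, noise$sd))
  }
  states <- heun_circuit_cpp(x0, as_par_vector(params), d$p_ext, d$p_iin, dt)
  structure(list(t = d$t, states = states, v_py = states[, 2] - states[, 3],
                 p_ext = d$p_ext, p_iin = d$p_iin, dt = dt, params = params,
                 protocol = protocol),
            class = "cm_trajectory")
}

#' Run the standard single-pulse stimulation protocol
#'
#' Convenience wrapper: a 5 s run with 1 s settling time followed by one
#' rectangular afferent pulse of the given intensity and duration, integrated
#' from the zero state.
#'
#' @param intensity pulse intensity (s^-1).
#' @param duration pulse duration (s).
#' @param params a [model_params()] object.
#' @param ... further arguments passed to [integrate_heun()].
#' @return A `cm_trajectory`.
#' @examples
#' \donttest{
#' tr <- run_protocol(100, 1, model_params())
#' max(tr$v_py)   # exceeds the 4 mV firing threshold during the pulse
#' }
#' @export
run_protocol <- function(intensity, duration, params, ...) {
  if (intensity < 0 || duration < 0)
    stop("intensity and duration must be non-negative")
  integrate_heun(params,
                 stimulus_protocol(intensity = intensity, duration = duration),
                 ...)
}

#' @export
print.cm_trajectory <- function(x, ...) {
  cat(sprintf("cm_trajectory: %.3g s at dt = %g ms (%d samples)\n",
              max(x$t), 1000 * x$dt, length(x$t)))
  cat(sprintf("  V_Py range [%.3f, %.3f] mV, terminal %.3f mV\n",
              min(x$v_py), max(x$v_py), x$v_py[length(x$v_py)]))
  invisible(x)
}

#' @export
as.data.frame.cm_trajectory <- function(x, ...) {
  p <- x$params
  data.frame(t = x$t,
             V1 = x$states[, 1], V2 = x$states[, 2], V3 = x$states[, 3],
             V4 = x$states[, 4], V5 = x$states[, 5],
             V_Py = x$v_py,
             phi_P = sigmoid_rate(x$v_py, p),
             phi_E = sigmoid_rate(x$states[, 1], p),
             phi_I = sigmoid_rate(x$states[, 4] - x$states[, 5], p))
}

#' Export a trajectory as CSV
#'
#' Columns: `t, V1..V5, V_Py, phi_P, phi_E, phi_I`.
#'
#' @param traj a `cm_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
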