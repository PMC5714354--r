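#' @name bifurcation
#' @title Equilibrium curves, folds, and Hopf points of the microcircuit
#'
#' @description
#' At steady state every channel satisfies `V = H tau u(V)`, and the external
#' drive enters the channel inputs monotonically.  The equilibrium curve of
#' the circuit can therefore be parameterized globally by the pyramidal
#' potential `y = V_Py`: given `y`, the remaining potentials follow in closed
#' form (for `b2 = 0` after solving one scalar fixed point for the IIN
#' self-feedback channel), and the drive `p_ext(y)` that holds the circuit at
#' that equilibrium is recovered by inverting the pyramidal channel.
#' Continuation along the branch reduces to a dense sweep in `y` with root
#' refinement — no step-size control or corrector iterations are needed, and
#' folds are exactly the turning points of `p_ext(y)`.
NULL

# Solve the IIN self-feedback channel's scalar steady state
#   V5 = (1-b2) Hi tau_i N_II S(V4 - V5)
# for a vector of V4 values.  The residual has slope >= 1, so undamped
# Newton converges from any start.
solve_v5 <- function(V4, params) {
  cc <- (1 - params$b2) * params$Hi * params$tau_i * params$N_II
  if (cc == 0) return(rep(0, length(V4)))
  V5 <- rep(cc * params$e0, length(V4))
  for (k in 1:80) {
    f <- V5 - cc * sigmoid_rate(V4 - V5, params)
    fp <- 1 + cc * sigmoid_slope(V4 - V5, params)
    step <- f / fp
    V5 <- V5 - step
    if (max(abs(step)) < 1e-13) break
  }
  V5
}

# Equilibrium states along the branch, parameterized by y = V_Py.
# Returns p_ext(y) and the 5 potentials; entries are NA where no finite
# drive supports an equilibrium with that V_Py (only possible for b1 = 1,
# where the EIN firing rate required of channel 2 leaves (0, 2 e0)).
branch_states <- function(y, params) {
  he_te <- params$He * params$tau_e
  phiP <- sigmoid_rate(y, params)
  V4 <- he_te * params$N_IP * phiP
  V5 <- solve_v5(V4, params)
  phiI <- sigmoid_rate(V4 - V5, params)
  V3 <- params$Hi * params$tau_i * params$N_PI * phiI
  V2 <- y + V3
  b1 <- params$b1
  if (b1 == 0) {
    p_ext <- V2 / he_te - params$N_PP * phiP
    V1 <- he_te * params$N_EP * phiP
  } else if (b1 == 1) {
    phiE <- V2 / (he_te * params$N_PE)
    ok <- phiE > 0 & phiE < 2 * params$e0
    V1 <- rep(NA_real_, length(y))
    V1[ok] <- sigmoid_inverse(phiE[ok], params)
    p_ext <- V1 / he_te - params$N_EP * phiP
  } else {
    # intermediate b1: V1 couples to p_ext; solve the monotone scalar
    # residual of channel 2 per point
    V1 <- p_ext <- rep(NA_real_, length(y))
    for (i in seq_along(y)) {
      g <- function(p) {
        v1 <- he_te * (params$N_EP * phiP[i] + b1 * p)
        he_te * (b1 * params$N_PE * sigmoid_rate(v1, params) +
                   (1 - b1) * (params$N_PP * phiP[i] + p)) - V2[i]
      }
      lo <- -1e4; hi <- 1e4
      r <- tryCatch(stats::uniroot(g, c(lo, hi), tol = 1e-11),
                    error = function(e) NULL)
      if (!is.null(r)) {
        p_ext[i] <- r$root
        V1[i] <- he_te * (params$N_EP * phiP[i] + b1 * r$root)
      }
    }
  }
  list(y = y, p_ext = p_ext, V = cbind(V1 = V1, V2 = V2, V3 = V3,
                                       V4 = V4, V5 = V5))
}

# scalar p_ext(y); NA where undefined
branch_pext <- function(y, params) branch_states(y, params)$p_ext

eig_at <- function(V, params) {
  eigen(circuit_jacobian(c(V, rep(0, 5)), params), only.values = TRUE)$values
}

# Fold type from the eigenvalues at the fold itself: discard the eigenvalue
# closest to zero (the fold eigenvalue); saddle-node if every remaining
# eigenvalue is stable, saddle-saddle otherwise.
fold_type_at <- function(y, params) {
  b <- branch_states(y, params)
  ev <- eig_at(b$V[1, ], params)
  rest <- ev[-which.min(abs(ev))]
  if (max(Re(rest)) < 0) "FOLD_SN" else "FOLD_SS"
}

# max real part over eigenvalues with appreciable imaginary part (the Hopf
# test function); -Inf when no complex pair exists at the point
max_re_complex <- function(y, params, im_tol = 1e-4) {
  b <- branch_states(y, params)
  ev <- eig_at(b$V[1, ], params)
  cplx <- ev[abs(Im(ev)) > im_tol]
  if (!length(cplx)) -Inf else max(Re(cplx))
}

#' Continue the equilibrium branch along the external drive
#'
#' Sweeps the pyramidal potential over `y_range`, evaluates the closed-form
#' equilibrium and its 10-dimensional Jacobian eigenvalues at each point, and
#' detects bifurcations: folds as sign changes of `dp_ext/dy` (refined with
#' [stats::optimize()] and typed as saddle-node or saddle-saddle from the
#' non-fold eigenvalues at the fold), and Hopf points as zero crossings of
#' the largest real part among complex eigenvalue pairs (refined by
#' bisection to well below 0.01 s^-1 in `p_ext`).  Hopf criticality is
#' determined by simulation probing on the unstable side (see
#' [hopf_criticality()]).
#'
#' @param params a [model_params()] object.
#' @param p_ext_range drive interval of interest (s^-1); points and events
#'   outside it are dropped.
#' @param y_range range of pyramidal potentials swept (mV).
#' @param n number of sweep points.
#' @param classify_hopf logical; probe sub/supercriticality of detected Hopf
#'   points by simulation (costs a few seconds per point).
#' @return A `cm_branch`: list with `points` (data frame `y`, `p_ext`,
#'   `V1..V5`, `max_re`, `stable`) and `events` (data frame `type`
#'   (`FOLD_SN`, `FOLD_SS`, `HOPF_SUB`, `HOPF_SUPER`, `HOPF`), `p_ext`,
#'   `V_Py`, `method`).
#' @examples
#' \donttest{
#' br <- continue_branch(model_params())   # lower fold near p_ext = 78 /s
#' br$events
#' }
#' @export
continue_branch <- function(params, p_ext_range = c(-60, 300),
                            y_range = c(-60, 40), n = 4001,
                            classify_hopf = FALSE) {
  ys <- seq(y_range[1], y_range[2], length.out = n)
  b <- branch_states(ys, params)
  ok <- which(is.finite(b$p_ext))
  if (!length(ok)) stop("no equilibria found in y_range")
  ys <- ys[ok]; pex <- b$p_ext[ok]; V <- b$V[ok, , drop = FALSE]
  ev <- lapply(seq_along(ys), function(i) eig_at(V[i, ], params))
  max_re <- vapply(ev, function(e) max(Re(e)), numeric(1))
  pts <- data.frame(y = ys, p_ext = pex, V, max_re = max_re,
                    stable = max_re < 0)

  events <- list()
  # folds: turning points of p_ext(y); ignore sign changes across gaps in
  # the valid y-range
  step <- (y_range[2] - y_range[1]) / (n - 1)
  dp <- diff(pex)
  contig <- diff(ys) < 1.5 * step
  fi <- which(diff(sign(dp)) != 0 & contig[-1] & contig[-length(contig)])
  for (i in fi) {
    lo <- ys[max(1, i - 1)]; hi <- ys[min(length(ys), i + 2)]
    o <- stats::optimize(function(y) branch_pext(y, params),
                         c(lo, hi), maximum = dp[i] > 0, tol = 1e-10)
    yf <- if (dp[i] > 0) o$maximum else o$minimum
    events[[length(events) + 1]] <-
      data.frame(type = fold_type_at(yf, params), p_ext = o$objective,
                 V_Py = yf, method = "eigenvalues_at_fold")
  }
  # Hopf: zero crossings of the complex-pair test function, excluding
  # crossings that coincide with a fold (where a complex pair forms)
  h <- vapply(seq_along(ys), function(i) {
    cplx <- ev[[i]][abs(Im(ev[[i]])) > 1e-4]
    if (!length(cplx)) -Inf else max(Re(cplx))
  }, numeric(1))
  hi_idx <- which(is.finite(h[-1]) & is.finite(h[-length(h)]) &
                    diff(sign(h)) != 0)
  fold_y <- vapply(events, function(e) e$V_Py, numeric(1))
  for (i in hi_idx) {
    if (length(fold_y) && min(abs(ys[i] - fold_y)) < 4 * mean(diff(ys)))
      next
    r <- tryCatch(stats::uniroot(function(y) max_re_complex(y, params),
                                 c(ys[i], ys[i + 1]), tol = 1e-11),
                  error = function(e) NULL)
    if (is.null(r)) next
    bh <- branch_states(r$root, params)
    evh <- eig_at(bh$V[1, ], params)
    pair <- evh[abs(Im(evh)) > 1e-4]
    if (!length(pair) || min(abs(Re(pair))) > 1e-3 * max(1, abs(bh$p_ext)))
      next
    type <- "HOPF"; method <- "eigenvalue_crossing"
    if (classify_hopf) {
      cr <- hopf_criticality(r$root, params)
      type <- if (cr == "subcritical") "HOPF_SUB" else "HOPF_SUPER"
      method <- "simulation_probe"
    }
    events[[length(events) + 1]] <-
      data.frame(type = type, p_ext = bh$p_ext, V_Py = r$root,
                 method = method)
  }
  events <- if (length(events)) do.call(rbind, events)
            else data.frame(type = character(), p_ext = numeric(),
                            V_Py = numeric(), method = character())
  keep <- pts$p_ext >= p_ext_range[1] & pts$p_ext <= p_ext_range[2]
  events <- events[events$p_ext >= p_ext_range[1] &
                     events$p_ext <= p_ext_range[2], , drop = FALSE]
  structure(list(points = pts[keep, , drop = FALSE], events = events,
                 params = params),
            class = "cm_branch")
}

#' @export
print.cm_branch <- function(x, ...) {
  cat(sprintf("cm_branch: %d equilibria, p_ext in [%.2f, %.2f] /s\n",
              nrow(x$points), min(x$points$p_ext), max(x$points$p_ext)))
  if (nrow(x$events)) print(x$events) else cat("  no bifurcation events\n")
  invisible(x)
}

#' Sub/supercritical classification of a Hopf point by simulation probing
#'
#' Integrates from a small perturbation of the equilibrium just on the
#' unstable side of the Hopf point.  If the trajectory settles into a
#' small-amplitude limit cycle around the equilibrium the Hopf is
#' supercritical; if it escapes the neighbourhood (toward a distant
#' attractor) it is subcritical.  Normal-form coefficients of the
#' 10-dimensional system are avoided deliberately; only the qualitative
#' label is needed.
#'
#' @param y_hopf pyramidal potential of the Hopf equilibrium (mV).
#' @param params a [model_params()] object.
#' @param delta_y offset (mV) along the branch used to pick the probe point
#'   on the unstable side.
#' @return `"subcritical"` or `"supercritical"`.
#' @export
hopf_criticality <- function(y_hopf, params, delta_y = 0.05) {
  side <- if (max_re_complex(y_hopf - delta_y, params) > 0) -1 else 1
  yp <- y_hopf + side * delta_y
  b <- branch_states(yp, params)
  x0 <- c(b$V[1, ], rep(0, 5)); x0[2] <- x0[2] + 0.01
  # hold the drive at the probe equilibrium's value for 10 s
  n <- 10001L
  pex <- rep(b$p_ext[1], n)
  states <- heun_circuit_cpp(x0, as_par_vector(params), pex, numeric(n), 1e-3)
  vpy <- states[, 2] - states[, 3]
  tail_dev <- max(abs(vpy[8001:n] - yp))
  if (tail_dev > 1) "subcritical" else "supercritical"
}

#' Locate all equilibria at a fixed external drive
#'
#' Damped Newton iteration on the five-dimensional steady-state residual
#' `V - H tau u(V)`, started from a deterministic grid of points along the
#' closed-form branch plus optional random starts; converged solutions are
#' de-duplicated and equipped with the eigenvalues of the full
#' 10-dimensional Jacobian.  The sigmoid is bounded, so at least one
#' equilibrium always exists; an empty result is an error.
#'
#' @param p_ext external drive (s^-1).
#' @param params a [model_params()] object.
#' @param n_starts number of random starts added to the deterministic grid.
#' @param seed optional seed for the random starts.
#' @return A data frame, one row per equilibrium: `V1..V5`, `V_Py`,
#'   `max_re`, `stable`, ordered by `V_Py`.
#' @export
find_equilibria <- function(p_ext, params, n_starts = 8, seed = 1) {
  he_te <- params$He * params$tau_e
  # deterministic starts: grid over plausible V_Py plus the map image of 0
  ygrid <- seq(-30, 25, length.out = 23)
  starts <- lapply(ygrid, function(y) {
    phiP <- sigmoid_rate(y, params)
    V4 <- he_te * params$N_IP * phiP
    V5 <- solve_v5(V4, params)
    V3 <- params$Hi * params$tau_i * params$N_PI *
      sigmoid_rate(V4 - V5, params)
    c(he_te * params$N_EP * phiP, y + V3, V3, V4, V5)
  })
  if (n_starts > 0) {
    if (!is.null(seed)) set.seed(seed)
    starts <- c(starts, lapply(seq_len(n_starts), function(i)
      stats::runif(5, -5, 15)))
  }
  resid <- function(V) V - steady_state_map(V, p_ext, params)
  jac5 <- function(V) {
    J <- matrix(0, 5, 5)
    h <- 1e-6
    for (j in 1:5) {
      e <- numeric(5); e[j] <- h
      J[, j] <- (resid(V + e) - resid(V - e)) / (2 * h)
    }
    J
  }
  sols <- list()
  for (V in starts) {
    for (it in 1:60) {
      f <- resid(V)
      if (max(abs(f)) < 1e-11) break
      step <- tryCatch(solve(jac5(V), f), error = function(e) NULL)
      if (is.null(step)) { V <- NULL; break }
      lam <- 1
      repeat {
        Vn <- V - lam * step
        if (max(abs(resid(Vn))) < max(abs(f)) || lam < 1e-4) break
        lam <- lam / 2
      }
      V <- Vn
    }
    if (!is.null(V) && max(abs(resid(V))) < 1e-9)
      sols[[length(sols) + 1]] <- V
  }
  if (!length(sols)) stop("no equilibrium converged (unexpected: the ",
                          "bounded sigmoid guarantees at least one)")
  M <- do.call(rbind, sols)
  keep <- !duplicated(round(M, 6))
  M <- M[keep, , drop = FALSE]
  # merge near-identical solutions
  ord <- order(M[, 2] - M[, 3])
  M <- M[ord, , drop = FALSE]
  vpy <- M[, 2] - M[, 3]
  dedup <- c(TRUE, diff(vpy) > 1e-5)
  M <- M[dedup, , drop = FALSE]
  max_re <- apply(M, 1, function(V) max(Re(eig_at(V, params))))
  out <- data.frame(M)
  names(out) <- paste0("V", 1:5)
  out$V_Py <- out$V2 - out$V3
  out$max_re <- max_re
  out$stable <- max_re < 0
  out[order(out$V_Py), ]
}

#' Count coexisting attractors at a fixed drive
#'
#' Counts stable equilibria from [find_equilibria()] and, optionally, probes
#' for a coexisting stable limit cycle by integrating from a perturbed
#' high-state initial condition and checking for sustained large-amplitude
#' oscillation.  Memory behavior requires at least two attractors at
#' `p_ext = 0`.
#'
#' @param params a [model_params()] object.
#' @param p_ext external drive (s^-1).
#' @param probe_limit_cycle logical; run the simulation probe.
#' @return A list with `regime` (`"monostable"`, `"bistable_nodes"`, or
#'   `"bistable_with_limit_cycle"`), `n_stable`, and the equilibrium table.
#' @export
bistability_check <- function(params, p_ext = 0, probe_limit_cycle = TRUE) {
  eq <- find_equilibria(p_ext, params)
  n_stable <- sum(eq$stable)
  if (n_stable >= 2)
    return(list(regime = "bistable_nodes", n_stable = n_stable,
                equilibria = eq))
  lc <- FALSE
  if (probe_limit_cycle) {
    top <- eq[which.max(eq$V_Py), ]
    x0 <- c(as.numeric(top[1, paste0("V", 1:5)]), rep(0, 5))
    x0[2] <- x0[2] + 0.5
    n <- 8001L
    states <- tryCatch(
      heun_circuit_cpp(x0, as_par_vector(params), rep(p_ext, n), numeric(n),
                       1e-3),
      error = function(e) NULL)
    if (!is.null(states)) {
      vpy <- states[, 2] - states[, 3]
      tail_v <- vpy[6001:8001]
      low <- eq$V_Py[eq$stable]
      ptp <- diff(range(tail_v))
      away <- if (length(low)) min(abs(mean(tail_v) - low)) > 0.5 else TRUE
      lc <- ptp > 1 && away
    }
  }
  regime <- if (n_stable >= 1 && lc) "bistable_with_limit_cycle"
            else "monostable"
  list(regime = regime, n_stable = n_stable, equilibria = eq)
}

#' Trace a fold locus through the synaptic-gain plane at zero drive
#'
#' For each inhibitory gain in `Hi_values`, finds the excitatory gain at
#' which the named fold of the equilibrium curve sits exactly at
#' `p_ext = 0` (a scan over `He_range` for a sign change of the fold's
#' `p_ext`, refined by [stats::uniroot()]), and classifies the fold there
#' from the at-fold eigenvalues.  Points where the fold type changes along
#' the locus (the saddle-node to saddle-saddle split, from which a Hopf
#' branch emanates) are refined by bisection in `Hi` and reported in the
#' `splits` attribute.
#'
#' @param params base parameters (architecture and gains other than He/Hi).
#' @param which_fold `"upper"` (larger `V_Py`) or `"lower"`.
#' @param Hi_values inhibitory gains (mV) at which to locate the locus.
#' @param He_range excitatory gain scan interval (mV).
#' @param n_scan number of He scan points per Hi.
#' @return A `cm_locus`: data frame `Hi`, `He`, `V_Py`, `fold_type`, with a
#'   `splits` attribute (data frame of refined type-change points).
#' @export
trace_codim2 <- function(params, which_fold = c("upper", "lower"),
                         Hi_values = seq(3, 9, by = 0.5),
                         He_range = c(1.2, 7.5), n_scan = 20) {
  which_fold <- match.arg(which_fold)
  locus_point <- function(Hi) {
    g <- function(He) {
      f <- named_fold(with_gains(params, He, Hi), which_fold)
      if (is.null(f)) NA_real_ else f$p_ext
    }
    Hes <- seq(He_range[1], He_range[2], length.out = n_scan)
    vals <- vapply(Hes, g, numeric(1))
    okv <- which(is.finite(vals))
    sc <- okv[which(diff(sign(vals[okv])) != 0 & diff(okv) == 1)]
    if (!length(sc)) return(NULL)
    He0 <- stats::uniroot(g, c(Hes[sc[1]], Hes[sc[1] + 1]), tol = 1e-8)$root
    p <- with_gains(params, He0, Hi)
    f <- named_fold(p, which_fold)
    data.frame(Hi = Hi, He = He0, V_Py = f$y,
               fold_type = fold_type_at(f$y, p))
  }
  rows <- lapply(Hi_values, function(Hi)
    tryCatch(locus_point(Hi), error = function(e) NULL))
  ok <- !vapply(rows, is.null, logical(1))
  if (!any(ok)) stop("fold locus not found in the given gain ranges")
  if (!all(ok))
    warning("fold locus lost at Hi = ",
            paste(Hi_values[!ok], collapse = ", "), "; curve truncated")
  out <- do.call(rbind, rows[ok])
  # refine fold-type changes along the locus by bisection in Hi
  splits <- list()
  tc <- which(out$fold_type[-1] != out$fold_type[-nrow(out)])
  for (i in tc) {
    lo <- out$Hi[i]; hi <- out$Hi[i + 1]
    t_lo <- out$fold_type[i]
    for (k in 1:12) {
      mid <- (lo + hi) / 2
      r <- tryCatch(locus_point(mid), error = function(e) NULL)
      if (is.null(r)) break
      if (r$fold_type == t_lo) lo <- mid else hi <- mid
    }
    splits[[length(splits) + 1]] <-
      data.frame(Hi = (lo + hi) / 2, from = out$fold_type[i],
                 to = out$fold_type[i + 1])
  }
  attr(out, "splits") <- if (length(splits)) do.call(rbind, splits)
                         else data.frame(Hi = numeric(), from = character(),
                                         to = character())
  class(out) <- c("cm_locus", "data.frame")
  out
}

with_gains <- function(params, He, Hi) {
  p <- unclass(params); p$He <- He; p$Hi <- Hi
  do.call(model_params, p[PAR_NAMES])
}

# the upper/lower fold of the branch, or NULL when absent
named_fold <- function(params, which_fold, y_range = c(-60, 40), n = 1601) {
  ys <- seq(y_range[1], y_range[2], length.out = n)
  b <- branch_states(ys, params)
  ok <- which(is.finite(b$p_ext))
  if (length(ok) < 5) return(NULL)
  ys <- ys[ok]; pex <- b$p_ext[ok]
  dp <- diff(pex)
  fi <- which(diff(sign(dp)) != 0)
  if (length(fi) < 2) return(NULL)
  folds <- lapply(fi, function(i) {
    o <- stats::optimize(function(y) branch_pext(y, params),
                         c(ys[max(1, i - 1)], ys[min(length(ys), i + 2)]),
                         maximum = dp[i] > 0, tol = 1e-10)
    yf <- if (dp[i] > 0) o$maximum else o$minimum
    list(y = yf, p_ext = o$objective)
  })
  yy <- vapply(folds, `[[`, numeric(1), "y")
  folds[[if (which_fold == "upper") which.max(yy) else which.min(yy)]]
}

#' Sweep the inhibitory self-feedback gain of the disinhibited circuit
#'
#' For each value of `N_II` (with `b1 = 0, b2 = 0`), computes the
#' equilibrium branch and summarizes its bifurcation events.  At
#' `N_II = 0` the disinhibited circuit coincides with the plain
#' two-population model.
#'
#' @param NII_values recurrent inhibitory self-feedback gains to sweep.
#' @param params base parameters; must have `b1 = 0, b2 = 0`.
#' @param p_ext_range drive window passed to [continue_branch()].
#' @return A list of event data frames, one per `N_II` value, named by value.
#' @export
nii_sweep <- function(NII_values, params = two_population_disinhibited(),
                      p_ext_range = c(-100, 400)) {
  if (params$b1 != 0 || params$b2 != 0)
    stop("nii_sweep requires the disinhibited architecture (b1 = 0, b2 = 0)")
  out <- lapply(NII_values, function(nii) {
    p <- unclass(params); p$N_II <- nii
    p <- do.call(model_params, p[PAR_NAMES])
    continue_branch(p, p_ext_range = p_ext_range)$events
  })
  names(out) <- as.character(NII_values)
  out
}

#' Export a branch as CSV plus a JSON event list
#'
#' @param branch a `cm_branch`.
#' @param path CSV output path; events go to a `.json` sidecar.
#' @return `path`, invisibly.
#' @export
write_branch <- function(branch, path) {
  utils::write.csv(branch$points, path, row.names = FALSE)
  jsonlite::write_json(branch$events, sub("\\.csv$", ".json", path),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
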