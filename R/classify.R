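#' Classification windows and firing threshold
#'
#' The stimulus-response taxonomy compares the maximum pyramidal potential
#' against a firing threshold in three windows of the standard 5 s protocol:
#' prestimulus (0.5-1 s), immediate response (1.1-3.5 s), and asymptotic
#' (4-5 s).  The 4 mV threshold corresponds to roughly a quarter of the
#' maximum firing rate under the default activation function, i.e. the level
#' at which a population drives its targets appreciably.
#'
#' @param prestimulus,immediate,asymptotic numeric length-2 `(start, end)`
#'   window bounds in seconds.
#' @param threshold firing threshold `u_th` (mV).
#' @return An object of class `cm_windows`.
#' @export
window_spec <- function(prestimulus = c(0.5, 1), immediate = c(1.1, 3.5),
                        asymptotic = c(4, 5), threshold = 4) {
  w <- list(prestimulus = prestimulus, immediate = immediate,
            asymptotic = asymptotic, threshold = threshold)
  b <- rbind(prestimulus, immediate, asymptotic)
  if (any(b[, 2] <= b[, 1]) || is.unsorted(as.vector(t(b))))
    stop("windows must be ordered and disjoint")
  class(w) <- "cm_windows"
  w
}

#' Classify a stimulus response as nonresponsive, transfer, or memory
#'
#' Computes the maximum of `V_Py` in each window and the activation bit
#' `max > threshold`.  An activity that merely oscillates about the threshold
#' counts as active, because the population then drives its targets at least
#' part of the time (the maximum criterion implements this).  Labels:
#' active in the asymptotic window means `MEMORY` (lasting activation after
#' stimulus offset); active only in the immediate window means `TRANSFER`;
#' bits `(0,0,0)` or `(1,1,1)` mean `NONRESPONSIVE`.  The combinations
#' `(1,1,0)` and `(1,0,0)` never arise under the standard protocols and are
#' mapped to `NONRESPONSIVE` with a warning.
#'
#' @param traj a `cm_trajectory` spanning all three windows.
#' @param windows a [window_spec()].
#' @return A `cm_behavior`: list with `label`, the activation `bits`
#'   (pre, imm, asym), the window maxima, and `oscillatory` (asymptotic
#'   peak-to-peak `V_Py` above 0.5 mV).
#' @export
classify_response <- function(traj, windows = window_spec()) {
  if (max(traj$t) < windows$asymptotic[2] - 1e-9)
    stop("trajectory does not span the classification windows")
  win_max <- function(w) {
    i <- traj$t >= w[1] & traj$t <= w[2]
    max(traj$v_py[i])
  }
  m <- c(pre = win_max(windows$prestimulus),
         imm = win_max(windows$immediate),
         asym = win_max(windows$asymptotic))
  bits <- as.integer(m > windows$threshold)
  label <- behavior_label(bits)
  ia <- traj$t >= windows$asymptotic[1] & traj$t <= windows$asymptotic[2]
  osc <- diff(range(traj$v_py[ia])) > 0.5
  structure(list(label = label, bits = bits, maxima = m, oscillatory = osc),
            class = "cm_behavior")
}

behavior_label <- function(bits) {
  if (bits[3] == 1L && bits[1] == 0L) return("MEMORY")
  if (all(bits == c(0L, 1L, 0L))) return("TRANSFER")
  if (all(bits == 0L) || all(bits == 1L)) return("NONRESPONSIVE")
  warning("activation triple (", paste(bits, collapse = ","),
          ") outside the standard taxonomy; labelled NONRESPONSIVE")
  "NONRESPONSIVE"
}

#' @export
print.cm_behavior <- function(x, ...) {
  cat(sprintf("%s  bits %d-%d-%d  maxima %.2f/%.2f/%.2f mV%s\n", x$label,
              x$bits[1], x$bits[2], x$bits[3], x$maxima[1], x$maxima[2],
              x$maxima[3], if (x$oscillatory) "  (oscillatory)" else ""))
  invisible(x)
}

new_cm_map <- function(axis1, axis2, labels, axes = c("intensity", "duration"),
                       extra = NULL, params = NULL) {
  structure(list(axis1 = axis1, axis2 = axis2, labels = labels, axes = axes,
                 extra = extra, params = params),
            class = "cm_map")
}

#' @export
print.cm_map <- function(x, ...) {
  cat(sprintf("cm_map: %d x %d grid (%s x %s)\n", length(x$axis1),
              length(x$axis2), x$axes[1], x$axes[2]))
  print(table(x$labels))
  invisible(x)
}

#' @export
as.data.frame.cm_map <- function(x, ...) {
  d <- expand.grid(axis1 = x$axis1, axis2 = x$axis2)
  names(d) <- x$axes
  d$label <- as.vector(x$labels)
  if (!is.null(x$extra)) for (k in names(x$extra)) d[[k]] <- as.vector(x$extra[[k]])
  d
}

#' Behavioral fingerprint over a stimulus grid
#'
#' Runs the standard single-pulse protocol for every combination of stimulus
#' intensity and duration and classifies each response.  The result is the
#' circuit's characteristic fingerprint: which regions of stimulus salience
#' are blocked, transferred, or memorized.  Cells are evaluated in a
#' deterministic row-major order and are mutually independent.
#'
#' @param params a [model_params()] object.
#' @param intensities stimulus intensity grid (s^-1).
#' @param durations stimulus duration grid (s).
#' @param dt integration step (s).
#' @param windows a [window_spec()].
#' @return A `cm_map` with a label matrix of dimension
#'   `length(intensities) x length(durations)`, plus an oscillation flag per
#'   cell.
#' @export
fingerprint <- function(params, intensities = seq(50, 250, length.out = 41),
                        durations = seq(0.5, 1.5, length.out = 41),
                        dt = 1e-3, windows = window_spec()) {
  if (!length(intensities) || !length(durations)) stop("empty stimulus grid")
  lab <- matrix(NA_character_, length(intensities), length(durations))
  osc <- matrix(NA, length(intensities), length(durations))
  for (j in seq_along(durations)) {
    for (i in seq_along(intensities)) {
      b <- tryCatch(
        classify_response(run_protocol(intensities[i], durations[j], params,
                                       dt = dt), windows),
        error = function(e) stop("fingerprint cell (", i, ",", j, "): ",
                                 conditionMessage(e)))
      lab[i, j] <- b$label
      osc[i, j] <- b$oscillatory
    }
  }
  new_cm_map(intensities, durations, lab, c("intensity", "duration"),
             extra = list(oscillatory = osc), params = params)
}

#' Dynamic function map over the synaptic-gain plane
#'
#' For every combination of excitatory and inhibitory synaptic gain, computes
#' the fingerprint and summarizes it by the set of behaviors present and the
#' modal behavior.  The sorted behavior set is the cell's category: it charts
#' how the local network balance (He, Hi) individualizes the circuit's
#' response repertoire.
#'
#' @param He_grid,Hi_grid synaptic gain grids (mV).
#' @param params base parameter set; `He`/`Hi` are overridden per cell.
#' @param intensities,durations stimulus grid forwarded to [fingerprint()].
#' @param dt integration step (s).
#' @return A `cm_map` over (He, Hi) whose labels are the sorted behavior sets
#'   (e.g. `"MEMORY+TRANSFER"`), with the modal behavior as an extra layer.
#' @export
dynamic_function_map <- function(He_grid, Hi_grid, params = model_params(),
                                 intensities = seq(50, 250, length.out = 9),
                                 durations = seq(0.5, 1.5, length.out = 9),
                                 dt = 1e-3) {
  if (!length(He_grid) || !length(Hi_grid)) stop("empty gain grid")
  sets <- matrix(NA_character_, length(He_grid), length(Hi_grid))
  modal <- matrix(NA_character_, length(He_grid), length(Hi_grid))
  base <- unclass(params)
  for (j in seq_along(Hi_grid)) {
    for (i in seq_along(He_grid)) {
      base$He <- He_grid[i]; base$Hi <- Hi_grid[j]
      p <- do.call(model_params, base[PAR_NAMES])
      fp <- fingerprint(p, intensities, durations, dt = dt)
      tab <- table(fp$labels)
      sets[i, j] <- paste(sort(names(tab)), collapse = "+")
      modal[i, j] <- names(tab)[which.max(tab)]
    }
  }
  new_cm_map(He_grid, Hi_grid, sets, c("He", "Hi"),
             extra = list(modal = modal), params = params)
}

#' Deactivation map: resetting the memory state through the IIN
#'
#' Starting from the high (memory) state, applies a rectangular impulse to
#' the inhibitory interneurons and records whether the circuit returns below
#' threshold.  The parameterization must be bistable at `p_ext = 0`
#' (checked via [bistability_check()]); otherwise there is no memory state
#' to reset.
#'
#' The protocol is: 1 s settling, a memory-inducing afferent pulse
#' (150 s^-1 for 1.5 s), the IIN impulse at 4.5 s, and a final assessment
#' window in the last second of the 8 s run.
#'
#' @param params a [model_params()] object, bistable at rest.
#' @param iin_intensities IIN impulse intensity grid (s^-1).
#' @param iin_durations IIN impulse duration grid (s).
#' @param dt integration step (s).
#' @param threshold firing threshold (mV).
#' @return A `cm_map` with labels `"DEACTIVATED"` / `"ACTIVE"`.
#' @export
deactivation_map <- function(params, iin_intensities = seq(0, 50, by = 5),
                             iin_durations = seq(0, 0.5, by = 0.05),
                             dt = 1e-3, threshold = 4) {
  bc <- bistability_check(params, 0)
  if (bc$regime == "monostable")
    stop("deactivation_map requires bistability at p_ext = 0 ",
         "(bistability_check reports monostable)")
  lab <- matrix(NA_character_, length(iin_intensities), length(iin_durations))
  for (j in seq_along(iin_durations)) {
    for (i in seq_along(iin_intensities)) {
      segs <- data.frame(
        target = c("p_ext", "p_iin"), onset = c(1, 4.5),
        duration = c(1.5, iin_durations[j]),
        intensity = c(150, iin_intensities[i]), stringsAsFactors = FALSE)
      tr <- integrate_heun(params,
                           stimulus_protocol(segments = segs, total_time = 8),
                           dt = dt)
      i_asym <- tr$t >= 7
      lab[i, j] <- if (max(tr$v_py[i_asym]) < threshold) "DEACTIVATED"
                   else "ACTIVE"
    }
  }
  new_cm_map(iin_intensities, iin_durations, lab,
             c("iin_intensity", "iin_duration"), params = params)
}

#' Stimulus-offset phase dependence of the transfer/memory outcome
#'
#' Near the transfer/memory boundary the outcome depends on where in the
#' circuit's intrinsic damped oscillation the stimulus switches off.  This
#' scan sweeps the stimulus duration on a fine grid at fixed intensity and
#' returns the per-duration label, exposing the alternating stripes of the
#' fingerprint.
#'
#' @param params a [model_params()] object.
#' @param intensity stimulus intensity (s^-1); should exceed the fold
#'   threshold for the alternation to appear.
#' @param durations fine duration grid (s).
#' @param dt integration step (s).
#' @return A data frame with `duration` and `label`.
#' @export
offset_phase_scan <- function(params, intensity = 100,
                              durations = seq(0.6, 0.75, by = 0.005),
                              dt = 1e-3) {
  lab <- vapply(durations, function(d)
    classify_response(run_protocol(intensity, d, params, dt = dt))$label,
    character(1))
  data.frame(duration = durations, label = lab, stringsAsFactors = FALSE)
}

#' Export a behavior map as CSV (long format) with a JSON metadata sidecar
#'
#' @param map a `cm_map`.
#' @param path CSV output path; a `.json` sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  meta <- list(axes = map$axes,
               params = if (!is.null(map$params)) unclass(map$params))
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
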