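#' Specify a network of coupled microcircuits
#'
#' Nodes are canonical microcircuits coupled through their pyramidal firing
#' rates.  An excitatory edge adds `gain * phi_P(source)` to the target's
#' afferent drive (`p_ext` route); an inhibitory edge adds it to the
#' target's IIN drive, the same route by which a brief impulse resets an
#' active circuit.  Contextual channels model top-down information as a
#' noisy inhibitory signal with a constant offset that degrades the
#' target's afferent input (subtracted from `p_ext`, floored at zero).
#'
#' @param nodes data frame with columns `name` and `module`; all nodes share
#'   `params` unless a `params` list-column is supplied.
#' @param edges data frame with columns `from`, `to`,
#'   `sign` (`"excitatory"`/`"inhibitory"`), and `gain` (dimensionless,
#'   scales firing rates into s^-1 drive units).
#' @param context optional data frame with columns `target`, `offset`
#'   (s^-1), and `sd` (s^-1 noise standard deviation).
#' @param params default [model_params()] applied to every node.
#' @return An object of class `cm_network`.
#' @export
network_spec <- function(nodes, edges = NULL, context = NULL,
                         params = model_params()) {
  stopifnot(all(c("name", "module") %in% names(nodes)))
  if (anyDuplicated(nodes$name)) stop("node names must be unique")
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        sign = character(), gain = numeric())
  stopifnot(all(c("from", "to", "sign", "gain") %in% names(edges)))
  dangling <- setdiff(c(edges$from, edges$to), nodes$name)
  if (length(dangling))
    stop("edge references unknown node(s): ", paste(dangling, collapse = ", "))
  if (!all(edges$sign %in% c("excitatory", "inhibitory")))
    stop("edge sign must be 'excitatory' or 'inhibitory'")
  if (any(edges$gain < 0)) stop("edge gains must be non-negative")
  if (!is.null(context)) {
    stopifnot(all(c("target", "offset", "sd") %in% names(context)))
    bad <- setdiff(context$target, nodes$name)
    if (length(bad)) stop("context targets unknown node(s): ",
                          paste(bad, collapse = ", "))
  }
  if (!("params" %in% names(nodes)))
    nodes$params <- replicate(nrow(nodes), params, simplify = FALSE)
  structure(list(nodes = nodes, edges = edges, context = context),
            class = "cm_network")
}

#' Word input schedule
#'
#' Each event delivers a rectangular afferent pulse to the named node —
#' for the sentence-parsing network, the arrival of one recognized word.
#'
#' @param node character vector of target node names.
#' @param onset,duration,intensity pulse parameters, recycled to the length
#'   of `node`.
#' @return A data frame of class `cm_schedule`, ordered by onset.
#' @export
word_schedule <- function(node, onset, duration = 1.2, intensity = 100) {
  d <- data.frame(node = node, onset = onset, duration = duration,
                  intensity = intensity, stringsAsFactors = FALSE)
  d <- d[order(d$onset), ]
  class(d) <- c("cm_schedule", "data.frame")
  d
}

#' Simulate a network of coupled microcircuits
#'
#' Every node integrates its own circuit dynamics (Heun, frozen per-step
#' drives); inter-node coupling uses the pyramidal firing rates of the
#' current stage state.  Contextual noise is Gaussian, resampled every step,
#' and reproducible given `seed`.
#'
#' @param spec a [network_spec()].
#' @param schedule a [word_schedule()] (may be empty).
#' @param total_time simulated time (s); defaults to 2 s past the last event.
#' @param dt integration step (s).
#' @param seed integer seed for the contextual noise.
#' @param threshold firing threshold (mV) for final activation bits.
#' @param asym_window length (s) of the terminal assessment window.
#' @return A `cm_parse`: list with the time grid, the `V_Py` matrix (time x
#'   node), per-node final activation bits, and the parse `outcome` (see
#'   [parse_outcome()]).
#' @export
simulate_network <- function(spec, schedule = NULL, total_time = NULL,
                             dt = 1e-3, seed = 1, threshold = 4,
                             asym_window = 1) {
  stopifnot(inherits(spec, "cm_network"))
  nodes <- spec$nodes
  nn <- nrow(nodes)
  if (is.null(schedule) || !nrow(schedule)) {
    if (is.null(total_time)) total_time <- 5
    schedule <- data.frame(node = character(), onset = numeric(),
                           duration = numeric(), intensity = numeric())
  } else if (is.null(total_time)) {
    total_time <- max(schedule$onset + schedule$duration) + 2
  }
  n <- as.integer(round(total_time / dt)) + 1L
  t <- (seq_len(n) - 1L) * dt
  idx <- stats::setNames(seq_len(nn), nodes$name)

  wordin <- matrix(0, n, nn)
  for (i in seq_len(nrow(schedule))) {
    ev <- schedule[i, ]
    on <- t >= ev$onset & t < ev$onset + ev$duration
    wordin[on, idx[[ev$node]]] <- wordin[on, idx[[ev$node]]] + ev$intensity
  }
  ctx <- matrix(0, n, nn)
  if (!is.null(spec$context) && nrow(spec$context)) {
    set.seed(seed)
    for (i in seq_len(nrow(spec$context))) {
      cc <- spec$context[i, ]
      ctx[, idx[[cc$target]]] <- ctx[, idx[[cc$target]]] +
        pmax(0, stats::rnorm(n, cc$offset, cc$sd))
    }
  }
  w_exc <- matrix(0, nn, nn); w_inh <- matrix(0, nn, nn)
  for (i in seq_len(nrow(spec$edges))) {
    e <- spec$edges[i, ]
    if (e$sign == "excitatory")
      w_exc[idx[[e$to]], idx[[e$from]]] <-
        w_exc[idx[[e$to]], idx[[e$from]]] + e$gain
    else
      w_inh[idx[[e$to]], idx[[e$from]]] <-
        w_inh[idx[[e$to]], idx[[e$from]]] + e$gain
  }
  pars <- do.call(rbind, lapply(nodes$params, as_par_vector))
  res <- heun_network_cpp(matrix(0, nn, 10), pars, wordin, ctx,
                          matrix(0, n, nn), w_exc, w_inh, dt)
  vpy <- res$vpy
  colnames(vpy) <- nodes$name
  i_asym <- t >= total_time - asym_window
  bits <- apply(vpy[i_asym, , drop = FALSE], 2, max) > threshold
  structure(list(t = t, vpy = vpy, final_active = bits,
                 outcome = parse_outcome(bits, spec), spec = spec,
                 schedule = schedule, seed = seed),
            class = "cm_parse")
}

#' Label the outcome of a sentence-parsing run
#'
#' The outcome is a pure function of the final activation bits.  The core
#' words are the nodes outside the two competing modifier modules.  If all
#' core words hold their activation and exactly one modifier is active, the
#' parse selected an interpretation: `interpretation_A` when the
#' object-modifier won (the prepositional phrase modifies the object),
#' `interpretation_B` when the verb-modifier won.  No lasting activation at
#' all is `memory_loss`; anything else is a `defective` trace.
#'
#' @param bits named logical vector of final activation per node.
#' @param spec the [network_spec()] (module labels identify the competing
#'   modifier nodes).
#' @return One of `"interpretation_A"`, `"interpretation_B"`,
#'   `"defective"`, `"memory_loss"`.
#' @export
parse_outcome <- function(bits, spec) {
  if (!any(bits)) return("memory_loss")
  vmod <- spec$nodes$name[spec$nodes$module == "V-mod"]
  omod <- spec$nodes$name[spec$nodes$module == "O-mod"]
  core <- setdiff(spec$nodes$name, c(vmod, omod))
  v_on <- any(bits[vmod]); o_on <- any(bits[omod])
  if (all(bits[core]) && xor(v_on, o_on))
    return(if (o_on) "interpretation_A" else "interpretation_B")
  "defective"
}

#' @export
print.cm_parse <- function(x, ...) {
  cat("cm_parse outcome:", x$outcome, "\n")
  on <- names(x$final_active)[x$final_active]
  cat("  finally active:", if (length(on)) paste(on, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Sub-threshold pre-activation of a node by upstream activity
#'
#' An active upstream circuit raises a downstream node's baseline pyramidal
#' potential without activating it — an expectation that moves the node
#' closer to its fold.  This measures that shift: the node's mean `V_Py`
#' over a window, minus its isolated resting potential.
#'
#' @param node node name.
#' @param trace a `cm_parse` from [simulate_network()].
#' @param window numeric `(start, end)` in seconds over which to measure;
#'   the node must stay below threshold throughout.
#' @param threshold firing threshold (mV).
#' @return Baseline shift in mV.
#' @export
preactivation_level <- function(node, trace, window, threshold = 4) {
  i <- trace$t >= window[1] & trace$t <= window[2]
  v <- trace$vpy[i, node]
  if (max(v) > threshold)
    stop("node '", node, "' is active in the window; ",
         "pre-activation is undefined")
  p <- trace$spec$nodes$params[[match(node, trace$spec$nodes$name)]]
  eq <- find_equilibria(0, p)
  rest <- min(eq$V_Py[eq$stable])
  mean(v) - rest
}

#' Network-balance perturbation experiment
#'
#' Re-runs a parsing simulation with the inhibitory synaptic gain `Hi` set
#' uniformly on all nodes to each given value.  A small bias of the local
#' balance toward inhibition degrades the circuits' memory operation and
#' breaks the structure-building process.
#'
#' @param spec a [network_spec()].
#' @param schedule a [word_schedule()].
#' @param Hi_values inhibitory gains (mV) to apply.
#' @param seed seed forwarded to [simulate_network()].
#' @param ... further arguments to [simulate_network()].
#' @return Named list of `cm_parse` results, one per `Hi` value.
#' @export
balance_perturbation <- function(spec, schedule, Hi_values = c(22, 23, 24),
                                 seed = 1, ...) {
  out <- lapply(Hi_values, function(Hi) {
    sp <- spec
    sp$nodes$params <- lapply(sp$nodes$params, function(p) {
      q <- unclass(p); q$Hi <- Hi
      do.call(model_params, q[PAR_NAMES])
    })
    simulate_network(sp, schedule, seed = seed, ...)
  })
  names(out) <- as.character(Hi_values)
  out
}

#' The six-node sentence-parsing demonstration network
#'
#' Builds the network for the ambiguous sentence
#' *"I hit the thief with the club"*: word-representing circuits for
#' `I` (subject), `hit` (verb), `the thief` (object), two competing `with`
#' circuits (verb-modifier and object-modifier modules, mutually inhibiting
#' through asymmetric connections), and `the club`.  Excitatory edges
#' pre-activate the syntactically expected successors; contextual
#' information inhibits the verb-modifier when it is high, selecting the
#' object-modifier reading.
#'
#' The connection weights are calibration artifacts: they were hand-tuned
#' (see `scripts/calibrate_network.R` in the source repository) to reproduce
#' the qualitative parsing outcomes, and are shipped in
#' `inst/extdata/sentence_demo.yaml`.
#'
#' @param context `"high"` or `"low"` contextual information targeting the
#'   verb-modifier.
#' @param params node parameter set (defaults to the three-population
#'   circuit).
#' @return A list with `spec` (a [network_spec()]) and `schedule`
#'   (a [word_schedule()]).
#' @export
sentence_demo <- function(context = c("high", "low"),
                          params = model_params()) {
  context <- match.arg(context)
  path <- system.file("extdata", "sentence_demo.yaml", package = "cmcircuit")
  cfg <- yaml::read_yaml(path)
  nodes <- do.call(rbind, lapply(cfg$nodes, function(x)
    data.frame(name = x$name, module = x$module, stringsAsFactors = FALSE)))
  edges <- do.call(rbind, lapply(cfg$edges, function(x)
    data.frame(from = x$from, to = x$to, sign = x$sign, gain = x$gain,
               stringsAsFactors = FALSE)))
  ctx_cfg <- cfg$context[[context]]
  ctx <- data.frame(target = ctx_cfg$target, offset = ctx_cfg$offset,
                    sd = ctx_cfg$sd, stringsAsFactors = FALSE)
  sched <- do.call(rbind, lapply(cfg$schedule, function(x)
    data.frame(node = x$node, onset = x$onset, duration = x$duration,
               intensity = x$intensity, stringsAsFactors = FALSE)))
  list(spec = network_spec(nodes, edges, ctx, params = params),
       schedule = word_schedule(sched$node, sched$onset, sched$duration,
                                sched$intensity))
}
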