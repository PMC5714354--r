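#' Model parameters for the canonical microcircuit
#'
#' Builds the full parameter set of the generalized canonical-microcircuit
#' neural mass model: synaptic gains and time constants of the excitatory and
#' inhibitory alpha-function kernels, dimensionless connectivity gains between
#' the three populations (pyramidal cells Py, excitatory interneurons EIN,
#' inhibitory interneurons IIN), the logistic activation-function constants,
#' and the two architectural switches.
#'
#' The defaults reproduce the standard parameterization of this model family
#' (the classic Jansen-Rit values plus the self-feedback gains of the
#' two-population mapping).  `b1` blends indirect excitatory feedback via the
#' EIN (`b1 = 1`, three-population architecture, external input arrives at
#' the EIN) with direct Py self-feedback (`b1 = 0`, two-population
#' architecture, external input arrives at the Py).  `b2 = 1` removes the
#' recurrent inhibitory self-feedback of the IIN; `b2 = 0` enables it
#' (disinhibition).
#'
#' @param He,Hi excitatory/inhibitory synaptic gain (mV).
#' @param tau_e,tau_i excitatory/inhibitory synaptic time constant (s).
#' @param N_EP,N_PE,N_IP,N_PI,N_PP,N_II dimensionless connectivity gains;
#'   the first subscript is the target population, the second the source.
#' @param e0 half of the maximum firing rate (s^-1).
#' @param r maximum slope of the activation function (mV^-1).
#' @param v0 half-activation membrane potential (mV).
#' @param b1,b2 architectural switches in `[0, 1]` (see Details).
#' @return An object of class `cm_params` (a validated named list).
#' @examples
#' p <- model_params()                  # three-population defaults
#' p2 <- model_params(b1 = 0, b2 = 1)   # two-population, direct feedback
#' @export
model_params <- function(He = 3.25, Hi = 22, tau_e = 0.010, tau_i = 0.020,
                         N_EP = 135, N_PE = 0.8 * N_EP, N_IP = 0.25 * N_EP,
                         N_PI = 0.25 * N_EP, N_PP = 113.4, N_II = 33.25,
                         e0 = 2.5, r = 0.56, v0 = 6, b1 = 1, b2 = 1) {
  p <- list(He = He, Hi = Hi, tau_e = tau_e, tau_i = tau_i,
            N_EP = N_EP, N_PE = N_PE, N_IP = N_IP, N_PI = N_PI,
            N_PP = N_PP, N_II = N_II, e0 = e0, r = r, v0 = v0,
            b1 = b1, b2 = b2)
  validate_params(p)
  class(p) <- "cm_params"
  p
}

validate_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num))
    stop("non-numeric or non-scalar parameter: ",
         paste(names(p)[!num], collapse = ", "))
  pos <- c("He", "Hi", "tau_e", "tau_i", "e0", "r")
  bad <- pos[vapply(pos, function(k) p[[k]] <= 0, logical(1))]
  if (length(bad))
    stop("parameter must be strictly positive: ", paste(bad, collapse = ", "))
  nn <- c("N_EP", "N_PE", "N_IP", "N_PI", "N_PP", "N_II")
  bad <- nn[vapply(nn, function(k) p[[k]] < 0, logical(1))]
  if (length(bad))
    stop("connectivity gain must be non-negative: ", paste(bad, collapse = ", "))
  for (k in c("b1", "b2"))
    if (p[[k]] < 0 || p[[k]] > 1)
      stop("architectural parameter ", k, " must lie in [0, 1]")
  invisible(p)
}

#' @export
print.cm_params <- function(x, ...) {
  arch <- if (x$b1 == 1) "three-population (indirect excitatory feedback)"
          else if (x$b1 == 0 && x$b2 == 1) "two-population (direct excitatory feedback)"
          else if (x$b1 == 0 && x$b2 == 0) "two-population with disinhibition"
          else sprintf("mixed architecture (b1 = %g, b2 = %g)", x$b1, x$b2)
  cat("Canonical microcircuit parameters [", arch, "]\n", sep = "")
  cat(sprintf("  He = %g mV, Hi = %g mV, tau_e = %g ms, tau_i = %g ms\n",
              x$He, x$Hi, 1000 * x$tau_e, 1000 * x$tau_i))
  cat(sprintf("  N_EP = %g, N_PE = %g, N_IP = %g, N_PI = %g, N_PP = %g, N_II = %g\n",
              x$N_EP, x$N_PE, x$N_IP, x$N_PI, x$N_PP, x$N_II))
  cat(sprintf("  sigmoid: e0 = %g /s, r = %g /mV, v0 = %g mV\n", x$e0, x$r, x$v0))
  invisible(x)
}

# fixed ordering shared with the compiled integrator
as_par_vector <- function(p) {
  c(p$He, p$Hi, p$tau_e, p$tau_i, p$N_EP, p$N_PE, p$N_IP, p$N_PI,
    p$N_PP, p$N_II, p$e0, p$r, p$v0, p$b1, p$b2)
}

PAR_NAMES <- c("He", "Hi", "tau_e", "tau_i", "N_EP", "N_PE", "N_IP", "N_PI",
               "N_PP", "N_II", "e0", "r", "v0", "b1", "b2")

#' Named architecture presets
#'
#' Convenience constructors for the three architectures studied with this
#' model: `three_population()` (`b1 = 1, b2 = 1`), `two_population()`
#' (`b1 = 0, b2 = 1`), and `two_population_disinhibited()`
#' (`b1 = 0, b2 = 0`, recurrent IIN self-feedback active with gain `N_II`).
#' All other parameters are the `model_params()` defaults unless overridden.
#'
#' @param ... overrides passed to [model_params()].
#' @return A `cm_params` object.
#' @export
three_population <- function(...) model_params(b1 = 1, b2 = 1, ...)

#' @rdname three_population
#' @export
two_population <- function(...) model_params(b1 = 0, b2 = 1, ...)

#' @rdname three_population
#' @export
two_population_disinhibited <- function(...) model_params(b1 = 0, b2 = 0, ...)

#' Read and write parameter sets as YAML
#'
#' Parameter files use the field's symbol names as keys (`He`, `Hi`, `tau_e`,
#' `tau_i`, `N_EP`, `N_PE`, `N_IP`, `N_PI`, `N_PP`, `N_II`, `e0`, `r`, `v0`,
#' `b1`, `b2`).  Time constants are stored in seconds.  Keys not listed above
#' are rejected; missing keys fall back to the defaults of [model_params()].
#' The preset name `"table1"` (or an empty file) yields the default
#' three-population parameterization.
#'
#' @param path file path, or the string `"table1"` for the built-in preset.
#' @param params a `cm_params` object.
#' @return `read_params()` returns a `cm_params`; `write_params()` returns
#'   `path` invisibly.
#' @export
read_params <- function(path) {
  if (identical(path, "table1")) return(model_params())
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), PAR_NAMES)
  if (length(unknown))
    stop("unknown parameter keys: ", paste(unknown, collapse = ", "))
  do.call(model_params, raw)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "cm_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
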