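# Model parameters and harmonic memory inputs.

#' Model parameters for the plasticity dynamics
#'
#' @param omega Forcing frequency of the harmonic memory input (rad per time
#'   unit). Default 1.5.
#' @param gamma Homeostatic decay rate of the connectivity (per time unit);
#'   forgets obsolete synaptic structure during storage. Default 0.5.
#' @param rho Learning rate of the timing-dependent plasticity (per time
#'   unit). Default 0.5.
#' @param tau Synaptic delay (time units). Default `pi / (2 * omega)`, a
#'   quarter forcing period, which maximizes the antisymmetric plasticity
#'   drive; with the default omega this is `pi / 3`.
#' @param dt Integration step for the storage phase. Default 0.1.
#' @param T Duration of the storage phase. Default 40.
#' @return An object of class `model_params`.
#' @export
model_params <- function(omega = 1.5, gamma = 0.5, rho = 0.5,
                         tau = pi / (2 * omega), dt = 0.1, T = 40) {
  p <- list(omega = omega, gamma = gamma, rho = rho, tau = tau, dt = dt, T = T)
  bad <- names(p)[!vapply(p, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0, logical(1L))]
  if (length(bad)) {
    stop("model parameters must be positive finite scalars; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (tau >= T) stop("tau must be smaller than the duration T", call. = FALSE)
  if (tau < dt) stop("tau must be at least one integration step dt", call. = FALSE)
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> omega=%g gamma=%g rho=%g tau=%g dt=%g T=%g\n",
              x$omega, x$gamma, x$rho, x$tau, x$dt, x$T))
  invisible(x)
}

#' Storage input specification: a sequential harmonic pulse
#'
#' The memory input `b(t) = sum_i sin(omega t - xi_i) m_i` streams the
#' memory representations with phase-staggered sampling times `xi_i`.
#'
#' @param memories Memory representations: an `N x n` matrix or a list of
#'   equal-length numeric vectors (columns are the `m_i`).
#' @param phases Sampling phases `xi_i` (radians), strictly increasing in
#'   `[0, pi)`. Default `pi * (i - 1) / n`, evenly sequenced on `[0, pi)`.
#' @param omega Forcing frequency.
#' @return An object of class `storage_spec`.
#' @export
storage_spec <- function(memories, phases = NULL, omega = 1.5) {
  M <- as_memory_matrix(memories)
  n <- ncol(M)
  if (all(M == 0)) stop("all memory representations are zero", call. = FALSE)
  phases <- phases %||% (pi * (seq_len(n) - 1) / n)
  if (length(phases) != n) {
    stop("length(phases) = ", length(phases), " does not match n = ", n)
  }
  if (any(phases < 0 | phases >= pi) || (n > 1L && any(diff(phases) <= 0))) {
    stop("phases must be strictly increasing within [0, pi)")
  }
  structure(list(memories = M, phases = phases, omega = omega,
                 n = n, N = nrow(M)),
            class = "storage_spec")
}

#' Cue specification for the retrieval phase
#'
#' A single-component cue `b(t) = sin(omega t) m_c`, or a multi-component cue
#' `b_c(t) = sum_c sin(omega t - xi_c) m_c` in which each component keeps its
#' original sampling phase.
#'
#' @param memories Cue representation(s): vector, `N x c` matrix, or list.
#' @param phases Phase per component (radians); default 0.
#' @param omega Forcing frequency.
#' @return An object of class `cue_spec`.
#' @export
cue_spec <- function(memories, phases = 0, omega = 1.5) {
  M <- as_memory_matrix(memories)
  if (ncol(M) == 0L) stop("cue has no components", call. = FALSE)
  if (length(phases) == 1L) phases <- rep(phases, ncol(M))
  if (length(phases) != ncol(M)) {
    stop("length(phases) does not match the number of cue components")
  }
  structure(list(memories = M, phases = phases, omega = omega,
                 n = ncol(M), N = nrow(M)),
            class = "cue_spec")
}

# shared evaluator for harmonic inputs; t may be scalar or vector
harmonic_input <- function(M, phases, omega, t) {
  S <- sin(outer(phases, omega * t, function(xi, wt) wt - xi))
  drop(M %*% S)
}

#' Evaluate the storage memory input
#'
#' @param spec A [storage_spec()].
#' @param t Time (scalar or vector).
#' @return State vector of length N (or an `N x length(t)` matrix).
#' @export
storage_input <- function(spec, t) {
  stopifnot(inherits(spec, "storage_spec"))
  harmonic_input(spec$memories, spec$phases, spec$omega, t)
}

#' Evaluate the retrieval cue input
#'
#' @param spec A [cue_spec()].
#' @param t Time (scalar or vector).
#' @return State vector of length N (or an `N x length(t)` matrix).
#' @export
cue_input <- function(spec, t) {
  stopifnot(inherits(spec, "cue_spec"))
  harmonic_input(spec$memories, spec$phases, spec$omega, t)
}
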