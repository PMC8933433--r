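# Memory-plane geometry.
#
# Expanding the harmonic storage input with sin(wt - xi) =
# sin(wt) cos(xi) - cos(wt) sin(xi) shows that b(t) = sin(wt) u - cos(wt) v
# with u = sum_i cos(xi_i) m_i and v = sum_i sin(xi_i) m_i: the input orbit is
# an ellipse inside the 2-D subspace S = span{u, v}, the memory plane. The
# converged connectivity has the structure alpha (v u^T - u v^T), a rotation
# generator acting inside S, and retrieval orbits approach S when the cue is
# relevant.

#' Memory plane spanned by a group of memories
#'
#' @param memories Memory representations (`N x n` matrix or list).
#' @param phases Sampling phases `xi_i`; default `pi (i - 1) / n`.
#' @return An object of class `memory_plane` with generating vectors `u`,
#'   `v`, an orthonormal `basis` (one column if the plane degenerates to a
#'   line), and a `degenerate` flag.
#' @export
memory_plane <- function(memories, phases = NULL) {
  M <- as_memory_matrix(memories)
  if (all(M == 0)) stop("all memory representations are zero", call. = FALSE)
  n <- ncol(M)
  phases <- phases %||% (pi * (seq_len(n) - 1) / n)
  stopifnot(length(phases) == n)
  u <- drop(M %*% cos(phases))
  v <- drop(M %*% sin(phases))
  G <- cbind(u, v)
  nrm <- sqrt(colSums(G^2))
  qrG <- qr(G, tol = 1e-10)
  rank <- qrG$rank
  if (rank == 0L) stop("memory plane is degenerate at the origin (u = v = 0)")
  basis <- qr.Q(qrG)[, seq_len(rank), drop = FALSE]
  structure(list(u = u, v = v, basis = basis, degenerate = rank < 2L),
            class = "memory_plane")
}

#' @export
print.memory_plane <- function(x, ...) {
  cat(sprintf("<memory_plane> N=%d, %s\n", length(x$u),
              if (x$degenerate) "degenerate (1-D)" else "2-D"))
  invisible(x)
}

#' Euclidean distance from a state to the memory plane
#'
#' @param x State vector, or `N x m` matrix of states (columns).
#' @param plane A [memory_plane()].
#' @return Distance(s) of `x` to its orthogonal projection onto the plane.
#' @export
plane_distance <- function(x, plane) {
  stopifnot(inherits(plane, "memory_plane"))
  B <- plane$basis
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  stopifnot(nrow(x) == nrow(B))
  # explicit residual (not the norm-difference identity, which loses half the
  # significant digits for states close to the plane)
  r <- x - B %*% crossprod(B, x)
  drop(sqrt(colSums(r^2)))
}

#' Analytic intersection times of the retrieval orbit with the memory plane
#'
#' The component of the steady retrieval orbit transverse to the memory plane
#' responds as `sin(omega t - atan(omega)) / sqrt(1 + omega^2)` and vanishes
#' exactly at `t = (atan(omega) + k pi) / omega`: those are the instants at
#' which the orbit penetrates the plane and decoding is cleanest.
#'
#' @param omega Forcing frequency (> 0).
#' @param k Integer index (vectorized); consecutive intersections are
#'   `pi / omega` apart.
#' @return Intersection time(s).
#' @export
intersection_time <- function(omega, k = 0L) {
  stopifnot(omega > 0)
  (atan(omega) + k * pi) / omega
}
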