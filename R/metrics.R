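# Retrieval-quality metrics.

#' Scaled cosine similarity of retrieved data along a trajectory
#'
#' For each original datum `f_i`, the retrieved datum at time `t` is
#' `g_i(t) = decode(x(t), r_i)` and its quality is the scaled cosine
#' similarity `s_i(t) = f_i^T g_i(t) / ||f_i||^2`, which combines direction
#' match with retrieved intensity. `p(t)` averages the per-datum similarities
#' and `p_bar` is the trapezoidal time-average of `p(t)`.
#'
#' Retrieved data oscillate between positive and negative versions of the
#' originals, so the default takes the absolute similarity per datum before
#' averaging (`mode = "absolute"`); a signed temporal average would cancel to
#' nearly zero. `mode = "signed"` is retained as an option.
#'
#' @param traj A [trajectory()] from retrieval.
#' @param originals Original data vectors (`D x n` matrix or list).
#' @param tags A [make_tag_set()] whose first `n` tags correspond to the
#'   originals.
#' @param mode `"absolute"` (default) or `"signed"`.
#' @return An object of class `retrieval_metrics`: list with `times`,
#'   `p_series`, `p_bar`, the per-datum similarity matrix `s`
#'   (times x data), and `mode`.
#' @export
retrieval_quality <- function(traj, originals, tags,
                              mode = c("absolute", "signed")) {
  stopifnot(inherits(traj, "trajectory"), inherits(tags, "tag_set"))
  mode <- match.arg(mode)
  Fm <- as_memory_matrix(originals, "originals")
  n <- ncol(Fm)
  R <- tags$vectors
  stopifnot(n <= ncol(R))
  D <- nrow(Fm); K <- nrow(R)
  if (D * K != nrow(traj$states)) {
    stop("trajectory dimension ", nrow(traj$states),
         " does not equal D * K = ", D * K)
  }
  nf2 <- colSums(Fm^2)
  if (any(nf2 == 0)) stop("original data vectors must have nonzero norm")
  # f_i^T decode(x, r_i) equals (f_i (x) r_i)^T x, one projection per datum
  P <- vapply(seq_len(n), function(i) {
    m_i <- as.vector(t(tcrossprod(Fm[, i], R[, i])))
    drop(crossprod(traj$states, m_i)) / nf2[i]
  }, numeric(length(traj$times)))
  if (!is.matrix(P)) P <- matrix(P, nrow = length(traj$times))
  p <- if (mode == "absolute") rowMeans(abs(P)) else rowMeans(P)
  span <- max(traj$times) - min(traj$times)
  p_bar <- if (span > 0) trapz(traj$times, p) / span else p[1L]
  structure(list(times = traj$times, p_series = p, p_bar = p_bar,
                 s = P, mode = mode),
            class = "retrieval_metrics")
}

#' @export
print.retrieval_metrics <- function(x, ...) {
  cat(sprintf("<retrieval_metrics> %d data, %d time points, p_bar = %.4g (%s)\n",
              ncol(x$s), length(x$times), x$p_bar, x$mode))
  invisible(x)
}

#' Cumulative role-fitness curves
#'
#' For word vectors `f_i` and role tags `r_j`, the role fitness
#' `P_ij(t) = integral from t0 to t of |f_i^T decode(x(s), r_j)| ds`
#' measures how strongly the trajectory retrieves word `i` in role `j`;
#' persistent retrieval shows as a steadily increasing curve. Curves are
#' non-decreasing by construction.
#'
#' @param traj A [trajectory()].
#' @param words Word vectors (`D x n_w` matrix or list).
#' @param roles A [make_tag_set()] of role tags.
#' @param t0 Lower integration limit; default the start of the trajectory.
#' @return An object of class `role_fitness`: list with `times` (grid from
#'   `t0`), array `P` of dimension time x word x role, and the label sets.
#' @export
role_fitness <- function(traj, words, roles, t0 = NULL) {
  stopifnot(inherits(traj, "trajectory"), inherits(roles, "tag_set"))
  Fm <- as_memory_matrix(words, "words")
  R <- roles$vectors
  t0 <- t0 %||% traj$times[1L]
  if (t0 < min(traj$times) || t0 > max(traj$times)) {
    stop("t0 = ", t0, " lies outside the trajectory span [",
         min(traj$times), ", ", max(traj$times), "]")
  }
  keep <- traj$times >= t0 - 1e-12
  times <- traj$times[keep]
  X <- traj$states[, keep, drop = FALSE]
  nw <- ncol(Fm); nr <- ncol(R)
  wlab <- colnames(Fm) %||% as.character(seq_len(nw))
  P <- array(0, dim = c(length(times), nw, nr),
             dimnames = list(NULL, wlab, roles$labels))
  for (i in seq_len(nw)) {
    for (j in seq_len(nr)) {
      m_ij <- as.vector(t(tcrossprod(Fm[, i], R[, j])))
      q <- abs(drop(crossprod(X, m_ij)))
      P[, i, j] <- cumtrapz(times, q)
    }
  }
  structure(list(times = times, P = P, words = wlab, roles = roles$labels),
            class = "role_fitness")
}

#' Identify dominantly retrieved (word, role) components
#'
#' A component is dominantly retrieved when its role-fitness curve keeps
#' increasing with a large slope. The slope of each curve is estimated by
#' least squares over the final `window_fraction` of the time grid; within
#' each role, a component is dominant when its slope is at least
#' `threshold_fraction` times the maximal slope for that role.
#'
#' @param rf A [role_fitness()] object.
#' @param window_fraction Fraction of the grid (from the end) used for the
#'   slope fit; default 0.5.
#' @param threshold_fraction Dominance threshold relative to the role maximum;
#'   default 0.5.
#' @return A data frame with columns `word`, `role`, `slope` and `dominant`.
#' @export
dominance <- function(rf, window_fraction = 0.5, threshold_fraction = 0.5) {
  stopifnot(inherits(rf, "role_fitness"))
  stopifnot(window_fraction > 0, window_fraction <= 1)
  times <- rf$times
  if (length(times) < 3L || dim(rf$P)[2L] == 0L) {
    stop("role-fitness curves are empty")
  }
  tcut <- max(times) - window_fraction * (max(times) - min(times))
  idx <- which(times >= tcut)
  tw <- times[idx]
  vt <- stats::var(tw)
  slopes <- apply(rf$P, c(2L, 3L), function(y) stats::cov(tw, y[idx]) / vt)
  out <- expand.grid(word = rf$words, role = rf$roles,
                     stringsAsFactors = FALSE)
  out$slope <- as.vector(slopes)
  role_max <- apply(slopes, 2L, max)
  out$dominant <- as.vector(sweep(slopes, 2L, threshold_fraction * role_max,
                                  ">=")) & out$slope > 0
  out
}
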