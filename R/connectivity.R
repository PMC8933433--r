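# Connectivity representations.
#
# The stored memory is an antisymmetric N x N connectivity matrix W. Three
# representations are supported behind a small set of generics:
#
#   * a plain dense matrix;
#   * `conn_factored`: the exact accumulation of the plasticity updates,
#     W = sum_i a_i (u_i v_i^T - v_i u_i^T), kept as the factor matrices U, V
#     and the coefficient vector a. The storage integrator produces this form
#     in low-memory mode; it is exact (not an approximation) and antisymmetric
#     by construction.
#   * `conn_lowrank`: an orthonormal low-rank form W ~= Q S Q^T with Q^T Q = I
#     and S small and antisymmetric, obtained by spectral truncation. The
#     converged connectivity is close to alpha (v u^T - u v^T), i.e. rank 2,
#     so this form is both a diagnostic (its singular values expose the
#     amplitude alpha and the rank-2 structure) and a fast carrier for the
#     retrieval dynamics.

conn_factored <- function(U, V, a, k = length(a)) {
  structure(list(U = U, V = V, a = a, k = k), class = "conn_factored")
}

conn_lowrank <- function(Q, S, d = NULL) {
  structure(list(Q = Q, S = S, d = d), class = "conn_lowrank")
}

#' Dimension of a connectivity object
#' @param W Connectivity (dense matrix, `conn_factored`, or `conn_lowrank`).
#' @return The number of neurons N.
#' @export
conn_dim <- function(W) {
  if (is.matrix(W)) return(nrow(W))
  if (inherits(W, "conn_factored")) return(nrow(W$U))
  if (inherits(W, "conn_lowrank")) return(nrow(W$Q))
  stop("not a connectivity object")
}

#' Apply a connectivity operator to vectors
#'
#' Computes `W %*% x` for any of the supported representations; `x` may be a
#' vector or a column matrix.
#'
#' @param W Connectivity object.
#' @param x Numeric vector or matrix with `conn_dim(W)` rows.
#' @return Vector or matrix of the same shape as `x`.
#' @export
conn_apply <- function(W, x) {
  if (is.matrix(W)) {
    y <- W %*% x
  } else if (inherits(W, "conn_factored")) {
    y <- W$U %*% (W$a * crossprod(W$V, x)) - W$V %*% (W$a * crossprod(W$U, x))
  } else if (inherits(W, "conn_lowrank")) {
    y <- W$Q %*% (W$S %*% crossprod(W$Q, x))
  } else {
    stop("not a connectivity object")
  }
  if (is.matrix(x)) y else drop(y)
}

#' Materialize a connectivity object as a dense matrix
#' @param W Connectivity object.
#' @return Dense `N x N` matrix.
#' @export
conn_dense <- function(W) {
  if (is.matrix(W)) return(W)
  if (inherits(W, "conn_factored")) {
    M <- W$U %*% (W$a * t(W$V))
    return(M - t(M))
  }
  if (inherits(W, "conn_lowrank")) {
    return(W$Q %*% tcrossprod(W$S, W$Q))
  }
  stop("not a connectivity object")
}

#' Frobenius norm of a connectivity object
#' @param W Connectivity object.
#' @return `||W||_F`.
#' @export
conn_frobenius <- function(W) {
  if (is.matrix(W)) return(norm(W, "F"))
  if (inherits(W, "conn_lowrank")) return(norm(W$S, "F"))
  if (inherits(W, "conn_factored")) {
    g <- factored_gram(W)
    return(factored_fnorm(W$a, g))
  }
  stop("not a connectivity object")
}

# Gram blocks of the factor matrices, used for exact Frobenius norms of
# factored connectivities (and of differences of snapshots sharing factors).
factored_gram <- function(W) {
  list(UU = crossprod(W$U), VV = crossprod(W$V), UV = crossprod(W$U, W$V))
}

# ||sum_i d_i (u_i v_i^T - v_i u_i^T)||_F from precomputed Gram blocks:
# expanding <A_i, A_j>_F = 2 [(u_i.u_j)(v_i.v_j) - (u_i.v_j)(u_j.v_i)].
factored_fnorm <- function(d, g) {
  q1 <- drop(crossprod(d, (g$UU * g$VV) %*% d))
  q2 <- drop(crossprod(d, (g$UV * t(g$UV)) %*% d))
  sqrt(max(0, 2 * (q1 - q2)))
}

#' Relative antisymmetry error
#'
#' `||W + W^T||_F / max(1, ||W||_F)`. Factored and low-rank forms are
#' antisymmetric by construction up to the symmetrization of their core, so
#' the error is computed on the core for those.
#'
#' @param W Connectivity object.
#' @return Non-negative scalar.
#' @export
conn_antisymmetry_error <- function(W) {
  if (is.matrix(W)) {
    return(norm(W + t(W), "F") / max(1, norm(W, "F")))
  }
  if (inherits(W, "conn_lowrank")) {
    return(norm(W$S + t(W$S), "F") / max(1, norm(W$S, "F")))
  }
  if (inherits(W, "conn_factored")) return(0)
  stop("not a connectivity object")
}

#' Singular values of a connectivity object
#'
#' For the factored form the spectrum is obtained from the compressed core,
#' which spans the full range of the operator, so the values are exact (the
#' omitted ones are zero).
#'
#' @param W Connectivity object.
#' @param n_values Number of leading singular values to return.
#' @return Numeric vector of length `n_values`, padded with zeros when the
#'   operator rank is smaller.
#' @export
conn_singular_values <- function(W, n_values = 6L) {
  d <- if (is.matrix(W)) {
    svd(W, nu = 0L, nv = 0L)$d
  } else if (inherits(W, "conn_lowrank")) {
    svd(W$S, nu = 0L, nv = 0L)$d
  } else if (inherits(W, "conn_factored")) {
    conn_compress(W, tol = 0)$d
  } else {
    stop("not a connectivity object")
  }
  out <- numeric(n_values)
  out[seq_len(min(n_values, length(d)))] <- d[seq_len(min(n_values, length(d)))]
  out
}

#' Compress a connectivity object to orthonormal low-rank form
#'
#' Builds `W ~= Q S Q^T` with orthonormal `Q` and a small antisymmetric core
#' `S`, truncating singular values below `tol` times the largest. For a
#' factored connectivity the orthonormal range basis is obtained from the
#' eigendecomposition of the Gram matrix of the factors, which keeps the cost
#' in fast BLAS-3 operations; directions whose Gram eigenvalue is below
#' 1e-12 of the largest (i.e. below sqrt(1e-12) in vector norm) are outside
#' the numerically resolvable range and are dropped.
#'
#' @param W Connectivity object.
#' @param tol Relative singular-value truncation threshold. Truncation always
#'   keeps complete singular-value pairs so the core stays antisymmetric.
#' @return A `conn_lowrank` object; its `d` element carries the full singular
#'   spectrum of `W` (before truncation) for diagnostics.
#' @export
conn_compress <- function(W, tol = 1e-9) {
  if (inherits(W, "conn_lowrank")) return(W)
  if (is.matrix(W)) {
    sv <- svd(W)
    d <- sv$d
    r <- rank_keep(d, tol)
    Z <- qr.Q(qr(cbind(sv$u[, seq_len(r), drop = FALSE],
                       sv$v[, seq_len(r), drop = FALSE])))
    S <- crossprod(Z, W %*% Z)
    return(conn_lowrank(Z, (S - t(S)) / 2, d = d))
  }
  if (!inherits(W, "conn_factored")) stop("not a connectivity object")
  B <- cbind(W$U, W$V)
  G <- crossprod(B)
  eg <- eigen(G, symmetric = TRUE)
  keep <- eg$values >= max(eg$values, 0) * 1e-12 & eg$values > 0
  if (!any(keep)) {
    # zero operator
    N <- nrow(B)
    return(conn_lowrank(matrix(0, N, 1L), matrix(0, 1L, 1L), d = 0))
  }
  Q <- B %*% sweep(eg$vectors[, keep, drop = FALSE], 2L,
                   sqrt(eg$values[keep]), "/")
  C <- crossprod(Q, W$U) %*% (W$a * t(crossprod(Q, W$V)))
  C <- C - t(C)
  sv <- svd(C)
  d <- sv$d
  r <- rank_keep(d, tol)
  Z <- qr.Q(qr(cbind(sv$u[, seq_len(r), drop = FALSE],
                     sv$v[, seq_len(r), drop = FALSE])))
  S <- crossprod(Z, C %*% Z)
  conn_lowrank(Q %*% Z, (S - t(S)) / 2, d = d)
}

# number of singular values kept: at least 2, whole pairs, above tol * d[1]
rank_keep <- function(d, tol) {
  if (length(d) == 0L || d[1L] <= 0) return(1L)
  r <- sum(d >= d[1L] * max(tol, 0))
  r <- max(r, 2L)
  if (r %% 2L == 1L && r < length(d)) r <- r + 1L
  min(r, length(d))
}

#' Sum two connectivity objects
#'
#' Used to combine separately learned memory groups into one connectivity
#' (`W* = W1* + W2* + ...`). Dense + dense stays dense; low-rank + low-rank
#' concatenates and re-orthonormalizes the bases; other mixtures are
#' materialized densely.
#'
#' @param A,B Connectivity objects of equal dimension.
#' @return A connectivity object representing `A + B`.
#' @export
conn_add <- function(A, B) {
  if (conn_dim(A) != conn_dim(B)) {
    stop("connectivity dimensions differ: ", conn_dim(A), " vs ", conn_dim(B))
  }
  if (is.matrix(A) && is.matrix(B)) return(A + B)
  if (inherits(A, "conn_lowrank") && inherits(B, "conn_lowrank")) {
    Q <- qr.Q(qr(cbind(A$Q, B$Q)))
    S <- crossprod(Q, A$Q) %*% tcrossprod(A$S, crossprod(Q, A$Q)) +
         crossprod(Q, B$Q) %*% tcrossprod(B$S, crossprod(Q, B$Q))
    return(conn_lowrank(Q, (S - t(S)) / 2))
  }
  conn_dense(A) + conn_dense(B)
}
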