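# Predictor-corrector integration of the storage and retrieval dynamics.
#
# Storage couples the neural state to the plasticity:
#
#   x' = -x + W x + b(t)
#   W' = -gamma W + rho (x x_tau^T - x_tau x^T),   x_tau = x(t - tau)
#
# The delayed outer-product rule is the Dirac-delta reduction of a
# timing-dependent plasticity kernel: pre-before-post pairs at lag tau
# potentiate W_ij while the reversed order depresses it, which makes the
# update antisymmetric by construction. Retrieval freezes the plasticity
# (gamma = rho = 0) and drives the now-linear system with a cue.
#
# Both phases use Heun's two-stage predictor-corrector (explicit Euler
# predictor, trapezoidal corrector), second-order accurate on smooth
# solutions. The delayed state is linearly interpolated on the stored grid;
# the pre-history x(s), s <= 0, is the constant initial state.

#' Trajectory container
#'
#' @param times Uniform time grid.
#' @param states `N x length(times)` matrix of state vectors (columns).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(times, states) {
  stopifnot(length(times) == ncol(states))
  structure(list(times = times, states = states), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> N=%d, %d time points on [%g, %g]\n",
              nrow(x$states), length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

# linear interpolation of the delayed state on the filled part of X;
# constant pre-history x0 for query times <= 0
delayed_state <- function(tq, X, dt, x0) {
  if (tq <= 0) return(x0)
  i <- floor(tq / dt + 1e-9)
  w <- tq / dt - i
  if (w < 1e-9) return(X[, i + 1L])
  (1 - w) * X[, i + 1L] + w * X[, i + 2L]
}

default_x0 <- function(N, scale, seed) {
  with_seed(seed, stats::rnorm(N, sd = 1e-3 * max(1, scale)))
}

#' Integrate the storage (plasticity) phase
#'
#' Advances the coupled state/connectivity delay system under the harmonic
#' memory input and records connectivity snapshots, by default once per
#' forcing period. From an antisymmetric (e.g. zero) initial connectivity,
#' every snapshot is antisymmetric because the plasticity update is.
#'
#' Two connectivity carriers are available. `"dense"` keeps the full `N x N`
#' matrix. `"factored"` accumulates the Heun-stage outer products together
#' with their exact homeostatic decay factors, which is algebraically the
#' same scheme (the two modes agree to rounding) but needs O(N * steps)
#' memory and is much faster for large N. `"auto"` picks factored above
#' N = 600.
#'
#' @param params A [model_params()].
#' @param spec A [storage_spec()]; its `omega` must match `params$omega`.
#' @param x0 Initial state; default: seeded Gaussian with standard deviation
#'   `1e-3 * max(1, max |m_i|)` ("appropriately small").
#' @param W0 Initial connectivity; default zero. Dense mode accepts any
#'   matrix; factored mode requires zero.
#' @param seed Seed for the default initial state.
#' @param mode `"auto"`, `"dense"` or `"factored"`.
#' @param snapshot_every Snapshot spacing in time units; default one forcing
#'   period `2 pi / omega`.
#' @return An object of class `storage_result`: list with `trajectory`,
#'   `snapshots` (list of `list(time, W)`), `Wstar` (the final snapshot) and
#'   `mode`.
#' @export
integrate_storage <- function(params, spec, x0 = NULL, W0 = NULL, seed = 1L,
                              mode = c("auto", "dense", "factored"),
                              snapshot_every = NULL) {
  stopifnot(inherits(params, "model_params"), inherits(spec, "storage_spec"))
  mode <- match.arg(mode)
  if (abs(spec$omega - params$omega) > 1e-12) {
    warning("storage_spec omega differs from model_params omega; ",
            "using the model parameters", call. = FALSE)
  }
  N <- spec$N
  if (mode == "auto") mode <- if (N > 600L) "factored" else "dense"
  dt <- params$dt; Tend <- params$T
  gamma <- params$gamma; rho <- params$rho
  tau <- params$tau; omega <- params$omega
  nsteps <- as.integer(round(Tend / dt))
  times <- seq(0, by = dt, length.out = nsteps + 1L)
  M <- spec$memories; phases <- spec$phases

  x0 <- x0 %||% default_x0(N, max(abs(M)), seed)
  stopifnot(length(x0) == N)
  X <- matrix(0, N, nsteps + 1L)
  X[, 1L] <- x0

  dense <- mode == "dense"
  if (dense) {
    W <- if (is.null(W0)) matrix(0, N, N) else conn_dense(W0)
    stopifnot(nrow(W) == N, ncol(W) == N)
  } else {
    if (!is.null(W0) && any(conn_dense(W0) != 0)) {
      stop("factored mode starts from zero connectivity; ",
           "use mode = \"dense\" for a nonzero W0", call. = FALSE)
    }
    U <- matrix(0, N, 2L * nsteps)
    V <- matrix(0, N, 2L * nsteps)
    a <- numeric(2L * nsteps)
    k <- 0L
  }

  # exact Heun coefficients for the homeostatic decay and the two
  # plasticity-stage outer products
  c_dec <- 1 - gamma * dt + (gamma * dt)^2 / 2
  c1 <- (rho * dt / 2) * (1 - gamma * dt)
  c2 <- rho * dt / 2

  period <- 2 * pi / omega
  snapshot_every <- snapshot_every %||% period
  snap_steps <- unique(pmin(nsteps, round(
    seq(snapshot_every, Tend + snapshot_every / 2, by = snapshot_every) / dt)))
  snap_steps <- sort(unique(c(snap_steps[snap_steps >= 1L], nsteps)))
  snaps <- vector("list", length(snap_steps))
  isnap <- 1L

  for (s in seq_len(nsteps)) {
    t0 <- times[s]; t1 <- times[s + 1L]
    x <- X[, s]
    xt0 <- delayed_state(t0 - tau, X, dt, x0)
    b0 <- drop(M %*% sin(omega * t0 - phases))
    b1 <- drop(M %*% sin(omega * t1 - phases))
    Wx <- if (dense) drop(W %*% x) else
      drop(U %*% (a * crossprod(V, x)) - V %*% (a * crossprod(U, x)))
    f0 <- -x + Wx + b0
    xp <- x + dt * f0
    xt1 <- delayed_state(t1 - tau, X, dt, x0)
    Wxp <- if (dense) drop(W %*% xp) else
      drop(U %*% (a * crossprod(V, xp)) - V %*% (a * crossprod(U, xp)))
    # predictor connectivity applied to the predictor state:
    # W~ = (1 - gamma dt) W + rho dt (x xt0^T - xt0 x^T)
    Wtxp <- (1 - gamma * dt) * Wxp +
      rho * dt * (sum(xt0 * xp) * x - sum(x * xp) * xt0)
    f1 <- -xp + Wtxp + b1
    xn <- x + (dt / 2) * (f0 + f1)
    if (!is.finite(sum(xn))) {
      stop("storage integration produced a non-finite state at step ", s,
           " (t = ", format(t1), ")", call. = FALSE)
    }
    X[, s + 1L] <- xn
    if (dense) {
      W <- c_dec * W +
        c1 * (tcrossprod(x, xt0) - tcrossprod(xt0, x)) +
        c2 * (tcrossprod(xp, xt1) - tcrossprod(xt1, xp))
    } else {
      a <- a * c_dec
      U[, k + 1L] <- x;  V[, k + 1L] <- xt0; a[k + 1L] <- c1
      U[, k + 2L] <- xp; V[, k + 2L] <- xt1; a[k + 2L] <- c2
      k <- k + 2L
    }
    if (isnap <= length(snap_steps) && s == snap_steps[isnap]) {
      snaps[[isnap]] <- if (dense) {
        list(time = t1, W = W)
      } else {
        list(time = t1, a = a, k = k) # factors attached after the loop
      }
      isnap <- isnap + 1L
    }
  }

  if (!dense) {
    # snapshots reference the final (immutable) factor matrices; coefficients
    # recorded at snapshot time are zero beyond the columns filled by then
    snaps <- lapply(snaps, function(sn) {
      list(time = sn$time, W = conn_factored(U, V, sn$a, sn$k))
    })
  }

  structure(list(trajectory = trajectory(times, X),
                 snapshots = snaps,
                 Wstar = snaps[[length(snaps)]]$W,
                 mode = mode,
                 params = params),
            class = "storage_result")
}

#' @export
print.storage_result <- function(x, ...) {
  cat(sprintf("<storage_result> N=%d, %s mode, %d snapshots, T=%g\n",
              conn_dim(x$Wstar), x$mode, length(x$snapshots), max(x$trajectory$times)))
  invisible(x)
}

#' Integrate the retrieval phase
#'
#' Advances the linear forced system `x' = -x + W* x + b(t)` (plasticity
#' frozen, no delay term remains) with the same predictor-corrector.
#'
#' @param Wstar Converged connectivity (dense matrix, factored, or low-rank).
#' @param cue A [cue_spec()].
#' @param x0 Initial state; default seeded Gaussian, standard deviation
#'   `1e-3 * max(1, max |m_c|)`.
#' @param dt Integration step (default 0.01).
#' @param T Duration (default 15).
#' @param seed Seed for the default initial state.
#' @param omega Forcing frequency; defaults to the cue's.
#' @return A [trajectory()].
#' @export
integrate_retrieval <- function(Wstar, cue, x0 = NULL, dt = 0.01, T = 15,
                                seed = 2L, omega = NULL) {
  stopifnot(inherits(cue, "cue_spec"))
  omega <- omega %||% cue$omega
  N <- conn_dim(Wstar)
  if (cue$N != N) {
    stop("cue dimension ", cue$N, " does not match connectivity dimension ", N)
  }
  nsteps <- as.integer(round(T / dt))
  times <- seq(0, by = dt, length.out = nsteps + 1L)
  M <- cue$memories; phases <- cue$phases
  x <- x0 %||% default_x0(N, max(abs(M)), seed)
  stopifnot(length(x) == N)
  X <- matrix(0, N, nsteps + 1L)
  X[, 1L] <- x
  for (s in seq_len(nsteps)) {
    b0 <- drop(M %*% sin(omega * times[s] - phases))
    b1 <- drop(M %*% sin(omega * times[s + 1L] - phases))
    f0 <- -x + conn_apply(Wstar, x) + b0
    xp <- x + dt * f0
    f1 <- -xp + conn_apply(Wstar, xp) + b1
    x <- x + (dt / 2) * (f0 + f1)
    if (!is.finite(sum(x))) {
      stop("retrieval integration produced a non-finite state at step ", s,
           " (t = ", format(times[s + 1L]), ")", call. = FALSE)
    }
    X[, s + 1L] <- x
  }
  trajectory(times, X)
}

#' Analytic periodic solution of the retrieval system
#'
#' The linear retrieval system under a sinusoidal cue has a unique
#' asymptotically stable periodic solution. For each cue component
#' `sin(omega t - xi) m`, solving the complex system
#' `((1 + i omega) I - W*) z = m` gives the steady state as the imaginary
#' part of the rotating phasor `e^{i(omega t - xi)} z`. An antisymmetric `W*`
#' has purely imaginary eigenvalues, so the shifted matrix is always
#' invertible. This closed form serves as an independent oracle for
#' [integrate_retrieval()].
#'
#' @param Wstar Connectivity object (antisymmetric).
#' @param cue A [cue_spec()].
#' @param omega Forcing frequency; defaults to the cue's.
#' @return A function mapping a time vector to the steady state (an
#'   `N x length(t)` matrix, dropped to a vector for scalar `t`).
#' @export
phasor_steady_state <- function(Wstar, cue, omega = NULL) {
  stopifnot(inherits(cue, "cue_spec"))
  omega <- omega %||% cue$omega
  N <- conn_dim(Wstar)
  if (cue$N != N) {
    stop("cue dimension ", cue$N, " does not match connectivity dimension ", N)
  }
  s <- 1 + 1i * omega
  solve_component <- function(m) {
    if (is.matrix(Wstar)) {
      z <- tryCatch(solve(s * diag(N) - Wstar, m), error = function(e)
        stop("phasor system is singular; the connectivity is not ",
             "antisymmetric or contains corrupt values", call. = FALSE))
    } else {
      lr <- conn_compress(Wstar)
      r <- ncol(lr$Q)
      qm <- crossprod(lr$Q, m)
      z <- tryCatch(
        drop(lr$Q %*% solve(s * diag(r) - lr$S, qm)) + (m - drop(lr$Q %*% qm)) / s,
        error = function(e)
          stop("phasor system is singular; the connectivity is not ",
               "antisymmetric or contains corrupt values", call. = FALSE))
    }
    z
  }
  Z <- vapply(seq_len(cue$n), function(j) solve_component(cue$memories[, j]),
              complex(N))
  if (!is.matrix(Z)) Z <- matrix(Z, ncol = cue$n)
  ReZ <- Re(Z); ImZ <- Im(Z)
  phases <- cue$phases
  function(t) {
    th <- outer(phases, omega * t, function(xi, wt) wt - xi)
    drop(ReZ %*% sin(th) + ImZ %*% cos(th))
  }
}

#' Check convergence of the stored connectivity
#'
#' The memories are considered stored once the connectivity is (numerically)
#' periodic: the relative Frobenius change over the last full forcing period,
#' `||W(t_end) - W(t_end - 2 pi / omega)||_F / ||W(t_end)||_F`, falls below
#' `tol`.
#'
#' @param snapshots List of `list(time, W)` as produced by
#'   [integrate_storage()]; must span at least one forcing period.
#' @param omega Forcing frequency.
#' @param tol Relative-change tolerance (default 1e-2).
#' @return List with `converged` (flag), `Wstar` (last snapshot),
#'   `rel_change`, and `times` (the two compared snapshot times).
#' @export
check_convergence <- function(snapshots, omega, tol = 1e-2) {
  if (length(snapshots) < 2L) stop("need at least two connectivity snapshots")
  times <- vapply(snapshots, `[[`, numeric(1L), "time")
  period <- 2 * pi / omega
  t_end <- times[length(times)]
  target <- t_end - period
  iprev <- which.min(abs(times - target))
  if (abs(times[iprev] - target) > period / 2 || iprev == length(times)) {
    stop("snapshots do not span a full forcing period before the last one")
  }
  Wend <- snapshots[[length(snapshots)]]$W
  Wprev <- snapshots[[iprev]]$W
  fn_end <- conn_frobenius(Wend)
  if (fn_end == 0) {
    return(list(converged = FALSE, Wstar = Wend, rel_change = Inf,
                times = c(times[iprev], t_end),
                message = "connectivity is identically zero"))
  }
  if (inherits(Wend, "conn_factored") && inherits(Wprev, "conn_factored") &&
      identical(dim(Wend$U), dim(Wprev$U))) {
    # snapshots from one run share the factor matrices; the difference is a
    # coefficient difference in the same basis, so its norm is exact
    g <- factored_gram(Wend)
    fn_diff <- factored_fnorm(Wend$a - Wprev$a, g)
    fn_end <- factored_fnorm(Wend$a, g)
  } else {
    fn_diff <- norm(conn_dense(Wend) - conn_dense(Wprev), "F")
  }
  rel <- fn_diff / fn_end
  list(converged = rel < tol, Wstar = Wend, rel_change = rel,
       times = c(times[iprev], t_end))
}
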