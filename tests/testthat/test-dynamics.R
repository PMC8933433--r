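# Harmonic inputs, storage/retrieval integration, and the phasor oracle.

test_that("harmonic storage input follows the phase-staggered sum", {
  M <- cbind(c(1, 0), c(0, 2))
  spec <- storage_spec(M, phases = c(0, pi / 2), omega = 1.5)
  t <- 0.7
  expected <- sin(1.5 * t) * M[, 1L] + sin(1.5 * t - pi / 2) * M[, 2L]
  expect_equal(storage_input(spec, t), expected)
  # omega t = xi_1 with a single memory gives the zero vector
  spec1 <- storage_spec(M[, 1L, drop = FALSE], phases = 0, omega = 2)
  expect_equal(storage_input(spec1, 0), c(0, 0))
  # equal memories at xi = 0, pi/2: sum of the two sines, evaluated directly
  m <- c(1, 2, 3)
  spec2 <- storage_spec(cbind(m, m + 1e-9), phases = c(0, pi / 2), omega = 1)
  wt <- pi / 4
  expect_equal(storage_input(spec2, wt),
               sin(wt) * m + sin(wt - pi / 2) * (m + 1e-9))
  # default phases are pi (i - 1) / n
  spec5 <- storage_spec(matrix(rnorm(10 * 5), 10L), omega = 1.5)
  expect_equal(spec5$phases, pi * (0:4) / 5)
})

test_that("input specs validate their arguments", {
  expect_error(storage_spec(list(c(1, 2), c(1, 2, 3))), "mixed lengths")
  expect_error(storage_spec(cbind(1:2, 3:4), phases = c(0.5, 0.2)),
               "strictly increasing")
  expect_error(storage_spec(cbind(1:2, 3:4), phases = c(0, pi)),
               "strictly increasing")
  expect_error(storage_spec(matrix(0, 3L, 2L)), "zero")
  expect_error(cue_spec(list()), "empty|no components")
  expect_error(model_params(tau = -1), "positive")
  expect_error(model_params(tau = 50, T = 40), "smaller")
})

test_that("cue input cancels in antiphase and at its sampling phase", {
  m <- rnorm(6)
  cue <- cue_spec(cbind(m, m), phases = c(0.3, 0.3 + pi), omega = 1.2)
  for (t in seq(0, 5, by = 0.37)) {
    expect_lt(max(abs(cue_input(cue, t))), 1e-12)
  }
  single <- cue_spec(m, omega = 1.2)
  expect_equal(cue_input(single, 0.8), sin(1.2 * 0.8) * m)
  expect_lt(max(abs(cue_input(single, 0))), 1e-12)
})

test_that("retrieval with zero coupling decays exponentially", {
  N <- 8L
  x0 <- rnorm(N)
  cue <- cue_spec(numeric(N), omega = 1.5) # b(t) = 0
  traj <- integrate_retrieval(matrix(0, N, N), cue, x0 = x0, dt = 0.01, T = 5)
  expected <- outer(x0, exp(-traj$times))
  expect_lt(max(abs(traj$states - expected)) / max(abs(x0)), 1e-4)
})

test_that("storage conserves antisymmetry and both carriers agree", {
  set.seed(71)
  D <- 10L; K <- 4L; n <- 3L
  ts <- make_tag_set(n, K, seed = 3L)
  Fm <- matrix(rnorm(D * n, sd = 0.1), D, n)
  M <- vapply(seq_len(n), function(i) encode(Fm[, i], ts$vectors[, i]),
              numeric(D * K))
  params <- model_params(T = 12)
  spec <- storage_spec(M)
  std <- integrate_storage(params, spec, seed = 5L, mode = "dense")
  stf <- integrate_storage(params, spec, seed = 5L, mode = "factored")
  for (sn in std$snapshots) {
    expect_lt(conn_antisymmetry_error(sn$W), 1e-10)
  }
  # identical trajectories and connectivities between the carriers
  expect_equal(std$trajectory$states, stf$trajectory$states,
               tolerance = 1e-12)
  Wd <- conn_dense(std$Wstar); Wf <- conn_dense(stf$Wstar)
  expect_lt(norm(Wd - Wf, "F") / norm(Wd, "F"), 1e-8)
  # a dense run from a nonzero antisymmetric start stays antisymmetric
  W0 <- rand_antisym(D * K, seed = 9L, spectral_norm = 0.05)
  std2 <- integrate_storage(params, spec, seed = 5L, W0 = W0, mode = "dense")
  expect_lt(conn_antisymmetry_error(std2$Wstar), 1e-10)
})

test_that("storage flags non-finite states with the offending step", {
  spec <- storage_spec(cbind(c(1, 0)), phases = 0)
  params <- model_params(T = 5)
  expect_error(integrate_storage(params, spec, x0 = c(Inf, 0)),
               "non-finite state at step")
})

test_that("homeostatic decay alone never converges to a nonzero fixed point", {
  N <- 6L
  params <- model_params(gamma = 0.5, rho = 1e-12, T = 20)
  W0 <- rand_antisym(N, seed = 2L, spectral_norm = 1)
  spec <- storage_spec(matrix(c(0.1, rep(0, N - 1L))), phases = 0)
  st <- integrate_storage(params, spec, W0 = W0, seed = 1L, mode = "dense")
  conv <- check_convergence(st$snapshots, params$omega)
  expect_false(conv$converged)
  # snapshots decay by the exact per-step Heun factor of W' = -gamma W
  c_dec <- 1 - params$gamma * params$dt + (params$gamma * params$dt)^2 / 2
  sn <- st$snapshots[[3L]]
  steps <- round(sn$time / params$dt)
  expect_equal(norm(sn$W, "F"), c_dec^steps * norm(W0, "F"),
               tolerance = 1e-6)
})

test_that("convergence check compares snapshots one period apart", {
  W <- rand_antisym(5L, seed = 4L)
  const <- lapply(c(2, 4.2, 6.3, 8.4), function(t) list(time = t, W = W))
  conv <- check_convergence(const, omega = 1.5)
  expect_true(conv$converged)
  expect_equal(conv$rel_change, 0)
  zero <- lapply(c(2, 6.3), function(t) list(time = t, W = matrix(0, 5, 5)))
  convz <- check_convergence(zero, omega = 1.5)
  expect_false(convz$converged)
  expect_error(check_convergence(const[1L], omega = 1.5), "two")
})

test_that("phasor oracle matches closed forms and has zero residual", {
  N <- 12L; omega <- 1.5
  m <- rnorm(N)
  cue <- cue_spec(m, omega = omega)
  # with W = 0 each component is the scalar forced response
  ss <- phasor_steady_state(matrix(0, N, N), cue)
  ts <- seq(0, 10, by = 0.5)
  expected <- outer(m, (sin(omega * ts) - omega * cos(omega * ts)) / (1 + omega^2))
  expect_equal(ss(ts), expected, tolerance = 1e-12)
  # residual of x' + x - W x - b(t) by central differences, random W
  W <- rand_antisym(N, seed = 8L, spectral_norm = 1.7)
  ss2 <- phasor_steady_state(W, cue)
  h <- 1e-5
  for (t in c(0.3, 2.1, 7.9)) {
    xdot <- (ss2(t + h) - ss2(t - h)) / (2 * h)
    resid <- xdot + ss2(t) - drop(W %*% ss2(t)) - cue_input(cue, t)
    expect_lt(max(abs(resid)), 1e-8 * sqrt(sum(m^2)))
  }
})

test_that("an in-plane cue keeps the steady orbit inside the memory plane", {
  # with two stored memories the plane is their span, so each stored
  # representation lies in the plane and its steady orbit stays there
  set.seed(15)
  D <- 12L; K <- 3L
  ts <- make_tag_set(2L, K, seed = 6L)
  Fm <- matrix(rnorm(D * 2L, sd = 0.3), D, 2L)
  M <- vapply(1:2, function(i) encode(Fm[, i], ts$vectors[, i]), numeric(D * K))
  spec <- storage_spec(M)
  st <- integrate_storage(model_params(), spec, seed = 3L, mode = "dense")
  plane <- memory_plane(M, spec$phases)
  ss <- phasor_steady_state(st$Wstar, cue_spec(3 * M[, 1L], omega = 1.5))
  tt <- seq(0, 2 * pi / 1.5, length.out = 100L)
  orbit <- ss(tt)
  expect_lt(max(plane_distance(orbit, plane)),
            1e-8 * max(sqrt(colSums(orbit^2))))
})

test_that("retrieval converges to the phasor steady state", {
  N <- 30L; omega <- 1.5
  W <- rand_antisym(N, seed = 13L, spectral_norm = 2)
  m <- rnorm(N)
  cue <- cue_spec(m, omega = omega)
  traj <- integrate_retrieval(W, cue, dt = 0.01, T = 15, seed = 1L)
  err <- final_period_error(traj, phasor_steady_state(W, cue), omega)
  expect_lt(err, 1e-3)
  # multi-component cue against the low-rank carrier
  lr <- conn_compress(W, tol = 0)
  cue2 <- cue_spec(cbind(m, rnorm(N)), phases = c(0, 1.1), omega = omega)
  traj2 <- integrate_retrieval(lr, cue2, dt = 0.01, T = 15, seed = 2L)
  err2 <- final_period_error(traj2, phasor_steady_state(lr, cue2), omega)
  expect_lt(err2, 1e-3)
})
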