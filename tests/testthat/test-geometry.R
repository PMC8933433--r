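# Memory-plane geometry and retrieval metrics.

test_that("the storage input lies in its memory plane at all times", {
  set.seed(19)
  M <- matrix(rnorm(40 * 5), 40L, 5L)
  spec <- storage_spec(M, omega = 1.5)
  plane <- memory_plane(M, spec$phases)
  expect_false(plane$degenerate)
  B <- plane$basis
  expect_lt(max(abs(crossprod(B) - diag(ncol(B)))), 1e-12)
  # u and v are in the span of the basis
  expect_lt(max(abs(plane$u - B %*% crossprod(B, plane$u))),
            1e-10 * sqrt(sum(plane$u^2)))
  for (t in seq(0.1, 6, by = 0.7)) {
    b <- storage_input(spec, t)
    expect_lt(plane_distance(b, plane), 1e-10 * sqrt(sum(b^2)))
  }
})

test_that("a single memory at phase zero gives a degenerate plane", {
  m <- rnorm(12)
  plane <- memory_plane(m, phases = 0)
  expect_true(plane$degenerate)
  expect_equal(plane$u, m)
  expect_equal(plane$v, 0 * m)
  expect_equal(ncol(plane$basis), 1L)
  expect_lt(plane_distance(3 * m, plane), 1e-10)
})

test_that("plane distance matches projection identities and a grid oracle", {
  set.seed(23)
  M <- matrix(rnorm(15 * 3), 15L, 3L)
  plane <- memory_plane(M)
  # in-plane point
  p <- drop(plane$basis %*% c(1.3, -0.4))
  expect_lt(plane_distance(p, plane), 1e-12)
  # orthogonal point has distance equal to its norm
  x <- rnorm(15)
  xp <- x - drop(plane$basis %*% crossprod(plane$basis, x))
  expect_equal(plane_distance(xp, plane), sqrt(sum(xp^2)), tolerance = 1e-10)
  # brute-force minimization over a dense grid of plane points
  x <- rnorm(15)
  cstar <- drop(crossprod(plane$basis, x))
  grid <- as.matrix(expand.grid(seq(cstar[1L] - 1, cstar[1L] + 1, length.out = 201L),
                                seq(cstar[2L] - 1, cstar[2L] + 1, length.out = 201L)))
  dists <- sqrt(colSums((x - plane$basis %*% t(grid))^2))
  expect_equal(plane_distance(x, plane), min(dists), tolerance = 1e-4)
})

test_that("intersection times follow the arctangent formula", {
  expect_equal(intersection_time(1.5, 0L), atan(1.5) / 1.5)
  expect_equal(intersection_time(1.5, 0L), 0.655196, tolerance = 1e-6)
  ks <- 0:5
  expect_equal(diff(intersection_time(2.2, ks)), rep(pi / 2.2, 5L))
})

test_that("retrieval quality reproduces closed-form cases", {
  D <- 7L; K <- 3L; n <- 3L
  ts <- make_tag_set(n, K, seed = 2L)
  Fm <- matrix(rnorm(D * n), D, n)
  M <- vapply(seq_len(n), function(i) encode(Fm[, i], ts$vectors[, i]),
              numeric(D * K))
  times <- seq(0, 2, by = 0.1)
  # constant state sum(m_i): every similarity is 1
  Xc <- matrix(rowSums(M), D * K, length(times))
  rq <- retrieval_quality(trajectory(times, Xc), Fm, ts)
  expect_equal(rq$p_series, rep(1, length(times)))
  expect_equal(rq$p_bar, 1)
  # zero state: p identically 0
  rq0 <- retrieval_quality(trajectory(times, 0 * Xc), Fm, ts)
  expect_equal(rq0$p_bar, 0)
  # p_bar is the trapezoidal time-average of p(t)
  Xr <- matrix(rnorm(D * K * length(times)), D * K)
  rqr <- retrieval_quality(trajectory(times, Xr), Fm, ts)
  manual <- sum(diff(times) * (rqr$p_series[-1L] + rqr$p_series[-length(times)]) / 2) /
    (max(times) - min(times))
  expect_equal(rqr$p_bar, manual, tolerance = 1e-12)
  # signed mode averages with sign
  rqs <- retrieval_quality(trajectory(times, -Xc), Fm, ts, mode = "signed")
  expect_equal(rqs$p_bar, -1)
  expect_error(retrieval_quality(trajectory(times, Xc), 0 * Fm, ts),
               "nonzero")
})

test_that("role fitness integrates |sin| and is non-decreasing", {
  D <- 5L; K <- 2L
  roles <- make_tag_set(2L, K, seed = 4L)
  f <- rand_unit(D, 31L)
  m <- encode(f, roles$vectors[, 1L])
  times <- seq(0, pi, length.out = 2001L)
  X <- outer(m, sin(times))
  words <- matrix(f, ncol = 1L); colnames(words) <- "w"
  rf <- role_fitness(trajectory(times, X), words, roles)
  expect_equal(rf$P[length(times), 1L, 1L], 2, tolerance = 1e-3)
  # orthogonal role stays at zero
  expect_lt(rf$P[length(times), 1L, 2L], 1e-10)
  expect_true(all(diff(rf$P[, 1L, 1L]) >= -1e-15))
  # zero trajectory: all curves zero
  rf0 <- role_fitness(trajectory(times, 0 * X), words, roles)
  expect_true(all(rf0$P == 0))
  expect_error(role_fitness(trajectory(times, X), words, roles, t0 = -1),
               "outside")
})

test_that("dominance applies the slope-ratio rule", {
  times <- seq(0, 10, by = 0.1)
  P <- array(0, c(length(times), 3L, 1L),
             dimnames = list(NULL, c("a", "b", "c"), "S"))
  P[, 1L, 1L] <- 1.0 * times
  P[, 2L, 1L] <- 0.45 * times
  P[, 3L, 1L] <- 0.05 * times
  rf <- structure(list(times = times, P = P, words = c("a", "b", "c"),
                       roles = "S"), class = "role_fitness")
  dom <- dominance(rf, window_fraction = 0.5, threshold_fraction = 0.5)
  expect_equal(dom$word[dom$dominant], "a")
  expect_equal(dom$slope, c(1.0, 0.45, 0.05), tolerance = 1e-10)
  # two equal slopes are co-dominant
  P[, 2L, 1L] <- 1.0 * times + 0.01 * sin(times)
  rf$P <- P
  dom2 <- dominance(rf)
  expect_setequal(dom2$word[dom2$dominant], c("a", "b"))
})
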