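# Shared fixtures, computed lazily and cached for the whole suite.

.fixtures <- new.env(parent = emptyenv())

# One stored group of five 16x16 synthetic images in the reference
# configuration (omega = 1.5, gamma = rho = 0.5, tau = pi/3, T = 40,
# dt = 0.1, sigma = 0.02), reused by every test that needs a converged
# connectivity.
fixture_image_store <- function() {
  if (is.null(.fixtures$store)) {
    .fixtures$store <- image_task_storage(seed = 101L)
  }
  .fixtures$store
}

fixture_image_report <- function(cue_mode) {
  key <- paste0("report_", cue_mode)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- run_image_task(cue_mode = cue_mode,
                                       store = fixture_image_store())
  }
  .fixtures[[key]]
}

fixture_vocab <- function() {
  if (is.null(.fixtures$vocab)) .fixtures$vocab <- build_sentences(seed = 42L)
  .fixtures$vocab
}

fixture_semantic <- function(cue) {
  key <- paste0("semantic_", cue)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- run_semantic_task(cue, vocab = fixture_vocab(),
                                          seed = 7L)
  }
  .fixtures[[key]]
}

# random antisymmetric matrix with prescribed spectral norm
rand_antisym <- function(N, seed, spectral_norm = 1) {
  A <- stdpmem:::with_seed(seed, matrix(rnorm(N * N), N, N))
  A <- A - t(A)
  A * spectral_norm / norm(A, "2")
}

rand_unit <- function(N, seed) {
  v <- stdpmem:::with_seed(seed, rnorm(N))
  v / sqrt(sum(v^2))
}

# relative L2 discrepancy between a trajectory and the analytic steady state
# over the final forcing period
final_period_error <- function(traj, oracle, omega) {
  keep <- traj$times >= max(traj$times) - 2 * pi / omega
  X <- traj$states[, keep, drop = FALSE]
  Y <- oracle(traj$times[keep])
  sqrt(sum((X - Y)^2) / sum(Y^2))
}
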