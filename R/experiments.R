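# Experiment drivers: grouped-image storage/retrieval, memory-capacity sweep,
# and semantic-sentence memory.

#' Build a noisy memory cue
#'
#' Contaminates a datum and its tag before binding:
#' `f~ = sqrt(1 - alpha^2) f + alpha zeta` and
#' `r~ = sqrt(1 - beta^2) r + beta eta`, where `zeta` is an isotropic random
#' vector scaled to `||zeta|| = ||f||` and `eta` an isotropic unit vector, so
#' the contaminated cue keeps approximately the magnitude of the clean one.
#' The noisy tag is not re-normalized (set `normalize_tag = TRUE` to force
#' unit length).
#'
#' @param f Original data vector.
#' @param r Unit tag vector.
#' @param alpha Data-noise level in `[0, 1]` (`alpha = 1` destroys all signal).
#' @param beta Tag-noise level in `[0, 1]`.
#' @param seed Seed for the noise draws.
#' @param normalize_tag Re-normalize the contaminated tag? Default `FALSE`.
#' @return Encoded cue vector (see [encode()]) with attributes `f_tilde` and
#'   `r_tilde`.
#' @export
make_noisy_cue <- function(f, r, alpha = 0.25, beta = 0.2, seed = 1L,
                           normalize_tag = FALSE) {
  if (alpha < 0 || alpha > 1 || beta < 0 || beta > 1) {
    stop("alpha and beta must lie in [0, 1]")
  }
  f <- as.numeric(f); r <- as.numeric(r)
  noise <- with_seed(seed, list(zeta = stats::rnorm(length(f)),
                                eta = stats::rnorm(length(r))))
  zeta <- noise$zeta * sqrt(sum(f^2)) / sqrt(sum(noise$zeta^2))
  eta <- noise$eta / sqrt(sum(noise$eta^2))
  f_t <- sqrt(1 - alpha^2) * f + alpha * zeta
  r_t <- sqrt(1 - beta^2) * r + beta * eta
  if (normalize_tag) r_t <- r_t / sqrt(sum(r_t^2))
  m <- suppressWarnings(encode(f_t, r_t))
  attr(m, "f_tilde") <- f_t
  attr(m, "r_tilde") <- r_t
  m
}

#' Store a group of synthetic images
#'
#' Generates `n_images` seeded synthetic images, maps them to data vectors
#' with amplitude `sigma`, binds each to an orthonormal placeholder tag, and
#' runs the storage dynamics with evenly sequenced phases
#' `xi_i = pi (i - 1) / n`.
#'
#' @param n_images Number of images (must not exceed `K`).
#' @param image_size Image side length (square images).
#' @param params [model_params()].
#' @param sigma Brightness amplitude used for storage (default 0.02).
#' @param K Tag dimension; defaults to `n_images`.
#' @param seed Master seed; image, tag and integrator seeds are derived from
#'   it.
#' @param style Synthetic image style (see [synth_image()]).
#' @param mode Connectivity carrier passed to [integrate_storage()].
#' @return List with the images, data vectors `F`, `tags`, memories `M`,
#'   `phases`, the `storage` result, convergence info `conv`, the compressed
#'   connectivity `Wstar`, the memory `plane`, and the geometry metadata.
#' @export
image_task_storage <- function(n_images = 5L, image_size = 16L,
                               params = model_params(), sigma = 0.02,
                               K = n_images, seed = 1L,
                               style = "blobs", mode = "auto") {
  stopifnot(n_images >= 1L)
  if (n_images > K) stop("n_images must not exceed the tag dimension K")
  H <- image_size; W <- image_size
  images <- lapply(seq_len(n_images), function(i) synth_image(seed * 101L + i, H, W, style))
  Fm <- vapply(images, image_to_vector, numeric(H * W), sigma = sigma)
  tags <- make_tag_set(n_images, K, seed = seed * 101L + 500L)
  M <- vapply(seq_len(n_images), function(i)
    encode(Fm[, i], tags$vectors[, i]), numeric(H * W * K))
  spec <- storage_spec(M, omega = params$omega)
  st <- integrate_storage(params, spec, seed = seed * 101L + 700L, mode = mode)
  conv <- check_convergence(st$snapshots, params$omega)
  list(images = images, F = Fm, tags = tags, M = M, phases = spec$phases,
       sigma = sigma, H = H, W = W, K = K,
       storage = st, conv = conv,
       Wstar = conn_compress(st$Wstar),
       plane = memory_plane(M, spec$phases),
       seed = seed, params = params, style = style)
}

#' Run the grouped-image retrieval task
#'
#' End-to-end reproduction of the auto-associative image experiment: store a
#' group of synthetic images, build a cue (`exact`, `noisy`, `occluded`, or
#' `irrelevant`), integrate the retrieval dynamics, and measure the retrieved
#' quality. The cue for the noisy/occluded/irrelevant modes uses a
#' contaminated tag with noise level `beta`; the irrelevant cue encodes an
#' independently seeded image that was never stored (a structure-free
#' `"noise"`-style image by default, standing in for an unrelated photograph).
#'
#' Reported quantities include the `p(t)` series, its temporal average
#' `p_bar`, the value `p(t_dagger)` at the last analytic plane-intersection
#' time within the window, the per-image cosine similarities there, and
#' reconstructed image snapshots at the intersection and at the
#' farthest-from-plane time of the final forcing period.
#'
#' @param n_images,image_size,params,sigma,K,seed,style See
#'   [image_task_storage()].
#' @param cue_mode One of `"exact"`, `"noisy"`, `"occluded"`, `"irrelevant"`.
#' @param alpha,beta Cue noise levels (defaults 0.25 / 0.2).
#' @param cue_index Which stored image the cue is derived from (default 1).
#' @param occlusion_box Box for `cue_mode = "occluded"`; default the lower
#'   half of the frame.
#' @param irrelevant_style Style of the never-stored cue image.
#' @param retrieval_T,retrieval_dt Retrieval duration and step (15 / 0.01).
#' @param sigma_display Display threshold for reconstructed snapshots.
#' @param store Optional precomputed [image_task_storage()] result, so that
#'   several cue modes can reuse one stored connectivity.
#' @param mode Connectivity carrier for storage.
#' @param noise_seed Seed for the cue noise draws; derived from the master
#'   seed when omitted.
#' @return An object of class `task_report`.
#' @export
run_image_task <- function(n_images = 5L, image_size = 16L,
                           params = model_params(),
                           cue_mode = c("exact", "noisy", "occluded", "irrelevant"),
                           alpha = 0.25, beta = 0.2, sigma = 0.02,
                           K = n_images, seed = 1L, style = "blobs",
                           cue_index = 1L, occlusion_box = NULL,
                           irrelevant_style = "noise",
                           retrieval_T = 15, retrieval_dt = 0.01,
                           sigma_display = 0.002, store = NULL, mode = "auto",
                           noise_seed = NULL) {
  cue_mode <- match.arg(cue_mode)
  store <- store %||% image_task_storage(n_images, image_size, params, sigma,
                                         K, seed, style, mode)
  H <- store$H; W <- store$W; K <- store$K
  Fm <- store$F; tags <- store$tags
  omega <- store$params$omega
  noise_seed <- noise_seed %||% (store$seed * 101L + 900L)

  cue_vec <- switch(cue_mode,
    exact = encode(Fm[, cue_index], tags$vectors[, cue_index]),
    noisy = make_noisy_cue(Fm[, cue_index], tags$vectors[, cue_index],
                           alpha = alpha, beta = beta, seed = noise_seed),
    occluded = {
      occlusion_box <- occlusion_box %||%
        c(floor(H / 2) + 1L, 1L, ceiling(H / 2), W)
      f_occ <- image_to_vector(occlude(store$images[[cue_index]], occlusion_box),
                               sigma = store$sigma)
      make_noisy_cue(f_occ, tags$vectors[, cue_index],
                     alpha = 0, beta = beta, seed = noise_seed)
    },
    irrelevant = {
      img <- synth_image(store$seed * 101L + 1000L, H, W, irrelevant_style)
      make_noisy_cue(image_to_vector(img, sigma = store$sigma),
                     tags$vectors[, cue_index],
                     alpha = 0, beta = beta, seed = noise_seed)
    })
  cue <- cue_spec(cue_vec, omega = omega)

  traj <- integrate_retrieval(store$Wstar, cue, dt = retrieval_dt,
                              T = retrieval_T,
                              seed = store$seed * 101L + 1100L)
  metrics <- retrieval_quality(traj, Fm, tags)

  # last analytic intersection within the window, after the transient
  k_max <- floor((omega * retrieval_T - atan(omega)) / pi)
  t_dagger <- intersection_time(omega, k_max)
  idx_dag <- which.min(abs(traj$times - t_dagger))
  p_tdagger <- metrics$p_series[idx_dag]
  cosines <- vapply(seq_len(ncol(Fm)), function(i) {
    g <- decode(traj$states[, idx_dag], tags$vectors[, i], D = H * W, K = K)
    abs(sum(g * Fm[, i])) / sqrt(sum(g^2) * sum(Fm[, i]^2))
  }, numeric(1L))

  # farthest-from-plane grid time over the final forcing period
  period <- 2 * pi / omega
  final <- which(traj$times >= max(traj$times) - period)
  dists <- plane_distance(traj$states[, final, drop = FALSE], store$plane)
  idx_far <- final[which.max(dists)]

  snap <- function(idx) lapply(seq_len(ncol(Fm)), function(i)
    vector_to_image(decode(traj$states[, idx], tags$vectors[, i],
                           D = H * W, K = K),
                    H, W, sigma_display))

  structure(list(
    cue_mode = cue_mode, store = store, trajectory = traj,
    metrics = metrics, p_bar = metrics$p_bar,
    t_dagger = traj$times[idx_dag], p_tdagger = p_tdagger,
    cosines_tdagger = cosines,
    t_farthest = traj$times[idx_far],
    snapshots_intersection = snap(idx_dag),
    snapshots_farthest = snap(idx_far),
    converged = store$conv$converged,
    provenance = list(seed = store$seed, cue_mode = cue_mode,
                      alpha = alpha, beta = beta, sigma = store$sigma,
                      image_size = image_size, n_images = ncol(Fm),
                      retrieval_T = retrieval_T, retrieval_dt = retrieval_dt,
                      params = unclass(store$params))),
    class = "task_report")
}

#' @export
print.task_report <- function(x, ...) {
  cat(sprintf("<task_report> cue=%s converged=%s p(t+)=%.4f p_bar=%.4f min|cos|(t+)=%.4f\n",
              x$cue_mode, x$converged, x$p_tdagger, x$p_bar,
              min(x$cosines_tdagger)))
  invisible(x)
}

#' Memory-capacity sweep
#'
#' Measures how the time-averaged retrieval performance `p_bar` degrades as
#' the number of stored patterns grows. For each `n`, random unit-norm
#' pattern vectors of dimension `D` are bound to orthonormal tags of
#' dimension `K`, stored, and retrieved with a clean cue equal to the first
#' stored representation; `p_bar` is averaged over `reps` replicates and a
#' log-log slope is fitted.
#'
#' @param D Pattern dimension (default 200).
#' @param K Tag dimension (default 20).
#' @param n_values Group sizes to sweep (each must be at most `K`).
#' @param reps Replicates per group size (default 5).
#' @param params [model_params()].
#' @param retrieval_T,retrieval_dt Retrieval duration and step.
#' @param seed Master seed.
#' @return An object of class `capacity_sweep`: list with the per-run table
#'   `results`, the per-n `summary`, and the fitted log-log `slope`.
#' @export
run_capacity_sweep <- function(D = 200L, K = 20L, n_values = c(2L, 4L, 8L, 16L),
                               reps = 5L, params = model_params(),
                               retrieval_T = 15, retrieval_dt = 0.01,
                               seed = 1L) {
  if (max(n_values) > K) {
    stop("n cannot exceed the tag dimension K = ", K,
         " (tags could not stay orthonormal)")
  }
  rows <- list()
  for (n in n_values) {
    for (rep in seq_len(reps)) {
      base <- seed * 100000L + rep * 1000L + n
      Fm <- with_seed(base, {
        A <- matrix(stats::rnorm(D * n), D, n)
        sweep(A, 2L, sqrt(colSums(A^2)), "/")
      })
      tags <- make_tag_set(n, K, seed = base + 1L)
      M <- vapply(seq_len(n), function(i)
        encode(Fm[, i], tags$vectors[, i]), numeric(D * K))
      if (!is.matrix(M)) M <- matrix(M, ncol = n)
      spec <- storage_spec(M, omega = params$omega)
      st <- integrate_storage(params, spec, seed = base + 2L)
      Wc <- conn_compress(st$Wstar)
      traj <- integrate_retrieval(Wc, cue_spec(M[, 1L], omega = params$omega),
                                  dt = retrieval_dt, T = retrieval_T,
                                  seed = base + 3L)
      pb <- retrieval_quality(traj, Fm, tags)$p_bar
      rows[[length(rows) + 1L]] <- data.frame(n = n, rep = rep, p_bar = pb)
    }
  }
  results <- do.call(rbind, rows)
  summary <- stats::aggregate(p_bar ~ n, data = results, FUN = mean)
  fit <- stats::lm(log(p_bar) ~ log(n), data = summary)
  structure(list(results = results, summary = summary,
                 slope = unname(stats::coef(fit)[2L]), fit = fit),
            class = "capacity_sweep")
}

#' @export
print.capacity_sweep <- function(x, ...) {
  cat("<capacity_sweep> mean p_bar by group size:\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("log-log slope: %.3f\n", x$slope))
  invisible(x)
}

#' Vocabulary and sentences for the semantic-memory task
#'
#' Eight orthonormal word vectors, four orthonormal role tags (subject,
#' predicate, object, modifier), and three sentences that bind a word to each
#' role:
#'
#' * S1: Mary(S) calling(P) John(O) livingroom(M)
#' * S2: John(S) chasing(P) dog(O) garden(M)
#' * S3: John(S) looking(P) Mary(O) garden(M)
#'
#' John occurs once as an object (S1) and twice as a subject (S2, S3); Mary
#' and garden also recur in different contexts, which is what makes single
#' word/role cues ambiguous or exclusive.
#'
#' @param D Word-vector dimension (default 8, the smallest supporting eight
#'   orthonormal words).
#' @param K Role dimension (default 4).
#' @param seed Seed for the orthonormal sets.
#' @return List with `words` (a `D x 8` matrix with word names as column
#'   names), `roles` (a [make_tag_set()] labelled S, P, O, M), and
#'   `sentences` (a list of data frames with columns `word`, `role`,
#'   `word_index`, `role_index`).
#' @export
build_sentences <- function(D = 8L, K = 4L, seed = 42L) {
  word_names <- c("Mary", "John", "dog", "calling", "chasing", "looking",
                  "livingroom", "garden")
  words <- make_tag_set(8L, D, seed = seed, labels = word_names)$vectors
  colnames(words) <- word_names
  roles <- make_tag_set(4L, K, seed = seed + 1L, labels = c("S", "P", "O", "M"))
  sent <- function(...) {
    b <- list(...)
    data.frame(word = vapply(b, `[[`, character(1L), 1L),
               role = vapply(b, `[[`, character(1L), 2L),
               word_index = match(vapply(b, `[[`, character(1L), 1L), word_names),
               role_index = match(vapply(b, `[[`, character(1L), 2L),
                                  roles$labels),
               stringsAsFactors = FALSE)
  }
  sentences <- list(
    S1 = sent(c("Mary", "S"), c("calling", "P"), c("John", "O"),
              c("livingroom", "M")),
    S2 = sent(c("John", "S"), c("chasing", "P"), c("dog", "O"),
              c("garden", "M")),
    S3 = sent(c("John", "S"), c("looking", "P"), c("Mary", "O"),
              c("garden", "M")))
  list(words = words, roles = roles, sentences = sentences)
}

#' Parse a semantic cue description
#'
#' Cues are written `"word:role"`, multi-component cues joined with `+`, e.g.
#' `"John:S+Mary:O"`. Each component keeps the sampling phase of its role
#' position, `xi_j = pi (j - 1) / 4`.
#'
#' @param cue Cue string.
#' @param vocab A [build_sentences()] vocabulary.
#' @param omega Forcing frequency for the resulting [cue_spec()].
#' @return A [cue_spec()].
#' @export
parse_semantic_cue <- function(cue, vocab, omega = 1.5) {
  parts <- strsplit(strsplit(cue, "+", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  comps <- lapply(parts, function(p) {
    if (length(p) != 2L) stop("cue components must be written word:role")
    i <- match(p[1L], colnames(vocab$words))
    j <- match(p[2L], vocab$roles$labels)
    if (is.na(i)) stop("unknown word in cue: ", p[1L])
    if (is.na(j)) stop("unknown role in cue: ", p[2L])
    list(m = encode(vocab$words[, i], vocab$roles$vectors[, j]),
         phase = pi * (j - 1) / 4)
  })
  cue_spec(lapply(comps, `[[`, "m"),
           phases = vapply(comps, `[[`, numeric(1L), "phase"),
           omega = omega)
}

#' Run the semantic-sentence retrieval task
#'
#' Stores each sentence separately as a harmonic stream of its four
#' word-role bindings (phases `pi (j - 1) / 4`), combines the converged
#' connectivities by summation, retrieves with the given cue, and evaluates
#' the role-fitness curves and the dominantly retrieved components.
#'
#' @param cue Cue description string, e.g. `"Mary:S"` or `"John:S+Mary:O"`.
#' @param params [model_params()].
#' @param vocab A [build_sentences()] vocabulary (built with `seed` when
#'   omitted).
#' @param retrieval_T Retrieval duration (default 30).
#' @param retrieval_dt Retrieval step (default 0.01).
#' @param seed Master seed.
#' @param window_fraction,threshold_fraction Dominance parameters (see
#'   [dominance()]).
#' @return An object of class `semantic_report`: list with the `role_fitness`
#'   curves, the `dominance` table, the set of `dominant` labels, per-sentence
#'   storage convergence, and provenance.
#' @export
run_semantic_task <- function(cue, params = model_params(), vocab = NULL,
                              retrieval_T = 30, retrieval_dt = 0.01,
                              seed = 1L, window_fraction = 0.5,
                              threshold_fraction = 0.5) {
  vocab <- vocab %||% build_sentences(seed = seed * 31L + 11L)
  phases <- pi * (0:3) / 4
  stores <- lapply(seq_along(vocab$sentences), function(k) {
    s <- vocab$sentences[[k]]
    M <- vapply(seq_len(nrow(s)), function(b)
      encode(vocab$words[, s$word_index[b]],
             vocab$roles$vectors[, s$role_index[b]]),
      numeric(nrow(vocab$words) * nrow(vocab$roles$vectors)))
    spec <- storage_spec(M, phases = phases, omega = params$omega)
    st <- integrate_storage(params, spec, seed = seed * 31L + 100L + k,
                            mode = "dense")
    list(st = st, conv = check_convergence(st$snapshots, params$omega))
  })
  Wsum <- Reduce(conn_add, lapply(stores, function(x) x$st$Wstar))
  cue_sp <- parse_semantic_cue(cue, vocab, omega = params$omega)
  traj <- integrate_retrieval(Wsum, cue_sp, dt = retrieval_dt,
                              T = retrieval_T, seed = seed * 31L + 200L)
  rf <- role_fitness(traj, vocab$words, vocab$roles)
  dom <- dominance(rf, window_fraction, threshold_fraction)
  structure(list(cue = cue, vocab = vocab, Wstar = Wsum,
                 trajectory = traj, role_fitness = rf, dominance = dom,
                 dominant = dom[dom$dominant, c("word", "role")],
                 converged = vapply(stores, function(x) x$conv$converged,
                                    logical(1L)),
                 provenance = list(seed = seed, cue = cue,
                                   retrieval_T = retrieval_T,
                                   retrieval_dt = retrieval_dt,
                                   params = unclass(params))),
            class = "semantic_report")
}

#' @export
print.semantic_report <- function(x, ...) {
  cat("<semantic_report> cue:", x$cue, "\ndominant components:\n")
  print(x$dominant, row.names = FALSE)
  invisible(x)
}
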