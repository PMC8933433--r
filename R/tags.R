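# Tag vectors and tensor-product encoding/decoding.
#
# A datum f in R^D is bound to a low-dimensional orthonormal tag r in R^K by
# the tensor (outer) product m = f (x) r, flattened so that the data index
# varies slowest: element (d, k) of the D x K outer product sits at position
# (d - 1) * K + k of the state vector. With unit tags the datum is recovered
# exactly by contracting the reshaped state with the tag, and with mutually
# orthonormal tags each component of a superposition is recovered selectively.

#' Construct a set of orthonormal tag vectors
#'
#' Tags mark the slot, modality, or grammatical role of a datum. They are
#' built by orthonormalizing seeded standard-normal draws (QR factorization
#' with a fixed sign convention), so the result is deterministic given the
#' seed.
#'
#' @param m Number of tags (must satisfy `m <= K`).
#' @param K Tag dimension.
#' @param seed Integer seed for the Gaussian draws.
#' @param labels Optional character labels, e.g. role names `c("S","P","O","M")`.
#'   Defaults to slot indices.
#' @return An object of class `tag_set` with elements `vectors` (a `K x m`
#'   matrix whose columns are orthonormal) and `labels`.
#' @examples
#' ts <- make_tag_set(5, 5, seed = 1)
#' crossprod(ts$vectors) # identity to machine precision
#' @export
make_tag_set <- function(m, K, seed = 1L, labels = NULL) {
  stopifnot(length(m) == 1L, length(K) == 1L, m >= 1L, K >= 1L)
  if (m > K) {
    stop("cannot build ", m, " orthonormal tags in dimension K = ", K,
         " (m must not exceed K)", call. = FALSE)
  }
  Q <- with_seed(seed, {
    A <- matrix(stats::rnorm(K * m), K, m)
    qrA <- qr(A)
    Qm <- qr.Q(qrA)
    # fix the sign ambiguity of the QR factor for reproducibility
    s <- sign(diag(qr.R(qrA)))
    s[s == 0] <- 1
    sweep(Qm, 2L, s, "*")
  })
  labels <- labels %||% as.character(seq_len(m))
  stopifnot(length(labels) == m)
  structure(list(vectors = Q, labels = labels), class = "tag_set")
}

#' @export
as.matrix.tag_set <- function(x, ...) x$vectors

#' @export
print.tag_set <- function(x, ...) {
  cat("<tag_set> ", ncol(x$vectors), " orthonormal tags in R^",
      nrow(x$vectors), " [", paste(x$labels, collapse = ", "), "]\n",
      sep = "")
  invisible(x)
}

#' Encode a data vector with a tag vector
#'
#' Computes the flattened tensor product `f (x) r`. The flattening convention
#' places element `(d, k)` of the `D x K` outer product at position
#' `(d - 1) * K + k`, i.e. the tag index varies fastest.
#'
#' @param f Numeric data vector of length `D`.
#' @param r Numeric tag vector of length `K`; must have unit length for exact
#'   decoding (a warning is raised otherwise, an error if zero).
#' @param label Optional label stored as an attribute.
#' @return Numeric vector of length `D * K` with attributes `D`, `K` and
#'   `label`.
#' @seealso [decode()]
#' @export
encode <- function(f, r, label = NULL) {
  f <- as.numeric(f); r <- as.numeric(r)
  if (anyNA(f) || any(!is.finite(f))) stop("f contains non-finite entries")
  nr <- sqrt(sum(r^2))
  if (nr == 0) stop("tag vector is zero; encoding would be unrecoverable")
  if (abs(nr - 1) > 1e-9) {
    warning("tag vector is not unit length (|r| = ", format(nr),
            "); decode() will not be exact", call. = FALSE)
  }
  m <- as.vector(t(tcrossprod(f, r)))
  attr(m, "D") <- length(f)
  attr(m, "K") <- length(r)
  if (!is.null(label)) attr(m, "label") <- label
  m
}

#' Decode a state vector with a tag vector
#'
#' Reshapes the state to a `D x K` array (inverse of the [encode()] layout)
#' and contracts with the tag: for a retrievable state
#' `x = sum_j c_j f_j (x) r_j` with orthonormal tags, decoding with `r_i`
#' returns `c_i f_i` exactly.
#'
#' @param x Numeric state vector of length `D * K`.
#' @param r Tag vector of length `K`.
#' @param D,K Data and tag dimensions; taken from the attributes of `x` when
#'   omitted.
#' @return Numeric vector of length `D`.
#' @export
decode <- function(x, r, D = NULL, K = NULL) {
  D <- D %||% attr(x, "D")
  K <- K %||% attr(x, "K")
  if (is.null(D) || is.null(K)) {
    stop("D and K must be supplied when x carries no dimension attributes")
  }
  x <- as.numeric(x); r <- as.numeric(r)
  if (length(x) != D * K) {
    stop("length(x) = ", length(x), " does not equal D * K = ", D * K)
  }
  if (length(r) != K) {
    stop("length(r) = ", length(r), " does not equal K = ", K)
  }
  drop(crossprod(matrix(x, nrow = K, ncol = D), r))
}
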