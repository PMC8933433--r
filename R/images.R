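# Image <-> data-vector translation and synthetic image fixtures.
#
# Brightness b in [0, 1] maps linearly to [-sigma, sigma] (pure black to
# -sigma, pure white to +sigma). The storage amplitude sigma keeps the
# encoded memories at a magnitude for which the plasticity dynamics converge;
# retrieved states are much weaker than the originals, so reconstruction uses
# a smaller display threshold sigma_display with clipping to pure black/white.

#' Map a grayscale image to a data vector
#'
#' Applies the affine map `b -> sigma * (2 b - 1)` per pixel and flattens the
#' image row-major (rows vary slowest).
#'
#' @param pixels Numeric `H x W` matrix of brightness values in `[0, 1]`.
#'   Out-of-range values are clipped with a warning.
#' @param sigma Brightness half-range, the amplitude assigned to pure white.
#' @return Numeric vector of length `H * W` with entries in `[-sigma, sigma]`.
#' @export
image_to_vector <- function(pixels, sigma = 0.02) {
  stopifnot(is.matrix(pixels), is.numeric(pixels), sigma > 0)
  if (any(pixels < 0 | pixels > 1)) {
    warning("brightness values outside [0, 1] were clipped", call. = FALSE)
    pixels <- pmin(pmax(pixels, 0), 1)
  }
  sigma * (2 * as.vector(t(pixels)) - 1)
}

#' Reconstruct a grayscale image from a data vector
#'
#' Inverse of [image_to_vector()] with clipping: values at or below
#' `-sigma_display` become pure black, at or above `+sigma_display` pure
#' white, linear in between. Retrieved vectors routinely exceed the display
#' range, which is why clipping (not rejection) is used.
#'
#' @param g Numeric vector of length `H * W`.
#' @param H,W Image dimensions.
#' @param sigma_display Positive display threshold (default 0.002, a tenth of
#'   the storage amplitude, chosen for visibility of the weak retrieved
#'   images).
#' @return `H x W` brightness matrix in `[0, 1]`.
#' @export
vector_to_image <- function(g, H, W, sigma_display = 0.002) {
  stopifnot(sigma_display > 0)
  g <- as.numeric(g)
  if (length(g) != H * W) {
    stop("length(g) = ", length(g), " does not equal H * W = ", H * W)
  }
  b <- (g / sigma_display + 1) / 2
  matrix(pmin(pmax(b, 0), 1), nrow = H, ncol = W, byrow = TRUE)
}

#' Generate a synthetic grayscale test image
#'
#' Deterministic fixtures standing in for photographs of objects on a light
#' background: `"blobs"` draws overlapping dark discs, `"shapes"` dark
#' rectangles and ellipses, both on a light background (object pixels below
#' 0.5, background above 0.5). `"noise"` is i.i.d. uniform brightness and
#' serves as an unrelated, structure-free image (e.g. for irrelevant-cue
#' retrieval).
#'
#' @param seed Integer seed; the same seed always yields the same image.
#' @param H,W Image dimensions (at least 4).
#' @param style One of `"blobs"`, `"shapes"`, `"noise"`.
#' @return `H x W` brightness matrix in `[0, 1]`.
#' @export
synth_image <- function(seed, H = 64, W = 64, style = c("blobs", "shapes", "noise")) {
  style <- match.arg(style)
  stopifnot(H >= 4, W >= 4)
  with_seed(seed, {
    if (style == "noise") {
      return(matrix(stats::runif(H * W), H, W))
    }
    img <- matrix(stats::runif(H * W, 0.85, 1), H, W)
    rows <- matrix(seq_len(H), H, W)
    cols <- matrix(seq_len(W), H, W, byrow = TRUE)
    n_obj <- sample(2:4, 1L)
    for (i in seq_len(n_obj)) {
      cr <- stats::runif(1, 0.2, 0.8) * H
      cc <- stats::runif(1, 0.2, 0.8) * W
      if (style == "blobs") {
        rad <- stats::runif(1, 0.12, 0.3) * min(H, W)
        mask <- (rows - cr)^2 + (cols - cc)^2 < rad^2
      } else {
        hh <- stats::runif(1, 0.1, 0.3) * H
        ww <- stats::runif(1, 0.1, 0.3) * W
        if (stats::runif(1) < 0.5) {
          mask <- abs(rows - cr) < hh & abs(cols - cc) < ww
        } else {
          mask <- ((rows - cr) / hh)^2 + ((cols - cc) / ww)^2 < 1
        }
      }
      img[mask] <- stats::runif(sum(mask), 0, 0.3)
    }
    pmin(pmax(img, 0), 1)
  })
}

#' Occlude a rectangular region of an image
#'
#' Pixels inside the box are set to mid-gray 0.5, which maps to exactly zero
#' in vector space, emulating a partially obstructed memory cue.
#'
#' @param pixels `H x W` brightness matrix.
#' @param box Integer vector `c(row, col, height, width)`: top-left corner and
#'   extent of the occluded region. A zero-area box leaves the image
#'   unchanged.
#' @return The occluded brightness matrix.
#' @export
occlude <- function(pixels, box) {
  stopifnot(is.matrix(pixels), length(box) == 4L)
  box <- as.integer(box)
  r0 <- box[1L]; c0 <- box[2L]; h <- box[3L]; w <- box[4L]
  if (h < 0L || w < 0L) stop("box height/width must be non-negative")
  if (h == 0L || w == 0L) return(pixels)
  if (r0 < 1L || c0 < 1L || r0 + h - 1L > nrow(pixels) ||
      c0 + w - 1L > ncol(pixels)) {
    stop("occlusion box extends outside the image bounds")
  }
  pixels[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- 0.5
  pixels
}

#' Read a grayscale image from a PNG file
#'
#' Multi-channel images are converted to grayscale by averaging the color
#' channels; an alpha channel is ignored.
#'
#' @param path Path to a PNG file.
#' @return `H x W` brightness matrix in `[0, 1]`.
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) return(a)
  nc <- min(dim(a)[3L], 3L)
  apply(a[, , seq_len(nc), drop = FALSE], c(1L, 2L), mean)
}

#' Write a grayscale image to a PNG file
#'
#' @param pixels `H x W` brightness matrix in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(pixels, path) {
  stopifnot(is.matrix(pixels))
  png::writePNG(pmin(pmax(pixels, 0), 1), target = path)
  invisible(path)
}
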