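# Image reconstruction from DC-centered k-space: zero-fill interpolation
# and centered 2D inverse discrete Fourier transform.

# Circular shifts between DC-at-corner and DC-at-center layouts. For even
# dimensions the two are identical; they differ for odd dimensions.
# fftshift2 moves DC from index 1 to 0-based index floor(n/2) on each axis;
# ifftshift2 is its exact inverse.
fftshift2 <- function(x) {
  r <- nrow(x); c <- ncol(x)
  ri <- ((seq_len(r) - 1L - r %/% 2L) %% r) + 1L
  ci <- ((seq_len(c) - 1L - c %/% 2L) %% c) + 1L
  x[ri, ci, drop = FALSE]
}

ifftshift2 <- function(x) {
  r <- nrow(x); c <- ncol(x)
  ri <- ((seq_len(r) - 1L + r %/% 2L) %% r) + 1L
  ci <- ((seq_len(c) - 1L + c %/% 2L) %% c) + 1L
  x[ri, ci, drop = FALSE]
}

#' Zero-fill a k-space matrix to a larger grid
#'
#' Symmetrically pads a DC-centered k-space matrix with zeros so that the
#' subsequent inverse Fourier transform yields an image interpolated onto a
#' finer grid (periodic-sinc interpolation). The field of view is unchanged:
#' zero-filling refines the pixel spacing, it does not extend coverage. The
#' acquired 32 x 32 silicon matrix is zero-filled to 256 x 256 to match the
#' anatomical grid before reconstruction.
#'
#' For an even padding amount the original block sits exactly centered; for
#' an odd amount, `ceiling(extra/2)` zero rows/columns are placed before the
#' block and `floor(extra/2)` after, so outputs are bit-reproducible.
#'
#' @param k A [kspace] object (DC-centered).
#' @param target_rows,target_cols Output dimensions; must be >= the input
#'   dimensions (cropping is refused).
#' @return A [kspace] object of the requested size containing the original
#'   coefficients centered on the grid and zeros elsewhere.
#' @seealso [reconstruct()]
#' @export
zero_fill <- function(k, target_rows, target_cols) {
  stopifnot(inherits(k, "kspace"))
  r <- nrow(k$data); c <- ncol(k$data)
  target_rows <- as.integer(target_rows); target_cols <- as.integer(target_cols)
  if (target_rows < r || target_cols < c)
    stop("target dimensions must be >= input dimensions (no cropping)")
  if (target_rows == r && target_cols == c) return(k)
  out <- matrix(complex(real = 0, imaginary = 0), target_rows, target_cols)
  pre_r <- ceiling((target_rows - r) / 2)
  pre_c <- ceiling((target_cols - c) / 2)
  out[pre_r + seq_len(r), pre_c + seq_len(c)] <- k$data
  kspace(out, nucleus = k$nucleus, fov_mm = k$fov_mm, meta = k$meta)
}

#' Reconstruct a magnitude image from k-space
#'
#' Applies the centered 2D inverse discrete Fourier transform (shift DC to
#' the corner, inverse FFT with 1/(rows*cols) normalization, shift back) and
#' takes the modulus. Phase is discarded: all downstream intensity statistics
#' assume a nonnegative image.
#'
#' @param k A [kspace] object.
#' @return A [magnitude_image] with pixel spacing `fov_mm / dim` and
#'   provenance flag `"reconstructed"`.
#' @examples
#' kdat <- matrix(0+0i, 4, 4); kdat[3, 3] <- 1 + 0i  # DC-centered delta
#' img <- reconstruct(kspace(kdat, "Si29", c(64, 64)))
#' all(abs(img$pixels - 1/16) < 1e-12)  # constant image
#' @export
reconstruct <- function(k) {
  stopifnot(inherits(k, "kspace"))
  z <- stats::fft(ifftshift2(k$data), inverse = TRUE) / length(k$data)
  spacing <- k$fov_mm / dim(k$data)
  magnitude_image(Mod(z), pixel_spacing_mm = spacing,
                  provenance = "reconstructed")
}

#' Scalar reference from a silicon-oil phantom acquisition
#'
#' The phantom is scanned just before particle injection; dividing each
#' study's silicon image by this scalar cancels day-to-day receiver drift.
#' The reference is taken as the maximum pixel magnitude of the phantom
#' image.
#'
#' @param phantom_image A [magnitude_image] of the phantom acquisition.
#' @return A positive scalar in the same receiver units as the image.
#' @export
phantom_reference <- function(phantom_image) {
  stopifnot(inherits(phantom_image, "magnitude_image"))
  m <- max(phantom_image$pixels)
  if (m <= 0) stop("phantom image is all zero; reference must be > 0")
  m
}
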