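#' Raw k-space acquisition matrix
#'
#' Container for one complex k-space acquisition, stored DC-at-center.
#' The silicon channel is nominally acquired as a 32 x 32 matrix and the
#' proton anatomical channel as 256 x 256, both over the same field of view.
#'
#' @param data Complex matrix (rows x cols), receiver units. Stored with the
#'   DC (zero-frequency) coefficient at the center of the grid.
#' @param nucleus One of `"Si29"` or `"H1"`.
#' @param fov_mm Numeric length-2, field of view in mm (row extent, column
#'   extent). Both components must be positive.
#' @param meta Named list of free-form string metadata.
#' @return An object of class `kspace`.
#' @examples
#' k <- kspace(matrix(complex(real = 1:4), 2, 2), "Si29", c(64, 64))
#' dim(k$data)
#' @export
kspace <- function(data, nucleus = c("Si29", "H1"), fov_mm = c(64, 64),
                   meta = list()) {
  nucleus <- match.arg(nucleus)
  if (!is.matrix(data)) data <- as.matrix(data)
  storage.mode(data) <- "complex"
  if (nrow(data) < 2L || ncol(data) < 2L)
    stop("k-space matrix must have both dimensions >= 2")
  if (any(!is.finite(Re(data))) || any(!is.finite(Im(data))))
    stop("k-space contains non-finite entries")
  fov_mm <- as.numeric(fov_mm)
  if (length(fov_mm) == 1L) fov_mm <- rep(fov_mm, 2L)
  if (length(fov_mm) != 2L || any(!is.finite(fov_mm)) || any(fov_mm <= 0))
    stop("fov_mm must be two positive finite numbers")
  structure(list(data = data, nucleus = nucleus, fov_mm = fov_mm,
                 meta = meta),
            class = "kspace")
}

#' @export
print.kspace <- function(x, ...) {
  cat(sprintf("<kspace> %s, %d x %d, FOV %g x %g mm\n", x$nucleus,
              nrow(x$data), ncol(x$data), x$fov_mm[1], x$fov_mm[2]))
  invisible(x)
}

#' Nonnegative magnitude image
#'
#' A reconstructed (or further processed) magnitude image with pixel spacing
#' in mm and a provenance flag set recording which processing steps have been
#' applied. Provenance flags are only ever added, never removed.
#'
#' @param pixels Nonnegative finite numeric matrix.
#' @param pixel_spacing_mm Numeric length-2, in-plane pixel spacing (row, col)
#'   in mm.
#' @param provenance Character vector of processing flags; subset of
#'   `c("reconstructed", "denoised", "phantom_normalized", "set_normalized",
#'   "masked")`.
#' @return An object of class `magnitude_image`.
#' @export
magnitude_image <- function(pixels, pixel_spacing_mm,
                            provenance = character()) {
  if (!is.matrix(pixels)) pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (any(!is.finite(pixels))) stop("image contains non-finite pixels")
  if (any(pixels < 0)) stop("magnitude image pixels must be nonnegative")
  pixel_spacing_mm <- as.numeric(pixel_spacing_mm)
  if (length(pixel_spacing_mm) == 1L)
    pixel_spacing_mm <- rep(pixel_spacing_mm, 2L)
  if (length(pixel_spacing_mm) != 2L || any(pixel_spacing_mm <= 0) ||
      any(!is.finite(pixel_spacing_mm)))
    stop("pixel_spacing_mm must be two positive numbers")
  allowed <- c("reconstructed", "denoised", "phantom_normalized",
               "set_normalized", "masked")
  provenance <- unique(as.character(provenance))
  bad <- setdiff(provenance, allowed)
  if (length(bad)) stop("unknown provenance flag(s): ",
                        paste(bad, collapse = ", "))
  structure(list(pixels = pixels, pixel_spacing_mm = pixel_spacing_mm,
                 provenance = provenance),
            class = "magnitude_image")
}

# add provenance flags while keeping existing ones (never removed)
add_provenance <- function(img, flag) {
  img$provenance <- unique(c(img$provenance, flag))
  img
}

#' @export
print.magnitude_image <- function(x, ...) {
  cat(sprintf("<magnitude_image> %d x %d, %g x %g mm/px, range [%g, %g]\n",
              nrow(x$pixels), ncol(x$pixels),
              x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
              min(x$pixels), max(x$pixels)))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " > "), "\n")
  invisible(x)
}

#' Multi-slice anatomical volume
#'
#' Ordered stack of real 2D slices (e.g. a proton RARE acquisition, nominally
#' 256 x 256 x 22 with 0.25 mm in-plane spacing and 0.75 mm slice thickness).
#'
#' @param slices 3D numeric array (rows x cols x slices) or a matrix for a
#'   single-slice volume.
#' @param pixel_spacing_mm In-plane pixel spacing, mm (length 2 or scalar).
#' @param slice_thickness_mm Positive slice thickness in mm.
#' @return An object of class `anat_volume` with fields `slices`,
#'   `pixel_spacing_mm`, `slice_thickness_mm`, `n_slices`.
#' @export
anat_volume <- function(slices, pixel_spacing_mm, slice_thickness_mm) {
  if (is.matrix(slices)) slices <- array(slices, c(dim(slices), 1L))
  if (!is.array(slices) || length(dim(slices)) != 3L)
    stop("slices must be a 3D array (rows x cols x slices)")
  storage.mode(slices) <- "double"
  slices <- array(as.vector(slices), dim(slices))  # drop foreign attributes
  if (any(!is.finite(slices))) stop("volume contains non-finite values")
  pixel_spacing_mm <- as.numeric(pixel_spacing_mm)
  if (length(pixel_spacing_mm) == 1L)
    pixel_spacing_mm <- rep(pixel_spacing_mm, 2L)
  if (any(pixel_spacing_mm <= 0)) stop("pixel spacing must be positive")
  slice_thickness_mm <- as.numeric(slice_thickness_mm)
  if (length(slice_thickness_mm) != 1L || slice_thickness_mm <= 0)
    stop("slice_thickness_mm must be a positive scalar")
  structure(list(slices = slices, pixel_spacing_mm = pixel_spacing_mm,
                 slice_thickness_mm = slice_thickness_mm,
                 n_slices = dim(slices)[3L]),
            class = "anat_volume")
}

#' @export
print.anat_volume <- function(x, ...) {
  d <- dim(x$slices)
  cat(sprintf("<anat_volume> %d x %d x %d slices, %g x %g mm/px, %g mm thick\n",
              d[1], d[2], d[3], x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
              x$slice_thickness_mm))
  invisible(x)
}
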