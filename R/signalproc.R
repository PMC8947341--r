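# Per-study noise estimation, threshold denoising, quadrangle ROI masking,
# phantom normalization and cross-study peak normalization.

#' Background noise statistics from the four image corners
#'
#' Pools the pixels of four square patches taken from the corners of a
#' magnitude image and returns their sample mean and standard deviation.
#' On the 256 x 256 zero-filled silicon grid the default corner fraction of
#' 1/8 gives the four 32 x 32 corner patches used to establish the per-study
#' background noise level; expressing the patch as a fraction lets other
#' matrix sizes degrade gracefully. Corner statistics are meant to be
#' computed on the reconstructed magnitude image, before masking,
#' thresholding or any normalization.
#'
#' For complex-Gaussian acquisition noise the background magnitude is
#' Rayleigh distributed, with mean `sigma * sqrt(pi/2)`.
#'
#' @param img A [magnitude_image].
#' @param corner_fraction Patch size as a fraction of each image dimension,
#'   in (0, 0.5]. The patch side per axis is `round(fraction * dim)`, at
#'   least 1 pixel.
#' @return An object of class `noise_stats`: list with `mean_bg`, `std_bg`
#'   (sample sd, n-1 denominator, pooled over all four patches) and
#'   `n_pixels`.
#' @export
corner_background <- function(img, corner_fraction = 0.125) {
  stopifnot(inherits(img, "magnitude_image"))
  if (!is.numeric(corner_fraction) || length(corner_fraction) != 1L ||
      corner_fraction <= 0 || corner_fraction > 0.5)
    stop("corner_fraction must be in (0, 0.5]")
  px <- img$pixels
  nr <- nrow(px); nc <- ncol(px)
  pr <- max(1L, as.integer(round(corner_fraction * nr)))
  pc <- max(1L, as.integer(round(corner_fraction * nc)))
  top <- seq_len(pr); bot <- nr - pr + seq_len(pr)
  left <- seq_len(pc); right <- nc - pc + seq_len(pc)
  pool <- c(px[top, left], px[top, right], px[bot, left], px[bot, right])
  structure(list(mean_bg = mean(pool),
                 std_bg = if (length(pool) > 1L) stats::sd(pool) else 0,
                 n_pixels = 4L * pr * pc),
            class = "noise_stats")
}

#' @export
print.noise_stats <- function(x, ...) {
  cat(sprintf("<noise_stats> mean %g, sd %g over %d corner pixels\n",
              x$mean_bg, x$std_bg, x$n_pixels))
  invisible(x)
}

#' Noise-adaptive threshold denoising
#'
#' Zeroes every pixel strictly below `multiplier * mean_bg`; pixels at or
#' above the threshold are kept unchanged. The default multiplier of 5 times
#' the mean corner background was found to eliminate signal outside the
#' subject that cannot be attributed to the particles, while the threshold
#' adapts to each study's own noise level. The comparison is strict so a
#' pixel exactly at the threshold survives.
#'
#' @param img A [magnitude_image].
#' @param noise A `noise_stats` object from [corner_background()].
#' @param multiplier Nonnegative threshold multiplier (default 5).
#' @return The thresholded image, with provenance flag `"denoised"` added.
#' @export
threshold_denoise <- function(img, noise, multiplier = 5) {
  stopifnot(inherits(img, "magnitude_image"), inherits(noise, "noise_stats"))
  if (!is.numeric(multiplier) || length(multiplier) != 1L || multiplier < 0)
    stop("multiplier must be a nonnegative scalar")
  thr <- multiplier * noise$mean_bg
  img$pixels[img$pixels < thr] <- 0
  add_provenance(img, "denoised")
}

#' Quadrangle region of interest
#'
#' A four-vertex polygon in pixel coordinates restricting analysis to the
#' subject's body, excluding e.g. the injection syringe and spilled particles
#' outside the torso. Vertices are ordered; the polygon must be simple
#' (non-self-intersecting) with nonzero area.
#'
#' @param vertices 4 x 2 numeric matrix of (x, y) pixel coordinates, or a
#'   length-8 vector `x1 y1 x2 y2 x3 y3 x4 y4`.
#' @return An object of class `quad_roi`.
#' @export
quad_roi <- function(vertices) {
  if (is.numeric(vertices) && is.null(dim(vertices))) {
    if (length(vertices) != 8L) stop("expected 8 numbers (x1 y1 ... x4 y4)")
    vertices <- matrix(vertices, ncol = 2L, byrow = TRUE)
  }
  vertices <- as.matrix(vertices)
  if (!all(dim(vertices) == c(4L, 2L)))
    stop("a quadrangle ROI needs exactly 4 (x, y) vertices")
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates")
  if (abs(polygon_area(vertices[, 1], vertices[, 2])) <= 0)
    stop("degenerate quadrangle: zero area")
  if (polygon_self_intersects(vertices))
    stop("quadrangle is self-intersecting; vertices must be in boundary order")
  structure(list(vertices = vertices), class = "quad_roi")
}

# signed shoelace area
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

# check non-adjacent edge pairs for proper crossing (quadrilateral: one pair)
polygon_self_intersects <- function(v) {
  seg <- function(i) rbind(v[i, ], v[i %% nrow(v) + 1L, ])
  cross <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
    (b[2] - a[2]) * (c[1] - a[1])
  proper <- function(p1, p2, p3, p4) {
    d1 <- cross(p3, p4, p1); d2 <- cross(p3, p4, p2)
    d3 <- cross(p1, p2, p3); d4 <- cross(p1, p2, p4)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  s1 <- seg(1L); s2 <- seg(2L); s3 <- seg(3L); s4 <- seg(4L)
  proper(s1[1, ], s1[2, ], s3[1, ], s3[2, ]) ||
    proper(s2[1, ], s2[2, ], s4[1, ], s4[2, ])
}

# Even-odd (crossing-number) point-in-polygon test on arbitrary points.
# Points exactly on a boundary segment count as inside. Vectorized over
# points; vx/vy are the polygon vertices in order.
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    # collinear and within the segment's bounding box -> on the boundary
    d <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    on_edge <- on_edge | (abs(d) < 1e-9 &
                            px >= pmin(xi, xj) - 1e-9 &
                            px <= pmax(xi, xj) + 1e-9 &
                            py >= pmin(yi, yj) - 1e-9 &
                            py <= pmax(yi, yj) + 1e-9)
    j <- i
  }
  inside | on_edge
}

# pixel-center coordinate grids in pixel units: centers at (j+0.5, i+0.5)
# for 0-based column j (x) and row i (y)
pixel_center_grid <- function(nr, nc) {
  list(x = matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc),
       y = matrix(rep(seq_len(nr) - 0.5, times = nc), nr, nc))
}

#' Mask an image to a quadrangle region of interest
#'
#' Zeroes every pixel whose center falls outside the polygon. Pixel centers
#' are at (i + 0.5, j + 0.5) in pixel units (0-based indices, row 0 at the
#' top of the displayed image); membership uses an even-odd crossing test
#' with boundary pixels counted as inside.
#'
#' @param img A [magnitude_image].
#' @param roi A [quad_roi()].
#' @return The masked image, provenance flag `"masked"` added.
#' @export
apply_roi_mask <- function(img, roi) {
  stopifnot(inherits(img, "magnitude_image"), inherits(roi, "quad_roi"))
  g <- pixel_center_grid(nrow(img$pixels), ncol(img$pixels))
  keep <- points_in_polygon(as.vector(g$x), as.vector(g$y),
                            roi$vertices[, 1], roi$vertices[, 2])
  img$pixels[!keep] <- 0
  add_provenance(img, "masked")
}

#' Normalize by the silicon-oil phantom reference
#'
#' Divides every pixel by the per-study phantom scalar recorded just before
#' injection, cancelling day-to-day receiver drift: scaling image and
#' reference by a common factor leaves the output unchanged.
#'
#' @param img A [magnitude_image].
#' @param reference Positive scalar, same receiver units as the image.
#' @return The normalized image, provenance flag `"phantom_normalized"`.
#' @export
phantom_normalize <- function(img, reference) {
  stopifnot(inherits(img, "magnitude_image"))
  if (!is.numeric(reference) || length(reference) != 1L ||
      !is.finite(reference) || reference <= 0)
    stop("phantom reference must be a positive finite scalar")
  img$pixels <- img$pixels / reference
  add_provenance(img, "phantom_normalized")
}

#' Normalize a set of studies by the universal peak
#'
#' Finds the single maximum pixel intensity across all images (the
#' "universal peak") and divides every image by it, so the set is displayed
#' and compared on one common scale with global maximum exactly 1. Division
#' by a common constant preserves every between-study intensity ratio.
#'
#' @param images List of [magnitude_image] objects, one per study.
#' @return An object of class `normalized_set`: list with `images` (each
#'   gains provenance `"set_normalized"`), `universal_peak`, and
#'   `per_study_peaks` (each image's pre-division maximum).
#' @export
set_normalize <- function(images) {
  if (!is.list(images) || length(images) < 1L)
    stop("need at least one image")
  if (!all(vapply(images, inherits, logical(1), "magnitude_image")))
    stop("all elements must be magnitude_image objects")
  peaks <- vapply(images, function(im) max(im$pixels), numeric(1))
  universal <- max(peaks)
  if (universal <= 0)
    stop("all images are zero; cannot determine a universal peak")
  out <- lapply(images, function(im) {
    im$pixels <- im$pixels / universal
    add_provenance(im, "set_normalized")
  })
  structure(list(images = out, universal_peak = universal,
                 per_study_peaks = peaks),
            class = "normalized_set")
}

#' @export
print.normalized_set <- function(x, ...) {
  cat(sprintf("<normalized_set> %d studies, universal peak %g\n",
              length(x$images), x$universal_peak))
  invisible(x)
}
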