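# Anatomical slice preparation and composite overlay of the processed
# silicon map on the proton anatomical image. Both acquisitions are taken
# successively without moving the subject, so spatial registration is the
# identity once the silicon k-space has been zero-filled to the anatomical
# grid; no resampling transform is applied.

#' Select one slice from an anatomical volume
#'
#' @param vol An [anat_volume].
#' @param index 0-based slice index in `[0, n_slices)` (matching the
#'   `display_slice` column of the study manifest).
#' @return A [magnitude_image] carrying the volume's in-plane spacing.
#' @export
select_slice <- function(vol, index) {
  stopifnot(inherits(vol, "anat_volume"))
  if (!is.numeric(index) || length(index) != 1L || index != round(index))
    stop("slice index must be a single integer")
  if (index < 0 || index >= vol$n_slices)
    stop(sprintf("slice index %d out of range [0, %d)", index, vol$n_slices))
  sl <- vol$slices[, , index + 1L]
  sl[sl < 0] <- 0
  magnitude_image(sl, pixel_spacing_mm = vol$pixel_spacing_mm)
}

#' Percentile contrast stretch with tail saturation
#'
#' Saturates the top and bottom `tail_percent` of pixel intensities and
#' rescales linearly to `[0, 1]`, the standard display enhancement for the
#' anatomical image. With `n` pixels and `k = ceiling(tail_percent/100 * n)`,
#' the k-th smallest value maps to 0 (everything at or below it clamps to 0)
#' and the k-th largest to 1. `tail_percent = 0` is a pure min-max rescale.
#' A constant image maps to all 0.5.
#'
#' @param img A [magnitude_image].
#' @param tail_percent Percentage saturated in each tail, in `[0, 50)`;
#'   default 1.
#' @return A [magnitude_image] with pixels in `[0, 1]`.
#' @export
contrast_stretch <- function(img, tail_percent = 1) {
  stopifnot(inherits(img, "magnitude_image"))
  if (!is.numeric(tail_percent) || length(tail_percent) != 1L ||
      tail_percent < 0 || tail_percent >= 50)
    stop("tail_percent must be in [0, 50)")
  px <- img$pixels
  n <- length(px)
  k <- ceiling(tail_percent / 100 * n)
  v <- sort(as.vector(px))
  lo <- if (k >= 1L) v[k] else v[1L]
  hi <- if (k >= 1L) v[n + 1L - k] else v[n]
  if (lo == hi) {
    img$pixels[] <- 0.5
    return(img)
  }
  out <- (px - lo) / (hi - lo)
  out[out < 0] <- 0
  out[out > 1] <- 1
  img$pixels <- out
  img
}

# small set of intensity -> RGB colormaps; "hot" is the conventional
# black-red-yellow-white ramp used for functional overlays
colormap_fun <- function(name) {
  switch(name,
    hot = function(v) cbind(pmin(3 * v, 1),
                            pmin(pmax(3 * v - 1, 0), 1),
                            pmin(pmax(3 * v - 2, 0), 1)),
    gray = ,
    grey = function(v) cbind(v, v, v),
    stop("unknown colormap: ", name)
  )
}

#' Composite overlay of silicon signal on the anatomical slice
#'
#' Fuses the processed (set-normalized, `[0, 1]`) silicon map onto the
#' grayscale anatomical slice with intensity-proportional transparency:
#' per pixel, `rgb = (1 - a) * gray(anat) + a * colormap(si)` with
#' `a = alpha_max * si`. Pixels with zero silicon signal show the anatomy
#' unchanged; the blend is a convex combination so every channel stays in
#' `[0, 1]`.
#'
#' @param anat Anatomical [magnitude_image], pixels in `[0, 1]` (use
#'   [contrast_stretch()] first); values outside are clipped.
#' @param si Processed silicon [magnitude_image], same shape as `anat`
#'   (zero-fill to the anatomical grid first), pixels in `[0, 1]`.
#' @param alpha_max Maximum overlay opacity in `[0, 1]`; default 0.7.
#' @param colormap_name Colormap for the silicon channel; default `"hot"`.
#' @param source_ids Optional pair of identifiers (anatomical, silicon)
#'   recorded in the overlay object.
#' @return An object of class `overlay_image`: list with `rgb`
#'   (rows x cols x 3 in `[0,1]`), `alpha_map`, `colormap_name`,
#'   `source_ids`.
#' @export
composite_overlay <- function(anat, si, alpha_max = 0.7,
                              colormap_name = "hot",
                              source_ids = c("anatomical", "silicon")) {
  stopifnot(inherits(anat, "magnitude_image"), inherits(si, "magnitude_image"))
  if (!identical(dim(anat$pixels), dim(si$pixels)))
    stop("shape mismatch between anatomical and silicon images; ",
         "zero-fill the silicon k-space to the anatomical grid first")
  if (!is.numeric(alpha_max) || alpha_max < 0 || alpha_max > 1)
    stop("alpha_max must be in [0, 1]")
  if (max(si$pixels) > 1 + 1e-9)
    stop("silicon image must be normalized to [0, 1] (set_normalize first)")
  g <- pmin(pmax(anat$pixels, 0), 1)
  s <- pmin(si$pixels, 1)
  cmap <- colormap_fun(colormap_name)
  col <- cmap(as.vector(s))
  a <- alpha_max * s
  nr <- nrow(g); nc <- ncol(g)
  rgb <- array(0, c(nr, nc, 3L))
  for (ch in 1:3)
    rgb[, , ch] <- (1 - a) * g + a * matrix(col[, ch], nr, nc)
  structure(list(rgb = rgb, alpha_map = a, colormap_name = colormap_name,
                 source_ids = as.character(source_ids)),
            class = "overlay_image")
}

#' @export
print.overlay_image <- function(x, ...) {
  cat(sprintf("<overlay_image> %d x %d, colormap %s (%s over %s)\n",
              dim(x$rgb)[1], dim(x$rgb)[2], x$colormap_name,
              x$source_ids[2], x$source_ids[1]))
  invisible(x)
}

#' Write an overlay to an 8-bit PNG
#'
#' Channels are quantized as `round(value * 255)` for reproducibility.
#'
#' @param overlay An `overlay_image`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_overlay_png <- function(overlay, path) {
  stopifnot(inherits(overlay, "overlay_image"))
  q <- round(overlay$rgb * 255) / 255
  png::writePNG(q, target = path)
  invisible(path)
}
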