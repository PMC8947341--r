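# SNR / CNR quantification over circular regions of interest and one-way
# analysis of variance across cohorts.
#
# SNR = |mu_t - mu_b| / sigma_b   (tumor ROI vs a region away from tumors)
# CNR = |mu_t - mu_m| / sigma_m   (tumor ROI vs torso excluding tumors)
#
# Both ratios are invariant under positive affine rescaling of the image,
# so the normalization stage cannot change them; statistics are computed on
# the masked, normalized (un-thresholded) silicon image because thresholding
# is a display step that would zero the background entirely.

#' Circular region of interest
#'
#' @param center Length-2 numeric, (x, y) ROI center in pixel coordinates
#'   (pixel centers at half-integers; see [apply_roi_mask()]).
#' @param diameter_mm Positive ROI diameter in mm. The standard tumor ROI is
#'   7 mm in diameter.
#' @return Object of class `circle_roi`.
#' @export
circle_roi <- function(center, diameter_mm = 7) {
  center <- as.numeric(center)
  if (length(center) != 2L || any(!is.finite(center)))
    stop("center must be finite (x, y)")
  if (!is.numeric(diameter_mm) || length(diameter_mm) != 1L ||
      diameter_mm <= 0)
    stop("diameter_mm must be a positive scalar")
  structure(list(center = center, diameter_mm = diameter_mm),
            class = "circle_roi")
}

#' Rasterize a circular ROI to a boolean mask
#'
#' A pixel belongs to the mask when the distance (in mm, via the pixel
#' spacing) from its center to the ROI center is at most `diameter_mm / 2`.
#'
#' @param shape Length-2 integer (rows, cols) of the target image.
#' @param spacing_mm Length-2 pixel spacing (row, col) in mm.
#' @param roi A [circle_roi()]; its center must lie within the image.
#' @return Logical matrix of the given shape; errors if the mask is empty.
#' @export
circle_mask <- function(shape, spacing_mm, roi) {
  stopifnot(inherits(roi, "circle_roi"))
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 2L)
  cx <- roi$center[1]; cy <- roi$center[2]
  if (cx < 0 || cx > nc || cy < 0 || cy > nr)
    stop("ROI center lies outside the image bounds")
  g <- pixel_center_grid(nr, nc)
  # x spans columns (spacing_mm[2]), y spans rows (spacing_mm[1])
  dx <- (g$x - cx) * spacing_mm[2]
  dy <- (g$y - cy) * spacing_mm[1]
  mask <- (dx * dx + dy * dy) <= (roi$diameter_mm / 2)^2
  if (!any(mask)) stop("ROI rasterizes to an empty mask")
  mask
}

mask_union <- function(shape, spacing_mm, rois) {
  m <- matrix(FALSE, shape[1], shape[2])
  for (r in rois) m <- m | circle_mask(shape, spacing_mm, r)
  m
}

as_roi_list <- function(x) if (inherits(x, "circle_roi")) list(x) else x

#' Signal-to-noise ratio over circular ROIs
#'
#' `SNR = |mu_t - mu_b| / sigma_b` where `mu_t` is the mean intensity over
#' the tumor ROI(s) and `mu_b`, `sigma_b` are the mean and sample standard
#' deviation over comparison ROI(s) of the same area placed away from the
#' tumors.
#'
#' @param img A [magnitude_image] (masked, normalized silicon image).
#' @param tumor A [circle_roi] or list of them (union of masks).
#' @param background A [circle_roi] or list of them, non-overlapping with
#'   the tumor ROIs.
#' @return List with `mu_t`, `mu_b`, `sigma_b`, `snr`.
#' @export
roi_snr <- function(img, tumor, background) {
  stopifnot(inherits(img, "magnitude_image"))
  shp <- dim(img$pixels); sp <- img$pixel_spacing_mm
  mt <- mask_union(shp, sp, as_roi_list(tumor))
  mb <- mask_union(shp, sp, as_roi_list(background))
  if (any(mt & mb)) stop("tumor and background ROIs overlap")
  mu_t <- mean(img$pixels[mt])
  mu_b <- mean(img$pixels[mb])
  sigma_b <- stats::sd(img$pixels[mb])
  if (!is.finite(sigma_b) || sigma_b <= 0)
    stop("background ROI has zero variance; SNR is undefined")
  list(mu_t = mu_t, mu_b = mu_b, sigma_b = sigma_b,
       snr = abs(mu_t - mu_b) / sigma_b)
}

#' Contrast-to-noise ratio against the torso
#'
#' `CNR = |mu_t - mu_m| / sigma_m` where `mu_m`, `sigma_m` are the mean and
#' sample standard deviation of the signal in the subject's torso excluding
#' the tumor regions.
#'
#' @param img A [magnitude_image].
#' @param tumor A [circle_roi] or list of them.
#' @param body_mask_minus_tumors Logical matrix, the torso mask with all
#'   tumor ROI pixels already excluded; must not overlap the tumor masks.
#' @return List with `mu_t`, `mu_m`, `sigma_m`, `cnr`.
#' @export
roi_cnr <- function(img, tumor, body_mask_minus_tumors) {
  stopifnot(inherits(img, "magnitude_image"),
            is.logical(body_mask_minus_tumors))
  shp <- dim(img$pixels)
  if (!identical(dim(body_mask_minus_tumors), shp))
    stop("body mask shape does not match the image")
  mt <- mask_union(shp, img$pixel_spacing_mm, as_roi_list(tumor))
  if (any(mt & body_mask_minus_tumors))
    stop("body mask must exclude all tumor ROI pixels")
  mu_t <- mean(img$pixels[mt])
  vals <- img$pixels[body_mask_minus_tumors]
  if (length(vals) < 2L) stop("body mask too small for statistics")
  mu_m <- mean(vals)
  sigma_m <- stats::sd(vals)
  if (!is.finite(sigma_m) || sigma_m <= 0)
    stop("torso region has zero variance; CNR is undefined")
  list(mu_t = mu_t, mu_m = mu_m, sigma_m = sigma_m,
       cnr = abs(mu_t - mu_m) / sigma_m)
}

# rasterize a polygon body outline (n x 2 matrix of x,y pixel coords) to a
# boolean mask over pixel centers
polygon_mask <- function(shape, poly) {
  g <- pixel_center_grid(shape[1], shape[2])
  matrix(points_in_polygon(as.vector(g$x), as.vector(g$y),
                           poly[, 1], poly[, 2]),
         shape[1], shape[2])
}

#' Quantify one study: SNR and CNR
#'
#' Convenience wrapper combining [roi_snr()] and [roi_cnr()] for one study's
#' processed silicon image.
#'
#' @param img Masked, normalized silicon [magnitude_image].
#' @param tumor_rois,nontumor_rois Lists of [circle_roi] (non-tumor ROIs are
#'   the same-diameter circles shifted to non-tumor regions).
#' @param body_poly Optional n x 2 polygon (x, y pixel coords) outlining the
#'   torso; if supplied, CNR is computed over this region minus the tumor
#'   ROIs.
#' @param study_id Identifier copied into the result.
#' @return Object of class `quant_result` with fields `study_id`, `snr`,
#'   `cnr` (NA if no body polygon), `mu_t`, `mu_b`, `sigma_b`, `mu_m`,
#'   `sigma_m`.
#' @export
quantify_study <- function(img, tumor_rois, nontumor_rois, body_poly = NULL,
                           study_id = "") {
  s <- roi_snr(img, tumor_rois, nontumor_rois)
  res <- list(study_id = study_id, snr = s$snr, cnr = NA_real_,
              mu_t = s$mu_t, mu_b = s$mu_b, sigma_b = s$sigma_b,
              mu_m = NA_real_, sigma_m = NA_real_)
  if (!is.null(body_poly)) {
    shp <- dim(img$pixels)
    body <- polygon_mask(shp, body_poly)
    mt <- mask_union(shp, img$pixel_spacing_mm, as_roi_list(tumor_rois))
    cn <- roi_cnr(img, tumor_rois, body & !mt)
    res$cnr <- cn$cnr; res$mu_m <- cn$mu_m; res$sigma_m <- cn$sigma_m
  }
  structure(res, class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("<quant_result> %s: SNR %.3f, CNR %s\n", x$study_id, x$snr,
              if (is.na(x$cnr)) "NA" else sprintf("%.3f", x$cnr)))
  invisible(x)
}

#' One-way analysis of variance across cohorts
#'
#' Computed directly from between- and within-group sums of squares so the
#' statistic is auditable against hand calculation; the p-value uses the F
#' survival function. Used to compare per-study SNR (or CNR) values between
#' the targeted cohort and the control cohorts.
#'
#' @param groups Named (or unnamed) list of numeric vectors, one per cohort;
#'   at least 2 groups, total observations > number of groups.
#' @return Object of class `cohort_comparison`: `group_labels`,
#'   `group_values`, `f_stat`, `p_value`, `df` (between, within).
#' @examples
#' cohort_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(6, 7, 8)))
#' @export
cohort_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups")
  groups <- lapply(groups, as.numeric)
  sizes <- lengths(groups)
  if (any(sizes < 1L)) stop("every group needs at least one value")
  n <- sum(sizes); g <- length(groups)
  if (n <= g) stop("total observations must exceed the number of groups")
  all_vals <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(all_vals))) stop("non-finite values in groups")
  grand <- mean(all_vals)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum(vapply(seq_len(g), function(i)
    sum((groups[[i]] - means[i])^2), numeric(1)))
  df1 <- g - 1L; df2 <- n - g
  if (ssw == 0 && ssb == 0)
    stop("all values identical across groups; F statistic undefined (0/0)")
  f_stat <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("group", seq_len(g))
  structure(list(group_labels = labels, group_values = groups,
                 f_stat = f_stat, p_value = p,
                 df = c(between = df1, within = df2)),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("<cohort_comparison> F(%d, %d) = %.4f, p = %.4g\n",
              x$df[1], x$df[2], x$f_stat, x$p_value))
  invisible(x)
}
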