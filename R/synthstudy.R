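# Synthetic dual-nuclei study generator. Emulates the geometry and artifact
# taxonomy of the in vivo acquisitions -- a torso-shaped anatomical slice
# stack, a sparse silicon signal with tumor foci, a syringe beacon and a
# particle spill outside the body, complex-Gaussian k-space noise (hence
# Rayleigh magnitude background) and optional ADC-clipping -- so that every
# pipeline stage is testable without animal data. All outputs are
# deterministic given the seed.

# run expr with a fixed RNG seed, restoring the caller's RNG state after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Parameters for the synthetic study generator
#'
#' Defaults mirror the nominal acquisition: a 32 x 32 silicon matrix and a
#' 256 x 256 x 22 anatomical volume over a 64 mm x 64 mm field of view.
#' Geometry is given in mm with x running along columns and y along rows,
#' origin at the top-left image corner.
#'
#' The default noise level (`noise_sigma = 1.6` per k-space channel on the
#' 32 x 32 grid, i.e. an image-domain per-channel sigma of 0.05) puts the
#' unit-amplitude tumor foci at 20 times the image noise sigma -- strong but
#' realistic for a hyperpolarized acquisition timed near peak polarization.
#' The syringe beacon is 5x brighter than the brightest tumor, emulating
#' concentrated leftover particles in the syringe tip dominating the raw
#' image.
#'
#' @param seed Integer RNG seed; every generated byte is reproducible.
#' @param torso List with `center_mm` (x, y) and `axes_mm` (semi-axes x, y)
#'   of the body ellipse.
#' @param tumors List of foci, each `list(center_mm = c(x, y), radius_mm,
#'   amplitude)`; rendered as Gaussian blobs with sd = radius/2. Centers
#'   must lie inside the torso.
#' @param syringe_beacon Optional `list(center_mm, radius_mm, amplitude)`
#'   outside the torso (the syringe stays in place during imaging).
#' @param spill Optional `list(center_mm, radius_mm, amplitude)` outside the
#'   torso (particles spilled onto the support gauze).
#' @param noise_sigma Per-channel standard deviation of the complex Gaussian
#'   k-space noise (receiver units on the `si_matrix` grid).
#' @param clip_level Optional positive bound emulating RF overflow: real and
#'   imaginary k-space channels are hard-clipped to +/- this value after
#'   noise. NULL disables clipping.
#' @param texture Amplitude of the smooth intra-body texture of the
#'   anatomical volume; 0 gives a two-level binary phantom.
#' @param si_matrix,anat_matrix Acquisition matrix sizes (default 32, 256).
#' @param n_slices Anatomical slices (default 22).
#' @param slice_thickness_mm Anatomical slice thickness (default 0.75).
#' @param fov_mm Shared field of view, mm (default 64).
#' @return Object of class `synth_params`.
#' @export
synth_params <- function(seed = 1L,
                         torso = list(center_mm = c(32, 34),
                                      axes_mm = c(14, 24)),
                         tumors = list(
                           list(center_mm = c(28, 44), radius_mm = 4,
                                amplitude = 1),
                           list(center_mm = c(37, 40), radius_mm = 3.5,
                                amplitude = 0.8)),
                         syringe_beacon = list(center_mm = c(32, 62),
                                               radius_mm = 3,
                                               amplitude = 3),
                         spill = list(center_mm = c(10, 34), radius_mm = 5,
                                      amplitude = 2),
                         noise_sigma = 1.6,
                         clip_level = NULL,
                         texture = 0.15,
                         si_matrix = 32L, anat_matrix = 256L,
                         n_slices = 22L, slice_thickness_mm = 0.75,
                         fov_mm = 64) {
  inside_torso <- function(c_mm) {
    d <- (c_mm - torso$center_mm) / torso$axes_mm
    sum(d^2) < 1
  }
  for (tu in tumors) {
    if (tu$amplitude < 0) stop("tumor amplitude must be >= 0")
    if (!inside_torso(tu$center_mm))
      stop("tumor center must lie inside the torso ellipse")
  }
  for (art in list(syringe_beacon, spill)) {
    if (is.null(art)) next
    if (art$amplitude < 0) stop("artifact amplitude must be >= 0")
    if (inside_torso(art$center_mm))
      stop("syringe/spill centers must lie outside the torso ellipse")
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (!is.null(clip_level) && clip_level <= 0)
    stop("clip_level must be positive (or NULL)")
  structure(list(seed = as.integer(seed), torso = torso, tumors = tumors,
                 syringe_beacon = syringe_beacon, spill = spill,
                 noise_sigma = noise_sigma, clip_level = clip_level,
                 texture = texture,
                 si_matrix = as.integer(si_matrix),
                 anat_matrix = as.integer(anat_matrix),
                 n_slices = as.integer(n_slices),
                 slice_thickness_mm = slice_thickness_mm,
                 fov_mm = fov_mm),
            class = "synth_params")
}

# render a field of Gaussian blobs sampled at pixel centers of an n x n
# grid over the FOV; blobs is a list of (center_mm, radius_mm, amplitude)
render_blobs <- function(blobs, n, fov_mm) {
  delta <- fov_mm / n
  xc <- (seq_len(n) - 0.5) * delta
  img <- matrix(0, n, n)
  gx <- matrix(rep(xc, each = n), n, n)   # x along columns
  gy <- matrix(rep(xc, times = n), n, n)  # y along rows
  for (b in blobs) {
    if (b$amplitude == 0) next
    s <- b$radius_mm / 2
    d2 <- (gx - b$center_mm[1])^2 + (gy - b$center_mm[2])^2
    img <- img + b$amplitude * exp(-d2 / (2 * s^2))
  }
  img
}

#' Generate a synthetic anatomical volume
#'
#' Renders the torso as a bright ellipse (axes shrinking toward the first
#' and last slices) with a smooth deterministic interior texture built from
#' a few random cosine modes, on a dark background. With `texture = 0` the
#' phantom is binary (two intensity levels).
#'
#' @param p A [synth_params()] object.
#' @return An [anat_volume] of `anat_matrix^2 x n_slices`, spacing
#'   `fov_mm / anat_matrix`.
#' @export
make_anatomical <- function(p) {
  stopifnot(inherits(p, "synth_params"))
  n <- p$anat_matrix; ns <- p$n_slices
  delta <- p$fov_mm / n
  xc <- (seq_len(n) - 0.5) * delta
  gx <- matrix(rep(xc, each = n), n, n)
  gy <- matrix(rep(xc, times = n), n, n)
  vol <- with_seed(p$seed, {
    # smooth texture: fixed low-frequency cosine modes
    modes <- replicate(4, list(fx = stats::runif(1, 0.02, 0.1),
                               fy = stats::runif(1, 0.02, 0.1),
                               ph = stats::runif(1, 0, 2 * pi)),
                       simplify = FALSE)
    tex <- matrix(0, n, n)
    for (m in modes)
      tex <- tex + cos(2 * pi * (m$fx * gx + m$fy * gy) + m$ph)
    tex <- tex / 4
    arr <- array(0, c(n, n, ns))
    half <- (ns - 1) / 2
    for (z in seq_len(ns)) {
      # elliptical cross-section tapering toward the end slices
      sc <- sqrt(pmax(0.25, 1 - ((z - 1 - half) / (half + 1.5))^2))
      ex <- p$torso$axes_mm[1] * sc
      ey <- p$torso$axes_mm[2] * sc
      inside <- ((gx - p$torso$center_mm[1]) / ex)^2 +
        ((gy - p$torso$center_mm[2]) / ey)^2 <= 1
      sl <- matrix(0, n, n)
      sl[inside] <- 0.8 + p$texture * tex[inside]
      arr[, , z] <- pmax(sl, 0)
    }
    arr
  })
  anat_volume(vol, pixel_spacing_mm = c(delta, delta),
              slice_thickness_mm = p$slice_thickness_mm)
}

#' Generate a synthetic silicon k-space acquisition
#'
#' The ground-truth image is the sum of Gaussian blobs (tumor foci, and the
#' optional syringe beacon and spill) sampled on the `si_matrix` grid. Its
#' forward centered DFT gives the noiseless k-space; i.i.d. complex Gaussian
#' noise (`noise_sigma` per channel) is added, which makes the magnitude
#' background Rayleigh distributed -- the correct MR noise model. If
#' `clip_level` is set, real and imaginary channels are then hard-clipped to
#' `+/- clip_level`, emulating RF overflow of the analog-to-digital
#' converter.
#'
#' @param p A [synth_params()].
#' @param tumor_amplitude_scale Multiplier applied to every tumor amplitude
#'   (0 for control cohorts: no particle retention at the lesion, artifacts
#'   and noise retained).
#' @param seed RNG seed for the noise; defaults to `p$seed`.
#' @return List with `kspace` (a [kspace]) and `ground_truth` (a noiseless
#'   [magnitude_image] on the silicon grid).
#' @export
make_silicon_kspace <- function(p, tumor_amplitude_scale = 1,
                                seed = p$seed) {
  stopifnot(inherits(p, "synth_params"))
  blobs <- lapply(p$tumors, function(tu) {
    tu$amplitude <- tu$amplitude * tumor_amplitude_scale
    tu
  })
  if (!is.null(p$syringe_beacon)) blobs <- c(blobs, list(p$syringe_beacon))
  if (!is.null(p$spill)) blobs <- c(blobs, list(p$spill))
  gt <- render_blobs(blobs, p$si_matrix, p$fov_mm)
  kdat <- fftshift2(stats::fft(gt))
  if (p$noise_sigma > 0) {
    nn <- length(kdat)
    noise <- with_seed(seed, complex(real = stats::rnorm(nn, 0, p$noise_sigma),
                                     imaginary = stats::rnorm(nn, 0,
                                                              p$noise_sigma)))
    kdat <- kdat + matrix(noise, nrow(kdat), ncol(kdat))
  }
  if (!is.null(p$clip_level)) {
    cl <- p$clip_level
    kdat <- complex(real = pmin(pmax(Re(kdat), -cl), cl),
                    imaginary = pmin(pmax(Im(kdat), -cl), cl))
    kdat <- matrix(kdat, p$si_matrix, p$si_matrix)
  }
  delta <- p$fov_mm / p$si_matrix
  list(kspace = kspace(kdat, nucleus = "Si29",
                       fov_mm = c(p$fov_mm, p$fov_mm)),
       ground_truth = magnitude_image(gt, pixel_spacing_mm = c(delta, delta)))
}

# ROI geometry for a generated study, in anatomical-grid pixel coordinates
synth_rois <- function(p) {
  px <- p$anat_matrix / p$fov_mm  # pixels per mm
  to_px <- function(mm) mm * px
  tumor_rois <- lapply(p$tumors, function(tu)
    circle_roi(to_px(tu$center_mm), diameter_mm = 7))
  # same-diameter circles reflected through the torso center, kept inside
  nontumor_rois <- lapply(p$tumors, function(tu) {
    shifted <- 2 * p$torso$center_mm - tu$center_mm
    shifted[2] <- shifted[2] - 6  # move further from the foci
    circle_roi(to_px(shifted), diameter_mm = 7)
  })
  bb_lo <- p$torso$center_mm - p$torso$axes_mm - 1
  # the quad hugs the caudal (bottom) torso edge so the syringe track
  # entering from below stays outside the analysis region
  bb_hi <- p$torso$center_mm + p$torso$axes_mm + c(1, 0)
  quad <- quad_roi(rbind(to_px(c(bb_lo[1], bb_lo[2])),
                         to_px(c(bb_hi[1], bb_lo[2])),
                         to_px(c(bb_hi[1], bb_hi[2])),
                         to_px(c(bb_lo[1], bb_hi[2]))))
  th <- seq(0, 2 * pi, length.out = 17L)[-17L]
  body <- cbind(to_px(p$torso$center_mm[1] + p$torso$axes_mm[1] * cos(th)),
                to_px(p$torso$center_mm[2] + p$torso$axes_mm[2] * sin(th)))
  list(tumor_rois = tumor_rois, nontumor_rois = nontumor_rois,
       roi_quad = quad, body_roi = body)
}

#' Generate a complete study set on disk
#'
#' Writes `4 * n_per_cohort` studies -- the targeted cohort with the
#' parameterized tumor amplitudes and the three control cohorts (biological,
#' chemical, pre-blocked) with tumor amplitude 0, noise and artifacts
#' retained -- together with a CSV manifest. Each study gets its own
#' k-space file and anatomical NIfTI volume. A per-study lognormal drift
#' factor scales both the silicon signal and the phantom reference,
#' emulating day-to-day scanner fluctuations that phantom normalization
#' must cancel.
#'
#' @param outdir Target directory (created if needed).
#' @param n_per_cohort Studies per cohort (default 3, i.e. 12 studies).
#' @param p A [synth_params()]; `p$seed` drives everything.
#' @param drift_sdlog Log-sd of the lognormal day-to-day drift (default
#'   0.15).
#' @param phantom_base Drift-free phantom reference level, receiver units
#'   (default 50).
#' @return The manifest as an `si_manifest` (also written to
#'   `<outdir>/manifest.csv`), with attribute `"path"`.
#' @export
make_study_set <- function(outdir, n_per_cohort = 3L, p = synth_params(),
                           drift_sdlog = 0.15, phantom_base = 50) {
  stopifnot(inherits(p, "synth_params"))
  if (n_per_cohort < 1L) stop("n_per_cohort must be >= 1")
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", outdir)
  n_stud <- 4L * n_per_cohort
  rng <- with_seed(p$seed, list(
    study_seeds = sample.int(.Machine$integer.max - 1L, n_stud),
    drift = exp(stats::rnorm(n_stud, 0, drift_sdlog))))
  rois <- synth_rois(p)
  idx <- 0L
  studies <- list()
  for (cohort in COHORTS) {
    amp <- if (cohort == "targeted") 1 else 0
    for (rep_i in seq_len(n_per_cohort)) {
      idx <- idx + 1L
      id <- sprintf("%s_%02d", cohort, rep_i)
      sk <- make_silicon_kspace(p, tumor_amplitude_scale = amp,
                                seed = rng$study_seeds[idx])
      # receiver drift scales the acquired signal and the phantom alike
      k <- sk$kspace
      k$data <- k$data * rng$drift[idx]
      si_path <- file.path(outdir, paste0(id, "_si.kspace"))
      write_kspace(k, si_path)
      pa <- p
      pa$seed <- rng$study_seeds[idx]
      anat_path <- file.path(outdir, paste0(id, "_anat.nii"))
      write_anatomical(make_anatomical(pa), anat_path)
      studies[[idx]] <- structure(list(
        study_id = id, cohort = cohort,
        silicon_path = si_path, anatomical_path = anat_path,
        phantom_reference = phantom_base * rng$drift[idx],
        display_slice = as.integer((p$n_slices - 1L) %/% 2L),
        roi_quad = rois$roi_quad,
        tumor_rois = rois$tumor_rois,
        nontumor_rois = rois$nontumor_rois,
        body_roi = rois$body_roi), class = "study_record")
    }
  }
  manifest <- structure(list(studies = studies,
                             defaults = default_parameters()),
                        class = "si_manifest")
  mpath <- file.path(outdir, "manifest.csv")
  write_manifest(manifest, mpath, relative_to = outdir)
  attr(manifest, "path") <- mpath
  manifest
}
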