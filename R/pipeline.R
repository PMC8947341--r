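# Batch driver: manifest -> per-study processing -> cross-study
# normalization -> overlays -> quantification, with a reproducible run
# record. A thin command-line wrapper over these functions is installed at
# inst/cli/hpsimri.R.
#
# Per-study order: read -> reconstruct + zero-fill to the anatomical grid ->
# corner noise statistics (on the un-masked reconstruction) -> quadrangle
# mask -> threshold -> phantom normalization; then set normalization across
# all studies; then contrast stretch / overlay / quantification.
# Quantification uses the masked, phantom- and set-normalized image WITHOUT
# the display threshold: background intensity is established per study
# before the image is altered for display, and thresholding would zero the
# background ROI entirely.

#' Batch run configuration
#'
#' Defaults reproduce the standard processing parameters: threshold at 5x
#' the mean corner background, corner patches of 1/8 of each dimension
#' (32 x 32 on the 256 grid), 1% tail saturation for anatomical display,
#' and overlay opacity 0.7.
#'
#' @param manifest_path Path to the study manifest (CSV or XLSX).
#' @param outdir Output directory.
#' @param threshold_multiplier,corner_fraction,tail_percent,alpha_max
#'   Processing parameters; `NULL` means take the manifest defaults (which
#'   are the values above unless overridden by a parameters sheet).
#' @param seed Optional integer seed (used by the simulate subcommand).
#' @param log_level `"info"` or `"quiet"`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(manifest_path = NULL, outdir = NULL,
                       threshold_multiplier = NULL, corner_fraction = NULL,
                       tail_percent = NULL, alpha_max = 0.7,
                       seed = NULL, log_level = c("info", "quiet")) {
  structure(list(manifest_path = manifest_path, outdir = outdir,
                 threshold_multiplier = threshold_multiplier,
                 corner_fraction = corner_fraction,
                 tail_percent = tail_percent, alpha_max = alpha_max,
                 seed = seed, log_level = match.arg(log_level)),
            class = "run_config")
}

log_msg <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet"))
    message("[hpsimri] ", sprintf(...))
}

#' Process a complete study set
#'
#' Runs the full comparative pipeline over every study in the manifest and
#' writes, per study, the processed silicon NIfTI, the composite overlay
#' PNG and the quantification (JSON + CSV); plus one cohort ANOVA and a run
#' record JSON holding all parameters, the per-study peaks and the
#' universal peak -- enough to re-execute the run bit-identically. Any study
#' failing validation aborts the whole run (cross-study normalization
#' depends on every study's peak), with the study id in the error message.
#'
#' @param cfg A [run_config()] with at least `manifest_path` and `outdir`.
#' @return Invisibly, a list with `studies` (per-study results), `noise`
#'   (per-study `noise_stats`), `normalized` (the `normalized_set`),
#'   `quant` (list of `quant_result`), `anova_snr`, `anova_cnr`
#'   (`cohort_comparison` or NULL), `run_record`, `files`.
#' @export
run_process <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$manifest_path) || is.null(cfg$outdir))
    stop("run_process needs manifest_path and outdir")
  manifest <- read_manifest(cfg$manifest_path)
  par <- manifest$defaults
  if (!is.null(cfg$threshold_multiplier))
    par$threshold_multiplier <- cfg$threshold_multiplier
  if (!is.null(cfg$corner_fraction))
    par$corner_fraction <- cfg$corner_fraction
  if (!is.null(cfg$tail_percent)) par$tail_percent <- cfg$tail_percent
  alpha_max <- if (is.null(cfg$alpha_max)) 0.7 else cfg$alpha_max
  n <- length(manifest$studies)
  log_msg(cfg, "processing %d studies from %s", n, cfg$manifest_path)

  display <- vector("list", n)   # mask -> threshold -> phantom-normalized
  quant_img <- vector("list", n) # mask -> phantom-normalized (no threshold)
  noise <- vector("list", n)
  anat_slices <- vector("list", n)
  for (i in seq_len(n)) {
    st <- manifest$studies[[i]]
    res <- tryCatch({
      k <- read_kspace(st$silicon_path)
      vol <- read_anatomical(st$anatomical_path)
      target <- dim(vol$slices)[1:2]
      rec <- reconstruct(zero_fill(k, target[1], target[2]))
      ns <- corner_background(rec, par$corner_fraction)
      masked <- if (!is.null(st$roi_quad))
        apply_roi_mask(rec, st$roi_quad) else rec
      disp <- threshold_denoise(masked, ns, par$threshold_multiplier)
      disp <- phantom_normalize(disp, st$phantom_reference)
      qimg <- phantom_normalize(masked, st$phantom_reference)
      sl <- select_slice(vol, st$display_slice)
      list(disp = disp, qimg = qimg, ns = ns, slice = sl)
    }, error = function(e)
      stop("study ", st$study_id, ": ", conditionMessage(e), call. = FALSE))
    display[[i]] <- res$disp
    quant_img[[i]] <- res$qimg
    noise[[i]] <- res$ns
    anat_slices[[i]] <- res$slice
    log_msg(cfg, "  %s: background mean %.4g, peak %.4g", st$study_id,
            res$ns$mean_bg, max(res$disp$pixels))
  }

  normalized <- set_normalize(display)
  log_msg(cfg, "universal peak: %.6g", normalized$universal_peak)
  # quantification images share the same common divisor (scale-invariant
  # statistics; kept on the displayed scale for interpretability)
  quant_img <- lapply(quant_img, function(im) {
    im$pixels <- im$pixels / normalized$universal_peak
    add_provenance(im, "set_normalized")
  })

  files <- character()
  quants <- vector("list", n)
  for (i in seq_len(n)) {
    st <- manifest$studies[[i]]
    stretched <- contrast_stretch(anat_slices[[i]], par$tail_percent)
    ov <- composite_overlay(stretched, normalized$images[[i]],
                            alpha_max = alpha_max,
                            source_ids = c(paste0(st$study_id, "_anat"),
                                           paste0(st$study_id, "_si")))
    q <- NULL
    if (length(st$tumor_rois) && length(st$nontumor_rois)) {
      q <- tryCatch(
        quantify_study(quant_img[[i]], st$tumor_rois, st$nontumor_rois,
                       body_poly = st$body_roi, study_id = st$study_id),
        error = function(e)
          stop("study ", st$study_id, ": ", conditionMessage(e),
               call. = FALSE))
    }
    quants[[i]] <- q
    files <- c(files,
               write_outputs(st, normalized$images[[i]], ov, q, cfg$outdir))
    # un-thresholded normalized image, the input to ROI statistics; lets
    # run_quantify() re-run statistics without redoing image processing
    qp <- file.path(cfg$outdir, paste0(st$study_id, "_silicon_quant.nii"))
    write_nifti_image(quant_img[[i]], qp)
    files <- c(files, qp)
  }

  cohorts <- vapply(manifest$studies, `[[`, character(1), "cohort")
  snr_groups <- split(vapply(quants, function(q)
    if (is.null(q)) NA_real_ else q$snr, numeric(1)), cohorts)
  snr_groups <- lapply(snr_groups, function(v) v[!is.na(v)])
  snr_groups <- snr_groups[lengths(snr_groups) > 0L]
  anova_snr <- NULL
  anova_cnr <- NULL
  if (length(snr_groups) >= 2L &&
      sum(lengths(snr_groups)) > length(snr_groups)) {
    anova_snr <- cohort_anova(snr_groups)
    cnr_groups <- split(vapply(quants, function(q)
      if (is.null(q)) NA_real_ else q$cnr, numeric(1)), cohorts)
    cnr_groups <- lapply(cnr_groups, function(v) v[!is.na(v)])
    cnr_groups <- cnr_groups[lengths(cnr_groups) > 0L]
    if (length(cnr_groups) >= 2L &&
        sum(lengths(cnr_groups)) > length(cnr_groups))
      anova_cnr <- cohort_anova(cnr_groups)
    anova_out <- list(
      snr = list(groups = anova_snr$group_values,
                 f_stat = anova_snr$f_stat, p_value = anova_snr$p_value,
                 df = unname(anova_snr$df)),
      cnr = if (!is.null(anova_cnr))
        list(groups = anova_cnr$group_values, f_stat = anova_cnr$f_stat,
             p_value = anova_cnr$p_value, df = unname(anova_cnr$df)))
    p <- file.path(cfg$outdir, "cohort_comparison.json")
    jsonlite::write_json(anova_out, p, auto_unbox = TRUE, digits = NA,
                         na = "null")
    files <- c(files, p)
    log_msg(cfg, "cohort ANOVA on SNR: F = %.3f, p = %.4g",
            anova_snr$f_stat, anova_snr$p_value)
  }

  run_record <- list(
    manifest_path = normalizePath(cfg$manifest_path),
    parameters = c(par, list(alpha_max = alpha_max)),
    study_ids = vapply(manifest$studies, `[[`, character(1), "study_id"),
    cohorts = cohorts,
    per_study_peaks = normalized$per_study_peaks,
    universal_peak = normalized$universal_peak,
    noise_mean_bg = vapply(noise, `[[`, numeric(1), "mean_bg"),
    package_version = as.character(utils::packageVersion("hpsimri")))
  rp <- file.path(cfg$outdir, "run_record.json")
  jsonlite::write_json(run_record, rp, auto_unbox = TRUE, digits = NA)
  files <- c(files, rp)

  invisible(list(studies = manifest$studies, noise = noise,
                 normalized = normalized, quant = quants,
                 quant_images = quant_img,
                 anova_snr = anova_snr, anova_cnr = anova_cnr,
                 run_record = run_record, files = files))
}

#' Generate a synthetic study set (simulate subcommand)
#'
#' Thin wrapper over [make_study_set()].
#'
#' @param outdir Target directory.
#' @param n_per_cohort Studies per cohort (default 3).
#' @param seed Integer seed.
#' @param p Optional [synth_params()]; `seed` overrides its seed when given.
#' @param log_level `"info"` or `"quiet"`.
#' @return The manifest (invisibly), with its path in attribute `"path"`.
#' @export
run_simulate <- function(outdir, n_per_cohort = 3L, seed = 1L,
                         p = NULL, log_level = "info") {
  if (is.null(p)) p <- synth_params(seed = seed)
  else if (!is.null(seed)) p$seed <- as.integer(seed)
  manifest <- make_study_set(outdir, n_per_cohort = n_per_cohort, p = p)
  if (!identical(log_level, "quiet"))
    message("[hpsimri] wrote ", length(manifest$studies),
            " studies; manifest: ", attr(manifest, "path"))
  invisible(manifest)
}

#' Re-run quantification over an existing run directory
#'
#' Reads the run record and the processed silicon images already in
#' `rundir`, recomputes the ROI statistics and cohort ANOVA, and rewrites
#' the quantification outputs. The image-processing stages are not re-run.
#'
#' @param rundir Directory produced by [run_process()].
#' @return Invisibly, list with `quant` and `anova_snr`.
#' @export
run_quantify <- function(rundir) {
  rp <- file.path(rundir, "run_record.json")
  if (!file.exists(rp)) stop("no run_record.json in ", rundir)
  rec <- jsonlite::fromJSON(rp, simplifyVector = TRUE)
  manifest <- read_manifest(rec$manifest_path)
  quants <- list()
  for (st in manifest$studies) {
    if (!(length(st$tumor_rois) && length(st$nontumor_rois))) next
    path <- file.path(rundir, paste0(st$study_id, "_silicon_quant.nii"))
    if (!file.exists(path))
      path <- file.path(rundir, paste0(st$study_id, "_silicon.nii"))
    if (!file.exists(path)) stop("missing processed image: ", path)
    vol <- read_anatomical(path)
    img <- select_slice(vol, 0L)
    q <- quantify_study(img, st$tumor_rois, st$nontumor_rois,
                        body_poly = st$body_roi, study_id = st$study_id)
    write_outputs(st, img, NULL, q, rundir)
    quants[[st$study_id]] <- q
  }
  cohorts <- vapply(manifest$studies, `[[`, character(1), "cohort")
  ids <- vapply(manifest$studies, `[[`, character(1), "study_id")
  vals <- vapply(ids, function(id)
    if (is.null(quants[[id]])) NA_real_ else quants[[id]]$snr, numeric(1))
  groups <- split(vals, cohorts)
  groups <- lapply(groups, function(v) v[!is.na(v)])
  groups <- groups[lengths(groups) > 0L]
  a <- if (length(groups) >= 2L && sum(lengths(groups)) > length(groups))
    cohort_anova(groups) else NULL
  invisible(list(quant = quants, anova_snr = a))
}
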