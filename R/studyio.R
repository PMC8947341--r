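# On-disk formats: the raw silicon k-space dialect, anatomical NIfTI
# volumes, the study manifest (CSV or XLSX) and processed outputs.
#
# K-space dialect: a single-line JSON text header terminated by "\n",
# followed by the payload as little-endian float32, real/imaginary
# interleaved, row-major. Header fields: dims [rows, cols], nucleus,
# fov_mm [r, c], endianness "little", optional meta map. This documented
# layout stands in for the scanner vendor's proprietary on-disk format,
# which is out of scope.

COHORTS <- c("targeted", "biological_control", "chemical_control",
             "preblocked")

#' Read a raw k-space file
#'
#' @param path Path to a k-space file in the package dialect (JSON header
#'   line + interleaved float32 payload).
#' @return A [kspace] object of the shape declared in the header.
#' @seealso [write_kspace()]
#' @export
read_kspace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  # read header bytes up to the first newline
  header_raw <- raw()
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0L) stop("malformed k-space file: no header line found")
    if (b == as.raw(10L)) break
    header_raw <- c(header_raw, b)
    if (length(header_raw) > 65536L)
      stop("malformed k-space file: header exceeds 64 KiB")
  }
  hdr <- tryCatch(jsonlite::fromJSON(rawToChar(header_raw)),
                  error = function(e)
                    stop("malformed k-space header: not valid JSON (",
                         conditionMessage(e), ")"))
  for (field in c("dims", "nucleus", "fov_mm", "endianness"))
    if (is.null(hdr[[field]]))
      stop("malformed k-space header: missing field '", field, "'")
  dims <- as.integer(hdr$dims)
  if (length(dims) != 2L || any(is.na(dims)) || any(dims < 2L))
    stop("malformed k-space header: field 'dims' must be two integers >= 2")
  if (!identical(hdr$endianness, "little"))
    stop("malformed k-space header: field 'endianness' must be \"little\"")
  if (!hdr$nucleus %in% c("Si29", "H1"))
    stop("malformed k-space header: field 'nucleus' must be Si29 or H1")
  n_expect <- 2L * dims[1L] * dims[2L]
  payload <- readBin(con, "numeric", n = n_expect + 1L, size = 4L,
                     endian = "little")
  if (length(payload) != n_expect)
    stop(sprintf(paste0("k-space payload truncated or oversized: header ",
                        "declares %d x %d (%d float32 values), found %s"),
                 dims[1L], dims[2L], n_expect,
                 if (length(payload) > n_expect) "more" else
                   as.character(length(payload))))
  re <- payload[seq(1L, n_expect, by = 2L)]
  im <- payload[seq(2L, n_expect, by = 2L)]
  mat <- matrix(complex(real = re, imaginary = im),
                nrow = dims[1L], ncol = dims[2L], byrow = TRUE)
  meta <- if (!is.null(hdr$meta)) lapply(hdr$meta, as.character) else list()
  kspace(mat, nucleus = hdr$nucleus, fov_mm = as.numeric(hdr$fov_mm),
         meta = meta)
}

#' Write a k-space object in the package dialect
#'
#' The header is written in a canonical form so that writing a k-space
#' object read from disk reproduces the original file byte for byte.
#' The payload is float32, so values are stored at single precision.
#'
#' @param k A [kspace] object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_kspace <- function(k, path) {
  stopifnot(inherits(k, "kspace"))
  hdr <- list(dims = dim(k$data), nucleus = k$nucleus,
              fov_mm = k$fov_mm, endianness = "little")
  if (length(k$meta)) hdr$meta <- k$meta
  header <- jsonlite::toJSON(hdr, auto_unbox = FALSE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(as.character(header)), con)
  writeBin(charToRaw("\n"), con)
  # row-major interleaved: transpose so R's column-major vector walks rows
  v <- as.vector(t(k$data))
  inter <- as.vector(rbind(Re(v), Im(v)))
  writeBin(inter, con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an anatomical NIfTI volume
#'
#' @param path NIfTI file (.nii or .nii.gz). A 2D file is accepted as a
#'   single-slice volume.
#' @return An [anat_volume]; slices ordered along the third axis, pixel
#'   spacing and slice thickness taken from the file's voxel dimensions.
#' @export
read_anatomical <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    stop("not a readable NIfTI file: ", path, " (",
                         conditionMessage(e), ")"))
  arr <- as.array(img)
  pd <- RNifti::pixdim(img)
  if (length(dim(arr)) == 2L) {
    arr <- array(arr, c(dim(arr), 1L))
    pd <- c(pd[1:2], 1)
  }
  if (length(dim(arr)) != 3L)
    stop("expected a 2D or 3D NIfTI volume, got ", length(dim(arr)), "D")
  anat_volume(arr, pixel_spacing_mm = pd[1:2], slice_thickness_mm = pd[3])
}

#' Write an anatomical volume as NIfTI
#'
#' @param vol An [anat_volume].
#' @param path Output path (.nii recommended; values stored as float32).
#' @return The path, invisibly.
#' @export
write_anatomical <- function(vol, path) {
  stopifnot(inherits(vol, "anat_volume"))
  arr <- vol$slices
  attr(arr, "pixdim") <- c(vol$pixel_spacing_mm, vol$slice_thickness_mm)
  img <- RNifti::asNifti(arr, datatype = "float", internal = FALSE)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

# write a 2D magnitude image as a single-slice NIfTI (float32)
write_nifti_image <- function(img, path) {
  stopifnot(inherits(img, "magnitude_image"))
  arr <- array(img$pixels, c(dim(img$pixels), 1L))
  attr(arr, "pixdim") <- c(img$pixel_spacing_mm, 1)
  nim <- RNifti::asNifti(arr, datatype = "float", internal = FALSE)
  RNifti::writeNifti(nim, path, datatype = "float")
  invisible(path)
}

parse_circle_rois <- function(s) {
  if (is.null(s) || is.na(s) || !nzchar(trimws(s))) return(list())
  parts <- strsplit(trimws(s), ";", fixed = TRUE)[[1]]
  lapply(parts, function(p) {
    v <- as.numeric(strsplit(trimws(p), "\\s+")[[1]])
    if (length(v) != 3L || any(is.na(v)))
      stop("bad circle ROI entry '", p, "': expected 'cx cy diameter_mm'")
    circle_roi(v[1:2], v[3])
  })
}

parse_polygon <- function(s) {
  if (is.null(s) || is.na(s) || !nzchar(trimws(s))) return(NULL)
  v <- as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  if (length(v) < 6L || length(v) %% 2L != 0L || any(is.na(v)))
    stop("bad polygon: expected an even list of >= 6 coordinates")
  matrix(v, ncol = 2L, byrow = TRUE)
}

format_circle_rois <- function(rois) {
  if (!length(rois)) return("")
  paste(vapply(rois, function(r)
    sprintf("%g %g %g", r$center[1], r$center[2], r$diameter_mm),
    character(1)), collapse = "; ")
}

format_polygon <- function(poly) {
  if (is.null(poly)) return("")
  paste(sprintf("%g", as.vector(t(poly))), collapse = " ")
}

MANIFEST_COLUMNS <- c("study_id", "cohort", "silicon_path",
                      "anatomical_path", "phantom_reference",
                      "display_slice")

default_parameters <- function() {
  list(threshold_multiplier = 5, tail_percent = 1, corner_fraction = 0.125)
}

#' Read a study manifest (CSV or XLSX)
#'
#' The manifest lists one imaging session per row. Required columns:
#' `study_id`, `cohort` (one of targeted, biological_control,
#' chemical_control, preblocked), `silicon_path`, `anatomical_path`,
#' `phantom_reference` (positive scalar), `display_slice` (0-based).
#' Optional columns: `roi_quad` ("x1 y1 ... x4 y4"), `tumor_rois` and
#' `nontumor_rois` ("cx cy diameter_mm; ..."), `body_roi` (polygon
#' "x1 y1 x2 y2 ..."). Relative file paths are resolved against the
#' manifest's directory.
#'
#' Processing parameters (threshold multiplier 5, tail saturation 1%,
#' corner fraction 1/8) come from built-in defaults, overridden by an XLSX
#' `parameters` sheet or a `name,value` CSV passed as `parameters_path`.
#'
#' @param path Manifest file (.csv, .xlsx or .xls).
#' @param parameters_path Optional CSV with columns `name`, `value`.
#' @return Object of class `si_manifest`: list with `studies` (list of
#'   `study_record`) and `defaults`.
#' @export
read_manifest <- function(path, parameters_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  params_df <- NULL
  if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  } else if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLSX manifests requires the 'readxl' package")
    df <- as.data.frame(readxl::read_excel(path, sheet = 1L,
                                           col_types = "text"))
    sheets <- readxl::excel_sheets(path)
    if ("parameters" %in% sheets)
      params_df <- as.data.frame(readxl::read_excel(path,
                                                    sheet = "parameters",
                                                    col_types = "text"))
  } else stop("unsupported manifest format: .", ext, " (use CSV or XLSX)")
  if (!is.null(parameters_path)) {
    params_df <- utils::read.csv(parameters_path, stringsAsFactors = FALSE,
                                 colClasses = "character")
  }
  missing_cols <- setdiff(MANIFEST_COLUMNS, names(df))
  if (length(missing_cols))
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L)
    stop("manifest contains no studies; at least one is required")
  if (anyDuplicated(df$study_id))
    stop("duplicate study_id in manifest: ",
         paste(unique(df$study_id[duplicated(df$study_id)]), collapse = ", "))
  bad_cohort <- setdiff(unique(df$cohort), COHORTS)
  if (length(bad_cohort))
    stop("unknown cohort value(s): ", paste(bad_cohort, collapse = ", "),
         "; allowed: ", paste(COHORTS, collapse = ", "))
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  }
  get_opt <- function(row, col) if (col %in% names(df)) df[row, col] else NA
  studies <- lapply(seq_len(nrow(df)), function(i) {
    pr <- as.numeric(df$phantom_reference[i])
    if (is.na(pr) || pr <= 0)
      stop("study ", df$study_id[i],
           ": phantom_reference must be a positive number")
    ds <- as.integer(df$display_slice[i])
    if (is.na(ds) || ds < 0)
      stop("study ", df$study_id[i],
           ": display_slice must be a nonnegative integer")
    rq <- get_opt(i, "roi_quad")
    quad <- if (!is.na(rq) && nzchar(trimws(rq)))
      quad_roi(as.numeric(strsplit(trimws(rq), "\\s+")[[1]])) else NULL
    structure(list(
      study_id = df$study_id[i],
      cohort = df$cohort[i],
      silicon_path = resolve(df$silicon_path[i]),
      anatomical_path = resolve(df$anatomical_path[i]),
      phantom_reference = pr,
      display_slice = ds,
      roi_quad = quad,
      tumor_rois = parse_circle_rois(get_opt(i, "tumor_rois")),
      nontumor_rois = parse_circle_rois(get_opt(i, "nontumor_rois")),
      body_roi = parse_polygon(get_opt(i, "body_roi"))
    ), class = "study_record")
  })
  defaults <- default_parameters()
  if (!is.null(params_df)) {
    if (!all(c("name", "value") %in% names(params_df)))
      stop("parameters sheet/file must have columns 'name' and 'value'")
    for (i in seq_len(nrow(params_df))) {
      nm <- params_df$name[i]
      if (!nm %in% names(defaults))
        stop("unknown parameter '", nm, "'; known: ",
             paste(names(defaults), collapse = ", "))
      defaults[[nm]] <- as.numeric(params_df$value[i])
    }
  }
  structure(list(studies = studies, defaults = defaults),
            class = "si_manifest")
}

#' @export
print.si_manifest <- function(x, ...) {
  cohorts <- vapply(x$studies, `[[`, character(1), "cohort")
  cat(sprintf("<si_manifest> %d studies (%s)\n", length(x$studies),
              paste(sprintf("%s: %d", names(table(cohorts)), table(cohorts)),
                    collapse = ", ")))
  invisible(x)
}

#' Write a study manifest as CSV
#'
#' @param manifest An `si_manifest`.
#' @param path Output CSV path.
#' @param relative_to Optional directory; file paths inside it are written
#'   relative to it.
#' @return The path, invisibly.
#' @export
write_manifest <- function(manifest, path, relative_to = NULL) {
  stopifnot(inherits(manifest, "si_manifest"))
  relativize <- function(p) {
    if (is.null(relative_to)) return(p)
    base <- paste0(normalizePath(relative_to, mustWork = FALSE), "/")
    np <- normalizePath(p, mustWork = FALSE)
    if (startsWith(np, base)) substring(np, nchar(base) + 1L) else p
  }
  rows <- lapply(manifest$studies, function(s) {
    data.frame(
      study_id = s$study_id, cohort = s$cohort,
      silicon_path = relativize(s$silicon_path),
      anatomical_path = relativize(s$anatomical_path),
      phantom_reference = s$phantom_reference,
      display_slice = s$display_slice,
      roi_quad = if (is.null(s$roi_quad)) "" else
        paste(sprintf("%g", as.vector(t(s$roi_quad$vertices))),
              collapse = " "),
      tumor_rois = format_circle_rois(s$tumor_rois),
      nontumor_rois = format_circle_rois(s$nontumor_rois),
      body_roi = format_polygon(s$body_roi),
      stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write the per-study processed outputs
#'
#' Writes the processed silicon image as NIfTI, the composite overlay as
#' PNG, and the quantification as JSON and CSV. Filenames are deterministic
#' functions of the study id: `<id>_silicon.nii`, `<id>_overlay.png`,
#' `<id>_quant.json`, `<id>_quant.csv`.
#'
#' @param study A `study_record`.
#' @param processed Processed silicon [magnitude_image].
#' @param overlay An `overlay_image` (or NULL to skip).
#' @param quant A `quant_result` (or NULL to skip).
#' @param outdir Output directory (created if absent).
#' @return Character vector of the files written.
#' @export
write_outputs <- function(study, processed, overlay, quant, outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  if (file.access(outdir, 2L) != 0L)
    stop("output directory is not writable: ", outdir)
  id <- study$study_id
  files <- character()
  p <- file.path(outdir, paste0(id, "_silicon.nii"))
  write_nifti_image(processed, p)
  files <- c(files, p)
  if (!is.null(overlay)) {
    p <- file.path(outdir, paste0(id, "_overlay.png"))
    write_overlay_png(overlay, p)
    files <- c(files, p)
  }
  if (!is.null(quant)) {
    qlist <- unclass(quant)
    p <- file.path(outdir, paste0(id, "_quant.json"))
    jsonlite::write_json(qlist, p, auto_unbox = TRUE, digits = NA,
                         na = "null")
    files <- c(files, p)
    p <- file.path(outdir, paste0(id, "_quant.csv"))
    utils::write.csv(as.data.frame(qlist), p, row.names = FALSE)
    files <- c(files, p)
  }
  files
}
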